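#' Fit a power law y = a x^b by log-log least squares
#'
#' Ordinary least squares of `log(y)` on `log(x)`; `b` is the slope with
#' its OLS standard error, `a = exp(intercept)`, and `r2` the coefficient
#' of determination on the log-log scale.
#'
#' @param x Strictly positive predictor (e.g. emitted positrons).
#' @param y Strictly positive response (e.g. homogeneity index).
#' @return A list of class `power_law_fit`: `a`, `b`, `u_b`, `r2`.
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points to fit a power law")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit requires strictly positive data")
  fit <- lm(log(y) ~ log(x))
  sm <- summary(fit)
  structure(
    list(a = exp(unname(coef(fit)[1])),
         b = unname(coef(fit)[2]),
         u_b = unname(sm$coefficients[2, "Std. Error"]),
         r2 = sm$r.squared),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^(%.3f +/- %.3f), r^2 = %.3f\n",
              x$a, x$b, x$u_b, x$r2))
  invisible(x)
}

#' Simulation study: homogeneity index versus emitted positrons
#'
#' Simulates a uniformly filled cylinder at each activity level, computes
#' the homogeneity index over an interior VOI (kept more than three PSF
#' widths from the cylinder wall so spill effects cancel) together with
#' the number of positrons emitted from that VOI during the scan, pools
#' the replicates, and fits the power law `HI = a N^b`. For
#' Poisson-limited counting noise the expected exponent is -0.5.
#'
#' @param levels Activity concentrations, Bq/mL (>= 4 values spanning at
#'   least 1.5 decades of expected positron counts).
#' @param acq A [pet_acq_params()] template; each replicate derives its
#'   own seed as `acq$seed + replicate index`.
#' @param replicates Replicates per level (default 3).
#' @param nuclide A [nuclide_constants()] object (default [y90_constants()]).
#' @param cylinder_d_mm,cylinder_h_mm Phantom cylinder size (default 60 mm).
#' @param voi_d_mm,voi_h_mm Interior VOI cylinder size (default 24 mm).
#' @return A list of class `hi_noise_study`: the `fit`
#'   ([fit_power_law()] result) and `data` (data.frame with columns
#'   `level_bq_ml`, `replicate`, `emitted_positrons`, `hi`).
#' @export
hi_noise_study <- function(levels, acq, replicates = 3L,
                           nuclide = y90_constants(),
                           cylinder_d_mm = 60, cylinder_h_mm = 60,
                           voi_d_mm = 24, voi_h_mm = 24) {
  stopifnot(inherits(acq, "pet_acq_params"), replicates >= 1L)
  levels <- sort(as.numeric(levels))
  if (length(levels) < 4L) stop("need at least 4 activity levels")
  if (any(levels <= 0)) stop("activity levels must be positive")
  if (any(diff(levels) <= 0)) stop("degenerate level spacing: levels must be distinct")
  if (log10(max(levels) / min(levels)) < 1.5) {
    stop("levels must span at least 1.5 decades")
  }

  vs <- c(2.73, 2.73, 3.27)
  margin <- 3 * max(acq$psf_fwhm_mm, vs)
  extent <- c(cylinder_d_mm, cylinder_d_mm, cylinder_h_mm) + 2 * margin
  shape <- ceiling(extent / vs)
  center <- shape * vs / 2
  spec <- phantom_spec(
    shape = shape, voxel_size_mm = vs,
    compartments = list(
      compartment("cylinder", "cylinder", center,
                  c(cylinder_d_mm, cylinder_h_mm), 1),
      compartment("voi", "cylinder", center, c(voi_d_mm, voi_h_mm), 1)
    )
  )
  ph <- build_phantom(spec)
  voi <- ph$masks$voi
  v_voi <- mask_volume_ml(voi)

  rows <- vector("list", length(levels) * replicates)
  k <- 0L
  for (i in seq_along(levels)) {
    truth <- voxel_grid(ph$activity$values * levels[i],
                        ph$activity$voxel_size_mm, unit = "Bq/mL")
    for (r in seq_len(replicates)) {
      k <- k + 1L
      acq_r <- acq
      acq_r$seed <- acq$seed + k
      img <- simulate_pet(truth, nuclide, acq_r)
      rows[[k]] <- data.frame(
        level_bq_ml = levels[i], replicate = r,
        emitted_positrons = emitted_positrons(levels[i], v_voi, nuclide,
                                              acq$scan_time_s),
        hi = homogeneity_index(img, voi)
      )
    }
  }
  data <- do.call(rbind, rows)
  structure(
    list(fit = fit_power_law(data$emitted_positrons, data$hi), data = data),
    class = "hi_noise_study"
  )
}

#' @export
print.hi_noise_study <- function(x, ...) {
  cat(sprintf("<hi_noise_study> %d points over %d levels\n",
              nrow(x$data), length(unique(x$data$level_bq_ml))))
  print(x$fit)
  invisible(x)
}
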