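#' 90Y PET calibration factor from a surrogate tracer
#'
#' A scanner calibrated with a conventional positron emitter (e.g. 18F)
#' can quantify 90Y by rescaling that calibration factor by the 90Y
#' beta-plus branch ratio (about 3.186e-5): only that fraction of decays
#' produces a detectable positron.
#'
#' @param cf_surrogate Calibration factor of the surrogate tracer.
#' @param branch_ratio Positron branch ratio of the nuclide being imaged.
#' @return `cf_surrogate / branch_ratio`.
#' @export
calibration_factor_y90 <- function(cf_surrogate, branch_ratio) {
  stopifnot(is.numeric(cf_surrogate), is.numeric(branch_ratio))
  if (branch_ratio <= 0) stop("branch_ratio must be > 0")
  cf_surrogate / branch_ratio
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`. Returns 0
#' by convention for degenerate input (n < 3 or zero variance).
#'
#' @param x Numeric vector.
#' @return Skewness coefficient (dimensionless).
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Summary statistics over a volume of interest
#'
#' Mean, SD, extrema, quartiles (linear interpolation between order
#' statistics, R quantile type 7) and adjusted Fisher-Pearson skewness of
#' the voxel values inside the mask.
#'
#' @param image A [voxel_grid()] in Bq/mL.
#' @param mask A non-empty [voi_mask()] sharing the image geometry.
#' @return A list of class `voi_stats`: `mean`, `sd`, `min`, `max`, `q1`,
#'   `q3`, `skewness`, `n_voxels`, `volume_ml`.
#' @export
voi_stats <- function(image, mask) {
  x <- masked_values(image, mask)
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  structure(
    list(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
         min = min(x), max = max(x), q1 = q[1], q3 = q[2],
         skewness = sample_skewness(x), n_voxels = length(x),
         volume_ml = mask_volume_ml(mask)),
    class = "voi_stats"
  )
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf(
    "<voi_stats> n = %d (%.4g mL); mean %.4g, sd %.4g, [q1 %.4g, q3 %.4g], range [%.4g, %.4g], skewness %.3g\n",
    x$n_voxels, x$volume_ml, x$mean, x$sd, x$q1, x$q3, x$min, x$max, x$skewness
  ))
  invisible(x)
}

#' Differential activity-concentration volume histogram (dAVH)
#'
#' The volume-fraction density over concentration: the fraction of VOI
#' volume per concentration bin, divided by the bin width, equal to the
#' negative discrete derivative of the cumulative volume fraction
#' `v(c) / V`. The density integrates to exactly 1.
#'
#' @param image A [voxel_grid()] in Bq/mL.
#' @param mask A non-empty [voi_mask()].
#' @param bin_width Concentration bin width, Bq/mL. Default:
#'   `(max - min) / 100` of the masked values (one bin if constant).
#' @return A list of class `avh`: `bin_edges` (Bq/mL, ascending) and
#'   `density` (fraction of VOI volume per Bq/mL).
#' @export
davh <- function(image, mask, bin_width = NULL) {
  x <- masked_values(image, mask)
  rng <- range(x)
  if (is.null(bin_width)) {
    bin_width <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 100 else max(rng[2], 1)
  }
  if (bin_width <= 0) stop("bin_width must be > 0")
  edges <- seq(rng[1], rng[2] + bin_width, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  density <- counts / length(x) / bin_width
  structure(list(bin_edges = edges, density = density), class = "avh")
}

#' Homogeneity index of a VOI
#'
#' Volume-weighted coefficient of variation of the activity concentration:
#' `HI = sqrt(sum(v_i / V * (c_i - C_mean)^2)) / C_mean`. With equal voxel
#' volumes this is the population SD over the mean. Counting noise makes
#' HI fall as the inverse square root of the number of detected events.
#'
#' @param image A [voxel_grid()] in Bq/mL.
#' @param mask A non-empty [voi_mask()].
#' @return HI (dimensionless, >= 0).
#' @export
homogeneity_index <- function(image, mask) {
  x <- masked_values(image, mask)
  m <- mean(x)
  if (m <= 0) stop("mean concentration must be > 0 for a homogeneity index")
  sqrt(mean((x - m)^2)) / m
}

#' Recovery coefficients from measured vs true concentrations
#'
#' RC_i = measured_i / true, paired with object volume and sorted by
#' volume. Recovery coefficients quantify partial-volume losses: spill-out
#' makes objects smaller than about three PSF widths read low.
#'
#' @param measured Measured mean concentrations, Bq/mL (one per object).
#' @param true_conc True fill concentration, Bq/mL (> 0).
#' @param volumes Object volumes, mL (aligned with `measured`).
#' @return A data.frame of class `rc_table` with columns `volume_ml`, `rc`.
#' @export
recovery_coefficients <- function(measured, true_conc, volumes) {
  if (true_conc <= 0) stop("true_conc must be > 0")
  stopifnot(length(measured) == length(volumes), all(volumes > 0))
  tab <- data.frame(volume_ml = as.numeric(volumes),
                    rc = as.numeric(measured) / true_conc)
  tab <- tab[order(tab$volume_ml), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("rc_table", "data.frame")
  tab
}

# Interpolate RC at a volume: linear in log(volume), clamped to table ends.
interp_rc <- function(table, volume_ml) {
  stopifnot(inherits(table, "rc_table"))
  if (nrow(table) < 2L) stop("RC table needs at least 2 rows for interpolation")
  approx(log(table$volume_ml), table$rc, xout = log(volume_ml),
         rule = 2)$y
}

#' Partial-volume correction of a measured mean concentration
#'
#' Divides the measured mean by the recovery coefficient interpolated at
#' the VOI volume (linear in log volume, clamped to the table range).
#'
#' @param mean_conc Measured mean concentration, Bq/mL.
#' @param volume Object volume used for the RC lookup, mL.
#' @param table An [recovery_coefficients()] table (>= 2 rows).
#' @return PVE-corrected concentration, Bq/mL.
#' @export
pve_correct <- function(mean_conc, volume, table) {
  if (volume <= 0) stop("volume must be > 0")
  mean_conc / interp_rc(table, volume)
}

#' Percent deviation of a measurement from the true value
#'
#' `100 * (measured - true) / true`.
#'
#' @param measured Measured value.
#' @param true_value Reference value (non-zero).
#' @return Signed percent deviation.
#' @export
percent_deviation <- function(measured, true_value) {
  if (any(true_value == 0)) stop("true_value must be non-zero")
  100 * (measured - true_value) / true_value
}

#' Number of positrons emitted from a VOI during a scan
#'
#' `N = C * V * BR * (1 - exp(-lambda t)) / lambda`: total decays over the
#' scan (with physical decay) times the positron branch ratio. For
#' `lambda * t << 1` this reduces to `C * V * BR * t`.
#'
#' @param conc Activity concentration, Bq/mL.
#' @param volume VOI volume, mL.
#' @param nuclide A [nuclide_constants()] object.
#' @param scan_time_s Scan duration, s.
#' @return Expected emitted positron count.
#' @export
emitted_positrons <- function(conc, volume, nuclide, scan_time_s) {
  stopifnot(conc >= 0, volume >= 0, scan_time_s >= 0,
            inherits(nuclide, "nuclide_constants"))
  lam <- decay_constant(nuclide)
  conc * volume * nuclide$branch_ratio_beta_plus *
    (1 - exp(-lam * scan_time_s)) / lam
}
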