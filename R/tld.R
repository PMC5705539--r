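#' One TLD chip reading with calibration and correction factors
#'
#' A thermoluminescent dosimeter measurement of absorbed dose to water
#' from a beta emitter in solution. The reading is converted to dose by a
#' chain of multiplicative factors: the 60Co calibration coefficient
#' `n_dw` (Gy per reader unit), the finite-volume factor `k_fv`
#' (radioactivity excluded from the chip volume), the energy/geometry
#' conversion `h` between measurement and calibration conditions, and the
#' holder-material factor `k_mat`. Each factor carries a relative
#' standard uncertainty; the correction factors come from an external
#' transport calculation and default to 1 with zero uncertainty, so real
#' use requires entering them explicitly.
#'
#' @param tl_signal TLD reading, reader units (>= 0).
#' @param n_dw Calibration coefficient, Gy per reader unit (> 0).
#' @param u_tl_rel,u_n_dw_rel,u_k_fv_rel,u_h_rel,u_k_mat_rel Relative
#'   standard uncertainties of the respective factors (>= 0).
#' @param k_fv,h,k_mat Dimensionless correction factors (> 0).
#' @param contaminated Flag: chip contaminated and to be excluded.
#' @return An object of class `tld_reading`.
#' @export
tld_reading <- function(tl_signal, n_dw, u_tl_rel = 0, u_n_dw_rel = 0,
                        k_fv = 1, u_k_fv_rel = 0, h = 1, u_h_rel = 0,
                        k_mat = 1, u_k_mat_rel = 0, contaminated = FALSE) {
  stopifnot(tl_signal >= 0, n_dw > 0, k_fv > 0, h > 0, k_mat > 0,
            u_tl_rel >= 0, u_n_dw_rel >= 0, u_k_fv_rel >= 0,
            u_h_rel >= 0, u_k_mat_rel >= 0, is.logical(contaminated))
  structure(
    list(tl_signal = tl_signal, n_dw = n_dw, u_tl_rel = u_tl_rel,
         u_n_dw_rel = u_n_dw_rel, k_fv = k_fv, u_k_fv_rel = u_k_fv_rel,
         h = h, u_h_rel = u_h_rel, k_mat = k_mat, u_k_mat_rel = u_k_mat_rel,
         contaminated = contaminated),
    class = "tld_reading"
  )
}

#' Absorbed dose to water from one TLD reading
#'
#' `D_w = TL * N_Dw * k_fv * H * k_mat`; the relative standard
#' uncertainty is the quadrature sum of the five factors' relative
#' uncertainties (uncorrelated assumption).
#'
#' @param reading A [tld_reading()]; contaminated chips are rejected.
#' @return A list: `dose_gy`, `rel_u`.
#' @export
tld_dose <- function(reading) {
  stopifnot(inherits(reading, "tld_reading"))
  if (reading$contaminated) {
    stop("contaminated chip: reading rejected, exclude it from analysis")
  }
  d <- reading$tl_signal * reading$n_dw * reading$k_fv * reading$h * reading$k_mat
  rel_u <- sqrt(reading$u_tl_rel^2 + reading$u_n_dw_rel^2 +
                reading$u_k_fv_rel^2 + reading$u_h_rel^2 + reading$u_k_mat_rel^2)
  list(dose_gy = d, rel_u = rel_u)
}

# Two-sided Grubbs critical value at significance alpha for n points.
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Aggregate TLD chip doses by inverse-variance weighting
#'
#' Weighted mean of the unflagged chips with weights `1 / sigma_i^2`
#' (`sigma_i = dose_i * rel_u_i`); the returned uncertainty is the
#' standard uncertainty of the weighted mean, `sqrt(1 / sum(w))`, which
#' never exceeds the smallest single-chip uncertainty. With equal
#' uncertainties this reduces to the arithmetic mean. Optionally,
#' outlying chips can be auto-flagged by an iterated two-sided Grubbs
#' test (each exclusion is reported with a message, never silent).
#'
#' @param doses Chip doses, Gy.
#' @param rel_u Relative standard uncertainties (aligned with `doses`).
#' @param contaminated Logical flags; flagged chips are excluded up front.
#' @param auto_flag If `TRUE`, iteratively apply a Grubbs outlier test.
#' @param alpha Grubbs test significance level (default 0.05).
#' @return A list: `dose_gy`, `u_gy`, `rel_u`, `n_used`, `excluded`
#'   (indices of all excluded chips).
#' @export
aggregate_chips <- function(doses, rel_u, contaminated = rep(FALSE, length(doses)),
                            auto_flag = FALSE, alpha = 0.05) {
  stopifnot(length(doses) == length(rel_u),
            length(doses) == length(contaminated),
            all(doses >= 0), all(rel_u >= 0))
  keep <- !contaminated
  if (!any(keep)) stop("all chips flagged: nothing to aggregate")

  if (auto_flag) {
    repeat {
      idx <- which(keep)
      if (length(idx) < 3L) break
      x <- doses[idx]
      g <- abs(x - mean(x)) / sd(x)
      i_max <- which.max(g)
      if (g[i_max] > grubbs_critical(length(x), alpha)) {
        message(sprintf("aggregate_chips: Grubbs test flagged chip %d (G = %.2f)",
                        idx[i_max], g[i_max]))
        keep[idx[i_max]] <- FALSE
      } else break
    }
  }

  idx <- which(keep)
  x <- doses[idx]
  sig <- x * rel_u[idx]
  if (all(sig == 0)) {
    m <- mean(x)
    u <- 0
  } else {
    if (any(sig == 0)) stop("mixing zero and non-zero uncertainties is ambiguous")
    w <- 1 / sig^2
    m <- sum(w * x) / sum(w)
    u <- sqrt(1 / sum(w))
  }
  list(dose_gy = m, u_gy = u, rel_u = if (m > 0) u / m else 0,
       n_used = length(idx), excluded = which(!keep))
}

#' Normalize an absorbed dose to the number of emitted beta particles
#'
#' Divides the measured dose by the number of decays in the surrounding
#' solution during the exposure,
#' `N = conc * volume * (1 - exp(-lambda t)) / lambda` (essentially every
#' 90Y decay emits one beta particle). The result, Gy per emitted
#' particle, is the geometry-specific quantity a transport calculation of
#' the same phantom predicts.
#'
#' @param d_w Absorbed dose to water, Gy.
#' @param conc Activity concentration of the solution, Bq/mL (> 0).
#' @param volume Radioactive solution volume, mL (> 0). The post-insertion
#'   liquid volume must be supplied explicitly: the normalization is
#'   directly proportional to it.
#' @param nuclide A [nuclide_constants()] object.
#' @param exposure_s Exposure duration, s (> 0).
#' @param rel_u_dw,rel_u_conc Relative standard uncertainties of the dose
#'   and of the activity concentration (combined in quadrature).
#' @return A list of class `dose_per_particle`: `value` (Gy/particle),
#'   `rel_u`, `n_particles`.
#' @export
dose_per_emitted_particle <- function(d_w, conc, volume, nuclide, exposure_s,
                                      rel_u_dw = 0, rel_u_conc = 0) {
  stopifnot(inherits(nuclide, "nuclide_constants"),
            d_w >= 0, rel_u_dw >= 0, rel_u_conc >= 0)
  if (conc <= 0 || volume <= 0 || exposure_s <= 0) {
    stop("conc, volume and exposure_s must be positive (zero emissions)")
  }
  lam <- decay_constant(nuclide)
  n <- conc * volume * (1 - exp(-lam * exposure_s)) / lam
  structure(
    list(value = d_w / n, rel_u = sqrt(rel_u_dw^2 + rel_u_conc^2),
         n_particles = n),
    class = "dose_per_particle"
  )
}

#' Read a TLD chip table from CSV
#'
#' Expected columns: `chip_id, tl_signal, n_dw, u_n_dw_rel, k_fv,
#' u_k_fv_rel, h, u_h_rel, k_mat, u_k_mat_rel, contaminated` (an optional
#' `u_tl_rel` column is honoured).
#'
#' @param path CSV file path.
#' @return A list of [tld_reading()] objects, named by `chip_id`.
#' @export
read_chip_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chip_id", "tl_signal", "n_dw", "u_n_dw_rel", "k_fv", "u_k_fv_rel",
            "h", "u_h_rel", "k_mat", "u_k_mat_rel", "contaminated")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("chip table missing columns: ", paste(missing, collapse = ", "))
  if (!"u_tl_rel" %in% names(df)) df$u_tl_rel <- 0
  out <- lapply(seq_len(nrow(df)), function(i) {
    tld_reading(df$tl_signal[i], df$n_dw[i], df$u_tl_rel[i], df$u_n_dw_rel[i],
                df$k_fv[i], df$u_k_fv_rel[i], df$h[i], df$u_h_rel[i],
                df$k_mat[i], df$u_k_mat_rel[i], as.logical(df$contaminated[i]))
  })
  names(out) <- df$chip_id
  out
}
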