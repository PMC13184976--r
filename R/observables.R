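# Experimental-data reduction and forward models: NOE buildup rates and
# distance calibration under the isolated spin pair approximation, the
# Karplus phi -> 3J(NH-HA) map, and RDC extraction from gel-compression
# coupling pairs.

#' Fit an NOE buildup rate
#'
#' Ordinary least-squares slope of intensity versus mixing time. The
#' initial-rate regime of an NOE buildup is linear with slope
#' proportional to the cross-relaxation rate, so the fitted slope is the
#' buildup rate sigma (intensity s^-1).
#'
#' @param mixing_times Mixing times in seconds, strictly increasing,
#'   at least 3.
#' @param intensities Cross-peak intensities (arbitrary units).
#' @param through_origin Force the fitted line through zero intensity at
#'   zero mixing time (default `FALSE`: free intercept, robust to
#'   baseline offsets).
#' @return The buildup rate (slope).
#' @export
fit_buildup <- function(mixing_times, intensities, through_origin = FALSE) {
  if (length(mixing_times) < 3 || length(intensities) < 3) {
    stop("insufficient data: need at least 3 buildup points", call. = FALSE)
  }
  if (length(mixing_times) != length(intensities)) {
    stop("mixing_times and intensities must have equal length",
         call. = FALSE)
  }
  if (any(diff(mixing_times) <= 0)) {
    stop("mixing times must be strictly increasing", call. = FALSE)
  }
  if (through_origin) {
    unname(stats::coef(stats::lm(intensities ~ mixing_times + 0))[1])
  } else {
    unname(stats::coef(stats::lm(intensities ~ mixing_times))[2])
  }
}

#' Calibrate a buildup rate to an interproton distance
#'
#' Internal referencing under the isolated spin pair approximation: the
#' buildup rate scales as \eqn{r^{-6}}, so
#' \eqn{r = r_{ref} (\sigma_{ref}/\sigma)^{1/6}} against the geminal
#' methylene reference pair at 1.78 A.
#'
#' @param sigma Buildup rate of the pair of interest.
#' @param sigma_ref Buildup rate of the reference pair.
#' @param r_ref Reference distance in Angstrom (default 1.78).
#' @return Distance in Angstrom.
#' @export
rate_to_distance <- function(sigma, sigma_ref, r_ref = 1.78) {
  if (any(sigma <= 0) || any(sigma_ref <= 0)) {
    stop("calibration error: buildup rates must be positive", call. = FALSE)
  }
  r_ref * (sigma_ref / sigma)^(1 / 6)
}

#' Encode a distance as a buildup rate (inverse calibration)
#'
#' @param r Distance in Angstrom.
#' @param sigma_ref Reference buildup rate.
#' @param r_ref Reference distance (default 1.78 A).
#' @return Buildup rate such that [rate_to_distance()] returns `r`.
#' @export
distance_to_rate <- function(r, sigma_ref, r_ref = 1.78) {
  if (any(r <= 0)) stop("calibration error: distance must be positive",
                        call. = FALSE)
  sigma_ref * (r_ref / r)^6
}

#' Karplus coefficients for 3J(NH-HA)
#'
#' \eqn{J(\phi) = A \cos^2\theta + B \cos\theta + C} with
#' \eqn{\theta = \phi + phase}. The default parameterization
#' (A = 6.51, B = -1.76, C = 1.60 Hz, phase = -60 deg) is a standard
#' HN-HA set; alternative literature sets can be supplied.
#'
#' @param A,B,C Coefficients in Hz.
#' @param phase Phase offset in degrees (theta = phi + phase).
#' @return An object of class `karplus_coefficients`.
#' @export
karplus_coefficients <- function(A = 6.51, B = -1.76, C = 1.60,
                                 phase = -60) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C), is.finite(phase))
  structure(list(A = A, B = B, C = C, phase = phase),
            class = "karplus_coefficients")
}

#' Karplus 3J(NH-HA) from a backbone phi torsion
#'
#' @param phi Backbone phi in degrees (vectorized).
#' @param k A [karplus_coefficients()].
#' @return Coupling in Hz.
#' @export
karplus_j <- function(phi, k = karplus_coefficients()) {
  ct <- cos(.deg2rad(phi + k$phase))
  k$A * ct^2 + k$B * ct + k$C
}

#' Population-averaged effective NOE distance
#'
#' \eqn{r_{eff} = (\sum_k p_k r_k^{-6})^{-1/6}} over the per-conformer
#' distances (ISPA-consistent averaging). \eqn{r^{-3}} averaging is
#' available for comparison.
#'
#' @param pool A [conformer_pool].
#' @param weights Nonnegative weights summing to 1.
#' @param pair List of two atom selectors.
#' @param exponent Averaging exponent, 6 (default) or 3.
#' @return Effective distance in Angstrom.
#' @export
predict_noe_distance <- function(pool, weights, pair, exponent = 6) {
  .check_weights(weights, length(pool))
  r <- vapply(pool$conformers, function(cf)
    distance(cf, pair[[1]], pair[[2]]), numeric(1))
  if (any(r == 0)) {
    stop("degenerate geometry: zero interproton distance", call. = FALSE)
  }
  sum(weights * r^(-exponent))^(-1 / exponent)
}

#' Population-averaged 3J(NH-HA) of a residue
#'
#' \eqn{\sum_k p_k J(\phi_k)}; linear in the weights.
#'
#' @param pool A [conformer_pool].
#' @param weights Nonnegative weights summing to 1.
#' @param residue Residue index (phi must be defined, i.e. residue >= 2).
#' @param k A [karplus_coefficients()].
#' @return Coupling in Hz.
#' @export
predict_j <- function(pool, weights, residue, k = karplus_coefficients()) {
  .check_weights(weights, length(pool))
  jk <- vapply(pool$conformers, function(cf)
    karplus_j(phi_angle(cf, residue), k), numeric(1))
  sum(weights * jk)
}

.check_weights <- function(w, n) {
  if (length(w) != n) {
    stop("weights must have one entry per conformer", call. = FALSE)
  }
  if (any(w < -1e-12) || abs(sum(w) - 1) > 1e-6) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
}

#' RDC from a gel-compression coupling pair
#'
#' The residual dipolar coupling is the difference between the splitting
#' measured on the compressed (aligned) sample and the relaxed
#' (isotropic) one: \eqn{D = T_{strong} - T_{weak}}.
#'
#' @param t_strong Coupling with compression, Hz.
#' @param t_weak Coupling without compression, Hz.
#' @return RDC in Hz (vectorized).
#' @export
rdc_from_couplings <- function(t_strong, t_weak) {
  stopifnot(is.numeric(t_strong), is.numeric(t_weak))
  t_strong - t_weak
}

# ---- restraint tables -------------------------------------------------------

#' Reduce a buildup-series table to NOE distance restraints
#'
#' Fits a buildup rate per row (columns `I_<ms>` hold intensities at the
#' mixing time in milliseconds), calibrates distances against the row
#' flagged `reference`, and attaches errors.
#'
#' Distance errors are propagated from the buildup-rate uncertainty
#' through the \eqn{r^{-6}} calibration: a relative rate error
#' \eqn{\epsilon} maps to a relative distance error \eqn{\epsilon/6}.
#'
#' @param noe Buildup table as produced by [simulate_observables()] or
#'   read from CSV: columns `res_i`, `atom_i`, `res_j`, `atom_j`,
#'   `reference`, and `I_<ms>` intensity columns.
#' @param r_ref Reference distance in Angstrom (default 1.78).
#' @param rel_rate_error Relative uncertainty assigned to each buildup
#'   rate (default 0.10); the distance error column is
#'   `r_obs * rel_rate_error / 6`.
#' @param through_origin Passed to [fit_buildup()].
#' @return Data frame of restraints: `res_i`, `atom_i`, `res_j`,
#'   `atom_j`, `sigma`, `r_obs`, `error`.
#' @export
noe_distances_from_buildups <- function(noe, r_ref = 1.78,
                                        rel_rate_error = 0.10,
                                        through_origin = FALSE) {
  icols <- grep("^I_\\d+$", names(noe), value = TRUE)
  if (length(icols) < 3) {
    stop("insufficient data: need at least 3 mixing-time columns",
         call. = FALSE)
  }
  times <- as.numeric(sub("^I_", "", icols)) / 1000
  ord <- order(times)
  icols <- icols[ord]; times <- times[ord]
  sigma <- vapply(seq_len(nrow(noe)), function(i)
    fit_buildup(times, as.numeric(noe[i, icols]),
                through_origin = through_origin), numeric(1))
  if (!any(noe$reference)) {
    stop("calibration error: no reference pair flagged", call. = FALSE)
  }
  sigma_ref <- mean(sigma[noe$reference])
  keep <- !noe$reference
  r_obs <- rate_to_distance(sigma[keep], sigma_ref, r_ref)
  data.frame(res_i = noe$res_i[keep], atom_i = noe$atom_i[keep],
             res_j = noe$res_j[keep], atom_j = noe$atom_j[keep],
             sigma = sigma[keep], r_obs = r_obs,
             error = r_obs * rel_rate_error / 6, stringsAsFactors = FALSE)
}

#' Read a restraint table from CSV/TSV
#'
#' @param path File path; tab- or comma-separated, with a header.
#' @return Data frame.
#' @export
read_restraint_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' Write a restraint table to CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraint_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
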