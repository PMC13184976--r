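# Boltzmann bookkeeping: folded-population differences expressed as
# stabilization energies, relative dimer interaction energies against a
# reference, fold-change summaries and the energy/population correlation
# report.

#' Energetics configuration
#'
#' @param R Gas constant, J mol^-1 K^-1 (default 8.314).
#' @param T Temperature in Kelvin (default 298.15, room temperature).
#' @param convention How a folded-population difference maps to an
#'   energy: `"population_ratio"` (default) gives
#'   \eqn{-RT \ln(p / p_{ref})}; `"odds_ratio"` gives
#'   \eqn{-RT \ln[(p/(1-p)) / (p_{ref}/(1-p_{ref}))]}, i.e. the
#'   two-state free-energy difference.
#' @return An object of class `energetics_config`.
#' @export
energetics_config <- function(R = 8.314, T = 298.15,
                              convention = c("population_ratio",
                                             "odds_ratio")) {
  convention <- match.arg(convention)
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  structure(list(R = R, T = T, convention = convention),
            class = "energetics_config")
}

#' Boltzmann stabilization energy from two folded fractions
#'
#' Converts the change in folded population relative to a reference
#' compound into an energy, in kJ mol^-1 (negative = the test compound
#' folds more, i.e. is stabilized).
#'
#' @param p Folded fraction of the compound of interest, in (0, 1).
#' @param p_ref Folded fraction of the reference, in (0, 1).
#' @param cfg An [energetics_config()].
#' @return Energy in kJ mol^-1.
#' @export
boltzmann_ddg <- function(p, p_ref, cfg = energetics_config()) {
  if (any(p <= 0) || any(p >= 1) || any(p_ref <= 0) || any(p_ref >= 1)) {
    stop("domain error: folded fractions must lie strictly in (0, 1)",
         call. = FALSE)
  }
  rt <- cfg$R * cfg$T / 1000 # kJ mol^-1
  if (cfg$convention == "population_ratio") {
    -rt * log(p / p_ref)
  } else {
    -rt * log((p / (1 - p)) / (p_ref / (1 - p_ref)))
  }
}

#' Invert the Boltzmann map: folded fraction from an energy
#'
#' @param ddg Energy in kJ mol^-1 (as from [boltzmann_ddg()]).
#' @param p_ref Reference folded fraction.
#' @param cfg An [energetics_config()].
#' @return Folded fraction p such that `boltzmann_ddg(p, p_ref, cfg)`
#'   equals `ddg`.
#' @export
boltzmann_inverse <- function(ddg, p_ref, cfg = energetics_config()) {
  rt <- cfg$R * cfg$T / 1000
  if (cfg$convention == "population_ratio") {
    p_ref * exp(-ddg / rt)
  } else {
    odds <- (p_ref / (1 - p_ref)) * exp(-ddg / rt)
    odds / (1 + odds)
  }
}

#' Relative interaction energies against a reference record
#'
#' Subtracts the reference interaction energy from each record:
#' \eqn{\Delta\Delta E_i = \Delta E_i - \Delta E_{ref}}, so the
#' reference maps to exactly 0 and the ordering of dE is preserved.
#'
#' @param records Data frame with columns `label` and `dE` (kJ mol^-1).
#' @param reference_label Label of the reference record.
#' @return The data frame with a `ddE` column appended.
#' @export
relative_energies <- function(records, reference_label) {
  if (!reference_label %in% records$label) {
    stop("lookup error: reference label '", reference_label,
         "' not found", call. = FALSE)
  }
  ref <- records$dE[records$label == reference_label][1]
  records$ddE <- records$dE - ref
  records
}

#' Fold change of a folded fraction relative to a reference
#'
#' @param p Folded fraction.
#' @param p_ref Reference folded fraction (> 0).
#' @return List with `ratio` (p / p_ref) and `fold_label` (nearest
#'   integer rendering, e.g. `"3-fold"`).
#' @export
fold_ratio <- function(p, p_ref) {
  if (p_ref <= 0) stop("reference fraction must be positive", call. = FALSE)
  ratio <- p / p_ref
  list(ratio = ratio, fold_label = sprintf("%d-fold", round(ratio)))
}

#' Correlation report between relative energies and bonded populations
#'
#' Pearson and Spearman coefficients between computed relative
#' interaction energies and experimentally determined halogen-bonded
#' populations, with the caveat that a monotone association need not be
#' linear.
#'
#' @param ddE Relative energies (kJ mol^-1), length >= 3.
#' @param xb_percent Halogen-bonded populations (percent), same length.
#' @return List with `pearson`, `spearman`, `n` and `caveat`.
#' @export
correlation_report <- function(ddE, xb_percent) {
  if (length(ddE) != length(xb_percent)) {
    stop("length mismatch between energies and populations", call. = FALSE)
  }
  if (length(ddE) < 3) {
    stop("need at least 3 compounds for a correlation", call. = FALSE)
  }
  list(pearson = stats::cor(ddE, xb_percent, method = "pearson"),
       spearman = stats::cor(ddE, xb_percent, method = "spearman"),
       n = length(ddE),
       caveat = paste("association may be monotone without being linear;",
                      "compare the rank and linear coefficients"))
}

#' Local sensitivity of folding to interaction strength
#'
#' Percentage-point change in folded population per kJ mol^-1 of
#' stabilization, evaluated at a folded fraction `p` by differentiating
#' the inverse Boltzmann map.
#'
#' @param p Folded fraction at which to evaluate.
#' @param cfg An [energetics_config()].
#' @return Percentage points per kJ mol^-1.
#' @export
folding_sensitivity <- function(p, cfg = energetics_config()) {
  rt <- cfg$R * cfg$T / 1000
  if (cfg$convention == "population_ratio") {
    100 * p / rt
  } else {
    100 * p * (1 - p) / rt
  }
}
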