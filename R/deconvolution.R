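# Backbone-stage ensemble deconvolution: non-negative least-squares fit
# of conformer populations to population-averaged NOE distances and
# 3J(NH-HA) couplings, and the folded-fraction summary.

#' Build the observable design matrix for the backbone fit
#'
#' NOE rows are transformed to \eqn{r^{-6}} space (predicted entry
#' \eqn{r_k^{-6}}, observed \eqn{r_{obs}^{-6}}, the error propagated as
#' \eqn{6 r^{-7} \Delta r}) so that the population-averaged model is
#' linear in the populations; J rows stay in Hz where the Karplus
#' average is already linear.
#'
#' @param pool A [conformer_pool].
#' @param noe NOE distance restraints: data frame with `res_i`, `atom_i`,
#'   `res_j`, `atom_j`, `r_obs`, `error` (as from
#'   [noe_distances_from_buildups()]), or `NULL`.
#' @param j J restraints: data frame with `residue`, `j_obs`, `error`,
#'   or `NULL`.
#' @param k [karplus_coefficients()] for the J predictions.
#' @param rel_error Fallback relative error when a table has no `error`
#'   column (default 0.10).
#' @return An object of class `observable_matrix`: list with `A`
#'   (restraints x conformers prediction matrix), `y` (observed vector),
#'   `w` (row weights 1/error in transformed space), `kind`
#'   (`"NOE"`/`"J"` per row), and bookkeeping for back-transformed
#'   residuals.
#' @export
build_design_matrix <- function(pool, noe = NULL, j = NULL,
                                k = karplus_coefficients(),
                                rel_error = 0.10) {
  n_conf <- length(pool)
  rows <- list(); y <- c(); w <- c(); kind <- c()
  if (!is.null(noe) && nrow(noe) > 0) {
    err <- if ("error" %in% names(noe)) noe$error else rel_error * noe$r_obs
    for (i in seq_len(nrow(noe))) {
      pair <- list(atom_sel(noe$res_i[i], noe$atom_i[i]),
                   atom_sel(noe$res_j[i], noe$atom_j[i]))
      r_k <- vapply(pool$conformers, function(cf)
        distance(cf, pair[[1]], pair[[2]]), numeric(1))
      if (any(r_k == 0)) {
        stop("degenerate geometry: zero distance in NOE row ", i,
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- r_k^(-6)
      y <- c(y, noe$r_obs[i]^(-6))
      w <- c(w, 1 / (6 * noe$r_obs[i]^(-7) * err[i]))
      kind <- c(kind, "NOE")
    }
  }
  if (!is.null(j) && nrow(j) > 0) {
    err <- if ("error" %in% names(j)) j$error else rel_error * abs(j$j_obs)
    for (i in seq_len(nrow(j))) {
      jk <- vapply(pool$conformers, function(cf)
        karplus_j(phi_angle(cf, j$residue[i]), k), numeric(1))
      rows[[length(rows) + 1L]] <- jk
      y <- c(y, j$j_obs[i])
      w <- c(w, 1 / err[i])
      kind <- c(kind, "J")
    }
  }
  if (length(rows) == 0) {
    stop("insufficient data: no restraint rows", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("restraint errors must be positive and finite", call. = FALSE)
  }
  structure(list(A = do.call(rbind, rows), y = y, w = w, kind = kind,
                 n_conf = n_conf),
            class = "observable_matrix")
}

# weighted NNLS with a soft unit-sum row, lambda relative to row weights
.nnls_unit_sum <- function(A, y, w, lambda_sum = NULL) {
  if (is.null(lambda_sum)) lambda_sum <- 10 * max(w)
  Aw <- A * w
  yw <- y * w
  Aaug <- rbind(Aw, rep(lambda_sum, ncol(A)))
  yaug <- c(yw, lambda_sum)
  fit <- pracma::lsqnonneg(Aaug, yaug)
  fit$x
}

#' Fit conformer populations by non-negative least squares
#'
#' Solves \eqn{\min \|W(Ap - y)\|^2 + \lambda^2 (\sum p - 1)^2} subject
#' to \eqn{p \ge 0} via NNLS on the augmented system, then renormalizes
#' the populations to sum exactly to 1. Residuals are reported in
#' natural units: Angstrom for NOE rows (after back-transform from
#' \eqn{r^{-6}} space) and Hz for J rows.
#'
#' @param m An [build_design_matrix()] result.
#' @param lambda_sum Weight of the soft unit-sum constraint; default 10x
#'   the largest row weight.
#' @param cond_threshold Design condition number above which
#'   `condition_flag` is set (default 1e8: near-exact collinearity).
#' @return An object of class `population_fit`: `populations`,
#'   `rmsd_by_kind` (named numeric), `sum_deviation` (|sum p - 1| before
#'   renormalization), `condition_flag`, `residuals`, `predicted`.
#' @export
fit_populations <- function(m, lambda_sum = NULL, cond_threshold = 1e8) {
  stopifnot(inherits(m, "observable_matrix"))
  if (all(m$A == 0)) {
    stop("singular fit: all-zero design matrix", call. = FALSE)
  }
  sv <- svd(m$A * m$w)$d
  cn <- if (min(sv) < .Machine$double.eps * max(sv)) Inf else
    max(sv) / min(sv)
  p_raw <- .nnls_unit_sum(m$A, m$y, m$w, lambda_sum)
  s <- sum(p_raw)
  if (s <= 0) {
    stop("singular fit: NNLS returned an all-zero population vector",
         call. = FALSE)
  }
  p <- p_raw / s
  pred <- as.numeric(m$A %*% p)
  resid <- pred - m$y
  rmsd_by_kind <- vapply(unique(m$kind), function(kd) {
    i <- m$kind == kd
    if (kd == "NOE") {
      # back-transform to Angstrom
      sqrt(mean((pred[i]^(-1 / 6) - m$y[i]^(-1 / 6))^2))
    } else {
      sqrt(mean(resid[i]^2))
    }
  }, numeric(1))
  structure(
    list(populations = p,
         rmsd_by_kind = rmsd_by_kind,
         sum_deviation = abs(s - 1),
         condition_flag = !is.finite(cn) || cn > cond_threshold,
         condition_number = cn,
         residuals = resid, predicted = pred),
    class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat("<population_fit>", length(x$populations), "conformers;",
      sum(x$populations > 1e-6), "populated\n")
  cat("  residual RMSD:",
      paste(sprintf("%s %.4g", names(x$rmsd_by_kind), x$rmsd_by_kind),
            collapse = ", "), "\n")
  if (x$condition_flag) cat("  WARNING: ill-conditioned design\n")
  invisible(x)
}

#' Folded beta-hairpin fraction of a population fit
#'
#' @param fit A [fit_populations()] result (or a bare population vector).
#' @param labels Logical vector: `TRUE` for folded conformers.
#' @return Folded population in percent.
#' @export
folded_fraction <- function(fit, labels) {
  p <- if (inherits(fit, "population_fit")) fit$populations else fit
  if (length(labels) != length(p)) {
    stop("labeling error: labels do not match the pool size", call. = FALSE)
  }
  100 * sum(p[as.logical(labels)])
}

#' Residual-resampling bootstrap of the folded fraction
#'
#' Refits the populations against observations perturbed by resampled
#' fit residuals, giving a distribution of folded fractions. Residuals
#' are standardized by the row weights before resampling (NOE rows live
#' in \eqn{r^{-6}} space, J rows in Hz, so raw residuals are not
#' exchangeable across kinds) and unscaled per row afterwards.
#' Deterministic given `seed`.
#'
#' @param m An [build_design_matrix()] result.
#' @param labels Folded labels as in [folded_fraction()].
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param lambda_sum Passed to [fit_populations()].
#' @return Numeric vector of `n_boot` folded fractions (percent).
#' @export
bootstrap_populations <- function(m, labels, n_boot, seed,
                                  lambda_sum = NULL) {
  stopifnot(inherits(m, "observable_matrix"))
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  seed <- .require_seed(seed)
  base <- fit_populations(m, lambda_sum)
  res_std <- base$residuals * m$w
  .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- sample(res_std, length(res_std), replace = TRUE)
      mb <- m
      mb$y <- base$predicted - res / m$w
      fb <- fit_populations(mb, lambda_sum)
      folded_fraction(fb, labels)
    }, numeric(1))
  })
}
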