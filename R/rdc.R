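# Side-chain-stage RDC analysis: Saupe alignment-tensor determination by
# SVD, population-averaged RDC prediction, the Cornilescu Q factor and
# condition-number diagnostics, and the alternating tensor/population fit.

#' Saupe alignment tensor
#'
#' Five independent components (Syy, Szz, Sxy, Sxz, Syz) of a 3x3
#' traceless symmetric order matrix; Sxx = -Syy - Szz. Any effective
#' dipolar prefactor (gyromagnetic ratios, bond length) is absorbed into
#' the component scale, so projections are directly in Hz.
#'
#' @param s Numeric vector of the 5 components.
#' @return An object of class `saupe_tensor`.
#' @export
saupe_tensor <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 5 || any(!is.finite(s))) {
    stop("a Saupe tensor needs 5 finite components", call. = FALSE)
  }
  structure(list(s = s), class = "saupe_tensor")
}

#' Reconstruct the 3x3 order matrix of a Saupe tensor
#'
#' @param tensor A [saupe_tensor()].
#' @return Symmetric traceless 3x3 matrix.
#' @export
saupe_matrix <- function(tensor) {
  s <- tensor$s
  matrix(c(-s[1] - s[2], s[3], s[4],
           s[3], s[1], s[5],
           s[4], s[5], s[2]), 3, 3)
}

#' @export
print.saupe_tensor <- function(x, ...) {
  cat("<saupe_tensor> (Syy, Szz, Sxy, Sxz, Syz) =",
      paste(sprintf("%.4g", x$s), collapse = ", "), "\n")
  invisible(x)
}

#' RDC design row for a bond orientation
#'
#' Coefficients mapping the 5 Saupe components to the predicted RDC of a
#' unit bond vector b:
#' \eqn{(b_y^2 - b_x^2,\; b_z^2 - b_x^2,\; 2 b_x b_y,\; 2 b_x b_z,\;
#' 2 b_y b_z)}. Even in b, so the bond direction sign is irrelevant.
#'
#' @param bond Numeric length-3 bond vector (normalized internally).
#' @return Numeric vector of 5 coefficients.
#' @export
rdc_design_row <- function(bond) {
  if (.vnorm(bond) < 1e-10) {
    stop("degenerate geometry: zero bond vector", call. = FALSE)
  }
  b <- .unit(bond)
  c(b[2]^2 - b[1]^2, b[3]^2 - b[1]^2,
    2 * b[1] * b[2], 2 * b[1] * b[3], 2 * b[2] * b[3])
}

.bond_vector <- function(cf, pair) {
  .atom_xyz(cf, pair[[2]]) - .atom_xyz(cf, pair[[1]])
}

# population-averaged design matrix: one row per RDC pair,
# row_j = sum_k p_k row(bond_{k,j})
.rdc_design_matrix <- function(pool, weights, pairs) {
  rows <- lapply(pairs, function(pr) {
    m <- vapply(pool$conformers, function(cf)
      rdc_design_row(.bond_vector(cf, pr)), numeric(5))
    as.numeric(m %*% weights)
  })
  do.call(rbind, rows)
}

# per-conformer RDC prediction matrix under one tensor:
# B[j, k] = row(bond_{k,j}) . s
.rdc_conformer_matrix <- function(pool, tensor, pairs) {
  s <- tensor$s
  do.call(rbind, lapply(pairs, function(pr) {
    vapply(pool$conformers, function(cf)
      sum(rdc_design_row(.bond_vector(cf, pr)) * s), numeric(1))
  }))
}

#' Predict population-averaged RDCs
#'
#' \eqn{D_{calc,j} = \sum_k p_k\, row(bond_{k,j}) \cdot s}: all
#' conformers share one common alignment tensor and the prediction is
#' linear in both the populations and the tensor components.
#'
#' @param pool A [conformer_pool].
#' @param weights Populations (nonnegative, summing to 1).
#' @param tensor A [saupe_tensor()].
#' @param pairs List of C-H selector pairs (C first, H second).
#' @return Numeric vector of predicted RDCs in Hz.
#' @export
predict_rdc <- function(pool, weights, tensor, pairs) {
  .check_weights(weights, length(pool))
  as.numeric(.rdc_design_matrix(pool, weights, pairs) %*% tensor$s)
}

#' Fit the alignment tensor by singular value decomposition
#'
#' Weighted linear least squares of the 5 Saupe components against the
#' observed RDCs, on the population-averaged design matrix; solved via
#' the SVD pseudoinverse. The condition number is the ratio of the
#' largest to the smallest singular value of the weighted design.
#'
#' @param pool A [conformer_pool].
#' @param weights Populations.
#' @param rdcs RDC table: `res_i`, `atom_i`, `res_j`, `atom_j`, `d_obs`,
#'   and optionally `error` (used as row weights 1/error).
#' @return List with `tensor` (a [saupe_tensor()]), `cn` (condition
#'   number), and `d_calc`.
#' @export
svd_fit_tensor <- function(pool, weights, rdcs) {
  pairs <- .rdc_pairs_from_table(rdcs)
  if (length(pairs) < 5) {
    stop("insufficient data: at least 5 RDCs are required to determine ",
         "the alignment tensor", call. = FALSE)
  }
  w <- if ("error" %in% names(rdcs)) 1 / rdcs$error else
    rep(1, length(pairs))
  A <- .rdc_design_matrix(pool, weights, pairs) * w
  y <- rdcs$d_obs * w
  dec <- svd(A)
  if (sum(dec$d > max(dec$d) * 1e-10) < 5) {
    stop("singular design: RDC bond orientations do not span 5 ",
         "independent directions", call. = FALSE)
  }
  cn <- max(dec$d) / min(dec$d)
  s <- dec$v %*% ((t(dec$u) %*% y) / dec$d)
  tensor <- saupe_tensor(s)
  d_calc <- as.numeric(.rdc_design_matrix(pool, weights, pairs) %*%
                         tensor$s)
  list(tensor = tensor, cn = cn, d_calc = d_calc)
}

.rdc_pairs_from_table <- function(rdcs) {
  lapply(seq_len(nrow(rdcs)), function(i)
    list(atom_sel(rdcs$res_i[i], rdcs$atom_i[i]),
         atom_sel(rdcs$res_j[i], rdcs$atom_j[i])))
}

#' Cornilescu quality factor
#'
#' \eqn{Q = rms(D_{obs} - D_{calc}) / rms(D_{obs})}. Q < 0.3 indicates a
#' good and Q < 0.4 an acceptable fit.
#'
#' @param d_obs Observed RDCs.
#' @param d_calc Back-calculated RDCs.
#' @return Dimensionless Q >= 0.
#' @export
q_factor <- function(d_obs, d_calc) {
  if (length(d_obs) != length(d_calc)) {
    stop("d_obs and d_calc must have equal length", call. = FALSE)
  }
  if (all(d_obs == 0)) {
    stop("undefined Q: all observed RDCs are zero", call. = FALSE)
  }
  sqrt(mean((d_obs - d_calc)^2)) / sqrt(mean(d_obs^2))
}

#' Verbal classification of a Q factor
#'
#' @param q Q factor.
#' @return `"good"` (Q < 0.3), `"acceptable"` (Q < 0.4) or `"poor"`.
#' @export
q_class <- function(q) {
  if (q < 0.3) "good" else if (q < 0.4) "acceptable" else "poor"
}

#' Simultaneous alignment-tensor and population fit
#'
#' Alternating optimization against the observed RDCs: an SVD tensor
#' update given the current populations, then an NNLS population update
#' (nonnegative, soft unit-sum) given the tensor, iterated until the Q
#' factor improves by less than `tol` or `max_iter` is reached. An
#' iteration that worsens Q is rejected and the previous state returned.
#' Condition numbers of 30 or above flag the tensor determination as
#' unreliable.
#'
#' @param pool A [conformer_pool].
#' @param rdcs RDC table as in [svd_fit_tensor()].
#' @param init Initial populations (default uniform).
#' @param max_iter Maximum alternating iterations (default 200).
#' @param tol Convergence tolerance on |delta Q| (default 1e-6).
#' @param cn_limit Condition-number reliability threshold (default 30).
#' @param lambda_sum Soft unit-sum weight for the population NNLS.
#' @return An object of class `rdc_fit`: `tensor`, `populations`, `q`,
#'   `cn`, `d_calc`, `q_trace`, `converged`, `cn_unreliable`, `q_class`.
#' @export
fit_tensor_and_populations <- function(pool, rdcs,
                                       init = NULL, max_iter = 200,
                                       tol = 1e-6, cn_limit = 30,
                                       lambda_sum = NULL) {
  pairs <- .rdc_pairs_from_table(rdcs)
  if (length(pairs) < 5) {
    stop("insufficient data: at least 5 RDCs are required", call. = FALSE)
  }
  n_conf <- length(pool)
  p <- if (is.null(init)) rep(1 / n_conf, n_conf) else init / sum(init)
  w <- if ("error" %in% names(rdcs)) 1 / rdcs$error else
    rep(1, length(pairs))
  d_obs <- rdcs$d_obs

  state <- NULL
  q_trace <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ten <- svd_fit_tensor(pool, p, rdcs)
    q_now <- q_factor(d_obs, ten$d_calc)
    if (!is.null(state) && q_now > state$q + 1e-12) {
      # reject the step; keep the previous (better) state
      converged <- TRUE
      break
    }
    state <- list(tensor = ten$tensor, cn = ten$cn, populations = p,
                  q = q_now, d_calc = ten$d_calc)
    q_trace <- c(q_trace, q_now)
    if (length(q_trace) >= 2 &&
        abs(q_trace[length(q_trace) - 1] - q_now) < tol) {
      converged <- TRUE
      break
    }
    if (n_conf == 1) {
      converged <- TRUE
      break
    }
    B <- .rdc_conformer_matrix(pool, ten$tensor, pairs)
    p_new <- .nnls_unit_sum(B, d_obs, w, lambda_sum)
    if (sum(p_new) <= 0) break
    p <- p_new / sum(p_new)
  }
  if (!converged) {
    cond <- structure(
      class = c("rdc_convergence_error", "error", "condition"),
      list(message = paste0(
        "convergence error: alternating RDC fit did not settle within ",
        max_iter, " iterations"),
        call = sys.call(-1), q_trace = q_trace))
    stop(cond)
  }
  structure(
    list(tensor = state$tensor, populations = state$populations,
         q = state$q, cn = state$cn, d_calc = state$d_calc,
         q_trace = q_trace, converged = converged,
         cn_unreliable = state$cn >= cn_limit,
         q_class = q_class(state$q)),
    class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("<rdc_fit> Q = %.3g (%s), CN = %.3g%s; %d conformers, %d populated\n",
              x$q, x$q_class, x$cn,
              if (x$cn_unreliable) " [UNRELIABLE]" else "",
              length(x$populations), sum(x$populations > 1e-6)))
  invisible(x)
}

#' Halogen-bonded population of an RDC fit
#'
#' @param fit An [fit_tensor_and_populations()] result (or a bare
#'   population vector).
#' @param xb_labels Logical vector: `TRUE` for halogen-bonded conformers.
#' @return Halogen-bonded population in percent.
#' @export
xb_population <- function(fit, xb_labels) {
  p <- if (inherits(fit, "rdc_fit")) fit$populations else fit
  if (length(xb_labels) != length(p)) {
    stop("labeling error: labels do not match the pool size", call. = FALSE)
  }
  100 * sum(p[as.logical(xb_labels)])
}
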