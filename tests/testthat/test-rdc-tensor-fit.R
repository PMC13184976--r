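test_that("design rows map Saupe components to dipolar projections", {
  # bond along z with an axial tensor: D = Szz
  row_z <- rdc_design_row(c(0, 0, 1))
  expect_equal(row_z, c(0, 1, 0, 0, 0))
  da <- 4.2
  axial <- saupe_tensor(c(-da, 2 * da, 0, 0, 0)) # Szz = 2Da, Sxx = Syy = -Da
  expect_equal(sum(row_z * axial$s), 2 * da)
  # magic-angle bond under the same axial tensor projects to zero
  th <- acos(1 / sqrt(3))
  row_m <- rdc_design_row(c(sin(th), 0, cos(th)))
  expect_equal(sum(row_m * axial$s), 0, tolerance = 1e-12)
  # even in the bond direction
  b <- c(0.3, -0.8, 0.52)
  expect_equal(rdc_design_row(b), rdc_design_row(-b))
  expect_error(rdc_design_row(c(0, 0, 0)), "degenerate")
})

test_that("saupe matrices are traceless and symmetric", {
  set.seed(5)
  for (i in 1:5) {
    m <- saupe_matrix(saupe_tensor(stats::rnorm(5)))
    expect_equal(m, t(m))
    expect_lte(abs(sum(diag(m))), 1e-12 * norm(m, "F"))
  }
})

test_that("predicted RDCs are linear in populations and tensor", {
  sim <- shared_sim()
  pool <- sim$pool
  pairs <- default_rdc_pairs(pool)
  ten <- sim$truth$tensor
  w1 <- rep(0, length(pool)); w1[1] <- 1
  w2 <- rep(0, length(pool)); w2[2] <- 1
  d1 <- predict_rdc(pool, w1, ten, pairs)
  d2 <- predict_rdc(pool, w2, ten, pairs)
  mix <- predict_rdc(pool, (w1 + w2) / 2, ten, pairs)
  expect_equal(mix, (d1 + d2) / 2)
  zero <- saupe_tensor(rep(0, 5))
  expect_equal(predict_rdc(pool, w1, zero, pairs), rep(0, length(pairs)))
})

test_that("SVD recovers a generating tensor from noiseless RDCs", {
  sim <- shared_sim()
  pool <- sim$pool
  pairs <- default_rdc_pairs(pool)
  w <- sim$truth$populations
  set.seed(31)
  for (i in 1:5) {
    s_true <- saupe_tensor(stats::rnorm(5) * 4)
    d <- predict_rdc(pool, w, s_true, pairs)
    tab <- rdc_table(pairs, d)
    fit <- svd_fit_tensor(pool, w, tab)
    expect_lte(max(abs(fit$tensor$s - s_true$s)) / max(abs(s_true$s)),
               1e-10)
    expect_gte(fit$cn, 1)
  }
})

test_that("degenerate RDC designs are rejected", {
  # five parallel bonds: rank-1 design
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.09),
               c(3, 0, 0), c(3, 0, 1.09),
               c(6, 0, 0), c(6, 0, 1.09),
               c(9, 0, 0), c(9, 0, 1.09),
               c(12, 0, 0), c(12, 0, 1.09))
  cf <- toy_conformer(xyz, elements = rep(c("C", "H"), 5))
  pool <- conformer_pool(list(cf))
  pairs <- lapply(seq(1, 9, 2), function(i) list(i, i + 1L))
  tab <- data.frame(res_i = 1L,
                    atom_i = paste0("A", seq(1, 9, 2)),
                    res_j = 1L,
                    atom_j = paste0("A", seq(2, 10, 2)),
                    d_obs = stats::rnorm(5), error = 0.5)
  expect_error(svd_fit_tensor(pool, 1, tab), "singular design")
  expect_error(svd_fit_tensor(pool, 1, tab[1:4, ]), "insufficient")
  expect_error(fit_tensor_and_populations(pool, tab[1:4, ]), "insufficient")
})

test_that("Q factor matches its closed-form toy cases", {
  expect_equal(q_factor(c(3, -4, 5), c(3, -4, 5)), 0)
  expect_equal(q_factor(c(3, -4, 5), c(0, 0, 0)), 1)
  expect_equal(q_factor(c(4, 3), c(4, 0)), 0.6)
  # scale invariance
  expect_equal(q_factor(10 * c(4, 3), 10 * c(4, 0)), 0.6)
  expect_error(q_factor(c(0, 0), c(1, 1)), "undefined Q")
  expect_error(q_factor(c(1, 2), c(1, 2, 3)), "equal length")
  expect_identical(q_class(0.005), "good")
  expect_identical(q_class(0.376), "acceptable")
  expect_identical(q_class(0.45), "poor")
})

test_that("alternating fit recovers populations and tensor without noise", {
  dp <- distinct_pool()
  pool <- dp$pool
  pairs <- default_rdc_pairs(pool)
  expect_length(pairs, 15)
  # truth concentrated on three distinct conformers
  w_true <- c(0.5, 0, 0, 0, 0.3, 0.2)
  d <- predict_rdc(pool, w_true, dp$tensor, pairs)
  tab <- rdc_table(pairs, d)
  fit <- fit_tensor_and_populations(pool, tab, tol = 1e-12,
                                    max_iter = 500)
  expect_lt(fit$q, 1e-8)
  expect_equal(fit$populations, w_true, tolerance = 1e-4)
  expect_false(fit$cn_unreliable)
  # Q trace decreases monotonically along accepted iterations
  expect_true(all(diff(fit$q_trace) <= 1e-12))
  # reconstructed order matrix stays physical
  m <- saupe_matrix(fit$tensor)
  expect_equal(m, t(m))
  expect_lte(abs(sum(diag(m))), 1e-10 * max(abs(m)))
})

test_that("a single-conformer pool reduces to the plain SVD fit", {
  dp <- distinct_pool()
  pool1 <- dp$pool[1]
  pairs <- default_rdc_pairs(pool1)
  d <- predict_rdc(pool1, 1, dp$tensor, pairs)
  fit <- fit_tensor_and_populations(pool1, rdc_table(pairs, d))
  expect_equal(fit$populations, 1)
  expect_lt(fit$q, 1e-10)
  ref <- svd_fit_tensor(pool1, 1, rdc_table(pairs, d))
  expect_equal(fit$tensor$s, ref$tensor$s, tolerance = 1e-8)
})

test_that("condition numbers at or above 30 are flagged unreliable", {
  dp <- distinct_pool()
  pool1 <- dp$pool[1]
  pairs <- default_rdc_pairs(pool1)
  d <- predict_rdc(pool1, 1, dp$tensor, pairs)
  fit <- fit_tensor_and_populations(pool1, rdc_table(pairs, d),
                                    cn_limit = 30)
  expect_identical(fit$cn_unreliable, fit$cn >= 30)
  # force the flag with an artificially low limit
  fit2 <- fit_tensor_and_populations(pool1, rdc_table(pairs, d),
                                     cn_limit = fit$cn * 0.99)
  expect_true(fit2$cn_unreliable)
})

test_that("halogen-bonded population sums the labelled conformers", {
  expect_equal(xb_population(c(1), TRUE), 100)
  expect_equal(xb_population(c(0.30, 0.70), c(TRUE, FALSE)), 30)
  expect_error(xb_population(c(0.5, 0.5), TRUE), "labeling error")
})

test_that("noiseless XB share is recovered exactly on a distinct pool", {
  dp <- distinct_pool()
  pool <- dp$pool
  sel <- xb_selectors(pool)
  xb <- vapply(pool$conformers, function(cf)
    classify_xb(cf, sel$donor, sel$acceptor,
                crit = xb_criteria(strict = FALSE)), logical(1))
  # put 40% of the truth on xb-labelled conformers
  w_true <- numeric(length(pool))
  w_true[which(xb)[1:2]] <- 0.2
  w_true[which(!xb)[1:2]] <- 0.3
  pairs <- default_rdc_pairs(pool)
  d <- predict_rdc(pool, w_true, dp$tensor, pairs)
  fit <- fit_tensor_and_populations(pool, rdc_table(pairs, d),
                                    tol = 1e-12, max_iter = 500)
  expect_equal(xb_population(fit, xb), 40, tolerance = 1e-2)
})
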