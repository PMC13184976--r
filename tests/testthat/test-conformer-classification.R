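test_that("vdW ratios reproduce the printed contact percentages", {
  expect_equal(vdw_ratio(3.02, "Br", "O")$percent, 90)
  expect_equal(vdw_ratio(3.42, "Br", "S")$percent, 94)
  expect_equal(vdw_ratio(3.05, "I", "O")$percent, 87)
  expect_equal(vdw_ratio(3.45, "I", "S")$percent, 91)
  expect_equal(vdw_ratio(3.02, "Br", "O")$raw, 100 * 3.02 / 3.37,
               tolerance = 1e-12)
  # exactly at the vdW sum the ratio is 100 for every element pair
  tab <- vdw_table()
  for (x in names(tab)) for (y in names(tab)) {
    expect_equal(vdw_ratio(vdw_sum(x, y, tab), x, y, tab)$raw, 100)
  }
  expect_error(vdw_ratio(3.0, "Xx", "O"), "table error")
  expect_error(vdw_ratio(-1, "Br", "O"), "positive")
  # the table is swappable
  tab2 <- vdw_table(I = 2.04)
  expect_equal(vdw_sum("I", "S", tab2), 3.84)
})

test_that("turn classification honours the type II' window with wrap-around", {
  cfg <- generator_config(seed = 1)
  tmpl <- build_folded_template(cfg)
  crit <- criteria_for_config(cfg)
  expect_true(classify_turn(tmpl, crit))
  # tolerance boundary: a 31 degree shift with a 30 degree window fails
  crit31 <- crit
  crit31$turn_targets[1, 2] <- crit$turn_targets[1, 2] + 31
  expect_false(classify_turn(tmpl, crit31))
  crit29 <- crit
  crit29$turn_targets[1, 2] <- crit$turn_targets[1, 2] + 29
  expect_true(classify_turn(tmpl, crit29))
  # mirror-image targets (type II turn) do not match a type II' conformer
  critII <- crit
  critII$turn_targets <- -crit$turn_targets
  expect_false(classify_turn(tmpl, critII))
  # wrap-around: targets near +/-180 treated circularly
  crit_wrap <- crit
  crit_wrap$turn_targets[1, ] <- c(175, -175)
  cf <- tmpl
  expect_silent(classify_turn(cf, crit_wrap))
})

test_that("interstrand hydrogen bonds are counted geometrically", {
  cfg <- generator_config(seed = 1)
  tmpl <- build_folded_template(cfg)
  crit <- criteria_for_config(cfg)
  expect_equal(count_interstrand_hbonds(tmpl, crit), 6L)
  # an extended strand conformer forms none
  ext <- hairpinxb:::.build_peptide(
    cfg,
    c(NA, rep(-139, 11)), rep(135, 12),
    hairpinxb:::.default_chis())
  expect_equal(count_interstrand_hbonds(ext, crit), 0L)
  expect_false(classify_folded(ext, crit))
  # displacing one strand by 5 A breaks the register
  shifted <- tmpl
  move <- tmpl$atoms$res_index >= 8
  shifted$xyz[move, ] <- shifted$xyz[move, ] +
    matrix(rep(c(0, 0, 5), each = sum(move)), ncol = 3)
  expect_lt(count_interstrand_hbonds(shifted, crit), 4L)
  expect_false(classify_folded(shifted, crit))
})

test_that("folded classification is a strict conjunction of its criteria", {
  cfg <- generator_config(seed = 1)
  tmpl <- build_folded_template(cfg)
  crit <- criteria_for_config(cfg)
  expect_true(classify_folded(tmpl, crit))
  det <- classify_folded(tmpl, crit, detail = TRUE)
  # tighten the CA-CA cutoff below the template mean: no longer folded
  crit_ca <- crit
  crit_ca$max_mean_ca_ca <- det$mean_ca_ca - 0.1
  expect_false(classify_folded(tmpl, crit_ca))
  # demand more hydrogen bonds than are geometrically present
  crit_hb <- crit
  crit_hb$hbond_max_dist <- 2.0 # only impossible bonds "count"
  expect_false(classify_folded(tmpl, crit_hb))
})

test_that("halogen-bond rule is inclusive in distance, exclusive in angle", {
  svdw <- vdw_sum("Br", "O")
  make_xb <- function(d, ang_deg) {
    a <- hairpinxb:::.deg2rad(180 - ang_deg)
    conformer(
      id = "xbtoy",
      atoms = data.frame(name = c("CD2", "X", "YD"),
                         element = c("C", "Br", "O"),
                         res_index = c(1L, 1L, 2L),
                         res_name = c("HIX", "HIX", "MEX"),
                         stringsAsFactors = FALSE),
      xyz = rbind(c(-1.89, 0, 0), c(0, 0, 0),
                  c(d * cos(a), d * sin(a), 0)))
  }
  donor <- list(atom_sel(1, "CD2"), atom_sel(1, "X"))
  acceptor <- atom_sel(2, "YD")
  # distance equal to the vdW sum counts as bonded ("equal or shorter"):
  # pin the table so the sum equals the measured distance exactly
  cf_eq <- make_xb(3.2, 150)
  d_meas <- distance(cf_eq, donor[[2]], acceptor)
  tab_eq <- vdw_table(Br = d_meas / 2, O = d_meas / 2)
  expect_true(classify_xb(cf_eq, donor, acceptor, vdw = tab_eq))
  expect_true(classify_xb(make_xb(3.02, 165.8), donor, acceptor))
  expect_false(classify_xb(make_xb(svdw + 0.01, 150), donor, acceptor))
  # an angle equal to the threshold fails the strict inequality: pin the
  # threshold to the measured angle exactly
  cf120 <- make_xb(3.0, 130)
  ang_meas <- angle(cf120, donor[[1]], donor[[2]], acceptor)
  expect_false(classify_xb(cf120, donor, acceptor,
                           crit = xb_criteria(min_angle = ang_meas)))
  expect_false(classify_xb(make_xb(3.0, 119.9), donor, acceptor))
  expect_true(classify_xb(make_xb(3.0, 120.1), donor, acceptor))
  # monotonicity: growing distance never turns a non-bond into a bond,
  # growing angle never turns a bond into a non-bond
  for (ang in c(110, 125, 140, 170)) {
    states <- vapply(seq(2.5, 4.2, 0.1), function(d)
      classify_xb(make_xb(d, ang), donor, acceptor), logical(1))
    expect_true(all(diff(as.integer(states)) <= 0))
  }
  for (d in c(2.8, 3.0, 3.3)) {
    states <- vapply(seq(95, 179, 3), function(ang)
      classify_xb(make_xb(d, ang), donor, acceptor), logical(1))
    expect_true(all(diff(as.integer(states)) >= 0))
  }
})

test_that("non-halogen donors error under strict mode, fail permissively", {
  cf <- conformer(
    id = "h", atoms = data.frame(
      name = c("CD2", "X", "YD"), element = c("C", "H", "O"),
      res_index = c(1L, 1L, 2L), res_name = c("A", "A", "B"),
      stringsAsFactors = FALSE),
    xyz = rbind(c(-1, 0, 0), c(0, 0, 0), c(2.5, 0, 0)))
  donor <- list(atom_sel(1, "CD2"), atom_sel(1, "X"))
  expect_error(classify_xb(cf, donor, atom_sel(2, "YD")),
               "classification error")
  expect_false(classify_xb(cf, donor, atom_sel(2, "YD"),
                           crit = xb_criteria(strict = FALSE)))
})

test_that("classifiers are invariant under rigid-body motion", {
  cfg <- generator_config(seed = 1)
  tmpl <- build_folded_template(cfg)
  crit <- criteria_for_config(cfg)
  sel <- xb_selectors(cfg)
  set.seed(2)
  for (i in 1:3) {
    moved <- transform_conformer(tmpl, random_rotation(),
                                 stats::rnorm(3, 0, 20))
    expect_true(classify_folded(moved, crit))
    expect_equal(count_interstrand_hbonds(moved, crit),
                 count_interstrand_hbonds(tmpl, crit))
    expect_identical(classify_xb(moved, sel$donor, sel$acceptor),
                     classify_xb(tmpl, sel$donor, sel$acceptor))
  }
})

test_that("pool classification returns one labelled row per conformer", {
  sim <- shared_sim()
  cfg <- generator_config(seed = 42, n_folded = 4, n_unfolded = 4)
  sel <- xb_selectors(sim$pool)
  tab <- classify_pool(sim$pool, criteria_for_config(cfg),
                       donor = sel$donor, acceptor = sel$acceptor,
                       xb_crit = xb_criteria(strict = FALSE))
  expect_equal(nrow(tab), length(sim$pool))
  expect_true(all(c("folded", "n_hbonds", "xb", "xb_vdw_percent") %in%
                    names(tab)))
  expect_identical(tab$folded, sim$truth$folded_labels)
})
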