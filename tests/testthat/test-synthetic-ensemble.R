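test_that("folded template satisfies turn, register and contact criteria", {
  cfg <- generator_config(seed = 1)
  tmpl <- build_folded_template(cfg)
  crit <- criteria_for_config(cfg)
  det <- classify_folded(tmpl, crit, detail = TRUE)
  expect_true(det$folded)
  expect_equal(det$n_hbonds, 6L)
  expect_lte(det$mean_ca_ca, 6.0)
  # D-Pro phi sits at the canonical type II' value
  expect_equal(phi_angle(tmpl, cfg$turn_position), 60, tolerance = 1e-6)
  expect_equal(psi_angle(tmpl, cfg$turn_position), -120, tolerance = 1e-6)
  # Br donor / O acceptor side chains posed at contact
  sel <- xb_selectors(cfg)
  expect_true(classify_xb(tmpl, sel$donor, sel$acceptor))
  # geminal Gly methylene pair provides the 1.78 A calibration distance
  gly <- cfg$turn_position + 1L
  expect_equal(distance(tmpl, atom_sel(gly, "HA1"), atom_sel(gly, "HA2")),
               1.78, tolerance = 0.01)
})

test_that("impossible generator configurations are rejected", {
  expect_error(generator_config(n_residues = 5), "construction error")
  expect_error(generator_config(n_residues = 12, turn_position = 5),
               "construction error")
  expect_error(generator_config(n_folded = -1), ">= 0")
  expect_error(generator_config(donor_element = "F"), "arg")
})

test_that("sample_pool is a pure function of the seed", {
  cfg <- generator_config(seed = 21, n_folded = 3, n_unfolded = 3)
  a <- sample_pool(cfg)
  b <- sample_pool(cfg)
  expect_identical(lapply(a$pool$conformers, `[[`, "xyz"),
                   lapply(b$pool$conformers, `[[`, "xyz"))
  expect_identical(a$truth, b$truth)
  expect_error(sample_pool(generator_config(n_folded = 2, n_unfolded = 0)),
               "seed")
})

test_that("generator labels agree with the classifiers applied post hoc", {
  sim <- shared_sim()
  cfg <- generator_config(seed = 42, n_folded = 4, n_unfolded = 4)
  crit <- criteria_for_config(cfg)
  cls <- classify_pool(sim$pool, crit)
  expect_identical(cls$folded, sim$truth$folded_labels)
  sel <- xb_selectors(sim$pool)
  xb <- vapply(sim$pool$conformers, function(cf)
    classify_xb(cf, sel$donor, sel$acceptor,
                crit = xb_criteria(strict = FALSE)), logical(1))
  expect_identical(xb, sim$truth$xb_labels)
  # truth populations are a normalized two-state mixture
  expect_equal(sum(sim$truth$populations), 1)
  expect_true(all(sim$truth$populations >= 0))
  expect_equal(sum(sim$truth$populations[sim$truth$folded_labels]), 0.5)
})

test_that("degenerate generator settings behave as documented", {
  # no folded conformers requested: none classify folded
  cfg0 <- generator_config(seed = 5, n_folded = 0, n_unfolded = 3)
  sim0 <- sample_pool(cfg0)
  cls <- classify_pool(sim0$pool, criteria_for_config(cfg0))
  expect_false(any(cls$folded))
  # zero jitter: all folded copies coincide with the template
  cfgj <- generator_config(seed = 6, n_folded = 3, n_unfolded = 0,
                           dihedral_jitter = 0)
  simj <- sample_pool(cfgj)
  expect_equal(heavy_atom_rmsd(simj$pool[[1]], simj$pool[[2]]), 0,
               tolerance = 1e-12)
  expect_equal(heavy_atom_rmsd(simj$pool[[1]], simj$pool[[3]]), 0,
               tolerance = 1e-12)
})

test_that("XB enrichment appends only constraint-satisfying conformers", {
  cfg <- generator_config(seed = 4, n_folded = 3, n_unfolded = 3)
  sim <- sample_pool(cfg)
  pool2 <- enrich_with_xb_conformers(sim$pool, cfg, n = 5, seed = 77)
  expect_equal(length(pool2), length(sim$pool) + 5)
  sel <- xb_selectors(pool2)
  svdw <- vdw_sum(cfg$donor_element, cfg$acceptor_element)
  for (k in (length(sim$pool) + 1):length(pool2)) {
    cf <- pool2[[k]]
    expect_true("xb_constrained" %in% cf$labels)
    expect_true(classify_xb(cf, sel$donor, sel$acceptor))
    expect_lte(distance(cf, sel$donor[[2]], sel$acceptor), svdw)
    expect_gt(angle(cf, sel$donor[[1]], sel$donor[[2]], sel$acceptor), 120)
  }
  # appended poses are mutually distinct
  for (k in 7:10) {
    expect_gt(heavy_atom_rmsd(pool2[[k]], pool2[[k + 1]]), 0.1)
  }
  # a donor without a sigma hole cannot be enriched
  cfg_h <- generator_config(seed = 4, donor_element = "H")
  expect_error(enrich_with_xb_conformers(sim$pool, cfg_h, n = 2, seed = 1),
               "enrichment error")
})

test_that("redundancy pruning removes near-duplicates at the 1.5 A cutoff", {
  cfgj <- generator_config(seed = 6, n_folded = 3, n_unfolded = 0,
                           dihedral_jitter = 0)
  simj <- sample_pool(cfgj)   # three identical folded copies
  pruned <- prune_redundant(simj$pool, cutoff = 1.5)
  expect_equal(length(pruned), 1)
})

test_that("noiseless simulated observables are exact forward-model values", {
  sim <- shared_sim()
  obs <- simulate_observables(sim$pool, sim$truth,
                              noise = noise_levels(0, 0, 0), seed = 31)
  # seven mixing times spanning 100-700 ms
  icols <- grep("^I_\\d+$", names(obs$noe), value = TRUE)
  expect_equal(sort(as.integer(sub("I_", "", icols))),
               seq(100L, 700L, 100L))
  # buildup slopes decode to the population-averaged effective distances
  noe_d <- noe_distances_from_buildups(obs$noe)
  for (i in seq_len(nrow(noe_d))) {
    pair <- list(atom_sel(noe_d$res_i[i], noe_d$atom_i[i]),
                 atom_sel(noe_d$res_j[i], noe_d$atom_j[i]))
    expect_equal(noe_d$r_obs[i],
                 predict_noe_distance(sim$pool, sim$truth$populations, pair),
                 tolerance = 1e-9)
  }
  # J table equals the population-averaged Karplus forward model
  for (i in seq_len(nrow(obs$j))) {
    expect_equal(obs$j$j_obs[i],
                 predict_j(sim$pool, sim$truth$populations,
                           obs$j$residue[i]),
                 tolerance = 1e-12)
  }
  # RDC table equals the Saupe projection, and T_strong - T_weak encodes it
  pairs <- default_rdc_pairs(sim$pool)
  expect_equal(obs$rdc$d_obs,
               predict_rdc(sim$pool, sim$truth$populations,
                           sim$truth$tensor, pairs),
               tolerance = 1e-12)
  expect_equal(rdc_from_couplings(obs$rdc$t_strong, obs$rdc$t_weak),
               obs$rdc$d_obs, tolerance = 1e-12)
})

test_that("observable simulation is deterministic and validates noise", {
  sim <- shared_sim()
  a <- simulate_observables(sim$pool, sim$truth, seed = 12)
  b <- simulate_observables(sim$pool, sim$truth, seed = 12)
  expect_identical(a, b)
  c <- simulate_observables(sim$pool, sim$truth, seed = 13)
  expect_false(identical(a$j$j_obs, c$j$j_obs))
  expect_error(noise_levels(noe_rate = -0.1), "config error")
  expect_error(simulate_observables(sim$pool,
                                    list(populations = c(1),
                                         tensor = sim$truth$tensor),
                                    seed = 1),
               "match the pool")
})

test_that("simulated RDCs span the experimentally observed magnitude", {
  sim <- shared_sim()
  obs <- simulate_observables(sim$pool, sim$truth,
                              noise = noise_levels(0, 0, 0), seed = 2)
  expect_lte(max(abs(obs$rdc$d_obs)), 13 + 1e-6)
  expect_gt(max(abs(obs$rdc$d_obs)), 3)
})
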