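test_that("distance matches hand geometry and is symmetric", {
  cf <- toy_conformer(rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1)))
  expect_equal(distance(cf, 1, 2), 5.0)
  expect_equal(distance(cf, 1, 1), 0.0)
  expect_equal(distance(cf, 1, 3), sqrt(3))
  expect_equal(distance(cf, 2, 1), distance(cf, 1, 2))
  expect_equal(distance(cf, c(1, "A1"), c(1, "A2")), 5.0)
  expect_error(distance(cf, c(2, "A1"), 1), "selection error")
})

test_that("vertex angles cover collinear, right-angle and equilateral cases", {
  col <- toy_conformer(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(angle(col, 1, 2, 3), 180)
  right <- toy_conformer(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(angle(right, 1, 2, 3), 90)
  eq <- toy_conformer(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  expect_equal(angle(eq, 1, 2, 3), 60)
  dup <- toy_conformer(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(angle(dup, 1, 2, 3), "degenerate")
})

test_that("dihedrals follow the IUPAC convention and flip under mirroring", {
  cis <- toy_conformer(rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)))
  expect_equal(dihedral(cis, 1, 2, 3, 4), 0)
  trans <- toy_conformer(rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                               c(2, -1, 0)))
  expect_equal(abs(dihedral(trans, 1, 2, 3, 4)), 180)
  skew <- toy_conformer(rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                              c(2, 0.5, 0.8)))
  d1 <- dihedral(skew, 1, 2, 3, 4)
  mirror <- skew
  mirror$xyz[, 3] <- -mirror$xyz[, 3]
  expect_equal(dihedral(mirror, 1, 2, 3, 4), -d1)
  lin <- toy_conformer(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)))
  expect_error(dihedral(lin, 1, 2, 3, 4), "degenerate")
})

test_that("geometry is invariant under rigid-body transforms", {
  set.seed(11)
  cf <- toy_conformer(matrix(stats::rnorm(15), 5, 3))
  for (rep in 1:5) {
    moved <- transform_conformer(cf, random_rotation(), stats::rnorm(3, 0, 10))
    expect_equal(distance(moved, 1, 2), distance(cf, 1, 2))
    expect_equal(angle(moved, 1, 2, 3), angle(cf, 1, 2, 3))
    expect_equal(dihedral(moved, 1, 2, 3, 4), dihedral(cf, 1, 2, 3, 4))
  }
})

test_that("heavy-atom RMSD: identity, rigid motion, symmetry, hand formula", {
  set.seed(3)
  xyz <- matrix(stats::rnorm(18, sd = 2), 6, 3)
  c1 <- toy_conformer(xyz, elements = c("C", "C", "N", "O", "H", "C"))
  expect_equal(heavy_atom_rmsd(c1, c1), 0)
  moved <- transform_conformer(c1, random_rotation(), c(5, -3, 2))
  expect_equal(heavy_atom_rmsd(c1, moved, superpose = TRUE), 0,
               tolerance = 1e-10)
  expect_gt(heavy_atom_rmsd(c1, moved, superpose = FALSE), 1)
  # hand-computable: no superposition, known displacement on heavy atoms
  c2 <- c1
  c2$xyz[1, ] <- c2$xyz[1, ] + c(1, 0, 0)    # heavy
  c2$xyz[5, ] <- c2$xyz[5, ] + c(9, 9, 9)    # hydrogen, must be ignored
  direct <- sqrt(sum(rowSums((c1$xyz[c(1:4, 6), ] -
                                c2$xyz[c(1:4, 6), ])^2)) / 5)
  expect_equal(heavy_atom_rmsd(c1, c2, superpose = FALSE), direct)
  expect_equal(heavy_atom_rmsd(c2, c1, superpose = FALSE),
               heavy_atom_rmsd(c1, c2, superpose = FALSE))
  expect_lte(heavy_atom_rmsd(c1, c2, superpose = TRUE),
             heavy_atom_rmsd(c1, c2, superpose = FALSE))
})

test_that("superposed RMSD agrees with an independent reference (bio3d)", {
  set.seed(8)
  c1 <- toy_conformer(matrix(stats::rnorm(24, sd = 3), 8, 3))
  c2 <- toy_conformer(c1$xyz + matrix(stats::rnorm(24, sd = 0.6), 8, 3))
  ours <- heavy_atom_rmsd(c1, c2, superpose = TRUE)
  ref <- bio3d::rmsd(as.numeric(t(c1$xyz)), as.numeric(t(c2$xyz)),
                     fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("multi-model PDB round trip preserves topology, coordinates, labels", {
  sim <- shared_sim()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_conformer_pool(sim$pool, path)
  back <- read_conformer_pool(path)
  expect_equal(length(back), length(sim$pool))
  expect_identical(pool_ids(back), pool_ids(sim$pool))
  expect_identical(back[[1]]$atoms$name, sim$pool[[1]]$atoms$name)
  expect_identical(back[[1]]$atoms$element, sim$pool[[1]]$atoms$element)
  expect_identical(pool_has_label(back, "folded"),
                   pool_has_label(sim$pool, "folded"))
  for (k in seq_len(length(back))) {
    expect_equal(back[[k]]$xyz, sim$pool[[k]]$xyz, tolerance = 1e-3)
  }
  # second read of the written file is byte-stable
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_conformer_pool(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("PDB parser enforces topology and reports malformed records", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.000   0.000   1.000  1.00  0.00           N",
    "ENDMDL")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_error(read_conformer_pool(path), "topology error")
  bad <- lines[1:4]
  bad[3] <- "ATOM      2  CA  ALA A   1       xxxxx   0.000   0.000"
  writeLines(bad, path)
  expect_error(read_conformer_pool(path), "line 3")
  # 2-model file parses to 2 conformers with shared topology
  ok <- c(lines[1:4],
          "MODEL        2",
          "ATOM      1  N   ALA A   1       0.000   0.000   1.000  1.00  0.00           N",
          "ATOM      2  CA  ALA A   1       1.458   0.000   1.000  1.00  0.00           C",
          "ENDMDL")
  writeLines(ok, path)
  pool <- read_conformer_pool(path)
  expect_equal(length(pool), 2)
  expect_equal(nrow(pool[[1]]$atoms), 2)
  # element falls back to the atom name when columns 77-78 are blank
  noelem <- c("MODEL        1",
              "ATOM      1  BR1 XBD A   1       0.000   0.000   0.000",
              "ATOM      2  CA  XBD A   1       1.900   0.000   0.000",
              "ATOM      3  CB  XBD A   1       2.900   1.000   0.000",
              "ENDMDL")
  writeLines(noelem, path)
  pool <- read_conformer_pool(path)
  expect_identical(pool[[1]]$atoms$element, c("Br", "C", "C"))
})

test_that("XYZ frames read as a pool; truncated frames are rejected", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "id=frame_a", "C 0 0 0", "O 1.2 0 0", "H -0.5 0.9 0"),
             path)
  pool <- read_conformer_pool(path)
  expect_equal(length(pool), 1)
  expect_identical(pool[[1]]$id, "frame_a")
  expect_equal(pool[[1]]$xyz[2, 1], 1.2)
  writeLines(c("4", "comment", "C 0 0 0", "O 1 0 0"), path)
  expect_error(read_conformer_pool(path), "truncated")
})

test_that("pools reject inconsistent members and duplicate ids", {
  c1 <- toy_conformer(rbind(c(0, 0, 0), c(1, 0, 0)), id = "a")
  c2 <- toy_conformer(rbind(c(0, 0, 0), c(2, 0, 0)), id = "a")
  expect_error(conformer_pool(list(c1, c2)), "unique")
  c3 <- toy_conformer(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), id = "b")
  expect_error(conformer_pool(list(c1, c3)), "topology")
  expect_error(conformer_pool(list()), "non-empty")
})
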