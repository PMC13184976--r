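# Synthetic beta-hairpin ensemble generator.
#
# Emits toy dodecapeptide conformers built in torsion space (NeRF chain
# extension with ideal bond lengths/angles): a folded template with a
# central D-Pro--Gly type II' turn and cross-strand donor/acceptor side
# chains, jittered folded copies, unfolded strand-torsion conformers, and
# halogen-bond-constrained enrichments, plus forward-simulated NOE/J/RDC
# observables with known ground truth.

# ideal covalent geometry (Angstrom / degrees)
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.01, b_ca_ha = 1.09,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8)

.halogen_bond_length <- function(elem) {
  switch(elem, Br = 1.89, I = 2.09, H = 1.08,
         stop("unsupported donor element: ", elem, call. = FALSE))
}

.acceptor_bond_length <- function(elem) {
  switch(elem, O = 1.42, S = 1.81, C = 1.53,
         stop("unsupported acceptor element: ", elem, call. = FALSE))
}

#' Generator configuration for the synthetic hairpin ensemble
#'
#' Defines the toy model system: a 12-residue peptide with a central
#' D-Pro--Gly type II' turn, a sigma-hole donor side chain (halogenated
#' imidazole) and a Lewis-base acceptor side chain (ether/thioether chain)
#' on the cross-strand pair two positions away from the turn. The
#' reference compound without a halogen bond is obtained with
#' `donor_element = "H"` and/or `acceptor_element = "C"`.
#'
#' @param n_residues Peptide length; must equal `2 * turn_position`
#'   (default 12).
#' @param turn_position Residue index of the D-Pro (first turn residue;
#'   default 6).
#' @param n_folded,n_unfolded Conformer counts for [sample_pool()]
#'   (defaults 10 / 10).
#' @param folded_fraction Ground-truth population of the folded state
#'   (default 0.5).
#' @param dihedral_jitter Gaussian jitter (degrees, sd) applied to strand
#'   backbone torsions of folded copies (default 5).
#' @param seed Integer seed; mandatory for any stochastic operation.
#' @param donor_element Halogen-bond donor element: `"Br"`, `"I"`, or
#'   `"H"` for the reference compound (default `"Br"`).
#' @param acceptor_element Acceptor element: `"O"`, `"S"`, or `"C"` for
#'   the reference compound (default `"O"`).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_residues = 12L, turn_position = 6L,
                             n_folded = 10L, n_unfolded = 10L,
                             folded_fraction = 0.5,
                             dihedral_jitter = 5,
                             seed = NULL,
                             donor_element = c("Br", "I", "H"),
                             acceptor_element = c("O", "S", "C")) {
  donor_element <- match.arg(donor_element)
  acceptor_element <- match.arg(acceptor_element)
  n_residues <- as.integer(n_residues)
  turn_position <- as.integer(turn_position)
  if (n_residues < 6 || turn_position < 4 ||
      n_residues != 2L * turn_position) {
    stop("construction error: need n_residues = 2 * turn_position with ",
         "turn_position >= 4", call. = FALSE)
  }
  if (n_folded < 0 || n_unfolded < 0) {
    stop("conformer counts must be >= 0", call. = FALSE)
  }
  if (folded_fraction < 0 || folded_fraction > 1) {
    stop("folded_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (dihedral_jitter < 0) {
    stop("dihedral_jitter must be >= 0", call. = FALSE)
  }
  structure(
    list(n_residues = n_residues, turn_position = turn_position,
         n_folded = as.integer(n_folded), n_unfolded = as.integer(n_unfolded),
         folded_fraction = folded_fraction,
         dihedral_jitter = dihedral_jitter, seed = seed,
         donor_element = donor_element, acceptor_element = acceptor_element,
         donor_residue = turn_position - 2L,
         acceptor_residue = turn_position + 3L),
    class = "generator_config")
}

.require_seed <- function(seed) {
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("a seed is mandatory for stochastic generator operations",
         call. = FALSE)
  }
  as.integer(seed)
}

# Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Hairpin classification criteria matching a generator configuration
#'
#' Derives the turn residues, cross-strand CA pair register and the six
#' designated interstrand hydrogen-bond pairs from the peptide layout.
#'
#' @param cfg A [generator_config()].
#' @return A [hairpin_criteria()] object.
#' @export
criteria_for_config <- function(cfg) {
  t <- cfg$turn_position
  n <- cfg$n_residues
  n_pairs <- t - 1L
  ca_pairs <- cbind(seq_len(n_pairs), rev((t + 2L):n))
  hb <- list()
  k <- t - 1L
  while (k >= 1L) {
    partner <- t + 2L + (t - 1L - k)
    hb[[length(hb) + 1L]] <- c(k, partner)
    hb[[length(hb) + 1L]] <- c(partner, k)
    k <- k - 2L
  }
  hbond_pairs <- do.call(rbind, hb)
  hairpin_criteria(
    turn_residues = c(t, t + 1L),
    ca_pairs = ca_pairs,
    hbond_pairs = hbond_pairs,
    min_hbonds = max(1L, nrow(hbond_pairs) - 2L))
}

#' Halogen-bond donor/acceptor selectors for a generated pool
#'
#' @param x A [generator_config()] or a generated [conformer_pool] /
#'   [conformer].
#' @return List with `donor` (list of C and X selectors) and `acceptor`
#'   (Y selector), as consumed by [classify_xb()].
#' @export
xb_selectors <- function(x) {
  if (inherits(x, "generator_config")) {
    dres <- x$donor_residue
    ares <- x$acceptor_residue
  } else {
    cf <- if (inherits(x, "conformer_pool")) x[[1]] else x
    dres <- unique(cf$atoms$res_index[cf$atoms$name == "X"])
    ares <- unique(cf$atoms$res_index[cf$atoms$name == "YD"])
    if (length(dres) != 1 || length(ares) != 1) {
      stop("selection error: pool has no unique donor/acceptor side chain",
           call. = FALSE)
    }
  }
  list(donor = list(atom_sel(dres, "CD2"), atom_sel(dres, "X")),
       acceptor = atom_sel(ares, "YD"))
}

# ---- torsion-space construction --------------------------------------------

# residue layout table for a config
.layout <- function(cfg) {
  n <- cfg$n_residues
  res_name <- rep("ALA", n)
  res_name[cfg$turn_position] <- "DPR"
  res_name[cfg$turn_position + 1L] <- "GLY"
  res_name[cfg$donor_residue] <- "HIX"
  res_name[cfg$acceptor_residue] <- "MEX"
  res_name
}

# canonical torsions: antiparallel beta strands, type II' turn at (t, t+1)
.canonical_torsions <- function(cfg) {
  n <- cfg$n_residues
  t <- cfg$turn_position
  phi <- rep(-139, n)
  psi <- rep(135, n)
  phi[t] <- 60; psi[t] <- -120     # D-Pro, i+1 of the turn
  phi[t + 1L] <- -80; psi[t + 1L] <- 0 # Gly, i+2
  phi[1] <- NA                      # undefined at the N terminus
  list(phi = phi, psi = psi)
}

.default_chis <- function() {
  list(donor = c(chi1 = -60, chi2 = 90),
       acceptor = c(chi1 = -60, chi2 = 180, chi3 = 70))
}

# Build the full toy peptide from torsions. Returns a conformer.
.build_peptide <- function(cfg, phi, psi, chis, id = "template",
                           labels = character()) {
  n <- cfg$n_residues
  res_name <- .layout(cfg)
  g <- .BB
  name <- character(); element <- character()
  res_index <- integer(); rnames <- character()
  xyz <- list()
  add <- function(res, nm, el, p) {
    name[[length(name) + 1L]] <<- nm
    element[[length(element) + 1L]] <<- el
    res_index[[length(res_index) + 1L]] <<- res
    rnames[[length(rnames) + 1L]] <<- res_name[[res]]
    xyz[[length(xyz) + 1L]] <<- p
  }
  # backbone trace
  N <- CA <- C <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  th <- .deg2rad(g$a_n_ca_c)
  C[[1]] <- CA[[1]] + g$b_ca_c * c(cos(pi - th), sin(pi - th), 0)
  for (i in 2:n) {
    N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                          g$b_c_n, g$a_ca_c_n, psi[[i - 1]])
    CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                           g$b_n_ca, g$a_c_n_ca, 180)
    C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]],
                          g$b_ca_c, g$a_n_ca_c, phi[[i]])
  }
  for (i in 1:n) {
    O[[i]] <- .place_atom(N[[i]], CA[[i]], C[[i]],
                          g$b_c_o, g$a_ca_c_o, psi[[i]] + 180)
  }
  for (i in 1:n) {
    add(i, "N", "N", N[[i]])
    if (res_name[[i]] != "DPR") {
      h <- if (i == 1) {
        .place_atom(C[[1]], CA[[1]], N[[1]], g$b_n_h, 118, 180)
      } else {
        N[[i]] + g$b_n_h * .unit(.unit(N[[i]] - C[[i - 1]]) +
                                 .unit(N[[i]] - CA[[i]]))
      }
      add(i, "H", "H", h)
    }
    add(i, "CA", "C", CA[[i]])
    td <- .tetra_dirs(N[[i]], CA[[i]], C[[i]])
    has_sidechain <- res_name[[i]] %in% c("HIX", "MEX")
    if (res_name[[i]] == "GLY") {
      add(i, "HA1", "H", CA[[i]] + g$b_ca_ha * td$d1)
      add(i, "HA2", "H", CA[[i]] + g$b_ca_ha * td$d2)
    } else if (has_sidechain) {
      add(i, "HA", "H", CA[[i]] + g$b_ca_ha * td$d2)
    } else {
      add(i, "HA", "H", CA[[i]] + g$b_ca_ha * td$d1)
    }
    if (res_name[[i]] == "HIX") {
      ch <- chis$donor
      CB <- CA[[i]] + 1.53 * td$d1
      CG <- .place_atom(N[[i]], CA[[i]], CB, 1.50, 113.8, ch[["chi1"]])
      ND1 <- .place_atom(CA[[i]], CB, CG, 1.38, 122, ch[["chi2"]])
      CE1 <- .place_atom(CB, CG, ND1, 1.32, 108, 180)
      NE2 <- .place_atom(CG, ND1, CE1, 1.35, 108, 0)
      CD2 <- .place_atom(ND1, CE1, NE2, 1.35, 108, 0)
      X <- .place_atom(CE1, NE2, CD2,
                       .halogen_bond_length(cfg$donor_element), 126, 180)
      tb <- .tetra_dirs(CA[[i]], CB, CG)
      add(i, "CB", "C", CB)
      add(i, "HB1", "H", CB + 1.09 * tb$d1)
      add(i, "HB2", "H", CB + 1.09 * tb$d2)
      add(i, "CG", "C", CG)
      add(i, "ND1", "N", ND1)
      add(i, "CE1", "C", CE1)
      add(i, "HE1", "H",
          CE1 + 1.08 * .unit(.unit(CE1 - ND1) + .unit(CE1 - NE2)))
      add(i, "NE2", "N", NE2)
      add(i, "CD2", "C", CD2)
      add(i, "X", cfg$donor_element, X)
    } else if (res_name[[i]] == "MEX") {
      ch <- chis$acceptor
      bl <- .acceptor_bond_length(cfg$acceptor_element)
      CB <- CA[[i]] + 1.53 * td$d1
      CG <- .place_atom(N[[i]], CA[[i]], CB, 1.53, 114, ch[["chi1"]])
      Y <- .place_atom(CA[[i]], CB, CG, bl, 112, ch[["chi2"]])
      ange <- if (cfg$acceptor_element == "S") 100 else 112
      CE <- .place_atom(CB, CG, Y, bl, ange, ch[["chi3"]])
      tb <- .tetra_dirs(CA[[i]], CB, CG)
      tg <- .tetra_dirs(CB, CG, Y)
      add(i, "CB", "C", CB)
      add(i, "HB1", "H", CB + 1.09 * tb$d1)
      add(i, "HB2", "H", CB + 1.09 * tb$d2)
      add(i, "CG", "C", CG)
      add(i, "HG1", "H", CG + 1.09 * tg$d1)
      add(i, "HG2", "H", CG + 1.09 * tg$d2)
      add(i, "YD", cfg$acceptor_element, Y)
      add(i, "CE", "C", CE)
      add(i, "HE1", "H", .place_atom(CG, Y, CE, 1.09, 109.5, 180))
    }
    add(i, "C", "C", C[[i]])
    add(i, "O", "O", O[[i]])
  }
  conformer(
    id = id,
    atoms = data.frame(name = name, element = element,
                       res_index = res_index, res_name = rnames,
                       stringsAsFactors = FALSE),
    xyz = do.call(rbind, xyz), labels = labels)
}

# hydrogen-bond register objective used to refine strand torsions:
# forms the six designated N-H...O=C bonds while holding the paired
# CA-CA spacing at sheet-like values and keeping the backbone clash-free
.hbond_objective <- function(cfg, crit, free_idx_phi, free_idx_psi,
                             phi0, psi0) {
  chis <- .default_chis()
  function(par) {
    phi <- phi0; psi <- psi0
    phi[free_idx_phi] <- par[seq_along(free_idx_phi)]
    psi[free_idx_psi] <- par[length(free_idx_phi) + seq_along(free_idx_psi)]
    cf <- try(.build_peptide(cfg, phi, psi, chis), silent = TRUE)
    if (inherits(cf, "try-error")) return(1e6)
    val <- 0
    for (k in seq_len(nrow(crit$hbond_pairs))) {
      don <- crit$hbond_pairs[k, 1]; acc <- crit$hbond_pairs[k, 2]
      d <- distance(cf, atom_sel(don, "N"), atom_sel(acc, "O"))
      val <- val + (d - 2.9)^2
      if (.layout(cfg)[don] != "DPR") {
        ang <- angle(cf, atom_sel(don, "N"), atom_sel(don, "H"),
                     atom_sel(acc, "O"))
        val <- val + 0.002 * max(0, 155 - ang)^2
      }
    }
    # paired CA-CA spacing of an antiparallel sheet
    for (k in seq_len(nrow(crit$ca_pairs))) {
      d <- distance(cf, atom_sel(crit$ca_pairs[k, 1], "CA"),
                    atom_sel(crit$ca_pairs[k, 2], "CA"))
      val <- val + 0.25 * (d - 5.0)^2
    }
    # steric term over backbone heavy atoms of non-adjacent residues
    bb <- cf$atoms$name %in% c("N", "CA", "C", "O")
    xyz <- cf$xyz[bb, , drop = FALSE]
    res <- cf$atoms$res_index[bb]
    dmat <- as.matrix(stats::dist(xyz))
    far <- abs(outer(res, res, "-")) >= 2 & upper.tri(dmat)
    val <- val + 2 * sum(pmax(0, 3.0 - dmat[far])^2)
    # keep strand torsions in the beta basin
    dev <- c(abs(phi[free_idx_phi] - phi0[free_idx_phi]),
             abs(psi[free_idx_psi] - psi0[free_idx_psi]))
    val + 1e-4 * sum(pmax(0, dev - 60)^2)
  }
}

# halogen-bond contact objective for the side-chain torsions: pose
# d(X...Y) at the target contact with a near-linear C-X...Y angle while
# keeping the side chains off the rest of the peptide
.contact_objective <- function(cfg, phi, psi, sel, target_d) {
  side_res <- c(cfg$donor_residue, cfg$acceptor_residue)
  function(par) {
    chis <- list(donor = c(chi1 = par[1], chi2 = par[2]),
                 acceptor = c(chi1 = par[3], chi2 = par[4], chi3 = par[5]))
    cf <- try(.build_peptide(cfg, phi, psi, chis), silent = TRUE)
    if (inherits(cf, "try-error")) return(1e6)
    d <- distance(cf, sel$donor[[2]], sel$acceptor)
    ang <- angle(cf, sel$donor[[1]], sel$donor[[2]], sel$acceptor)
    val <- (d - target_d)^2 + 0.002 * max(0, 160 - ang)^2
    # steric term: side-chain heavy atoms vs heavy atoms of other residues
    heavy <- which(!(cf$atoms$element %in% c("H", "D")))
    res <- cf$atoms$res_index[heavy]
    is_side <- res %in% side_res &
      !(cf$atoms$name[heavy] %in% c("N", "CA", "C", "O"))
    xyz <- cf$xyz[heavy, , drop = FALSE]
    for (i in which(is_side)) {
      others <- which(res != res[i])
      dd <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - xyz[i, ])^2))
      xy_pair <- (cf$atoms$name[heavy][i] %in% c("X", "YD")) &
        (cf$atoms$name[heavy][others] %in% c("X", "YD"))
      val <- val + 0.5 * sum(pmax(0, 2.8 - dd[!xy_pair])^2)
    }
    val
  }
}

.template_cache <- new.env(parent = emptyenv())

# Idealized template torsions for the default 12-residue layout (turn at
# 6/7): strand torsions refined once, by the quasi-Newton pass below,
# from canonical antiparallel-beta starting values so that all six
# designated interstrand hydrogen bonds form around the type II' turn;
# side-chain torsions posed at van der Waals contact per element pair.
.IDEAL12 <- list(
  phi = c(NA, -110.946, -96.7605, -109.654, -146.4387, 60, -80,
          -104.873, -150.0438, -119.7864, -123.7154, -125.6125),
  psi = c(145.8616, 80.0567, 107.4883, 123.3571, 77.9315, -120, 0,
          144.7663, 124.9441, 139.57, 130.6164, 62.5465),
  contact_chis = list(
    `Br|O` = c(72.3334, 69.9209, -68.6889, -45.4988, 195.6987),
    `Br|S` = c(72.9592, 72.1486, -62.5403, -59.3902, 214.6392),
    `I|O` = c(74.4730, 68.0697, -69.5429, -39.1836, 192.7614),
    `I|S` = c(74.7417, 69.0487, -63.2623, -48.6685, 199.4003)))

.chis_from_par <- function(par) {
  list(donor = c(chi1 = par[1], chi2 = par[2]),
       acceptor = c(chi1 = par[3], chi2 = par[4], chi3 = par[5]))
}

#' Build the idealized folded hairpin template
#'
#' Constructs the peptide in torsion space at canonical type II' turn
#' torsions, (+60, -120) for the D-Pro and (-80, 0) for the Gly, with
#' strand residues started at antiparallel beta values and refined by a
#' deterministic quasi-Newton pass so that the six designated interstrand
#' amide hydrogen bonds are formed. Donor and acceptor side-chain
#' torsions are then posed at van der Waals contact (for a halogen
#' donor). The result passes [classify_folded()] by construction; it
#' passes [classify_xb()] when the donor is Br or I.
#'
#' @param cfg A [generator_config()].
#' @return A [conformer] labelled `"folded"` (and `"xb"` when posed at
#'   contact).
#' @export
build_folded_template <- function(cfg) {
  key <- paste(cfg$n_residues, cfg$turn_position, cfg$donor_element,
               cfg$acceptor_element, sep = "|")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  crit <- criteria_for_config(cfg)
  t <- cfg$turn_position
  strand <- setdiff(seq_len(cfg$n_residues), c(t, t + 1L))
  free_phi <- setdiff(strand, 1L)
  free_psi <- strand
  default_layout <- cfg$n_residues == 12L && cfg$turn_position == 6L
  if (default_layout) {
    phi <- .IDEAL12$phi
    psi <- .IDEAL12$psi
  } else {
    tor <- .canonical_torsions(cfg)
    obj <- .hbond_objective(cfg, crit, free_phi, free_psi, tor$phi,
                            tor$psi)
    par0 <- c(tor$phi[free_phi], tor$psi[free_psi])
    opt <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    phi <- tor$phi; psi <- tor$psi
    phi[free_phi] <- opt$par[seq_along(free_phi)]
    psi[free_psi] <- opt$par[length(free_phi) + seq_along(free_psi)]
  }

  halogen_pair <- cfg$donor_element %in% c("Br", "I") &&
    cfg$acceptor_element %in% c("O", "S")
  ckey <- paste(cfg$donor_element, cfg$acceptor_element, sep = "|")
  labels <- "folded"
  sel <- xb_selectors(cfg)
  if (default_layout && halogen_pair) {
    chis <- .chis_from_par(.IDEAL12$contact_chis[[ckey]])
    labels <- c(labels, "xb")
  } else if (default_layout) {
    # reference compound: same side-chain pose as the halogenated
    # analogue, no sigma-hole donor
    chis <- .chis_from_par(.IDEAL12$contact_chis[["Br|O"]])
  } else if (halogen_pair) {
    target <- 0.9 * vdw_sum(cfg$donor_element, cfg$acceptor_element)
    cobj <- .contact_objective(cfg, phi, psi, sel, target)
    starts <- list(c(-60, 90, -60, 180, 70), c(72, 70, -69, -45, 190),
                   c(180, 90, -60, -60, 180), c(-60, -90, 180, 60, -60),
                   c(60, 120, -170, 170, 60))
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, cobj, method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    chis <- .chis_from_par(best$par)
    labels <- c(labels, "xb")
  } else {
    chis <- .default_chis()
  }
  cf <- .build_peptide(cfg, phi, psi, chis, id = "template",
                       labels = labels)
  if (!classify_folded(cf, crit)) {
    stop("construction error: template failed the folded-hairpin criteria",
         call. = FALSE)
  }
  if ("xb" %in% labels &&
      !classify_xb(cf, sel$donor, sel$acceptor, crit = xb_criteria())) {
    stop("construction error: posed template failed the halogen-bond ",
         "criteria", call. = FALSE)
  }
  attr(cf, "torsions") <- list(phi = phi, psi = psi, chis = chis)
  .template_cache[[key]] <- cf
  cf
}

# clash test used by the unfolded sampler: non-bonded heavy atoms closer
# than 0.7 * (sum of vdW radii) reject a conformer
.has_clash <- function(cf, vdw = vdw_table()) {
  heavy <- which(!(cf$atoms$element %in% c("H", "D")))
  xyz <- cf$xyz[heavy, , drop = FALSE]
  res <- cf$atoms$res_index[heavy]
  rad <- unname(unlist(vdw)[cf$atoms$element[heavy]])
  dmat <- as.matrix(stats::dist(xyz))
  cut <- 0.7 * outer(rad, rad, "+")
  far <- abs(outer(res, res, "-")) >= 2
  any(dmat[far] < cut[far])
}

.jitter_folded <- function(cfg, template, crit, max_tries = 500) {
  tor <- attr(template, "torsions")
  t <- cfg$turn_position
  strand <- setdiff(seq_len(cfg$n_residues), c(t, t + 1L))
  for (try_k in seq_len(max_tries)) {
    phi <- tor$phi; psi <- tor$psi
    phi[setdiff(strand, 1L)] <- phi[setdiff(strand, 1L)] +
      stats::rnorm(length(strand) - 1, 0, cfg$dihedral_jitter)
    psi[strand] <- psi[strand] +
      stats::rnorm(length(strand), 0, cfg$dihedral_jitter)
    chis <- tor$chis
    chis$donor <- chis$donor + stats::rnorm(2, 0, 3 * cfg$dihedral_jitter)
    chis$acceptor <- chis$acceptor +
      stats::rnorm(3, 0, 3 * cfg$dihedral_jitter)
    cf <- .build_peptide(cfg, phi, psi, chis)
    if (classify_folded(cf, crit)) return(cf)
  }
  stop("construction error: could not draw a folded conformer within the ",
       "jitter budget", call. = FALSE)
}

.sample_unfolded <- function(cfg, crit, max_tries = 500) {
  n <- cfg$n_residues
  t <- cfg$turn_position
  strand <- setdiff(seq_len(n), c(t, t + 1L))
  tor <- .canonical_torsions(cfg)
  for (try_k in seq_len(max_tries)) {
    phi <- tor$phi; psi <- tor$psi
    # broad beta/PPII basin, register destroyed by the spread
    phi[setdiff(strand, 1L)] <- stats::runif(length(strand) - 1, -160, -60)
    psi[strand] <- stats::runif(length(strand), 60, 175)
    phi[t] <- 60 + stats::rnorm(1, 0, 10)
    psi[t] <- -120 + stats::rnorm(1, 0, 10)
    phi[t + 1L] <- -80 + stats::rnorm(1, 0, 10)
    psi[t + 1L] <- 0 + stats::rnorm(1, 0, 10)
    chis <- list(donor = stats::runif(2, -180, 180),
                 acceptor = stats::runif(3, -180, 180))
    names(chis$donor) <- c("chi1", "chi2")
    names(chis$acceptor) <- c("chi1", "chi2", "chi3")
    cf <- .build_peptide(cfg, phi, psi, chis)
    if (classify_folded(cf, crit)) next
    if (.has_clash(cf)) next
    return(cf)
  }
  stop("construction error: could not draw an unfolded conformer",
       call. = FALSE)
}

#' Sample a synthetic conformer pool with known ground truth
#'
#' Draws `n_folded` jittered copies of the folded template plus
#' `n_unfolded` conformers with randomized strand torsions (drawn from a
#' broad beta/PPII basin, clash-checked, and verified to fail the folded
#' classifier). Ground-truth populations split `folded_fraction` equally
#' over the folded conformers and the rest equally over the unfolded
#' ones. Deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()] with a `seed`.
#' @return List with `pool` (a [conformer_pool]) and `truth` (list with
#'   `populations`, `folded_labels`, `xb_labels`, `tensor`).
#' @export
sample_pool <- function(cfg) {
  seed <- .require_seed(cfg$seed)
  template <- build_folded_template(cfg)
  crit <- criteria_for_config(cfg)
  sel <- xb_selectors(cfg)
  xcrit <- xb_criteria(strict = FALSE)
  .with_seed(seed, {
    confs <- list()
    for (k in seq_len(cfg$n_folded)) {
      cf <- .jitter_folded(cfg, template, crit)
      cf$id <- sprintf("folded_%02d", k)
      cf$labels <- "folded"
      if (classify_xb(cf, sel$donor, sel$acceptor, crit = xcrit)) {
        cf$labels <- c(cf$labels, "xb")
      }
      confs[[length(confs) + 1L]] <- cf
    }
    for (k in seq_len(cfg$n_unfolded)) {
      cf <- .sample_unfolded(cfg, crit)
      cf$id <- sprintf("unfolded_%02d", k)
      cf$labels <- character()
      confs[[length(confs) + 1L]] <- cf
    }
    pool <- conformer_pool(confs)
    nf <- cfg$n_folded; nu <- cfg$n_unfolded
    pops <- c(if (nf > 0) rep(cfg$folded_fraction / nf, nf),
              if (nu > 0) rep((1 - cfg$folded_fraction) / nu, nu))
    pops <- pops / sum(pops)
    tensor <- .random_tensor_for_pool(pool, max_abs_hz = 13)
    list(pool = pool,
         truth = list(populations = pops,
                      folded_labels = pool_has_label(pool, "folded"),
                      xb_labels = pool_has_label(pool, "xb"),
                      tensor = tensor))
  })
}

#' Enrich a pool with halogen-bond-constrained conformers
#'
#' Appends `n` conformers built from folded members of the pool with
#' donor/acceptor side-chain torsions resampled subject to the
#' halogen-bond constraint: d(X...Y) at most the van der Waals sum and
#' C-X...Y angle above 120 degrees. Appended conformers that duplicate an
#' existing one at 1.5 A heavy-atom RMSD are redrawn (redundancy pass),
#' so every append passes [classify_xb()] and is geometrically distinct.
#'
#' Side-chain resampling only moves a dozen atoms of a ~90-heavy-atom
#' peptide, so duplicates among the appends are screened at a cutoff
#' scaled to that motion (default 0.15 A); whole-pool pruning at the
#' 1.5 A backbone scale is available separately via [prune_redundant()].
#'
#' @param pool A [conformer_pool] from [sample_pool()].
#' @param cfg The [generator_config()] the pool was built with.
#' @param n Number of conformers to append.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per append (default 200).
#' @param redundancy_cutoff Heavy-atom RMSD below which a candidate is
#'   considered a duplicate of an already-appended conformer and redrawn.
#' @return The enriched [conformer_pool]; new members carry labels
#'   `"folded"`, `"xb"`, `"xb_constrained"`.
#' @export
enrich_with_xb_conformers <- function(pool, cfg, n, seed,
                                      max_tries = 200,
                                      redundancy_cutoff = 0.15) {
  seed <- .require_seed(seed)
  if (!cfg$donor_element %in% c("Br", "I")) {
    stop("enrichment error: donor element '", cfg$donor_element,
         "' has no sigma hole", call. = FALSE)
  }
  template <- build_folded_template(cfg)
  tor <- attr(template, "torsions")
  crit <- criteria_for_config(cfg)
  sel <- xb_selectors(cfg)
  xcrit <- xb_criteria()
  svdw <- vdw_sum(cfg$donor_element, cfg$acceptor_element)
  .with_seed(seed, {
    confs <- pool$conformers
    added <- 0L
    tries <- 0L
    while (added < n) {
      tries <- tries + 1L
      if (tries > max_tries * n) {
        stop("enrichment error: halogen-bond constraint unsatisfiable ",
             "within the sampling budget", call. = FALSE)
      }
      phi <- tor$phi; psi <- tor$psi
      strand <- setdiff(seq_len(cfg$n_residues),
                        c(cfg$turn_position, cfg$turn_position + 1L))
      phi[setdiff(strand, 1L)] <- phi[setdiff(strand, 1L)] +
        stats::rnorm(length(strand) - 1, 0, cfg$dihedral_jitter)
      psi[strand] <- psi[strand] +
        stats::rnorm(length(strand), 0, cfg$dihedral_jitter)
      chis <- list(
        donor = tor$chis$donor + stats::rnorm(2, 0, 12),
        acceptor = tor$chis$acceptor + stats::rnorm(3, 0, 12))
      cf <- .build_peptide(cfg, phi, psi, chis)
      d <- distance(cf, sel$donor[[2]], sel$acceptor)
      ang <- angle(cf, sel$donor[[1]], sel$donor[[2]], sel$acceptor)
      if (d > svdw || ang <= xcrit$min_angle) next
      if (!classify_folded(cf, crit)) next
      # redundancy pass among the appended side-chain poses
      new_ones <- confs[seq_len(length(confs)) > length(pool$conformers)]
      dup <- any(vapply(new_ones, function(old)
        heavy_atom_rmsd(old, cf) < redundancy_cutoff, logical(1)))
      if (dup) next
      added <- added + 1L
      cf$id <- sprintf("xbenr_%02d", added)
      cf$labels <- c("folded", "xb", "xb_constrained")
      confs[[length(confs) + 1L]] <- cf
    }
    conformer_pool(confs)
  })
}

#' Remove redundant conformers by heavy-atom RMSD
#'
#' Keeps the first representative of each cluster of conformers closer
#' than `cutoff` after superposition.
#'
#' @param pool A [conformer_pool].
#' @param cutoff Heavy-atom RMSD cutoff in Angstrom (default 1.5).
#' @return The pruned [conformer_pool].
#' @export
prune_redundant <- function(pool, cutoff = 1.5) {
  keep <- list()
  for (cf in pool$conformers) {
    dup <- any(vapply(keep, function(old)
      heavy_atom_rmsd(old, cf) < cutoff, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- cf
  }
  conformer_pool(keep)
}

# random traceless symmetric alignment tensor scaled so the simulated
# RDCs over the pool span roughly the observed -13..+6 Hz range
.random_tensor_for_pool <- function(pool, max_abs_hz = 13) {
  s <- stats::rnorm(5)
  pairs <- default_rdc_pairs(pool)
  w <- rep(1 / length(pool), length(pool))
  d <- predict_rdc(pool, w, saupe_tensor(s), pairs)
  saupe_tensor(s * max_abs_hz / max(abs(d)))
}

#' Per-kind observation noise levels for the forward simulation
#'
#' @param noe_rate Relative Gaussian noise on NOE buildup rates
#'   (default 0.05, i.e. 5 percent).
#' @param j Absolute Gaussian noise on 3J couplings in Hz (default 0.3).
#' @param rdc Absolute Gaussian noise on RDCs in Hz (default 0.5).
#' @return Named list of noise levels.
#' @export
noise_levels <- function(noe_rate = 0.05, j = 0.3, rdc = 0.5) {
  if (noe_rate < 0 || j < 0 || rdc < 0) {
    stop("config error: noise levels must be >= 0", call. = FALSE)
  }
  list(noe_rate = noe_rate, j = j, rdc = rdc)
}

#' Forward-simulate noisy NMR observables from a pool and ground truth
#'
#' NOE buildup series over 7 mixing times (100-700 ms) are generated from
#' the population-averaged \eqn{r^{-6}} effective distances via the
#' internally referenced rate model (the geminal Gly methylene pair at
#' 1.78 A is the reference); 3J couplings from population-averaged
#' Karplus values; RDCs from the population-averaged Saupe projection,
#' also expressed as a T_strong/T_weak coupling pair around a 145 Hz
#' one-bond coupling. Gaussian noise is applied per kind; the NOE noise
#' acts multiplicatively on the buildup rate. Deterministic given `seed`.
#'
#' Cross-relaxation falls off as \eqn{r^{-6}}, so pairs whose
#' population-averaged effective distance exceeds `max_noe_dist` give no
#' detectable cross peak and are dropped from the emitted table, mimicking
#' the detection limit of a NOESY experiment.
#'
#' @param pool A [conformer_pool].
#' @param truth Ground-truth list with `populations` and `tensor` (as from
#'   [sample_pool()]).
#' @param noise A [noise_levels()] list.
#' @param seed Integer seed.
#' @param k [karplus_coefficients()] used for the J forward model.
#' @param max_noe_dist NOE detectability cutoff on the effective distance
#'   in Angstrom (default 5.5).
#' @return List of data frames `noe` (buildup series, wide mixing-time
#'   columns `I_100` ... `I_700`), `j` and `rdc`.
#' @export
simulate_observables <- function(pool, truth, noise = noise_levels(),
                                 seed, k = karplus_coefficients(),
                                 max_noe_dist = 5.5) {
  seed <- .require_seed(seed)
  p <- truth$populations
  if (length(p) != length(pool)) {
    stop("truth populations do not match the pool size", call. = FALSE)
  }
  mixing <- seq(0.1, 0.7, by = 0.1)
  noe_pairs <- default_noe_pairs(pool)
  jres <- default_j_residues(pool)
  rdc_pairs <- default_rdc_pairs(pool)
  .with_seed(seed, {
    # NOE buildups: sigma proportional to r_eff^-6, internally referenced
    sigma_ref <- 1.0
    r_ref <- 1.78
    rows <- lapply(seq_along(noe_pairs$pairs), function(q) {
      pr <- noe_pairs$pairs[[q]]
      is_ref <- noe_pairs$reference[[q]]
      r_eff <- if (is_ref) r_ref else predict_noe_distance(pool, p, pr)
      if (!is_ref && r_eff > max_noe_dist) return(NULL) # below detection
      sig <- sigma_ref * (r_ref / r_eff)^6
      sig <- sig * (1 + stats::rnorm(1, 0, noise$noe_rate))
      ints <- sig * mixing
      out <- data.frame(res_i = as.integer(pr[[1]][1]), atom_i = pr[[1]][2],
                        res_j = as.integer(pr[[2]][1]), atom_j = pr[[2]][2],
                        reference = is_ref, stringsAsFactors = FALSE)
      for (m in seq_along(mixing)) {
        out[[sprintf("I_%d", round(1000 * mixing[[m]]))]] <- ints[[m]]
      }
      out
    })
    noe <- do.call(rbind, rows)
    j <- data.frame(
      residue = jres,
      j_obs = vapply(jres, function(r)
        predict_j(pool, p, r, k) + stats::rnorm(1, 0, noise$j), numeric(1)),
      error = rep(max(noise$j, 0.1), length(jres)))
    d_true <- predict_rdc(pool, p, truth$tensor, rdc_pairs)
    d_obs <- d_true + stats::rnorm(length(d_true), 0, noise$rdc)
    t_weak <- rep(145, length(d_obs))
    rdc <- data.frame(
      res_i = vapply(rdc_pairs, function(pr) as.integer(pr[[1]][1]),
                     integer(1)),
      atom_i = vapply(rdc_pairs, function(pr) pr[[1]][2], character(1)),
      res_j = vapply(rdc_pairs, function(pr) as.integer(pr[[2]][1]),
                     integer(1)),
      atom_j = vapply(rdc_pairs, function(pr) pr[[2]][2], character(1)),
      t_strong = t_weak + d_obs, t_weak = t_weak,
      d_obs = d_obs, error = rep(max(noise$rdc, 0.1), length(d_obs)),
      stringsAsFactors = FALSE)
    list(noe = noe, j = j, rdc = rdc)
  })
}

# ---- default restraint sets derived from the pool topology -----------------

.ha_name <- function(cf, res) {
  if (any(cf$atoms$res_index == res & cf$atoms$name == "HA")) "HA" else "HA1"
}

.has_atom <- function(cf, res, name) {
  any(cf$atoms$res_index == res & cf$atoms$name == name)
}

#' Default backbone NOE pair set for a generated pool
#'
#' Sequential HA(i)-HN(i+1) and HN(i)-HN(i+1) pairs plus the cross-strand
#' HN-HN and HA-HA pairs of the hairpin register, and the geminal Gly
#' methylene reference pair.
#'
#' @param pool A [conformer_pool] from the generator.
#' @return List with `pairs` (list of selector pairs) and `reference`
#'   (logical vector marking the calibration pair).
#' @export
default_noe_pairs <- function(pool) {
  cf <- pool[[1]]
  n <- max(cf$atoms$res_index)
  t <- unique(cf$atoms$res_index[cf$atoms$res_name == "DPR"])[1]
  pairs <- list(); ref <- logical()
  addp <- function(a, b, is_ref = FALSE) {
    pairs[[length(pairs) + 1L]] <<- list(a, b)
    ref[[length(ref) + 1L]] <<- is_ref
  }
  for (i in seq_len(n - 1)) {
    if (.has_atom(cf, i + 1, "H")) {
      addp(atom_sel(i, .ha_name(cf, i)), atom_sel(i + 1, "H"))
      if (.has_atom(cf, i, "H")) {
        addp(atom_sel(i, "H"), atom_sel(i + 1, "H"))
      }
    }
  }
  if (!is.na(t)) {
    for (k in seq_len(t - 1L)) {
      partner <- n + 1L - k
      if (partner <= t + 1L) next
      if (.has_atom(cf, k, "H") && .has_atom(cf, partner, "H")) {
        addp(atom_sel(k, "H"), atom_sel(partner, "H"))
      }
      addp(atom_sel(k, .ha_name(cf, k)),
           atom_sel(partner, .ha_name(cf, partner)))
      if (.has_atom(cf, partner, "H")) {
        addp(atom_sel(k, .ha_name(cf, k)), atom_sel(partner, "H"))
      }
      if (.has_atom(cf, k, "H")) {
        addp(atom_sel(k, "H"), atom_sel(partner, .ha_name(cf, partner)))
      }
    }
  }
  gly <- unique(cf$atoms$res_index[cf$atoms$res_name == "GLY"])[1]
  if (!is.na(gly)) {
    addp(atom_sel(gly, "HA1"), atom_sel(gly, "HA2"), is_ref = TRUE)
  }
  list(pairs = pairs, reference = ref)
}

#' Default J-coupling residue set for a generated pool
#'
#' All residues with a defined phi torsion and an amide proton (i.e.
#' excluding the N terminus and the D-Pro).
#'
#' @param pool A [conformer_pool] from the generator.
#' @return Integer vector of residue indices.
#' @export
default_j_residues <- function(pool) {
  cf <- pool[[1]]
  n <- max(cf$atoms$res_index)
  Filter(function(r) .has_atom(cf, r, "H"), 2:n)
}

#' Default one-bond C-H RDC pair set for a generated pool
#'
#' CA-HA bonds of the strand residues plus the side-chain C-H bonds of
#' the halogen-bond donor (CB-HB1, CE1-HE1) and acceptor (CB-HB1,
#' CG-HG1, CE-HE1); 15 pairs for the default 12-residue layout.
#'
#' @param pool A [conformer_pool] from the generator.
#' @return List of selector pairs (C atom first, H atom second).
#' @export
default_rdc_pairs <- function(pool) {
  cf <- pool[[1]]
  n <- max(cf$atoms$res_index)
  t <- unique(cf$atoms$res_index[cf$atoms$res_name == "DPR"])[1]
  pairs <- list()
  for (i in seq_len(n)) {
    if (!is.na(t) && i %in% c(t, t + 1L)) next
    pairs[[length(pairs) + 1L]] <-
      list(atom_sel(i, "CA"), atom_sel(i, .ha_name(cf, i)))
  }
  dres <- unique(cf$atoms$res_index[cf$atoms$name == "X"])[1]
  ares <- unique(cf$atoms$res_index[cf$atoms$name == "YD"])[1]
  if (!is.na(dres)) {
    pairs[[length(pairs) + 1L]] <- list(atom_sel(dres, "CB"),
                                        atom_sel(dres, "HB1"))
    pairs[[length(pairs) + 1L]] <- list(atom_sel(dres, "CE1"),
                                        atom_sel(dres, "HE1"))
  }
  if (!is.na(ares)) {
    pairs[[length(pairs) + 1L]] <- list(atom_sel(ares, "CB"),
                                        atom_sel(ares, "HB1"))
    pairs[[length(pairs) + 1L]] <- list(atom_sel(ares, "CG"),
                                        atom_sel(ares, "HG1"))
    pairs[[length(pairs) + 1L]] <- list(atom_sel(ares, "CE"),
                                        atom_sel(ares, "HE1"))
  }
  pairs
}
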