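#' Van der Waals radius table
#'
#' Bondi radii for the elements that occur in the model peptides. The sum
#' of two radii (\eqn{\Sigma vdW}) is the contact criterion used by the
#' halogen-bond classifier. The table is swappable: pass a named numeric
#' vector of radii in Angstrom to override or extend the defaults.
#'
#' @param ... Named radii overriding the defaults, e.g. `I = 2.04`.
#' @return Named numeric vector of radii (Angstrom), class `vdw_table`.
#' @export
vdw_table <- function(...) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           Br = 1.85, I = 1.98)
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("vdW overrides must be named", call. = FALSE)
    }
    tab[names(extra)] <- extra
  }
  if (any(tab <= 0)) stop("vdW radii must be positive", call. = FALSE)
  structure(tab, class = "vdw_table")
}

.vdw_radius <- function(vdw, elem) {
  elem <- as.character(elem)
  if (!elem %in% names(vdw)) {
    stop("table error: element '", elem, "' not in vdW table", call. = FALSE)
  }
  unname(vdw[[elem]])
}

#' Sum of van der Waals radii for an element pair
#'
#' @param x_elem,y_elem Element symbols.
#' @param vdw A [vdw_table()].
#' @return \eqn{\Sigma vdW} in Angstrom.
#' @export
vdw_sum <- function(x_elem, y_elem, vdw = vdw_table()) {
  .vdw_radius(vdw, x_elem) + .vdw_radius(vdw, y_elem)
}

#' Contact distance as a percentage of the van der Waals sum
#'
#' @param d Distance in Angstrom.
#' @param x_elem,y_elem Element symbols of the two contact atoms.
#' @param vdw A [vdw_table()].
#' @return List with `raw` (percent, unrounded) and `percent` (nearest
#'   integer), e.g. a 3.02 A Br...O contact is 89.6 -> 90 percent.
#' @export
vdw_ratio <- function(d, x_elem, y_elem, vdw = vdw_table()) {
  if (!is.numeric(d) || d <= 0) {
    stop("distance must be positive", call. = FALSE)
  }
  raw <- 100 * d / vdw_sum(x_elem, y_elem, vdw)
  list(raw = raw, percent = round(raw))
}

#' Folded beta-hairpin classification criteria
#'
#' A conformer is folded when (i) the two central turn residues have
#' backbone torsions within `turn_tolerance` of the type II' targets,
#' (ii) the mean cross-strand CA-CA distance over the designated residue
#' pairs is at most `max_mean_ca_ca`, and (iii) at least `min_hbonds` of
#' the designated interstrand amide hydrogen bonds are formed
#' (donor-acceptor heavy-atom distance at most `hbond_max_dist` and
#' N-H...O angle at least `hbond_min_angle`).
#'
#' @param turn_residues Residue indices of the two turn positions i+1, i+2
#'   (the D-Pro and the Gly).
#' @param turn_targets 2x2 matrix of target (phi, psi) rows for the turn
#'   residues; default canonical type II' values (+60, -120) / (-80, 0).
#' @param turn_tolerance Angular tolerance in degrees (default 30).
#' @param ca_pairs 2-column matrix of cross-strand residue pairs whose
#'   CA-CA distances are averaged.
#' @param max_mean_ca_ca Maximum mean CA-CA distance in Angstrom
#'   (default 6.0).
#' @param hbond_pairs 2-column matrix of (donor residue, acceptor residue)
#'   pairs: amide N-H of the first, carbonyl O of the second.
#' @param min_hbonds Minimum number of formed hydrogen bonds (default 4).
#' @param hbond_max_dist Donor-acceptor N...O cutoff in Angstrom
#'   (default 3.5).
#' @param hbond_min_angle Minimum N-H...O angle in degrees (default 120).
#' @return An object of class `hairpin_criteria`.
#' @export
hairpin_criteria <- function(turn_residues = c(6L, 7L),
                             turn_targets = rbind(c(60, -120), c(-80, 0)),
                             turn_tolerance = 30,
                             ca_pairs = cbind(c(1, 2, 3, 4, 5),
                                              c(12, 11, 10, 9, 8)),
                             max_mean_ca_ca = 6.0,
                             hbond_pairs = rbind(c(5, 8), c(8, 5),
                                                 c(3, 10), c(10, 3),
                                                 c(1, 12), c(12, 1)),
                             min_hbonds = 4,
                             hbond_max_dist = 3.5,
                             hbond_min_angle = 120) {
  if (min_hbonds > nrow(hbond_pairs)) {
    stop("min_hbonds exceeds the number of listed hydrogen-bond pairs",
         call. = FALSE)
  }
  structure(
    list(turn_residues = as.integer(turn_residues),
         turn_targets = turn_targets,
         turn_tolerance = turn_tolerance,
         ca_pairs = ca_pairs,
         max_mean_ca_ca = max_mean_ca_ca,
         hbond_pairs = hbond_pairs,
         min_hbonds = as.integer(min_hbonds),
         hbond_max_dist = hbond_max_dist,
         hbond_min_angle = hbond_min_angle),
    class = "hairpin_criteria")
}

#' Halogen-bond classification criteria
#'
#' The geometric definition of a formed halogen bond: donor-acceptor
#' distance d(X...Y) equal to or shorter than the van der Waals sum
#' (inclusive), and C-X...Y angle strictly greater than `min_angle`.
#'
#' @param min_angle Minimum C-X...Y angle in degrees, exclusive
#'   (default 120).
#' @param donor_elements Allowed sigma-hole donor elements.
#' @param acceptor_elements Allowed Lewis-base acceptor elements.
#' @param strict Error (rather than return `FALSE`) when the donor element
#'   cannot form a sigma hole (default `TRUE`).
#' @return An object of class `xb_criteria`.
#' @export
xb_criteria <- function(min_angle = 120,
                        donor_elements = c("Br", "I"),
                        acceptor_elements = c("O", "S"),
                        strict = TRUE) {
  if (min_angle <= 90 || min_angle >= 180) {
    stop("min_angle must lie in (90, 180)", call. = FALSE)
  }
  structure(
    list(min_angle = min_angle,
         donor_elements = donor_elements,
         acceptor_elements = acceptor_elements,
         strict = isTRUE(strict)),
    class = "xb_criteria")
}

.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Type II' turn test
#'
#' `TRUE` iff both turn residues' (phi, psi) lie within the angular
#' tolerance of the targets, with wrap-around at +/-180.
#'
#' @param cf A [conformer].
#' @param crit A [hairpin_criteria()].
#' @return Logical.
#' @export
classify_turn <- function(cf, crit = hairpin_criteria()) {
  for (k in 1:2) {
    res <- crit$turn_residues[[k]]
    ph <- phi_angle(cf, res)
    ps <- psi_angle(cf, res)
    if (.ang_diff(ph, crit$turn_targets[k, 1]) > crit$turn_tolerance ||
        .ang_diff(ps, crit$turn_targets[k, 2]) > crit$turn_tolerance) {
      return(FALSE)
    }
  }
  TRUE
}

#' Count formed interstrand hydrogen bonds
#'
#' Applies the N...O distance / N-H...O angle rule to each designated
#' donor/acceptor pair.
#'
#' @param cf A [conformer].
#' @param crit A [hairpin_criteria()].
#' @return Integer count in 0..nrow(hbond_pairs).
#' @export
count_interstrand_hbonds <- function(cf, crit = hairpin_criteria()) {
  n <- 0L
  for (k in seq_len(nrow(crit$hbond_pairs))) {
    don <- crit$hbond_pairs[k, 1]
    acc <- crit$hbond_pairs[k, 2]
    d <- distance(cf, atom_sel(don, "N"), atom_sel(acc, "O"))
    if (d > crit$hbond_max_dist) next
    ang <- angle(cf, atom_sel(don, "N"), atom_sel(don, "H"),
                 atom_sel(acc, "O"))
    if (ang >= crit$hbond_min_angle) n <- n + 1L
  }
  n
}

.mean_ca_ca <- function(cf, crit) {
  mean(vapply(seq_len(nrow(crit$ca_pairs)), function(k) {
    distance(cf, atom_sel(crit$ca_pairs[k, 1], "CA"),
             atom_sel(crit$ca_pairs[k, 2], "CA"))
  }, numeric(1)))
}

#' Folded beta-hairpin test
#'
#' Conjunction of the turn-torsion window, the mean cross-strand CA-CA
#' proximity and the interstrand hydrogen-bond count.
#'
#' @param cf A [conformer].
#' @param crit A [hairpin_criteria()].
#' @param detail Return the component measurements instead of a single
#'   logical.
#' @return Logical, or (with `detail = TRUE`) a list with `folded`,
#'   `turn_ok`, `mean_ca_ca`, `n_hbonds`.
#' @export
classify_folded <- function(cf, crit = hairpin_criteria(), detail = FALSE) {
  turn_ok <- classify_turn(cf, crit)
  mca <- .mean_ca_ca(cf, crit)
  nhb <- count_interstrand_hbonds(cf, crit)
  folded <- turn_ok && mca <= crit$max_mean_ca_ca && nhb >= crit$min_hbonds
  if (detail) {
    list(folded = folded, turn_ok = turn_ok, mean_ca_ca = mca,
         n_hbonds = nhb)
  } else {
    folded
  }
}

#' Halogen-bond test
#'
#' `TRUE` iff d(X...Y) is at most the van der Waals sum (inclusive
#' boundary) and the C-X...Y angle strictly exceeds the threshold.
#'
#' @param cf A [conformer].
#' @param donor Length-2 list of atom selectors `list(C, X)`: the carbon
#'   bearing the halogen and the halogen itself.
#' @param acceptor Atom selector of the Lewis-base acceptor Y.
#' @param vdw A [vdw_table()].
#' @param crit An [xb_criteria()].
#' @param detail Return measurements instead of a single logical.
#' @return Logical, or (with `detail = TRUE`) a list with `xb`, `d`,
#'   `sum_vdw`, `angle`, `ratio_percent`.
#' @export
classify_xb <- function(cf, donor, acceptor, vdw = vdw_table(),
                        crit = xb_criteria(), detail = FALSE) {
  ix <- .resolve_atom(cf, donor[[2]])
  iy <- .resolve_atom(cf, acceptor)
  x_elem <- cf$atoms$element[ix]
  y_elem <- cf$atoms$element[iy]
  if (!x_elem %in% crit$donor_elements) {
    if (crit$strict) {
      stop("classification error: '", x_elem,
           "' is not a sigma-hole halogen-bond donor", call. = FALSE)
    }
    return(if (detail) list(xb = FALSE, d = NA_real_, sum_vdw = NA_real_,
                            angle = NA_real_, ratio_percent = NA_real_)
           else FALSE)
  }
  if (!y_elem %in% crit$acceptor_elements && crit$strict) {
    stop("classification error: '", y_elem,
         "' is not an accepted halogen-bond acceptor", call. = FALSE)
  }
  d <- distance(cf, donor[[2]], acceptor)
  svdw <- vdw_sum(x_elem, y_elem, vdw)
  ang <- angle(cf, donor[[1]], donor[[2]], acceptor)
  xb <- (d <= svdw) && (ang > crit$min_angle)
  if (detail) {
    list(xb = xb, d = d, sum_vdw = svdw, angle = ang,
         ratio_percent = round(100 * d / svdw))
  } else {
    xb
  }
}

#' Classify every conformer of a pool
#'
#' Convenience wrapper producing a per-conformer table of the folded and
#' halogen-bond classifications plus the underlying measurements.
#'
#' @param pool A [conformer_pool].
#' @param crit A [hairpin_criteria()].
#' @param donor,acceptor Halogen-bond selectors as in [classify_xb()], or
#'   `NULL` to skip the halogen-bond columns.
#' @param vdw A [vdw_table()].
#' @param xb_crit An [xb_criteria()].
#' @return Data frame with one row per conformer: `id`, `folded`,
#'   `turn_ok`, `mean_ca_ca`, `n_hbonds`, and if donor/acceptor are given
#'   `xb`, `xb_dist`, `xb_angle`, `xb_vdw_percent`.
#' @export
classify_pool <- function(pool, crit = hairpin_criteria(),
                          donor = NULL, acceptor = NULL,
                          vdw = vdw_table(), xb_crit = xb_criteria()) {
  rows <- lapply(seq_len(length(pool)), function(k) {
    cf <- pool[[k]]
    f <- classify_folded(cf, crit, detail = TRUE)
    row <- data.frame(id = cf$id, folded = f$folded, turn_ok = f$turn_ok,
                      mean_ca_ca = f$mean_ca_ca, n_hbonds = f$n_hbonds,
                      stringsAsFactors = FALSE)
    if (!is.null(donor) && !is.null(acceptor)) {
      x <- classify_xb(cf, donor, acceptor, vdw, xb_crit, detail = TRUE)
      row$xb <- x$xb
      row$xb_dist <- x$d
      row$xb_angle <- x$angle
      row$xb_vdw_percent <- x$ratio_percent
    }
    row
  })
  do.call(rbind, rows)
}
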