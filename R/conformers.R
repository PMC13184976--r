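#' Construct a conformer
#'
#' A conformer holds an ordered atom table and one set of 3D coordinates.
#' Atom order is fixed and shared by all conformers of a pool, which is what
#' lets restraint selectors and design matrices line up across models.
#'
#' @param id Character id, unique within a pool.
#' @param atoms Data frame with columns `name` (atom label), `element`
#'   (element symbol), `res_index` (1-based residue number) and `res_name`
#'   (3-letter residue code).
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param labels Character vector of free-form tags (e.g. `"folded"`,
#'   `"xb_constrained"`).
#' @return An object of class `conformer`.
#' @export
conformer <- function(id, atoms, xyz, labels = character()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "res_index", "res_name")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3 || nrow(xyz) != nrow(atoms)) {
    stop("xyz must be a numeric matrix with one row per atom and 3 columns",
         call. = FALSE)
  }
  if (!all(is.finite(xyz))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(!nzchar(atoms$element))) {
    stop("element symbols must be non-empty", call. = FALSE)
  }
  dimnames(xyz) <- NULL
  structure(
    list(id = as.character(id),
         atoms = atoms[, need],
         xyz = xyz,
         labels = as.character(labels)),
    class = "conformer"
  )
}

#' Construct a conformer pool
#'
#' @param conformers List of [conformer] objects sharing an identical atom
#'   topology (same atom count, names, ordering, residues).
#' @return An object of class `conformer_pool`.
#' @export
conformer_pool <- function(conformers) {
  if (length(conformers) == 0) {
    stop("pool must be non-empty", call. = FALSE)
  }
  ref <- conformers[[1]]
  ids <- vapply(conformers, function(cf) cf$id, character(1))
  if (anyDuplicated(ids)) {
    stop("conformer ids must be unique within a pool", call. = FALSE)
  }
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    if (!inherits(cf, "conformer")) {
      stop("all pool members must be conformer objects", call. = FALSE)
    }
    if (nrow(cf$atoms) != nrow(ref$atoms) ||
        !identical(cf$atoms$name, ref$atoms$name) ||
        !identical(cf$atoms$res_index, ref$atoms$res_index)) {
      stop("topology error: conformer '", cf$id,
           "' does not match the pool topology", call. = FALSE)
    }
  }
  structure(list(conformers = conformers), class = "conformer_pool")
}

#' @export
length.conformer_pool <- function(x) length(x$conformers)

#' @export
`[[.conformer_pool` <- function(x, i) x$conformers[[i]]

#' @export
`[.conformer_pool` <- function(x, i) conformer_pool(x$conformers[i])

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer>", x$id, "-", nrow(x$atoms), "atoms,",
      max(x$atoms$res_index), "residues")
  if (length(x$labels)) cat(" [", paste(x$labels, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat("<conformer_pool>", length(x), "conformers,",
      nrow(x[[1]]$atoms), "atoms each\n")
  invisible(x)
}

#' Conformer ids of a pool
#' @param pool A [conformer_pool].
#' @return Character vector of ids.
#' @export
pool_ids <- function(pool) {
  vapply(pool$conformers, function(cf) cf$id, character(1))
}

#' Per-conformer label test
#'
#' @param pool A [conformer_pool].
#' @param label Label string to test for.
#' @return Logical vector, one entry per conformer.
#' @export
pool_has_label <- function(pool, label) {
  vapply(pool$conformers, function(cf) label %in% cf$labels, logical(1))
}

# ---- atom selection ---------------------------------------------------------

# A selector is either a single integer atom index or a length-2 vector
# c(res_index, atom_name). Returns the atom row index.
.resolve_atom <- function(cf, sel) {
  if (length(sel) == 1 && is.numeric(sel)) {
    i <- as.integer(sel)
    if (is.na(i) || i < 1 || i > nrow(cf$atoms)) {
      stop("selection error: atom index ", sel, " out of range",
           call. = FALSE)
    }
    return(i)
  }
  if (length(sel) != 2) {
    stop("selection error: selector must be an index or c(res_index, name)",
         call. = FALSE)
  }
  res <- suppressWarnings(as.integer(sel[[1]]))
  nm <- as.character(sel[[2]])
  if (is.na(res)) {
    stop("selection error: residue index '", sel[[1]], "' is not an integer",
         call. = FALSE)
  }
  hit <- which(cf$atoms$res_index == res & cf$atoms$name == nm)
  if (length(hit) != 1) {
    stop("selection error: atom ", res, ":", nm,
         if (length(hit) == 0) " not found" else " ambiguous", call. = FALSE)
  }
  hit
}

.atom_xyz <- function(cf, sel) cf$xyz[.resolve_atom(cf, sel), ]

#' Atom selector helper
#'
#' @param res_index 1-based residue number.
#' @param name Atom name within that residue.
#' @return A length-2 selector usable by [distance()], [angle()],
#'   [dihedral()] and the restraint tables.
#' @export
atom_sel <- function(res_index, name) {
  c(as.character(as.integer(res_index)), as.character(name))
}

# ---- geometric primitives ---------------------------------------------------

#' Interatomic distance
#'
#' @param cf A [conformer].
#' @param i,j Atom selectors (`c(res_index, name)` or integer index).
#' @return Euclidean distance in Angstrom.
#' @export
distance <- function(cf, i, j) {
  .vnorm(.atom_xyz(cf, i) - .atom_xyz(cf, j))
}

#' Vertex angle at atom b
#'
#' @param cf A [conformer].
#' @param a,b,c2 Atom selectors; the angle is measured at `b`.
#' @return Angle in degrees in \[0, 180\].
#' @export
angle <- function(cf, a, b, c2) {
  .angle3(.atom_xyz(cf, a), .atom_xyz(cf, b), .atom_xyz(cf, c2))
}

#' Torsion angle a-b-c2-d
#'
#' IUPAC sign convention: positive clockwise looking from `b` to `c2`.
#'
#' @param cf A [conformer].
#' @param a,b,c2,d Atom selectors.
#' @return Dihedral in degrees in (-180, 180\].
#' @export
dihedral <- function(cf, a, b, c2, d) {
  .dihedral4(.atom_xyz(cf, a), .atom_xyz(cf, b),
             .atom_xyz(cf, c2), .atom_xyz(cf, d))
}

#' Heavy-atom RMSD between two conformers
#'
#' Root-mean-square deviation over all non-hydrogen atoms (element H or D),
#' optionally minimised over rigid-body transforms (Kabsch superposition).
#'
#' @param c1,c2 Conformers sharing one topology.
#' @param superpose Superpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(c1, c2, superpose = TRUE) {
  if (nrow(c1$atoms) != nrow(c2$atoms) ||
      !identical(c1$atoms$name, c2$atoms$name) ||
      !identical(c1$atoms$res_index, c2$atoms$res_index)) {
    stop("topology error: conformers do not share a topology", call. = FALSE)
  }
  heavy <- !(toupper(c1$atoms$element) %in% c("H", "D"))
  if (superpose && sum(heavy) < 3) {
    stop("need at least 3 heavy atoms to superpose", call. = FALSE)
  }
  .rmsd_xyz(c1$xyz[heavy, , drop = FALSE],
            c2$xyz[heavy, , drop = FALSE], superpose = superpose)
}

#' Backbone phi torsion of a residue
#'
#' C(i-1)-N(i)-CA(i)-C(i); needs residue `res - 1` present.
#'
#' @param cf A [conformer].
#' @param res Residue index (>= 2).
#' @return Torsion in degrees.
#' @export
phi_angle <- function(cf, res) {
  dihedral(cf, atom_sel(res - 1, "C"), atom_sel(res, "N"),
           atom_sel(res, "CA"), atom_sel(res, "C"))
}

#' Backbone psi torsion of a residue
#'
#' N(i)-CA(i)-C(i)-N(i+1); needs residue `res + 1` present.
#'
#' @param cf A [conformer].
#' @param res Residue index.
#' @return Torsion in degrees.
#' @export
psi_angle <- function(cf, res) {
  dihedral(cf, atom_sel(res, "N"), atom_sel(res, "CA"),
           atom_sel(res, "C"), atom_sel(res + 1, "N"))
}
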