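# Internal vector geometry helpers. All coordinates are plain numeric
# length-3 vectors in Angstrom; angles handled in degrees at the interface.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-10) {
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  }
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vertex angle at b in degrees, range [0, 180].
.angle3 <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  cosang <- max(-1, min(1, sum(u * v)))
  .rad2deg(acos(cosang))
}

# Torsion a-b-c-d, IUPAC sign convention, degrees in (-180, 180].
.dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    stop("degenerate geometry: collinear atoms in dihedral", call. = FALSE)
  }
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- .rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF atom placement: position atom D bonded to C, with bond length r,
# angle B-C-D theta (deg) and torsion A-B-C-D chi (deg).
.place_atom <- function(a, b, c, r, theta, chi) {
  th <- .deg2rad(theta)
  ch <- -.deg2rad(chi) # frame below is left-handed w.r.t. IUPAC torsions
  d2 <- c(r * cos(pi - th),
          r * sin(pi - th) * cos(ch),
          r * sin(pi - th) * sin(ch))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  as.numeric(c + m %*% d2)
}

# Kabsch optimal rotation of y onto x (both n x 3, centred by caller).
.kabsch_rotation <- function(x, y) {
  h <- crossprod(y, x)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# RMSD between two n x 3 coordinate matrices, optionally after optimal
# rigid-body superposition.
.rmsd_xyz <- function(x, y, superpose = TRUE) {
  if (superpose) {
    cx <- colMeans(x)
    cy <- colMeans(y)
    xc <- sweep(x, 2, cx)
    yc <- sweep(y, 2, cy)
    rot <- .kabsch_rotation(xc, yc)
    y <- yc %*% rot
    x <- xc
  }
  sqrt(mean(rowSums((x - y)^2)))
}

# The two unit vectors completing a tetrahedral centre at ca whose other
# two substituents are towards n and c. dir1 is the pro-S/"CB-like" side
# for an L-configured centre built with our backbone conventions.
.tetra_dirs <- function(n, ca, c) {
  u <- .unit(n - ca)
  v <- .unit(c - ca)
  bis <- -.unit(u + v)           # in-plane bisector, away from n/c
  perp <- .unit(.cross(u, v))    # out of the n-ca-c plane
  half <- .deg2rad(109.5 / 2)
  d1 <- .unit(bis * cos(half) + perp * sin(half))
  d2 <- .unit(bis * cos(half) - perp * sin(half))
  list(d1 = d1, d2 = d2)
}
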