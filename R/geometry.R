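# Ideal helix construction and rigid placement on skeleton axes.
#
# All coordinates are in Angstrom. Backbone atoms are built from internal
# coordinates (bond lengths, bond angles, torsions) with the natural
# extension reference frame, then expressed in a canonical local frame:
# helix axis along +z through the Calpha centroid, first Calpha at azimuth 0.

#' Ideal helix geometry parameters
#'
#' Bond lengths, bond angles and backbone torsions used to construct a
#' perfectly straight helix. Defaults are standard trans-peptide values with
#' helical torsions phi = -60 deg, psi = -50 deg.
#'
#' @param phi,psi Backbone dihedrals in degrees.
#' @param omega Peptide-bond dihedral in degrees (trans = 180).
#' @param b_n_ca,b_ca_c,b_c_n Bond lengths N-CA, CA-C, C-N in Angstrom.
#' @param b_c_o Carbonyl C=O bond length in Angstrom.
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca Backbone bond angles in degrees.
#' @param a_ca_c_o CA-C-O bond angle in degrees.
#' @return Object of class `helix_geometry`.
#' @export
helix_geometry <- function(phi = -60, psi = -50, omega = 180,
                           b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                           b_c_o = 1.231,
                           a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                           a_c_n_ca = 121.7, a_ca_c_o = 120.8) {
  stopifnot(b_n_ca > 0, b_ca_c > 0, b_c_n > 0, b_c_o > 0)
  for (a in c(a_n_ca_c, a_ca_c_n, a_c_n_ca, a_ca_c_o))
    if (a <= 0 || a >= 180) stop("bond angles must lie in (0, 180) degrees")
  structure(list(phi = phi, psi = psi, omega = omega,
                 b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
                 b_c_o = b_c_o,
                 a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n,
                 a_c_n_ca = a_c_n_ca, a_ca_c_o = a_ca_c_o),
            class = "helix_geometry")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C, bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg). Natural extension reference frame construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Signed dihedral in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# Angle at p2 of the triple p1-p2-p3, degrees.
bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Build an ideal straight helix backbone in a canonical local frame
#'
#' Constructs N, CA, C, O atoms for `n_residues` residues from the torsions
#' and covalent geometry in `geom`, then moves the chain to a canonical
#' frame: the least-squares Calpha axis along +z (oriented from the first to
#' the last residue), the Calpha centroid at the origin, and the first
#' Calpha at azimuth 0 (positive x half-plane).
#'
#' @param n_residues Number of residues (>= 2).
#' @param geom A [helix_geometry()] object.
#' @return Object of class `ideal_helix`: list with `n`, `xyz` (a
#'   `4*n x 3` matrix, residue-major atom order N, CA, C, O), `atom` and
#'   `resno_local` labels, and the per-residue geometric `rise` along the
#'   fitted axis.
#' @export
build_ideal_helix <- function(n_residues, geom = helix_geometry()) {
  if (n_residues < 2) stop("a helix needs at least 2 residues")
  n <- as.integer(n_residues)
  xyz <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)
  atom <- rep(c("N", "CA", "C", "O"), n)
  resno <- rep(seq_len(n), each = 4L)
  idx <- function(i, name) (i - 1L) * 4L + match(name, c("N", "CA", "C", "O"))

  # seed residue 1 in an arbitrary frame
  xyz[idx(1, "N"), ] <- c(0, 0, 0)
  xyz[idx(1, "CA"), ] <- c(geom$b_n_ca, 0, 0)
  ang <- deg2rad(geom$a_n_ca_c)
  xyz[idx(1, "C"), ] <- xyz[idx(1, "CA"), ] +
    geom$b_ca_c * c(-cos(ang), sin(ang), 0)

  for (i in seq_len(n)) {
    N <- xyz[idx(i, "N"), ]; CA <- xyz[idx(i, "CA"), ]; C <- xyz[idx(i, "C"), ]
    if (i < n) {
      Nn <- place_atom(N, CA, C, geom$b_c_n, geom$a_ca_c_n, geom$psi)
      xyz[idx(i + 1L, "N"), ] <- Nn
      CAn <- place_atom(CA, C, Nn, geom$b_n_ca, geom$a_c_n_ca, geom$omega)
      xyz[idx(i + 1L, "CA"), ] <- CAn
      xyz[idx(i + 1L, "C"), ] <- place_atom(C, Nn, CAn, geom$b_ca_c,
                                            geom$a_n_ca_c, geom$phi)
    }
    # carbonyl O trans to the next N (torsion psi + 180)
    xyz[idx(i, "O"), ] <- place_atom(N, CA, C, geom$b_c_o, geom$a_ca_c_o,
                                     geom$psi + 180)
  }

  # canonical frame: helix axis -> +z, axis mid-span -> origin, first CA
  # at azimuth 0
  ca <- xyz[atom == "CA", , drop = FALSE]
  ax <- helix_axis(ca)
  z <- ax$dir
  cen <- (ax$p0 + ax$p1) / 2
  xref <- c(1, 0, 0)
  if (abs(sum(xref * z)) > 0.99) xref <- c(0, 1, 0)
  x <- unitv(xref - sum(xref * z) * z)
  y <- cross3(z, x)
  R <- rbind(x, y, z)            # world -> local
  xyz <- t(R %*% (t(xyz) - cen)) # rotate into frame
  # spin about z so the first CA sits at azimuth 0
  ca1 <- xyz[idx(1, "CA"), ]
  th <- atan2(ca1[2], ca1[1])
  ct <- cos(-th); st <- sin(-th)
  Rz <- matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- xyz %*% t(Rz)

  ca <- xyz[atom == "CA", , drop = FALSE]
  rise <- (ca[n, 3] - ca[1, 3]) / (n - 1)
  structure(list(n = n, xyz = xyz, atom = atom, resno_local = resno,
                 rise = rise, geom = geom),
            class = "ideal_helix")
}

# Total-least-squares line through a point cloud (rows of `pts`).
# Direction oriented from the first towards the last point.
fit_axis_points <- function(pts) {
  cen <- colMeans(pts)
  sv <- svd(sweep(pts, 2, cen))
  dir <- sv$v[, 1]
  if (sum(dir * (pts[nrow(pts), ] - pts[1, ])) < 0) dir <- -dir
  proj <- as.vector(sweep(pts, 2, cen) %*% dir)
  resid <- sqrt(sum((sweep(pts, 2, cen) - outer(proj, dir))^2))
  list(point = cen, dir = unitv(dir), length = max(proj) - min(proj),
       p0 = cen + min(proj) * dir, p1 = cen + max(proj) * dir,
       residual = resid)
}

#' Helix axis of a Calpha trace
#'
#' Exact for an ideal (constant-geometry) helix: the axis direction is the
#' normal of the plane spanned by second differences of the Calpha chain
#' (chord second differences of a circular helix are perpendicular to its
#' axis), and the axis position is the least-squares circle centre of the
#' Calphas projected on that plane. This avoids the tilt a total-least-
#' squares line picks up from partial helical turns. Falls back to the TLS
#' line for fewer than 4 points.
#'
#' @param ca Matrix of Calpha coordinates (rows in chain order).
#' @return Same structure as [fit_axis_line()]: `point`, `dir`, `length`,
#'   `p0`, `p1`, `residual` (here: circle-fit RMS).
#' @export
helix_axis <- function(ca) {
  n <- nrow(ca)
  if (n < 4) return(fit_axis_points(ca))
  chords <- diff(ca)
  dd <- diff(chords)             # second differences, perpendicular to axis
  z <- c(0, 0, 0)
  for (i in seq_len(nrow(dd) - 1)) z <- z + cross3(dd[i, ], dd[i + 1, ])
  z <- unitv(z)
  if (sum(z * (ca[n, ] - ca[1, ])) < 0) z <- -z
  # in-plane circle fit (Kasa): centre of the projected Calphas
  xref <- c(1, 0, 0)
  if (abs(sum(xref * z)) > 0.99) xref <- c(0, 1, 0)
  x <- unitv(xref - sum(xref * z) * z)
  y <- cross3(z, x)
  u <- as.vector(ca %*% x)
  v <- as.vector(ca %*% y)
  A <- cbind(2 * u, 2 * v, 1)
  sol <- qr.solve(A, u^2 + v^2)
  cen2 <- sol[1:2]
  r2 <- sqrt(pmax(sol[3] + sum(cen2^2), 0))
  resid <- sqrt(mean((sqrt((u - cen2[1])^2 + (v - cen2[2])^2) - r2)^2))
  point <- cen2[1] * x + cen2[2] * y      # a point on the axis (w = 0)
  w <- as.vector(ca %*% z)
  list(point = point + mean(w) * z, dir = z, length = max(w) - min(w),
       p0 = point + min(w) * z, p1 = point + max(w) * z, residual = resid)
}

#' Fit a straight axis line to a skeleton polyline
#'
#' Total-least-squares line through the polyline points; the direction is
#' oriented from the first to the last stored point, so `p0` corresponds to
#' the start side of the polyline.
#'
#' @param skeleton A `skeleton` record (see [read_skeletons()]) or a plain
#'   numeric matrix of points.
#' @return List with `point` (centroid), `dir` (unit vector), `length`
#'   (span of point projections), `p0`/`p1` (projected end points on the
#'   line) and `residual` (root sum of squared orthogonal distances).
#' @export
fit_axis_line <- function(skeleton) {
  pts <- if (is.matrix(skeleton)) skeleton else skeleton$points
  if (nrow(pts) < 2) stop("need at least 2 points to fit an axis")
  fit_axis_points(pts)
}

#' Place an ideal helix on a skeleton axis
#'
#' Maps the canonical local frame of `ideal` onto the world frame of `axis`:
#' local +z goes to `direction * axis$dir`, the Calpha centroid goes to the
#' axis midpoint shifted by `t` along the axis, and `theta` spins the helix
#' about the axis. The azimuth-zero reference is the world +x axis projected
#' perpendicular to the helix axis (+y fallback when the axis is nearly
#' parallel to x).
#'
#' @param ideal An [build_ideal_helix()] result.
#' @param axis An axis as returned by [fit_axis_line()].
#' @param direction +1 to run N->C along the stored polyline direction, -1
#'   to run against it.
#' @param theta Rotation about the axis, degrees.
#' @param t Translation along the axis, Angstrom.
#' @return `4*n x 3` matrix of world coordinates (same row order as
#'   `ideal$xyz`).
#' @export
place_helix <- function(ideal, axis, direction = 1L, theta = 0, t = 0) {
  stopifnot(direction %in% c(-1L, 1L))
  B <- placement_basis(axis, direction)
  center <- (axis$p0 + axis$p1) / 2 + t * axis$dir
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  Rz <- matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  # world = center + B %*% Rz %*% local
  t(B %*% Rz %*% t(ideal$xyz)) + rep(center, each = nrow(ideal$xyz))
}

# Orthonormal basis (columns x', y', z') for placement: z' = direction*axis,
# x' = world +x projected off the axis (fallback +y), y' completes RH frame.
placement_basis <- function(axis, direction) {
  z <- direction * axis$dir
  xref <- c(1, 0, 0)
  if (abs(sum(xref * z)) > 0.99) xref <- c(0, 1, 0)
  x <- unitv(xref - sum(xref * z) * z)
  y <- cross3(z, x)
  cbind(x, y, z)
}

#' Sequence window assigned to a skeleton
#'
#' The window has the skeleton's estimated residue count and is centred at
#' the segment centre shifted by `s` residues. For even lengths the centre
#' is the left-of-centre residue. A window that sticks out past the sequence
#' is slid back inside; if that slide exceeds `s_max` the placement is
#' invalid and `NULL` is returned.
#'
#' @param segment A segment record (list with `start`, `end`).
#' @param skeleton_residues Window length in residues.
#' @param s Integer shift.
#' @param seq_len Sequence length.
#' @param s_max Maximum tolerated clamping slide (residues).
#' @return Integer `c(start, end)` (1-based inclusive), or `NULL` when the
#'   window cannot be placed.
#' @export
assign_window <- function(segment, skeleton_residues, s, seq_len, s_max = 2L) {
  m <- as.integer(skeleton_residues)
  if (m < 1L || m > seq_len) return(NULL)
  cc <- (segment$start + segment$end) %/% 2L   # left-of-centre for even length
  start <- cc + as.integer(s) - (m - 1L) %/% 2L
  end <- start + m - 1L
  slide <- 0L
  if (start < 1L) slide <- 1L - start
  if (end > seq_len) slide <- seq_len - end
  if (abs(slide) > s_max) return(NULL)
  c(start + slide, end + slide)
}
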