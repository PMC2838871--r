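# Internal-angle fragment geometry: the (phi1, phi2, theta) representation of
# four consecutive C-alpha atoms, conversions between angles and Cartesian
# coordinates, and the two distance metrics used throughout (aRMSD in angle
# space, cRMSD after optimal superposition).

DEG <- 180 / pi

.norm3 <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a C-alpha trace
#'
#' A `ca_trace` is the ordered list of C-alpha coordinates of one chain (or
#' one model of an ensemble), the unit every other operation consumes.
#'
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param residue_ids integer residue labels, one per atom (default `1:N`).
#' @param chain_id single-character chain label.
#' @param id structure identifier used in reports and FASTA headers.
#' @return An object of class `ca_trace` with fields `coords`, `residue_ids`,
#'   `chain_id`, `id`.
#' @export
ca_trace <- function(coords, residue_ids = NULL, chain_id = "A", id = "trace") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("'coords' must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (is.null(residue_ids)) residue_ids <- seq_len(nrow(coords))
  if (length(residue_ids) != nrow(coords))
    stop("'residue_ids' must match the number of atoms")
  structure(list(coords = coords, residue_ids = as.integer(residue_ids),
                 chain_id = as.character(chain_id), id = as.character(id)),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s chain %s: %d C-alpha atoms\n",
              x$id, x$chain_id, nrow(x$coords)))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) nrow(x$coords)

.as_coords <- function(x) {
  if (inherits(x, "ca_trace")) return(x$coords)
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("expected an N x 3 coordinate matrix")
  storage.mode(m) <- "double"
  m
}

.check_angles <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) != 3L || !all(is.finite(angles)))
    stop("angles must be a finite numeric triple (phi1, phi2, theta)")
  if (angles[1L] <= 0 || angles[1L] > 180 || angles[2L] <= 0 || angles[2L] > 180)
    stop("phi1 and phi2 must lie in (0, 180] degrees")
  if (angles[3L] <= -180 || angles[3L] > 180)
    stop("theta must lie in (-180, 180] degrees")
  angles
}

#' Normalise a torsion angle to (-180, 180]
#'
#' Exactly -180 is mapped to +180.
#'
#' @param theta angle(s) in degrees.
#' @return Angle(s) in the half-open interval (-180, 180].
#' @export
wrap_theta <- function(theta) {
  out <- ((theta + 180) %% 360) - 180
  out[out <= -180] <- 180  # -180 and +180 are the same torsion; pick +180
  out
}

#' Internal angles of a four-atom fragment
#'
#' Computes the two pseudo-bond angles and the pseudo-torsion that fully
#' describe the conformation of four consecutive C-alpha atoms: phi1 is the
#' angle over atoms 1-2-3, phi2 over atoms 2-3-4, and theta the dihedral over
#' atoms 1-2-3-4 (IUPAC right-hand sign convention, cis = 0).  These are
#' coarse-grained backbone angles, not the Ramachandran (Phi, Psi) pair.
#'
#' @param frag 4 x 3 coordinate matrix (or `ca_trace` of length 4).
#' @return Named numeric vector `c(phi1, phi2, theta)` in degrees; phi in
#'   (0, 180], theta in (-180, 180].
#' @examples
#' fragment_angles(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
#' @export
fragment_angles <- function(frag) {
  x <- .as_coords(frag)
  if (nrow(x) != 4L) stop("a fragment has exactly 4 atoms")
  if (!all(is.finite(x))) stop("degenerate geometry: non-finite coordinates")
  b1 <- x[2L, ] - x[1L, ]
  b2 <- x[3L, ] - x[2L, ]
  b3 <- x[4L, ] - x[3L, ]
  scale <- max(.norm3(b1), .norm3(b2), .norm3(b3))
  for (i in 1:3) for (j in (i + 1):4)
    if (.norm3(x[i, ] - x[j, ]) < 1e-8 * max(scale, 1))
      stop("degenerate geometry: coincident points")
  phi1 <- acos(max(-1, min(1, sum(-b1 * b2) / (.norm3(b1) * .norm3(b2))))) * DEG
  phi2 <- acos(max(-1, min(1, sum(-b2 * b3) / (.norm3(b2) * .norm3(b3))))) * DEG
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  tol <- 1e-10 * scale^2
  if (.norm3(n1) < tol || .norm3(n2) < tol)
    stop("torsion undefined: collinear atom triple")
  # atan2 dihedral: positive = clockwise rotation of bond 3-4 viewed down 2->3
  theta <- atan2(.norm3(b2) * sum(b1 * n2), sum(n1 * n2)) * DEG
  if (phi1 == 0) phi1 <- .Machine$double.eps  # open interval at 0
  if (phi2 == 0) phi2 <- .Machine$double.eps
  c(phi1 = phi1, phi2 = phi2, theta = wrap_theta(theta))
}

#' Place an atom from internal coordinates
#'
#' Given three anchor atoms `a`, `b`, `c`, returns the position `d` with bond
#' length `|c - d| = bond`, bond angle `angle(b, c, d)` and torsion
#' `dihedral(a, b, c, d)` as requested.  This is the elementary step of
#' head-to-tail fragment growth: each appended atom realises one letter's
#' (phi2, theta) pair exactly while the new window's phi1 is inherited from
#' the previous fragment (three shared atoms).
#'
#' @param a,b,c numeric 3-vectors, the three preceding atoms.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees (0, 180].
#' @param torsion dihedral in degrees (-180, 180].
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle / DEG
  tor <- torsion / DEG
  bc <- c - b
  bc <- bc / .norm3(bc)
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- .norm3(n)
  if (nn < 1e-12) stop("torsion undefined: collinear anchor atoms")
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build canonical fragment coordinates from internal angles
#'
#' Inverse of [fragment_angles()]: realises an angle triple as four Cartesian
#' points with uniform virtual C-alpha--C-alpha bonds.  Atom 1 sits at the
#' origin, atom 2 on the +x axis, atom 3 in the xy-plane (positive y), atom 4
#' wherever phi2 and theta demand.  The default 3.8 Angstrom bond is the
#' canonical trans-peptide C-alpha spacing.
#'
#' @param angles numeric triple `(phi1, phi2, theta)` in degrees.
#' @param bond virtual bond length in Angstrom (> 0).
#' @return 4 x 3 coordinate matrix; `fragment_angles()` of the result
#'   recovers `angles`.
#' @examples
#' build_fragment(c(90, 90, 0), bond = 1)
#' @export
build_fragment <- function(angles, bond = 3.8) {
  angles <- .check_angles(angles)
  if (!is.finite(bond) || bond <= 0) stop("'bond' must be positive")
  p1 <- c(0, 0, 0)
  p2 <- c(bond, 0, 0)
  phi1 <- angles[1L] / DEG
  p3 <- p2 + bond * c(-cos(phi1), sin(phi1), 0)
  p4 <- place_atom(p1, p2, p3, bond, angles[2L], angles[3L])
  rbind(p1, p2, p3, p4, deparse.level = 0)
}

#' Angular RMSD between fragment conformations (aRMSD)
#'
#' Root-mean-square deviation over the three internal angles,
#' `sqrt((dphi1^2 + dphi2^2 + dtheta^2) / 3)`, with the theta difference
#' taken on its periodic range so that it always lies in [0, 180].
#' This is the clustering metric of the angle space.
#'
#' @param a numeric triple `(phi1, phi2, theta)`.
#' @param b numeric triple, or an n x 3 matrix of triples (vectorised).
#' @return aRMSD in degrees (scalar, or length-n vector when `b` is a matrix).
#' @export
angle_distance <- function(a, b) {
  a <- as.numeric(a)
  if (is.matrix(b)) {
    d1 <- abs(b[, 1L] - a[1L])
    d2 <- abs(b[, 2L] - a[2L])
    dt <- abs(b[, 3L] - a[3L])
    dt <- pmin(dt, 360 - dt)
    return(unname(sqrt((d1^2 + d2^2 + dt^2) / 3)))
  }
  b <- as.numeric(b)
  dt <- abs(a[3L] - b[3L])
  dt <- min(dt, 360 - dt)
  sqrt((abs(a[1L] - b[1L])^2 + abs(a[2L] - b[2L])^2 + dt^2) / 3)
}

# Fast minimal cRMSD between two centred point sets via the closed-form
# singular-value route (Kabsch/quaternion-equivalent): rmsd^2 =
# (Gx + Gy - 2 * (s1 + s2 + sign(det C) * s3)) / n with C the 3x3
# cross-covariance.  X, Y already centred.
.centred_rmsd <- function(Xc, Yc, Gx, Gy) {
  C <- crossprod(Xc, Yc)
  s <- svd(C)
  dsum <- s$d[1L] + s$d[2L] + sign(det(C)) * s$d[3L]
  n <- nrow(Xc)
  sqrt(max(0, (Gx + Gy - 2 * dsum) / n))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits `mobile` onto `target` over a proper rotation and a
#' translation and reports the minimal coordinate RMSD (cRMSD).  Reflections
#' are never returned: if the best orthogonal transform is improper the last
#' singular direction is flipped.
#'
#' @param mobile,target N x 3 coordinate matrices (or `ca_trace`s), N >= 3.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (3-vector), `crmsd` (Angstrom), and `fitted`, the
#'   transformed mobile coordinates `(mobile - centroid) R + translation`.
#' @export
superpose <- function(mobile, target) {
  X <- .as_coords(mobile)
  Y <- .as_coords(target)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal length")
  if (nrow(X) < 3L) stop("superposition needs at least 3 points")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("coordinates must be finite")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  C <- crossprod(Xc, Yc)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  sv <- svd(Xc)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1e-12))
    warning("near-collinear point set: rotation is ill-determined")
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Xc %*% R
  crmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  fitted <- sweep(fitted, 2L, cy, "+")
  structure(list(rotation = R, translation = cy - as.numeric(cx %*% R),
                 crmsd = crmsd, fitted = fitted),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> cRMSD = %.4g Angstrom\n", x$crmsd))
  invisible(x)
}

#' Minimal cRMSD without the transform
#'
#' Convenience wrapper returning only the optimal-superposition RMSD; used in
#' inner loops where the rotation itself is not needed.
#'
#' @inheritParams superpose
#' @return cRMSD in Angstrom.
#' @export
crmsd <- function(mobile, target) {
  X <- .as_coords(mobile)
  Y <- .as_coords(target)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal length")
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  .centred_rmsd(Xc, Yc, sum(Xc^2), sum(Yc^2))
}

#' Sliding-window fragment angles of a chain
#'
#' Slices a C-alpha trace of length N into its N-3 overlapping four-residue
#' fragments and computes each fragment's internal angles.  Neighbouring
#' windows share three atoms, so phi2 of window i equals phi1 of window i+1
#' exactly.  Windows spanning a chain break (a consecutive C-alpha distance
#' outside `break_range`) are flagged invalid and carry NA angles.
#'
#' @param trace `ca_trace` (length >= 4) or N x 3 coordinate matrix.
#' @param break_range length-2 numeric: admissible consecutive C-alpha
#'   distances in Angstrom (default `c(2, 6)`); `NULL` disables break
#'   detection (e.g. for synthetic frames with deliberate coordinate noise).
#' @return `data.frame` with one row per window: `pos` (1-based index of the
#'   window's first residue), `phi1`, `phi2`, `theta`, `valid`.
#' @export
chain_to_fragments <- function(trace, break_range = c(2, 6)) {
  X <- .as_coords(trace)
  n <- nrow(X)
  if (n < 4L) stop("a trace must contain at least 4 C-alpha atoms")
  dists <- sqrt(rowSums((X[-1L, , drop = FALSE] - X[-n, , drop = FALSE])^2))
  bond_ok <- if (is.null(break_range)) rep(TRUE, n - 1L) else
    is.finite(dists) & dists >= break_range[1L] & dists <= break_range[2L]
  nw <- n - 3L
  out <- data.frame(pos = seq_len(nw), phi1 = NA_real_, phi2 = NA_real_,
                    theta = NA_real_, valid = FALSE)
  for (i in seq_len(nw)) {
    if (!all(bond_ok[i:(i + 2L)])) next
    ang <- tryCatch(fragment_angles(X[i:(i + 3L), ]), error = function(e) NULL)
    if (is.null(ang)) next
    out$phi1[i] <- ang[1L]
    out$phi2[i] <- ang[2L]
    out$theta[i] <- ang[3L]
    out$valid[i] <- TRUE
  }
  out
}

#' Internal degrees of freedom of a fragment
#'
#' A four-atom fragment has 3 x 4 Cartesian coordinates; removing the six
#' rigid-body degrees of freedom and the three fixed virtual bonds leaves
#' `3 * 4 - 6 - 3 = 3` internal degrees of freedom, which is why the triple
#' (phi1, phi2, theta) describes a conformation completely.
#'
#' @param n_atoms number of atoms in the fragment (default 4).
#' @return Integer count of internal degrees of freedom.
#' @export
fragment_dof <- function(n_atoms = 4L) {
  as.integer(3L * n_atoms - 6L - (n_atoms - 1L))
}
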