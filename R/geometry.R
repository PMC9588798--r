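# Structural measurements on atomic models: least-squares superposition,
# distances, the pivot reference frame at the hinge, and in-plane /
# out-of-plane Fab arm orientation angles.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the sum of squared
#' distances between paired atoms, and reports the post-fit RMSD. Pairing
#' is positional: the i-th atom of the mobile selection is paired with the
#' i-th atom of the reference selection. When selections are omitted, atoms
#' are paired by the (residue number, atom name) intersection of the two
#' models.
#'
#' @param mobile,reference `atomic_model` objects.
#' @param mobile_sel,reference_sel optional `domain_selection`s; both must
#'   yield the same number (>= 3) of atoms.
#' @return a list of class `rigid_transform` with elements `R` (3x3
#'   rotation), `t` (translation applied after rotation), and `rmsd`
#'   (Angstrom). `R %*% x + t` maps mobile coordinates onto the reference.
#' @export
superpose <- function(mobile, reference,
                      mobile_sel = NULL, reference_sel = NULL) {
  xm <- if (is.null(mobile_sel)) mobile$atoms else select_atoms(mobile, mobile_sel)
  xr <- if (is.null(reference_sel)) reference$atoms else select_atoms(reference, reference_sel)
  if (is.null(mobile_sel) && is.null(reference_sel) && nrow(xm) != nrow(xr)) {
    km <- paste(xm$resno, xm$elety)
    kr <- paste(xr$resno, xr$elety)
    shared <- intersect(km, kr)
    xm <- xm[match(shared, km), , drop = FALSE]
    xr <- xr[match(shared, kr), , drop = FALSE]
  }
  if (nrow(xm) != nrow(xr))
    stop("pairing error: selections yield ", nrow(xm), " vs ", nrow(xr), " atoms")
  if (nrow(xm) < 3)
    stop("underdetermined: need >= 3 atom pairs, got ", nrow(xm))
  P <- as.matrix(xm[, c("x", "y", "z")])
  Q <- as.matrix(xr[, c("x", "y", "z")])
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  fitted <- t(R %*% t(P)) + matrix(tvec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(R = R, t = tvec, rmsd = rmsd), class = "rigid_transform")
}

#' Apply a rigid transform to a model or coordinate matrix
#'
#' @param x an `atomic_model` or n x 3 matrix.
#' @param transform a `rigid_transform` from [superpose()].
#' @return object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  f <- function(xyz) t(transform$R %*% t(xyz)) +
    matrix(transform$t, nrow(xyz), 3, byrow = TRUE)
  if (inherits(x, "atomic_model")) set_model_xyz(x, f(model_xyz(x))) else f(x)
}

#' Euclidean distance between two atoms
#'
#' @param model an `atomic_model`.
#' @param a,b atom addresses: lists or vectors `(chain, resno, elety)`;
#'   `elety` defaults to `"CA"`.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(model, a, b) {
  addr <- function(z) {
    z <- as.list(z)
    atom_coord(model, z[[1]], as.integer(z[[2]]),
               if (length(z) >= 3) z[[3]] else "CA")
  }
  sqrt(sum((addr(a) - addr(b))^2))
}

#' Maximum extended length of a peptide linker
#'
#' Upper bound on the end-to-end length of a fully extended linker of `n`
#' residues at 3.5 Angstrom per residue.
#'
#' @param n_residues residue count (>= 0).
#' @param per_residue extension per residue in Angstrom (default 3.5).
#' @return length in Angstrom.
#' @export
max_extended_length <- function(n_residues, per_residue = 3.5) {
  if (any(n_residues < 0)) stop("residue count must be >= 0")
  n_residues * per_residue
}

#' Pivot reference frame
#'
#' The frame that defines the in-plane angle alpha and out-of-plane angle
#' beta of a Fab arm: a pivot point at the hinge, an in-plane zero axis
#' (the two-fold symmetry axis of the Cmu4 dimer), and the normal of the
#' Cmu4-Cmu3 platform plane. `beta_sign` selects which side of the platform
#' counts as positive beta (the J-chain hairpin-3 side is negative by the
#' convention used here).
#'
#' @param pivot xyz of the pivot point (Angstrom).
#' @param zero_axis unit vector of the alpha = 0 direction (in-plane).
#' @param normal unit normal of the platform plane (beta = 0).
#' @param beta_sign +1 or -1, sign convention for beta.
#' @return an object of class `pivot_frame` with an additional `transverse`
#'   axis completing the right-handed basis.
#' @export
pivot_frame <- function(pivot, zero_axis, normal, beta_sign = 1) {
  stopifnot(length(pivot) == 3, beta_sign %in% c(-1, 1))
  zero_axis <- unitize(zero_axis)
  normal <- unitize(normal)
  if (abs(sum(zero_axis * normal)) > 1e-6)
    stop("in-plane zero axis must be orthogonal to the plane normal")
  transverse <- unitize(crossprod_vec(normal, zero_axis))
  structure(list(pivot = as.numeric(pivot), zero_axis = zero_axis,
                 normal = normal, transverse = transverse,
                 beta_sign = beta_sign),
            class = "pivot_frame")
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Derive the pivot frame from a core model
#'
#' The in-plane zero axis is the axis of the two-fold rotation that best
#' maps one chain of the Cmu4 dimer onto the other; the platform normal is
#' the normal of the least-squares plane through the core selection's
#' atoms; the pivot point is the midpoint of the hinge-terminal residue
#' pair at the Cmu2/Cmu3 interface.
#'
#' @param core an `atomic_model` of the core.
#' @param dimer_sel_a,dimer_sel_b `domain_selection`s for the two chains of
#'   the two-fold dimer, yielding equal atom counts paired in order.
#' @param cterm_pair list of two atom addresses (see [atom_distance()])
#'   whose midpoint is the pivot point.
#' @param beta_sign sign convention passed through to [pivot_frame()].
#' @return a `pivot_frame`.
#' @export
define_pivot_frame <- function(core, dimer_sel_a, dimer_sel_b, cterm_pair,
                               beta_sign = 1) {
  tr <- superpose(core, core, dimer_sel_a, dimer_sel_b)
  ang <- rotation_angle(tr$R)
  if (abs(ang - 180) > 20)
    stop("symmetry error: dimer rotation is ", round(ang, 1),
         " deg, not a two-fold")
  axis <- rotation_axis(tr$R)
  # platform normal: smallest principal axis of the core selection
  coords <- rbind(as.matrix(select_atoms(core, dimer_sel_a)[, c("x", "y", "z")]),
                  as.matrix(select_atoms(core, dimer_sel_b)[, c("x", "y", "z")]))
  cen <- colMeans(coords)
  ev <- eigen(stats::cov(coords), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  # orthogonalise the two-fold axis against the plane normal
  axis <- unitize(axis - sum(axis * normal) * normal)
  addr <- function(z) {
    z <- as.list(z)
    atom_coord(core, z[[1]], as.integer(z[[2]]),
               if (length(z) >= 3) z[[3]] else "CA")
  }
  pivot <- (addr(cterm_pair[[1]]) + addr(cterm_pair[[2]])) / 2
  pivot_frame(pivot, axis, normal, beta_sign = beta_sign)
}

# axis and angle of a rotation matrix
rotation_angle <- function(R) rad2deg(acos(clamp1((sum(diag(R)) - 1) / 2)))

rotation_axis <- function(R) {
  # eigenvector with eigenvalue 1; stable for angles near 180 deg
  M <- R + t(R) + (1 - sum(diag(R))) * diag(3)
  j <- which.max(diag(M))
  unitize(M[, j])
}

#' Measure the orientation of a Fab arm
#'
#' The arm direction is the unit vector from the hinge-terminal atom (the
#' C-terminus of Cmu2) to the centroid of the constant-domain selection.
#' Alpha is the signed angle of its in-plane projection measured from the
#' frame's zero axis; beta is the signed elevation out of the platform
#' plane. When the arm is parallel to the plane normal the in-plane
#' projection is degenerate and alpha is reported as 0.
#'
#' @param model an `atomic_model`.
#' @param frame a `pivot_frame`.
#' @param cterm atom address of the arm origin (chain, resno, elety).
#' @param constant_sel `domain_selection` for the constant domain; its
#'   CA-atom centroid defines the arm end point. Pass `elety = "CA"`
#'   filters in the selection if the model has side chains.
#' @return a list of class `fab_orientation`: `alpha`, `beta` (degrees, in
#'   [-180, 180]) and `direction` (unit vector).
#' @export
measure_fab_orientation <- function(model, frame, cterm, constant_sel) {
  stopifnot(inherits(frame, "pivot_frame"))
  z <- as.list(cterm)
  origin <- atom_coord(model, z[[1]], as.integer(z[[2]]),
                       if (length(z) >= 3) z[[3]] else "CA")
  dom <- select_atoms(model, constant_sel)
  centroid <- colMeans(as.matrix(dom[, c("x", "y", "z")]))
  v <- centroid - origin
  if (sqrt(sum(v^2)) < 1e-9) stop("degenerate geometry: zero-length arm")
  u <- unitize(v)
  s <- sum(u * frame$normal)
  beta <- frame$beta_sign * rad2deg(asin(clamp1(s)))
  px <- sum(u * frame$zero_axis)
  py <- sum(u * frame$transverse)
  alpha <- if (sqrt(px^2 + py^2) < 1e-9) 0 else rad2deg(atan2(py, px))
  structure(list(alpha = alpha, beta = beta, direction = u),
            class = "fab_orientation")
}

#' Angle between two Fab arms
#'
#' @param fab1,fab2 `fab_orientation` objects (or unit vectors).
#' @return angle in degrees, in [0, 180].
#' @export
inter_arm_angle <- function(fab1, fab2) {
  d1 <- if (inherits(fab1, "fab_orientation")) fab1$direction else unitize(fab1)
  d2 <- if (inherits(fab2, "fab_orientation")) fab2$direction else unitize(fab2)
  rad2deg(acos(clamp1(sum(d1 * d2))))
}
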