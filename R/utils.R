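# Small internal geometry helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation by `angle` degrees
#' about the (not necessarily unit) vector `axis`.
#'
#' @param axis numeric length-3 axis vector.
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  u <- axis / n
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# numerical clamp for acos/asin arguments
clamp1 <- function(x) pmin(1, pmax(-1, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
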