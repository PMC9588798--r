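# Voxel density maps, pseudo-atom Gaussian rendering, rigid pivoting, and
# motion-blurred pivot-ensemble simulation.
#
# A density_map holds a 3D numeric array `values` (x fastest, column-major),
# an isotropic voxel size in Angstrom, and the coordinate of the first voxel
# centre (`origin`). All geometry is in Angstrom.

#' Density map constructor
#'
#' @param values 3D numeric array (axis order x, y, z).
#' @param voxel isotropic voxel size in Angstrom (> 0).
#' @param origin xyz coordinate of the centre of voxel (1,1,1).
#' @return an object of class `density_map`.
#' @export
density_map <- function(values, voxel, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(voxel) == 1, voxel > 0, length(origin) == 3)
  if (!all(is.finite(values))) stop("density values must be finite")
  structure(list(values = values, voxel = as.numeric(voxel),
                 origin = as.numeric(origin), axis_order = "xyz"),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels @ %.3f A, origin (%.1f, %.1f, %.1f)\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range [%.4g, %.4g], integral %.4g\n",
              min(x$values), max(x$values), map_integral(x)))
  invisible(x)
}

#' Integral of a density map
#'
#' Sum of voxel values times voxel volume.
#' @param map a `density_map`.
#' @return numeric integral (Angstrom^3 weighted density).
#' @export
map_integral <- function(map) sum(map$values) * map$voxel^3

#' Grid specification enclosing one or more models
#'
#' @param models an `atomic_model` or list of them.
#' @param voxel voxel size in Angstrom.
#' @param margin clearance beyond the atom bounding box in Angstrom.
#' @param center optional xyz; when given, the grid is a cube centred there
#'   with half-extent `half_extent`.
#' @param half_extent cube half-extent, used with `center`.
#' @return list with `origin`, `dim`, `voxel`.
#' @export
grid_spec <- function(models = NULL, voxel = 2.0, margin = 8,
                      center = NULL, half_extent = NULL) {
  if (!is.null(center)) {
    stopifnot(!is.null(half_extent))
    n <- 2L * as.integer(ceiling(half_extent / voxel)) + 1L
    origin <- center - (n - 1) / 2 * voxel
    return(list(origin = origin, dim = rep(n, 3L), voxel = voxel))
  }
  if (inherits(models, "atomic_model")) models <- list(models)
  xyz <- do.call(rbind, lapply(models, model_xyz))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  n <- as.integer(ceiling((hi - lo) / voxel)) + 1L
  list(origin = lo, dim = n, voxel = voxel)
}

# splat unit-integral Gaussians at xyz into an accumulator array
.splat <- function(vals, grid, xyz, sigma, weight = 1) {
  h <- grid$voxel
  dm <- grid$dim
  hw <- ceiling(5 * sigma / h)   # kernel half-width in voxels
  norm1 <- 1 / (sqrt(2 * pi) * sigma)
  for (k in seq_len(nrow(xyz))) {
    fidx <- (xyz[k, ] - grid$origin) / h + 1   # fractional voxel index
    c0 <- round(fidx)
    ix <- max(1, c0[1] - hw):min(dm[1], c0[1] + hw)
    iy <- max(1, c0[2] - hw):min(dm[2], c0[2] + hw)
    iz <- max(1, c0[3] - hw):min(dm[3], c0[3] + hw)
    gx <- norm1 * exp(-((ix - fidx[1]) * h)^2 / (2 * sigma^2))
    gy <- norm1 * exp(-((iy - fidx[2]) * h)^2 / (2 * sigma^2))
    gz <- norm1 * exp(-((iz - fidx[3]) * h)^2 / (2 * sigma^2))
    vals[ix, iy, iz] <- vals[ix, iy, iz] + weight * outer(gx, outer(gy, gz))
  }
  vals
}

#' Render an atomic model as a Gaussian pseudo-atom density
#'
#' Each atom contributes an isotropic 3D Gaussian of width `atom_sigma`
#' (Angstrom) and unit integral; the map is the sum of contributions. All
#' atoms are weighted equally: the analysis operates on shape envelopes at
#' low threshold, so element-dependent scattering factors are not applied.
#'
#' @param model an `atomic_model`.
#' @param grid a grid specification from [grid_spec()].
#' @param atom_sigma Gaussian width per atom in Angstrom (default 2.0).
#' @return a `density_map`.
#' @export
render_density <- function(model, grid, atom_sigma = 2.0) {
  xyz <- model_xyz(model)
  hi <- grid$origin + (grid$dim - 1) * grid$voxel
  outside <- rowSums(sweep(xyz, 2, grid$origin, `<`)) > 0 |
    rowSums(sweep(xyz, 2, hi, `>`)) > 0
  if (any(outside))
    stop("bounds error: ", sum(outside), " atom(s) outside the grid")
  vals <- array(0, grid$dim)
  vals <- .splat(vals, grid, xyz, atom_sigma)
  density_map(vals, grid$voxel, grid$origin)
}

#' Rotate a model rigidly about the pivot
#'
#' Applies the hinge rotation `(alpha, beta)` about the frame axes through
#' the pivot point: the arm is elevated by `beta` about the transverse axis
#' and swung in-plane by `alpha` about the platform normal, composed so
#' that [measure_fab_orientation()] on the rotated rest arm reads back
#' exactly `(alpha, beta)`. The pivot point does not move and all pairwise
#' distances are preserved.
#'
#' @param model an `atomic_model`.
#' @param frame a `pivot_frame`.
#' @param alpha in-plane angle, degrees.
#' @param beta out-of-plane angle, degrees.
#' @param inverse apply the inverse rotation instead.
#' @return the rotated `atomic_model`.
#' @export
rotate_about_pivot <- function(model, frame, alpha, beta, inverse = FALSE) {
  stopifnot(inherits(frame, "pivot_frame"))
  R <- rotation_matrix(frame$normal, alpha) %*%
    rotation_matrix(frame$transverse, -beta * frame$beta_sign)
  if (inverse) R <- t(R)
  xyz <- model_xyz(model)
  xyz0 <- sweep(xyz, 2, frame$pivot)
  set_model_xyz(model, t(R %*% t(xyz0)) +
                  matrix(frame$pivot, nrow(xyz), 3, byrow = TRUE))
}

#' Orientation grid for a pivot ensemble
#'
#' The Cartesian product of in-plane and out-of-plane angle samples with
#' per-pair weights (uniform by default, normalised to sum to one). An
#' optional cosine taper down-weights extreme orientations.
#'
#' @param alpha in-plane samples, degrees.
#' @param beta out-of-plane samples, degrees.
#' @param weights optional non-negative weight per (alpha, beta) pair, in
#'   `expand.grid(alpha, beta)` order.
#' @param taper `"uniform"` (default) or `"cosine"`.
#' @return data frame of class `orientation_grid` with columns `alpha`,
#'   `beta`, `weight`.
#' @export
orientation_grid <- function(alpha = 0, beta = 0, weights = NULL,
                             taper = c("uniform", "cosine")) {
  taper <- match.arg(taper)
  g <- expand.grid(alpha = alpha, beta = beta)
  if (nrow(g) == 0) stop("config error: empty orientation grid")
  if (is.null(weights)) {
    weights <- if (taper == "cosine") {
      amax <- max(abs(g$alpha), 1e-9); bmax <- max(abs(g$beta), 1e-9)
      cos(deg2rad(g$alpha) / 2 * (90 / amax)) *
        cos(deg2rad(g$beta) / 2 * (90 / bmax))
    } else rep(1, nrow(g))
  }
  if (length(weights) != nrow(g) || any(weights < 0))
    stop("config error: weights must be non-negative, one per pair")
  g$weight <- weights / sum(weights)
  structure(g, class = c("orientation_grid", "data.frame"))
}

#' Simulate the motion-blurred density of a pivoting rigid body
#'
#' Renders the model at every orientation of the grid and averages the
#' renders with the grid weights: the output models a reconstructed map as
#' the convolution of the molecule's density with the distribution of its
#' hinge motion.
#'
#' @param model an `atomic_model` (the moving rigid body).
#' @param frame a `pivot_frame`.
#' @param ogrid an `orientation_grid`.
#' @param grid a grid specification from [grid_spec()].
#' @param atom_sigma per-atom Gaussian width in Angstrom.
#' @param static optional `atomic_model` rendered once without rotation
#'   (e.g. the rigid core).
#' @return a `density_map`.
#' @export
simulate_pivot_ensemble <- function(model, frame, ogrid, grid,
                                    atom_sigma = 2.0, static = NULL) {
  stopifnot(inherits(ogrid, "orientation_grid"))
  vals <- array(0, grid$dim)
  hi <- grid$origin + (grid$dim - 1) * grid$voxel
  for (i in seq_len(nrow(ogrid))) {
    rot <- rotate_about_pivot(model, frame, ogrid$alpha[i], ogrid$beta[i])
    xyz <- model_xyz(rot)
    if (any(sweep(xyz, 2, grid$origin, `<`)) || any(sweep(xyz, 2, hi, `>`)))
      stop("bounds error: rotated model leaves the grid at (",
           ogrid$alpha[i], ", ", ogrid$beta[i], ") deg")
    vals <- .splat(vals, grid, xyz, atom_sigma, weight = ogrid$weight[i])
  }
  if (!is.null(static)) vals <- .splat(vals, grid, model_xyz(static), atom_sigma)
  density_map(vals, grid$voxel, grid$origin)
}

#' Overlap fraction of two maps at a threshold
#'
#' Jaccard fraction: voxels above threshold in both maps divided by voxels
#' above threshold in either.
#'
#' @param a,b `density_map`s on identical grids.
#' @param threshold map value threshold.
#' @return fraction in [0, 1] (1 when both sets are empty).
#' @export
map_overlap <- function(a, b, threshold) {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$voxel - b$voxel) > 1e-9 || any(abs(a$origin - b$origin) > 1e-6))
    stop("geometry error: maps are on different grids")
  A <- a$values > threshold
  B <- b$values > threshold
  union <- sum(A | B)
  if (union == 0) return(1)
  sum(A & B) / union
}
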