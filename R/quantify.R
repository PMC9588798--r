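# Quantification of the angular motion range of a flexible arm from a
# density map: smooth, take cross-sections, fit/locate the arc centre,
# profile grey values versus angle at the arc radii, and bound the range
# with a background-SNR criterion.

#' Smooth a map with an isotropic 3D Gaussian
#'
#' Separable truncated-Gaussian convolution (kernel half-width 4 sigma),
#' with edge renormalisation so a constant map is unchanged. `sigma_px = 0`
#' returns the input untouched.
#'
#' @param map a `density_map`.
#' @param sigma_px Gaussian sigma in pixels (voxels), >= 0. Default 3.
#' @return the smoothed `density_map`.
#' @export
smooth_map <- function(map, sigma_px = 3) {
  if (sigma_px < 0) stop("smoothing sigma must be >= 0")
  if (sigma_px == 0) return(map)
  v <- map$values
  d <- dim(v)
  K <- lapply(d, .gauss_band, sigma = sigma_px)
  # axis 1
  v <- array(K[[1]] %*% matrix(v, d[1], d[2] * d[3]), d)
  # axis 2
  v <- aperm(array(K[[2]] %*% matrix(aperm(v, c(2, 1, 3)), d[2], d[1] * d[3]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  v <- aperm(array(K[[3]] %*% matrix(aperm(v, c(3, 1, 2)), d[3], d[1] * d[2]),
                   c(d[3], d[1], d[2])), c(2, 3, 1))
  density_map(v, map$voxel, map$origin)
}

# 1D convolution matrix with a truncated normalised Gaussian and mirror
# boundary: constants are preserved exactly and interior mass is conserved
.gauss_band <- function(n, sigma) {
  hw <- min(ceiling(4 * sigma), n - 1)
  w <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (o in -hw:hw) {
    j <- seq_len(n) + o
    j <- ifelse(j < 1, 1 - j + 1, ifelse(j > n, 2 * n - j + 1, j))  # mirror
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[o + hw + 1]
  }
  K
}

#' Cross-section of a map
#'
#' Trilinear interpolation of the map on a 2D lattice at voxel pitch in the
#' plane defined by a point, two orthonormal in-plane basis vectors `u`,
#' `v`, and the implied normal. Lattice points falling outside the grid are
#' NA. The section pixel at in-plane coordinates (0, 0) is the plane point.
#'
#' @param map a `density_map`.
#' @param point xyz point in the plane (Angstrom).
#' @param u,v orthonormal in-plane basis vectors; profile angle 0 lies
#'   along `u`, positive angles toward `v`.
#' @param half_extent half-width of the sampled lattice in Angstrom;
#'   defaults to covering the whole grid.
#' @return object of class `cross_section`: `image` (matrix, rows index the
#'   `u` coordinate), `s`, `t` (pixel centre coordinates along `u`, `v`),
#'   `pixel`, `point`, `u`, `v`.
#' @export
extract_cross_section <- function(map, point, u, v, half_extent = NULL) {
  u <- unitize(u); v <- unitize(v)
  if (abs(sum(u * v)) > 1e-8) stop("section basis must be orthonormal")
  h <- map$voxel
  if (is.null(half_extent)) half_extent <- max(dim(map$values)) * h / 2
  s <- seq(-half_extent, half_extent, by = h)
  t <- seq(-half_extent, half_extent, by = h)
  P <- cbind(rep(s, times = length(t)), rep(t, each = length(s)))
  pts <- matrix(point, nrow(P), 3, byrow = TRUE) + P[, 1] %o% u + P[, 2] %o% v
  val <- .trilinear(map, pts)
  if (all(is.na(val))) stop("geometry error: plane does not intersect the grid")
  structure(list(image = matrix(val, length(s), length(t)),
                 s = s, t = t, pixel = h, point = point, u = u, v = v),
            class = "cross_section")
}

.trilinear <- function(map, pts) {
  d <- dim(map$values)
  f <- sweep(pts, 2, map$origin) / map$voxel + 1  # fractional indices
  i0 <- floor(f)
  w <- f - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] <= d[1] - 1 & i0[, 2] <= d[2] - 1 & i0[, 3] <= d[3] - 1
  # include exact top boundary
  top <- abs(f - matrix(d, nrow(f), 3, byrow = TRUE)) < 1e-9
  i0[top] <- i0[top] - 1
  w[top] <- 1
  ok <- ok | (rowSums(top) > 0 &
                i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
                i0[, 1] <= d[1] - 1 & i0[, 2] <= d[2] - 1 & i0[, 3] <= d[3] - 1)
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0k <- i0[ok, , drop = FALSE]; wk <- w[ok, , drop = FALSE]
  g <- function(dx, dy, dz) {
    idx <- cbind(i0k[, 1] + dx, i0k[, 2] + dy, i0k[, 3] + dz)
    wt <- (if (dx == 0) 1 - wk[, 1] else wk[, 1]) *
      (if (dy == 0) 1 - wk[, 2] else wk[, 2]) *
      (if (dz == 0) 1 - wk[, 3] else wk[, 3])
    map$values[idx] * wt
  }
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) acc <- acc + g(dx, dy, dz)
  out[ok] <- acc
  out
}

#' Convert a cross-section to 8-bit grey values
#'
#' Linear min-max rescale to integers 0-255 (round half up); a constant
#' image maps to all zeros. NA pixels stay NA.
#'
#' @param section a `cross_section`.
#' @return the quantised `cross_section`.
#' @export
to_8bit <- function(section) {
  img <- section$image
  rng <- range(img, na.rm = TRUE)
  section$image <- if (rng[2] > rng[1])
    floor((img - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  else img * 0
  section
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) fit followed by geometric Gauss-Newton refinement of
#' the summed squared radial residuals.
#'
#' @param points n x 2 matrix of 2D points (n >= 3, not collinear).
#' @return list of class `arc_fit`: `center` (length 2), `radius`,
#'   `residual` (rms radial residual).
#' @export
fit_arc_circle <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 3) stop("need >= 3 points for a circle fit")
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2)
    stop("degenerate fit: points are collinear")
  sol <- qr.solve(A, x^2 + y^2)
  cen <- sol[1:2]
  r <- sqrt(sol[3] + sum(cen^2))
  # geometric refinement
  obj <- function(p) {
    ri <- sqrt((x - p[1])^2 + (y - p[2])^2)
    sum((ri - p[3])^2)
  }
  opt <- stats::optim(c(cen, r), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  cen <- opt$par[1:2]; r <- opt$par[3]
  ri <- sqrt((x - cen[1])^2 + (y - cen[2])^2)
  structure(list(center = cen, radius = r,
                 residual = sqrt(mean((ri - r)^2))),
            class = "arc_fit")
}

#' Grey-value profile along an arc
#'
#' Samples the section image by bilinear interpolation along a circle of
#' given radius about a centre, at a series of angles measured from the
#' section's `u` axis (positive toward `v`).
#'
#' @param section a `cross_section`.
#' @param center length-2 centre in section coordinates (same units as
#'   `section$s`).
#' @param radius arc radius (Angstrom).
#' @param window half-window of scanned angles in degrees.
#' @param step angular step in degrees (default 1).
#' @return object of class `angular_profile`: `angles` (deg, ascending),
#'   `values`, `radius`, `center`.
#' @export
angular_profile <- function(section, center, radius, window = 85, step = 1) {
  angles <- seq(-window, window, by = step)
  th <- deg2rad(angles)
  ps <- center[1] + radius * cos(th)
  pt <- center[2] + radius * sin(th)
  val <- .bilinear(section, ps, pt)
  if (any(is.na(val)))
    stop("bounds error: sampling ring leaves the section image")
  structure(list(angles = angles, values = val, radius = radius,
                 center = center), class = "angular_profile")
}

.bilinear <- function(section, ps, pt) {
  img <- section$image
  h <- section$pixel
  fi <- (ps - section$s[1]) / h + 1
  fj <- (pt - section$t[1]) / h + 1
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  d <- dim(img)
  top_i <- abs(fi - d[1]) < 1e-9; i0[top_i] <- i0[top_i] - 1; wi[top_i] <- 1
  top_j <- abs(fj - d[2]) < 1e-9; j0[top_j] <- j0[top_j] - 1; wj[top_j] <- 1
  ok <- i0 >= 1 & j0 >= 1 & i0 <= d[1] - 1 & j0 <= d[2] - 1
  out <- rep(NA_real_, length(ps))
  if (!any(ok)) return(out)
  i0k <- i0[ok]; j0k <- j0[ok]; wik <- wi[ok]; wjk <- wj[ok]
  v <- img[cbind(i0k, j0k)] * (1 - wik) * (1 - wjk) +
    img[cbind(i0k + 1, j0k)] * wik * (1 - wjk) +
    img[cbind(i0k, j0k + 1)] * (1 - wik) * wjk +
    img[cbind(i0k + 1, j0k + 1)] * wik * wjk
  out[ok] <- v
  out
}

#' Background statistics of a section
#'
#' Sample mean and standard deviation (n - 1 denominator) over pixels
#' outside an exclusion region.
#'
#' @param section a `cross_section`.
#' @param exclude_center length-2 centre of the excluded disc (section
#'   coordinates); default the section centre (0, 0).
#' @param exclude_radius radius of the excluded disc in Angstrom. Pixels
#'   inside it are not background.
#' @param mask optional logical matrix (same shape as the image); TRUE
#'   pixels are additionally excluded.
#' @return list of class `background_stats`: `mean`, `sd`, `n`.
#' @export
background_stats <- function(section, exclude_center = c(0, 0),
                             exclude_radius = 0, mask = NULL) {
  img <- section$image
  S <- matrix(section$s, nrow(img), ncol(img))
  Tt <- matrix(section$t, nrow(img), ncol(img), byrow = TRUE)
  keep <- !is.na(img) &
    (S - exclude_center[1])^2 + (Tt - exclude_center[2])^2 >= exclude_radius^2
  if (!is.null(mask)) keep <- keep & !mask
  px <- img[keep]
  if (length(px) < 2)
    stop("sampling error: fewer than 2 background pixels after exclusion")
  structure(list(mean = mean(px), sd = stats::sd(px), n = length(px)),
            class = "background_stats")
}

#' Background signal-to-noise ratio
#'
#' The boundary criterion statistic: `(grey - mean(BKG)) / sd(BKG)`. A
#' profile point is considered part of the motion range while this ratio is
#' at least the threshold (2 by convention).
#'
#' @param grey grey value(s).
#' @param bkg a `background_stats`.
#' @return dimensionless ratio(s).
#' @export
snr_ratio <- function(grey, bkg) {
  stopifnot(inherits(bkg, "background_stats"))
  if (bkg$sd <= 0)
    stop("degenerate background: standard deviation is zero")
  (grey - bkg$mean) / bkg$sd
}

#' Boundary of the motion range from an angular profile
#'
#' Walks outward from the central peak in each sign direction. The grey
#' threshold is `bkg$mean + max(threshold * bkg$sd,
#' rel_floor * (peak - bkg$mean))`; the relative floor keeps the criterion
#' defined on noise-free maps whose background deviation is zero. The
#' boundary per sign is the outermost resolvable arc peak (local profile
#' maximum, away from the centre) whose height passes
#' `bkg$mean + max(threshold * bkg$sd, peak_floor * (peak - bkg$mean))`;
#' profiles with no off-centre local maxima (monotone or plateau-shaped)
#' fall back to the linearly interpolated threshold crossing of the
#' outermost significant run. A run still above threshold at the window
#' edge is reported at the edge and flagged.
#'
#' @param profile an `angular_profile`.
#' @param bkg a `background_stats`.
#' @param threshold SNR threshold (default 2).
#' @param rel_floor relative floor for the crossing threshold (default 0.15
#'   of the background-subtracted central peak).
#' @param peak_floor relative floor for counting an arc peak as present
#'   (default 0.3).
#' @param min_run minimum run length (samples) for a significant segment.
#' @return list of class `motion_boundary`: `negative`, `positive`
#'   (degrees, both >= 0 magnitudes of the boundary angles),
#'   `at_window_edge` (logical length 2), `grey_threshold`.
#' @export
motion_boundary <- function(profile, bkg, threshold = 2, rel_floor = 0.15,
                            peak_floor = 0.3, min_run = 3) {
  stopifnot(inherits(profile, "angular_profile"))
  th <- profile$angles
  v <- profile$values
  step <- th[2] - th[1]
  central <- abs(th) <= max(15, 3 * step)
  peak <- max(v[central])
  if (bkg$sd > 0 && peak < bkg$mean + threshold * bkg$sd)
    stop("no-signal error: central peak does not exceed the criterion")
  height <- peak - bkg$mean
  if (height <= 0) stop("no-signal error: central peak at background level")
  t_edge <- bkg$mean + max(threshold * bkg$sd, rel_floor * height)
  t_peak <- bkg$mean + max(threshold * bkg$sd, peak_floor * height)
  mask <- v >= t_edge
  if (!any(mask & central))
    stop("no-signal error: centre of the profile is below threshold")
  # strict interior local maxima
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE)
  one_sign <- function(sgn) {
    idx <- if (sgn > 0) which(th >= 0) else rev(which(th <= 0))
    vv <- v[idx]
    mm <- mask[idx]
    # significant runs walking outward from the centre
    r <- rle(mm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keepruns <- which(r$values & r$lengths >= min_run)
    if (length(keepruns) == 0) keepruns <- which(r$values)[1]
    if (length(keepruns) == 0 || all(is.na(keepruns)))
      return(list(boundary = 0, edge = FALSE))
    last <- max(keepruns)
    outer_i <- ends[last]
    edge <- outer_i == length(idx) && vv[outer_i] > t_edge
    at_edge <- outer_i == length(idx)
    # outermost eligible off-centre peak within significant runs
    run_members <- unlist(lapply(keepruns, function(k) starts[k]:ends[k]))
    cand <- idx[run_members]
    cand <- cand[is_max[cand] & v[cand] >= t_peak &
                   abs(th[cand]) > max(2 * step, 3)]
    if (length(cand) > 0) {
      b <- max(abs(th[cand]))
      return(list(boundary = b, edge = FALSE))
    }
    if (at_edge) return(list(boundary = abs(th[idx[outer_i]]), edge = TRUE))
    # interpolated crossing between the last in-run sample and the next
    i1 <- idx[outer_i]
    i2 <- if (sgn > 0) i1 + 1 else i1 - 1
    frac <- if (v[i1] == v[i2]) 0 else (v[i1] - t_edge) / (v[i1] - v[i2])
    list(boundary = abs(th[i1]) + frac * step, edge = FALSE)
  }
  neg <- one_sign(-1)
  pos <- one_sign(+1)
  structure(list(negative = neg$boundary, positive = pos$boundary,
                 at_window_edge = c(negative = neg$edge, positive = pos$edge),
                 grey_threshold = t_edge),
            class = "motion_boundary")
}

#' Locate the arc radii of a pivoting-arm density
#'
#' Ring-mean radial profile: on the two mid-sections through the pivot
#' (in-plane and out-of-plane), the map value is averaged along the arc of
#' each radius over the angular window and scaled by r, and the two
#' sections are summed. Because every orientation of a pivoting rigid body
#' keeps its domains at fixed distance from the pivot, the domains appear
#' as local maxima at their true radii regardless of how widely the
#' ensemble is spread, and averaging along the ring suppresses voxel
#' noise. Maxima below a relative floor or below a robust noise floor
#' (median + 5 MAD of the outermost rings) are ignored.
#'
#' @param map a (smoothed) `density_map`.
#' @param frame a `pivot_frame`; rings are centred on the pivot.
#' @param r_min,r_max radial search range in Angstrom; `r_max` defaults to
#'   just inside the grid.
#' @param window angular half-window of the ring average, degrees.
#' @param floor_frac local maxima below `floor_frac` of the profile
#'   maximum are ignored.
#' @return data frame with columns `radius` and `value` (summed ring mean
#'   times r), one row per detected arc, ordered by radius.
#' @export
detect_arc_radii <- function(map, frame, r_min = 12, r_max = NULL,
                             window = 85, floor_frac = 0.08) {
  h <- map$voxel
  lo <- map$origin; hi <- map$origin + (dim(map$values) - 1) * h
  if (is.null(r_max))
    r_max <- 0.95 * min(pmin(frame$pivot - lo, hi - frame$pivot))
  sec_ip <- extract_cross_section(map, frame$pivot, frame$zero_axis,
                                  frame$transverse)
  sec_op <- extract_cross_section(map, frame$pivot, frame$zero_axis,
                                  frame$normal * frame$beta_sign)
  th <- deg2rad(seq(-window, window, by = 1))
  radii <- seq(r_min, r_max, by = h)
  ring_mean <- function(sec, r) {
    val <- .bilinear(sec, r * cos(th), r * sin(th))
    if (all(is.na(val))) NA_real_ else mean(val, na.rm = TRUE)
  }
  prof <- vapply(radii, function(r)
    (ring_mean(sec_ip, r) + ring_mean(sec_op, r)) * r, numeric(1))
  usable <- is.finite(prof)
  radii <- radii[usable]
  prof <- prof[usable]
  if (length(prof) < 5) return(data.frame(radius = numeric(0), value = numeric(0)))
  n <- length(prof)
  tail_i <- radii > r_min + 0.8 * (max(radii) - r_min)
  noise_floor <- if (sum(tail_i) >= 5)
    stats::median(prof[tail_i]) + 5 * stats::mad(prof[tail_i]) else 0
  is_max <- c(FALSE, prof[2:(n - 1)] > prof[1:(n - 2)] &
                prof[2:(n - 1)] >= prof[3:n], FALSE)
  sel <- which(is_max & prof > pmax(floor_frac * max(prof), noise_floor))
  data.frame(radius = radii[sel], value = prof[sel])
}

#' Ridge points along an arc band
#'
#' For each scanned angle, the radial position of the maximum grey value
#' within a radial band; points brighter than half the band maximum are
#' returned as 2D coordinates for circle fitting.
#'
#' @param section a `cross_section`.
#' @param center approximate centre (section coordinates).
#' @param radius nominal arc radius; the band is `radius +- band`.
#' @param band radial half-band in Angstrom (default 10).
#' @param window angular half-window (degrees).
#' @return n x 2 matrix of points.
#' @export
arc_ridge_points <- function(section, center, radius, band = 10, window = 80) {
  angles <- seq(-window, window, by = 2)
  rr <- seq(max(section$pixel, radius - band), radius + band,
            by = section$pixel / 2)
  pts <- NULL
  vals <- NULL
  for (a in deg2rad(angles)) {
    val <- .bilinear(section, center[1] + rr * cos(a), center[2] + rr * sin(a))
    if (all(is.na(val))) next
    j <- which.max(val)
    pts <- rbind(pts, c(center[1] + rr[j] * cos(a), center[2] + rr[j] * sin(a)))
    vals <- c(vals, val[j])
  }
  keep <- vals > 0.5 * max(vals)
  pts[keep, , drop = FALSE]
}

#' Measure the angular motion range of a map
#'
#' The full pipeline: Gaussian smoothing, six consecutive cross-sections at
#' one-voxel spacing centred on the mid-plane for each axis, optional 8-bit
#' conversion, automatic arc-radius detection on the middle section,
#' background statistics outside the cloud, angular profiles at the inner
#' and outer arc radii, and the SNR boundary criterion per section and
#' sign. The reported range per axis and sign is the arithmetic mean over
#' sections of the chosen arc's boundaries.
#'
#' @param map a `density_map`.
#' @param frame a `pivot_frame` supplying the pivot (arc centre) and axes.
#' @param axes which axes to measure (`"in_plane"`, `"out_of_plane"`).
#' @param n_sections number of consecutive sections per axis (default 6).
#' @param smooth_sigma_px smoothing sigma in voxels (default 3).
#' @param use_8bit convert sections to 8-bit grey values first (default
#'   TRUE, mirroring the reference image pipeline).
#' @param arc which arc defines the reported range: `"outer"` (variable
#'   domain, default: the arm-tip arc has the largest radius and therefore
#'   the best angular resolution at a given smoothing width) or `"inner"`
#'   (constant domain). Boundaries for both arcs are always reported in
#'   `sections`.
#' @param radii optional numeric vector `c(inner, outer)` overriding
#'   automatic arc-radius detection.
#' @param window,step angular window half-width and step in degrees.
#' @param threshold SNR threshold (default 2).
#' @param rel_floor,peak_floor see [motion_boundary()].
#' @param bkg_factor background pixels lie farther than
#'   `bkg_factor * outer radius` from the centre (default 1.5).
#' @param refit_center re-estimate the arc centre per section by circle
#'   fitting of ridge points instead of using the frame pivot.
#' @return object of class `motion_range`: `sections` (data frame: axis,
#'   arc, section, sign, boundary, at_window_edge), `summary` (data frame:
#'   axis, arc, sign, mean boundary), `radii`, and the call parameters.
#' @export
motion_range <- function(map, frame,
                         axes = c("in_plane", "out_of_plane"),
                         n_sections = 6, smooth_sigma_px = 3,
                         use_8bit = FALSE, arc = c("outer", "inner"),
                         radii = NULL, window = 85, step = 1,
                         threshold = 2, rel_floor = 0.15, peak_floor = 0.3,
                         bkg_factor = 1.5, refit_center = FALSE) {
  stopifnot(inherits(map, "density_map"), inherits(frame, "pivot_frame"))
  arc <- match.arg(arc)
  axes <- match.arg(axes, c("in_plane", "out_of_plane"), several.ok = TRUE)
  sm <- smooth_map(map, smooth_sigma_px)
  h <- map$voxel
  offsets <- (seq_len(n_sections) - (n_sections + 1) / 2) * h
  rows <- list()
  radii_used <- radii
  if (is.null(radii_used)) {
    arcs <- detect_arc_radii(sm, frame)
    if (nrow(arcs) < 2)
      stop("could not detect inner/outer arc radii; supply `radii`")
    radii_used <- utils::tail(arcs$radius, 2)
  }
  names(radii_used) <- c("inner", "outer")
  for (ax in axes) {
    if (ax == "in_plane") {
      nrm <- frame$normal; u <- frame$zero_axis; v <- frame$transverse
    } else {
      nrm <- frame$transverse; u <- frame$zero_axis
      v <- frame$normal * frame$beta_sign
    }
    for (si in seq_along(offsets)) {
      sec <- extract_cross_section(sm, frame$pivot + offsets[si] * nrm, u, v)
      if (use_8bit) sec <- to_8bit(sec)
      center <- c(0, 0)
      if (refit_center) {
        pts <- arc_ridge_points(sec, c(0, 0), radii_used[["inner"]],
                                window = window)
        if (nrow(pts) >= 3) {
          ft <- fit_arc_circle(pts)
          center <- ft$center
        }
      }
      bkg <- background_stats(sec, exclude_center = center,
                              exclude_radius = bkg_factor * radii_used[["outer"]])
      for (which_arc in c("inner", "outer")) {
        prof <- angular_profile(sec, center, radii_used[[which_arc]],
                                window = window, step = step)
        b <- motion_boundary(prof, bkg, threshold = threshold,
                             rel_floor = rel_floor, peak_floor = peak_floor)
        rows[[length(rows) + 1]] <- data.frame(
          axis = ax, arc = which_arc, section = si,
          sign = c("negative", "positive"),
          boundary = c(b$negative, b$positive),
          at_window_edge = as.logical(b$at_window_edge))
      }
    }
  }
  sections <- do.call(rbind, rows)
  summ <- stats::aggregate(boundary ~ axis + arc + sign, sections, mean)
  structure(list(sections = sections, summary = summ,
                 radii = radii_used, arc = arc,
                 params = list(n_sections = n_sections,
                               smooth_sigma_px = smooth_sigma_px,
                               use_8bit = use_8bit, window = window,
                               step = step, threshold = threshold,
                               rel_floor = rel_floor, peak_floor = peak_floor,
                               bkg_factor = bkg_factor)),
            class = "motion_range")
}

#' @export
print.motion_range <- function(x, ...) {
  cat("motion_range (reported arc:", x$arc, ")\n")
  s <- x$summary[x$summary$arc == x$arc, ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %-8s %6.1f deg\n", s$axis[i], s$sign[i], s$boundary[i]))
  invisible(x)
}

#' Mean boundary of a motion range result
#'
#' @param x a `motion_range`.
#' @param axis `"in_plane"` or `"out_of_plane"`.
#' @param arc arc choice; defaults to the one configured in the result.
#' @return mean boundary over sections and signs, degrees.
#' @export
range_envelope <- function(x, axis, arc = NULL) {
  stopifnot(inherits(x, "motion_range"))
  arc <- arc %||% x$arc
  s <- x$summary
  mean(s$boundary[s$axis == axis & s$arc == arc])
}
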