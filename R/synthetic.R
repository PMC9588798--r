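# Ground-truth generators: toy hinge models with two splayed arms, pivot
# ensemble maps with known angular ranges, and two-state FRET traces with
# known correction factors and kinetics.

#' Hinge ground truth
#'
#' Study conditions for a synthetic hinged two-arm rigid body: a fixed core
#' slab in the platform plane plus two pseudo-atom arms from a single pivot,
#' splayed symmetrically about their bisector in the out-of-plane plane.
#' Defaults mirror a pentamer subunit: pivot ranges of +-50 degrees sampled
#' at 10 degree intervals, a 50 degree inter-arm splay, and an arm carrying
#' pseudo-domain clusters at 25 (stem), 65 (constant domain) and 100
#' (variable domain) Angstrom from the pivot.
#'
#' @param in_plane_range,out_of_plane_range pivot half-ranges in degrees.
#' @param splay inter-arm splay angle in degrees, in [0, 180].
#' @param arm_length arm length in Angstrom.
#' @param noise_sd additive voxel noise sd relative to the map peak.
#' @param step orientation sampling interval in degrees.
#' @return list of class `hinge_truth`.
#' @export
hinge_truth <- function(in_plane_range = 50, out_of_plane_range = 50,
                        splay = 50, arm_length = 110, noise_sd = 0,
                        step = 10) {
  stopifnot(in_plane_range >= 0, out_of_plane_range >= 0,
            splay >= 0, splay <= 180, arm_length > 0, noise_sd >= 0,
            step > 0)
  structure(list(in_plane_range = in_plane_range,
                 out_of_plane_range = out_of_plane_range,
                 splay = splay, arm_length = arm_length,
                 noise_sd = noise_sd, step = step),
            class = "hinge_truth")
}

# fixed pseudo-domain cluster: centre + 6 axial + 8 cube-corner offsets
# (mirror-symmetric about every coordinate plane)
.cluster_offsets <- function(r = 4) {
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  dimnames(corners) <- NULL
  rbind(c(0, 0, 0), r * diag(3), -r * diag(3), r * corners)
}

#' Build a toy hinge model
#'
#' Deterministic construction: core slab disc in the platform plane (away
#' from the arms), a shared stem cluster on the bisector, and two arms of
#' line atoms with constant- and variable-domain clusters, splayed by
#' `truth$splay` in the out-of-plane plane about the +x bisector. The pivot
#' is at the origin; the frame is (zero axis = +x, normal = +z).
#'
#' @param truth a `hinge_truth`.
#' @return list with `model` (`atomic_model`), `frame` (`pivot_frame`) and
#'   `truth`.
#' @export
make_toy_hinge_model <- function(truth) {
  stopifnot(inherits(truth, "hinge_truth"))
  L <- truth$arm_length
  # core slab: disc of atoms in z = 0 behind the pivot
  g <- expand.grid(x = seq(-56, -4, by = 4), y = seq(-26, 26, by = 4))
  keep <- (g$x + 30)^2 + g$y^2 <= 28^2
  core <- cbind(g$x[keep], g$y[keep], 0)
  # one arm template along +x: line atoms plus domain clusters
  line <- cbind(seq(6, L, by = 3), 0, 0)
  clus <- function(r0) sweep(.cluster_offsets(), 2, c(r0, 0, 0), `+`)
  arm <- rbind(line, clus(0.59 * L), clus(0.91 * L))
  stem <- clus(0.23 * L)
  elev <- function(xyz, phi) {           # elevation in the xz plane
    R <- rotation_matrix(c(0, 1, 0), -phi)
    t(R %*% t(xyz))
  }
  arm1 <- elev(arm, truth$splay / 2)
  arm2 <- elev(arm, -truth$splay / 2)
  n_core <- nrow(core); n_stem <- nrow(stem); n_arm <- nrow(arm)
  atoms <- data.frame(
    chain = c(rep("C", n_core), rep("S", n_stem),
              rep("P", n_arm), rep("Q", n_arm)),
    resno = c(seq_len(n_core), seq_len(n_stem), seq_len(n_arm), seq_len(n_arm)),
    resid = "GLY", elety = "CA", elesy = "C",
    x = c(core[, 1], stem[, 1], arm1[, 1], arm2[, 1]),
    y = c(core[, 2], stem[, 2], arm1[, 2], arm2[, 2]),
    z = c(core[, 3], stem[, 3], arm1[, 3], arm2[, 3]),
    stringsAsFactors = FALSE)
  model <- new_atomic_model(atoms, metadata = "synthetic toy hinge")
  frame <- pivot_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  n_line <- nrow(line); n_clus <- nrow(.cluster_offsets())
  const_rng <- c(n_line + 1, n_line + n_clus)          # constant-domain cluster
  list(model = model, frame = frame, truth = truth,
       arms = list(
         P = list(cterm = list("P", 1),
                  constant_sel = domain_selection("P", const_rng)),
         Q = list(cterm = list("Q", 1),
                  constant_sel = domain_selection("Q", const_rng))))
}

# moving part of the toy model (arms + stem; the core slab stays fixed)
.split_toy_model <- function(model) {
  a <- model$atoms
  moving <- a$chain %in% c("S", "P", "Q")
  list(moving = new_atomic_model(a[moving, , drop = FALSE], model$metadata),
       static = new_atomic_model(a[!moving, , drop = FALSE], model$metadata))
}

#' Simulate a pivot-ensemble map with known ground truth
#'
#' Renders the toy hinge model over the orientation grid implied by the
#' truth (uniform weights at `truth$step` degree intervals over the stated
#' half-ranges on each axis) and optionally adds i.i.d. Gaussian voxel
#' noise scaled to the noise-free peak. The core slab is rendered once,
#' unrotated.
#'
#' @param toy result of [make_toy_hinge_model()].
#' @param voxel voxel size in Angstrom; 1.5 by default so the angular
#'   point-spread at the constant-domain radius resolves the orientation
#'   comb.
#' @param atom_sigma per-atom Gaussian width (Angstrom).
#' @param seed RNG seed for the noise draw (recorded in the output).
#' @param half_extent cube half-extent in Angstrom; sized so that the
#'   background annulus beyond 1.5 x the outer arc radius is populated.
#' @return list with `map` (`density_map`), `ogrid`, `truth`, `seed`.
#' @export
make_pivot_map <- function(toy, voxel = 1.5, atom_sigma = 2.0, seed = 1,
                           half_extent = NULL) {
  truth <- toy$truth
  alpha <- if (truth$in_plane_range > 0)
    seq(-truth$in_plane_range, truth$in_plane_range, by = truth$step) else 0
  beta <- if (truth$out_of_plane_range > 0)
    seq(-truth$out_of_plane_range, truth$out_of_plane_range, by = truth$step) else 0
  ogrid <- orientation_grid(alpha = alpha, beta = beta)
  if (is.null(half_extent)) half_extent <- 1.62 * 0.91 * truth$arm_length
  grid <- grid_spec(center = toy$frame$pivot, half_extent = half_extent,
                    voxel = voxel)
  parts <- .split_toy_model(toy$model)
  map <- simulate_pivot_ensemble(parts$moving, toy$frame, ogrid, grid,
                                 atom_sigma = atom_sigma,
                                 static = parts$static)
  if (truth$noise_sd > 0) map <- add_map_noise(map, truth$noise_sd, seed)
  list(map = map, ogrid = ogrid, truth = truth, seed = seed)
}

#' Add i.i.d. Gaussian voxel noise to a map
#'
#' @param map a `density_map`.
#' @param noise_sd_rel noise sd as a fraction of the map maximum.
#' @param seed RNG seed.
#' @return the noisy `density_map`.
#' @export
add_map_noise <- function(map, noise_sd_rel, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sd_abs <- noise_sd_rel * max(map$values)
  map$values <- map$values +
    array(stats::rnorm(length(map$values), 0, sd_abs), dim(map$values))
  map
}

#' FRET ground truth
#'
#' Generating conditions for two-state single-molecule FRET traces:
#' efficiency states, Markov interchange rates, bleed-through and
#' detection-factor corrections, intensities, intensity-proportional
#' Gaussian noise (Poisson surrogate), exponential single-step
#' photobleaching, and frame pitch.
#'
#' @param states FRET efficiencies of the states, each in (0, 1).
#' @param k12,k21 interchange rates, 1/s (state 1 -> 2 and 2 -> 1).
#' @param donor_bleed fraction of donor fluorescence bleeding into the
#'   FRET channel.
#' @param direct_excitation fraction of the directly-excited acceptor
#'   intensity appearing in the FRET channel.
#' @param gamma detection factor relating FRET- to donor-channel intensity.
#' @param total_intensity donor-excited photon budget per frame.
#' @param acceptor_intensity directly-excited acceptor intensity.
#' @param noise_scale Gaussian noise sd = `noise_scale * sqrt(intensity)`.
#' @param bleach_mean_a,bleach_mean_d mean acceptor/donor bleach times, s.
#' @param frame_s frame pitch in seconds (default 0.03).
#' @return list of class `fret_truth`.
#' @export
fret_truth <- function(states = c(0.35, 0.75), k12 = 2, k21 = 2,
                       donor_bleed = 0.09, direct_excitation = 0.08,
                       gamma = 1.8, total_intensity = 500,
                       acceptor_intensity = 400, noise_scale = 1,
                       bleach_mean_a = 6, bleach_mean_d = 12,
                       frame_s = 0.03) {
  stopifnot(all(states > 0 & states < 1), k12 >= 0, k21 >= 0,
            donor_bleed >= 0, direct_excitation >= 0, gamma > 0,
            frame_s > 0)
  structure(as.list(environment()), class = "fret_truth")
}

#' Simulate single-molecule FRET traces
#'
#' Inverts the efficiency relation: at true state efficiency E and photon
#' budget I, the clean channels are `D = I (1 - E)`,
#' `F = gamma I E + donor_bleed * D + direct_excitation * A`, with `A`
#' constant per molecule while the acceptor is alive. State paths follow a
#' two-state Markov chain with exponential dwells; acceptor and donor
#' photobleach in a single step at exponential times; Gaussian noise with
#' variance proportional to intensity approximates shot noise. Donor-only
#' and acceptor-only control molecules for correction-factor estimation are
#' generated with the same machinery.
#'
#' @param truth a `fret_truth`.
#' @param n_molecules number of molecules.
#' @param duration trace length in seconds.
#' @param seed RNG seed (recorded in the output).
#' @param kind `"fret"` (default), `"donor_only"`, or `"acceptor_only"`.
#' @return list of class `fret_sim`: `traces` (data frame: molecule,
#'   frame, time, D, F, A), `labels` (data frame: molecule, frame, state,
#'   donor_alive, acceptor_alive), `truth`, `seed`, `kind`.
#' @export
simulate_fret_traces <- function(truth, n_molecules = 100, duration = 10,
                                 seed = 1,
                                 kind = c("fret", "donor_only", "acceptor_only")) {
  stopifnot(inherits(truth, "fret_truth"))
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  dt <- truth$frame_s
  nf <- floor(duration / dt)
  p12 <- 1 - exp(-truth$k12 * dt)
  p21 <- 1 - exp(-truth$k21 * dt)
  traces <- vector("list", n_molecules)
  labels <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    state <- integer(nf)
    state[1] <- sample(1:2, 1)
    if (nf > 1) {
      u <- stats::runif(nf - 1)
      for (i in 2:nf) {
        flip <- if (state[i - 1] == 1) u[i - 1] < p12 else u[i - 1] < p21
        state[i] <- if (flip) 3 - state[i - 1] else state[i - 1]
      }
    }
    tb_a <- stats::rexp(1, 1 / truth$bleach_mean_a)
    tb_d <- stats::rexp(1, 1 / truth$bleach_mean_d)
    tt <- (seq_len(nf) - 1) * dt
    a_alive <- tt < tb_a
    d_alive <- tt < tb_d
    E <- truth$states[state]
    I <- truth$total_intensity
    if (kind == "donor_only") { E[] <- 0; a_alive[] <- FALSE }
    if (kind == "acceptor_only") { d_alive[] <- FALSE; E[] <- 0 }
    A <- truth$acceptor_intensity * a_alive
    E_eff <- E * a_alive * d_alive
    D <- I * (1 - E_eff) * d_alive
    Fch <- truth$gamma * I * E_eff +
      truth$donor_bleed * D + truth$direct_excitation * A
    nz <- function(x) {
      x + stats::rnorm(length(x), 0, truth$noise_scale * sqrt(pmax(x, 0) + 1))
    }
    traces[[m]] <- data.frame(molecule = m, frame = seq_len(nf), time = tt,
                              D = nz(D), F = nz(Fch), A = nz(A))
    labels[[m]] <- data.frame(molecule = m, frame = seq_len(nf),
                              state = state, donor_alive = d_alive,
                              acceptor_alive = a_alive)
  }
  structure(list(traces = do.call(rbind, traces),
                 labels = do.call(rbind, labels),
                 truth = truth, seed = seed, kind = kind),
            class = "fret_sim")
}

#' Write simulated traces as delimited text
#'
#' @param sim a `fret_sim`.
#' @param path output CSV path (columns molecule, frame, time, D, F, A).
#' @return `path`, invisibly.
#' @export
write_traces <- function(sim, path) {
  utils::write.csv(sim$traces, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from delimited text
#'
#' @param path CSV with columns molecule, frame, D, F and optionally A,
#'   time.
#' @return data frame of traces.
#' @export
read_traces <- function(path) {
  tr <- utils::read.csv(path)
  req <- c("molecule", "frame", "D", "F")
  if (!all(req %in% names(tr)))
    stop("trace table must have columns: ", paste(req, collapse = ", "))
  tr
}
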