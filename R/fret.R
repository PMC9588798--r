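# Single-molecule FRET trace analysis: correction factors (bleed-through,
# direct excitation, detection factor gamma), efficiency calculation,
# photobleach-step detection, one/two-state mixture fitting and dwell
# analysis.

#' Correction factors for FRET efficiency
#'
#' Channel corrections: `donor_bleed` is the fraction of donor fluorescence
#' bleeding into the FRET channel (F/D in donor-only molecules),
#' `direct_excitation` the fraction of the directly-excited acceptor
#' intensity appearing in the FRET channel (F/A in acceptor-only
#' molecules), and `gamma` the detection factor relating FRET- to
#' donor-channel intensities. Typical values are 0.09, 0.08 and 1.8. These
#' are fluorescence correction factors, unrelated to the angular
#' coordinates of the hinge modules.
#'
#' @param donor_bleed,direct_excitation fractions >= 0.
#' @param gamma detection factor > 0.
#' @return list of class `correction_factors`.
#' @export
correction_factors <- function(donor_bleed = 0.09, direct_excitation = 0.08,
                               gamma = 1.8) {
  stopifnot(donor_bleed >= 0, direct_excitation >= 0, gamma > 0)
  structure(list(donor_bleed = donor_bleed,
                 direct_excitation = direct_excitation, gamma = gamma),
            class = "correction_factors")
}

#' Estimate donor bleed-through from donor-only molecules
#'
#' Mean of F/D over all pre-bleach frames of donor-only molecules.
#'
#' @param traces data frame with columns `molecule`, `D`, `F` (donor-only
#'   molecules).
#' @param truncate_at_bleach drop frames from the detected donor bleach
#'   step onward (default TRUE).
#' @return estimated bleed fraction.
#' @export
estimate_donor_bleed <- function(traces, truncate_at_bleach = TRUE) {
  .estimate_ratio(traces, num = "F", den = "D",
                  truncate_at_bleach = truncate_at_bleach)
}

#' Estimate direct acceptor excitation from acceptor-only molecules
#'
#' Mean of F/A over all pre-bleach frames of acceptor-only molecules.
#'
#' @param traces data frame with columns `molecule`, `A`, `F`.
#' @param truncate_at_bleach drop frames from the detected acceptor bleach
#'   step onward.
#' @return estimated direct-excitation fraction.
#' @export
estimate_direct_excitation <- function(traces, truncate_at_bleach = TRUE) {
  .estimate_ratio(traces, num = "F", den = "A",
                  truncate_at_bleach = truncate_at_bleach)
}

.estimate_ratio <- function(traces, num, den, truncate_at_bleach) {
  stopifnot(is.data.frame(traces), all(c("molecule", num, den) %in% names(traces)))
  vals <- unlist(lapply(split(traces, traces$molecule), function(tr) {
    x <- tr[[den]]
    y <- tr[[num]]
    n <- length(x)
    if (truncate_at_bleach && n >= 10) {
      st <- detect_bleach_step(x)
      if (st$class == "single") { x <- x[seq_len(st$index - 1)]
                                  y <- y[seq_len(st$index - 1)] }
    }
    # keep frames where the denominator channel is clearly pre-bleach:
    # anchor on the brightest frames so early-bleaching molecules do not
    # let post-bleach noise through
    keep <- x > 0.25 * stats::quantile(x, 0.98, na.rm = TRUE)
    if (sum(keep) < 2) return(numeric(0))
    y[keep] / x[keep]
  }))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0)
    stop("degenerate: no frames with positive denominator intensity")
  mean(vals)
}

#' Detection factor gamma from acceptor photobleaching
#'
#' `gamma = (F_before - F_after) / (D_after - D_before)`, with F and D
#' averaged over windows on each side of the acceptor bleach step (the
#' step frame excluded). When correction factors are supplied, the FRET
#' channel is first bleed-corrected (`F - donor_bleed * D`, minus
#' `direct_excitation * A` while the acceptor is alive), which removes the
#' bleed-through bias from the estimate.
#'
#' @param trace data frame (one molecule) with columns `D`, `F` and
#'   optionally `A`.
#' @param bleach_frame index of the acceptor bleach step, strictly inside
#'   the trace.
#' @param window frames averaged on each side (default 10).
#' @param factors optional list with `donor_bleed`, `direct_excitation`
#'   for bleed correction (gamma in it is ignored).
#' @return list: `gamma`, `valid` (FALSE when the FRET channel shows no
#'   drop, i.e. gamma <= 0).
#' @export
estimate_gamma <- function(trace, bleach_frame, window = 10, factors = NULL) {
  n <- nrow(trace)
  if (bleach_frame <= 1 || bleach_frame >= n)
    stop("bleach frame must be strictly inside the trace")
  ib <- max(1, bleach_frame - window):(bleach_frame - 1)
  ia <- (bleach_frame + 1):min(n, bleach_frame + window)
  D <- trace$D; Fch <- trace$F
  if (!is.null(factors)) {
    A <- if ("A" %in% names(trace)) trace$A else 0
    pre <- seq_len(n) < bleach_frame
    Fch <- Fch - factors$donor_bleed * D -
      factors$direct_excitation * ifelse(pre, A, 0)
  }
  dD <- mean(D[ia]) - mean(D[ib])
  if (dD <= 0)
    stop("no-recovery error: donor does not recover after acceptor bleach")
  # non-zero FRET before the bleach: the pre-bleach FRET signal must stand
  # clear of its own window noise, otherwise the ratio is ill-conditioned
  # (e.g. the donor already bleached)
  se_f <- stats::sd(Fch[ib]) / sqrt(length(ib))
  if (!is.finite(se_f)) se_f <- 0
  g <- (mean(Fch[ib]) - mean(Fch[ia])) / dD
  ok <- mean(Fch[ib]) - mean(Fch[ia]) > 5 * se_f
  list(gamma = g, valid = is.finite(g) && g > 0 && ok)
}

#' Recovered donor fluorescence
#'
#' Total donor-excited fluorescence with the FRET-channel share mapped back
#' to donor units: `D + F / gamma`.
#'
#' @param D,F donor and FRET channel intensities.
#' @param gamma detection factor (> 0).
#' @return recovered donor intensity.
#' @export
recovered_donor <- function(D, F, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  D + F / gamma
}

#' FRET efficiency from corrected channel intensities
#'
#' `E = (F - a D - b A) / (F - a D - b A + gamma D)` with `a` the donor
#' bleed fraction and `b` the direct-excitation fraction. Frames with a
#' non-positive denominator are masked (NA), as are efficiencies outside
#' `mask_limits`.
#'
#' @param D,F,A channel intensities (vectors of equal length; `A` may be a
#'   single snapshot value).
#' @param factors a `correction_factors`.
#' @param mask_limits efficiencies outside this interval are masked as
#'   artifacts; NULL disables the mask.
#' @return efficiency vector with masked frames as NA.
#' @export
fret_efficiency <- function(D, F, A = 0, factors = correction_factors(),
                            mask_limits = c(-0.2, 1.2)) {
  num <- F - factors$donor_bleed * D - factors$direct_excitation * A
  den <- num + factors$gamma * D
  E <- ifelse(den > 0, num / den, NA_real_)
  if (!is.null(mask_limits))
    E[!is.na(E) & (E < mask_limits[1] | E > mask_limits[2])] <- NA_real_
  E
}

#' Detect a single photobleach step
#'
#' Locates downward steps as peaks of a two-window mean difference that
#' exceed `k` times the local noise sd (estimated from first differences);
#' classifies the series as `"none"` (no qualifying step), `"single"`
#' (one step whose post-step level is consistent with background), or
#' `"multi"` (two or more qualifying steps; such molecules are rejected
#' from analysis).
#'
#' @param series intensity series (length >= 10).
#' @param k step threshold in noise-sd units (default 4).
#' @param window averaging window on each side, frames.
#' @param post_frac post-step mean must be below this fraction of the
#'   pre-step mean to qualify as bleached-to-background.
#' @return list: `class` ("none"/"single"/"multi"), `index` (frame of the
#'   step, NA unless single), `n_steps`.
#' @export
detect_bleach_step <- function(series, k = 4, window = 10, post_frac = 0.25) {
  n <- length(series)
  if (n < 10) stop("series too short for step detection (need >= 10)")
  w <- min(window, floor((n - 1) / 2))
  idx <- 4:(n - 2)
  # local noise: pooled per-frame sd of the two windows, so that a long
  # low-noise post-bleach tail cannot shrink the criterion for the
  # pre-bleach segment (intensity-proportional noise is heteroscedastic);
  # windows shrink near the trace edges so early/late steps stay visible
  stats_t <- vapply(idx, function(t) {
    before <- series[max(1, t - w):(t - 1)]
    after <- series[t:min(n, t + w - 1)]
    c(mean(before) - mean(after),
      sqrt((stats::var(before) + stats::var(after)) / 2))
  }, numeric(2))
  score <- stats_t[1, ]
  local_sd <- pmax(stats_t[2, ], 1e-12)
  qual <- score >= k * local_sd & score > 0
  if (!any(qual)) return(list(class = "none", index = NA_integer_, n_steps = 0L))
  # merge contiguous qualifying stretches into candidate steps
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  segs <- which(r$values)
  cand <- vapply(segs, function(s) {
    rngk <- starts[s]:ends[s]
    idx[rngk[which.max(score[rngk])]]
  }, numeric(1))
  n_steps <- length(cand)
  if (n_steps >= 2) return(list(class = "multi", index = NA_integer_,
                                n_steps = n_steps))
  step_i <- as.integer(cand[1])
  pre <- mean(series[seq_len(step_i - 1)])
  post <- mean(series[step_i:n])
  if (pre > 0 && post > post_frac * pre)
    return(list(class = "none", index = NA_integer_, n_steps = 0L))
  list(class = "single", index = step_i, n_steps = 1L)
}

#' Fit one or two Gaussian states to pooled FRET values
#'
#' Maximum-likelihood Gaussian mixtures with k = 1 and k = 2 components
#' (unequal variances), selected by BIC. Components are returned sorted by
#' ascending mean.
#'
#' @param E pooled efficiency values (NA dropped; >= 100 required).
#' @param k_max maximum number of states (1 or 2).
#' @return list of class `state_fit`: `k`, `means`, `sds`, `weights`,
#'   `bic` (named vector for the fitted k), `fits` (the mclust objects).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_states <- function(E, k_max = 2) {
  E <- E[is.finite(E)]
  if (length(E) < 100) stop("need >= 100 efficiency values to fit states")
  # deterministic initialisation subset (no RNG)
  init <- if (length(E) > 3000)
    list(subset = unique(round(seq(1, length(E), length.out = 3000))))
  else NULL
  fits <- lapply(seq_len(k_max), function(g)
    mclust::Mclust(E, G = g, modelNames = "V", initialization = init,
                   verbose = FALSE))
  if (any(vapply(fits, is.null, logical(1))))
    stop("fit error: mixture estimation did not converge")
  bic <- vapply(fits, function(f) as.numeric(f$bic), numeric(1))
  names(bic) <- paste0("k", seq_len(k_max))
  best <- unname(which.max(bic))
  f <- fits[[best]]
  mu <- as.numeric(f$parameters$mean)
  sg <- sqrt(as.numeric(f$parameters$variance$sigmasq))
  if (length(sg) == 1) sg <- rep(sg, length(mu))
  wt <- as.numeric(f$parameters$pro)
  o <- order(mu)
  structure(list(k = best, means = mu[o], sds = sg[o], weights = wt[o],
                 bic = bic, fits = fits),
            class = "state_fit")
}

#' @export
print.state_fit <- function(x, ...) {
  cat("state_fit: k =", x$k, "\n")
  for (i in seq_len(x$k))
    cat(sprintf("  state %d: mean %.3f sd %.3f weight %.2f\n",
                i, x$means[i], x$sds[i], x$weights[i]))
  cat("  BIC:", paste(sprintf("%s=%.1f", names(x$bic), x$bic), collapse = ", "),
      "\n")
  invisible(x)
}

#' Dwell analysis of two-state traces
#'
#' Assigns frames to the nearer state with hysteresis (a switch requires
#' the efficiency to enter the target state's mean +- 1 sd band, which
#' suppresses noise-induced chatter), then counts transitions per second of
#' valid observation time and state occupancies.
#'
#' @param E efficiency series (NA frames are gaps: they contribute no time
#'   and no transitions).
#' @param fit a `state_fit` with k = 2.
#' @param frame_s frame pitch in seconds (default 0.03).
#' @param molecule optional grouping vector; transitions are never counted
#'   across molecules.
#' @return list of class `dwell_result`: `applicable`, `transitions`,
#'   `time_s`, `rate_per_s`, `occupancy` (length 2).
#' @export
dwell_analysis <- function(E, fit, frame_s = 0.03, molecule = NULL) {
  stopifnot(inherits(fit, "state_fit"))
  if (fit$k != 2)
    return(structure(list(applicable = FALSE), class = "dwell_result"))
  if (is.null(molecule)) molecule <- rep(1, length(E))
  lo_enter <- fit$means[1] + fit$sds[1]   # enter state 1 when E <= this
  hi_enter <- fit$means[2] - fit$sds[2]   # enter state 2 when E >= this
  if (lo_enter >= hi_enter) {             # overlapping bands: midpoint rule
    mid <- mean(fit$means)
    lo_enter <- hi_enter <- mid
  }
  transitions <- 0L
  frames_in <- c(0L, 0L)
  for (mol in split(seq_along(E), molecule)) {
    state <- NA_integer_
    for (i in mol) {
      e <- E[i]
      if (is.na(e)) next
      new_state <- state
      if (is.na(state)) {
        new_state <- if (abs(e - fit$means[1]) <= abs(e - fit$means[2])) 1L else 2L
      } else if (state == 1L && e >= hi_enter) new_state <- 2L
      else if (state == 2L && e <= lo_enter) new_state <- 1L
      if (!is.na(state) && new_state != state) transitions <- transitions + 1L
      state <- new_state
      frames_in[state] <- frames_in[state] + 1L
    }
  }
  time_s <- sum(frames_in) * frame_s
  structure(list(applicable = TRUE, transitions = transitions,
                 time_s = time_s,
                 rate_per_s = if (time_s > 0) transitions / time_s else NA_real_,
                 occupancy = frames_in / max(1L, sum(frames_in))),
            class = "dwell_result")
}

#' End-to-end FRET experiment analysis
#'
#' The full trace pipeline: bleed-through from donor-only molecules, direct
#' excitation from acceptor-only molecules, gamma from donor recovery after
#' acceptor photobleaching (bleed-corrected, averaged over molecules with a
#' single acceptor bleach step and donor recovery), per-frame efficiencies
#' on pre-bleach frames of single-step molecules, pooled mixture fit, and
#' dwell analysis.
#'
#' @param traces data frame of FRET molecules (molecule, frame, D, F, A).
#' @param donor_only,acceptor_only data frames of control molecules.
#' @param frame_s frame pitch, seconds.
#' @param k_max maximum states for the mixture fit.
#' @return list of class `fret_analysis`: `factors`
#'   (`correction_factors`), `gamma_n` (molecules used for gamma), `E`
#'   (pooled efficiencies), `molecule` (grouping of `E`), `fit`
#'   (`state_fit`), `dwell` (`dwell_result`).
#' @export
analyze_fret_experiment <- function(traces, donor_only, acceptor_only,
                                    frame_s = 0.03, k_max = 2) {
  a <- estimate_donor_bleed(donor_only)
  b <- estimate_direct_excitation(acceptor_only)
  # acceptor bleaching is read from the directly-excited acceptor channel,
  # which is constant across FRET states; the FRET and donor channels step
  # at every state transition and would misclassify dynamic molecules.
  per_mol <- split(traces, traces$molecule)
  stepsA <- lapply(per_mol, function(tr) detect_bleach_step(tr$A))
  gammas <- c()
  for (i in seq_along(per_mol)) {
    tr <- per_mol[[i]]
    stA <- stepsA[[i]]
    if (stA$class != "single") next
    g <- tryCatch(estimate_gamma(tr, stA$index,
                                 factors = list(donor_bleed = a,
                                                direct_excitation = b)),
                  error = function(e) NULL)
    if (!is.null(g) && g$valid) gammas <- c(gammas, g$gamma)
  }
  if (length(gammas) == 0)
    stop("no molecules with usable acceptor photobleaching for gamma")
  # mean over molecules after a MAD screen: a single ill-conditioned
  # recovery ratio otherwise dominates the pooled factor
  gmed <- stats::median(gammas)
  gmad <- stats::mad(gammas)
  core <- gammas[abs(gammas - gmed) <= 3 * max(gmad, 1e-6)]
  factors <- correction_factors(a, b, mean(core))
  # donor bleaching is read from the recovered donor fluorescence, which is
  # constant across FRET states once gamma is known.
  E_all <- c(); mol_all <- c()
  for (i in seq_along(per_mol)) {
    tr <- per_mol[[i]]
    stA <- stepsA[[i]]
    if (stA$class == "none") {
      # no acceptor step seen: require an acceptor actually present at the
      # start, otherwise the acceptor died before the movie (dark spot)
      a_noise <- stats::mad(diff(tr$A)) / sqrt(2)
      if (mean(tr$A[1:3]) <= 5 * max(a_noise, 1e-12)) next
    }
    rec <- recovered_donor(tr$D, tr$F, factors$gamma)
    stD <- detect_bleach_step(rec)
    if (stA$class == "multi" || stD$class == "multi") next
    if (stA$class == "none" && stD$class == "none") next  # no single-step bleach
    last <- min(c(stA$index, stD$index, nrow(tr) + 1), na.rm = TRUE) - 1
    if (last < 5) next
    keep <- seq_len(last)
    # acceptor must still be bright at the end of the kept range: a spot
    # whose acceptor died within the first frames carries no usable FRET
    a_noise <- stats::mad(diff(tr$A)) / sqrt(2)
    if (mean(tr$A[utils::tail(keep, 5)]) <= 5 * max(a_noise, 1e-12)) next
    E <- fret_efficiency(tr$D[keep], tr$F[keep], tr$A[keep], factors)
    E_all <- c(E_all, E)
    mol_all <- c(mol_all, rep(tr$molecule[1], length(E)))
  }
  fit <- fit_states(E_all, k_max = k_max)
  dw <- dwell_analysis(E_all, fit, frame_s = frame_s, molecule = mol_all)
  structure(list(factors = factors, gamma_n = length(gammas),
                 E = E_all, molecule = mol_all, fit = fit, dwell = dw),
            class = "fret_analysis")
}

#' @export
print.fret_analysis <- function(x, ...) {
  cat(sprintf("fret_analysis: donor bleed %.3f, direct excitation %.3f, gamma %.3f (n=%d)\n",
              x$factors$donor_bleed, x$factors$direct_excitation,
              x$factors$gamma, x$gamma_n))
  print(x$fit)
  if (isTRUE(x$dwell$applicable))
    cat(sprintf("  transitions: %.2f per s, occupancy %.2f/%.2f\n",
                x$dwell$rate_per_s, x$dwell$occupancy[1], x$dwell$occupancy[2]))
  invisible(x)
}
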