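# Accessible-volume dye modelling: sterically allowed dye positions on a
# flexible linker attached at a residue's C-beta, and FRET-weighted
# inter-dye distance prediction.

#' Accessible volume of a dye on a flexible linker
#'
#' Candidate dye positions on a uniform grid within the linker length of
#' the attachment point (the C-beta atom of the labelled residue; a
#' pseudo-C-beta is constructed from backbone N, CA, C for glycine).
#' Positions are kept when (i) the dye sphere does not clash with any
#' model atom and (ii) the straight path from the attachment point is not
#' obstructed within the linker half-width (no path search). Weights are
#' equal.
#'
#' @param model an `atomic_model`; the labelled residue's side chain is
#'   assumed already removed beyond C-beta.
#' @param residue atom-address style list/vector `(chain, resno)` of the
#'   labelled residue.
#' @param linker_length maximum dye-centre distance from the attachment
#'   point, Angstrom (default 20).
#' @param linker_width linker diameter used for path obstruction, Angstrom
#'   (default 4.5).
#' @param dye_radius dye sphere radius, Angstrom (default 3.5).
#' @param grid_pitch candidate grid pitch, Angstrom (default 1).
#' @param atom_radius model atom radius used in clash tests (default 1.7).
#' @return list of class `dye_cloud`: `positions` (n x 3), `weights`,
#'   `attachment`, and the linker parameters.
#' @export
accessible_volume <- function(model, residue, linker_length = 20,
                              linker_width = 4.5, dye_radius = 3.5,
                              grid_pitch = 1, atom_radius = 1.7) {
  if (linker_length <= dye_radius)
    stop("linker length must exceed the dye radius")
  z <- as.list(residue)
  chain <- z[[1]]; resno <- as.integer(z[[2]])
  attach <- tryCatch(atom_coord(model, chain, resno, "CB"), error = function(e) {
    # pseudo-C-beta for glycine from backbone geometry
    N <- atom_coord(model, chain, resno, "N")
    CA <- atom_coord(model, chain, resno, "CA")
    C <- atom_coord(model, chain, resno, "C")
    b1 <- unitize(CA - N); b2 <- unitize(CA - C)
    bis <- unitize(b1 + b2); perp <- unitize(crossprod_vec(b1, b2))
    CA + 1.53 * unitize(bis * sin(deg2rad(54.75)) + perp * cos(deg2rad(54.75)))
  })
  a <- model$atoms
  obst <- !(a$chain == chain & a$resno == resno)   # attachment residue excluded
  atoms <- as.matrix(a[obst, c("x", "y", "z"), drop = FALSE])
  # candidate grid
  g <- seq(-linker_length, linker_length, by = grid_pitch)
  cand <- as.matrix(expand.grid(x = g, y = g, z = g))
  cand <- cand[rowSums(cand^2) <= linker_length^2, , drop = FALSE]
  cand <- sweep(cand, 2, attach, `+`)
  keep <- rep(TRUE, nrow(cand))
  if (nrow(atoms) > 0) {
    # exact dye-sphere clash test
    keep <- .min_dist2(cand, atoms) >= (dye_radius + atom_radius)^2
    # straight-line reachability at linker half-width
    if (any(keep)) {
      ck <- cand[keep, , drop = FALSE]
      free <- rep(TRUE, nrow(ck))
      r_path2 <- (linker_width / 2 + atom_radius)^2
      for (f in seq(0.15, 0.95, by = 0.1)) {
        idx <- which(free)
        if (length(idx) == 0) break
        pts <- ck[idx, , drop = FALSE] * f +
          matrix(attach * (1 - f), length(idx), 3, byrow = TRUE)
        bad <- .min_dist2(pts, atoms) < r_path2
        free[idx[bad]] <- FALSE
      }
      keep[keep] <- free
    }
  }
  if (!any(keep))
    stop("buried-site error: no sterically allowed dye position")
  pos <- cand[keep, , drop = FALSE]
  structure(list(positions = pos, weights = rep(1 / nrow(pos), nrow(pos)),
                 attachment = attach,
                 linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius, grid_pitch = grid_pitch),
            class = "dye_cloud")
}

# squared distance from each row of P to its nearest row of A
.min_dist2 <- function(P, A) {
  if (nrow(P) == 0) return(numeric(0))
  pa <- rowSums(P^2)
  aa <- rowSums(A^2)
  out <- rep(Inf, nrow(P))
  chunk <- max(1, floor(2e7 / nrow(P)))
  for (j0 in seq(1, nrow(A), by = chunk)) {
    jj <- j0:min(nrow(A), j0 + chunk - 1)
    d2 <- outer(pa, aa[jj], `+`) - 2 * P %*% t(A[jj, , drop = FALSE])
    out <- pmin(out, d2[cbind(seq_len(nrow(d2)), max.col(-d2, "first"))])
  }
  out
}

#' @export
print.dye_cloud <- function(x, ...) {
  cat(sprintf("dye_cloud: %d positions, linker %.1f A, dye radius %.1f A\n",
              nrow(x$positions), x$linker_length, x$dye_radius))
  invisible(x)
}

#' FRET-weighted mean inter-dye distance and predicted efficiency
#'
#' The predicted efficiency is the pair average of `1 / (1 + (r/R0)^6)`
#' over donor-acceptor position pairs; the FRET-weighted mean distance is
#' the single distance whose efficiency equals that average. Clouds larger
#' than `max_points` are deterministically thinned before the exact pair
#' average.
#'
#' @param donor,acceptor `dye_cloud` objects.
#' @param R0 Forster radius in Angstrom (default 51, i.e. 5.1 nm for the
#'   Alexa Fluor 555/647 pair).
#' @param max_points per-cloud cap on positions entering the pair average.
#' @return list of class `distance_prediction`: `E`, `mean_distance`
#'   (Angstrom), `R0`.
#' @export
mean_fret_distance <- function(donor, acceptor, R0 = 51, max_points = 3000) {
  stopifnot(inherits(donor, "dye_cloud"), inherits(acceptor, "dye_cloud"))
  thin <- function(P) {
    n <- nrow(P)
    if (n <= max_points) return(P)
    P[unique(round(seq(1, n, length.out = max_points))), , drop = FALSE]
  }
  P <- thin(donor$positions); Q <- thin(acceptor$positions)
  Emean <- 0
  chunk <- max(1, floor(4e6 / nrow(Q)))
  nP <- nrow(P)
  for (i0 in seq(1, nP, by = chunk)) {
    ii <- i0:min(nP, i0 + chunk - 1)
    d2 <- outer(rowSums(P[ii, , drop = FALSE]^2), rowSums(Q^2), `+`) -
      2 * P[ii, , drop = FALSE] %*% t(Q)
    d2[d2 < 0] <- 0
    Emean <- Emean + sum(1 / (1 + (d2 / R0^2)^3))
  }
  Emean <- Emean / (nP * nrow(Q))
  r_eff <- if (Emean >= 1) 0 else R0 * ((1 - Emean) / Emean)^(1 / 6)
  structure(list(E = Emean, mean_distance = r_eff, R0 = R0),
            class = "distance_prediction")
}

#' @export
print.distance_prediction <- function(x, ...) {
  cat(sprintf("distance_prediction: E = %.3f, FRET-weighted distance %.1f A (R0 = %.0f A)\n",
              x$E, x$mean_distance, x$R0))
  invisible(x)
}
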