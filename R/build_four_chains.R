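#' Build the minimal four-chains model
#'
#' Four freely rotating PEG chains of `n_segments_per_chain` beads each are
#' attached to a single physical crosslink (four AA anchor beads clustered at
#' the origin region) while the opposite (free) chain ends are pinned at the
#' requested end-to-end distance. The four end-to-end vectors lie on a cone
#' about the z axis with azimuths 0/90/180/270 degrees, with the cone opening
#' chosen so that each pair of *adjacent* end-to-end vectors encloses exactly
#' `mutual_angle`. Anchor and pinned end beads are flagged as positionally
#' restrained; the interior beads are free. The slack of each chain (contour
#' length minus end-to-end distance) is laid out as a smooth bulged arc in a
#' random plane so that all bond lengths start near their rest length.
#'
#' @param n_segments_per_chain PEG beads per chain (default 60).
#' @param mutual_angle angle between adjacent chain end-to-end vectors,
#'   degrees, in [0, 90].
#' @param end_to_end anchor-to-pinned-end distance (nm); must not exceed the
#'   contour length `n_segments_per_chain * r0`.
#' @param seed integer seed (arc-plane orientation and velocities).
#' @param temperature temperature of the velocity draw (K).
#' @param ff force field.
#' @param box_edge cubic box edge (nm); default is generous so that periodic
#'   images do not interact.
#' @return a [particle_system()]; `$topology$four_chains` records per-chain
#'   anchor/end indices and the ideal end-to-end directions.
#' @export
build_four_chains <- function(n_segments_per_chain = 60, mutual_angle = 10,
                              end_to_end = 4.5, seed = 1, temperature = 300,
                              ff = default_forcefield(),
                              box_edge = 2 * end_to_end + 6) {
  if (mutual_angle < 0 || mutual_angle > 90)
    stop("mutual_angle must lie in [0, 90] degrees")
  r0 <- ff$bonds$r0[1]
  contour <- n_segments_per_chain * r0
  if (end_to_end > contour)
    stop("end_to_end (", end_to_end, " nm) exceeds the chain contour length (",
         contour, " nm)")
  alpha <- mutual_angle * pi / 180
  # adjacent cone vectors at azimuth 90 deg apart: cos(alpha) = cos^2(beta)
  beta <- acos(sqrt(cos(alpha)))
  phis <- (0:3) * pi / 2
  u <- cbind(sin(beta) * cos(phis), sin(beta) * sin(phis), rep(cos(beta), 4))

  npc <- n_segments_per_chain + 1L      # AA anchor + PEG beads
  n <- 4L * npc
  center <- rep(box_edge / 2, 3)
  # anchors: a tight square (radius 0.28 nm, within the 0.65 nm cluster
  # cutoff but clear of the AA repulsive core) in the xy plane = one crosslink
  anchors <- center + 0.28 * cbind(cos(phis + pi / 4), sin(phis + pi / 4), 0)

  with_seed(seed, {
    pos <- matrix(NA_real_, n, 3)
    species <- character(n)
    restrained <- rep(FALSE, n)
    anchor_idx <- end_idx <- integer(4)
    for (ch in 1:4) {
      off <- (ch - 1L) * npc
      a <- anchors[ch, ]
      e <- a + end_to_end * u[ch, ]
      path <- bulged_arc(a, e, contour, n_segments_per_chain)
      pos[off + seq_len(npc), ] <- path
      species[off + seq_len(npc)] <- c("AA", rep(c("CH2", "CH2", "O"),
                                                 length.out = n_segments_per_chain))
      anchor_idx[ch] <- off + 1L
      end_idx[ch] <- off + npc
      restrained[c(off + 1L, off + npc)] <- TRUE
    }
    species_chain <- c("AA", rep(c("CH2", "CH2", "O"),
                                 length.out = n_segments_per_chain))
    topo <- chain_topology(4L, npc, species_chain)
    topo$sfcs <- topo$sfcs[0, ]          # SFC taxonomy applies to the network model
    topo$four_chains <- list(anchors = anchor_idx, ends = end_idx,
                             directions = u, end_to_end = end_to_end,
                             mutual_angle = mutual_angle)
    sys <- particle_system(pos, species, rep(box_edge, 3), topology = topo,
                           restrained = restrained)
    sys <- assign_forcefield(sys, ff)
    sys <- thermalize_here(sys, temperature)
    sys
  })
}

# n+1 points from a to e whose polyline length equals `contour`, bulging
# sinusoidally in a random plane perpendicular to the chord
bulged_arc <- function(a, e, contour, n) {
  chord <- e - a
  d <- sqrt(sum(chord^2))
  tgrid <- seq(0, 1, length.out = 2001)
  if (contour <= d * 1.0001) {
    amp <- 0
  } else {
    arclen <- function(A) {
      x <- d * tgrid
      y <- A * sin(pi * tgrid)
      sum(sqrt(diff(x)^2 + diff(y)^2))
    }
    amp <- uniroot(function(A) arclen(A) - contour, c(0, contour))$root
  }
  ref <- if (abs(chord[1]) < 0.9 * d) c(1, 0, 0) else c(0, 1, 0)
  perp <- pracma_cross(chord / max(d, 1e-12), ref)
  perp <- perp / sqrt(sum(perp^2))
  ang <- runif(1, 0, 2 * pi)
  perp2 <- pracma_cross(chord / max(d, 1e-12), perp)
  bdir <- cos(ang) * perp + sin(ang) * perp2
  # arc-length-uniform parameter values
  x <- d * tgrid; y <- amp * sin(pi * tgrid)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  targets <- seq(0, s[length(s)], length.out = n + 1)
  tt <- approx(s, tgrid, xout = targets)$y
  out <- matrix(NA_real_, n + 1, 3)
  for (i in seq_len(n + 1)) {
    out[i, ] <- a + tt[i] * chord + amp * sin(pi * tt[i]) * bdir
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mutual angles between adjacent chain end-to-end vectors
#'
#' For a four-chains system, returns the four angles (degrees) between the
#' end-to-end vectors of adjacent chains (1-2, 2-3, 3-4, 4-1).
#'
#' @param system a system built by [build_four_chains()].
#' @export
four_chain_angles <- function(system) {
  fc <- system$topology$four_chains
  if (is.null(fc)) stop("not a four-chains system")
  v <- system$positions[fc$ends, , drop = FALSE] -
       system$positions[fc$anchors, , drop = FALSE]
  v <- v / sqrt(rowSums(v^2))
  adj <- cbind(1:4, c(2, 3, 4, 1))
  acos(pmin(1, pmax(-1, rowSums(v[adj[, 1], ] * v[adj[, 2], ])))) * 180 / pi
}
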