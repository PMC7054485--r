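#' Build the micellar hydrogel network model
#'
#' Constructs the periodic coarse-grained network: `n_chains` self-avoiding
#' random-walk chains with the alternating repeat unit AA-(CH2,CH2,O)x3
#' (one acrylic-acid bead followed by three PEG monomers of three beads each,
#' 10 beads per repeat), solvated by `n_water` single-bead water molecules
#' inserted at non-overlapping positions in a periodic box. Velocities are
#' drawn from the Maxwell-Boltzmann distribution at `temperature` and the
#' centre-of-mass momentum is removed. The default arguments reproduce the
#' reference composition: 8 chains x 200 groups solvated by 2,447 waters in a
#' 5 nm cubic box.
#'
#' The topology records bonds between consecutive backbone beads, angles for
#' consecutive triples, per-particle chain membership, the ordered AA indices
#' of each chain, and one short flexible chain (SFC) per consecutive AA pair;
#' every SFC spans 11 beads (two bounding AA plus nine PEG beads).
#'
#' @param n_chains number of macromolecular chains.
#' @param groups_per_chain beads per chain; must be a positive multiple of 10.
#' @param box_edge cubic box edge (nm).
#' @param n_water number of water beads.
#' @param seed integer seed; the build is bit-reproducible for a fixed seed.
#' @param temperature temperature for the velocity draw (K).
#' @param ff force field used for masses/charges and later dynamics.
#' @param overlap_tol minimum allowed distance (nm) between non-bonded
#'   particles during construction.
#' @param max_restarts chain-growth restarts before the build signals a
#'   packing failure.
#' @return a [particle_system()] with assigned force field. When `n_water > 0`
#'   the water beads carry a uniform countercharge that neutralises the system.
#' @export
build_network <- function(n_chains = 8, groups_per_chain = 200, box_edge = 5,
                          n_water = 2447, seed = 1, temperature = 300,
                          ff = default_forcefield(), overlap_tol = 0.21,
                          max_restarts = 60) {
  if (groups_per_chain <= 0 || groups_per_chain %% 10 != 0)
    stop("groups_per_chain must be a positive multiple of 10 (AA + 9 PEG beads)")
  if (box_edge <= 0) stop("box_edge must be positive")
  box <- rep(box_edge, 3)
  r0 <- ff$bonds$r0[1]
  unit <- c("AA", rep(c("CH2", "CH2", "O"), 3))
  species_chain <- rep(unit, groups_per_chain / 10)
  n_poly <- n_chains * groups_per_chain
  n_total <- n_poly + n_water

  with_seed(seed, {
    grid <- overlap_grid(box, overlap_tol)
    pos <- matrix(NA_real_, n_total, 3)
    idx <- 0L
    for (ch in seq_len(n_chains)) {
      placed <- grow_chain(groups_per_chain, r0, box, grid, pos, idx,
                           overlap_tol, max_restarts)
      pos <- placed$pos; grid <- placed$grid
      idx <- idx + groups_per_chain
    }
    for (w in seq_len(n_water)) {
      ok <- FALSE
      for (try in 1:2000) {
        p <- runif(3) * box
        if (grid_clear(grid, pos, p, box, overlap_tol)) { ok <- TRUE; break }
      }
      if (!ok) stop("packing failure: could not insert water bead ", w,
                    " without overlap; enlarge the box or reduce n_water")
      idx <- idx + 1L
      pos[idx, ] <- p
      grid <- grid_add(grid, idx, p, box)
    }

    species <- c(rep(species_chain, n_chains), rep("W", n_water))
    chain <- c(rep(seq_len(n_chains), each = groups_per_chain),
               rep(NA_integer_, n_water))
    topo <- chain_topology(n_chains, groups_per_chain, species_chain)
    sys <- particle_system(pos, species, box, topology = topo)
    sys <- assign_forcefield(sys, ff)
    # neutralise the AA partial charges with a uniform water countercharge
    if (n_water > 0) {
      qpoly <- sum(sys$charges[seq_len(n_poly)])
      sys$charges[species == "W"] <- -qpoly / n_water
    }
    sys <- thermalize_here(sys, temperature)
    sys <- wrap_positions(sys)
    sys
  })
}

# bonds/angles/chain bookkeeping for identical chains laid out consecutively
chain_topology <- function(n_chains, groups_per_chain, species_chain) {
  bi <- bj <- integer(0); bt <- character(0)
  ai <- aj <- ak <- integer(0); at <- character(0)
  aa_by_chain <- vector("list", n_chains)
  sfc <- list()
  for (ch in seq_len(n_chains)) {
    off <- (ch - 1L) * groups_per_chain
    i1 <- off + seq_len(groups_per_chain - 1L)
    bi <- c(bi, i1); bj <- c(bj, i1 + 1L)
    bt <- c(bt, paste(species_chain[-groups_per_chain],
                      species_chain[-1], sep = "-"))
    if (groups_per_chain >= 3) {
      i2 <- off + seq_len(groups_per_chain - 2L)
      ai <- c(ai, i2); aj <- c(aj, i2 + 1L); ak <- c(ak, i2 + 2L)
      at <- c(at, paste(species_chain[1:(groups_per_chain - 2)],
                        species_chain[2:(groups_per_chain - 1)],
                        species_chain[3:groups_per_chain], sep = "-"))
    }
    aa_local <- which(species_chain == "AA")
    aa_by_chain[[ch]] <- off + aa_local
    if (length(aa_local) >= 2) {
      for (s in seq_len(length(aa_local) - 1L)) {
        sfc[[length(sfc) + 1L]] <- data.frame(
          chain = ch, aa_i = off + aa_local[s], aa_j = off + aa_local[s + 1L],
          first = off + aa_local[s] + 1L, last = off + aa_local[s + 1L] - 1L)
      }
    }
  }
  n <- n_chains * groups_per_chain
  list(bonds = data.frame(i = bi, j = bj, type = bt),
       angles = data.frame(i = ai, j = aj, k = ak, type = at),
       chain = rep(seq_len(n_chains), each = groups_per_chain),
       aa_by_chain = aa_by_chain,
       sfcs = if (length(sfc)) do.call(rbind, sfc) else
         data.frame(chain = integer(), aa_i = integer(), aa_j = integer(),
                    first = integer(), last = integer()))
}

# self-avoiding random-walk growth of one chain; returns updated pos and grid
grow_chain <- function(n, r0, box, grid, pos, idx0, tol, max_restarts) {
  for (restart in seq_len(max_restarts)) {
    trial <- matrix(NA_real_, n, 3)
    trial[1, ] <- runif(3) * box
    ok <- grid_clear(grid, pos, trial[1, ], box, tol)
    if (!ok) next
    prev_dir <- NULL
    failed <- FALSE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:200) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        # avoid immediate backfolding onto the previous bond
        if (!is.null(prev_dir) && sum(dir * prev_dir) < -0.5) next
        p <- trial[i - 1, ] + r0 * dir
        # self-avoidance beyond 1-2 and 1-3 neighbours
        if (i > 3) {
          d <- min_image(sweep(trial[1:(i - 3), , drop = FALSE], 2, p), box)
          if (min(rowSums(d^2)) < tol^2) next
        }
        if (!grid_clear(grid, pos, p, box, tol)) next
        trial[i, ] <- p; prev_dir <- dir; placed <- TRUE; break
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) {
      for (i in seq_len(n)) {
        pos[idx0 + i, ] <- trial[i, ]
        grid <- grid_add(grid, idx0 + i, trial[i, ], box)
      }
      return(list(pos = pos, grid = grid))
    }
  }
  stop("packing failure: could not grow a self-avoiding chain of ", n,
       " beads in the requested box")
}

## --- simple periodic cell grid for overlap rejection ---------------------

overlap_grid <- function(box, tol) {
  ncell <- pmax(1L, floor(box / tol))
  list(ncell = ncell, cs = box / ncell,
       cells = vector("list", prod(ncell)))
}

grid_cell_id <- function(grid, p, box) {
  ix <- (floor(p / grid$cs)) %% grid$ncell
  as.integer(1 + ix[1] + grid$ncell[1] * (ix[2] + grid$ncell[2] * ix[3]))
}

grid_add <- function(grid, idx, p, box) {
  p <- p - floor(p / box) * box
  id <- grid_cell_id(grid, p, box)
  grid$cells[[id]] <- c(grid$cells[[id]], idx)
  grid
}

# TRUE when p is at least tol (minimum image) from every registered particle
grid_clear <- function(grid, pos, p, box, tol) {
  p <- p - floor(p / box) * box
  base <- floor(p / grid$cs)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    ix <- (base + c(dx, dy, dz)) %% grid$ncell
    id <- as.integer(1 + ix[1] + grid$ncell[1] * (ix[2] + grid$ncell[2] * ix[3]))
    members <- grid$cells[[id]]
    if (length(members)) {
      d <- min_image(sweep(pos[members, , drop = FALSE], 2, p), box)
      if (min(rowSums(d^2)) < tol^2) return(FALSE)
    }
  }
  TRUE
}

# Maxwell-Boltzmann draw using the *current* RNG stream (no reseeding)
thermalize_here <- function(system, temperature) {
  m <- system$masses
  n <- n_particles(system)
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(.kB * temperature / m)
  free <- !system$restrained
  if (any(free)) {
    com <- colSums(v[free, , drop = FALSE] * m[free]) / sum(m[free])
    v[free, ] <- sweep(v[free, , drop = FALSE], 2, com)
  }
  v[system$restrained, ] <- 0
  system$velocities <- v
  system
}
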