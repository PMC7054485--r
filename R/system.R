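#' Particle system container
#'
#' Holds positions, velocities, species, charges, masses, the periodic
#' orthorhombic box and the molecular topology of a coarse-grained
#' configuration. All three box axes are periodic.
#'
#' @param positions N x 3 matrix of coordinates (nm).
#' @param species character vector of length N; one of "AA", "CH2", "O", "W"
#'   in the shipped model, but arbitrary labels are allowed.
#' @param box numeric length-3 (Lx, Ly, Lz) in nm, all > 0.
#' @param velocities optional N x 3 matrix (nm/ps); zero if omitted.
#' @param charges optional numeric length N (e).
#' @param masses optional numeric length N (g/mol).
#' @param topology optional list with elements `bonds` (data.frame i, j, type),
#'   `angles` (data.frame i, j, k, type), `chain` (integer chain id per
#'   particle, NA for solvent), `aa_by_chain` (list of ordered AA indices per
#'   chain) and `sfcs` (data.frame chain, aa_i, aa_j, first, last).
#' @param restrained optional logical length N; restrained particles are held
#'   fixed by the integrator.
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(positions, species, box, velocities = NULL,
                            charges = NULL, masses = NULL, topology = NULL,
                            restrained = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  stopifnot(ncol(positions) == 3, length(species) == nrow(positions),
            length(box) == 3)
  if (any(box <= 0)) stop("all box edges must be positive")
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(restrained)) restrained <- rep(FALSE, n)
  if (is.null(topology))
    topology <- list(bonds = data.frame(i = integer(), j = integer(), type = character()),
                     angles = data.frame(i = integer(), j = integer(), k = integer(),
                                         type = character()),
                     chain = rep(NA_integer_, n), aa_by_chain = list(),
                     sfcs = data.frame(chain = integer(), aa_i = integer(),
                                       aa_j = integer(), first = integer(),
                                       last = integer()))
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 species = as.character(species), charges = charges,
                 masses = masses, box = as.numeric(box), topology = topology,
                 restrained = restrained, forcefield = NULL, time = 0),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(x$species)
  cat("particle_system:", n_particles(x), "particles\n")
  cat("  box:", paste(signif(x$box, 5), collapse = " x "), "nm\n")
  if (length(tab)) cat("  species:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  nb <- nrow(x$topology$bonds); na <- nrow(x$topology$angles)
  cat("  bonds:", nb, " angles:", na, " SFCs:", nrow(x$topology$sfcs), "\n")
  cat("  force field:", if (is.null(x$forcefield)) "unassigned" else "assigned", "\n")
  invisible(x)
}

#' Number of particles
#' @param system a [particle_system()].
#' @export
n_particles <- function(system) nrow(system$positions)

#' Wrap coordinates into the primary periodic cell
#'
#' Maps every coordinate into [0, L) per axis.
#' @param system a [particle_system()].
#' @return the system with wrapped positions.
#' @export
wrap_positions <- function(system) {
  p <- system$positions
  for (d in 1:3) p[, d] <- p[, d] - floor(p[, d] / system$box[d]) * system$box[d]
  system$positions <- p
  system
}

# minimum-image displacement vectors between rows of a and b (or a single row b)
min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Minimum-image distance between two particles
#' @param system a [particle_system()].
#' @param i,j particle indices.
#' @export
min_image_dist <- function(system, i, j) {
  d <- min_image(system$positions[i, , drop = FALSE] -
                 system$positions[j, , drop = FALSE], system$box)
  sqrt(rowSums(d^2))
}

# all pairwise minimum-image distances between rows of pts (matrix), as a
# dense symmetric matrix; fine for the few hundred AA groups involved
min_image_dist_matrix <- function(pts, box) {
  n <- nrow(pts)
  D <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pts[, k], pts[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    D <- D + dk^2
  }
  sqrt(D)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns velocities from the Maxwell-Boltzmann distribution at `temperature`
#' and removes the centre-of-mass momentum. Restrained particles get zero
#' velocity. Requires masses (assign a force field first).
#'
#' @param system a [particle_system()] with masses.
#' @param temperature target temperature (K).
#' @param seed integer seed; the draw is deterministic for a fixed seed.
#' @export
thermalize <- function(system, temperature = 300, seed = 1) {
  m <- system$masses
  if (is.null(m)) stop("masses unassigned; call assign_forcefield() first")
  n <- n_particles(system)
  v <- with_seed(seed, matrix(rnorm(3 * n), n, 3)) * sqrt(.kB * temperature / m)
  free <- !system$restrained
  if (any(free)) {
    com <- colSums(v[free, , drop = FALSE] * m[free]) / sum(m[free])
    v[free, ] <- sweep(v[free, , drop = FALSE], 2, com)
  }
  v[system$restrained, ] <- 0
  system$velocities <- v
  system
}

# 0-based integer arrays and pair tables for the C++ engine
engine_args <- function(system) {
  ff <- system$forcefield
  if (is.null(ff)) stop("force field unassigned; call assign_forcefield() first")
  sp <- ff$lj$species
  type <- match(system$species, sp) - 1L
  k <- length(sp)
  eps <- outer(ff$lj$eps, ff$lj$eps, function(a, b) sqrt(a * b))
  sig <- outer(ff$lj$sigma, ff$lj$sigma, "+") / 2
  topo <- system$topology
  bkey <- vapply(ff$bonds$type, normalize_bond_type, "")
  akey <- vapply(ff$angles$type, normalize_angle_type, "")
  if (nrow(topo$bonds)) {
    bi <- match(vapply(topo$bonds$type, normalize_bond_type, ""), bkey)
    bonds <- cbind(topo$bonds$i - 1L, topo$bonds$j - 1L)
    bond_k <- ff$bonds$k[bi]; bond_r0 <- ff$bonds$r0[bi]
  } else {
    bonds <- matrix(integer(0), 0, 2); bond_k <- bond_r0 <- numeric(0)
  }
  if (nrow(topo$angles)) {
    ai <- match(vapply(topo$angles$type, normalize_angle_type, ""), akey)
    angles <- cbind(topo$angles$i - 1L, topo$angles$j - 1L, topo$angles$k - 1L)
    ang_k <- ff$angles$k[ai]; ang_t0 <- ff$angles$theta0[ai]
  } else {
    angles <- matrix(integer(0), 0, 3); ang_k <- ang_t0 <- numeric(0)
  }
  ch <- system$charges; if (is.null(ch)) ch <- rep(0, n_particles(system))
  m <- system$masses; if (is.null(m)) m <- rep(1, n_particles(system))
  list(pos = system$positions, charge = ch, mass = m, type = type, ntypes = k,
       eps = eps, sig = sig, box = system$box, cutoff = ff$cutoff,
       coulk = ff$coul_k, bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
       angles = angles, ang_k = ang_k, ang_t0 = ang_t0,
       frozen = system$restrained)
}
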