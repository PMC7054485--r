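#' Coarse-grained force field
#'
#' Container for all interaction parameters of the Hamiltonian
#' \deqn{H = \sum_{n_b} U_b + \sum_{n_a} U_a + \sum_{n_p} U_{el} + \sum_{n_p} U_{LJ}}
#' with harmonic bonds \eqn{U_b = k_b (r - r_0)^2 / 2}, harmonic angles
#' \eqn{U_a = k_a (\theta - \theta_0)^2 / 2}, 12-6 Lennard-Jones pair terms
#' (potential-shifted to zero at the cutoff, Lorentz-Berthelot combination)
#' and reaction-field-damped Coulomb interactions (potential and force both
#' vanish at the cutoff). First (1-2) and second (1-3) bonded neighbours are
#' excluded from the nonbonded sums.
#'
#' @param bonds data.frame with columns `type` (e.g. "AA-CH2"), `k`
#'   (kJ/mol/nm^2) and `r0` (nm). Bond type labels are symmetric:
#'   "A-B" and "B-A" are the same type.
#' @param angles data.frame with columns `type` (e.g. "AA-CH2-CH2"), `k`
#'   (kJ/mol/rad^2) and `theta0` (rad); "A-B-C" equals "C-B-A".
#' @param lj data.frame with columns `species`, `eps` (kJ/mol), `sigma` (nm).
#' @param charges named numeric, partial charge per species (e).
#' @param masses named numeric, mass per species (g/mol).
#' @param cutoff nonbonded cutoff (nm).
#' @param coul_k Coulomb prefactor (kJ nm / mol / e^2).
#' @return an object of class `forcefield`.
#' @seealso [default_forcefield()], [assign_forcefield()]
#' @export
forcefield <- function(bonds, angles, lj, charges, masses,
                       cutoff = 1.2, coul_k = .coul_k) {
  stopifnot(is.data.frame(bonds), all(c("type", "k", "r0") %in% names(bonds)),
            is.data.frame(angles), all(c("type", "k", "theta0") %in% names(angles)),
            is.data.frame(lj), all(c("species", "eps", "sigma") %in% names(lj)))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(bonds$k < 0) || any(angles$k < 0) || any(lj$eps < 0) || any(lj$sigma < 0))
    stop("force constants, eps and sigma must be non-negative")
  if (!all(names(charges) %in% lj$species) || !all(names(masses) %in% lj$species))
    stop("charges and masses must be named by species present in the LJ table")
  structure(list(bonds = bonds, angles = angles, lj = lj,
                 charges = charges, masses = masses,
                 cutoff = cutoff, coul_k = coul_k),
            class = "forcefield")
}

#' Default coarse-grained parameter set
#'
#' The shipped defaults for the AA/PEG/water bead model: soft harmonic bonds
#' (k = 4000 kJ/mol/nm^2, r0 = 0.15 nm), tetrahedral harmonic angles
#' (k = 50 kJ/mol/rad^2, theta0 = 109.47 deg), per-species Lennard-Jones
#' parameters with a strongly self-attracting AA bead (the driver of micelle
#' formation), AA partial charge -0.2 e (neutralised at build time by a water
#' countercharge), and a 1.2 nm cutoff. These constants are this package's own
#' documented parameterisation of the model; see the methods vignette for the
#' reasoning behind each value.
#'
#' @param cutoff nonbonded cutoff in nm (default 1.2).
#' @return a [forcefield()] object covering species AA, CH2, O, W.
#' @export
default_forcefield <- function(cutoff = 1.2) {
  sp <- c("AA", "CH2", "O", "W")
  bb <- c("AA", "CH2", "O")   # backbone species
  pairs <- outer(bb, bb, paste, sep = "-")
  bonds <- data.frame(type = unique(vapply(pairs, normalize_bond_type, "")),
                      k = 4000, r0 = 0.15)
  triples <- as.vector(outer(as.vector(pairs), bb,
                             function(p, v) {
                               e <- do.call(rbind, strsplit(p, "-"))
                               paste(e[, 1], v, e[, 2], sep = "-")
                             }))
  ang <- unique(vapply(triples, normalize_angle_type, ""))
  angles <- data.frame(type = ang, k = 50, theta0 = 109.47 * pi / 180)
  lj <- data.frame(species = sp,
                   eps = c(5.0, 0.40, 0.60, 0.65),
                   sigma = c(0.45, 0.39, 0.30, 0.3166))
  charges <- c(AA = -0.2, CH2 = 0, O = 0, W = 0)
  masses <- c(AA = 72.06, CH2 = 14.03, O = 16.00, W = 18.02)
  forcefield(bonds, angles, lj, charges, masses, cutoff = cutoff)
}

# "B-A" -> "A-B"
normalize_bond_type <- function(type) {
  p <- strsplit(type, "-", fixed = TRUE)[[1]]
  if (length(p) != 2) stop("malformed bond type: ", type)
  paste(sort(p)[1], sort(p)[2], sep = "-")
}

# "C-B-A" -> "A-B-C" (vertex stays in the middle)
normalize_angle_type <- function(type) {
  p <- strsplit(type, "-", fixed = TRUE)[[1]]
  if (length(p) != 3) stop("malformed angle type: ", type)
  ends <- sort(c(p[1], p[3]))
  paste(ends[1], p[2], ends[2], sep = "-")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("Coarse-grained force field\n")
  cat("  species:", paste(x$lj$species, collapse = ", "), "\n")
  cat("  bond types:", nrow(x$bonds), " angle types:", nrow(x$angles), "\n")
  cat("  cutoff:", x$cutoff, "nm\n")
  invisible(x)
}

#' Attach a force field to a particle system
#'
#' Validates that every species, bond type and angle type present in the
#' system has a parameter entry (validation is total; there are no silent
#' defaults), then attaches per-particle masses and charges and the
#' interaction constants. Pre-existing per-particle charges (e.g. the water
#' countercharge set by [build_network()]) are preserved.
#'
#' @param system a [particle_system()].
#' @param params a [forcefield()].
#' @return the system, carrying `forcefield` and per-particle `masses`/`charges`.
#' @export
assign_forcefield <- function(system, params) {
  stopifnot(inherits(system, "particle_system"), inherits(params, "forcefield"))
  if (n_particles(system) == 0) {
    system$forcefield <- params
    return(system)
  }
  missing_sp <- setdiff(unique(system$species), params$lj$species)
  if (length(missing_sp))
    stop("no LJ parameters for species: ", paste(missing_sp, collapse = ", "))
  missing_sp <- setdiff(unique(system$species), names(params$masses))
  if (length(missing_sp))
    stop("no mass for species: ", paste(missing_sp, collapse = ", "))
  missing_sp <- setdiff(unique(system$species), names(params$charges))
  if (length(missing_sp))
    stop("no charge for species: ", paste(missing_sp, collapse = ", "))
  topo <- system$topology
  if (!is.null(topo) && nrow(topo$bonds)) {
    bt <- unique(vapply(topo$bonds$type, normalize_bond_type, ""))
    missing_bt <- setdiff(bt, vapply(params$bonds$type, normalize_bond_type, ""))
    if (length(missing_bt))
      stop("no bond parameters for type(s): ", paste(missing_bt, collapse = ", "))
  }
  if (!is.null(topo) && nrow(topo$angles)) {
    at <- unique(vapply(topo$angles$type, normalize_angle_type, ""))
    missing_at <- setdiff(at, vapply(params$angles$type, normalize_angle_type, ""))
    if (length(missing_at))
      stop("no angle parameters for type(s): ", paste(missing_at, collapse = ", "))
  }
  if (params$cutoff > min(system$box) / 2)
    stop("cutoff exceeds half the smallest box edge")
  system$masses <- unname(params$masses[system$species])
  if (is.null(system$charges))
    system$charges <- unname(params$charges[system$species])
  system$forcefield <- params
  system
}
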