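#' Potential energy breakdown
#'
#' Evaluates the Hamiltonian of the assigned force field for the current
#' configuration: harmonic bond and angle terms, shifted Lennard-Jones and
#' reaction-field Coulomb nonbonded terms (minimum-image convention, cutoff,
#' 1-2 and 1-3 exclusions). `total` is the exact sum of the four components.
#'
#' @param system a [particle_system()] with assigned force field.
#' @return list with `bond`, `angle`, `lj`, `coulomb`, `total` (kJ/mol).
#' @export
potential_energy <- function(system) {
  a <- engine_args(system)
  engine_energy(a$pos, a$charge, a$mass, a$type, a$ntypes, a$eps, a$sig,
                a$box, a$cutoff, a$coulk, a$bonds, a$bond_k, a$bond_r0,
                a$angles, a$ang_k, a$ang_t0, a$frozen, with_forces = FALSE)
}

#' Analytic forces
#'
#' @param system a [particle_system()] with assigned force field.
#' @return N x 3 matrix of forces (kJ/mol/nm) with the energy breakdown in
#'   attribute `"energy"`. Restrained particles have zero force.
#' @export
compute_forces <- function(system) {
  a <- engine_args(system)
  r <- engine_energy(a$pos, a$charge, a$mass, a$type, a$ntypes, a$eps, a$sig,
                     a$box, a$cutoff, a$coulk, a$bonds, a$bond_k, a$bond_r0,
                     a$angles, a$ang_k, a$ang_t0, a$frozen, with_forces = TRUE)
  f <- r$forces
  attr(f, "energy") <- r[c("bond", "angle", "lj", "coulomb", "total")]
  f
}

#' One constant-volume uniaxial deformation increment
#'
#' Scales Lz by `(1 + rate * dt)` and Lx, Ly each by its inverse square root,
#' remapping all coordinates affinely; the box volume is unchanged to machine
#' precision. `rate = 0` is the identity.
#'
#' @param system a [particle_system()].
#' @param rate stretching rate (1/ns); non-negative for stretch, negative
#'   values compress z.
#' @param dt increment duration (ps).
#' @export
apply_deformation_increment <- function(system, rate, dt) {
  s <- 1 + rate * 1e-3 * dt
  if (s <= 0) stop("deformation increment would collapse the box")
  xy <- 1 / sqrt(s)
  system$box <- system$box * c(xy, xy, s)
  system$positions <- sweep(system$positions, 2, c(xy, xy, s), "*")
  system
}

#' Deformation protocol
#'
#' Describes a rate-controlled constant-volume uniaxial experiment:
#' a linear-engineering-strain ramp at `rate` up to `target_ratio`
#' (ramp duration = target_ratio / rate), an optional hold, and an optional
#' reverse ramp back to the undeformed shape at the same rate.
#'
#' @param rate stretching rate (1/ns), > 0 unless `target_ratio` is 0.
#' @param target_ratio target engineering strain (1.0 = 100% stretch).
#' @param hold hold duration after the ramp (ns).
#' @param reverse if TRUE, compress back to the original shape after the hold.
#' @param temperature thermostat set point (K).
#' @param dt timestep (ps).
#' @param friction Langevin friction (1/ps); 0 gives NVE dynamics.
#' @param stride frame recording stride (steps).
#' @param record_velocities record per-frame velocities (needed for velocity
#'   autocorrelation analysis).
#' @return an object of class `deformation_protocol`.
#' @export
deformation_protocol <- function(rate, target_ratio, hold = 0, reverse = FALSE,
                                 temperature = 300, dt = 0.002, friction = 1,
                                 stride = 500, record_velocities = FALSE) {
  if (target_ratio < 0) stop("target_ratio must be >= 0")
  if (target_ratio > 0 && rate <= 0) stop("rate must be positive for a ramp")
  structure(list(rate = rate, target_ratio = target_ratio, hold = hold,
                 reverse = reverse, temperature = temperature, dt = dt,
                 friction = friction, stride = as.integer(stride),
                 record_velocities = record_velocities),
            class = "deformation_protocol")
}

#' @export
print.deformation_protocol <- function(x, ...) {
  ramp <- if (x$target_ratio > 0) x$target_ratio / x$rate else 0
  cat("deformation_protocol: rate", x$rate, "1/ns, target ratio", x$target_ratio,
      sprintf("(ramp %.4g ns)", ramp), "\n  hold", x$hold, "ns, reverse:",
      x$reverse, "| T =", x$temperature, "K, dt =", x$dt, "ps\n")
  invisible(x)
}

# low-level engine call; zscale is the per-step Lz multiplier (possibly all 1)
run_md <- function(system, n_steps, dt, temperature, friction, zscale = NULL,
                   stride = 500L, log_stride = NULL, record_vel = FALSE,
                   seed = NULL) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  a <- engine_args(system)
  if (is.null(zscale)) zscale <- numeric(0)
  if (is.null(log_stride)) log_stride <- max(1L, min(stride, 1000L))
  call_engine <- function() {
    engine_run(a$pos, system$velocities, a$charge, a$mass, a$type, a$ntypes,
               a$eps, a$sig, a$box, a$cutoff, a$coulk, a$bonds, a$bond_k,
               a$bond_r0, a$angles, a$ang_k, a$ang_t0, a$frozen,
               as.integer(n_steps), dt, friction, temperature,
               zscale, as.integer(stride), as.integer(log_stride), 0.3,
               system$time, record_vel)
  }
  res <- if (is.null(seed)) call_engine() else with_seed(seed, call_engine())
  log <- as.data.frame(res$log)
  names(log) <- c("time", "temperature", "bond", "angle", "lj", "coulomb",
                  "potential", "kinetic", "Lx", "Ly", "Lz")
  traj <- structure(list(times = res$times, boxes = res$frame_box,
                         positions = res$frame_pos,
                         velocities = if (record_vel) res$frame_vel else NULL,
                         log = log, species = system$species,
                         topology = system$topology,
                         forcefield = system$forcefield,
                         restrained = system$restrained,
                         charges = system$charges, masses = system$masses),
                    class = "md_trajectory")
  final <- system
  final$positions <- res$pos
  final$velocities <- res$vel
  final$box <- as.numeric(res$box)
  final$time <- system$time + n_steps * dt
  list(trajectory = traj, system = final)
}

#' Run a deformation protocol
#'
#' Executes ramp, hold and optional reverse phases with the Langevin
#' thermostat, applying the affine constant-volume box update every step so
#' that the engineering strain grows linearly in time (100% stretch at rate r
#' takes exactly 1/r ns). Frames are recorded every `protocol$stride` steps.
#'
#' @param system a [particle_system()] with assigned force field.
#' @param protocol a [deformation_protocol()].
#' @param seed integer seed for the thermostat noise; runs are reproducible
#'   for a fixed seed.
#' @return list with `trajectory` (class `md_trajectory`) and `system`
#'   (the final configuration).
#' @export
run_protocol <- function(system, protocol, seed = 1) {
  stopifnot(inherits(protocol, "deformation_protocol"))
  dt <- protocol$dt
  r <- protocol$rate * 1e-3          # 1/ps
  phases <- list()
  if (protocol$target_ratio > 0) {
    n_ramp <- max(1L, round(protocol$target_ratio / (r * dt)))
    tgrid <- (0:n_ramp) * dt
    lam <- 1 + r * tgrid
    phases$ramp <- lam[-1] / lam[-length(lam)]
  }
  if (protocol$hold > 0) {
    n_hold <- max(1L, round(protocol$hold * 1000 / dt))
    phases$hold <- rep(1, n_hold)
  }
  if (protocol$reverse && protocol$target_ratio > 0) {
    n_ramp <- length(phases$ramp)
    tgrid <- (0:n_ramp) * dt
    lam <- (1 + protocol$target_ratio) - r * tgrid
    if (any(lam <= 0)) stop("reverse ramp would collapse the box")
    phases$reverse <- lam[-1] / lam[-length(lam)]
  }
  if (!length(phases)) phases$hold <- rep(1, max(1L, round(1 / dt)))

  with_seed(seed, {
    parts <- list()
    for (ph in names(phases)) {
      zs <- phases[[ph]]
      out <- run_md(system, length(zs), dt, protocol$temperature,
                    protocol$friction, zscale = zs, stride = protocol$stride,
                    record_vel = protocol$record_velocities)
      out$trajectory$phase <- rep(ph, length(out$trajectory$times))
      parts[[ph]] <- out$trajectory
      system <- out$system
    }
    traj <- merge_trajectories(parts)
    traj$protocol <- protocol
    list(trajectory = traj, system = system)
  })
}

merge_trajectories <- function(parts) {
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (p in parts[-1]) {
      # drop the duplicated initial frame of each continuation
      keep <- if (length(p$times) > 1) -1L else TRUE
      out$times <- c(out$times, p$times[keep])
      out$boxes <- rbind(out$boxes, p$boxes[keep, , drop = FALSE])
      out$positions <- c(out$positions, p$positions[keep])
      if (!is.null(out$velocities)) out$velocities <- c(out$velocities, p$velocities[keep])
      out$phase <- c(out$phase, p$phase[keep])
      out$log <- rbind(out$log, p$log[-1, , drop = FALSE])
    }
  }
  out
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", length(x$times), "frames,",
      length(x$species), "particles\n")
  cat(sprintf("  time %.4g .. %.4g ps\n", x$times[1], x$times[length(x$times)]))
  b0 <- x$boxes[1, ]; b1 <- x$boxes[nrow(x$boxes), ]
  cat(sprintf("  box %.3g x %.3g x %.3g -> %.3g x %.3g x %.3g nm\n",
              b0[1], b0[2], b0[3], b1[1], b1[2], b1[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame as a particle system
#'
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return a [particle_system()].
#' @export
traj_frame <- function(traj, i) {
  if (i < 1 || i > length(traj$times)) stop("frame index out of range")
  sys <- particle_system(traj$positions[[i]], traj$species, traj$boxes[i, ],
                         velocities = if (!is.null(traj$velocities))
                           traj$velocities[[i]] else NULL,
                         charges = traj$charges, masses = traj$masses,
                         topology = traj$topology, restrained = traj$restrained)
  sys$forcefield <- traj$forcefield
  sys$time <- traj$times[i]
  sys
}

#' Equilibrate at constant box
#'
#' Convenience wrapper: Langevin dynamics without deformation.
#'
#' @param system a [particle_system()] with assigned force field.
#' @param time_ps simulation length (ps).
#' @param temperature thermostat set point (K).
#' @param dt timestep (ps).
#' @param friction Langevin friction (1/ps).
#' @param seed integer seed.
#' @param stride frame stride.
#' @param record_velocities record per-frame velocities.
#' @return list with `trajectory` and final `system`.
#' @export
equilibrate <- function(system, time_ps, temperature = 300, dt = 0.002,
                        friction = 1, seed = 1, stride = 500,
                        record_velocities = FALSE) {
  n <- max(1L, round(time_ps / dt))
  with_seed(seed, run_md(system, n, dt, temperature, friction, stride = stride,
                         record_vel = record_velocities))
}

#' Steepest-descent energy minimisation
#'
#' Relaxes bad contacts with an adaptive-step steepest descent. Restrained
#' particles do not move.
#'
#' @param system a [particle_system()] with assigned force field.
#' @param max_steps iteration budget.
#' @param ftol force-norm convergence threshold (kJ/mol/nm).
#' @return the relaxed system; the energy breakdown of the final
#'   configuration is stored in attribute `"energy"`.
#' @export
minimize_system <- function(system, max_steps = 500, ftol = 10) {
  a <- engine_args(system)
  r <- engine_minimize(a$pos, a$charge, a$mass, a$type, a$ntypes, a$eps, a$sig,
                       a$box, a$cutoff, a$coulk, a$bonds, a$bond_k, a$bond_r0,
                       a$angles, a$ang_k, a$ang_t0, a$frozen,
                       as.integer(max_steps), 0.002, ftol)
  system$positions <- r$pos
  attr(system, "energy") <- r$energy
  system
}
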