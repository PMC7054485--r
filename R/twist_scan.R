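#' Twist-energy scan of the four-chains model
#'
#' Imposes a range of end twists on a four-chains system and reports the
#' potential energy of the relaxed configuration at each twist, together
#' with the energy-minimizing twist angle. A twist of phi rotates the four
#' pinned chain ends rigidly by phi about the fiber axis (z, through the
#' crosslink centroid) while the crosslink anchors stay fixed — a
#' counter-rotation of the two bundle ends. At each twist the interior beads
#' are relaxed from the supplied configuration by steepest-descent
#' minimization (deterministic) and the final potential energy is recorded.
#'
#' The minimizing angle is estimated by a parabola fit through the scan
#' points within `fit_window` degrees of the discrete minimum, which
#' resolves the minimum below the grid resolution.
#'
#' @param system a system from [build_four_chains()], ideally thermally
#'   pre-equilibrated so the chains have realistic slack conformations.
#' @param twists twist angles to scan (degrees).
#' @param relax_steps minimization iterations per twist.
#' @param fit_window half-width (degrees) of the parabola fit around the
#'   discrete minimum.
#' @return object of class `twist_scan`: data.frame with `twist` (deg) and
#'   `energy` (kJ/mol), with attributes `twist_min` (parabola estimate, deg)
#'   and `twist_argmin` (grid minimum, deg).
#' @export
twist_energy_scan <- function(system, twists = seq(0, 6, by = 0.5),
                              relax_steps = 1500, fit_window = 1.6) {
  fc <- system$topology$four_chains
  if (is.null(fc)) stop("twist_energy_scan needs a four-chains system")
  origin <- colMeans(system$positions[fc$anchors, , drop = FALSE])
  energies <- vapply(twists, function(phi) {
    s <- system
    s$positions[fc$ends, ] <- rotate_about_axis(
      system$positions[fc$ends, , drop = FALSE], c(0, 0, 1),
      phi * pi / 180, origin)
    s <- minimize_system(s, max_steps = relax_steps, ftol = 1)
    attr(s, "energy")$total
  }, 1)
  df <- data.frame(twist = twists, energy = energies)
  i0 <- which.min(energies)
  win <- abs(twists - twists[i0]) <= fit_window + 1e-9
  tmin <- twists[i0]
  if (sum(win) >= 3) {
    fit <- lm(energy ~ twist + I(twist^2), data = df[win, ])
    a <- coef(fit)[["I(twist^2)"]]; b <- coef(fit)[["twist"]]
    if (is.finite(a) && a > 0) {
      vertex <- -b / (2 * a)
      if (vertex >= min(twists[win]) && vertex <= max(twists[win]))
        tmin <- vertex
    }
  }
  structure(df, class = c("twist_scan", "data.frame"),
            twist_min = tmin, twist_argmin = twists[i0])
}

#' @export
print.twist_scan <- function(x, ...) {
  cat("twist_scan:", nrow(x), "angles,",
      sprintf("minimum-energy twist %.2f deg (grid %.2f deg)\n",
              attr(x, "twist_min"), attr(x, "twist_argmin")))
  invisible(x)
}

#' @export
plot.twist_scan <- function(x, ...) {
  plot(x$twist, x$energy - min(x$energy), type = "b",
       xlab = "imposed twist (deg)", ylab = "relative energy (kJ/mol)", ...)
  abline(v = attr(x, "twist_min"), col = 2, lty = 2)
  invisible(x)
}

#' Stable twist of the four-chains model
#'
#' Builds the four-chains model in the unstretched class (end-to-end
#' distance a configurable fraction of the contour length, adjacent chains
#' at a small mutual angle), equilibrates each replicate briefly, scans
#' imposed end twists of both signs, and locates the minimum of the
#' replicate-averaged potential-energy curve.
#'
#' A thermal snapshot is chiral, so a single replicate may prefer either
#' twist sense; the model is achiral on average. Each replicate's relaxed
#' energies at +phi and -phi are therefore folded into a symmetric curve in
#' |phi| (after subtracting the replicate's untwisted energy), the folded
#' curves are averaged over replicates, and the reported stable twist is the
#' parabola vertex around the discrete minimum of that mean curve.
#'
#' @param n_replicates independent builds/equilibrations to average over.
#' @param seed base seed; replicate r uses seed + r - 1.
#' @param mutual_angle initial adjacent-chain angle (degrees).
#' @param re_fraction end-to-end distance as a fraction of contour length;
#'   the default 0.5 places the chains mid-way through the unstretched
#'   (slack but bridging) regime.
#' @param equil_ps pre-equilibration length (ps).
#' @param twists magnitude grid (degrees, >= 0); both signs are scanned.
#' @param relax_steps minimization iterations per twist.
#' @param fit_window half-width (degrees) of the parabola fit.
#' @return list with `twist_min` (degrees), `curve` (mean relative energy vs
#'   |twist|), `per_replicate` curves and the raw `scans`.
#' @export
stable_twist <- function(n_replicates = 4, seed = 1, mutual_angle = 10,
                         re_fraction = 0.5, equil_ps = 40,
                         twists = seq(0, 8, by = 0.5), relax_steps = 4000,
                         fit_window = 1.6) {
  stopifnot(all(twists >= 0))
  grid <- sort(unique(c(-twists, twists)))
  scans <- vector("list", n_replicates)
  folded <- matrix(NA_real_, n_replicates, length(twists))
  for (r in seq_len(n_replicates)) {
    s <- seed + r - 1
    sys <- build_four_chains(60, mutual_angle, re_fraction * 60 * 0.15,
                             seed = s)
    sys <- minimize_system(sys, 400)
    sys <- equilibrate(sys, equil_ps, seed = s, stride = 10000)$system
    sc <- twist_energy_scan(sys, twists = grid, relax_steps = relax_steps,
                            fit_window = fit_window)
    scans[[r]] <- sc
    e0 <- sc$energy[sc$twist == 0]
    folded[r, ] <- vapply(twists, function(p)
      mean(sc$energy[abs(sc$twist) == p]) - e0, 1)
  }
  curve <- data.frame(twist = twists, energy = colMeans(folded))
  i0 <- which.min(curve$energy)
  win <- abs(curve$twist - curve$twist[i0]) <= fit_window + 1e-9
  tmin <- curve$twist[i0]
  if (sum(win) >= 3) {
    fit <- lm(energy ~ twist + I(twist^2), data = curve[win, ])
    a <- coef(fit)[["I(twist^2)"]]; b <- coef(fit)[["twist"]]
    if (is.finite(a) && a > 0) {
      vertex <- -b / (2 * a)
      if (vertex >= min(curve$twist[win]) && vertex <= max(curve$twist[win]))
        tmin <- vertex
    }
  }
  list(twist_min = tmin, curve = curve, per_replicate = folded, scans = scans)
}
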