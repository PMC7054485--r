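#' Synthetic bundle fixture with known ground truth
#'
#' Builds a configuration of `n_chains` SFCs (11 beads each: AA + 9 PEG + AA)
#' strung between two synthetic AA clusters separated by `re` along z. Chain
#' k's end-to-end vector is rotated about the x axis by (k-1) * mutual_angle,
#' so all pairwise angles are multiples of `mutual_angle`. Interior beads lie
#' on the straight connecting line plus isotropic Gaussian noise. The
#' expected bundle answer implied by the geometry is computed from the
#' pairwise-angle arithmetic (independent of the detector).
#'
#' @param n_chains number of SFCs.
#' @param mutual_angle angle between consecutive chain vectors (degrees).
#' @param re end-to-end distance (nm); must not exceed the 1.5 nm SFC contour.
#' @param noise Gaussian positional noise sigma (nm) on interior beads.
#' @param seed integer seed.
#' @param align_threshold threshold used to derive the expected answer.
#' @return list with `system`, `expected_n_bundles`, `expected_members`
#'   (SFC ids of the expected bundle, or NULL) and `params`.
#' @export
make_bundle_fixture <- function(n_chains, mutual_angle, re, noise = 0,
                                seed = 1, align_threshold = 30) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  contour <- 10 * 0.15
  if (re > contour + 1e-9)
    stop("impossible geometry: re exceeds the SFC contour length (1.5 nm)")
  box <- rep(max(4, 2 * re + 2), 3)
  base <- c(box[1] / 2, box[2] / 2, (box[3] - re) / 2)
  dirs <- t(vapply(seq_len(n_chains), function(k) {
    a <- (k - 1) * mutual_angle * pi / 180
    c(0, sin(a), cos(a))
  }, numeric(3)))
  with_seed(seed, {
    pos <- NULL; species <- character(0)
    bi <- bj <- integer(0); bt <- character(0)
    sfc <- list()
    unit <- c("AA", rep(c("CH2", "CH2", "O"), 3), "AA")
    for (k in seq_len(n_chains)) {
      # spread chain start points slightly so each cluster is a small blob
      off <- 0.12 * c(cos(2 * pi * k / n_chains), sin(2 * pi * k / n_chains), 0)
      a <- base + off
      e <- a + re * dirs[k, ]
      tgrid <- seq(0, 1, length.out = 11)
      p <- outer(1 - tgrid, a) + outer(tgrid, e)
      if (noise > 0)
        p[2:10, ] <- p[2:10, ] + matrix(rnorm(27, sd = noise), 9, 3)
      i0 <- length(species)
      pos <- rbind(pos, p)
      species <- c(species, unit)
      bi <- c(bi, i0 + 1:10); bj <- c(bj, i0 + 2:11)
      bt <- c(bt, paste(unit[1:10], unit[2:11], sep = "-"))
      sfc[[k]] <- data.frame(chain = k, aa_i = i0 + 1L, aa_j = i0 + 11L,
                             first = i0 + 2L, last = i0 + 10L)
    }
    topo <- list(bonds = data.frame(i = bi, j = bj, type = bt),
                 angles = data.frame(i = integer(), j = integer(),
                                     k = integer(), type = character()),
                 chain = rep(seq_len(n_chains), each = 11),
                 aa_by_chain = lapply(seq_len(n_chains),
                                      function(k) c((k - 1) * 11 + 1L, k * 11L)),
                 sfcs = do.call(rbind, sfc))
    sys <- particle_system(pos, species, box, topology = topo)
    sys <- assign_forcefield(sys, default_forcefield())
    # ground truth from pairwise-angle arithmetic
    expected <- NULL
    if (n_chains >= 3 && re > 0.65) {
      ang <- outer(seq_len(n_chains), seq_len(n_chains),
                   function(a, b) abs(a - b) * mutual_angle)
      ang <- pmin(ang %% 180, 180 - ang %% 180)
      if (all(ang <= align_threshold)) expected <- seq_len(n_chains)
    }
    list(system = sys,
         expected_n_bundles = if (is.null(expected)) 0L else 1L,
         expected_members = expected,
         params = list(n_chains = n_chains, mutual_angle = mutual_angle,
                       re = re, noise = noise, seed = seed))
  })
}

#' Layered AA fixture for profile analysis
#'
#' AA beads arranged in z planes at the given spacing (box z edge =
#' `spacing * n_layers`, so the layering is perfectly periodic), with
#' Gaussian z jitter. The ground-truth spacing is recorded in the result.
#'
#' @param spacing layer spacing (nm).
#' @param n_layers number of layers.
#' @param jitter Gaussian sigma (nm) applied to each bead's z coordinate.
#' @param seed integer seed.
#' @param n_per_layer beads per layer.
#' @param xy_edge box edge in x and y (nm).
#' @return list with `system` and `truth` (the spacing).
#' @export
make_layered_fixture <- function(spacing, n_layers, jitter = 0, seed = 1,
                                 n_per_layer = 40, xy_edge = 5) {
  box <- c(xy_edge, xy_edge, spacing * n_layers)
  with_seed(seed, {
    n <- n_layers * n_per_layer
    z <- rep((seq_len(n_layers) - 0.5) * spacing, each = n_per_layer)
    if (jitter > 0) z <- z + rnorm(n, sd = jitter)
    pos <- cbind(runif(n) * xy_edge, runif(n) * xy_edge, z)
    sys <- particle_system(pos, rep("AA", n), box)
    list(system = wrap_positions(sys), truth = spacing)
  })
}

#' Clustered AA point fixture
#'
#' Gaussian blobs of AA beads for cluster-identification and Delaunay tests.
#'
#' @param n_clusters number of blobs.
#' @param pts_per_cluster beads per blob.
#' @param sd blob standard deviation (nm).
#' @param box_edge cubic box edge (nm).
#' @param seed integer seed.
#' @return a [particle_system()] of AA beads.
#' @export
make_clustered_points <- function(n_clusters = 4, pts_per_cluster = 10,
                                  sd = 0.15, box_edge = 6, seed = 1) {
  with_seed(seed, {
    centers <- matrix(runif(3 * n_clusters) * box_edge, ncol = 3)
    pos <- do.call(rbind, lapply(seq_len(n_clusters), function(k)
      sweep(matrix(rnorm(3 * pts_per_cluster, sd = sd), ncol = 3), 2,
            centers[k, ], "+")))
    wrap_positions(particle_system(pos, rep("AA", nrow(pos)),
                                   rep(box_edge, 3)))
  })
}

#' Planted rotational-diffusion unit-vector series
#'
#' Unit vectors diffusing on the sphere with rotational correlation time
#' `tau_star`: each step applies a random rotation whose three axis
#' components are independent Gaussians of variance `dt / tau_star`, so the
#' planted decay of the orientational autocorrelation is exactly
#' exp(-t / tau_star). Used as the analytic oracle for relaxation-time
#' recovery.
#'
#' @param tau_star planted correlation time (ps), > 0.
#' @param n_steps number of steps (series length is n_steps + 1).
#' @param dt time step (ps).
#' @param seed integer seed.
#' @param n_vectors number of independent vectors.
#' @return array (n_steps + 1) x n_vectors x 3 with attributes `tau_star`
#'   and `dt`.
#' @export
make_planted_correlation <- function(tau_star, n_steps, dt, seed = 1,
                                     n_vectors = 1) {
  if (tau_star <= 0) stop("tau_star must be positive")
  with_seed(seed, {
    arr <- array(NA_real_, c(n_steps + 1, n_vectors, 3))
    for (v in seq_len(n_vectors)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      arr[1, v, ] <- u
      sdstep <- sqrt(dt / tau_star)
      for (s in seq_len(n_steps)) {
        w <- rnorm(3, sd = sdstep)
        th <- sqrt(sum(w^2))
        if (th > 0) u <- as.vector(rotate_about_axis(rbind(u), w / th, th))
        arr[s + 1, v, ] <- u
      }
    }
    attr(arr, "tau_star") <- tau_star
    attr(arr, "dt") <- dt
    arr
  })
}
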