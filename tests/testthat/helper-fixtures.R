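# shared fixtures and independent oracles

# force field covering every species pair/triple with the default constants,
# handy for arbitrary test topologies
full_ff <- function(cutoff = 1.2, charges = c(AA = -0.2, CH2 = 0, O = 0, W = 0)) {
  bb <- c("AA", "CH2", "O", "W")
  pr <- as.vector(outer(bb, bb, paste, sep = "-"))
  bonds <- data.frame(type = unique(vapply(pr, fibrilMD:::normalize_bond_type, "")),
                      k = 4000, r0 = 0.15)
  tri <- expand.grid(a = bb, v = bb, c = bb)
  ang <- unique(vapply(paste(tri$a, tri$v, tri$c, sep = "-"),
                       fibrilMD:::normalize_angle_type, ""))
  angles <- data.frame(type = ang, k = 50, theta0 = 1.911)
  forcefield(bonds, angles, default_forcefield()$lj, charges,
             c(AA = 72.06, CH2 = 14.03, O = 16.00, W = 18.02),
             cutoff = cutoff)
}

empty_topology <- function(n) {
  list(bonds = data.frame(i = integer(), j = integer(), type = character()),
       angles = data.frame(i = integer(), j = integer(), k = integer(),
                           type = character()),
       chain = rep(NA_integer_, n), aa_by_chain = list(),
       sfcs = data.frame(chain = integer(), aa_i = integer(),
                         aa_j = integer(), first = integer(),
                         last = integer()))
}

# harmonic dimer along z with opposing velocities; pure bond interaction
harmonic_dimer <- function(sep = 0.18, v = 0.1) {
  topo <- empty_topology(2)
  topo$bonds <- data.frame(i = 1L, j = 2L, type = "CH2-CH2")
  sys <- particle_system(rbind(c(2, 2, 2), c(2, 2, 2 + sep)),
                         c("CH2", "CH2"), c(5, 5, 5), topology = topo)
  sys <- assign_forcefield(sys, full_ff())
  sys$velocities <- rbind(c(0, 0, v), c(0, 0, -v))
  sys
}

# independent R evaluation of the Hamiltonian: plain double loops, no reuse
# of the engine's code paths
brute_energy <- function(sys) {
  ff <- sys$forcefield
  box <- sys$box
  mi <- function(d) d - box * round(d / box)
  p <- sys$positions
  eb <- 0
  topo <- sys$topology
  if (nrow(topo$bonds)) {
    key <- vapply(ff$bonds$type, fibrilMD:::normalize_bond_type, "")
    for (b in seq_len(nrow(topo$bonds))) {
      i <- topo$bonds$i[b]; j <- topo$bonds$j[b]
      r <- sqrt(sum(mi(p[i, ] - p[j, ])^2))
      k <- match(fibrilMD:::normalize_bond_type(topo$bonds$type[b]), key)
      eb <- eb + 0.5 * ff$bonds$k[k] * (r - ff$bonds$r0[k])^2
    }
  }
  ea <- 0
  if (nrow(topo$angles)) {
    key <- vapply(ff$angles$type, fibrilMD:::normalize_angle_type, "")
    for (a in seq_len(nrow(topo$angles))) {
      i <- topo$angles$i[a]; j <- topo$angles$j[a]; k2 <- topo$angles$k[a]
      v1 <- mi(p[i, ] - p[j, ]); v2 <- mi(p[k2, ] - p[j, ])
      th <- acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2)))))
      k <- match(fibrilMD:::normalize_angle_type(topo$angles$type[a]), key)
      ea <- ea + 0.5 * ff$angles$k[k] * (th - ff$angles$theta0[k])^2
    }
  }
  excl <- matrix(FALSE, nrow(p), nrow(p))
  if (nrow(topo$bonds))
    for (b in seq_len(nrow(topo$bonds)))
      excl[topo$bonds$i[b], topo$bonds$j[b]] <-
        excl[topo$bonds$j[b], topo$bonds$i[b]] <- TRUE
  if (nrow(topo$angles))
    for (a in seq_len(nrow(topo$angles)))
      excl[topo$angles$i[a], topo$angles$k[a]] <-
        excl[topo$angles$k[a], topo$angles$i[a]] <- TRUE
  elj <- ec <- 0
  rc <- ff$cutoff
  q <- sys$charges; if (is.null(q)) q <- rep(0, nrow(p))
  for (i in seq_len(nrow(p) - 1)) {
    for (j in (i + 1):nrow(p)) {
      if (excl[i, j]) next
      r <- sqrt(sum(mi(p[i, ] - p[j, ])^2))
      if (r >= rc) next
      si <- match(sys$species[i], ff$lj$species)
      sj <- match(sys$species[j], ff$lj$species)
      eps <- sqrt(ff$lj$eps[si] * ff$lj$eps[sj])
      sig <- (ff$lj$sigma[si] + ff$lj$sigma[sj]) / 2
      if (eps > 0)
        elj <- elj + 4 * eps * ((sig / r)^12 - (sig / r)^6) -
                     4 * eps * ((sig / rc)^12 - (sig / rc)^6)
      if (q[i] * q[j] != 0)
        ec <- ec + ff$coul_k * q[i] * q[j] *
              (1 / r + r^2 / (2 * rc^3) - 3 / (2 * rc))
    }
  }
  list(bond = eb, angle = ea, lj = elj, coulomb = ec,
       total = eb + ea + elj + ec)
}

# brute-force union-find single-linkage components (independent of igraph)
uf_components <- function(pts, box, cutoff) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pts[i, ] - pts[j, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots[order(match(roots, roots))]))
}

# random multi-cluster SFC geometry for bundle-detection oracle tests
random_sfc_system <- function(n_sfc, n_clusters = 3, seed = 1) {
  withr_seed <- function(expr) fibrilMD:::with_seed(seed, expr)
  withr_seed({
    box <- rep(8, 3)
    centers <- matrix(runif(3 * n_clusters, 2, 6), ncol = 3)
    # keep blobs >= 1.5 nm apart so cluster identity is unambiguous
    for (it in 1:200) {
      D <- as.matrix(dist(centers))
      diag(D) <- Inf
      if (min(D) > 1.6) break
      w <- which(D == min(D), arr.ind = TRUE)[1, ]
      centers[w[1], ] <- runif(3, 2, 6)
    }
    unit <- c("AA", rep(c("CH2", "CH2", "O"), 3), "AA")
    pos <- NULL; species <- character(0)
    bi <- bj <- integer(0); bt <- character(0); sfc <- list()
    for (k in seq_len(n_sfc)) {
      pair <- sample(n_clusters, 2)
      a <- centers[pair[1], ] + rnorm(3, sd = 0.08)
      dir <- centers[pair[2], ] - a
      dir <- dir / sqrt(sum(dir^2))
      # random re in (0.7, 1.4); some chains share the pair and align
      re <- runif(1, 0.7, 1.4)
      e <- a + re * dir + rnorm(3, sd = 0.12)
      tg <- seq(0, 1, length.out = 11)
      pchain <- outer(1 - tg, a) + outer(tg, e)
      i0 <- length(species)
      pos <- rbind(pos, pchain); species <- c(species, unit)
      bi <- c(bi, i0 + 1:10); bj <- c(bj, i0 + 2:11)
      bt <- c(bt, paste(unit[1:10], unit[2:11], sep = "-"))
      sfc[[k]] <- data.frame(chain = k, aa_i = i0 + 1L, aa_j = i0 + 11L,
                             first = i0 + 2L, last = i0 + 10L)
    }
    topo <- list(bonds = data.frame(i = bi, j = bj, type = bt),
                 angles = empty_topology(1)$angles,
                 chain = rep(seq_len(n_sfc), each = 11),
                 aa_by_chain = lapply(seq_len(n_sfc),
                                      function(k) c((k - 1) * 11 + 1L, k * 11L)),
                 sfcs = do.call(rbind, sfc))
    sys <- particle_system(pos, species, box, topology = topo)
    assign_forcefield(sys, default_forcefield())
  })
}

# exhaustive bundle oracle: every maximal >=3-subset of mutually aligned
# two-cluster SFCs sharing a cluster pair, via direct combn enumeration
oracle_bundles <- function(system, sfcs, clusters, align_threshold = 30,
                           re_min = 0.65) {
  cand <- sfcs[sfcs$re > re_min & sfcs$connectivity == "two-cluster", ]
  if (nrow(cand) < 3) return(list())
  v <- fibrilMD:::min_image(system$positions[cand$aa_j, , drop = FALSE] -
                            system$positions[cand$aa_i, , drop = FALSE],
                            system$box)
  v <- v / sqrt(rowSums(v^2))
  key <- paste(pmin(cand$cluster_i, cand$cluster_j),
               pmax(cand$cluster_i, cand$cluster_j), sep = "-")
  aligned <- function(rows) {
    for (a in seq_along(rows)) for (b in seq_len(a - 1)) {
      ang <- acos(min(1, abs(sum(v[rows[a], ] * v[rows[b], ]))))
      if (ang > align_threshold * pi / 180 + 1e-12) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (kk in unique(key)) {
    rows <- which(key == kk)
    if (length(rows) < 3) next
    subsets <- list()
    for (m in length(rows):3) {
      cmb <- utils::combn(rows, m)
      for (cix in seq_len(ncol(cmb))) {
        s <- cmb[, cix]
        if (!aligned(s)) next
        dominated <- any(vapply(subsets, function(t) all(s %in% t), TRUE))
        if (!dominated) subsets[[length(subsets) + 1]] <- s
      }
    }
    for (s in subsets) out[[length(out) + 1]] <- sort(cand$sfc[s])
  }
  out[order(vapply(out, `[`, 1L, 1))]
}

# Cayley-Menger volume from the six edge lengths (independent of the
# coordinate determinant used by the implementation)
cayley_menger_volume <- function(v) {
  d2 <- as.matrix(dist(v))^2
  B <- rbind(c(0, 1, 1, 1, 1),
             cbind(1, d2))
  sqrt(max(0, det(B) / 288))
}

# order-insensitive comparison key for bundle member sets
canon_bundles <- function(bs) {
  key <- vapply(bs, function(m) paste(m, collapse = "-"), "")
  bs[order(key)]
}
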