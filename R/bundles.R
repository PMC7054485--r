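#' Detect bundles of aligned short flexible chains
#'
#' A bundle is a maximal group of three or more SFCs that (a) each have an
#' end-to-end distance above `re_min`, (b) span the same unordered pair of
#' physical clusters, and (c) are mutually aligned: every pair of end-to-end
#' vectors encloses at most `align_threshold` degrees (vectors are treated as
#' undirected, angles folded to <= 90 degrees). Within each cluster pair the
#' maximal mutually-aligned groups are enumerated exactly (maximal cliques of
#' the pairwise-alignment graph), so the result is deterministic and agrees
#' with exhaustive subset enumeration by construction.
#'
#' @param system a [particle_system()].
#' @param sfcs SFC table from [sfc_records()]; computed if NULL.
#' @param clusters `physical_clusters` for the same frame; computed if NULL.
#' @param align_threshold maximal pairwise angle (degrees), default 30.
#' @param re_min minimum member end-to-end distance (nm), default 0.65.
#' @param cutoff cluster cutoff used when `clusters` is NULL.
#' @return object of class `bundle_set`: a list of bundles, each with
#'   `members` (SFC ids), `cluster_pair`, endpoint centres `M1`, `M2`, unit
#'   `fiber` vector M1 -> M2, and the end AA groups `end1`, `end2`.
#' @export
detect_bundles <- function(system, sfcs = NULL, clusters = NULL,
                           align_threshold = 30, re_min = 0.65,
                           cutoff = 0.65) {
  if (is.null(clusters)) clusters <- identify_clusters(system, cutoff)
  if (is.null(sfcs)) sfcs <- sfc_records(system, clusters)
  cand <- sfcs[sfcs$re > re_min & sfcs$connectivity == "two-cluster", , drop = FALSE]
  bundles <- list()
  if (nrow(cand)) {
    v <- min_image(system$positions[cand$aa_j, , drop = FALSE] -
                   system$positions[cand$aa_i, , drop = FALSE], system$box)
    v <- v / sqrt(rowSums(v^2))
    pair_key <- paste(pmin(cand$cluster_i, cand$cluster_j),
                      pmax(cand$cluster_i, cand$cluster_j), sep = "-")
    cosmax <- cos(align_threshold * pi / 180)
    for (key in sort(unique(pair_key))) {
      rows <- which(pair_key == key)
      if (length(rows) < 3) next
      cmat <- abs(v[rows, , drop = FALSE] %*% t(v[rows, , drop = FALSE]))
      adj <- cmat >= cosmax - 1e-12
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      cl <- igraph::max_cliques(g, min = 3)
      for (q in cl) {
        members <- sort(cand$sfc[rows[as.integer(q)]])
        bundles[[length(bundles) + 1L]] <-
          make_bundle(system, sfcs, members, key)
      }
    }
  }
  if (length(bundles)) {
    ord <- order(vapply(bundles, function(b) b$cluster_pair, ""),
                 vapply(bundles, function(b) b$members[1], 1L))
    bundles <- bundles[ord]
  }
  structure(bundles, class = "bundle_set",
            align_threshold = align_threshold, re_min = re_min)
}

make_bundle <- function(system, sfcs, members, key) {
  rows <- sfcs[match(members, sfcs$sfc), ]
  c1 <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]][1])
  # end 1 = chain-end AA groups sitting in the lower-labelled cluster
  end1 <- ifelse(rows$cluster_i == c1, rows$aa_i, rows$aa_j)
  end2 <- ifelse(rows$cluster_i == c1, rows$aa_j, rows$aa_i)
  M1 <- unwrap_center(system$positions[end1, , drop = FALSE], system$box)
  M2pts <- system$positions[end2, , drop = FALSE]
  # keep M2 in the image nearest to M1
  d <- min_image(sweep(M2pts, 2, M1), system$box)
  M2 <- M1 + colMeans(d)
  fib <- M2 - M1
  nf <- sqrt(sum(fib^2))
  list(members = members, cluster_pair = key, end1 = end1, end2 = end2,
       M1 = M1, M2 = M2, fiber = if (nf > 0) fib / nf else c(NA, NA, NA))
}

unwrap_center <- function(pts, box) {
  ref <- pts[1, ]
  ref + colMeans(min_image(sweep(pts, 2, ref), box))
}

#' @export
print.bundle_set <- function(x, ...) {
  cat("bundle_set:", length(x), "bundle(s)\n")
  for (i in seq_along(x))
    cat(sprintf("  [%d] clusters %s, %d SFCs: %s\n", i, x[[i]]$cluster_pair,
                length(x[[i]]$members), paste(x[[i]]$members, collapse = " ")))
  invisible(x)
}

#' Fiber vector of a chain set
#'
#' The normalized sum of the chain end-to-end vectors.
#'
#' @param vectors matrix with one end-to-end vector per row.
#' @return unit length-3 vector.
#' @export
fiber_vector <- function(vectors) {
  vectors <- rbind(vectors)
  if (!nrow(vectors)) stop("need at least one chain vector")
  s <- colSums(vectors)
  n <- sqrt(sum(s^2))
  if (n < 1e-10) stop("degenerate input: chain vectors sum to zero")
  s / n
}

#' Orientational order parameter P2
#'
#' The second Legendre polynomial of the segment-fiber angle,
#' \deqn{P_2 = (3 \langle \cos^2\theta \rangle - 1) / 2,}
#' averaged over the next-nearest-neighbour segment vectors
#' \eqn{v_i = A_{i+2} - A_i} of all listed chains. P2 = 1 for segments
#' parallel to the fiber vector, -0.5 for perpendicular, ~0 for isotropic.
#'
#' @param system a [particle_system()].
#' @param chain_ids chains whose segments enter the average (default all).
#' @param fiber unit reference vector (default +z, the stretch axis).
#' @return object of class `orientation_result`: list with `p2`, `angles`
#'   (rad) and `n_segments`.
#' @export
order_parameter_p2 <- function(system, chain_ids = NULL, fiber = c(0, 0, 1)) {
  chain <- system$topology$chain
  if (is.null(chain_ids)) chain_ids <- sort(unique(chain[!is.na(chain)]))
  segs <- list()
  for (ch in chain_ids) {
    idx <- which(!is.na(chain) & chain == ch)
    if (length(idx) < 3) stop("chain ", ch, " has fewer than 3 groups")
    a <- system$positions[idx[seq_len(length(idx) - 2)], , drop = FALSE]
    b <- system$positions[idx[-(1:2)], , drop = FALSE]
    segs[[length(segs) + 1]] <- min_image(b - a, system$box)
  }
  segs <- do.call(rbind, segs)
  p2_from_segments(segs, fiber)
}

#' P2 from raw segment vectors
#'
#' @param segments matrix of segment vectors (rows).
#' @param axis reference direction (need not be normalized).
#' @return an `orientation_result` (see [order_parameter_p2()]).
#' @export
p2_from_segments <- function(segments, axis) {
  segments <- rbind(segments)
  n <- sqrt(rowSums(segments^2))
  if (any(n < 1e-12)) stop("zero-length segment")
  axis <- axis / sqrt(sum(axis^2))
  ct <- as.vector(segments %*% axis) / n
  ct <- pmin(1, pmax(-1, ct))
  structure(list(p2 = 0.5 * (3 * mean(ct^2) - 1), angles = acos(ct),
                 n_segments = nrow(segments)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("P2 = %.4f over %d segments\n", x$p2, x$n_segments))
  invisible(x)
}

#' Per-end bundle rotation between two frames
#'
#' For each bundle end, the mean signed angular displacement of its member
#' chain-end AA groups about the bundle axis (the frame-t0 fiber vector),
#' measured in the plane perpendicular to the axis relative to that end's
#' centre of mass; the sign follows the right-hand rule about the fiber
#' vector.
#'
#' @param bundle one element of a `bundle_set` detected at frame t0.
#' @param frame_t0,frame_t [particle_system()] snapshots at the two times.
#' @return numeric length 2: rotation angles (rad) of end 1 and end 2.
#' @export
bundle_rotation <- function(bundle, frame_t0, frame_t) {
  axis <- bundle$fiber
  if (any(!is.finite(axis))) stop("bundle has a degenerate fiber vector")
  rot_end <- function(groups) {
    p0 <- frame_t0$positions[groups, , drop = FALSE]
    p1 <- frame_t$positions[groups, , drop = FALSE]
    c0 <- unwrap_center(p0, frame_t0$box)
    c1 <- unwrap_center(p1, frame_t$box)
    r0 <- min_image(sweep(p0, 2, c0), frame_t0$box)
    r1 <- min_image(sweep(p1, 2, c1), frame_t$box)
    proj <- function(m) m - outer(as.vector(m %*% axis), axis)
    r0 <- proj(r0); r1 <- proj(r1)
    ang <- numeric(nrow(r0))
    for (i in seq_len(nrow(r0))) {
      a <- r0[i, ]; b <- r1[i, ]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na < 1e-9 || nb < 1e-9) { ang[i] <- NA_real_; next }
      cr <- pracma_cross(a, b)
      ang[i] <- atan2(sum(cr * axis), sum(a * b))
    }
    mean(ang, na.rm = TRUE)
  }
  c(rot_end(bundle$end1), rot_end(bundle$end2))
}

#' Bundle twist between two frames
#'
#' Twist is the difference of the two per-end rotation angles; synchronized
#' rotation of both ends gives zero twist.
#'
#' @inheritParams bundle_rotation
#' @return twist angle (rad).
#' @export
bundle_twist <- function(bundle, frame_t0, frame_t) {
  r <- bundle_rotation(bundle, frame_t0, frame_t)
  r[1] - r[2]
}

#' Match bundles between two frames
#'
#' A bundle at t0 is considered persistent at t when some bundle at t spans
#' the same unordered cluster pair and shares at least `min_shared` member
#' SFCs with it.
#'
#' @param b0,b1 `bundle_set`s from two frames (cluster labels must be
#'   comparable, e.g. via [match_clusters()]).
#' @param min_shared minimum shared members (default 2).
#' @return integer vector: for each bundle in `b0` the index of its match in
#'   `b1`, or NA.
#' @export
match_bundles <- function(b0, b1, min_shared = 2) {
  vapply(seq_along(b0), function(i) {
    for (j in seq_along(b1)) {
      if (b0[[i]]$cluster_pair == b1[[j]]$cluster_pair &&
          length(intersect(b0[[i]]$members, b1[[j]]$members)) >= min_shared)
        return(j)
    }
    NA_integer_
  }, 1L)
}

#' Rotate points about an axis
#'
#' Rodrigues rotation of a point set about an arbitrary axis through
#' `origin`; used to script rigid bundle rotations and impose end twists.
#'
#' @param points matrix of points (rows).
#' @param axis rotation axis (normalized internally).
#' @param angle rotation angle (rad), right-hand rule.
#' @param origin point on the axis.
#' @export
rotate_about_axis <- function(points, axis, angle, origin = c(0, 0, 0)) {
  points <- rbind(points)
  u <- axis / sqrt(sum(axis^2))
  p <- sweep(points, 2, origin)
  cosA <- cos(angle); sinA <- sin(angle)
  dotu <- as.vector(p %*% u)
  crossu <- t(apply(p, 1, function(r) pracma_cross(u, r)))
  out <- p * cosA + crossu * sinA + outer(dotu * (1 - cosA), u)
  sweep(out, 2, origin, "+")
}
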