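#' Identify physical clusters of AA groups
#'
#' Single-linkage clustering of the AA beads: two AA groups belong to the same
#' physical cluster (micelle core) when their minimum-image distance is below
#' `cutoff`; clusters are the connected components of this graph. Singletons
#' are allowed; the clusters partition the AA groups.
#'
#' @param system a [particle_system()] with at least one AA group.
#' @param cutoff AA-AA linkage distance (nm), > 0. The default 0.65 nm matches
#'   the loop2/unstretched class boundary.
#' @return object of class `physical_clusters`: list with `aa_indices` (global
#'   particle indices), `membership` (cluster label per AA group), `centroids`
#'   (one row per cluster label, periodic-aware), `sizes`, `cutoff`.
#' @export
identify_clusters <- function(system, cutoff = 0.65) {
  if (cutoff <= 0) stop("cutoff must be positive")
  aa <- which(system$species == "AA")
  if (!length(aa)) stop("system contains no AA groups")
  pts <- wrap_positions(system)$positions[aa, , drop = FALSE]
  D <- min_image_dist_matrix(pts, system$box)
  adj <- D <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel deterministically by lowest member index
  first <- tapply(seq_along(comp), comp, min)
  relab <- match(comp, as.integer(names(sort(first))))
  cl <- structure(list(aa_indices = aa, membership = as.integer(relab),
                       centroids = cluster_centroids(pts, relab, system$box),
                       sizes = as.integer(table(relab)), cutoff = cutoff),
                  class = "physical_clusters")
  cl
}

# periodic-aware centroids: unwrap each cluster relative to its first member
cluster_centroids <- function(pts, membership, box) {
  labs <- sort(unique(membership))
  out <- matrix(NA_real_, length(labs), 3)
  for (k in seq_along(labs)) {
    m <- pts[membership == labs[k], , drop = FALSE]
    ref <- m[1, ]
    d <- min_image(sweep(m, 2, ref), box)
    c0 <- ref + colMeans(d)
    out[k, ] <- c0 - floor(c0 / box) * box
  }
  out
}

#' @export
print.physical_clusters <- function(x, ...) {
  cat("physical_clusters:", length(unique(x$membership)), "clusters over",
      length(x$aa_indices), "AA groups (cutoff", x$cutoff, "nm)\n")
  cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Match cluster identities across consecutive frames
#'
#' Relabels the clusters of `current` so that each one inherits the label of
#' the `previous` cluster with which it shares the most AA members (ties are
#' broken by the lowest shared member index; unmatched clusters get fresh
#' labels). Both clusterings must cover the same AA groups.
#'
#' @param previous,current `physical_clusters` from consecutive frames.
#' @return `current` with relabelled `membership`, `centroids` and `sizes`.
#' @export
match_clusters <- function(previous, current) {
  if (!identical(previous$aa_indices, current$aa_indices))
    stop("cluster sets cover different AA groups")
  ncur <- max(current$membership)
  overlap <- matrix(0L, ncur, max(previous$membership))
  for (i in seq_along(current$membership))
    overlap[current$membership[i], previous$membership[i]] <-
      overlap[current$membership[i], previous$membership[i]] + 1L
  new_label <- rep(NA_integer_, ncur)
  taken <- logical(ncol(overlap))
  ord <- order(-apply(overlap, 1, max), seq_len(ncur))
  for (ci in ord) {
    best <- which(overlap[ci, ] == max(overlap[ci, ]) & !taken)
    if (length(best) && max(overlap[ci, ]) > 0) {
      new_label[ci] <- best[1]
      taken[best[1]] <- TRUE
    }
  }
  # unmatched clusters take the lowest labels not claimed by a match
  free <- setdiff(seq_len(ncur + ncol(overlap)), new_label)
  new_label[is.na(new_label)] <- free[seq_len(sum(is.na(new_label)))]
  out <- current
  out$membership <- new_label[current$membership]
  cent <- matrix(NA_real_, max(new_label), 3)
  sizes <- integer(max(new_label))
  for (ci in seq_len(ncur)) {
    cent[new_label[ci], ] <- current$centroids[ci, ]
    sizes[new_label[ci]] <- sum(current$membership == ci)
  }
  out$centroids <- cent
  out$sizes <- sizes
  out
}

#' Delaunay volume fraction of physical clusters
#'
#' Tetrahedralizes the AA positions (augmented with periodic images of points
#' within `edge_threshold` of the box faces), keeps every tetrahedron whose
#' six edges are all `<= edge_threshold` and whose centroid lies in the
#' primary box, and reports the summed tetrahedron volume divided by the box
#' volume. The reciprocal `damage = 1 / fraction` measures the degree of
#' physical-network damage.
#'
#' @param system a [particle_system()] with >= 4 non-coplanar AA groups.
#' @param edge_threshold maximum simplex edge length (nm); defaults to the
#'   cluster cutoff 0.65 nm.
#' @param clusters optional `physical_clusters`; when supplied, only AA groups
#'   in clusters of two or more members enter the triangulation.
#' @return list with `fraction` (in [0, 1]), `damage` (1/fraction; `Inf` when
#'   no simplex passes the filter), `n_kept`, `n_simplices`.
#' @export
cluster_volume_fraction <- function(system, edge_threshold = 0.65,
                                    clusters = NULL) {
  aa <- which(system$species == "AA")
  if (!is.null(clusters)) {
    keep <- clusters$sizes[clusters$membership] >= 2
    aa <- clusters$aa_indices[keep]
  }
  if (length(aa) < 4) stop("need at least 4 AA groups for a tetrahedralization")
  pts <- wrap_positions(system)$positions[aa, , drop = FALSE]
  box <- system$box
  aug <- augment_periodic(pts, box, edge_threshold)
  tets <- tryCatch(delaunay3d(aug),
                   error = function(e) stop("degenerate AA point set: ",
                                            conditionMessage(e)))
  if (nrow(tets) == 0) stop("degenerate AA point set (no tetrahedra)")
  vol <- 0
  kept <- 0L
  thr2 <- edge_threshold^2
  for (r in seq_len(nrow(tets))) {
    v <- aug[tets[r, ], , drop = FALSE]
    ok <- TRUE
    for (a in 1:3) for (b in (a + 1):4) {
      if (sum((v[a, ] - v[b, ])^2) > thr2) { ok <- FALSE; break }
    }
    if (!ok) next
    ctr <- colMeans(v)
    if (any(ctr < 0) || any(ctr >= box)) next
    kept <- kept + 1L
    vol <- vol + abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ],
                               v[4, ] - v[1, ]))) / 6
  }
  fraction <- vol / prod(box)
  list(fraction = fraction,
       damage = if (fraction > 0) 1 / fraction else Inf,
       n_kept = kept, n_simplices = nrow(tets))
}

# replicate points lying within `margin` of a face into the neighbouring images
augment_periodic <- function(pts, box, margin) {
  out <- pts
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    shift <- c(sx, sy, sz) * box
    img <- sweep(pts, 2, shift, "+")
    keep <- img[, 1] > -margin & img[, 1] < box[1] + margin &
            img[, 2] > -margin & img[, 2] < box[2] + margin &
            img[, 3] > -margin & img[, 3] < box[3] + margin
    if (any(keep)) out <- rbind(out, img[keep, , drop = FALSE])
  }
  out
}
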