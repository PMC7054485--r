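#' Classify short flexible chains by end-to-end distance and connectivity
#'
#' The four SFC classes, with half-open boundaries assigned to the lower
#' class: loop1 (re <= 0.42 nm), loop2 (0.42 < re <= 0.65), unstretched
#' (0.65 < re <= 0.85), stretched (re > 0.85). Loops live inside a single
#' physical cluster ("same-cluster"); unstretched and stretched chains bridge
#' two clusters ("two-cluster"). When the supplied connectivity conflicts
#' with the distance class, the class is still assigned by `re` and the case
#' is flagged in the `"inconsistent"` attribute.
#'
#' @param re end-to-end distance(s), nm, >= 0.
#' @param connectivity "same-cluster" or "two-cluster", recycled to the
#'   length of `re`.
#' @param boundaries the three class boundaries (nm).
#' @return factor with levels loop1, loop2, unstretched, stretched and a
#'   logical attribute `"inconsistent"`.
#' @export
classify_sfc <- function(re, connectivity,
                         boundaries = c(0.42, 0.65, 0.85)) {
  if (any(re < 0)) stop("end-to-end distance must be non-negative")
  connectivity <- match.arg(connectivity, c("same-cluster", "two-cluster"),
                            several.ok = TRUE)
  connectivity <- rep_len(connectivity, length(re))
  cls <- cut(re, c(-Inf, boundaries, Inf),
             labels = c("loop1", "loop2", "unstretched", "stretched"),
             right = TRUE)
  is_loop <- cls %in% c("loop1", "loop2")
  inconsistent <- (is_loop & connectivity == "two-cluster") |
                  (!is_loop & connectivity == "same-cluster")
  attr(cls, "inconsistent") <- inconsistent
  cls
}

#' Per-frame SFC records
#'
#' Builds the per-SFC table for one configuration: end-to-end distance of the
#' bounding AA pair (minimum image), cluster connectivity, class and
#' inconsistency flag. Every SFC receives exactly one class.
#'
#' @param system a [particle_system()] whose topology defines SFCs.
#' @param clusters `physical_clusters` for the same frame; computed at the
#'   default cutoff when omitted.
#' @param cutoff cluster cutoff used when `clusters` is NULL.
#' @return data.frame with columns `sfc`, `chain`, `aa_i`, `aa_j`, `re`,
#'   `cluster_i`, `cluster_j`, `connectivity`, `class`, `inconsistent`.
#' @export
sfc_records <- function(system, clusters = NULL, cutoff = 0.65) {
  sfcs <- system$topology$sfcs
  if (!nrow(sfcs)) stop("system topology defines no SFCs")
  if (is.null(clusters)) clusters <- identify_clusters(system, cutoff)
  lab <- function(idx) clusters$membership[match(idx, clusters$aa_indices)]
  d <- min_image(system$positions[sfcs$aa_i, , drop = FALSE] -
                 system$positions[sfcs$aa_j, , drop = FALSE], system$box)
  re <- sqrt(rowSums(d^2))
  ci <- lab(sfcs$aa_i); cj <- lab(sfcs$aa_j)
  conn <- ifelse(ci == cj, "same-cluster", "two-cluster")
  cls <- classify_sfc(re, conn)
  data.frame(sfc = seq_len(nrow(sfcs)), chain = sfcs$chain,
             aa_i = sfcs$aa_i, aa_j = sfcs$aa_j, re = re,
             cluster_i = ci, cluster_j = cj, connectivity = conn,
             class = as.character(cls),
             inconsistent = attr(cls, "inconsistent"))
}

#' Class-transition counts between consecutive frames
#'
#' Counts per-SFC class changes between consecutive analysis frames. The
#' result is a 4 x 4 matrix (rows = class before, columns = class after) with
#' the neighbour-transition fraction (|class step| = 1 among off-diagonal
#' moves) and the number of skip transitions (|class step| >= 2) attached as
#' attributes.
#'
#' @param x either a character/factor matrix of classes (SFCs x frames) or an
#'   `md_trajectory`, in which case [sfc_records()] is evaluated on every
#'   selected frame.
#' @param frames frame indices to analyse when `x` is a trajectory (default
#'   all).
#' @param cutoff cluster cutoff for per-frame cluster identification.
#' @return the 4 x 4 transition count matrix with attributes
#'   `"neighbor_fraction"` and `"n_skip"`.
#' @export
transition_matrix <- function(x, frames = NULL, cutoff = 0.65) {
  lv <- c("loop1", "loop2", "unstretched", "stretched")
  if (inherits(x, "md_trajectory")) {
    if (is.null(frames)) frames <- seq_len(n_frames(x))
    if (length(frames) < 2) stop("need at least 2 frames")
    cls <- vapply(frames, function(i)
      as.character(sfc_records(traj_frame(x, i), cutoff = cutoff)$class),
      character(nrow(x$topology$sfcs)))
  } else {
    cls <- as.matrix(x)
    if (ncol(cls) < 2) stop("need at least 2 frames")
  }
  if (!all(cls %in% lv)) stop("unknown class labels in input")
  m <- matrix(0L, 4, 4, dimnames = list(from = lv, to = lv))
  for (f in seq_len(ncol(cls) - 1)) {
    a <- factor(cls[, f], lv); b <- factor(cls[, f + 1], lv)
    m <- m + table(a, b)
  }
  step <- abs(outer(1:4, 1:4, "-"))
  off <- sum(m[step > 0])
  attr(m, "neighbor_fraction") <- if (off > 0) sum(m[step == 1]) / off else NA_real_
  attr(m, "n_skip") <- sum(m[step >= 2])
  m
}
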