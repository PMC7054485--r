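#' Per-frame structural analysis of a trajectory
#'
#' Runs the full structural battery on every selected frame: physical
#' clusters (identity-matched across frames), Delaunay cluster volume
#' fraction and damage 1/V_PCL, SFC class census, bundle census and the
#' global P2 of all chain segments against the stretch axis (+z).
#'
#' @param traj an `md_trajectory` from a network system.
#' @param cluster_cutoff AA cluster cutoff (nm).
#' @param edge_threshold Delaunay simplex edge threshold (nm).
#' @param align_threshold bundle alignment threshold (degrees).
#' @param frames frame indices (default: every `stride`-th frame).
#' @param stride frame stride when `frames` is NULL.
#' @return data.frame with one row per analysed frame; the per-frame
#'   `bundle_set`s are attached as attribute `"bundles"` and the matched
#'   clusterings as `"clusters"`.
#' @export
analyze_structure <- function(traj, cluster_cutoff = 0.65,
                              edge_threshold = 0.65, align_threshold = 30,
                              frames = NULL, stride = 1) {
  if (is.null(frames)) frames <- seq(1, n_frames(traj), by = stride)
  rows <- vector("list", length(frames))
  bundles <- vector("list", length(frames))
  clusts <- vector("list", length(frames))
  prev <- NULL
  for (k in seq_along(frames)) {
    fr <- traj_frame(traj, frames[k])
    cl <- identify_clusters(fr, cluster_cutoff)
    if (!is.null(prev)) cl <- match_clusters(prev, cl)
    prev <- cl
    clusts[[k]] <- cl
    vf <- tryCatch(cluster_volume_fraction(fr, edge_threshold),
                   error = function(e) list(fraction = NA_real_,
                                            damage = NA_real_))
    sf <- sfc_records(fr, cl)
    bs <- detect_bundles(fr, sf, cl, align_threshold)
    bundles[[k]] <- bs
    p2 <- order_parameter_p2(fr)
    cls <- table(factor(sf$class, c("loop1", "loop2", "unstretched",
                                    "stretched")))
    strain <- fr$box[3] / traj$boxes[1, 3] - 1
    rows[[k]] <- data.frame(
      frame = frames[k], time = traj$times[frames[k]],
      Lz = fr$box[3], strain = strain,
      n_clusters = length(unique(cl$membership)), vpcl = vf$fraction,
      damage = vf$damage,
      loop1 = as.integer(cls["loop1"]), loop2 = as.integer(cls["loop2"]),
      unstretched = as.integer(cls["unstretched"]),
      stretched = as.integer(cls["stretched"]),
      inconsistent = sum(sf$inconsistent),
      n_bundles = length(bs),
      bundle_sfcs = if (length(bs)) length(unique(unlist(
        lapply(bs, `[[`, "members")))) else 0L,
      p2_z = p2$p2)
  }
  out <- do.call(rbind, rows)
  attr(out, "bundles") <- bundles
  attr(out, "clusters") <- clusts
  out
}

#' Fraction of reference bundles surviving at each analysed frame
#'
#' Bundles detected at the reference frame are tracked forward by cluster
#' pair and member overlap ([match_bundles()]); the survival fraction at
#' each frame is the fraction of reference bundles still matched.
#'
#' @param structure result of [analyze_structure()].
#' @param ref index (into the analysed frames) of the reference frame.
#' @return data.frame with `time` and `survival` (NA before `ref`; 1 at
#'   `ref`). When the reference frame has no bundles, survival is NA
#'   throughout.
#' @export
bundle_survival <- function(structure, ref = 1) {
  bundles <- attr(structure, "bundles")
  b0 <- bundles[[ref]]
  n <- nrow(structure)
  surv <- rep(NA_real_, n)
  if (length(b0)) {
    for (k in ref:n)
      surv[k] <- mean(!is.na(match_bundles(b0, bundles[[k]])))
  }
  data.frame(time = structure$time, survival = surv)
}

#' Run a full deformation experiment
#'
#' Executes build -> minimize -> equilibrate -> deform (ramp/hold/optional
#' reverse) -> structural analysis for one or more independent replicates,
#' and aggregates the per-frame analysis tables (mean and sd across
#' replicates). When `cfg$outdir` is set, per-replicate and aggregate tables
#' plus a provenance record (configuration, hash, seeds, package version)
#' are written there as tab-separated text.
#'
#' @param cfg a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return list of class `experiment_report`: `per_seed` (list of per-frame
#'   tables), `aggregate` (mean/sd table), `trajectories`, `config`, `hash`,
#'   `seeds`.
#' @export
run_experiment <- function(cfg) {
  validate_run_config(cfg)
  hash <- config_hash(cfg)
  seeds <- cfg$seed + seq_len(cfg$n_replicates) - 1
  per <- list(); trajs <- list()
  for (s in seeds) {
    sys <- build_network(cfg$system$n_chains, cfg$system$groups_per_chain,
                         cfg$system$box_edge, cfg$system$n_water, seed = s,
                         temperature = cfg$system$temperature,
                         ff = default_forcefield(cutoff = cfg$system$cutoff))
    sys <- minimize_system(sys, cfg$minimize_steps)
    if (cfg$equilibration_ps > 0)
      sys <- equilibrate(sys, cfg$equilibration_ps,
                         temperature = cfg$system$temperature,
                         dt = cfg$protocol$dt,
                         friction = cfg$protocol$friction,
                         seed = s, stride = 10^6)$system
    prot <- deformation_protocol(cfg$protocol$rate, cfg$protocol$target_ratio,
                                 hold = cfg$protocol$hold,
                                 reverse = isTRUE(cfg$protocol$reverse),
                                 temperature = cfg$system$temperature,
                                 dt = cfg$protocol$dt,
                                 friction = cfg$protocol$friction,
                                 stride = cfg$protocol$stride)
    run <- run_protocol(sys, prot, seed = s)
    tab <- analyze_structure(run$trajectory,
                             cluster_cutoff = cfg$analysis$cluster_cutoff,
                             edge_threshold = cfg$analysis$edge_threshold,
                             align_threshold = cfg$analysis$align_threshold,
                             stride = cfg$analysis$analysis_stride)
    per[[as.character(s)]] <- tab
    trajs[[as.character(s)]] <- run$trajectory
  }
  agg <- aggregate_reports(per)
  report <- structure(list(per_seed = per, aggregate = agg,
                           trajectories = trajs, config = cfg, hash = hash,
                           seeds = seeds),
                      class = "experiment_report")
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(per))
      write_analysis_table(per[[s]],
                           file.path(cfg$outdir, paste0("structure_seed", s, ".tsv")),
                           name = paste0("structure seed ", s),
                           config_hash = hash)
    write_analysis_table(agg, file.path(cfg$outdir, "structure_aggregate.tsv"),
                         name = "structure aggregate", config_hash = hash)
    write_run_config(cfg, file.path(cfg$outdir, "config.yaml"))
    writeLines(c(paste("config_hash:", hash),
                 paste("seeds:", paste(seeds, collapse = " ")),
                 paste("fibrilMD:", as.character(utils::packageVersion("fibrilMD")))),
               file.path(cfg$outdir, "provenance.txt"))
  }
  report
}

aggregate_reports <- function(per) {
  nmin <- min(vapply(per, nrow, 1L))
  num <- setdiff(names(per[[1]]), c("frame"))
  rows <- lapply(seq_len(nmin), function(i) {
    vals <- vapply(per, function(tab) as.numeric(tab[i, num]),
                   numeric(length(num)))
    vals <- matrix(vals, nrow = length(num))
    out <- data.frame(frame = per[[1]]$frame[i])
    for (k in seq_along(num)) {
      out[[paste0(num[k], "_mean")]] <- mean(vals[k, ], na.rm = TRUE)
      out[[paste0(num[k], "_sd")]] <- if (ncol(vals) > 1)
        sd(vals[k, ], na.rm = TRUE) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", length(x$seeds), "replicate(s), seeds",
      paste(x$seeds, collapse = " "), "\n")
  cat("  config hash:", x$hash, "\n")
  last <- x$aggregate[nrow(x$aggregate), ]
  cat(sprintf("  final: strain %.2f, damage %.3g, bundles %.2f\n",
              last$strain_mean, last$damage_mean, last$n_bundles_mean))
  invisible(x)
}
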