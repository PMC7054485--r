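#' Run configuration
#'
#' Assembles a validated configuration for [run_experiment()]: system
#' composition, deformation protocol, analysis thresholds, recording strides
#' and seeds. Unspecified fields take the defaults of the chosen scale.
#'
#' `scale = "reduced"` is a desk-scale system (2 chains x 100 groups, 300
#' waters, 3 nm box, 0.5 target ratio) that exercises every pipeline stage in
#' minutes; it is NOT the reference composition. `scale = "full"` is the
#' reference system: 8 chains x 200 groups, 2,447 waters, 5 nm cubic box,
#' 100% stretch.
#'
#' @param scale "reduced" or "full".
#' @param ... named overrides of any nested field, e.g.
#'   `protocol = list(rate = 1)` or `seed = 7`.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(scale = c("reduced", "full"), ...) {
  scale <- match.arg(scale)
  base <- list(
    scale = scale,
    system = list(n_chains = 2, groups_per_chain = 100, box_edge = 3,
                  n_water = 300, temperature = 300, cutoff = 1.0),
    protocol = list(rate = 1, target_ratio = 0.5, hold = 1, reverse = FALSE,
                    dt = 0.005, friction = 1, stride = 2000),
    equilibration_ps = 100,
    minimize_steps = 400,
    analysis = list(cluster_cutoff = 0.65, align_threshold = 30,
                    edge_threshold = 0.65, n_bins = 24,
                    analysis_stride = 1),
    seed = 1,
    n_replicates = 1,
    outdir = NULL)
  if (scale == "full") {
    base$system <- list(n_chains = 8, groups_per_chain = 200, box_edge = 5,
                        n_water = 2447, temperature = 300, cutoff = 1.2)
    base$protocol <- list(rate = 0.1, target_ratio = 1, hold = 10,
                          reverse = FALSE, dt = 0.002, friction = 1,
                          stride = 5000)
    base$equilibration_ps <- 1000
    base$minimize_steps <- 1000
  }
  cfg <- utils::modifyList(base, list(...))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  a <- cfg$analysis
  if (any(c(a$cluster_cutoff, a$align_threshold, a$edge_threshold) <= 0))
    stop("analysis thresholds must be positive")
  if (cfg$protocol$target_ratio > 0 && cfg$protocol$rate <= 0)
    stop("protocol rate must be positive")
  if (cfg$system$n_chains < 1 || cfg$system$groups_per_chain < 10)
    stop("invalid system composition")
  invisible(cfg)
}

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path file path.
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Configuration hash
#'
#' MD5 digest of the canonical YAML serialization, recorded in every output
#' table so a run can be reproduced exactly.
#'
#' @param cfg a `run_config`.
#' @return hex digest string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config (", x$scale, " scale)\n", sep = "")
  cat("  system:", x$system$n_chains, "x", x$system$groups_per_chain,
      "groups +", x$system$n_water, "W in", x$system$box_edge, "nm box\n")
  cat("  protocol: rate", x$protocol$rate, "1/ns to ratio",
      x$protocol$target_ratio, "hold", x$protocol$hold, "ns\n")
  cat("  seed:", x$seed, " replicates:", x$n_replicates, "\n")
  invisible(x)
}
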