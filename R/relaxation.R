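#' Time-autocorrelation function
#'
#' Computes \eqn{f(t) = \langle x(0) \cdot x(t) \rangle}, averaged over all
#' entities and (by default) over sliding time origins. Unit-vector
#' observables (bond vectors, bundle axes) should be normalized with
#' `unit = TRUE`; scalar indicator observables (cluster membership) are
#' handled as one-dimensional vectors. With `normalize = TRUE` the series is
#' scaled so that f(0) = 1 exactly.
#'
#' @param x observable series: a T x d matrix (one entity) or a T x n x d
#'   array (n entities observed over T frames).
#' @param max_lag largest lag in frames (default half the series).
#' @param dt frame interval (ps) used to express lag times.
#' @param normalize scale so that f(0) = 1.
#' @param unit normalize every observation vector to unit length first
#'   (zero-norm vectors are an error).
#' @param origin_stride average over time origins 1, 1+stride, ...; use a
#'   stride of `nrow(x)` for a single-origin estimate.
#' @param label observable label carried into downstream tables.
#' @return object of class `correlation_series`: list with `lag` (ps), `f`,
#'   `dt`, `label`, `n_entities`.
#' @export
autocorrelation <- function(x, max_lag = NULL, dt = 1, normalize = TRUE,
                            unit = FALSE, origin_stride = 1,
                            label = "observable") {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1, ncol(x)))
  if (length(dim(x)) != 3) stop("x must be a T x d matrix or T x n x d array")
  T_ <- dim(x)[1]; n <- dim(x)[2]; d <- dim(x)[3]
  if (T_ < 2) stop("need at least 2 samples")
  if (unit) {
    nrm <- sqrt(apply(x^2, c(1, 2), sum))
    if (any(nrm < 1e-12)) stop("zero-norm vector where a unit vector is required")
    x <- x / array(rep(nrm, d), c(T_, n, d))
  }
  if (is.null(max_lag)) max_lag <- T_ %/% 2
  max_lag <- min(max_lag, T_ - 1)
  f <- numeric(max_lag + 1)
  for (lag in 0:max_lag) {
    origins <- seq(1, T_ - lag, by = origin_stride)
    prod <- x[origins, , , drop = FALSE] * x[origins + lag, , , drop = FALSE]
    f[lag + 1] <- mean(apply(prod, c(1, 2), sum))
  }
  if (normalize) {
    if (abs(f[1]) < 1e-300) stop("cannot normalize: f(0) = 0")
    f <- f / f[1]
  }
  structure(list(lag = (0:max_lag) * dt, f = f, dt = dt, label = label,
                 n_entities = n),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("correlation_series '%s': %d lags (0..%.4g ps), f(0) = %.4g\n",
              x$label, length(x$lag), max(x$lag), x$f[1]))
  invisible(x)
}

#' Fit an exponential decay to a correlation series
#'
#' Least-squares fit of \eqn{A \exp(-t/\tau)} over the lags where f exceeds
#' the noise floor. The fit is flagged unusable when it fails, when the
#' series does not decay, or when the fitted relaxation time exceeds
#' `window_factor` times the observation window (the series then carries no
#' information about its own decay, as for unstable observables).
#'
#' @param corr a `correlation_series`.
#' @param noise_floor smallest usable f value (default 0.05).
#' @param window_factor usability cap: require tau <= window_factor * max lag.
#' @return object of class `relaxation_fit`: list with `tau` (ps),
#'   `amplitude`, `half_time` (tau * ln 2), `residual` (RMS), `usable`,
#'   `reason`, `label`.
#' @export
fit_exponential <- function(corr, noise_floor = 0.05, window_factor = 10) {
  stopifnot(inherits(corr, "correlation_series"))
  keep <- corr$f > noise_floor & corr$lag >= 0
  t <- corr$lag[keep]; f <- corr$f[keep]
  bad <- function(reason) structure(
    list(tau = NA_real_, amplitude = NA_real_, half_time = NA_real_,
         residual = NA_real_, usable = FALSE, reason = reason,
         label = corr$label), class = "relaxation_fit")
  if (length(t) < 5) return(bad("fewer than 5 lags above the noise floor"))
  pos <- f > 0
  ll <- lm(log(f[pos]) ~ t[pos])
  slope <- unname(coef(ll)[2])
  if (!is.finite(slope) || slope >= 0) return(bad("series does not decay"))
  tau0 <- -1 / slope
  A0 <- exp(unname(coef(ll)[1]))
  fit <- tryCatch(
    nls(f ~ A * exp(-t / tau), start = list(A = A0, tau = tau0),
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- tau0; A <- A0
    res <- sqrt(mean((f - A * exp(-t / tau))^2))
  } else {
    cf <- coef(fit)
    tau <- unname(cf["tau"]); A <- unname(cf["A"])
    res <- sqrt(mean(resid(fit)^2))
  }
  if (!is.finite(tau) || tau <= 0) return(bad("non-positive fitted tau"))
  window <- max(corr$lag)
  if (tau > window_factor * window)
    return(bad(sprintf("tau (%.3g ps) exceeds %g x observation window",
                       tau, window_factor)))
  structure(list(tau = tau, amplitude = A, half_time = tau * log(2),
                 residual = res, usable = TRUE, reason = "ok",
                 label = corr$label),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  if (x$usable)
    cat(sprintf("relaxation_fit '%s': tau = %.4g ps (half-time %.4g ps), RMS %.3g\n",
                x$label, x$tau, x$half_time, x$residual))
  else cat(sprintf("relaxation_fit '%s': unusable (%s)\n", x$label, x$reason))
  invisible(x)
}

#' Weissenberg number and deformation regime
#'
#' \eqn{Wi = \dot\gamma \tau}: the ratio of elastic to viscous character of a
#' relaxation process under deformation at rate \eqn{\dot\gamma}. The regime
#' is viscous for Wi below `thresholds[1]`, elastic for Wi above
#' `thresholds[2]` (an order of magnitude above unity, the "Wi >> 1" limit)
#' and viscoelastic between; the nominal viscoelastic band is Wi of order
#' 0.5 to 2.
#'
#' @param rate deformation rate (1/ps), >= 0; vectorized.
#' @param tau relaxation time (ps), > 0; vectorized.
#' @param thresholds length-2: viscous/viscoelastic and
#'   viscoelastic/elastic boundaries (default c(0.5, 10)).
#' @return data.frame with columns `rate`, `tau`, `wi`, `regime` ("v", "ve"
#'   or "e").
#' @export
weissenberg <- function(rate, tau, thresholds = c(0.5, 10)) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(rate < 0)) stop("rate must be non-negative")
  wi <- rate * tau
  regime <- ifelse(wi < thresholds[1], "v",
                   ifelse(wi > thresholds[2], "e", "ve"))
  data.frame(rate = rate, tau = tau, wi = wi, regime = regime)
}

#' Relaxation suite over the standard observation windows
#'
#' Computes the five relaxation observables on their designated windows and
#' assembles the summary table of relaxation times, half-times, Weissenberg
#' numbers and regimes. The windows follow the standard protocol: velocity
#' autocorrelation on the short window (1 ps sampled every 1 fs at full
#' scale), bond and conformation vectors on the intermediate window (100 ps /
#' 0.1 ps), cluster membership and bundle orientation on the long window
#' (100 ns / 0.1 ns); any trajectory with the matching stride can stand in
#' for a window at reduced scale.
#'
#' @param short `md_trajectory` with per-frame velocities (velocity window);
#'   NULL to skip.
#' @param mid `md_trajectory` for bond and conformation vectors; NULL to skip.
#' @param long `md_trajectory` for cluster membership and bundle orientation;
#'   NULL to skip.
#' @param rate deformation rate (1/ps) used for the Weissenberg number.
#' @param cluster_cutoff AA cluster cutoff (nm).
#' @param align_threshold bundle alignment threshold (degrees).
#' @param noise_floor,window_factor passed to [fit_exponential()].
#' @param origin_stride origin-averaging stride for [autocorrelation()].
#' @return data.frame with one row per computed observable: `observable`,
#'   `tau`, `half_time`, `wi`, `regime`, `usable`, `reason`.
#' @export
relaxation_suite <- function(short = NULL, mid = NULL, long = NULL,
                             rate = 0, cluster_cutoff = 0.65,
                             align_threshold = 30, noise_floor = 0.05,
                             window_factor = 10, origin_stride = 1) {
  series <- list()
  if (!is.null(short)) {
    if (is.null(short$velocities))
      stop("velocity window trajectory lacks recorded velocities")
    series$velocity <- autocorrelation(
      frames_to_array(short$velocities, which(!short$restrained)),
      dt = frame_dt(short), origin_stride = origin_stride, label = "velocity")
  }
  if (!is.null(mid)) {
    series$bond <- autocorrelation(
      bond_vector_array(mid), dt = frame_dt(mid), unit = TRUE,
      origin_stride = origin_stride, label = "bond")
    series$conformation <- autocorrelation(
      segment_vector_array(mid), dt = frame_dt(mid), unit = TRUE,
      origin_stride = origin_stride, label = "conformation")
  }
  if (!is.null(long)) {
    series$cluster <- autocorrelation(
      cluster_membership_array(long, cluster_cutoff), dt = frame_dt(long),
      origin_stride = origin_stride, label = "cluster")
    bo <- bundle_orientation_array(long, cluster_cutoff, align_threshold)
    series$bundle <- if (is.null(bo)) NULL else
      autocorrelation(bo, dt = frame_dt(long), unit = TRUE,
                      origin_stride = origin_stride, label = "bundle")
  }
  rows <- lapply(names(series), function(nm) {
    if (is.null(series[[nm]]))
      return(data.frame(observable = nm, tau = NA_real_, half_time = NA_real_,
                        wi = NA_real_, regime = NA_character_, usable = FALSE,
                        reason = "no stable bundles in the window"))
    ft <- fit_exponential(series[[nm]], noise_floor, window_factor)
    wi <- if (ft$usable) weissenberg(rate, ft$tau) else
      data.frame(wi = NA_real_, regime = NA_character_)
    data.frame(observable = nm, tau = ft$tau, half_time = ft$half_time,
               wi = wi$wi[1], regime = wi$regime[1], usable = ft$usable,
               reason = ft$reason)
  })
  out <- do.call(rbind, rows)
  attr(out, "series") <- series
  out
}

frame_dt <- function(traj) {
  if (length(traj$times) < 2) stop("trajectory has fewer than 2 frames")
  diff(traj$times[1:2])
}

frames_to_array <- function(frames, rows) {
  T_ <- length(frames); n <- length(rows)
  arr <- array(NA_real_, c(T_, n, 3))
  for (t in seq_len(T_)) arr[t, , ] <- frames[[t]][rows, , drop = FALSE]
  arr
}

# polymer bond vectors per frame (minimum image)
bond_vector_array <- function(traj) {
  b <- traj$topology$bonds
  if (!nrow(b)) stop("trajectory topology has no bonds")
  T_ <- length(traj$positions)
  arr <- array(NA_real_, c(T_, nrow(b), 3))
  for (t in seq_len(T_)) {
    p <- traj$positions[[t]]
    arr[t, , ] <- min_image(p[b$j, , drop = FALSE] - p[b$i, , drop = FALSE],
                            traj$boxes[t, ])
  }
  arr
}

# next-nearest-neighbour segment vectors per frame
segment_vector_array <- function(traj) {
  chain <- traj$topology$chain
  ids <- sort(unique(chain[!is.na(chain)]))
  pairs <- do.call(rbind, lapply(ids, function(ch) {
    idx <- which(!is.na(chain) & chain == ch)
    cbind(idx[seq_len(length(idx) - 2)], idx[-(1:2)])
  }))
  T_ <- length(traj$positions)
  arr <- array(NA_real_, c(T_, nrow(pairs), 3))
  for (t in seq_len(T_)) {
    p <- traj$positions[[t]]
    arr[t, , ] <- min_image(p[pairs[, 2], , drop = FALSE] -
                            p[pairs[, 1], , drop = FALSE], traj$boxes[t, ])
  }
  arr
}

# indicator of continued presence in the initial physical cluster
cluster_membership_array <- function(traj, cutoff) {
  T_ <- length(traj$positions)
  cl0 <- identify_clusters(traj_frame(traj, 1), cutoff)
  naa <- length(cl0$aa_indices)
  arr <- array(NA_real_, c(T_, naa, 1))
  arr[1, , 1] <- 1
  prev <- cl0
  for (t in 2:T_) {
    cl <- identify_clusters(traj_frame(traj, t), cutoff)
    cl <- match_clusters(prev, cl)
    arr[t, , 1] <- as.numeric(cl$membership == cl0$membership)
    prev <- cl
  }
  arr
}

# unit axis of every t0 bundle tracked through the window; NULL if none
bundle_orientation_array <- function(traj, cutoff, align_threshold) {
  f0 <- traj_frame(traj, 1)
  cl0 <- identify_clusters(f0, cutoff)
  b0 <- detect_bundles(f0, clusters = cl0, align_threshold = align_threshold,
                       cutoff = cutoff)
  if (!length(b0)) return(NULL)
  T_ <- length(traj$positions)
  arr <- array(NA_real_, c(T_, length(b0), 3))
  for (k in seq_along(b0)) arr[1, k, ] <- b0[[k]]$fiber
  prev <- cl0
  for (t in 2:T_) {
    ft <- traj_frame(traj, t)
    cl <- match_clusters(prev, identify_clusters(ft, cutoff))
    bt <- detect_bundles(ft, clusters = cl, align_threshold = align_threshold,
                         cutoff = cutoff)
    m <- if (length(bt)) match_bundles(b0, bt) else rep(NA_integer_, length(b0))
    for (k in seq_along(b0)) {
      arr[t, k, ] <- if (is.na(m[k])) arr[t - 1, k, ] else bt[[m[k]]]$fiber
    }
    prev <- cl
  }
  arr
}
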