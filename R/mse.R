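#' Multiscale-entropy parameters
#'
#' Pattern length `m`, similarity criterion `r_fraction` (tolerance as a
#' fraction of the original series SD) and the number of coarse-graining
#' scales. The defaults (m = 2, r = 0.50, 22 scales) are the conventional
#' settings for single-trial EEG epochs at 500 Hz, where scale tau averages
#' tau consecutive samples (a 2 ms window at scale 1, 44 ms at scale 22).
#'
#' @param m Pattern length (>= 1).
#' @param r_fraction Similarity criterion as a fraction of SD (> 0).
#' @param n_scales Number of timescales (>= 1).
#' @return Object of class `mse_params`.
#' @export
mse_params <- function(m = 2, r_fraction = 0.5, n_scales = 22) {
  stopifnot(m >= 1, r_fraction > 0, n_scales >= 1)
  structure(list(m = as.integer(m), r_fraction = r_fraction,
                 n_scales = as.integer(n_scales)), class = "mse_params")
}

#' Coarse-grain a time series
#'
#' Averages data points within consecutive non-overlapping windows of length
#' `tau`; trailing samples that do not fill a window are discarded, so the
#' output has `floor(length(x) / tau)` points.
#'
#' @param x Numeric vector.
#' @param tau Scale factor (window length in samples, >= 1).
#' @return The coarse-grained series.
#' @export
#' @examples
#' coarse_grain(1:6, 2) # 1.5 3.5 5.5
coarse_grain <- function(x, tau) {
  stopifnot(tau >= 1)
  n <- length(x)
  if (tau > n) stop("scale factor exceeds series length")
  tau <- as.integer(tau)
  if (tau == 1L) return(x)
  nc <- n %/% tau
  colMeans(matrix(x[seq_len(nc * tau)], nrow = tau))
}

#' Sample entropy
#'
#' The negative log conditional probability that two sequences matching for
#' `m` points (Chebyshev distance <= `r`, self-matches excluded) also match
#' at the next point. Pairs are counted over the `length(x) - m` templates
#' that can be extended by one point, so the m- and (m+1)-point counts range
#' over the same template set. Returns `NA` when either count is zero (no
#' evidence either way), with the counts attached as attributes.
#'
#' @param x Numeric vector (length > m + 1), finite.
#' @param m Pattern length.
#' @param r Absolute tolerance (same units as `x`, > 0).
#' @return Entropy in nats (`NA` if undefined), with attributes `A` and `B`
#'   (the matched (m+1)- and m-template pair counts).
#' @export
#' @examples
#' sample_entropy(sin(seq(0, 20 * pi, length.out = 300)), m = 2, r = 0.1)
sample_entropy <- function(x, m = 2, r) {
  stopifnot(r > 0, length(x) > m + 1)
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  e <- if (ab[1] > 0 && ab[2] > 0) -log(ab[1] / ab[2]) else NA_real_
  structure(e, A = ab[1], B = ab[2])
}

#' Multiscale entropy of a single trial
#'
#' Sample entropy of the series coarse-grained at scales 1..`n_scales`. The
#' tolerance is fixed once per trial as `r_fraction` times the SD of the
#' original (scale-1) series and is not recomputed at coarser scales, so
#' entropy typically decreases with scale for uncorrelated noise (the
#' coarse-grained variance shrinks under a fixed r) but not for long-range
#' correlated signals.
#'
#' @param x Numeric vector: one trial, one channel, full epoch.
#' @param params An [mse_params()].
#' @return Numeric vector of per-scale entropies (nats); `NA` where
#'   undefined. A zero-SD series yields all-`NA` with a warning.
#' @export
mse_trial <- function(x, params = mse_params()) {
  stopifnot(inherits(params, "mse_params"))
  if (any(!is.finite(x))) stop("non-finite values in input series")
  n <- length(x)
  if (n %/% params$n_scales < params$m + 2)
    warning("coarse-grained length at the maximum scale is below m + 2; ",
            "coarse-scale entropies may be undefined")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance series: entropy undefined at all scales")
    return(rep(NA_real_, params$n_scales))
  }
  mse_trial_cpp(as.numeric(x), params$m, params$r_fraction * s,
                params$n_scales)
}

#' Single-trial multiscale entropy for a whole epoch set
#'
#' Computes [mse_trial()] for every trial and channel. The per-series
#' tolerance is `r_fraction` x SD of that trial-channel series.
#'
#' @param epochs An [epoch_set()].
#' @param params An [mse_params()].
#' @param window `"full"` uses the whole epoch; `"post"` restricts to
#'   samples at t >= 0 ms.
#' @return Numeric array trials x channels x scales (`NA` where undefined).
#' @export
mse_trials <- function(epochs, params = mse_params(),
                       window = c("full", "post")) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(params, "mse_params"))
  window <- match.arg(window)
  dat <- epochs$data
  if (window == "post") dat <- dat[, , epochs$times >= 0, drop = FALSE]
  d <- dim(dat)
  if (d[1] < 1) stop("empty trial set")
  mse_epochs_cpp(dat, as.integer(d), params$m, params$r_fraction,
                 params$n_scales)
}

#' Condition-level multiscale-entropy matrix
#'
#' Averages single-trial entropies over trials per channel x scale cell,
#' ignoring trials whose entropy is undefined at that cell; the number of
#' contributing trials is recorded per cell, and a cell with no defined
#' trial is `NA`.
#'
#' @param epochs An [epoch_set()], or a precomputed trials x channels x
#'   scales array from [mse_trials()] (pass `channels` and `sampling_rate`
#'   via `epochs` only in the former case).
#' @param params An [mse_params()].
#' @param window Passed to [mse_trials()].
#' @param condition Label stored with the result.
#' @return Object of class `mse_matrix` with fields `entropy`
#'   (channels x scales), `n_valid_trials` (channels x scales),
#'   `scale_window_ms` and `condition`.
#' @export
mse_condition <- function(epochs, params = mse_params(),
                          window = c("full", "post"), condition = "all") {
  stopifnot(inherits(epochs, "epoch_set"))
  tri <- mse_trials(epochs, params, window)
  mse_average(tri, channels = epochs$channels,
              sampling_rate = epochs$sampling_rate, condition = condition)
}

#' Average a single-trial entropy array into an `mse_matrix`
#'
#' @param trial_entropy Trials x channels x scales array (from [mse_trials()]).
#' @param channels Channel labels.
#' @param sampling_rate Hz, used for the per-scale window length in ms.
#' @param condition Label stored with the result.
#' @param trials Optional trial subset to average over.
#' @return An `mse_matrix` (see [mse_condition()]).
#' @export
mse_average <- function(trial_entropy, channels, sampling_rate,
                        condition = "all", trials = NULL) {
  d <- dim(trial_entropy)
  stopifnot(length(d) == 3, d[2] == length(channels))
  if (!is.null(trials))
    trial_entropy <- trial_entropy[trials, , , drop = FALSE]
  if (dim(trial_entropy)[1] < 1) stop("empty condition: no trials to average")
  ent <- apply(trial_entropy, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  nv <- apply(trial_entropy, c(2, 3), function(v) sum(!is.na(v)))
  dimnames(ent) <- dimnames(nv) <- list(channels, NULL)
  structure(list(entropy = ent, n_valid_trials = nv,
                 scale_window_ms = seq_len(d[3]) * 1000 / sampling_rate,
                 channels = channels, condition = condition),
            class = "mse_matrix")
}

#' @export
print.mse_matrix <- function(x, ...) {
  cat("MSE matrix (", x$condition, "): ", nrow(x$entropy), " channels x ",
      ncol(x$entropy), " scales (", x$scale_window_ms[1], "-",
      x$scale_window_ms[length(x$scale_window_ms)], " ms windows)\n", sep = "")
  invisible(x)
}

#' Export an `mse_matrix` as a long-format data frame
#'
#' @param x An `mse_matrix`.
#' @param participant Optional participant id column value.
#' @return Data frame with columns participant, condition, channel, scale,
#'   window_ms, entropy, n_valid_trials.
#' @export
mse_long <- function(x, participant = NA) {
  stopifnot(inherits(x, "mse_matrix"))
  ns <- ncol(x$entropy)
  data.frame(participant = participant, condition = x$condition,
             channel = rep(x$channels, ns),
             scale = rep(seq_len(ns), each = nrow(x$entropy)),
             window_ms = rep(x$scale_window_ms, each = nrow(x$entropy)),
             entropy = as.vector(x$entropy),
             n_valid_trials = as.vector(x$n_valid_trials),
             stringsAsFactors = FALSE)
}
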