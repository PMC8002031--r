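#' Exclude response-time outliers
#'
#' Removes trials whose RT lies more than `sd_crit` standard deviations from
#' the mean of their condition cell. Group statistics (mean, SD) are computed
#' once on all trials of the group, in a single pass, before any removal:
#' the rule is deliberately not iterated, so re-running it on its own output
#' would use different statistics.
#'
#' @param trials Data frame of trial rows with an `rt_ms` column.
#' @param group_vars Columns defining the condition cell within which mean
#'   and SD are computed (default participant x session x lexicality).
#' @param sd_crit Exclusion criterion in SD units.
#' @return List with `retained` (the surviving rows, original order) and
#'   `report` (per-group n, n_excluded, mean, sd). Groups with fewer than
#'   two trials have undefined SD; they are retained whole, with a warning.
#' @export
exclude_rt_outliers <- function(trials,
                                group_vars = c("participant", "session", "lexicality"),
                                sd_crit = 2.5) {
  stopifnot(is.data.frame(trials), "rt_ms" %in% names(trials),
            all(group_vars %in% names(trials)))
  if (any(!is.finite(trials$rt_ms) | trials$rt_ms <= 0))
    stop("rt_ms must be finite and positive")
  key <- interaction(trials[group_vars], drop = TRUE, lex.order = TRUE)
  gm <- tapply(trials$rt_ms, key, mean)
  gs <- tapply(trials$rt_ms, key, stats::sd)
  if (anyNA(gs))
    warning("group(s) with < 2 trials: SD undefined, all their trials retained")
  m <- gm[as.character(key)]
  s <- gs[as.character(key)]
  out <- !is.na(s) & abs(trials$rt_ms - m) > sd_crit * s
  counts <- table(key)
  report <- data.frame(group = names(counts), n = as.integer(counts),
                       n_excluded = as.integer(tapply(out, key, sum)),
                       mean_rt = as.numeric(gm), sd_rt = as.numeric(gs),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = trials[!out, , drop = FALSE], report = report)
}

#' Exclude incorrect-response trials
#'
#' Keeps rows with `correct == 1`. In the analysis chain this is applied
#' after RT-outlier exclusion.
#'
#' @param trials Data frame with a `correct` column (0/1).
#' @return The correct-trial rows.
#' @export
exclude_incorrect <- function(trials) {
  stopifnot(is.data.frame(trials), "correct" %in% names(trials))
  trials[trials$correct == 1, , drop = FALSE]
}

#' Partition trials into chronological segments
#'
#' Divides `n_trials` retained trials, in presentation order, into `k`
#' consecutive segments of near-equal size: each segment gets
#' `floor(n_trials / k)` trials, and the remainder is distributed one trial
#' at a time to the earliest segments. With 950 trials and k = 10, every
#' segment has 95 trials and Segment 1 holds trials 1-95.
#'
#' @param n_trials Number of retained trials (must be >= k).
#' @param k Number of segments.
#' @return Integer vector of length `n_trials`: the segment index (1..k) of
#'   each trial, with attribute `sizes` (per-segment counts).
#' @export
#' @examples
#' table(partition_segments(1003))
partition_segments <- function(n_trials, k = 10) {
  stopifnot(length(n_trials) == 1, length(k) == 1, k >= 1)
  if (n_trials < k)
    stop("cannot partition ", n_trials, " trials into ", k, " segments")
  n_trials <- as.integer(n_trials)
  k <- as.integer(k)
  base <- n_trials %/% k
  extra <- n_trials %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  structure(rep(seq_len(k), times = sizes), sizes = sizes)
}

#' Average epochs into an event-related potential
#'
#' Per-trial, per-channel baseline correction (subtracting the mean over the
#' baseline interval, half-open `[baseline[1], baseline[2])` ms so t = 0
#' belongs to the post-stimulus period), followed by the arithmetic mean
#' over trials.
#'
#' @param epochs An [epoch_set()] with at least one trial.
#' @param baseline Length-2 ms interval for baseline correction; must lie
#'   within the epoch.
#' @param condition Label stored with the result.
#' @return Object of class `erp_waveform`: channels x samples mean voltage
#'   matrix plus `n_trials` and `condition`.
#' @export
average_erp <- function(epochs, baseline = c(-200, 0), condition = "all") {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[1]
  if (n_tr < 1) stop("cannot average an empty trial set")
  bl <- epochs$times >= baseline[1] & epochs$times < baseline[2]
  if (!any(bl)) stop("baseline interval contains no samples")
  dat <- epochs$data
  blmean <- apply(dat[, , bl, drop = FALSE], c(1, 2), mean)
  dat <- sweep(dat, c(1, 2), blmean)
  m <- apply(dat, c(2, 3), mean)
  dimnames(m) <- list(epochs$channels, NULL)
  structure(list(mean = m, times = epochs$times, channels = epochs$channels,
                 n_trials = n_tr, condition = condition,
                 baseline = baseline),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat("ERP waveform (", x$condition, "): ", nrow(x$mean), " channels x ",
      ncol(x$mean), " samples, average of ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}
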