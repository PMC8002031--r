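#' Epoched EEG container
#'
#' Holds one participant-condition's trials as a trials x channels x samples
#' voltage array (microvolts) together with the time axis (ms relative to
#' stimulus onset), channel labels and per-trial metadata.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param times_ms Strictly increasing, uniformly spaced time axis in ms;
#'   length must equal the sample dimension.
#' @param channels Channel labels; length must equal the channel dimension.
#' @param trial_meta Data frame with one row per trial (typically rt_ms,
#'   correct, lexicality, session, trial).
#' @param sampling_rate Sampling rate in Hz; must match the time-axis spacing.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, channels, trial_meta, sampling_rate) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times_ms) != dim(data)[3])
    stop("times_ms length must equal the sample dimension")
  if (length(channels) != dim(data)[2])
    stop("channels length must equal the channel dimension")
  if (!is.data.frame(trial_meta) || nrow(trial_meta) != dim(data)[1])
    stop("trial_meta must have one row per trial")
  dt <- diff(times_ms)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)
    stop("times_ms must be strictly increasing with uniform spacing")
  if (abs(dt[1] - 1000 / sampling_rate) > 1e-6)
    stop("time-axis spacing must equal 1000 / sampling_rate ms")
  structure(list(data = data, times = as.numeric(times_ms),
                 channels = as.character(channels),
                 trial_meta = trial_meta,
                 sampling_rate = sampling_rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoched EEG:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat(sprintf("  time %g..%g ms @ %g Hz\n", min(x$times), max(x$times),
              x$sampling_rate))
  invisible(x)
}

#' Subset an epoch set by trial
#'
#' @param x An [epoch_set()].
#' @param trials Integer or logical index into the trial dimension.
#' @return A new `epoch_set` with the selected trials (metadata subset too).
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[trials, , , drop = FALSE], x$times, x$channels,
            x$trial_meta[trials, , drop = FALSE], x$sampling_rate)
}

#' Write an epoch set to a plain-text directory container
#'
#' The container is a directory holding `meta.json` (time axis, channels,
#' sampling rate, dimensions), `trials.csv` (trial metadata) and `data.csv`
#' (the voltage array flattened to one row per trial-channel pair).
#'
#' @param x An [epoch_set()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  jsonlite::write_json(
    list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
         times_ms = x$times, channels = x$channels,
         sampling_rate = x$sampling_rate),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(x$trial_meta, file.path(path, "trials.csv"),
                   row.names = FALSE)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  utils::write.table(flat, file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Container directory.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  tm <- utils::read.csv(file.path(path, "trials.csv"))
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"), sep = ","))
  dimnames(flat) <- NULL
  dat <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                      meta$n_trials)), c(3, 2, 1))
  epoch_set(dat, meta$times_ms, meta$channels, tm, meta$sampling_rate)
}
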