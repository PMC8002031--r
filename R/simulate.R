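#' Specify a simulated ERP component
#'
#' A component is a Gaussian-windowed half-cycle sinusoid added to a set of
#' channels, peaking at `peak_latency` with total support `width`, with one
#' amplitude per session so that practice-related amplitude change can be
#' planted.
#'
#' @param name Component label (e.g. "N170", "P200", "N400", "LPC").
#' @param channels Channel labels the component loads on; must be a subset
#'   of the montage in use.
#' @param peak_latency Peak time in ms after stimulus onset.
#' @param width Total support of the component in ms (the Gaussian window
#'   has SD `width / 4`).
#' @param amplitude_by_session Numeric vector, one peak amplitude in microvolts
#'   per session. Negative values give negative-going components.
#' @param polarity Optional sign (+1/-1) multiplied into the amplitudes;
#'   kept separate so that a named negativity can carry positive magnitudes.
#' @return An object of class `erp_component`.
#' @export
erp_component <- function(name, channels, peak_latency, width,
                          amplitude_by_session, polarity = 1) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(channels), length(channels) >= 1,
            is.numeric(peak_latency), length(peak_latency) == 1,
            is.numeric(width), width > 0,
            is.numeric(amplitude_by_session),
            polarity %in% c(-1, 1))
  structure(list(name = name, channels = channels,
                 peak_latency = peak_latency, width = width,
                 amplitude_by_session = polarity * amplitude_by_session),
            class = "erp_component")
}

#' Default planted ERP components
#'
#' Four components whose session-to-session amplitude changes emulate the
#' qualitative pattern reported for prolonged lexical-decision performance:
#' relative to Session 1, in Sessions 2-3 the N170 becomes more negative,
#' the P200 and N400 more positive, and the LPC less positive. The absolute
#' microvolt values are free parameters of the simulation, chosen as
#' conventional ERP magnitudes.
#'
#' @param n_sessions Number of sessions (amplitude vectors are recycled or
#'   truncated to this length, first session kept distinct).
#' @return List of [erp_component()] objects.
#' @export
default_components <- function(n_sessions = 3) {
  grp <- channel_groups()
  later <- function(s1, rest) c(s1, rep(rest, n_sessions - 1))
  list(
    erp_component("N170", intersect(grp$occipito_parietal,
                                    c("P7", "P8", "PO7", "PO8", "PO3", "PO4", "O1", "O2")),
                  peak_latency = 185, width = 90,
                  amplitude_by_session = later(-2, -6)),
    erp_component("P200", c(grp$frontal[grp$frontal %in% c("F3", "Fz", "F4", "F1", "F2")],
                            grp$fronto_central),
                  peak_latency = 200, width = 100,
                  amplitude_by_session = later(2, 5)),
    erp_component("N400", c("F3", "Fz", "F4", "FC1", "FCz", "FC2"),
                  peak_latency = 385, width = 160,
                  amplitude_by_session = later(-4, -1)),
    erp_component("LPC", c("CP1", "CPz", "CP2", "P3", "Pz", "P4"),
                  peak_latency = 750, width = 500,
                  amplitude_by_session = later(5, 2))
  )
}

#' Shifted-lognormal response-time and accuracy model
#'
#' Trial RTs are drawn from a shifted lognormal: `rt = shift + exp(mu + sigma Z)`.
#' Participant-level heterogeneity enters through the per-cell mean:
#' participant p's latent mean in cell (session, lexicality) is
#' `mean_ms + sd_ms * z`, where the standard-normal deviate `z` is correlated
#' `cor_cells` across cells within a participant (session-to-session RT is
#' highly reliable in practice, so the default correlation is high). The
#' defaults emulate the session-wise RT means/SDs and accuracies typical of
#' a three-session prolonged lexical-decision study, with RT decreasing over
#' sessions for both words and nonwords.
#'
#' @param mean_ms 3 x 2 matrix (sessions x lexicality word/nonword) of target
#'   between-participant mean RTs in ms.
#' @param sd_ms Matching matrix of between-participant SDs of participant
#'   mean RTs in ms.
#' @param accuracy Matching matrix of response-accuracy probabilities.
#' @param shift_ms Lognormal shift (non-decision floor), ms.
#' @param sigma_trial Trial-level lognormal shape parameter.
#' @param cor_cells Correlation of a participant's latent means across cells.
#' @return Object of class `rt_model`.
#' @export
rt_model <- function(mean_ms = matrix(c(811.16, 763.96, 727.24,
                                        924.97, 824.87, 778.75), 3, 2),
                     sd_ms = matrix(c(123.41, 120.24, 103.49,
                                      185.92, 136.99, 115.08), 3, 2),
                     accuracy = matrix(c(0.87, 0.86, 0.86,
                                        0.92, 0.94, 0.93), 3, 2),
                     shift_ms = 200, sigma_trial = 0.35, cor_cells = 0.8) {
  dm <- list(paste0("session", seq_len(nrow(mean_ms))), c("word", "nonword"))
  if (!all(is.finite(mean_ms), is.finite(sd_ms), is.finite(accuracy),
           is.finite(shift_ms), is.finite(sigma_trial), is.finite(cor_cells)))
    stop("rt_model parameters must be finite")
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy probabilities must lie in [0, 1]")
  if (any(mean_ms <= shift_ms)) stop("mean RTs must exceed the lognormal shift")
  if (any(sd_ms < 0) || sigma_trial < 0) stop("scale parameters must be non-negative")
  dimnames(mean_ms) <- dimnames(sd_ms) <- dimnames(accuracy) <- dm
  structure(list(mean_ms = mean_ms, sd_ms = sd_ms, accuracy = accuracy,
                 shift_ms = shift_ms, sigma_trial = sigma_trial,
                 cor_cells = cor_cells),
            class = "rt_model")
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: epoched
#' 64-channel EEG at 500 Hz, epochs -200..+1000 ms around stimulus onset,
#' three sessions, 1/f-like background noise whose spectral exponent can
#' differ by session (more negative-sloped noise is more regular and lowers
#' fine-scale sample entropy), planted ERP components, and a shifted-lognormal
#' RT/accuracy model.
#'
#' @param n_participants Number of participants.
#' @param n_sessions Number of EEG sessions.
#' @param trials_per_session Trials simulated per session (before exclusions).
#' @param channels Channel labels (defaults to the 64-channel montage).
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_window Length-2 ms window relative to stimulus onset.
#' @param noise_slope Spectral exponent of the 1/f^slope background noise,
#'   one value per session. Sessions 2-3 default to a steeper slope than
#'   Session 1, planting the fine-scale entropy decrease.
#' @param noise_sd Background-noise SD in microvolts.
#' @param components List of [erp_component()] objects; `list()` for none.
#' @param rt RT/accuracy model from [rt_model()].
#' @param seed Master integer seed; all per-participant streams derive from it.
#' @return Object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, trials_per_session = 20, seed = 1)
#' ep <- generate_epochs(cfg, participant = 1, session = 1)
#' dim(ep$data)
sim_config <- function(n_participants = 20, n_sessions = 3,
                       trials_per_session = 1000,
                       channels = eeg_montage(), sampling_rate = 500,
                       epoch_window = c(-200, 1000),
                       noise_slope = c(1.0, 1.3, 1.3), noise_sd = 10,
                       components = default_components(n_sessions),
                       rt = rt_model(), seed = 1L) {
  stopifnot(n_participants >= 1, n_sessions >= 1, trials_per_session >= 1,
            sampling_rate > 0, length(epoch_window) == 2,
            epoch_window[1] < epoch_window[2], noise_sd >= 0)
  if (length(noise_slope) == 1) noise_slope <- rep(noise_slope, n_sessions)
  if (length(noise_slope) != n_sessions)
    stop("noise_slope must have one value per session")
  n_samples <- round(diff(epoch_window) / 1000 * sampling_rate)
  times <- epoch_window[1] + (seq_len(n_samples) - 1) * 1000 / sampling_rate
  for (cm in components) {
    if (!inherits(cm, "erp_component")) stop("components must be erp_component objects")
    bad <- setdiff(cm$channels, channels)
    if (length(bad))
      stop("component '", cm$name, "' uses unknown channel label(s): ",
           paste(bad, collapse = ", "))
    if (cm$peak_latency < 0 || cm$peak_latency > epoch_window[2])
      stop("component '", cm$name,
           "' peak latency lies outside the post-stimulus epoch window")
    if (length(cm$amplitude_by_session) == 1)
      cm$amplitude_by_session <- rep(cm$amplitude_by_session, n_sessions)
    if (length(cm$amplitude_by_session) != n_sessions)
      stop("component '", cm$name, "': need one amplitude per session")
  }
  if (nrow(rt$mean_ms) < n_sessions)
    stop("rt model must cover every session")
  structure(list(n_participants = n_participants, n_sessions = n_sessions,
                 trials_per_session = trials_per_session, channels = channels,
                 sampling_rate = sampling_rate, epoch_window = epoch_window,
                 times = times, n_samples = n_samples,
                 noise_slope = noise_slope, noise_sd = noise_sd,
                 components = components, rt = rt, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic substream seed for (participant, session, purpose), kept
# below 2^31 so it is a valid R integer seed. Purposes: 1 = behaviour,
# 2 = noise. Independent of call order, so any cell can be regenerated alone.
stream_seed <- function(master, participant, session, purpose) {
  h <- (as.double(master) %% 2147483647)
  for (k in c(participant, session, purpose)) {
    h <- (h * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# One trial-block of 1/f^slope noise via frequency-domain synthesis:
# deterministic amplitude spectrum |X(f)| proportional to f^(-slope/2),
# uniform random phases, Hermitian symmetry, inverse FFT. Returned columns
# are independent channels, each standardized to unit SD.
pink_noise <- function(n_samples, n_series, slope) {
  n <- n_samples
  half <- floor(n / 2)
  freq <- seq_len(half)
  amp <- freq^(-slope / 2)
  out <- matrix(0, n, n_series)
  for (j in seq_len(n_series)) {
    phase <- stats::runif(half, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    full <- complex(real = numeric(n))
    full[2:(half + 1)] <- spec
    if (n %% 2 == 0) full[half + 1] <- complex(real = amp[half]) # Nyquist real
    if (half > 1) full[n:(n - half + 2)] <- Conj(full[2:half])
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    out[, j] <- x / stats::sd(x)
  }
  out
}

# Component waveform on the epoch time axis: Gaussian-windowed half-cycle
# sinusoid with compact support [peak - width/2, peak + width/2], peak
# amplitude `amp` at `peak_latency`.
component_waveform <- function(times, peak_latency, width, amp) {
  u <- times - peak_latency
  inside <- abs(u) <= width / 2
  w <- numeric(length(times))
  w[inside] <- amp * exp(-0.5 * (u[inside] / (width / 4))^2) *
    cos(pi * u[inside] / width)
  w
}

# Trial-level behaviour for one participant x session cell, drawn from its
# dedicated substream so epochs and behaviour logs always agree.
simulate_cell_behaviour <- function(config, participant, session) {
  rt <- config$rt
  n <- config$trials_per_session
  # participant-level deviate shared across cells comes from its own
  # substream (session slot 0) so cells stay independently regenerable
  zp <- with_seed(stream_seed(config$seed, participant, 0L, 1L), stats::rnorm(1))
  with_seed(stream_seed(config$seed, participant, session, 1L), {
    lex <- sample(rep(c("word", "nonword"), length.out = n))
    rho <- rt$cor_cells
    rts <- numeric(n)
    correct <- integer(n)
    for (lx in c("word", "nonword")) {
      idx <- which(lex == lx)
      zc <- rho * zp + sqrt(1 - rho^2) * stats::rnorm(1)
      m <- rt$mean_ms[session, lx] + rt$sd_ms[session, lx] * zc
      m <- max(m, rt$shift_ms + 50)
      mu <- log(m - rt$shift_ms) - rt$sigma_trial^2 / 2
      rts[idx] <- rt$shift_ms +
        exp(stats::rnorm(length(idx), mu, rt$sigma_trial))
      correct[idx] <- stats::rbinom(length(idx), 1, rt$accuracy[session, lx])
    }
    blocks <- ceiling(seq_len(n) / max(1, ceiling(n / 3)))
    data.frame(participant = as.integer(participant),
               session = as.integer(session),
               block = blocks, trial = seq_len(n), lexicality = lex,
               rt_ms = rts, correct = correct, stringsAsFactors = FALSE)
  })
}

#' Generate behavioural trial logs
#'
#' Draws per-trial response time and accuracy rows for every participant and
#' session of the configuration (or a subset), using the same deterministic
#' per-cell random streams as [generate_epochs()], so that epochs and
#' behaviour always describe the same trials.
#'
#' @param config A [sim_config()].
#' @param participants Participants to generate (default all).
#' @param sessions Sessions to generate (default all).
#' @return Data frame with columns participant, session, block, trial,
#'   lexicality, rt_ms, correct.
#' @export
generate_behaviour <- function(config, participants = seq_len(config$n_participants),
                               sessions = seq_len(config$n_sessions)) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (p in participants)
    for (s in sessions)
      rows[[length(rows) + 1L]] <- simulate_cell_behaviour(config, p, s)
  do.call(rbind, rows)
}

#' Generate one participant-session block of epoched EEG
#'
#' Each trial epoch is the sum of per-channel 1/f^slope background noise
#' (frequency-domain synthesis with random phases; the slope is the
#' session's `noise_slope`) and the configured ERP component waveforms at
#' their session amplitudes on their channel sets. The per-trial behaviour
#' rows (RT, accuracy, lexicality) are attached as trial metadata. Output
#' is deterministic in (seed, participant, session) and independent of which
#' other cells have been generated.
#'
#' @param config A [sim_config()].
#' @param participant Participant index.
#' @param session Session index.
#' @return An [epoch_set()] of dimension trials x channels x samples (microvolts).
#' @export
generate_epochs <- function(config, participant, session) {
  stopifnot(inherits(config, "sim_config"),
            participant >= 1, participant <= config$n_participants,
            session >= 1, session <= config$n_sessions)
  meta <- simulate_cell_behaviour(config, participant, session)
  n_tr <- config$trials_per_session
  n_ch <- length(config$channels)
  n_sm <- config$n_samples
  dat <- with_seed(stream_seed(config$seed, participant, session, 2L), {
    a <- array(0, dim = c(n_tr, n_ch, n_sm))
    for (tr in seq_len(n_tr)) {
      nz <- pink_noise(n_sm, n_ch, config$noise_slope[session]) * config$noise_sd
      a[tr, , ] <- t(nz)
    }
    a
  })
  for (cm in config$components) {
    amp <- cm$amplitude_by_session
    if (length(amp) == 1) amp <- rep(amp, config$n_sessions)
    w <- component_waveform(config$times, cm$peak_latency, cm$width,
                            amp[session])
    ch_idx <- match(cm$channels, config$channels)
    wmat <- matrix(w, nrow = n_tr, ncol = n_sm, byrow = TRUE)
    for (ci in ch_idx)
      dat[, ci, ] <- dat[, ci, ] + wmat
  }
  epoch_set(dat, times_ms = config$times, channels = config$channels,
            trial_meta = meta, sampling_rate = config$sampling_rate)
}
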