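# Brute-force pair-counting oracle for sample entropy, written directly
# from the definition (all ordered template pairs i < j, Chebyshev
# distance, templates restricted to those extensible by one point).
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# Tiny simulation config: few channels, short sessions, no planted effects
# unless overridden.
tiny_config <- function(n_participants = 3, trials = 20, seed = 1,
                        channels = eeg_montage()[1:8], components = list(),
                        noise_slope = c(1, 1, 1), ...) {
  sim_config(n_participants = n_participants, trials_per_session = trials,
             channels = channels, components = components,
             noise_slope = noise_slope, seed = seed, ...)
}

# PLS input with iid-noise features and no condition effect: 3 conditions
# per subject, exchangeable by construction.
null_pls_input <- function(n_subjects = 20, n_features = 30) {
  x <- matrix(rnorm(3 * n_subjects * n_features), 3 * n_subjects, n_features)
  list(x = x, conditions = rep(c("c1", "c2", "c3"), each = n_subjects),
       subjects = rep(seq_len(n_subjects), 3))
}

# Fitted log-log spectral slope of a set of series (rows = series).
fit_spectral_slope <- function(series_mat) {
  n <- ncol(series_mat)
  half <- floor(n / 2)
  pw <- rowMeans(apply(series_mat, 1, function(x) {
    Mod(stats::fft(x))[2:(half + 1)]^2
  }))
  f <- seq_len(half)
  keep <- f <= half
  -unname(stats::coef(stats::lm(log(pw[keep]) ~ log(f[keep])))[2])
}
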