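---
title: "Tracking neural change over prolonged task performance: ERPs, multiscale entropy and task PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking neural change over prolonged task performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msepls)
```

## The analysis problem

When a participant performs many thousands of lexical-decision trials over
several EEG sessions, both behaviour and brain signals change: response
times shorten, stimulus-locked potentials shift, and the moment-to-moment
irregularity of the ongoing signal is reorganised. `msepls` implements the
complete analysis chain for studying such change from epoched multichannel
EEG (64 channels, 500 Hz, epochs from −200 to +1000 ms around stimulus
onset) together with trial-level behaviour:

1. **Trial exclusion and condition assembly** — response-time outliers
   beyond ±2.5 SD of each participant × session × lexicality cell are
   removed first (statistics computed once, on all trials of the cell),
   then incorrect responses; the retained correct trials are either pooled
   per session (across-session analysis) or split into 10 chronological
   segments of near-equal size (within-session analysis).
2. **ERP averaging** — per-trial baseline correction over the 200 ms
   pre-stimulus interval, then the arithmetic mean across trials per
   channel.
3. **Multiscale entropy (MSE)** — sample entropy of each single trial at 22
   coarse-graining scales, averaged over trials per condition.
4. **Task partial least squares (PLS)** — a singular value decomposition of
   the mean-centered condition × feature matrix, with permutation tests for
   latent-variable significance and bootstrap ratios for feature stability.
5. **Behavioural inference** — 2 (lexicality) × 3 (session)
   repeated-measures ANOVAs with Mauchly tests, Greenhouse–Geisser
   correction and generalized eta-squared, plus Bonferroni-corrected paired
   follow-ups with Cohen's $d_z$.

Because the artifact must be testable without any data download, the
package ships a synthetic-data generator whose defaults plant exactly the
statistical structure the analyses are designed to detect.

## Sample entropy and multiscale entropy

Sample entropy of a series $x_1,\dots,x_N$ with pattern length $m$ and
tolerance $r$ is

$$\mathrm{SampEn}(m, r) = -\ln\frac{A}{B},$$

where $B$ counts the ordered pairs of distinct $m$-point templates whose
Chebyshev distance is at most $r$, and $A$ counts the pairs that still
match when extended by one point. Templates are restricted to the $N - m$
starting positions that admit the extension, so $A$ and $B$ range over the
same template set, and self-matches are excluded. Both counts are computed
exactly in compiled code; the unit is nats.

For MSE, the series is first coarse-grained: scale $\tau$ replaces each
non-overlapping window of $\tau$ samples by its mean (trailing remainder
discarded, so a 600-sample epoch has $\lfloor 600/22\rfloor = 27$ points at
the coarsest default scale). At 500 Hz, scale 1 corresponds to 2 ms
windows and scale 22 to 44 ms windows. The defaults $m = 2$, $r = 0.50$
SD, 22 scales are the conventional single-trial EEG settings.

Three numerical decisions deserve note:

* **The tolerance is fixed once per trial-channel series** as 0.50 × the SD
  of the *original* (scale-1) series, not recomputed per scale. This is
  the classic MSE convention; it makes entropy decline across scales for
  uncorrelated noise (coarse-graining shrinks the variance while $r$ stays
  put), which is itself diagnostic of signal structure. It also makes every
  entropy value exactly invariant to rescaling a trial by a positive
  constant, which the tests verify.
* **Undefined entropies** ($A = 0$ or $B = 0$, most likely on the 27-point
  coarse series) are returned as `NA` rather than infinity, and
  condition-level averaging simply omits them while recording
  `n_valid_trials` per channel × scale cell, so that
  `n_valid + n_undefined = n_trials` always holds. A zero-variance series
  is undefined at all scales, with a warning.
* **The entropy window** defaults to the full epoch (−200..+1000 ms, 600
  samples), maximising series length at coarse scales; a post-stimulus-only
  window is available via `window = "post"` in `mse_trials()` /
  `mse_condition()` for users who prefer not to mix pre- and post-stimulus
  samples.

## Task PLS

`task_pls()` is the package's central model-fitting function. Rows of the
input matrix are subject × condition observations and columns are features
(channel × timepoint voltages for ERPs, channel × scale entropies for MSE).
The fit:

1. averages subject rows within condition into a condition × feature
   matrix;
2. centers each column at its grand mean across conditions (the standard
   task-PLS mean-centering approach);
3. takes the SVD. Each latent variable (LV) pairs **design saliences** (a
   contrast over conditions), **feature saliences** (a weighting over
   electrodes and timepoints/scales) and a **singular value**;
   `covariance_explained` for LV $k$ is $s_k^2 / \sum_j s_j^2$.

Signs of an SVD are arbitrary, so each LV is normalised deterministically:
the largest-magnitude feature salience is made positive. Singular values
below a rank tolerance are dropped, so identical condition means yield an
empty LV list rather than numerical noise, and two-condition designs yield
exactly one LV with design saliences $\pm 1/\sqrt 2$.

**Permutation test.** Each permutation independently reshuffles the
condition labels within every subject (subject order fixed), refits, and
the p-value for LV $k$ is the fraction of permuted singular values at
position $k$ that reach the observed one. The p-value is deliberately
$k/n_{\mathrm{perm}}$, not $(k+1)/(n+1)$, matching the "number of times out
of 500" definition of the source toolbox lineage; the cost is that an
overwhelming effect can report $p = 0$, which should be read as
$p < 1/n_{\mathrm{perm}}$.

**Bootstrap ratios.** Each bootstrap resamples subjects with replacement,
keeping every subject's full condition set intact, and refits. Because the
latent axes of a resample can be reflected or rotated relative to the
original, each resample's design-salience basis is aligned to the original
by an orthogonal Procrustes rotation before the feature saliences are
accumulated; without this, axis flips masquerade as instability and
inflate the standard errors. The bootstrap ratio (BSR) of a feature is its
original salience divided by the SD of its bootstrap distribution;
$|\mathrm{BSR}| \ge 2$ is the conventional stability criterion. A zero
bootstrap SD with a zero salience is reported as 0 (no signal, no
instability); a zero SD with a nonzero salience is reported as `NA`
(degenerate resampling, e.g. identical subjects).

`stable_windows()` turns a BSR vector into the report format used in this
literature: per channel, the maximal contiguous runs of
$|\mathrm{BSR}| \ge$ threshold, each with the sign of its saliences. The
minimum run length is a free parameter nowhere stated in the source
procedures; the default for ERP features is 5 consecutive samples (10 ms
at 500 Hz), chosen to suppress single-sample crossings, and 1 for scale
features, where 22 positions leave no room for a longer requirement.

**Alpha families.** Following the study design, across-session analyses
are tested at $\alpha = 0.05$ and each within-session analysis at the
Bonferroni-corrected $\alpha = 0.008$.

## The behavioural chain

`rm_anova()` implements one- and two-factor fully-within ANOVAs by an
explicit sums-of-squares decomposition, testing each effect against its
own effect × subject interaction. For effects with ≥ 2 numerator df,
Mauchly's test is computed on orthonormal effect contrasts, and when it
rejects at 0.05 the Greenhouse–Geisser corrected p-value
($\varepsilon$-scaled df, with $\varepsilon \in (1/(k-1), 1]$) is adopted —
mirroring how such results are conventionally reported. The effect size is
generalized eta-squared with all subject-related variance in the
denominator (the Olejnik–Algina/Bakeman definition):
$\eta^2_G = SS_{\mathrm{eff}} / (SS_{\mathrm{eff}} + SS_{\mathrm{subj}} +
\sum SS_{\mathrm{err}})$. Follow-up paired t-tests report Cohen's
$d_z$ (mean difference over SD of differences), the convention consistent
with the magnitudes reported in this literature (e.g. $d = 0.80$ at
$t(19) = 3.58$). The ANOVA chain is written from first principles rather
than delegated, because no single installed package exposes the combination
of $\eta^2_G$, Mauchly and GG used here; the test suite cross-checks it
against `aov()` error strata and `car::Anova()`'s sphericity machinery.

The exclusion order — RT outliers on all trials first, incorrect trials
second — follows the reported framing of the exclusions; the outlier
statistics are single-pass by design and the tests pin this down (re-running
the rule on its own output uses new statistics and is *not* a no-op). A
`sd_crit` argument and the grouping columns are exposed for users who need
the alternative order or grouping.

## What the synthetic generator emulates

`sim_config()` defines the study conditions:

* **Geometry:** 20 participants, 3 sessions, ~1000 trials/session, 64
  channels (10/20 labels), 500 Hz, epochs −200..+1000 ms (600 samples).
* **Background noise:** per trial and channel, $1/f^{\beta}$ noise built by
  frequency-domain synthesis — amplitude spectrum $\propto f^{-\beta/2}$,
  uniform random phases, inverse FFT, standardised to `noise_sd` (default
  10 µV). The session-wise exponent (default 1.0, 1.3, 1.3) is the lever
  for planted entropy effects: steeper spectra are more regular, lowering
  fine-scale sample entropy in Sessions 2–3, the direction reported for
  practice-related change. A property test verifies the realised spectral
  slope to ±0.2.
* **ERP components:** Gaussian-windowed half-cycle sinusoids with compact
  support, one amplitude per session, added on their channel groups. The
  defaults plant the across-session pattern characteristic of prolonged
  lexical decision — N170 more negative, P200 and N400 more positive, LPC
  less positive from Session 1 to Sessions 2–3, at occipito-parietal,
  frontal/fronto-central and centro-parietal sites respectively. The
  absolute microvolt values are free parameters (no per-electrode
  magnitudes are published); they are sized (session differences of 3–4 µV
  against 10 µV single-trial noise) so that the planted LV1 is a decisive
  effect even in a reduced 5-subject, 100-trial simulation, emulating the
  unambiguous ($p < 0.001$) first latent variable such analyses report at
  full scale.
* **Behaviour:** shifted-lognormal RTs, $rt = \text{shift} + e^{\mu +
  \sigma Z}$, with participant-level latent means correlated 0.8 across
  cells (session-to-session RT is highly reliable) and cell targets set to
  the session-wise means/SDs and accuracies of a three-session
  lexical-decision study (words ≈ 811/764/727 ms, nonwords ≈ 925/825/779
  ms; accuracies 0.86–0.94). With these conditions the full chain
  reproduces exclusion rates of ~2.5% (RT outliers) and ~11–12% (incorrect
  responses) and detects the nonword session effect in well over 80% of
  replicates at $n = 20$.
* **Reproducibility:** every participant × session cell draws from its own
  deterministic substream of the master seed, so any cell can be
  regenerated bit-identically in isolation and in any order.

What the generator does **not** emulate: volume-conducted inter-channel
correlation beyond shared components, non-stationary artefacts (blinks,
muscle), subject-level variation in component amplitude or latency, and any
within-session drift (the within-session analysis families are therefore
null under the defaults). Passing tests consequently demonstrate that the
chain recovers the planted across-session structure and is calibrated under
exchangeable nulls — not that it would reproduce any particular real
dataset's statistics.

## Problem sizes used by the tests

The shipped tests and the acceptance script run the chain at deliberately
reduced scale, chosen as the smallest sizes at which each property is
informative: the planted-effect recovery uses 5 subjects × 3 sessions ×
100 trials on the full 64-channel montage with 100 permutations and 100
bootstraps; permutation calibration uses 200 null datasets of 20 subjects ×
40 features with 100 permutations; the null-pipeline uniformity check uses
100 replicate pipelines of 4 subjects × 12 trials × 4 channels; behavioural
detection uses 40 replicates at the full 20 × 3 × 1000 design. The
full-scale study profile (`run_config()` defaults: 500 permutations, 500
bootstraps, 20 participants) is the intended setting for real use.

## A worked miniature

```{r example, eval = FALSE}
sim <- sim_config(n_participants = 5, trials_per_session = 100, seed = 1)
maps <- replicate(5, list(), simplify = FALSE)
for (p in 1:5) for (s in 1:3) {
  ep <- generate_epochs(sim, p, s)
  kept <- exclude_incorrect(exclude_rt_outliers(ep$trial_meta)$retained)
  ep <- subset_trials(ep, match(rownames(kept), rownames(ep$trial_meta)))
  maps[[p]][[s]] <- average_erp(ep)$mean
}
st <- stack_features(maps, sim$channels, sim$times, "time_ms")
fit <- task_pls(st$x, st$conditions, st$subjects,
                n_perm = 100, n_boot = 100, seed = 2,
                feature_index = st$feature_index)
print(fit)
stable_windows(fit, lv = 1, threshold = 2, min_run = 5)
```

For the full replica — eight PLS families plus the behavioural chain in one
call — see `run_study()` and `write_report()`.

## Known limitations

* The permutation p-value can be exactly 0; report it as
  $p < 1/n_{\mathrm{perm}}$.
* With very few subjects the bootstrap underestimates salience SEs, so
  null-feature BSRs exceed the 2.0 threshold more often than the nominal
  ~5%; stability reports at $n \le 5$ should be read qualitatively.
* Mean-centering is fixed to the grand-mean-over-conditions option; other
  task-PLS centering variants (e.g. within-subject centering) are not
  implemented.
* The on-disk epochs container is a plain-text directory format designed
  for portability of small fixtures, not for large-scale storage.
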