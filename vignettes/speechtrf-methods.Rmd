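---
title: "Encoding models of continuous speech: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models of continuous speech: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtrf)
```

# The problem

When a listener hears continuous speech, slow cortical activity follows the
stimulus: encoding models quantify this *neural tracking* by predicting a
neural time series from time-resolved stimulus features through a linear
convolution kernel, the temporal response function (TRF),

$$y_j(t) \;=\; \sum_{f} \sum_{k} \beta_{jf}(\tau_k)\, x_f(t - \tau_k) \;+\;
\varepsilon_j(t),$$

where $x_f$ are stimulus feature channels, $\tau_k$ are lags, and $j$
indexes cortical sources.  The scientific questions this package is built
for contrast *acoustic* features (the envelope and its onsets) against
*phonemic* features (phoneme onsets and cohort-model statistics) and ask
how linguistic structure and language familiarity modulate each: which
features uniquely improve prediction (variance partitioning by ablation),
and at which latencies the kernels differ between experimental conditions
(cluster-based permutation tests on weight timecourses).

This vignette documents the models, the tunable parameters, the synthetic
validation data, and the numerical choices, in that order.

# Feature computation

## Cohort statistics

The cohort model treats word recognition as incremental filtering of a
frequency-weighted lexicon.  With `cohort`$_{i}$ the set of words
compatible with the first $i$ phonemes and $m_i$ its total frequency
mass, the conditional probability of phoneme $i$ is $P_i = m_i/m_{i-1}$,
its surprisal $-\log_2 P_i$ (bits), and its entropy the Shannon entropy of
the frequency-weighted distribution over possible next symbols.  These
are computed exactly (integer masses, logs at the last step), and the
suite checks them against brute-force enumeration of the lexicon.

Three decisions the equations do not settle:

* **Conditioning of entropy.**  We condition the next-phoneme distribution
  on the cohort *after* consuming phoneme $i$ (uncertainty about phoneme
  $i{+}1$); `condition_entropy_on = "before"` gives the alternative.
* **Word-end outcome.**  When a cohort member is an exact match of the
  prefix, its mass feeds a terminal "word ends here" outcome
  (`include_word_end = TRUE` by default); otherwise next-phoneme
  distributions are improper whenever words are prefixes of longer words.
* **Empty cohorts.**  Pseudoword streams guarantee that the cohort
  empties.  The default fallback scores such phonemes uniformly over the
  inventory (probability $1/|V|$, surprisal and entropy $\log_2|V|$) and
  flags the event; `fallback = "restart"` instead re-enters the lexicon
  word-initially.  The uniform default is deterministic and
  lexicon-independent, and the flags keep every fallback auditable.

Lexicons are filtered to forms made only of Unicode letters (which keeps
Turkish dotted/dotless i and Chinese characters), duplicate forms merge by
summing frequency, and non-positive frequencies are rejected.

## Acoustic features

`gammatone_spectrogram()` computes an 8-band spectrogram with 4th-order
gammatone filters whose centre frequencies are equally spaced on the
Glasberg–Moore ERB-number scale, $E(f) = 21.4\log_{10}(1+0.00437 f)$,
between 20 and 5000 Hz.  Each band's envelope is extracted by half-wave
rectification followed by a 4th-order zero-phase Butterworth low-pass at
40 Hz and polyphase resampling to the 100 Hz predictor grid; amplitude is
kept linear (no power, no compression).  The rectify-and-low-pass
envelope, its 40 Hz cutoff, and the absence of compression are declared
defaults, all exposed as arguments.  `onset_spectrogram()` implements
acoustic-edge detection as the half-wave rectified first difference of
each band, scaled by the frame rate — the definition "sudden increases in
the envelope" — structured so a multi-delay edge-detection variant can be
added behind the same interface.

## Predictors, normalisation, padding, lag design

All features live on a 100 Hz grid.  Event-valued features (phoneme
onset, surprisal, entropy, and word-level features taken from an external
table) are impulse-coded into the frame containing their onset
(`floor(onset × rate)`, frames are left-closed).  Channels are z-scored
with statistics computed over *unpadded* samples only — padding must stay
exactly zero, and statistics should not depend on how much padding a trial
received — then every trial is zero-padded 50 ms before its onset and
700 ms after its offset so lagged regressors near the edges neither wrap
nor truncate.

The kernel is parameterised on a lag axis covering $[-50, 700)$ ms in
10 ms steps — left-closed, right-open, hence exactly **75 lags** — with a
50 ms Hamming window centred on each lag as the basis (centred vs
left-aligned is an argument; centred is the default).  The inclusive
reading "between −50 and 700 ms" would give 76 points; only the half-open
convention is consistent with 75.  Regressors are built per trial and
never mix samples across trial boundaries.

# TRF estimation by boosting

`fit_trf()` estimates kernels per source by greedy coordinate-wise
boosting of the l2 error: starting from all-zero coefficients, each
iteration changes the single (channel, lag) coefficient by $\pm$`step`
that maximally reduces the training error, breaking ties toward the lowest
channel/lag index so fits are bit-reproducible.  Trials are partitioned
into 5 contiguous blocks; for each test fold, the cyclic successor fold is
the validation set and the rest the training set.  Training stops when the
validation error has *risen for `patience` consecutive iterations* (or no
move helps), and the kernel at minimum validation error is kept.  An
earlier implementation stopped when the validation error had merely
failed to improve for `patience` iterations; that reading stalls on
validation plateaus far from convergence and was rejected when it failed
the noiseless recovery oracle.

Two structural points:

* **Affine fit.**  Channels and response are centred over the training
  rows before fitting (a rank-1 update of the cached Gram matrices) and
  the intercept is recovered at prediction time.  Without this, the
  z-scored response carries a constant component that the intercept-free
  convolution cannot represent — enough to cap noiseless held-out $R^2$
  near 0.988 — because lagged regressors have small nonzero means near
  trial edges.
* **Gram-space iterations.**  The boosting loop runs entirely on
  precomputed Gram matrices, making each iteration $O(p)$ and letting
  ablation refits reuse sub-blocks of the same Grams.  Fits are exact
  restatements of the naive algorithm, verified against brute-force
  forward-model evaluation.

Defaults: `step = 0.005` (in normalised units), `patience = 10`,
`max_iter = 10000`, 5 folds.  These are conventional for this estimator
family and are deliberately ordinary config keys: the package's claims are
recovery properties, not particular coefficient values.  On small dense
full-rank problems (tens of coefficients) the fixed increment becomes the
resolution limit, and a finer step (e.g. 0.001 with patience 50) is
appropriate; the least-squares benchmark in the test suite does exactly
that.

Held-out accuracy is the proportion of variance explained,
$1 - SS_{res}/SS_{tot}$, on the test fold with padded samples excluded; it
may be negative.  *Accuracy improvement* for a feature family is the full
model's accuracy minus that of a model refitted without the family's
channels (same folds, same hyperparameters).  Reported kernels are the
mean over folds; the *effective kernel* (`effective_kernel()`) — the
coefficients convolved with the basis window along the lag axis — is what
the model actually applies to each channel and the quantity used for
weight comparisons, since rough directions within the basis span are
unidentifiable in prediction space.

# Group-level statistics

`weight_timecourse()` reduces a model to the mean over sources and
channels of the absolute effective weights per lag (a sum is available;
the mean is scale-invariant across source counts).  The first and last
20 ms of the lag window are masked as edge artifacts and excluded from all
statistics.

`cluster_permutation()` compares paired condition timecourses: per-lag
paired t statistics, contiguous suprathreshold runs (threshold: two-sided
t critical value at $\alpha = 0.05$ for $n-1$ df — the common default, and
a config key), cluster mass as the sum of t within a run, and a null
distribution of the maximum absolute cluster mass over random sign flips
of subject differences, 30,000 permutations by default.  P values use the
add-one convention $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$, so
$p \ge 1/(n_{perm}+1)$ and exact zeros cannot occur.  The suite checks the
Monte-Carlo p against exhaustive $2^n$ enumeration at small $n$, the
false-positive rate under the null, and detection of an injected
300–500 ms effect.  `improvement_ttest()` is the one-sample two-sided
t test of source-averaged improvements against zero, and `peak_latency()`
extracts window maxima (early $-50$–$100$, mid $100$–$350$, late
$350$–$700$ ms; ties resolve to the earliest lag).  Group comparisons
beyond these (mixed-effects models, aligned-rank ANOVA) are deliberately
exported as tidy tables for external statistical software rather than
reimplemented.

# Synthetic validation data

`make_experiment()` builds a full study around known ground truth:

* **Lexicon** — 20 bi-syllabic CV-CV words with Zipf frequencies.
* **Stimuli** — isochronous streams of 16 syllables of exactly 250 ms
  (200 ms variant available), i.e. 4 s sequences of 8 bi-syllabic words;
  5% cosine ramps at both token ends; sequences RMS-normalised to
  −15 dBFS.  Syllable tokens are harmonic complexes with
  consonant-dependent onsets (noise bursts for stops) — enough spectral
  and temporal structure for the gammatone and edge features, not a
  speech synthesizer.  Conditions: `words`, `random_syllables` (a
  permutation of the same syllable multiset), `sentences` (fixed 4-word
  role templates), `word_list` (those words shuffled).
* **Ground truth** — per family, a gamma-density bump on the lag axis
  (acoustic families peaking near 100 ms, phoneme features near 400 ms,
  in line with reported latencies for such responses), per-channel
  amplitude variation, multiplicative condition effects restricted to lag
  windows, per-subject amplitude jitter, per-source gains, and white
  Gaussian noise at a requested signal-to-noise variance ratio (a 1/f
  option is out of scope; recovery targets are defined under white
  noise).
* **Presets** — `words_vs_syllables` multiplies the phoneme kernel by 1.5
  in the words condition; `sentences_vs_wordlist` by 1.3 in sentences;
  `familiarity` multiplies the acoustic-edge kernel by 1.3 over
  $[-50, 150]$ ms in the "unfamiliar" condition; `null` injects nothing.
  The familiarity preset deliberately injects only the edge effect:
  because phoneme onsets coincide with acoustic edges, a simultaneous
  phoneme-kernel modulation spills into the edge weight estimates at mid
  lags and can mask the early edge contrast — one injected effect per
  correlated family keeps the designed contrast identifiable.

Each simulated subject receives an independently sampled stimulus
sequence set.  This matters: with one shared stimulus set, the
stimulus-sampling component of estimation error is identical across
subjects, and paired condition contrasts between *different* stimulus
sets inherit it as a spurious fixed effect.  Experiments of this kind
randomise stimulus selection per participant for the same reason.  In the
familiarity preset the two conditions share each subject's streams, so
that contrast is estimation-bias-free by construction.  Per-subject gains
and jitter are drawn once and held fixed across conditions.

Desk-scale defaults, chosen once: 15 subjects, 4 simulated sources, 8
sequences per condition, SNR 0.5.  The subject count matches the group
size of the study design this emulates; source and sequence counts are
set so a full preset (simulation, per-subject fits, ablations,
permutation tests) completes in minutes on one CPU while leaving the
injected effects comfortably detectable.  The acceptance script runs the
presets with 2 sources for the same reason.

What passing these simulations does *not* show: the generator has white
noise, linear superposition, no kernel variability across trials, no
source leakage or sensor-level mixing, and isochronous, acoustically toy
stimuli.  Recovery here validates the estimator and inference machinery,
not robustness to the full physics of magnetoencephalography.

A realistic consequence of the design worth knowing: phoneme onsets
coincide with acoustic edges in any speech-like stimulus, so much of the
onset-locked phoneme response is equally expressible by lagged edge
channels, and the *unique* (ablation) contribution of phoneme features
can be far smaller than their kernels suggest.  Weight-timecourse contrasts are
therefore the more sensitive probe of phoneme-level condition effects —
which is also how the ablation and weight analyses divide labour in the
literature.  The same collinearity makes weight estimates share credit
across families: a condition effect injected into one family partially
surfaces in the correlated family's weights, and a *windowed* kernel
modulation (the familiarity preset's early edge boost) is recovered at
attenuated amplitude.  Synthetic consonants therefore have
identity-dependent durations (vowel onsets stagger across syllables),
which keeps the phoneme impulse trains from being shifted copies of the
edge trains; without this, a windowed edge effect can be silently
reassigned to phoneme weights.  Even so, detection of the windowed edge
contrast is power-limited at desk scale — its direction is stable across
seeds, its cluster significance is not guaranteed at every seed.

# Numerical choices and edge cases

* Probabilities are ratios of integer masses; logs are taken last.
* Impulse coding uses `floor(onset × rate)`; onsets are continuous, so
  ties are not special-cased.
* Zero-variance channels are fatal in `normalize_channels()` (a
  degenerate predictor is a configuration error, not something to mask
  silently).
* Zero-variance lags under permutation get $t = 0$ rather than NaN; a
  contrast of identical conditions yields no clusters.
* Boosting determinism: coordinate ties go to the lowest index; the
  validation fold is the cyclic successor of the test fold (a fixed
  rotation rather than a seeded draw, so fits need no RNG at all).
* Silence is a valid input to the filterbank (all-zero output); a sample
  rate below twice the top band is fatal.

# Known limitations

* The edge detector is the rectified first derivative; the multi-delay
  neural edge model used by some toolboxes is not yet implemented (the
  interface anticipates it).
* Sentence-condition word-level features use unigram surprisal and seeded
  pseudo-entropies as stand-ins for language-model values; real analyses
  should supply a word-feature table.
* Spatiotemporal (source × lag) clustering is out of scope; clustering is
  across lag only, on source-averaged timecourses.
* The boosting step is global across channels; per-family steps or bases
  are not supported.
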