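# speechtrf

Forward encoding models ("temporal response functions", TRFs) of neural
responses to continuous speech, for researchers who want to ask *which*
speech features the brain tracks — acoustic envelope and acoustic edges
versus phoneme-level information — and *when*, under different linguistic
conditions.

The core model predicts a source-level neural time series from lagged
stimulus features,

    y_j(t) = Σ_f Σ_k β_jf(τ_k) · x_f(t − τ_k) + ε_j(t),

with kernels β on a lag axis of 75 points covering [−50, 700) ms at
100 Hz, parameterised in a basis of 50 ms Hamming windows.  The package
implements, end to end:

* **Cohort-model phoneme statistics** — incremental conditional
  probability, surprisal (−log₂ P, bits) and next-phoneme Shannon entropy
  over a frequency-weighted pronunciation lexicon, with configurable
  fallback for out-of-lexicon (pseudoword) input.
* **Acoustic features** — an 8-band gammatone spectrogram on the
  ERB-number scale (20–5000 Hz) and an acoustic-edge (onset) spectrogram
  from half-wave rectified envelope derivatives.
* **TRF estimation by boosting** — greedy coordinate-wise l2 fitting with
  5-fold cross-validation over contiguous trial blocks and early stopping
  on a validation fold; accuracy as held-out proportion of variance
  explained; feature attribution by ablation (full minus reduced model).
* **Group statistics** — one-sample t tests of accuracy improvements,
  cluster-based sign-flip permutation tests across lag on TRF weight
  timecourses (30,000 permutations, 20 ms edge masks), and early/mid/late
  peak-latency extraction.
* **A synthetic-data module** — toy lexicons, isochronous syllable streams
  (16 × 250 ms syllables = 4 s sequences, cosine ramps, −15 dBFS), known
  ground-truth kernels with injected condition effects, and simulated
  multi-subject source responses, so the whole pipeline is testable
  against ground truth without any data downloads.

I/O helpers read and write WAV audio, Praat TextGrids, TSV lexicons and
event tables, and tidy TSV result tables ready for external mixed-model
software.

## Worked example

Cohort statistics on a three-word toy lexicon (frequencies ba:2, bi:1,
da:1).  Hearing "b" keeps {ba, bi} (probability 3/4); hearing "a" then
keeps {ba} (probability 2/3 of the remaining mass):

```r
library(speechtrf)
lex <- lexicon(c("ba", "bi", "da"), c(2, 1, 1),
               list(c("b", "a"), c("b", "i"), c("d", "a")))
word_surprisal_profile(lex, c("b", "a"))
#> # A tibble: 2 × 6
#>   position phoneme probability surprisal_bits entropy_bits fallback
#>      <int> <chr>         <dbl>          <dbl>        <dbl> <lgl>
#> 1        1 b             0.75           0.415        0.918 FALSE
#> 2        2 a             0.667          0.585        0     FALSE
```

0.918 bits is the entropy of the next phoneme after "b" (a with mass 2,
i with mass 1); after "ba" the continuation is certain, so entropy is 0.

A full synthetic contrast — words versus random-syllable streams with the
phoneme kernel amplified ×1.5 in the words condition — simulated,
fitted and tested:

```r
cfg <- default_config(n_subjects = 15, n_sources = 2,
                      n_permutations = 2000, seed = 7)
exp <- run_simulate(cfg)   # per-subject streams, predictors, responses
fit <- run_fit(exp, cfg)   # boosting TRFs + ablations per subject
st  <- run_stats(fit, cfg) # t tests, cluster permutation, latencies

st$ttests
#> # A tibble: 4 × 7
#>   condition        family         estimate statistic    df     p.value     n
#> 1 random_syllables acoustic_edges  0.00623      8.65    14 0.000000548    15
#> 2 random_syllables phoneme         0.00267      2.62    14 0.0201         15
#> 3 words            acoustic_edges  0.00451      5.58    14 0.0000676      15
#> 4 words            phoneme         0.0129       6.90    14 0.00000735     15

dplyr::filter(st$cluster_table, family == "phoneme", p < 0.05)
#> # A tibble: 2 × 6
#>   family  cluster_start_ms cluster_end_ms  sign  mass        p
#> 1 phoneme               20             60     1  15.4 0.0500
#> 2 phoneme              100            670     1 267.  0.000500
```

Both feature families contribute significantly to held-out accuracy in
both conditions, the phoneme contribution is larger in word streams than
in random syllables (0.0129 vs 0.0027), and the dominant weight cluster
(100–670 ms, p = 0.0005, positive sign = words > syllables) recovers the
injected phoneme-kernel enhancement around its ~400 ms peak.

Plots: `autoplot(model)` for kernels, `plot_weight_timecourse()` for
condition contrasts, `autoplot(spectrogram)` for features.

## Package layout

* `R/lexicon.R`, `R/cohort.R` — lexicons and cohort statistics
* `R/acoustics.R` — gammatone filterbank, ERB centres, onset spectrogram
* `R/predictors.R`, `R/lagdesign.R` — impulse coding, normalisation,
  padding, Hamming-basis lag expansion
* `R/boosting.R` — the boosting estimator, prediction, accuracy, ablation
* `R/stats.R` — t tests, cluster permutation, peak latencies
* `R/synthetic.R` — lexicon/stream/ground-truth/response generators and
  experiment presets
* `R/pipeline.R` — config-driven `run_simulate()` / `run_fit()` /
  `run_stats()` and bundle export; a thin CLI lives in
  `inst/cli/speechtrf.R`
* `vignettes/speechtrf-methods.Rmd` — the methods and design notes
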