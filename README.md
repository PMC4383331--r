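# tffo: time-frequency feature optimization for single-electrode EEG discrimination

`tffo` discriminates two subject populations — schizophrenia patients
and healthy controls is the motivating case — from **short,
stimulus-locked EEG segments recorded at a single electrode**.  The
premise: when a predictive stimulus sequence builds an expectation,
the two groups differ in a narrow region of the time-frequency plane
(beta-band activity in specific windows after the stimulus, at
frontal-central sites), and that region can be *found* by exhaustive
search rather than assumed.

The pipeline has four stages:

1. **Preprocessing** — zero-phase 0.1–30 Hz Butterworth band-pass,
   total-energy normalization, ICA-based blink removal, epoching into
   1.2 s frames starting 200 ms before each predictive ("P") stimulus,
   and exclusion of epochs with misses (no button press 150–1150 ms
   post-stimulus), saccades, or amplitude above 75 µV at any
   electrode, with a complete audit log.
2. **Time-frequency transform** — the discrete Stockwell transform

   S(τ, f) = ∫ x(t) · g_f(τ − t) · e^(−j2πft) dt,

   a short-time Fourier transform whose Gaussian window narrows with
   frequency, computed by the FFT algorithm for all voices up to
   Nyquist.
3. **Feature extraction** — the magnitude map of the average of the
   first *n* surviving epochs, restricted to a time window [a, b] ×
   frequency band {f} and flattened into a feature vector per subject.
4. **Classification and optimization** — K-nearest-neighbour
   classification (Euclidean distance, leave-one-out over subjects,
   the closest neighbour casting the deciding vote on even-K ties,
   1 ≤ K ≤ ⌊events/2⌋), evaluated over the full grid electrode ×
   window × band × event count × K.  Marginal analyses over each grid
   dimension give the electrode ranking and the event-count, window
   and band curves; a permutation test calibrates significance.

Two companions complete the package: a **severity module** (ridge
regression of an exponential hospitalization rank on the log distance
from each patient to the healthy-group feature centroid, plus
severe-half concordance checks) and two **latency baselines**
(PE-Latency: 2-means on mean peak-energy latency; P300-RF-Latency:
the same KNN pipeline on histograms of peak-energy latency in the
P300 range).

Because the clinical recordings behind this design are not publicly
deposited, the package ships a first-class **synthetic cohort
generator**: 1/f background noise with a shared volume-conduction
component, stimulus-locked Gabor bursts whose amplitude and latency
jitter differ between groups (optionally graded by a latent severity
that also drives hospitalizations, medication load and SAPS/SANS
counts), trial-wise habituation, and injectable
blink/saccade/miss/amplitude artifacts with a ground-truth table.
Every downstream stage is tested against this generator's known
truth.

## Worked example

```r
library(tffo)

## 1. Simulate a 25 + 25 cohort with severity-linked deficits
spec <- cohort_spec(n_per_group = 25,
                    channel_labels = c("F2", "FC3", "AFz", "FCz", "Cz", "Pz"),
                    effect_channels = c("F2", "FC3"),
                    effect_band = c(15, 20),
                    effect_windows = list(c(200, 300)),
                    n_stimuli_per_block = 45,
                    seed = 43)
cohort <- generate_cohort(spec, severity = severity_model())

## 2. Preprocess: band-pass + normalize, ICA blink removal, epoch + exclude
epochs <- preprocess_cohort(cohort, ica = TRUE)
table(attr(epochs, "exclusion_log")$reason)
#> amplitude      miss   saccade
#>        36        76        38

## 3. Single-electrode classification in the beta band after the stimulus
feats <- extract_features(epochs, window_spec(200, 300, 15, 20),
                          electrode = "F2", n_events = 8)
loo_cv(feats, K = 3)
#> <tffo_cv> n = 50, K = 3: accuracy 0.820, specificity 0.880, sensitivity 0.760
significance(feats, K = 3, seed = 1)$p_value
#> [1] 0.005

## 4. Feature optimization: scan electrodes x windows x bands x K
wins <- enumerate_windows(t_range = c(0, 1000), t_widths = 100,
                          t_steps = 50, f_widths = 5, f_steps = 2.5,
                          f_range = c(0, 30))
grid <- run_grid(epochs, electrodes = c("F2", "FC3", "Cz", "Pz"),
                 windows = wins, n_events = 8, K = 1:4)
m <- marginal(grid, "electrode")
m[order(-m$best_accuracy), ]
#>   electrode mean_accuracy best_accuracy n_cells
#> 3       FC3     0.5076316          0.92     836
#> 2        F2     0.4852871          0.84     836
#> 1        Cz     0.5002871          0.76     836
#> 4        Pz     0.4876555          0.76     836
top_cell(grid)
#>      electrode t_start t_end f_low f_high n_events K n_subjects accuracy
#> 1087       FC3     250   350  17.5   22.5        8 3         50     0.92
#>      specificity sensitivity
#> 1087        0.84           1

## 5. Severity: distance to the healthy centroid vs clinical covariates
sv <- severity_distance(feats)
pat <- sv$group == "patient"
ids <- vapply(cohort, `[[`, "", "subject_id")
meta <- function(field) vapply(cohort, function(r)
  if (r$group == "patient") r$metadata[[field]] else NA_real_,
  0)[match(sv$subject_id[pat], ids)]
fit_severity(sv$transformed_distance[pat],
             hospitalization_rank(meta("hospitalizations")))
#> <tffo_ridge> penalty 0.3259: slope 2.374, R^2 0.461 (LOO 0.376)
severe_half_check(sv$distance[pat], meta("sans"))$count
#> [1] 5
```

Reading the numbers: the exclusion table shows the audit log by
reason; with the effect injected on F2/FC3 in 15–20 Hz at
200–300 ms, a single electrode already separates the groups well
above chance (0.82, permutation p = 0.005), the grid search ranks the
effect electrodes first and its best cell (an overlapping window/band
on FC3) reaches 0.92 with no missed patient, and the distance of each
patient to the healthy feature centroid recovers the latent severity
that generated the cohort (ridge R² = 0.46 in-sample, 0.38
leave-one-out; all 5 of the most symptomatic patients fall in the
severe half of the distance ranking).  Because mild synthetic
patients are nearly healthy by construction, single-cell accuracy
saturates below 1 — the optimization stage, not any fixed window, is
what the method is about.

A thin command-line front end is installed as `exec/tffo`
(`tffo simulate | classify | severity`).

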