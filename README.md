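# emgsynergy

Muscle-synergy analysis of multi-channel surface EMG recorded during
horizontal center-out motor tasks — isometric force generation against a
fixed handle and point-to-point reaching — for motor-control researchers
who want a tested, end-to-end R implementation of the standard synergy
pipeline: envelope preprocessing, non-negative matrix factorization with
VAF-based model-order selection, cross-task/cross-location synergy
comparison against permutation-null thresholds, cross-validated EMG
reconstruction with TOST equivalence, and directional tuning analysis with
circular statistics.

## The model

The EMG envelope matrix (muscles × samples) is approximated by a low-rank
nonnegative factorization

```
EMG ≈ W · C,      W ≥ 0 (muscles × K, unit-norm columns),  C ≥ 0 (K × samples)
```

estimated by multiplicative-update NNMF. Reconstruction quality is the
variance accounted for, `VAF = 100 · (1 − SSE/SST)` with uncentered SST;
the number of synergies K is the smallest order satisfying jointly
gVAF > 90%, ΔgVAF < 5 points for one more synergy, and per-muscle VAF > 60%.
Synergy similarity is the scalar product of unit-norm weight vectors,
judged against the 95th percentile of 499,500 pairwise products among
1,000 randomly resampled synergies (Bonferroni-corrected percentile for
multi-location comparisons). Activation tuning is summarized per target
direction in local coordinates (Left −28°, Right +22.4°), with tuning
directions from the curve's vector sum, a change-point activation
threshold for counting active synergies, and Watson–Williams circular
ANOVA for directional differences.

Because no recordings ship with the package, a first-class synthetic
generator produces EMG with known ground truth — nonnegative synergies with
rectified-cosine directional tuning, ramp-and-hold (isometric) or
minimum-jerk burst (reaching) envelopes, rest baselines, envelope-band
noise at a controlled SNR, trial-to-trial gain jitter and an optional ECG
artifact — so every stage is validated against a generative model.

## Worked example

```r
library(emgsynergy)

gt <- make_ground_truth(n_muscles = 13, n_synergies = 3, seed = 42)
ds <- synthesize_dataset(gt, task = "reaching", location = "Distal",
                         n_reps = 5, seed = 42, fs_emg = 500, fs_aux = 500)
ds
#> <emg_dataset> 60 trials | task=reaching location=Distal participant=S1 | 13 muscles

pooled <- preprocess_dataset(ds)   # envelopes, onsets, 150-sample trials, pooling
dim(pooled$matrix)
#> 13 9000

fit <- nnmf(pooled, k = 3, restarts = 5, max_iter = 500, tol = 1e-5, seed = 1)
fit$vaf$gvaf
#> 97.7

# compare extracted synergies (mapped back to raw units) with ground truth
m <- match_synergies(denormalize_synergies(fit$W, pooled), gt$W_true)
round(m$pairs, 3)
#>   a b similarity
#> 1 1 3      0.999
#> 2 2 2      0.999
#> 3 3 1      0.998

curve <- compute_tuning_curve(fit$C, "Distal")
round(tuning_direction(curve)$angle_deg[m$pairs$a], 1)
#> 313.5 188.4  68.1        # generative preferred: 308, 188, 68
```

The three extracted synergies match the generative weights at similarity
≥ 0.998 and their tuning directions land within ~6° of the generative
preferred directions; the gVAF of 97.7% at the true order reflects the
simulated SNR of 10 after envelope filtering.

The `analysis/` directory holds the full study as numbered drivers —
`01_simulate.R` through `05_tuning.R` — which simulate both tasks at two
starting locations, preprocess, select the model order, compare synergies
across conditions against the permutation null, cross-validate with TOST,
and compute tuning curves, thresholds, per-direction synergy counts and
circular statistics, writing tables under `results/`. The methods vignette
(`vignettes/muscle-synergy-methods.Rmd`) documents the models, parameter
defaults and design decisions, including why VAF-based model-order
selection on broadly tuned synthetic data tends to return one synergy
fewer than the generative order.

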