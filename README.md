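# copingmanifold

Analysis of prefrontal single-cell calcium dynamics during repeated threat
exposure. When a mouse is suspended by its tail (tail suspension, TS), it
alternates between active coping (struggle) and passive coping (immobility).
`copingmanifold` implements the analysis pipeline for asking whether, and
how stably, a cortical population encodes that behavior: per-neuron tuning
scores, population decoding with surrogate controls, and low-dimensional
manifold alignment across days and across animals. A synthetic multi-animal,
multi-day session generator with known ground truth makes every stage
testable without any recorded data.

The package is aimed at systems neuroscientists working with 1-photon
miniscope recordings (20 Hz calcium traces plus behavioral annotations), but
every stage operates on plain matrices and label vectors.

## The methods at its core

* **TS selectivity score** — per neuron, with both contexts min-max scaled
  jointly:

  `S = (m_TS - m_base) / (m_TS + m_base)  in [-1, 1]`,

  where `m` are mean scaled signals (or transient rates); `S < -0.2` marks
  baseline-selective, `S > 0.2` TS-selective neurons.

* **Movement score** — Pearson correlation between a neuron's trace and the
  animal's speed within a context; `|r| > 0.2` defines struggle- and
  immobility-tuned cells. Linear-model explained variance with circular-shift
  surrogate significance (shifts of 20–120 s, 95th percentile of 1,000
  surrogates) quantifies how much of a trace movement explains.

* **Balanced cross-validated decoding** — logistic regression (C = 0.1
  context, C = 0.01 coping), linear SVC, ridge classifier/regression
  (penalty 50), Gaussian naive Bayes; contiguous 10-fold CV over balanced
  frames, chance level from per-neuron circular-shift surrogates evaluated
  with identical fold indices, within and across conditions and days.

* **Manifold alignment** — traces are Gaussian-smoothed, quantile-scaled to
  [0, 1], embedded in 5 dimensions (isomap, n-neighbours 500, fit on a 60%
  temporal stride; PCA and spectral as alternatives), centered and scaled to
  unit Frobenius norm. Each struggle/immobility epoch is rescaled to 20
  progression digits and averaged into a 5 × 40 template manifold. Two
  templates A (target) and B (reference) are aligned by orthogonal
  Procrustes:

  `argmin_Q ||A Q - B||_F,   t(A) B = U S t(V),   Q = U t(V)`,

  and the full manifold follows as `M Q`. Controls: 100 Haar-random
  rotations (det +1) and circular-shift shuffling before embedding.

## Worked example

```r
library(copingmanifold)

params <- generator_params()          # 200 neurons, 10 min baseline + 10 min TS
config <- analysis_config()

out <- generate_session(params, day = 1, seed = 1)
session <- out$session

tun <- tuning_table(session, config)
mean(tun$selectivity_class == "baseline")   # 0.345 of neurons score baseline-selective
mean(tun$selectivity_class == "TS")         # 0.295 score TS-selective
cor(out$truth$movement_beta, tun$movement_score_TS, method = "spearman")
# 0.9067  -- estimated movement tuning tracks the generative coefficients

res <- decode_binary(session$calcium$values, session$behavior$coping,
                     model = "logistic", C = config$coping_C,
                     n_surrogates = 20, seed = 2)
res
#> <decoding_result> coping (logistic): within -> within
#>   mean score 0.968 over 10 folds (n = 8868 frames); surrogate mean 0.529 (20 reps)
```

The selective fractions exceed the generator's context-gain fractions (0.20
and 0.12) because movement-coupled neurons shift their TS mean as well — the
net context effect, not the gain label alone, is what the score measures.
Struggle vs immobility is decoded at 0.97 accuracy while time-shifted
surrogates sit at the balanced-accuracy chance level of 0.5.
Multi-day and multi-animal analyses follow the same pattern
(`generate_multiday()`, `across_day_decode()`, `ts_manifold()`,
`cross_manifold_decode()`), and `run_study()` runs the whole pipeline into a
JSON-serializable report.

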