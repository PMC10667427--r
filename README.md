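# emgseq

Hand-gesture classification from the **transient state** of multichannel
surface-EMG envelopes, using **muscular activation sequences** — the order
in which the six forearm channels first exceed task-specific activation
thresholds — as compact time-domain features. The package is aimed at
myoelectric-control researchers who want a reference implementation of the
full feature-extraction chain, its baselines and its evaluation metrics,
exercisable end to end on a synthetic envelope generator with known ground
truth.

## The method

Each acquisition (4 s, 6 channels, 1 kHz, starting from ≥ 500 ms of rest)
passes through:

1. **Double-threshold onset detection.** A per-dataset low threshold
   `TH_Low = μ + x·σ` (rest-phase mean and sd pooled over channels and
   acquisitions; `x` tuned so false activations in the first 100 ms stay
   below 5%, default 15). A channel crosses when it exceeds `TH_Low`
   throughout 50 ms; the Start of Activation (SoA) is the earliest
   crossing, and channels that never cross are flagged Not Active.
2. **High-threshold ladders.** Per task and channel, candidates start at
   80% of the mean envelope peak within 300 ms of the SoA and decrease
   multiplicatively by 10% per step while above 50% of the peak (at most
   5 steps); candidates at or below `TH_Low` become the unreachable
   sentinel `NA_VALUE`.
3. **Exhaustive combinatorial search.** All `#step^6` combinations of one
   candidate per channel are enumerated; the combination whose modal
   activation sequence is most repeated across the task's training
   acquisitions becomes the representative threshold vector (4 × 6 matrix
   over tasks).
4. **Sequence encoding and refinement.** Channels are ranked by crossing
   time within 300 ms of the SoA (trailing zeros for inactive channels);
   each acquisition is encoded under all four task vectors, truncated to
   the first three activations, and concatenated into a 12-element
   feature.
5. **Classification and evaluation.** NLR (one-vs-all logistic regression
   on interaction-expanded features), SVM (RBF), a logistic MLP (1–5
   hidden layers) and one-vs-all LDA, on a per-task 80/20 split; baseline
   ETS (transient envelope) and ESS (steady-state MAV) features; offline
   accuracy, normality-gated method comparison, class-selection timing,
   and an online simulation reporting motion completion rate (MCR) and
   motion selection time (MST).

See `vignettes/activation-sequences.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

```r
library(emgseq)

## one simulated subject: 50 repetitions x 4 gestures, known ground truth
recs <- generateDataset(defaultProfiles(), defaultNoiseModel(),
                        repsPerGesture = 50, seed = 42)

res <- runSubjectPipeline(recs, nSteps = 4, x = 15, classifier = "nlr",
                          seed = 42)
res$restModel
#> RestModel: mu = 0.0119974 V, sigma = 0.000702601 V, x = 15 -> TH_Low = 0.0225364 V
res$thresholds$vectors$Spherical
#> ThresholdVector [Spherical, #step = 4]: 0.6744 0.2619 1.2102 0.8439 0.5605 NA
res$thresholds$details$Spherical$modalSequence
#> [1] 4 1 3 5 2 0
```

The rest model recovers the generator's rest statistics (0.012 V mean,
0.0007 V sd), and the searched modal sequence for *Spherical* is exactly
its injected recruitment order 4 → 1 → 3 → 5 → 2 with channel 6 inactive
(`NA` threshold). At `nSteps = 4` the search enumerated `4^5 = 1024`
combinations for this five-channel gesture.

```r
cat(sprintf("held-out accuracy: %.1f%%\n", res$accuracy))
#> held-out accuracy: 100.0%
cat(sprintf("sequence recovery: %.1f%%\n", 100 * res$seqMatchRate))
#> sequence recovery: 100.0%
cat(sprintf("timing gap (ESS - sequence): %.0f +/- %.0f ms\n",
            mean(res$timing$gapMs), sd(res$timing$gapMs)))
#> timing gap (ESS - sequence): 2183 +/- 290 ms
```

Held-out accuracy is the NLR test-set accuracy on the 12-element sequence
features; sequence recovery is the fraction of acquisitions whose encoded
partial sequence equals the generator's ground-truth order prefix; the
timing gap is how much earlier the last partial-sequence activation occurs
than the steady-state anchor (its magnitude reflects the generator's
plateau placement — only its positive sign is a property of the method).

```r
trials <- recs[recordingIds(res$table)[res$split$test]]
online <- onlineSimulate(res$model, trials, res$restModel,
                         res$thresholds$vectors, seed = 42)
online$perTask
#>        task attempts completed mcr mstMeanMs    mstSdMs
#> 1  Platform       10        10 100  260.7175 14.9443037
#> 2     Point       10        10 100  302.6686  0.2572004
#> 3 Spherical       10        10 100  201.0492 10.7327120
#> 4       Tip       10        10 100  220.0547 11.6581692
```

Every held-out trial is completed (MCR 100%) with motion selection times
of 200–300 ms from movement onset — *Point* decides at the window end
because it recruits only two channels.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/emgseq.R` (`simulate`, `onset`, `evaluate` subcommands, CSV/
JSON in and out).

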