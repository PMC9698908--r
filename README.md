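# ppgaffect

Affective computing from single-channel photoplethysmography (PPG) in R.

A PPG pulse reflects the blood-volume change of one cardiac cycle in the
peripheral microvasculature. Emotional activation reshapes the pulse through
autonomic control of the heart and the vessel bed, and this package
classifies short PPG recordings into emotional states using only five
morphological indices of each beat:

| index | definition | units |
|-------|------------|-------|
| BVA | amplitude from a beat's onset valley to its systolic peak | mV |
| ST  | systolic upstroke time, onset valley to peak | ms |
| DT  | diastolic time, peak to the next valley | ms |
| PPI | interval between consecutive peaks | ms |
| VVI | interval between consecutive onset valleys (= ST + DT) | ms |

The pipeline mirrors a five-stage emotion-recall protocol in hypertensive
patients (sitting baseline, then neutral / anger / happiness / sadness
recall; one 3-min recording per stage; 43 subjects):

1. **Synthetic cohort generation** (`synthesize_cohort`) — raised-cosine
   pulse trains whose per-stage beat statistics follow the published stage
   means and SDs, with subject-level random effects, sensor noise and
   baseline wander, plus a beat-level ground-truth table per record.
2. **Delineation** (`delineate_record`) — zero-phase band-pass filtering,
   prominence- and spacing-gated systolic peak detection, valley location,
   and the five indices per beat.
3. **Featurization** (`featurize_cohort`, `assemble_matrix`) — six 30-s
   segments per recording; mean and SD of each index give 10 features per
   segment; differential features subtract the subject's baseline; z-score
   normalization is fitted on training rows only.
4. **Feature selection** (`full_search`, `ga_select`) — wrapper selection
   with classification accuracy as fitness: exhaustive enumeration of all
   2^n − 1 subsets for 10-feature blocks, a genetic algorithm for the
   20-feature combined block.
5. **Classification and validation** (`train_classifier`,
   `resubstitution_accuracy`, `kfold_cv_accuracy`, `run_experiment`) —
   one-against-all RBF SVM (C = 10, gamma ≈ 1/n after z-scoring), validated
   by resubstitution and by deterministic six-fold segment cross-validation.

No public recordings exist for this protocol, so the synthetic cohort is a
first-class, tested component: every downstream stage is verified against
the generator's ground truth.

## Worked example

Synthesize 30 s of baseline-stage PPG at 1024 Hz with default sensor noise,
delineate it, and reduce it to the 10 segment features:

```r
library(ppgaffect)
rec <- synthesize_record(default_stage_params()[1, ], duration_s = 30,
                         fs = 1024, seed = 42)
beats <- delineate_record(rec$record, filter = "on")
head(beats[, c("onset_s", "peak_s", "bva_mV", "st_ms", "dt_ms", "vvi_ms")], 4)
#>   onset_s peak_s bva_mV  st_ms  dt_ms vvi_ms
#> 1    0.00   0.27  10.78 265.62 705.08 970.70
#> 2    0.97   1.14  11.52 169.92 658.20 828.12
#> 3    1.80   2.01  12.22 210.94 407.23 618.16
#> 4    2.42   2.65   9.60 228.52 672.85 901.37
```

Each row is one beat: the onset valley at `onset_s`, the systolic peak
`st_ms` milliseconds later and `bva_mV` millivolts higher, and the next
valley after a further `dt_ms`. Collapsing the segment to its
representative features:

```r
round(segment_features(segment_beats(beats, 30)), 2)
#> bva_mean  bva_std  st_mean   st_std  dt_mean   dt_std ppi_mean  ppi_std
#>    10.66     3.98   213.84    49.62   655.69    75.17   865.81    81.64
#> vvi_mean  vvi_std
#>   869.53    90.13
```

The 33 beats of this half-minute average a 213.8 ms upstroke and a 10.66 mV
amplitude — one draw from the baseline-stage distribution (population mean
196 ms, 11.8 mV).

## The full analysis

The numbered scripts under `analysis/` run the complete study on a
43-subject synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R       # cohort + ground-truth summary
Rscript analysis/02_delineate_features.R    # delineation, segment features
Rscript analysis/03_baseline_vs_state.R     # baseline-vs-emotion tasks
Rscript analysis/04_emotion_categorization.R  # 2C/3C/4C tasks, 3 feature sets
Rscript analysis/05_feature_selection.R     # full search + GA selection
```

On the shipped cohort seed, stage 3 prints (accuracy %, 10 waveform
features):

```
     validation neutral anger happiness sadness
 resubstitution   86.82 99.81     97.87   96.12
        sixfold   67.64 98.45     92.83   91.67
```

Anger — the strongest vasoconstrictive response in the stage parameters —
is nearly perfectly separable from baseline, while the mild neutral-recall
shift overlaps baseline heavily. Stage 4 shows differential features
(91–92%) beating raw waveform features (86–87%) on the emotion
categorization tasks, and the combined 20-feature set doing best (~94%),
which is the motivation for baseline subtraction: it cancels stable
subject-level offsets. Stage 5's wrapper selection adds another 0.5–1.4
points per cell (combined 20 features: 95.45 / 95.64 / 95.54 % on 2C/3C/4C
with 13–14 features retained), and its incidence grid shows the BVA mean
and differential BVA mean selected in every task — pulse amplitude is the
most informative index.

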