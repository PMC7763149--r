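# behavacc

Classifying animal behaviour from body-mounted tri-axial accelerometers,
built around a four-class shark ethogram: **rest**, **swim**, **vertical
swim** and **chew**. The package takes a 10 Hz, ±2 g stream `(t, x, y, z)`
through the standard biologging chain:

1. **Static/dynamic split** — static acceleration by a centred 5-sample
   moving average per axis; dynamic = raw − static.
2. **Derived channels** — ODBA `= |Xdyn|+|Ydyn|+|Zdyn|`, VeDBA
   `= √(Xdyn²+Ydyn²+Zdyn²)`, movement variation
   `= |Xᵢ₊₁−Xᵢ|+|Yᵢ₊₁−Yᵢ|+|Zᵢ₊₁−Zᵢ|`, energy `= √(X²+Y²+Z²)`, pitch
   `= atan(−Xs/√(Ys²+Zs²))·180/π`, roll `= atan2(Ys, Zs)·180/π`.
3. **Epoch features** — non-overlapping 1 s or 2 s single-behaviour
   windows, each summarised into 66 statistics (mean, SD, min, max,
   skewness, kurtosis of 9 channels; Q10/Q90 of the 6 derived channels).
4. **Ethogram rules** — Welch t-tests on four ODBA/VeDBA summaries decide
   whether the two swimming modes merge into one class.
5. **Model comparison** — event-level 80/20 split, minority up-sampling,
   repeated stratified k-fold tuning of eight classifier types (CART, RF,
   SVM, XGB, C50*, GBM*, Nnet, AvNnet; * = boosted-tree approximations,
   flagged in outputs).
6. **Evaluation** — per-class sensitivity/specificity/precision/F-measure,
   accuracy, macro-averaged F `= ΣFᵢ/M` and Cohen's kappa
   `= (p₀−pₑ)/(1−pₑ)`, plus permutation feature importance.

A seeded synthetic generator emulates the four behaviour signatures
(rest: near-static; swim: 0.7 Hz y-axis tailbeat; vertical swim: ~90°
pitch shift with the largest tailbeats; chew: brief fast x-axis pulses),
so the entire pipeline is testable with no tag data. The package also
bundles reference test-set confusion matrices from a captive Port Jackson
shark study (SVM/RF/XGB at both epoch lengths, 82 test epochs each) that
pin the evaluation layer to independently printed numbers.

## Worked example

```r
library(behavacc)

cfg <- generator_config(session_length = 120, seed = 42)
sch <- sample_schedule(cfg)
head(sch, 3)
#>   event_id      label     start       end
#> 1        1       rest   0.00000  97.10489
#> 2        2       chew  97.10489 101.56990
#> 3        3 swim_floor 101.56990 120.00000

st <- synthesize_stream(sch, cfg)
st
#> <accel_stream> 1200 samples at 10 Hz (120.0 s)
#>   time            x             y         z
#> 1  0.0  0.004955336 -0.0119807288 1.0171701
#> 2  0.1 -0.006842633 -0.0025726346 0.9939851
#> ...

tab <- build_feature_table(list(demo = list(stream = st, events = sch)), 2)
dim(tab)   # 59 epochs x (66 features + label, event_id, session)
```

The rest posture reads ≈ (0, 0, 1) g with small noise; a 2 s epoch of it
yields 66 named statistics (`x_mean`, `odba_q90`, ...). Scaling up to the
default 4 sessions × 600 s and the full eight-model comparison is one
call: `run_pipeline(list(seed = 1))` (add `quick = TRUE` for the reduced
single-configuration grids).

Feeding the bundled reference counts through the metric layer:

```r
class_metrics(reference_confusion_matrices()$SVM_2s)
#> <class_metrics> n = 82 | accuracy 89.0% | macro-F 90.0% | kappa 0.841
#>          class sensitivity specificity precision f_measure
#>           chew       68.4%       98.4%     92.9%     78.8%
#>           rest      100.0%       93.5%     83.3%     90.9%
#>           swim       91.4%       91.5%     88.9%     90.1%
#>  vertical_swim      100.0%      100.0%    100.0%    100.0%
```

Read: of the 19 observed chew epochs the SVM recovered 13 (sensitivity
68.4%), and of the 14 epochs it called chew, 13 were right (precision
92.9%); overall 73/82 epochs correct (accuracy 89.0%), with macro-F 90.0%
weighting the rare classes equally and kappa 0.841 correcting agreement
for chance.

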