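# emgintent

Motion-intent recognition from a **single surface-EMG (sEMG) sensor**.

Human–machine interfaces for assistive devices usually multiply sensors to
gain robustness. This package implements the opposite strategy: extract as
much as possible from one channel. An electrode over one muscle (e.g. the
trapezius descendens, or the platysma in the neck) records that muscle's
activity *and* attenuated crosstalk from its neighbours, and different
movements leave distinct signatures in the signal's frequency domain. The
package is aimed at researchers prototyping sEMG-driven controllers — e.g.
neuroprosthesis triggering for users with tetraplegia — who need transparent
(white-box) classifiers and an end-to-end, reproducible evaluation harness.

## What it computes

1. **Conditioning** — 20–500 Hz 4th-order Butterworth band-pass (causal by
   default, zero-phase optional), optional FIR decimation (×4, order 80) for
   10 kHz recordings, and a rectified 2 Hz-low-pass envelope for plotting.
2. **Features** — over a 0.2 s window sliding every 10 ms, the Welch PSD
   (0.05 s Hann segments, 50% overlap, ≤ 8 Hz bins) is reduced to four
   features on the 20–500 Hz band: band power `P = ∫ S(f) df`, PSD peak
   `max S(f)`, mean frequency `MNF = ∫ f·S(f) df / ∫ S(f) df` and median
   frequency `MDF` with `∫_0^MDF S(f) df = P / 2`.
3. **Classifiers** —
   * a CART decision tree: Gini impurity `G = 1 − Σ p_c²`, balanced class
     weights `w_c = N / (n_classes · N_c)`, pre-pruning (max depth, min leaf,
     min split) chosen by grid search;
   * a thresholding classifier: per action occurrence, take the maximum of
     each feature over its action window; the per-class medians of those
     maxima are lower bounds and (multi-class) the third quartiles are upper
     bounds; a vector gets the highest class whose bounds it satisfies on
     all four features.
4. **Evaluation** — ground-truth *action windows* of twice the nominal
   movement duration starting at each instruction; a window counts as any
   wrong action predicted inside it, else as the correct action if detected,
   else no-action; stratified k-fold cross-validation over windows; optional
   testing against unknown actions.
5. **Simulation** — a synthetic sEMG generator (band-limited bursts with
   effort-coupled spectra, crosstalk gains, calibrated SNR, instruction-cycle
   timing) with presets for the able-bodied 10 kHz protocol (`protocol_a`)
   and the tetraplegic platysma protocol (`protocol_b_p2`), so the whole
   pipeline runs with no external data.

See the methods vignette (`vignettes/single-sensor-emg.Rmd`) for the model
details and design rationale.

## Worked example

Simulate the platysma-sensor protocol (two days, 15 platysma contractions PC
and 15 shoulder raises SR per day), extract features and cross-validate the
three-way thresholding classifier on day 1:

```r
library(emgintent)
study <- simulate_preset("protocol_b_p2", seed = 7)
day1  <- study[[1]]
day1
#> <sim_session> day 1: 30 events, 749.0 s @ 2150 Hz
#>   realised SNR (dB): PC=9.04, SR=5.45

track <- session_features(day1)           # 73179 feature vectors
cv <- crossvalidate(track, day1$windows, method = "threshold",
                    k = 5, seed = 7, mode = "multiclass")
cv$confusion
#>            prediction
#> truth       no_action  PC  SR
#>   no_action       331   0   0
#>   PC                8   7   0
#>   SR               11   0   4
cv$accuracy
#> 0.947
```

The realised SNRs confirm the generator hit its calibration targets (9 and
5.5 dB). The confusion matrix is in *windows*: all 331 no-action windows are
clean (no false triggers — the property that matters for a neuroprosthesis),
while about half of the action occurrences are detected, which is the
intrinsic ceiling of a median-of-maxima threshold on held-out occurrences;
the overall window accuracy is 94.7%. The fitted model orders classes by
band power:

```r
fit_thresholds(instance_maxima(track, day1$windows), "multiclass")
#> <threshold_model> multiclass, classes by ascending power: SR < PC
```

The decision-tree pipeline is wrapped the same way:

```r
res <- eval_protocol_a(seed = 1)   # binary SR, 4-way, and unknown-action runs
res$binary$accuracy; res$multiclass$accuracy; res$binary_unknown$accuracy
```

## Command line

A thin CLI over the same functions lives at `inst/cli/emgintent`:

```sh
Rscript inst/cli/emgintent simulate --preset protocol_b_p2 --seed 7 --out data/
Rscript inst/cli/emgintent features --in data/recording_day1.csv --out feats.csv
Rscript inst/cli/emgintent train    --features feats.csv --events data/events_day1.csv \
                                    --method threshold --mode multiclass --out model.json
Rscript inst/cli/emgintent evaluate --features feats.csv --events data/events_day1.csv \
                                    --method threshold --folds 5 --seed 7 --out eval/
```

`--config file.yaml` supplies defaults; explicit flags override it.

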