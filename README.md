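# fetaltdi

ECG-free analysis of color tissue-Doppler (TDI) myocardial velocity traces
of the fetal heart.

Fetal cardiac function can be assessed from the longitudinal velocity of
the myocardium, sampled by a region of interest (ROI) at the
atrioventricular (AV) plane. Without a fetal ECG, however, the cardiac
cycle's time events must be found from the velocity signal itself.
`fetaltdi` does this automatically: each transition of myocardial work
produces an abrupt *shift* in myocardial acceleration, and the package
segments every cardiac cycle into its six phases — atrial contraction
(the cycle start), pre-ejection, ventricular ejection, post-ejection,
rapid filling and slow filling (diastasis) — by detecting those shifts
and matching them to a phase template. From the segmentation it extracts:

* **peak myocardial velocities** Sm (systolic, > 0), Em (early diastolic,
  < 0) and Am (atrial contraction, < 0), in cm/s;
* **cycle time intervals**: the six phase durations in ms, which sum
  exactly to the cycle length;
* an **acceleration score** (3 = clear, well-defined shifts; 2 = less
  well-defined, often biphasic; 1 = indistinct, flat) grading trace
  quality;
* **feasibility** and **ROI-comparison summaries** (median (IQR) percent
  differences against the 2 × 2 mm reference ROI).

Formally, for a velocity trace $v(t)$ sampled at rate $f_s$ (≈190 Hz), the
analyzer computes $a(t) = \dot v(t)$ by central differences after a
3-point moving average and one of four filter settings, estimates the
period $T$ from the autocorrelation within 80–220 bpm, and assigns
acceleration-shift candidates $c_1 < \dots < c_6$ to the phase onsets by
minimizing $\sum_e (c_e/T - p_e)^2$ subject to ordering, per-event
tolerance windows, and allowed shift kinds, where $p_e$ are template prior
fractions. Then
$S_m = \max_{t \in [c_3, c_4)} v(t)$,
$E_m = \min_{t \in [c_5, c_6)} v(t)$,
$A_m = \min_{t \in [c_1, c_2)} v(t)$.

Because no raw fetal echo recordings are public, the package includes a
synthetic fetal heart: an AV-plane velocity waveform with the six-phase
morphology, exact zero net displacement per beat, linear apex-ward decay
over a gestational-age-dependent ventricular length (15.6 / 23.3 /
32.5 mm for GA groups I/II/III), ROI spatial averaging, additive Gaussian
noise, and exact ground-truth event times for every cycle.

The intended users are researchers in fetal echocardiography and
physiological signal processing who want a tested, scriptable
implementation of acceleration-shift cycle segmentation with a simulator
for method validation.

## Worked example

```r
library(fetaltdi)

params <- heart_model_params(heart_rate = 140, noise_sd = 0.5, ga_weeks = 38)
field  <- generate_field(params, seed = 42)
trace  <- sample_roi(field, recommend_roi(38), label = "left_wall")
result <- analyze_trace(trace)
result
#> <analysis_result 'left_wall'> success
#>   6 cycles, filter setting 1, acceleration score 3
#>   Sm 4.58  Em -5.34  Am -3.94 cm/s (medians across cycles)

round(result$intervals$durations, 1)
#> atrial_contraction       pre_ejection           ejection      post_ejection
#>               66.3               17.0              154.7               17.0
#>      rapid_filling       slow_filling
#>              109.5               64.2
```

Reading: the noisy recording (noise 0.5 cm/s on peaks of ~5 cm/s) was
analyzable with the mildest filter setting; all six complete cycles
segmented, earning quality score 3. The recovered peaks are slightly below
the generator's +5.0 / −6.0 / −4.5 cm/s because the 6 × 4 mm ROI averages
myocardium away from the AV-plane — exactly the ROI-size attenuation the
`roi_study()` experiment quantifies. The ejection duration, 154.7 ms, is
within one frame of the ground-truth 0.35 × 428.6 = 150 ms. Feasibility
percentages and ROI-length fractions reproduce printed clinical arithmetic
exactly:

```r
feasibility(data.frame(wall = c("right_wall", "left_wall", "septum"),
                       n_success = c(81, 71, 51), n_total = c(87, 87, 87)))
#> <feasibility_summary>
#>   right_wall   93 % (81/87)
#>   left_wall    82 % (71/87)
#>   septum       59 % (51/87)
#>   overall      78 % (203/261)
roi_fraction(8, 32.5)
#> [1] 25
```

## Command line

```sh
Rscript inst/exec/fetaltdi simulate  --ga 38 --n 5 --seed 7 --out data/
Rscript inst/exec/fetaltdi analyze   --in data/trace_001.csv --out result.json
Rscript inst/exec/fetaltdi score     --in data/trace_001.csv
Rscript inst/exec/fetaltdi roi-study --ga 33 --seed 1 --out roi.csv
Rscript inst/exec/fetaltdi report    --in result.json --out summary.json
```

`--seed` controls all randomness; `--config cfg.yaml` overrides the
defaults in `default_config()`; `analyze --strict` exits 2 when a trace is
unanalyzable.

## Documentation

The methods vignette (`vignettes/automated-tdi-analysis.Rmd`) describes
the model, the synthetic generator and its limits, the numerical choices,
and the design decisions in detail.
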