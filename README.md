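# neuritemito

Quantification stack for in-vivo fluorescence imaging of mitochondria in
neuronal processes (developed around *C. elegans* AVA interneuron
experiments, but generic over calibrated TIFF stacks). The package covers
the five measurement modalities such a study chains together, plus the
statistical layer, plus a synthetic-microscopy generator with recorded
ground truth so every stage is testable by parameter recovery:

| stage | what it measures |
|---|---|
| `calcium_events` | ΔF/F_min normalization of GCaMP traces, event detection, per-event peak and area, total activity, stimulus-aligned evoked responses |
| `ratiometric_ros` | per-mitochondrion roGFP excitation ratio F_ratio = (F405−B405)/(F488−B488) at the best-focus z-plane, with automatic segmentation, background annuli, and BIC-selected unimodal/bimodal population analysis |
| `frap_analysis` | FRAP series over a pre/0–16 min schedule, percent and subtract normalizations, one-phase recovery fit Y(t) = plateau·(1−e^(−kt)), extra sum-of-squares F-test curve comparison, linescan puncta areas |
| `kymograph_transport` | kymographs along a neurite path, transport-event detection with sub-pixel tracking, events/minute, instantaneous segment velocities |
| `proximity_analysis` | boundary-to-boundary axial distance of each mitochondrion to the nearest receptor punctum and the proximal (<1 µm) fraction |
| `stats` | one-way ANOVA with Dunnett's many-to-one test, paired t, ROUT outlier removal (Q = 1%), the FRAP animal-exclusion rule, Pearson effect-size screen |

The core quantities, in the field's notation:

- ΔF/F_min = (F − F_min)/F_min with F_min the mean of the lowest 5% of
  background-corrected samples.
- F_ratio = (F405 − B405)/(F488 − B488), higher = more oxidized.
- FRAP percent normalization: 100·(F(t) − F(0))/(F_pre − F(0)); recovery
  model Y(t) = plateau·(1 − e^(−kt)); curves compared by
  F = ((SS_shared − SS_separate)/Δdf)/(SS_separate/df), Bonferroni-adjusted,
  significant at adjusted p < 0.01.
- Transport rate = events · 60/duration_s; a 1 s stimulus every 30 s is
  33.3 mHz.

## Worked example

```r
library(neuritemito)

# simulate a 2.5 min mitoGCaMP recording: 5 stimuli at 30 s period
proto <- stimulation_protocol(1, period_s = 30, total_duration_s = 150)
proto$frequency_mHz
#> [1] 33.33333

sim <- gen_calcium_recording(proto, list(mito_spec("first-dominant")), seed = 1)
dff <- compute_dff(sim$traces[[1]])
ev  <- detect_events(dff)
round(ev$peak_dff, 3)
#> [1] 1.535 1.010 0.666 0.428 0.289
max_event_amplitude(ev)          # largest evoked ΔF/F_min of this mitochondrion
#> [1] 1.534569
round(total_activity(dff, ev), 2) # summed event area, ΔF/F·s
#> [1] 14.24
```

The five detected peaks decay stimulus-by-stimulus — the "first-dominant"
responder class — and the first-window amplitude (~1.5 ΔF/F_min) matches
the generator's truth record (`sim$truth$events$amplitude[1]` = 1.5) to
within the 1%-noise measurement error.

A ratiometric example with known redox heterogeneity:

```r
sc <- gen_rogfp_scene(n_mito = 6,
                      ratio_model = list(means = c(0.05, 0.09),
                                         sds = c(0.01, 0.01),
                                         weights = c(0.5, 0.5)), seed = 7)
ratios <- measure_scene_ratios(sc$stack405, sc$stack488)
pop <- population_modality(draw_ratio_population(200,
         list(means = c(0.05, 0.09), sds = c(0.01, 0.01),
              weights = c(0.5, 0.5)), seed = 7))
pop
#> <modality_report> 2 component(s); means = 0.051, 0.0896; BIC1 = -952.5, BIC2 = -1001.1
```

## Command line

```sh
neuritemito simulate  --config sim.json   --out out/sim --seed 3
neuritemito calcium   --config ca.json    --out out/ca
neuritemito frap      --config frap.json  --out out/frap
```

(`exec/neuritemito` is the launcher; configs are JSON, see the vignette
for per-stage schemas. Every run writes its outputs as CSV/JSON plus a
`run_manifest.json` recording inputs, parameters, seed, and version.)

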