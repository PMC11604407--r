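# cardiogate

ECG-less (intrinsic) retrospective cardiorespiratory gating for micro-CT,
with the downstream cardiac-function readouts, validated end to end on a
synthetic beating mouse-thorax phantom.

Mouse cardiac CT must freeze a heart beating at 5-10 Hz during a scan
lasting a minute. Instead of hardware triggers, retrospective gating reads
the physiology out of the projection data itself: surrogate respiratory and
cardiac signals are extracted by summing pixel intensities inside ROIs that
a thorax template places via mutual-information registration; projections
acquired during inspiration are rejected (~70% survive); each survivor is
assigned its fraction of the cardiac cycle from the detected beat-to-beat
intervals -- so variable cycle lengths are handled exactly -- and grouped
into 12 phases (`[k/12, (k+1)/12)`; at 400 bpm a cycle is 150 ms and a
phase 12.5 ms); each phase is reconstructed separately. From the per-phase
images the package measures

* EDV / ESV (max / min cavity volume over bins) and **EF** = (EDV−ESV)/EDV,
* LVIDd / LVIDs and **FS** = (LVIDd−LVIDs)/LVIDd,
* segmental endocardial strain **ΔL/L₀** over six base-to-apex segments
  plus their mean (GLS),
* heart-failure severity (EF <20% severe, 20-40% moderate, >40% mild) and
  fibrosis severity (>40% / 20-40% / <20%) classes.

Every stage is exercised against a 4D digital thorax slice whose cardiac
phase, respiratory state and cavity area are known analytically: a
contrast-filled LV cavity contracting with a raised-cosine waveform
(default area-EF 60%, 400 bpm, 5% per-beat jitter), diaphragm motion with a
30% inspiratory duty cycle at 120 breaths/min, continuous-rotation
parallel-beam acquisition (720 views/rotation, 200 µm detector pitch, 40
frames/s, 60 s), optional Poisson photon noise. Reconstruction is by
filtered back-projection (Ram-Lak / Shepp-Logan) and by ordered-subset
SIRT (24 subsets, 3 iterations), whose image levels stay consistent across
phase bins regardless of per-bin projection counts.

## Worked example

The numbered scripts under `analysis/` run the study stage by stage
(simulate → gate → reconstruct → metrics → rate sweep) and write their
tables under `results/`. The whole chain in code:

```r
library(cardiogate)

cfg <- run_config(seed = 1)          # default phantom + geometry + gating
res <- run_pipeline(cfg, out_dir = "results/run")
res$gating
#> gating_result: 2400 projections; 71.6% retained
#>   est heart rate: 396 bpm; est resp rate: 120 /min
#>   per-bin counts: 149 136 148 140 144 140 143 140 150 139 149 141
res$metrics
#> cardiac_metrics:
#>   EDV 14.80 uL (bin 0), ESV 6.36 uL (bin 4)
#>   EF 57.0% (mild heart failure class), FS 33.3% (LVIDd 3.60 / LVIDs 2.40 mm)
#>   GLS -0.351; cycle 151.5 ms, phase 12.63 ms at 396 bpm
```

Reading: of 2400 acquired projections, 71.6% survive inspiration rejection
(the phantom spends 30% of each breath inspiring); the heart rate is
recovered at 396 bpm against a configured 400 with 5% beat jitter (the
realized mean rate of a jittered scan sits slightly below nominal); the
phase-resolved cavity volumes peak in bin 0 (end-diastole) and bottom in
bin 4 (end-systole, 35% into the cycle), giving EF 57.0% against the
phantom's analytic 60% -- within the accuracy the 12-bin time averaging
permits. Assigned cardiac phases track the phantom truth with a circular
MAE of ~0.02 cycle (`analysis/02_gate.R` prints it), and
`analysis/03_reconstruct.R` shows reconstructed soft-tissue levels varying
<2% across bins holding 136-150 projections for the iterative method.
`analysis/05_rate_sweep.R` sweeps 100-700 bpm and recovers rates up to
700 bpm within ±5%.

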