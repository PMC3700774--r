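# ciliamotion

Quantitative analysis of passive, flow-driven primary-cilium motion in
intravital fluorescence time-lapse movies of the kidney, together with a
fully seeded synthetic movie generator so that every stage of the analysis
can be validated against known ground truth.

## The problem

Primary cilia in the proximal tubule of a living, anesthetized mouse do not
stand perpendicular to the epithelium: the high filtrate flow bends them
flat along the tubule wall, pivoting about a fixed point just above the
base. Under pulsatile flow they oscillate through an arc of roughly 106°
at about 4.6 Hz, spending the majority of each cycle pressed against the
wall; the whole field moves in unison, and the motion ceases at death, the
cilia relaxing back to perpendicular. Quantifying this motion from
time-lapse movies (≈26 frames/s, tens of seconds) requires: a
range-of-motion projection, recovery of the swept arc and its pivot, a
line-scan kymograph along the tip path, a tip-angle trace, and spectral,
sweep, dwell-time, and synchrony statistics.

## The model

Each cilium is modelled as a rigid distal segment of length *L* pivoting
about a fixed hinge *h* pixels above its base on the wall (x axis). The
in-plane tip angle (0° = wall-parallel downstream, 90° = perpendicular)
follows the saturating-dwell drive

θ(t) = θ_min + S · u(t)^p,  u(t) = (1 + sin(2π f t + φ)) / 2

with sweep span *S*, drive frequency *f*, and shape exponent *p* ≥ 1. For
p > 1 occupancy concentrates near the wall-parallel extreme: the fraction of
a cycle spent in the lowest tenth of the path is
1/2 + asin(2·0.1^(1/p) − 1)/π, which exceeds one half for p > log₂10 ≈ 3.32
(the default preset uses p = 4, giving 0.54). Movies are rendered with a
Gaussian PSF, a per-cell photon budget diluted across the cell's cilia
(brightness ∝ 1/N), uniform background, and Poisson shot noise.

Analysis statistics: mean-subtracted Hann-windowed FFT with parabolic peak
interpolation (dominant frequency), min–max or percentile sweep, equal-angle
path-decile dwell fractions, pairwise phase-locking values from the
analytic-signal phase at the consensus frequency, and a three-way motion
classification (oscillating / static_bent / static_perpendicular).

## Worked example

```r
library(ciliamotion)

sc  <- scenario_preset("renal_anesthetized")  # 4.58 Hz, 106 deg, 26 fps, 40 s
sim <- simulate_field(sc)                     # 1040-frame Poisson-noised movie
report <- cmd_analyze(sim$movie)              # full chain, auto arc fit
tidy(report)
#>   cilium_id frequency_hz resolution_hz     snr freq_valid ... motion_class
#> 1         1         4.58         0.025 669276. TRUE       ... oscillating
report$per_cilium$dwell[[1]][1, ]
#>     bin angle_lo angle_hi fraction
#> 1     1     1.60     12.5   0.518        # majority of time wall-proximal
cmd_compare(report, sim$traces)
#>   cilium_id frequency_error_hz sweep_error_deg angle_rmse_deg dwell_tv_distance
#> 1         1         0.00000479            3.43          0.964            0.0250
```

The recovered frequency (4.580 Hz, resolution 0.025 Hz) and the
wall-proximal dwell fraction (0.52 from the noisy movie; 0.54 in the
ground-truth trace) match the generator's stated kinematics; the per-frame
tip-angle RMS error of the full pipeline is under 1°.

A thin command-line front end ships in `inst/cli/ciliamotion`
(`simulate` / `analyze` / `compare`; exit codes 0/2/3 for
success / input error / stage failure).

## Acceptance script

`scripts/acceptance.R` recomputes the headline motion parameters from
scratch with the installed package — the dominant frequency of the analytic
renal tip-angle trace, the dominant frequency recovered by the complete
noisy movie pipeline, and the min–max sweep angle — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The generator is phenomenological (rigid pivoting segment, not an elastic
cantilever), two-dimensional, and single-filament per region of interest;
see the methods vignette (`vignettes/cilia-motion-analysis.Rmd`) for the
model's assumptions, parameter choices, and what a passing test does and
does not establish.
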