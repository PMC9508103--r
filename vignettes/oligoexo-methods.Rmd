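---
title: "Models and methods behind oligoexo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oligoexo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoexo)
```

# Scope

`oligoexo` implements the quantitative analysis of pHluorin-reported
exocytosis in oligodendrocytes, from raw time-lapse stacks to the
interpretive models built on top of the event statistics: photobleaching
correction and dF/F normalisation, detection of fusion puncta by a
baseline-SD criterion, classification of full-vesicle fusion versus
kiss-and-run by the border decay ratio, paranodal spatial statistics
within myelin sheaths, node-of-Ranvier classification from dual-channel
line scans, the N·L·I myelin-coverage model and a spherical-vesicle
membrane budget. Because no raw imaging data are publicly deposited for
this system, a seeded synthetic-imaging module generates ground-truthed
stacks so that every downstream stage is testable end to end.

# Detection model

Detection expects a bleach-corrected, registered single-channel stack.
The criterion is expressed entirely in noise-relative units, which makes
it invariant to any positive rescaling of the intensities:

1. `correct_bleaching()` fits `mean(t) = A exp(-t/tau) + C` to the
   frame-wise spatial mean and divides each frame by the fitted curve
   normalised to `t = 0`. A linear pre-test skips the fit when the frame
   means show no decline beyond their own residual scatter, so stacks
   without bleaching pass through unchanged (`tau = Inf`).
2. `compute_dff()` forms `(F - Fbar)/Fbar` per pixel against the
   all-time average `Fbar`; pixels with non-positive temporal means
   (outside the cell) are zeroed. dF/F outside the cell mask is also
   zeroed during detection: a near-zero denominator otherwise produces
   meaningless maxima at the mask edge.
3. Candidate local maxima on dF/F (pre-filtered at
   `candidate_threshold_sd` robust SDs, default 5) are merged within
   `min_separation_um` (1 µm) and grown into a connected ROI above a
   third of the peak. The baseline F0 and SD are the mean and SD of the
   ROI trace over the 4 frames preceding the event; acceptance requires
   a peak at least 4 SD above F0, at least 3 consecutive
   supra-threshold frames, a 2-D Gaussian shape at the peak frame, and
   a total centroid displacement below 0.5 µm (non-motile).

Two thresholds deserve comment because the underlying publications give
no numeric value for them. *Gaussian shape* is scored as the R² of a
symmetric 2-D Gaussian with offset fitted to the baseline-subtracted
peak-frame patch (half-width 0.3 µm; subtracting the pre-event baseline
cancels static cell structure). The default acceptance threshold is
R² ≥ 0.7: fusion puncta ride on a spreading pedestal of
membrane-incorporated fluorophore and are not single Gaussians, and on
patches sized to the punctum the R² of a genuinely punctate event
plateaus near 0.75–0.9 even at high amplitude. At 0.7 the gate still
rejects diffuse or elongated intensity fluctuations while accepting
8–10 SD puncta. *Non-motile* is operationalised as total
intensity-weighted centroid displacement ≤ 0.5 µm over the
supra-threshold run, measured on a window wide enough (displacement
limit + 0.5 µm) to see genuine drift.

# The synthetic-imaging model

`render_stack()` produces
`background × cell_mask × exp(-t/tau_bleach) + Σ events + noise`, with
events evaluated analytically at pixel centers (no rasterisation) and
i.i.d. Gaussian read noise added last. Amplitudes are specified in
multiples of the noise SD and normalised so that the *realised* peak
pixel height equals `amplitude_sd × noise_sd`, whatever the kinetics —
so the SD-based detection criterion reads directly on the generator's
amplitude parameter. Defaults emulate widefield imaging of cultured
oligodendrocytes at 250 ms/frame for 1 min, 0.1 µm pixels, a
diffraction-limited PSF (σ = 0.10 µm) and ~2% read noise.

Event kinetics are the one place where the generator goes beyond the
minimal textbook picture, because the downstream discriminant (the
border decay ratio) is sensitive to kinetic detail:

* **Full-vesicle fusion.** A fluorescence rise with time constant
  `rise_tau_s` (0.2 s; pHluorin dequenching is not instantaneous)
  precedes an exponential decay (`decay_tau_s`, 1.5 s). A fraction
  `full_fusion_immobile_fraction` (0.4) of the fluorophores remains
  incorporated at the fusion site at PSF width; the rest is dispersed
  by the vesicle collapse over `full_fusion_spread_sigma_um` (0.3 µm)
  within a frame and then continues to spread diffusively
  (`σ² = spread² + 2 D t`, `D` = 0.025 µm²/s). Total intensity is
  conserved up to the decay, so summed above-background intensity is
  constant when decay is disabled while the peak pixel falls — the
  defining signature of radial spreading. Because the dispersed pool
  already covers the 250–500 nm annulus at the aligned peak and then
  drains outward, the border trace decays slightly faster than the
  center, reproducing the empirically observed full-fusion border
  decay ratio just below 1. With these defaults the noiseless ratio is
  ≈ 0.90, chosen once to sit near the reference population center of
  0.89; these are emulation parameters, not measurements.
* **Kiss-and-run.** The main punctum keeps a fixed width while its
  amplitude decays (no spreading). A faint halo
  (`kiss_halo_fraction` = 0.06 of the peak, σ = 0.35 µm) decaying five
  to ten times faster (`kiss_halo_tau_factor` = 0.1) emulates the brief
  cloud of cargo released through the transient fusion pore; it is what
  gives the border trace its fast, small decay rather than leaving it
  entirely at the noise floor. The halo is capped so that the noiseless
  annulus gain stays below 5% of the center peak (measured: ≈ 4.7%),
  preserving the non-spreading phenotype.

The default amplitude (20 SD) reflects that pHluorin fusion events are
bright relative to camera read noise — the vesicle lumen dequenches all
at once — and is the regime in which the 250–500 nm annulus, whose mean
intensity is intrinsically only a few percent of the peak, carries
enough signal for decay fitting. Detection-oriented tests use dimmer
(8–10 SD) events; the detection criterion itself is amplitude-calibrated
by construction.

What the generator does **not** emulate: optics-accurate PSFs, Poisson
shot noise (the additive-Gaussian choice makes the SD criterion exactly
interpretable; a shot-noise flag is reserved), camera gain or offset,
stage drift or registration error, 3-D structure, and two-color
bleed-through. Passing tests on this generator therefore demonstrate
correctness of the analysis logic under the stated statistical
assumptions, not robustness to every artifact of real microscopy.

# Fusion-mode classification

For each event, `extract_traces()` measures the mean intensity in a
250 nm-radius disk (center) and in the 250–500 nm annulus (border =
(outer-disk sum − inner-disk sum)/annulus pixel count), with disk
membership decided by pixel-center distance — at 0.1 µm pixels the
inner disk holds 21 pixels. Traces are aligned by re-assigning the
center maximum to t₀ (`align_to_peak()`), and both are fitted with
`A exp(-t/τ) + C` (`fit_decay()`); the offset accommodates the nonzero
membrane baseline, and the half-life is reported analytically as
`τ ln 2`. Fits with R² < 0.5, vanishing amplitude, or τ outside
`[frame interval/10, 100 × span]` are invalid. Both fits are restricted
to the event's decay segment — `t ≤ 3` center time constants, estimated
from an initial center fit — so the long post-event noise tail does not
dominate the least squares.

The border decay ratio `t½(border)/t½(center)` clusters into two
populations; the higher-mean component (reference: 0.89 ± 0.14) is full
fusion, and the classification threshold is `mu − 3σ` (0.47 under the
defaults), boundary-inclusive. The rule is one-sided — the minimal
reading of the stated criterion — with a strict two-sided variant
behind `two_sided = TRUE` (ratios above `mu + 3σ` then become
`unclassifiable`). `fit_ratio_population()` re-fits the two-component
Gaussian mixture to an experiment's own ratios (mclust, deterministic
model-based initialisation, so results are seed-free), falling back to
the reference values below 20 valid ratios or for degenerate mixtures.

One classification rule is this package's own: when the center decay
fits cleanly but the border trace has no fittable decay (amplitude
indistinguishable from zero, or no structure above the annulus noise
floor), `classify_events()` calls the event kiss-and-run by default
(`no_border_signal_as_kiss`). The absence of persistent border
fluorescence *is* the non-spreading phenotype — the limit of a border
half-life of zero — and leaving such events unclassifiable would
systematically discard the dimmest kiss-and-run events.

# Spatial statistics within sheaths

A sheath is a 1-D coordinate system of length L with 3 µm paranodal
margins at each end; an event at `s ≤ 3` or `s ≥ L − 3` is paranodal
(boundary inclusive, mirroring the fusion-rule convention). For sheaths
with `L ≤ 6` µm the whole sheath is paranodal. Under spatial uniformity
the expected paranodal fraction is `min(6/L, 1)`; `summarize_spatial()`
reports the mean ± SEM of per-sheath fractions — the sheath, not the
event, is the unit of analysis, matching how such data are reported —
with an event-weighted variant available. No hypothesis test is
attached by design; the summary mirrors the descriptive mean ± SEM
reporting convention.

# Morphometry

* **Coverage model:** regional myelin coverage is approximated by
  N · L · I (oligodendrocyte count × mean sheath length × mean sheaths
  per cell); genotype comparisons use the ratio, which is invariant to
  any common rescaling.
* **Membrane budget:** each full fusion deposits the surface of one
  spherical vesicle, `π d²` (the diameter is the configured unit to
  avoid radius/diameter confusion). With 23 events/min, 80% full
  fusion, 48 h, and 100–200 nm vesicles this yields 52,992 events and
  1665–6659 µm², i.e. 27.7–111.0% of a measured 6000 µm² of added
  membrane. Outputs are exact; a `printed` presentation applies
  3-significant-figure areas and whole-percent truncation.
* **Node classification:** maxima are counted per channel on optionally
  smoothed line scans (default σ = 2 samples, prominence ≥ 20% of
  range). Prominence uses the standard topographic definition (walk to
  the first strictly higher point, base = minimum en route); plateaus
  count once at their center. Both channels are thresholded against
  their *joint* intensity range, so a channel containing only noise
  reports no maxima — the profile-based equivalent of the binary
  thresholding the original workflow applied before counting. The rule
  table is: Caspr 2 + AnkG 1 → mature; 1 + 1 → heminode; a maximum in
  exactly one channel → cluster; anything else → none (flagged).
* **Sheath diameter:** the distance between the two most prominent
  maxima of a perpendicular line scan — most prominent rather than
  first two, for robustness to shoulder noise; more than two qualifying
  maxima flags the measurement ambiguous.

# Numerical choices and degenerate inputs

* Physical coordinates are micrometres from the top-left pixel center;
  pixel indices are 0-based in coordinates, 1-based in R arrays;
  nm-to-pixel rounding is round-half-up via distance comparison with a
  relative 1e-9 guard at the disk rim (grid arithmetic otherwise drops
  boundary pixels).
* Nonlinear fits use Levenberg–Marquardt (minpack.lm) with multi-start
  over a small τ grid; ties and non-convergence degrade to explicit
  invalid states with reason codes, never silent numbers.
* Constant traces, empty sheaths, flat profiles, edge-clipped annuli
  and zero-rate simulations all take explicit, tested paths.
* One top-level seed spawns label-keyed substreams
  (`substream_seed()`), so each stage is independently reproducible and
  bit-identical under identical inputs.

# Problem sizes used by the test suite

The suite validates detection on 50 seeded 100×100×120 stacks with six
implanted 10-SD events each (recall and precision ≥ 0.95 against ground
truth), decay fitting on a noiseless τ grid plus 200 noisy replicates at
SNR 10 (median τ within 5%), fusion-mode recovery on 500 simulated
events per mode at 20 SD (≥ 95% accuracy; fitted full-fusion mixture
mean within [0.7, 1.1]), the spatial null on 200 seeded 25-sheath
replicates against the closed form, node classification on 300
noiseless and 500 noisy profiles, and maxima counting exhaustively
against a brute-force oracle on all ternary profiles up to length 8.
These sizes give stable statistics for every stochastic criterion while
keeping the full suite to a few minutes on one CPU.

# Known limitations

* The kinetic constants of the event model (decay, diffusion, rise,
  halo) are emulation parameters calibrated once so the simulated
  full-fusion ratio population centers near the reference 0.89; they
  are not measurements, and analyses of real data should re-fit the
  ratio mixture with `fit_ratio_population()`.
* Inputs are assumed registered; rigid-registration preprocessing is
  out of scope.
* The detector's candidate generation (local maxima on dF/F) is
  validated against this package's acceptance criteria, not against
  any external implementation's internals.
* Sheath event positions are 1-D inputs; tracing sheaths out of images
  is not implemented.
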