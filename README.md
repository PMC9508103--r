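# oligoexo

Quantitative analysis of pHluorin-reported exocytosis in
oligodendrocytes, and the morphometric models used to interpret it.

Oligodendrocytes wrap axons in myelin, a membrane expansion of several
thousand µm² per cell within days. VAMP2/3-dependent vesicle fusion
delivers that membrane, and pH-sensitive pHluorin reporters make single
fusion events visible as transient fluorescent puncta in time-lapse
microscopy. `oligoexo` provides the full analysis chain for such data:

* **Event detection** — photobleaching correction by exponential fit,
  ΔF/F normalisation against the all-time average, and detection of
  non-motile Gaussian-shaped puncta whose ROI intensity rises at least
  4 baseline standard deviations above the pre-event baseline
  (F₀, mean of the 4 preceding frames) for ≥ 3 consecutive frames;
  events are assigned to soma vs. processes/sheet by a soma mask.
* **Fusion-mode classification** — each event's fluorescence is
  measured in a 250 nm center disk and the 250–500 nm border annulus;
  after aligning to the center maximum, both traces are fitted with
  `A·exp(−t/τ) + C` and the **border decay ratio**
  t½ᵇᵒʳᵈᵉʳ/t½ᶜᵉⁿᵗᵉʳ classifies the event: ratios within 3 SD of the
  full-fusion population (0.89 ± 0.14) are full-vesicle fusion, ratios
  below μ − 3σ = 0.47 are kiss-and-run. A two-component Gaussian
  mixture can re-fit (μ, σ) from the data.
* **Spatial statistics** — the fraction of sheath events within the
  3 µm paranodal margins, versus the uniform-placement expectation
  min(2·3/L, 1) averaged per sheath.
* **Morphometry** — node-of-Ranvier classification from Caspr/AnkG
  line-scan maxima (2+1 mature, 1+1 heminode, single-channel cluster);
  sheath diameter as the distance between the two most prominent
  MBP-track maxima; the myelin-coverage model N·L·I (cell count ×
  mean sheath length × sheaths per cell) with genotype ratios; and the
  spherical-vesicle membrane budget n·π·d² against a measured membrane
  growth reference.
* **Synthetic imaging** — a seeded generator that renders
  ground-truthed pHluorin stacks (Gaussian puncta with radial
  spreading or kiss-and-run kinetics on an oligodendrocyte-shaped
  mask, exponential bleaching, Gaussian read noise), sheath event
  layouts and node line-scan profiles, so the whole pipeline is
  testable without raw data.

## Worked example

```r
library(oligoexo)

geom   <- make_oligo_geometry(c(100L, 100L), pixel_size_um = 0.1)
params <- acquisition_params(n_frames = 240L, image_shape = c(100L, 100L))
events <- sample_events(rate_per_min = 23, full_fraction = 0.8,
                        duration_s = 60, geometry = geom, seed = 42)
sim       <- render_stack(params, geom, events, seed = 42)
corrected <- correct_bleaching(sim$stack)$stack
detected  <- assign_compartment(
  accepted_events(detect_events(corrected, detection_params(), geom)), geom)
classified <- classify_events(corrected, detected, use_population_fit = FALSE)

nrow(events); nrow(detected)
#> [1] 29
#> [1] 25
event_frequency(detected, duration_s = 60)
#> [1] 25
table(classified$fusion_mode)
#>    full_fusion   kiss_and_run unclassifiable
#>             16              3              6
```

29 events were simulated at 23/min over one minute; 25 pass the full
acceptance criteria (the rest fall too close to the movie start, the
image edge, or another event), giving 25 events/cell/min. Of the
classified events, full fusion dominates, as expected from the 80%
full-fusion simulation mix; `unclassifiable` marks events whose decay
could not be fitted (for example, a peak on the final frames).

The interpretive models print the headline numbers directly:

```r
membrane_budget(budget_params())
#> Membrane budget: 52992 full-fusion events
#>   area added: 1665-6659 um^2 (27.7-111.0% of reference)

ibot <- coverage_inputs(1558, 39.6, 6.85, "iBot")
ctrl <- coverage_inputs(1999, 54.2, 9.78, "control")
round(relative_coverage(ibot, ctrl), 3)
#> [1] 0.399
```

At 23 events/min with 80% full fusion over 48 h, 52,992 vesicles of
100–200 nm diameter deposit 1665–6659 µm² of membrane — 27.7–111.0% of
the 6000 µm² a pre-myelinating oligodendrocyte adds over the same
window, i.e. exocytosis at the measured rate can account for the
observed membrane growth. The coverage ratio of 0.399 quantifies the
myelin deficit of the exocytosis-blocked (iBot) genotype relative to
control.

An end-to-end run (simulate → detect → classify → spatial → budget)
with artifact files and a checksummed manifest:

```r
run_pipeline(list(seed = 1L), out_dir = "demo_run")
```

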