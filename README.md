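# dmnfudyn

Spatiotemporal **follow-up (FU) dynamics** of default-mode-network EEG
sources, for researchers studying how resting-state brain dynamics change
across age.

Resting-state EEG power is famously stable across early adulthood — but
*how* activity moves between regions can still reorganize. This package
implements an analysis chain that quantifies exactly that:

1. **Topographical band power.** Welch/FFT spectra with a cos² taper
   (2000 ms segments, 50% overlap), absolute and relative power in seven
   bands (δ 1–4, θ 4–8, α-low 8–10.5, α-high 10.5–13, β-low 13–21.5,
   β-high 21.5–30, γ 30–35 Hz) averaged over ten standard 10-10 electrode
   clusters, Spearman-correlated with age and state/trait covariates.
2. **Seeded source waveforms.** A fixed 28-source default-mode-network
   model (14 bilateral structures at Talairach centers) is seeded into
   band-pass-filtered data through an analytic 3-shell spherical head
   model; per sample, moments solve min‖d − Ls‖² + λ‖s‖², and each
   regional source yields a non-negative moment-magnitude waveform (nAm).
3. **The FU statistic.** Waveforms are summed into band-specific time
   bins (δ 8 Hz … γ 70 Hz), normalized per source to each 1-s epoch's
   maximum, binarized where a source holds *more than 1/28* of the
   instantaneous total, and transitions are counted:
   `FU[A, B] += 1` whenever A is active at bin t and B at bin t+1.
   The result is a directed 28×28 mean transition matrix per second.
4. **Age correlations and causal network diagrams (CND).** Per-pair
   Pearson correlation of FU counts with age; significant effects are
   classified into signed uni-/bi-directional edges (p < 0.05,
   uncorrected by convention; optional BH switch).
5. **Synthetic cohorts.** A generator produces whole studies with known,
   age-modulated lagged source coupling, so the full chain is validated
   by parameter recovery rather than by faith.

## Worked example

Simulate a small cohort with an age-modulated frontal→occipitotemporal
coupling, run the pipeline, and correlate FU entries with age:

```r
library(dmnfudyn)

model   <- load_dmnsm()                          # 28 regional sources
montage <- standard_montage(bremen_channels())   # 64-channel 10-10 cap
L       <- compute_leadfield(model, montage)     # 64 x 84, uV/nAm

cohort <- generate_cohort(40, setNames(rep(4L, 10), 19:28), seed = 2)
study  <- simulate_study(cohort, band = "alpha_low",
                         coupling = demo_coupling(), seed = 11,
                         leadfield = L, montage = montage)

pa  <- pearson_fu_age(study$fu, study$ages)
cnd <- build_cnd(pa$r, pa$p, alpha = 0.05)
head(fu_tidy(study$fu[[1]])[order(-fu_tidy(study$fu[[1]])$fu_per_s), ], 3)
pa$r["lMFG", "rOTJ"]
```

Output (seed 11):

```
    source_from source_to fu_per_s
262        rACC      rACC 11.42308
668        rPCC      rPCC 11.30769
639        lPCC      lPCC 11.26923
[1] 0.7094328
```

The largest FU entries sit on the diagonal — steady-state self-persistence
of each source — and the simulated lMFG→rOTJ edge carries a strong
positive age correlation (r = 0.71 across 40 participants; the pair tops
all 756 off-diagonal entries, and `cnd` classifies it as a positive
edge). With `coupling = NULL` the expected count of significant edges
falls at the 5% chance level.

Plotting: `plot_fu_matrix(study$fu[[1]])` renders the transition heat
map, `plot_cnd(cnd, sources = model$short)` the network diagram.

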