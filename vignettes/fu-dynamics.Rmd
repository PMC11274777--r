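---
title: "Follow-up dynamics of default-mode EEG sources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Follow-up dynamics of default-mode EEG sources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package computes

`dmnfudyn` analyzes resting-state EEG from two complementary
perspectives:

1. **Signal space.** Average power spectra (Welch-style FFT with a
   cosine-squared taper) are reduced to absolute and relative band powers
   in seven classical bands (delta 1--4, theta 4--8, alpha-low 8--10.5,
   alpha-high 10.5--13, beta-low 13--21.5, beta-high 21.5--30, gamma
   30--35 Hz) over ten standard electrode clusters, and rank-correlated
   with age and state/trait covariates.
2. **Source space.** A fixed 28-source default-mode-network model (14
   bilateral structures at published Talairach centers) is seeded into
   band-pass-filtered data through an analytic three-shell spherical head
   model. The resulting moment-magnitude waveforms ("nAm" traces) are
   coarse-grained in time, binarized by an equal-share criterion, and
   summarized as a directed *follow-up* (FU) matrix: how often source B
   is active in the time bin right after source A. Per-participant FU
   matrices are Pearson-correlated with age and the significant,
   signed, uni-/bi-directional effects are drawn as causal network
   diagrams (CNDs) — correlational direction summaries, not formal causal
   inference.

A synthetic-data module generates whole cohorts with known ground truth
so that every stage — forward model, inverse seeding, FU counting,
edge statistics — is testable end to end without any clinical recording.

# The source model and head model

The source model is a fixed list of 28 regional sources; each is a
triplet of orthogonal unit dipoles at one Talairach coordinate, which
captures activity of any orientation at that location. Left/right
structures mirror exactly in the x coordinate.

The forward solution uses three concentric shells with conventional
radii 85/79/73 mm (scalp/skull/brain) and conductivities
0.33/0.0042/0.33 S/m, all configurable. For each spherical-harmonic
degree the radial boundary problem is solved exactly as a small linear
system (with row/column equilibration, since the radial powers span many
orders of magnitude at high degree), giving a per-degree gain relative
to the infinite-medium dipole expansion; with equal conductivities the
gain reduces to the classical \((2n+1)/n\) of a homogeneous sphere, and
the implementation is tested against the analytically summed closed form
of that case to \(10^{-6}\) relative accuracy. The series is truncated
when terms fall below \(10^{-8}\) relative. Lead fields are expressed in
µV/nAm and average-referenced.

Talairach coordinates are placed in the sphere by an affine map,
`pos = 0.9 * (coord - (0, -15, 0))`: the sphere center sits slightly
posterior of the anterior commissure and the isotropic scale keeps every
model source strictly inside the brain shell (the most eccentric source,
the left intraparietal sulcus, lands at 68 mm of 73 mm). There is no
published mapping to honor here — the affine is a documented stand-in,
so absolute nAm magnitudes are nominal and all downstream statistics are
designed to be scale-free (see below).

Electrode positions are idealized 10-10 coordinates constructed from the
proportional system (vertex at the pole, 18° steps, great-circle
interpolation for intermediate rows), not digitized positions; none were
available. Two 64-channel laboratory montages are built in, and a small
alias table reconciles their naming quirks (`FC7/FC8` for the FT sites;
the cluster tokens `P9`/`P10` resolve to `PO9`/`PO10` on caps without
those positions).

# Source-waveform estimation and its rank limit

Per time sample the component moments solve
\(\min_s \lVert d - Ls\rVert^2 + \lambda\lVert s\rVert^2\), with
\(\lambda\) defaulting to 0.01 times the mean singular value of the lead
field. Each source's waveform is the Euclidean norm of its three
components — non-negative by construction, which is what the FU
normalization assumes.

One structural fact shapes the validation design: with 64
average-referenced channels the data space has rank 63, while 28 free
regional sources span 84 unknowns. Free-orientation seeding is therefore
necessarily regularized and exhibits cross-talk (in simulations the
median waveform correlation with ground truth is about 0.5). For
validation studies where the generator's true orientations are known,
the estimator supports *oriented seeding* — one fixed-orientation dipole
per source, 28 columns, full column rank — which inverts noiseless data
exactly. The round-trip and parameter-recovery checks use oriented
seeding deliberately: they are meant to validate the FU statistic and
the pipeline plumbing, not to hide the (well-understood) ill-posedness
of the free inverse problem, which we report rather than suppress.

# The FU statistic

For each band the waveforms are summed into coarse bins at a fixed
per-band rate (delta 8, theta 16, alpha-low 22, alpha-high 26, beta-low
43, beta-high 60, gamma 70 Hz — the published table is honored verbatim,
including alpha-low's 22 Hz where the doubling rule would give 21; the
rule `2 * upper edge` is the fallback for custom bands). Non-integer
samples-per-bin are handled by equal-time bin edges (counts differing by
one), never by resampling, so bin counts are exact and energy is
preserved. Each source is then normalized to its own within-epoch
maximum (percent of epoch max), which removes depth- and
cytoarchitecture-dependent amplitude differences; a source that is
identically zero within an epoch makes that epoch degenerate and it is
excluded with a flag. A source is *active* in a bin when its share
strictly exceeds \(1/n\) of the summed value of all \(n = 28\) sources
(ties are inactive). Finally, for every consecutive bin pair each
(active at \(t\), active at \(t+1\)) ordered source pair increments
`FU[A, B]`; the diagonal (A = B) is kept and carries steady-state
activation. Counts are averaged over surviving one-second epochs, giving
mean FU counts per second.

Two invariances are tested explicitly: per-source rescaling of raw
magnitudes never changes the binary pattern (the epoch-max normalization
cancels it), and the FU counter agrees exactly with a brute-force
nested-loop enumeration on random binary matrices.

# Epoch rejection

Epochs whose source magnitudes spike are rejected by a pooled 2-SD rule:
per source, mean and SD are pooled over all samples of all epochs, and
an epoch is dropped when any source strictly exceeds `mean + k*SD`
anywhere inside it (`k = 2`). This rule is extremely sensitive by
construction — it takes a joint maximum over 28 sources × 512 samples —
and for *clean stationary Gaussian* magnitudes it would reject nearly
every epoch, because a narrowband envelope exceeds its own 2-SD level
with high probability somewhere in a second of data. It is intended to
catch isolated artifact spikes that survive ocular correction.
Accordingly, the synthetic study driver `simulate_study()` disables it
by default (its recordings contain no artifact outliers), while
`process_fu()` keeps `k = 2` for data that may contain residual
artifacts. Rejection is permutation-invariant over epochs and tested on
constructed spike fixtures.

# What the synthetic generator emulates — and what it does not

Cohorts reproduce a reference age distribution exactly (54 participants,
19--29 years, mean 23.7, SD 2.8) with state ratings and NEO-FFI trait
scores drawn independently of age (the reference cohort showed no
trait-age correlations); means and SDs match the reference sample and
values are clipped to their scales. Sources carry independent
band-limited Gaussian noise at 50 nAm RMS (about 10 µV RMS at the
scalp), optionally coupled in ordered pairs: the target's trace is an
RMS-preserving mixture `sqrt(1-w^2) * own + w * lagged(driver)` whose
weight `w` varies linearly with age. At `w = 1` the target is exactly
the lagged driver. Scalp data are the lead field times oriented moments
plus white sensor noise (default 1 µV) and stereotyped blinks
(frontopolar-dominant topography decaying with spherical distance,
300 ms raised-cosine pulse, Poisson event times with a 0.5 s refractory
gap).

The reference validation coupling (`demo_coupling()`) drives the right
occipitotemporal junction from the left middle frontal gyrus at a lag of
46 samples (about two alpha-low bins) with weight `0.5 + 0.08*(age -
mean age)`. The published source of this analysis reports only the sign
and significance of age effects, not effect sizes, so the slope is a
free design parameter: it was fixed, once, large enough that a
40-participant study detects the edge with a comfortable margin
(FU-vs-age r around 0.65 against a 756-pair noise floor of about 0.5) —
recovery failures should indicate pipeline defects, not sampling noise.
A lag of two bins rather than one was chosen because narrowband
envelopes persist over many bins, making the FU statistic nearly
direction-symmetric at short lags.

What the generator does *not* emulate: 1/f background spectra, alpha
peaks riding on broadband activity, muscle or cardiac artifacts,
inter-individual head geometry, volume-conduction model mismatch, or
non-Gaussian burstiness of real oscillations. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under
the stated model, not robustness to everything real data can do.

# Numerical choices

* **Spectra.** 2000 ms segments (0.5 Hz grid at 512 Hz), 50% overlap,
  cos² taper; with this combination every time point contributes equally
  to the mean spectrum. Powers are corrected by the window's power gain
  so the spectrum sums to the signal's mean square (Parseval, tested to
  1%). Band edges shared by adjacent bands are resolved half-open,
  `[low, high)`, so the seven relative powers partition unity exactly;
  the relative-power denominator is the union of the analyzed bands,
  1--35 Hz.
* **Filtering.** Zero-phase (forward-backward) Butterworth band-pass,
  order 4 per pass. Note that a tone at a band's upper corner (10 Hz in
  alpha-low) keeps ≥ 0.9 amplitude gain while out-of-band rejection
  exceeds 20 dB an octave away.
* **Blink correction.** Adaptive template correction: windows whose
  dominant topography correlates with the blink template above 0.8 or
  whose amplitude exceeds 150 µV count as artifact; a PCA of the
  remaining data supplies brain topographies (components above a
  variance fraction, default 0.01), and the artifact coefficient from
  the joint least-squares decomposition is subtracted. The variance
  cutoff trades blink removal against brain-subspace completeness: data
  whose brain activity spreads over many small components (as with 28
  simulated sources) benefit from a lower cutoff such as 0.001, which is
  what the injection/recovery test uses.
* **Interpolation.** Spherical splines of order m = 4 with ridge
  1e-5, series truncated at degree 50; reproduce constants exactly and
  held-out smooth topographies with r > 0.95.
* **Correlations.** Spearman maps use tie-corrected ranks with the
  two-sided t approximation; FU-age grids use Pearson r with two-sided
  p from the t distribution on n-2 df. No multiple-testing correction is
  applied by default (matching the uncorrected p < 0.05 convention of
  the analysis this package operationalizes); a Benjamini-Hochberg
  switch is available and clearly beyond that convention. Edges with
  both directions significant but opposite signs are rendered as two
  uni-directional edges; diagonal self-persistence effects are reported
  separately, never as edges.

# Validation studies and problem sizes

The package's own acceptance checks run, among smaller oracles:

* a noiseless 28-source forward-inverse round trip (10 epochs, oriented
  seeding): residual variance below 1e-6 % and waveform correlation
  above 0.999 for every source;
* 1000 random binary matrices against the brute-force FU counter;
* twenty independent 40-participant studies (ages 19--28, four per year,
  26 one-second epochs each) with the reference coupling: the simulated
  edge must top the 756-pair correlation grid with positive sign in at
  least 80% of runs; plus twenty null studies (no coupling) whose
  *mean* significant-edge count must fall inside central 95% binomial
  bounds of a 5% rate. The mean, rather than a single count, is the
  right quantity here: each of the 756 tests is marginally calibrated,
  but tests sharing a row or column of the FU matrix are correlated, so
  the per-study count is about three times as dispersed as a binomial
  would suggest.

These sizes keep a complete run within a few minutes on one core while
leaving the statistical assertions well-powered.

# Known limitations

* The free regional inverse is rank-limited (63 < 84) and its waveforms
  carry cross-talk; quantitative per-source conclusions should rely on
  oriented or reduced models, or on scale-free statistics like FU.
* Absolute nAm units depend on the stand-in Talairach-to-sphere affine
  and the unit-RMS convention; they are nominal.
* The FU statistic discards phase and amplitude information by design
  and is reported per second of data; it is a descriptive dynamics
  summary.
* EDF/BDF writers store one data record per file with a data-fitted
  symmetric physical range — convenient and lossless to within
  quantization for analysis round trips, but not tuned for archival
  interchange with strict-reader hardware tools.
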