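---
title: "Models and numerical methods in chromakit"
author: "chromakit authors"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromakit bundles the bespoke computations needed to dissect how a
chromatin remodeler (SRCAP) and its histone-variant cargo (H2A.Z) regulate
transcription-factor binding in embryonic stem cells: single-molecule
binding kinetics, motif-level CpG and promoter/enhancer statistics,
rule-based chromatin peak classification, and probe-radius DNA
accessibility. This vignette explains the models behind each component, the
parameters that matter, and the numerical choices made where the design was
genuinely open.

## 1. The three-state kinetic model and its simulator

A nuclear transcription factor is modeled as switching between three
states: freely diffusing (`free`), transiently bound (`transient`, sub-second
dwell, nonspecific sites), and stably bound (`stable`, tens-to-hundreds of
seconds, specific sites). Transitions form a continuous-time Markov chain
with star topology around `free`:

* `k_bind_T`, `k_bind_S` (1/s): association into the transient / stable state;
* `k_off_T`, `k_off_S` (1/s): dissociation; residence times are their inverses.

The stationary occupancies are proportional to `1`, `k_bind_T/k_off_T` and
`k_bind_S/k_off_S`; `kinetic_params_for_occupancy()` inverts this so
simulations can be parameterized by target occupancies.

`simulate_tracks()` emulates the three imaging schemes of single-molecule
experiments: a fast scheme (10 ms exposure, no dark time, 2500 frames) for
jump-distance analysis, and two slow schemes for residence times — 500 ms
continuous illumination, and a time-lapse alternating one 500 ms frame with
a 10 s dark time (10.5 s cycle). Free molecules diffuse with `D_free`
(default 3 um^2/s) inside a reflecting disk (`nucleus_radius`, 5 um); bound
molecules are immobile up to the localization error `sigma_loc` (30 nm),
into which slow chromatin motion is folded. Positions are taken at
mid-exposure; motion blur during the exposure is not rendered, but its main
observable consequence is modeled: when the within-frame smear
`sqrt(4 D exposure)` of a free molecule exceeds `blur_cutoff` (0.5 um), the
molecule is not localized in that frame. Without this rule, chance
proximity of free molecules across the 10.5 s dark gaps creates spurious
two-frame "tracks" that no dissociation model can describe; with it, slow
movies contain bound molecules only, exactly as in experiments.

Photobleaching removes the fluorophore with probability `p_bleach` per
illuminated frame, regardless of state. Localizations are linked the way a
tracking program links them: consecutive frames within the scheme's
tracking radius (4 / 3 / 5 pixels of 130 nm for the three presets) join one
track, larger jumps or frame gaps start a new one, and tracks need at least
two localizations. Tracks reaching the final movie frame are flagged
`touches_movie_end` so survival analysis can censor them (dropped by
default).

The simulator returns exact ground truth: state occupancies, sojourn
statistics, and the realized stable-association event rate per
molecule-second of non-stable time — the quantity the inferred binding
frequency is checked against.

## 2. Bound fractions from jump distances

For fast-scheme tracks, the cumulative distribution of squared
frame-to-frame displacements u is fit with
`F(u) = 1 - sum_i A_i exp(-u / (4 D_i dt))`, the standard multi-component
apparent-diffusion decomposition (3 components by default). Amplitudes are
constrained to the simplex by a softmax reparameterization and coefficients
to a strictly increasing sequence by positive increments above a floor
(`d_floor`, 1e-4 um^2/s); optimization uses BFGS with an analytic gradient
and 10 random multi-starts. The slowest amplitude `A_1` is the bound
fraction; there is no explicit localization-noise term — the noise floor
appears as `D_1 ~ sigma_loc^2/dt`. Components whose coefficients collapse
onto each other (ratio < 1.15) are merged amplitude-weighted, so that a
genuinely single-component sample is reported as one dominant amplitude
rather than an arbitrary split. Uncertainties are standard deviations over
400 refits on 80% subsamples drawn without replacement, each started from
the full-data optimum.

## 3. Dissociation-rate spectra from multi-scheme survival times

The survival time of a slow-scheme track is `(frames - 1) * cycle_time`.
Molecular dissociation scales with real time while photobleaching and
tracking loss scale with the number of illuminated frames, so fitting the
continuous and time-lapse schemes globally separates the two: that is the
purpose of the spectrum fit in `fit_grid_spectrum()`.

The observation model is explicit about where tracks come from. A track of
rate component k in scheme c (cycle time tau_c) decays per frame by
`lambda = k tau_c + a_b`, where `a_b` is the per-frame bleaching number.
Tracks arise from two channels:

* **standing stock** — molecules already bound when the movie starts; their
  component follows the length-biased state weights `S_k / k_k`;
* **binding events** — molecules binding during the movie; their component
  follows the event amplitudes `S_k`, they enter the frame grid at a
  uniform phase, and short events are truncated by the factor
  `c = (1 - exp(-k tau_c)) / (k tau_c)`.

At stationarity the binding flux equals occupancy divided by mean residence
time, which fixes the relative intensity of the two channels with no free
parameter: the per-rate track weight is `S_k (1/k_k + W_c c_k) exp(-lambda)`
with `W_c` the bleach-limited observation window. Both channels share the
same geometric survival shape by memorylessness.

Amplitudes on a fixed log-spaced grid (200 rates, 1e-4 to 10 per second)
are estimated by maximum likelihood on this truncated geometric mixture.
We initially implemented the more common least-squares/NNLS fit of the
stacked survival curves and found it structurally unsound for amplitude
recovery in the multi-scheme setting: with no per-scheme scale the shared
spectrum cannot match the scheme-dependent probability that an event yields
an observable track, and with a free per-scheme scale the problem becomes
ill-posed (grid rates too fast to ever produce a track can absorb simplex
mass and overfit noise). The multinomial likelihood resolves both issues;
it is maximized by an EM iteration with an inclusion-probability
correction, and since nonparametric maximum-likelihood mixtures are
discrete, the converged solution is consolidated by likelihood-guided
support reduction: contiguous amplitude blobs are collapsed onto single
grid rates whenever that costs no likelihood, recursively splitting blobs
that resist. No smoothness penalty is applied anywhere. A strict NNLS
solver over the same grid is retained internally as a convex baseline and
is exercised against a direct two-exponential fit in the test suite.

The bleaching number is profiled on an outer scan (60 values, 0 to 1.5 per
frame). Because candidate values must be compared at converged likelihoods,
the best scan candidates are re-fit with the full EM-plus-collapse routine
and the winner refined on a local grid. Uncertainties come from refitting
resamples of 80% of tracks (500 by default), with the bleaching number
re-scanned locally around the point estimate.

Event amplitudes `S_k` are converted to state amplitudes
`s_k = (S_k/k_k) / sum_j (S_j/k_j)` (`state_spectrum()`), the instantaneous
occupancy of each bound state.

## 4. Long-bound fraction, search time, binding frequency

Molecules binding longer than 50 s are taken as specifically bound; the
absolute long-bound fraction is `f_long = A_1 * sum_{1/k >= 50 s} s_k`
(`long_bound_fraction()`; the threshold is an argument). With
`tau_long` the state-weighted mean residence time of the long components,
flux balance over the three-state model gives the mean search time — all
time spent not stably bound, free or transiently bound, between two stable
binding events:

```
tau_search = (1 - f_long) * tau_long / f_long,    nu = 1 / tau_search.
```

The literature formula this condenses is a declared modeling decision: the
search time counts all non-stably-bound time, with no separate
transient-state correction term, and it is isolated in one operation
(`binding_frequency()`) so an alternative convention is a one-line change.
`f_long = 0` gives `nu = 0` with an infinite search time; `f_long = 1` is
rejected.

### Accuracy and the limits of desk-scale movies

The estimator quality is set almost entirely by how many slow-scheme tracks
survive bleaching. The package's tests exercise two regimes. In a
well-powered regime (about 2000 molecules per scheme, `p_bleach` 0.05) the
pipeline recovers bound fractions within a few percent absolute, long
residence times within tens of percent, and ratios of binding frequencies
between two conditions within 25%. In a deliberately harsh regime (500
molecules per scheme, `p_bleach` 0.3) molecules survive ~3 illuminated
frames, the slow schemes yield only ~100-200 tracks, and the time-lapse
decay is the *sum* `k_stable tau_c + a_b`: separating the two terms then
rests on a handful of long continuous-scheme tracks. In that regime the
bound fraction is still recovered accurately, but the long residence time
and binding frequency are close to their information limit — a
structure-informed maximum-likelihood fit that knows the true number of
components shows the same instability — and the corresponding end-to-end
checks can fail for unlucky seeds. This is a property of the imaging
conditions, not of the solver, and mirrors why real experiments image at
low power (little bleaching) and pool thousands of tracks.

## 5. Motif statistics

The CpG score of a position frequency matrix quantifies how strongly a
motif demands a CpG dinucleotide, weighted by how heavily the matrix is
populated at the contributing positions: with `P(C)_i` the C fraction at
position i and `Weight_i` the column sum over the mean of all 4N entries,
the score sums `P(C)_i P(G)_{i+1} (Weight_i + Weight_{i+1})` over adjacent
position pairs. PFMs are used as raw counts exactly as distributed (no
pseudocounts); the score is invariant to rescaling the whole matrix and —
because a CG dinucleotide is its own reverse complement — provably
invariant under reverse complementation. Motifs with score strictly greater
than 6 are called CpG-containing. A single-position motif scores 0 (empty
sum); all-zero columns are rejected.

The promoter-versus-enhancer score of a motif is the fraction of its
occurrences falling in promoters among those falling in promoters or
enhancers; occurrences in neither are excluded from the denominator, and an
occurrence overlapping both annotations counts as promoter (promoters are
built first; the event is reported when it happens). The pioneer-factor
tally reports the fraction of up- and down-regulated motifs on a
pioneer-TF list plus a two-sided exact hypergeometric test of the 2x2
table.

## 6. Chromatin bookkeeping rules

* **Spike-in factors**: `min(counts)/count_s` per sample, so factors lie in
  (0, 1], the minimum-count sample is the reference, and applying them
  equalizes the implied spike-in depths exactly. Factors are applied at
  the score-table level.
* **Differential classes**: relative change `(treat - ctrl)/(ctrl + 0.5)`
  against 20% (histone marks) or 30% (TFs). The reference condition is the
  denominator; the 0.5 pseudocount guards near-zero peaks. Exact
  antisymmetry under swapping the conditions holds when the pseudocount is
  zero and both directions clear the threshold.
* **H2A.Z levels**: rank-based classes — lowest 3% `No`, rest of the first
  quartile `Low`, upper quartile `High`, remainder `Intermediate`; ties
  break by input order, so any monotone transform of the scores gives the
  same classes. On 100 distinct scores the sizes are exactly 3/22/50/25.
* **Fragility**: MNase-low over MNase-high score ratio; a zero denominator
  yields NA with a warning unless a pseudocount is supplied.
* **Rescued peaks**: with losses `delta = ctrl - iaa` per cell line, a peak
  is rescued when `delta_cd > 1.1 * delta_wt` and `delta_cd > 0`. An
  alternative formulation (wild-type signal under treatment stays within
  10% of its control) is available via `rule = "results"`; the two are not
  asserted to be the same rule.
* **Turnover groups**: earliest of 2/4/6/8 h at which the loss fraction
  versus t = 0 reaches 0.5 ("losing most" of the signal), else `stable`.
* **Methylation classes**: hyper/hypo when the percentage changes by at
  least 5 points (boundaries inclusive), else stable.
* **z-score k-means**: rows standardized across samples, constant rows
  dropped with a warning, Euclidean k-means with k = 6 and 10 seeded
  restarts. Labels are identifiable only up to permutation; tests compare
  partitions.

Regulatory annotation uses 0-based half-open coordinates throughout, with
overlap meaning at least one shared base pair. Promoters span 1 kb upstream
to 500 bp downstream of the TSS, strand-aware; active/bivalent/inactive
classes compose H3K4me3 and H3K27me3 overlaps. Enhancer candidates outside
all promoters are active (H3K27ac and H3K4me1), poised (H3K4me1 and
H3K27me3) or inactive (no H3K4me1). The TSS nucleosome is TSS +/- 20 bp and
the -1/+1 nucleosome windows are its 400 bp strand-aware flanks. Interval
overlap is delegated to GenomicRanges/IRanges at the package boundary.

## 7. Probe-radius DNA accessibility

`sasa()` implements Shrake–Rupley with a deterministic golden-spiral point
set (960 points per atom by default): a surface point on the
probe-expanded sphere of an atom is accessible if it lies outside every
neighbor's expanded sphere; neighbor candidates come from spatial binning,
which keeps transcription-factor-sized probes (20–30 A pseudo-spheres)
tractable. Element radii default to C 1.70, N 1.55, O 1.52, P 1.80, S 1.80,
H 1.20 A and can be overridden; because the radii set of any particular
external tool is not reproduced, the supported quantity is the free/bound
*ratio*, not absolute areas. Determinism makes the computation exactly
translation-invariant and testable; under rotation, agreement is limited by
the point discretization (about 0.1% at 960 points), which is also why the
point count, not a tolerance, is the convergence knob (960 vs 3840 points
changes totals by < 0.5% on the toy complex).

`probe_sweep_ratio()` computes the SASA of a selected atom group (DNA
residues DA/DT/DG/DC by default) inside the free context and inside the
bound context over a list of probe radii and reports the free/bound ratio.
The "free" context defaults to the full nucleosome (DNA plus histones);
a DNA-only selection is equally possible by passing a predicate. Waters,
ions and ligands are dropped on reading. The toy fixture
(`make_toy_complex()`) is a ring of DNA-labeled pseudo-atoms with an
optional occluder sphere on a separate chain; a 1000 A occluder tangent to
the ring plane approximates a half-space and buries half the ring, which
pins the expected ratio near 2 for probes small relative to the ring.

## 8. What the synthetic data do and do not show

The generators reproduce the statistical structure the analysis relies on —
three-state kinetics with localization noise and per-frame bleaching, the
three illumination schemes, planted peak classes with exact effect sizes,
spike-in counts, toy motifs and toy structures — and they are bit-reproducible
given a seed (every stochastic function requires one). They do not emulate
detection physics (PSF shape, spot detection, localization outliers),
anomalous diffusion beyond a multi-component approximation, chromatin
motion beyond the localization-noise term, read-level genomics (alignment,
peak calling, duplicate structure) or real structural chemistry. Passing
tests therefore demonstrate correctness of the computations under the
stated models, not robustness to every artifact of real data.

Problem sizes used by the test suite and the acceptance script were chosen
to make each check informative at interactive runtimes: 1e4 events for
spectrum localization checks, 500–2000 molecules per scheme for pipeline
recovery, 200 peaks for classification, 960–3840 sphere points for SASA.
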