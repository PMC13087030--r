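# chromakit

Chromatin remodelers can regulate transcription factors without using their
catalytic activity at all — simply by sitting on nucleosomes and blocking
access to binding sites. Testing that idea quantitatively requires a chain
of bespoke computations that no single existing package provides:
single-molecule binding kinetics (how often and how long a TF binds
chromatin), motif-level statistics (which motifs are CpG-rich or
promoter-biased), spike-in-calibrated peak classification (which loci lose
a histone variant, how fast, and whether a rescue construct restores them),
and steric accessibility of nucleosomal DNA to TF-sized probes. chromakit
implements that chain for studies of the SRCAP remodeler and its cargo
histone variant H2A.Z in mouse embryonic stem cells, together with
synthetic-data generators that give every stage a known ground truth — so
the whole pipeline runs and is testable without downloading any deposited
data.

It is aimed at quantitative biologists analyzing single-molecule tracking
and chromatin-genomics experiments, and at method developers who need a
transparent, tested reference implementation of these estimators.

## The models

**Single-molecule kinetics.** A TF switches between freely diffusing,
transiently bound and stably bound states (a continuous-time Markov chain).
From fast movies (10 ms frames), the cumulative distribution of squared
jump distances is fit with

> F(u) = 1 − Σᵢ Aᵢ exp(−u / (4 Dᵢ Δt)),  D₁ < D₂ < D₃,

and the slowest amplitude A₁ is the overall bound fraction. From slow
movies (500 ms continuous illumination, and 500 ms frames separated by 10 s
dark times), fluorescence survival times are decomposed over a log-spaced
grid of dissociation rates k with a global per-frame photobleaching number
a_b — fitting both illumination schemes jointly is what separates
dissociation (scales with time) from bleaching (scales with frames).
Event amplitudes S_k are reweighted into state amplitudes
s_k ∝ S_k / k, the fraction bound longer than 50 s is
f_long = A₁ · Σ_{1/k ≥ 50 s} s_k, and flux balance gives the search time
and binding frequency:

> τ_search = (1 − f_long) · τ_long / f_long,  ν = 1 / τ_search.

**Motif statistics.** For a motif with N positions, the CpG score is
Σ_{i=1}^{N−1} P(C)ᵢ · P(G)ᵢ₊₁ · (Weightᵢ + Weightᵢ₊₁), with P(C)ᵢ the C
fraction of counts at position i and Weightᵢ the column sum over the mean
of all 4N matrix entries; motifs scoring > 6 are called CpG-containing.
The P/E score is the fraction of a motif's occurrences in promoters among
those in promoters or enhancers, and the pioneer-factor tally tests the
2×2 association of up/down motifs with a pioneer-TF list by an exact test.

**Chromatin rules.** Spike-in factors min(counts)/countₛ; differential
classes at 20% (histone marks) / 30% (TFs) relative change; H2A.Z level
quartile classes (3% lowest = No); MNase-low/high fragility ratios;
rescued peaks (loss difference with a 10% margin); turnover groups
(earliest timepoint losing half the signal); ±5-point methylation margins;
strand-aware promoter (−1 kb/+500 bp), enhancer and ±1-nucleosome windows;
six-cluster k-means on per-row z-scores.

**Steric accessibility.** Shrake–Rupley solvent-accessible surface area
with deterministic golden-spiral points and arbitrary probe radii; for a
DNA selection evaluated inside a "free" and a remodeler-"bound" context,
the free/bound SASA ratio over 20–30 Å probes measures how much DNA a
TF-sized pseudo-sphere can still reach.

## Worked example

Simulate a TF with a 30% bound fraction (half transient with 1 s residence,
half stable with 100 s residence) under all three imaging schemes, and run
the full kinetics pipeline:

```r
library(chromakit)
params <- kinetic_params_for_occupancy(0.15, 0.15, k_off_T = 1, k_off_S = 0.01,
                                       p_bleach = 0.05)
fast <- illumination_scheme("fast")
cont <- illumination_scheme("continuous")
tl   <- illumination_scheme("timelapse")
sim_fast <- simulate_tracks(params, fast, n_molecules = 1000, seed = 1)
sim_cont <- simulate_tracks(params, cont, n_molecules = 1000, seed = 2)
sim_tl   <- simulate_tracks(params, tl,   n_molecules = 1000, seed = 3)
res <- smt_kinetics(sim_fast$tracks, fast,
                    list(sim_cont$tracks, sim_tl$tracks), list(cont, tl),
                    n_boot_jumps = 50, n_boot_grid = 0, seed = 4)
res$kinetics
#> # A tibble: 1 × 5
#>   f_bound f_long tau_long tau_search      nu
#>     <dbl>  <dbl>    <dbl>      <dbl>   <dbl>
#> 1   0.290  0.145     83.3       490. 0.00204
```

The planted truth was f_bound 0.30, f_long 0.15, τ_long 100 s and
ν = 0.00176 /s: the pipeline recovers the bound fraction and long-bound
fraction within a few percent and the binding frequency within ~15% at this
data volume. The motif, normalization and accessibility components run on
generated fixtures the same way:

```r
fx <- make_genomic_fixture(n_peaks = 100, seed = 7)
cpg_score(fx$pwms$toy_uniform)      #> 0.5
cpg_score(fx$pwms$toy_perfect_cg)   #> 8
spike_in_factors(fx$spike_counts)
#>   sample  count factor
#> 1 ctrl   100000    1
#> 2 iaa    200000    0.5

toy <- make_toy_complex(150, 150,
                        occluder = list(center = c(1000, 0, 0), radius = 1000))
probe_sweep_ratio(toy$free, toy$bound, radii = c(20, 25, 30), n_points = 960)
#>   probe_radius sasa_free sasa_bound ratio
#> 1           20   130094.     62659.  2.08
#> 2           25   159857.     75367.  2.12
#> 3           30   189427.     87207.  2.17
```

A ring of DNA pseudo-atoms half-buried by an occluder is about twofold less
accessible to 20–30 Å probes — the toy analogue of DNA on a remodeler-bound
nucleosome.

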