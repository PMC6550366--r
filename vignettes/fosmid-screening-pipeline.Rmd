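---
title: "Methods: simulation and analysis of fosmid GH screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of fosmid GH screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the forward models, estimators, parameter
defaults and numerical choices of `fosmidscreen`. It is a methods
reference, not a tutorial; the README and the `analysis/` drivers show
the pipeline in use. Chunks are not evaluated.

# 1. Forward models (the generator)

## 1.1 Library and enzymes

`simulate_library(config)` draws, for each of
`n_libraries * clones_per_library` clones, a Bernoulli indicator with
success probability `active_fraction` (default 1/239). An active clone
carries `1 + Poisson(extra_enzyme_lambda)` enzymes (default lambda 0.5),
reflecting that a 35-kb insert can encode more than one hydrolase. Each
enzyme (`simulate_enzyme()`) gets:

* a GH family from a fixed weighted pool (GH3-heavy, matching the
  families commonly recovered from gut and environmental libraries);
* a primary panel substrate (weighted draw) with `kcat` log-uniform on
  `kcat_range` (default 1–100 s⁻¹) and `Km` log-uniform on `km_range`
  (default 0.02–2 mM); with probability 0.25 a secondary substrate at
  0.05–0.5 × the primary `kcat`;
* a pH optimum uniform on `ph_opt_range` (4.5–7.5) with Gaussian
  activity profile of width `ph_width` (1 pH unit);
* a denaturation midpoint `Tm` uniform on `tm_range` (38–74 °C) and
  van't Hoff enthalpy uniform on `dh_vh_range` (150–400 kJ/mol);
* a mechanism, retaining with probability `retaining_fraction` (0.58).

Clone IDs follow the `library_plate_well` convention
(`"LIB01_02_C11"`). All draws are fixed by `config$seed`
(`set.seed()` at entry), so a configuration file fully reproduces a
library.

## 1.2 Endpoint screening plates

`simulate_screen_plate()` models a one-hour endpoint read. Every well
draws additive Gaussian background
`N(background_rfu_mean, background_rfu_sd)` (defaults 100 ± 10 RFU),
plus optional additive row/column effects (`row_effect_sd`,
`col_effect_sd`, default 0) used to stress the plate statistic. An
active well adds

```
signal = calibration_slope * min(v0 * t, conc) * lognormal(cv = signal_cv)
```

where `v0` is the summed Michaelis–Menten velocity of the clone's
enzymes at the screening concentration (`clone_velocity()`:
`Σ kcat_i · E · S / (1000 · Km_i + S)`, `S` in µM, `Km` in mM,
`E = lysate_enzyme_conc_um`, default 0.01 µM). The `min(v0·t, conc)` cap
encodes full substrate conversion; the lognormal factor (cv 0.1, mean
exactly 1) models expression and pipetting variability. The screening
substrate concentration is 500 µM (0.5 mM).

`lysate_enzyme_conc_um` is the single effective expressed-enzyme
concentration in a well; it is the bridge between a drawn `kcat` and an
observable well velocity, and is deliberately a configuration parameter
because expression levels are the least-constrained part of any
functional screen.

## 1.3 Product time courses

`simulate_timecourse()` evaluates the integrated single-substrate
Michaelis–Menten progress curve

```
Vmax * t = P + Km * ln(S0 / (S0 - P))
```

solved for `P` at each time point by bisection on `[0, S0)` (200
iterations, relative tolerance 1e-12, with an explicit full-conversion
shortcut). The trajectory is therefore exact at all depletion levels —
not a linearization — which is what makes the 10%-consumption
initial-rate rule testable. Multiple enzymes on a clone are collapsed to
a single effective (Vmax, Km) that matches the exact initial velocity.
Fluorescence is `slope * P(t) + intercept` plus additive Gaussian noise.

## 1.4 pH, thermal and inactivation series

* `simulate_ph_series()`: rate ∝ `exp(-(pH - opt)² / (2 width²))` —
  a single-mode Gaussian profile, adequate for the argmax-on-a-grid
  estimator (real profiles can be asymmetric; see §5).
* `simulate_thermal_series()`: residual activity after pre-incubation is
  `rate_ref * f(T)` with the two-state folded fraction
  `f(T) = 1 / (1 + exp[(ΔH/R)(1/Tm - 1/T)])`, `R = 8.3145e-3`
  kJ mol⁻¹ K⁻¹, temperatures converted to kelvin internally. At `T = Tm`
  the rate is exactly half the reference.
* `simulate_inactivation()`: a retaining enzyme is fully inactivated by
  the 2-fluoroglycoside (residual rate → 0), an inverting one is not
  (residual ≈ control); relative noise applies to both rates.

## 1.5 Inserts, annotation and catalog structure

`simulate_insert_and_annotation()` draws an insert length from
`N(insert_len_mean, insert_len_sd)` truncated at 2 kb (defaults
35,047 ± 4,852 bp) and places `max(3, Poisson(len/1000 · gene_density))`
non-overlapping ORF slots with random strands. Background slots are
annotated GH / CE / CBM / `unannotated` at fixed low rates; the clone's
active enzymes claim slots with their drawn families. With probability
`pul_fraction` a SusC–SusD–GH3 cassette is planted on one strand in
transcriptional order (reversed in coordinates on the minus strand).
ORFs are abstract coordinate/strand/family records; no codon structure
or promoters are simulated.

`plant_duplicates()` copies inserts between clone pairs with a
per-base substitution rate (default 2%), modeling clones picked twice
from the same source DNA. `simulate_catalog_study()` composes a hit set
with exact planted structure — `n_pul` PUL fosmids, `n_multi_gh` fosmids
with ≥ 5 GH ORFs, `n_dup_pairs` duplicate pairs — on disjoint index
sets, so the expected catalog outputs are known exactly
(e.g. 164 fosmids with 49 duplicate pairs → 115 nonredundant clusters).

# 2. Screening statistics

`robust_zscore()` computes, per plate,
`z = (x - median(x)) / (1.4826 · MAD(x))`. The 1.4826 factor makes the
MAD consistent for the normal distribution, so background wells have
approximately unit-variance scores while the statistic ignores up to
50% contamination. A plate whose MAD is zero is rejected as degenerate.
Full plates require ≥ 8 finite wells; bare numeric vectors only ≥ 2, so
small worked examples remain expressible.

Why robust: with a mean/SD Z-score the active wells inflate the SD and
mask themselves — at contamination fraction `f` their score cannot
exceed ≈ `sqrt((1-f)/f)` (≈ 4.4 at 5%) regardless of effect size, so
every hit is lost at a calling threshold of 10. The test suite
demonstrates this on a planted plate.

`call_hits()` applies a strict threshold (`z > 10`; a score exactly at
the threshold does not pass) per plate. `validate_hits()` requires
exactly three replicate plates, scores each replicate with the same
per-plate statistic, and confirms a hit when the **median** replicate Z
exceeds the threshold — one failed replicate cannot veto, one inflated
replicate cannot rescue. Candidates absent from a replicate are a hard
error naming the missing clone IDs. Replicates are full-plate rescreens
(statistics are always computed in the context of a mostly-inactive
plate; a rearrayed all-hits plate would invalidate the median/MAD
background model).

# 3. Characterization estimators

* **Initial rates** (`estimate_initial_rate()`): fluorescence is
  converted to product with a `calibration` (buffer-specific linear
  standard curve, `fit_calibration()`); only points with
  `P(t) ≤ 0.10 · conc0` are kept; a free-intercept least-squares slope,
  × 60, gives µM/min. Fewer than three qualifying points returns the
  flag `"depleted"` instead of an extrapolated rate. When a time course
  carries an OD600 the rate is divided by it (per-cell-density
  normalization, on by default).
* **Substrate preference** (`substrate_preference()`): argmax over the
  fixed eight-substrate MU panel; ties break to the earlier panel
  member; all-zero/missing/depleted profiles give `"none"`. The result
  is invariant under positive scaling of all rates. The panel is fixed
  at eight MU glycosides (cellobioside, lactoside, glucoside,
  galactoside, xyloside, arabinofuranoside, mannoside,
  N-acetyl-glucosaminide); substrates outside the panel are rejected by
  the simulators with an informative error.
* **pH optimum** (`ph_optimum()`): grid argmax on the citrate-phosphate
  series (pH 4–7.7). A maximum on the top grid point is treated as
  censored: the glycyl-glycine extension series (pH 7–9.8) is required
  (error if absent) and the global argmax over both series is returned.
  Ties break to lower pH.
* **Thermal stability** (`fit_vant_hoff()`): nonlinear least squares
  (`minpack.lm::nlsLM`) of the two-state model, ≥ 4 points, with a
  multi-start grid — `Tm` at the temperatures bracketing the half-max
  rate × `ΔH ∈ {100, 200, 400}` kJ/mol — keeping the converged fit with
  the lowest residual sum of squares. Curves with no clear decrease
  (min rate > 0.75 × max) are rejected as unidentifiable, and a fitted
  `Tm` more than 10 °C outside the grid is flagged `extrapolated`.
* **Mechanism** (`classify_mechanism()`): retaining iff
  residual/control < 0.5; a nonpositive control rate is an error.

# 4. Kinetics

`fit_michaelis_menten()` fits `v = Vmax·S/(Km+S)` per replicate with
`nlsLM` (`Vmax` initialized at the maximum observed rate, `Km` by
interpolating the concentration at half of it) and reports the mean
across replicates with the sample SD as uncertainty, the convention used
for triplicate enzymology tables. `kcat = Vmax/[E]`. A fitted `Km` more
than 10 × the largest assayed concentration is flagged
`poorly_determined`. `specificity_constant()` forms `kcat/Km` with
first-order propagation `sd = ratio·sqrt((sd_kcat/kcat)² + (sd_km/km)²)`.
`protein_conc_from_a280()` converts A280 to µM via Beer–Lambert with a
sequence-derived molar extinction coefficient (default
128,480 M⁻¹ cm⁻¹).

# 5. Cataloging

* **Pairwise identity** (`pairwise_identity()`): end-gap-free global
  alignment (`Biostrings::pairwiseAlignment`, `type = "overlap"`,
  match +1 / mismatch −1, gap opening 4 / extension 1). Identity is
  matches over alignment columns; coverage is the aligned span over the
  shorter sequence. Both orientations are tried by default (reverse
  complement via `revcomp()`).
* **Clustering** (`cluster_redundant()`): pairs passing > 95% identity
  and > 90% coverage are edges; clusters are the connected components
  (`igraph`), so redundancy is single-linkage. A k-mer (k = 15)
  containment prefilter (threshold 0.02) skips alignments between
  unrelated inserts — at 2% substitution divergence true duplicates
  share most 15-mers while random 35-kb inserts share essentially none —
  and also picks the alignment orientation. Representatives are the
  longest insert per cluster; IDs are sorted for determinism. The
  `analysis/` and acceptance runs use 4-kb inserts so the full
  all-pairs alignment pass stays fast; the rule itself is
  length-agnostic and the tests verify identity values against an
  independent column-count oracle.
* **PULs** (`detect_puls()`): an adjacent same-strand SusC→SusD pair in
  transcriptional order — `(SusC, SusD, "+")` in coordinates on the
  plus strand, `(SusD, SusC, "-")` on the minus strand. The call
  records whether a GH3 ORF follows within the next 3 downstream ORFs
  and which GH16/GH144 families occur within a ± 10-ORF window.
  `max_intervening > 0` relaxes adjacency and flags such calls.
* **Multi-GH clusters** (`detect_gh_clusters()`): a fosmid with ≥ 5
  `GH*` ORFs is flagged.
* **Bookkeeping**: `hit_rate()` is `round(clones/hits)` (NA for zero
  hits); `dual_screen_accounting()` gives
  `unique = A + B − both` and `single = unique − both`;
  `screen_summary()` assembles per-library and total rates, dual-screen
  accounting and ORF statistics into one object with TSV writers.

# 6. What the generator emulates — and what it does not

Emulated: rare actives among a large inactive background; saturating
endpoint signal; exact substrate-depletion kinetics; buffer-grid pH
profiles with censoring at the top of the primary buffer range;
two-state thermal denaturation; mechanism-specific inactivation;
redundant library picks; PUL-like gene cassettes.

Not emulated: plate spatial gradients are off by default (available via
`row_effect_sd`/`col_effect_sd`); expression variation beyond a single
lognormal factor; product inhibition and enzyme inactivation during the
assay; asymmetric pH profiles; sequencing error beyond substitutions in
planted duplicates; real gene structure (ORFs are abstract labeled
intervals); chimeric inserts.

# 7. Numerical and design choices

* Bisection for the progress curve (no closed form in elementary
  functions; the Lambert-W form would add a dependency) — verified in
  the tests against a fine-step Runge–Kutta integration of
  `dP/dt = Vmax(S0−P)/(Km+S0−P)`.
* Multi-start `nlsLM` for the van't Hoff fit: the RSS surface has a
  `Tm`–`ΔH` trade-off ridge and single starts can stall on flat curves.
* Strict `>` at both screening thresholds, first-maximum tie-breaks
  (panel order for substrates, lower pH for optima) — deterministic
  outputs for identical inputs.
* `"depleted"` as a value, not an error: a too-fast time course is an
  expected outcome of a fixed sampling grid, and preference profiling
  must continue past it.
* OD600 normalization defaults to on whenever an OD is present, since
  lysate rates are only comparable per cell density; pass
  `normalize_od = FALSE` for purified-enzyme assays.
* Triplicate rescreens are simulated as full-plate reads (see §2).
* All scaled-down problem sizes in tests and drivers (4-kb clustering
  inserts, plate counts, replicate counts) are the package's own
  runtime choices and are documented where used.
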