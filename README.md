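# fosmidscreen

Simulation and analysis of plate-based functional metagenomic screens for
glycoside hydrolases (GHs).

In a functional screen, a large-insert fosmid library built from an
environmental or host-associated microbial community is arrayed in 384-well
plates and assayed with a fluorogenic substrate — typically a
4-methylumbelliferyl (MU) glycoside — so that any clone expressing an
enzyme that cleaves the glycosidic bond releases fluorescent MU. Active
clones are rare (on the order of one per few hundred clones), so hit
calling must be robust to the contamination the hits themselves introduce
into plate statistics. Confirmed hits are then characterized
biochemically: substrate preference across an MU-glycoside panel, pH
optimum, thermal stability, catalytic mechanism, and Michaelis–Menten
kinetics. Finally the hit inserts are sequenced and catalogued: redundant
clones are collapsed, GH family content is tabulated, and multi-gene
structures such as polysaccharide utilization loci (PULs) are detected.

`fosmidscreen` implements this entire pipeline against a fully specified
forward model, so every estimator can be tested against planted ground
truth:

1. **Simulate** — `simulate_library()`, `simulate_screen()`,
   `simulate_timecourse()`, `simulate_insert_and_annotation()`,
   `simulate_catalog_study()`. Plate reads are additive Gaussian
   background plus Michaelis–Menten signal under multiplicative lognormal
   noise; time courses follow the exact integrated progress curve
   `Vmax·t = P + Km·ln(S0/(S0−P))`.
2. **Screen** — per-plate robust Z-scores
   `z = (x − median) / (1.4826 · MAD)` with strict thresholds (Z > 10
   primary, Z > 3 secondary) and triplicate validation by the median
   replicate Z (`robust_zscore()`, `call_hits()`, `validate_hits()`).
3. **Characterize** — calibrated initial rates restricted to ≤ 10%
   substrate consumption, substrate preference over the eight-substrate MU
   panel, pH optimum with a censoring-aware buffer extension, van't Hoff
   two-state thermal denaturation
   `v(T) = v0 / (1 + exp[(ΔH/R)(1/Tm − 1/T)])`, and
   retaining/inverting mechanism classification from 2-fluoroglycoside
   inactivation (`estimate_initial_rate()`, `substrate_preference()`,
   `ph_optimum()`, `fit_vant_hoff()`, `classify_mechanism()`).
4. **Kinetics** — per-replicate Michaelis–Menten fits reported as
   mean ± SD, `kcat = Vmax/[E]`, and specificity constants `kcat/Km` with
   first-order error propagation (`fit_michaelis_menten()`,
   `specificity_constant()`).
5. **Catalog** — redundancy clustering at > 95% identity over > 90% of the
   shorter insert (end-gap-free alignment with a k-mer containment
   prefilter), GH-family abundance tables, SusC/SusD PUL detection in
   transcriptional order, ≥ 5-GH cluster flagging, and screen bookkeeping
   (`cluster_redundant()`, `detect_puls()`, `tabulate_gh_abundance()`,
   `screen_summary()`).

## Worked example

Screen one 384-well plate at an elevated active fraction, validate the
hit in triplicate, characterize it, and fit its kinetics:

```r
library(fosmidscreen)

cfg <- simulation_config(active_fraction = 1 / 96, seed = 7)
clones <- simulate_library(cfg)

plate <- simulate_screen(clones, "MU-C", config = cfg)[[1]]
hits <- call_hits(plate, threshold = 10)
subset(hits, passed)[, c("clone_id", "well", "zscore", "passed")]
#>        clone_id well zscore passed
#> 92 LIB01_01_D20  D20   99.5   TRUE

reps <- lapply(1:3, function(i) simulate_screen_plate(clones, "MU-C", config = cfg))
val <- validate_hits(subset(hits, passed), reps)
val[, c("clone_id", "zscore", "validated")]
#>        clone_id zscore validated
#> 92 LIB01_01_D20   99.5      TRUE

hit <- clones[[match(val$clone_id[1], sapply(clones, `[[`, "clone_id"))]]
prof <- characterize_clone(hit, cfg, noise_sd = 1, series_noise = 0.03)
#> LIB01_01_D20: optimal substrate MU-C, pH optimum 6.1, Tm 65.9 C, inverting

grid_um <- c(0.5, 1, 2, 5, 10, 20, 50, 100, 200, 500, 1000)
true_v <- sapply(grid_um, function(s)
  clone_velocity(hit$enzymes, prof$optimal_substrate, s, 0.002))
set.seed(1)
rates <- sapply(1:3, function(r) true_v * (1 + rnorm(11, 0, 0.05)))
fit <- fit_michaelis_menten(rate_dataset(grid_um, rates, 0.002, prof$optimal_substrate))
#> kcat = 29.4 +/- 0.2 s^-1, Km = 0.033 +/- 0.001 mM, kcat/Km = 879 +/- 23 mM^-1 s^-1
```

## Analysis workflow

`analysis/` holds five numbered drivers that run the pipeline end to end
on a simulated two-library screen (4,608 clones, twelve plates). Run them
in order from the repository root after installing the package; small
tables land in `results/`, regenerable raw data in `scratch/` (not
tracked):

```sh
Rscript analysis/01_simulate.R      # library + endpoint screen
Rscript analysis/02_screen.R        # robust-Z hit calling + triplicate validation
Rscript analysis/03_characterize.R  # panel rates, pH, Tm, mechanism per hit
Rscript analysis/04_kinetics.R      # Michaelis-Menten fits + specificity constants
Rscript analysis/05_catalog.R       # clustering, PULs, GH abundance, bookkeeping
```

Output from a full run (seeds fixed in the scripts):

```
Simulated 4608 clones in 2 libraries across 12 plates.
Latent truth: 19 clones carry at least one active enzyme (expected ~19.3 at 1/239).
Primary screen: 13 / 4608 wells exceed robust Z = 10.
Triplicate validation: 13 / 13 primary hits confirmed.
Characterized 13 validated hits.
Tm range 37.6-70.7 C (mean 54.0 C); pH optima 4.6-7.3.
Highest specificity constant: LIB01_06_L14 on MU-Glc, kcat/Km = 1060 +/- 97 mM^-1 s^-1
Redundancy: 164 fosmids collapse to 115 nonredundant clusters (49 planted duplicate pairs).
PULs: adjacent same-strand SusC/SusD pairs on 11 fosmids (11 planted).
Multi-GH: 25 fosmids carry >= 5 GH ORFs (15.2%; 25 planted).
```

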