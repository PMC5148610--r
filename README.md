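# oplconnect

Quantitative analysis of photoreceptor-to-bipolar-cell connectivity in
serial block-face EM reconstructions of the mouse outer plexiform layer
(OPL), for retinal connectomics researchers who have skeletons, terminal
geometries and contact-point tables — or who want a fully labelled
synthetic volume to develop against.

Dense EM of the outer retina yields thousands of membrane contacts between
bipolar cell (BC) dendrites and cone pedicles / rod spherules, of which only
a fraction are synapses. The staining used for dense reconstruction shows no
ribbons or postsynaptic densities, so synapses must be inferred from the
stereotyped geometry of the photoreceptor synapse: invaginating dendritic
tips (ON-CBCs, RBCs), basal contacts at the pedicle base (OFF-CBCs), and
non-synaptic peripheral touches everywhere else.

The package implements, as tested tibble-first functions:

* **`simulate_opl()`** — a synthetic OPL generator (cone mosaic with ~5%
  S-cones, dense half-field rod array, per-type BC mosaics with realistic
  dendritic-field areas and coverage factors, rule-based synaptic wiring,
  spurious peripheral contacts, SAC/ChAT band surfaces, CBC5 axonal clouds)
  with full ground truth;
* **`extract_contact_features()`** — per contact-set (one BC, one terminal):
  contact area *a*, eccentricity *b*, normalized contact height *c*,
  along-dendrite distances to branch point *d* and dendritic tip *e*, the
  dendrite–optical-axis angle *f*, point count *g*, and for OFF-CBC rod
  contacts the distance *h* to the nearest synaptic RBC contact;
* **`train_contact_classifier()` / `loo_cross_validate()`** — per-group RBF
  C-SVMs (OFF/ON/RBC × cone/rod) with leave-one-out grid selection,
  fold-internal standardisation, and Table-style FPR/FNR/total-score
  reports;
* **`find_scone_candidates()` / `classify_scones()` /
  `binomial_test_exact()`** — strict and liberal S-cone identification from
  CBC9 connectivity (CBC9 contacts every S-cone in reach, at dendritic
  tips), with the exact upper-tail binomial test
  P(X ≥ k | n, p₀);
* **`classify_cbc5()`** — CBC5 → 5T/5O/5I via SAC-band-corrected axonal
  depth profiles, PCA, a 3-component Gaussian mixture, and greedy
  shift/swap refinement of the cost
  ℒ = λ₁ Σᵢ (xᵢ−μ_cᵢ)ᵀ Σ_cᵢ⁻¹ (xᵢ−μ_cᵢ) + λ₂ Σ_{i≠j} δ_{cᵢcⱼ} O_ij,OPL / Σᵢ A_i,OPL
  + λ₂ Σ_{i≠j} δ_{cᵢcⱼ} O_ij,IPL / Σᵢ A_i,IPL,
  penalising same-cluster convex-hull overlap in both plexiform layers;
* **`convergence_divergence()`, `coverage_factors()`,
  `contact_distance_kde()`, `rod_connectivity()`, `rbc_group_compare()`,
  `bootstrap_ci()`, `contact_type_tally()`** — the headline circuit
  statistics with 95% percentile bootstrap CIs;
* **`run_opl_pipeline()`** — simulate/ingest → features → classify →
  S-cones → CBC5 → connectivity in one reproducible, seeded call, with
  SWC/CSV/JSON round-tripping (`read_swc()`, `write_opl_dataset()`, …).

## Worked example

```r
library(oplconnect)
library(dplyr)

cfg <- opl_config(field_size = c(60, 50), seed = 1,
  bc_type_params = default_bc_type_params() |>
    filter(type %in% c("CBC2", "CBC6", "CBC9", "RBC")) |>
    mutate(n_cells = c(6L, 10L, 3L, 20L)))
sim <- simulate_opl(cfg)
sim
#> <opl_sim> 56 cones (4 S), 716 rods, 39 BCs, 844 contact points in 521 contact-sets

run <- run_opl_pipeline(cfg, dataset = sim)
glance(run$cv_reports$ON_CBC_cone)
#> # A tibble: 1 × 7
#>   group       n_train false_positive_rate false_negative_rate total_score  cost gamma
#>   ON_CBC_cone      87                   0                   0           1     1  0.01
```

The ON-CBC classifier separates synaptic from peripheral contact-sets
perfectly here (synthetic contacts are cleaner than EM data, where ~90% is
typical). The S-cone stage recovers all four planted S-cones from CBC9
wiring alone:

```r
c(candidates = nrow(run$scones$candidates),
  strict_S  = sum(run$scones$strict$spectral == "S"),
  in_reach  = length(run$scones$in_reach))
#> candidates 4   strict_S 4   in_reach 53

run$coverage
#> # A tibble: 4 × 6
#>   type  n_cells hull_area_mean hull_area_sd hull_coverage cone_coverage
#> 1 CBC2        6           202.        17.8           1.23          1.19
#> 2 CBC6       10           128.         8.49          1.29          1.27
#> 3 CBC9        3          2252.       128.            1.83          2.16
#> 4 RBC        20           129.         7.51          2.29          2.58
```

Coverage factors (summed hull areas over their union) land on the
configured per-type targets — e.g. CBC9's sparse giant fields at 1.83, the
RBC mosaic at 2.29. At the full default field size an RBC collects ≈35 rods
(here, on a 60 × 50 µm field, `run$rods$rods_per_type` reports 28.8 with CI
[22.4, 34.4] for the 12 RBCs with somata inside the rod area).

The exact binomial test asks whether a liberal S-cone call of 14 out of 124
in-reach cones is compatible with the ~5% S-cones known from
immunostaining:

```r
binomial_test_exact(14, 124, 0.05)
#> 0.0037428
```

## Documentation

The methods vignette (`vignettes/outer-retina-connectivity.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and the
numerical conventions (tie-breaks, tolerances, degenerate inputs).
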