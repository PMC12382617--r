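# ebikin

Dose–response kinetics of antibiotic degradation under electron-beam
irradiation (EBI).

Water contaminated with antibiotic residues can be treated with accelerated
electrons: direct ionization and water-radiolysis radicals (OH•, H•,
hydrated electrons) break the molecules down. For anyone analyzing such
treatments — radiation chemists, environmental analytical chemists, water
treatment engineers — this package turns triplicate LC-MS peak-area dose
series into kinetic coefficients, removal statistics, dosimetry
calibrations and degradation-marker rankings.

## The model

The parent antibiotic decays first-order in absorbed dose *D* (kGy):

    C_a(D) = C0 · exp(−α D)

A degradation product accumulates from the parent and decays itself, but
only above a threshold dose D0 (the dose needed to drive the ionization
events that form it):

    dC_p/dD = −β C_p + k C_a(D),   C_p(D0) = 0
    C_p(D)  = H(D−D0) · k C0/(β−α) · [e^{(β−α)D} − e^{(β−α)D0}] · e^{−β D}

Estimation is sequential: (C0, α) per antibiotic by Levenberg–Marquardt,
then (β, D0, k) per product with the parent frozen, the non-smooth D0
handled by grid search with analytic profiling of k and a Nelder–Mead
refinement. Because the product model is linear in the parent's C0, a
fitted marker inverts to the initial contamination level:
Ĉ0 = Σ y·f / Σ f² with f the unit-C0 prediction.

Around the kinetics: removal percentages with Student-t intervals, a
balanced two-factor ANOVA (direct sums-of-squares) with Tukey pairwise
comparisons, Fricke ferrous-sulfate dosimetry with a zero-intercept
charge→dose calibration, a curated ledger of DFT bond-dissociation
energies and ionization-event counts for marker ranking, and a synthetic
generator emulating the triplicate measurement design (multiplicative
noise ≤ 20% CV, ND-censoring below the detection limit).

## Worked example

```r
library(ebikin)

models <- reference_models()                      # bundled coefficient set
tab <- simulate_noiseless(models["tetracycline"], c(0, 0.1, 1, 3, 7))
fit_antibiotic(tab, "tetracycline")
#> antibiotic fit [tetracycline]: C0 = 100, alpha = 1.28 +/- 0 kGy^-1, R_corr = 1 (n = 5)

removal_percent(fit_antibiotic(tab, "tetracycline")$model, 7)
#> [1] 99.98716
```

The fitted α = 1.28 kGy⁻¹ is the decomposition rate per unit dose; at
7 kGy it implies 99.99% removal of tetracycline. The same pipeline on the
threshold-dose product model recovers a product's (β, D0, k) and ranks
markers by how many ionization events their formation requires:

```r
rank_markers(load_pathway_ledger())[, c("rank", "product", "total_events", "fitted_D0_kGy")]
#>    rank product   total_events fitted_D0_kGy
#>       1 DP-TC-399            2          0.09
#>       2 DP-TC-460            2          0.98
#>       3 DP-TC-383            4          0.09
#>       4 DP-TC-415            4          0.53
#>       5 DP-TC-436            5          1.04
```

Products needing only two ionization events appear at the lowest doses and
are the reliable markers; reconstructing the initial contamination from a
simulated noisy dose series of the top marker returns
`100.4 +/- 1.4 rel.un.` against a truth of 100.

## The analysis workflow

The `analysis/` directory holds the narrative drivers, run in order from
the repository root after installing the package:

1. `01_simulate_dose_series.R` — simulate the noiseless and noisy campaigns
2. `02_fit_kinetics.R` — recover all kinetic coefficients
3. `03_removal_anova.R` — removal tables, two-factor ANOVA, Tukey pairs
4. `04_dosimetry.R` — Fricke dose and charge→dose calibration
5. `05_rank_markers.R` — marker ranking and contamination reconstruction

Each writes its tables under `results/`.

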