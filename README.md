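# protacfold

Conformational-ensemble analysis for bifunctional degraders (PROTACs),
aimed at the question a linker designer actually asks: *does this molecule
fold in an apolar environment and hide its polarity, and does that folding
track with cell permeability?*

PROTACs sit far beyond rule-of-5 space, yet some cross membranes well. The
accepted rationale is chameleonic folding: in chloroform-like environments a
permeable PROTAC adopts folded conformations stabilized by intramolecular
hydrogen bonds (IMHBs), burying polar surface that it re-exposes in water.
`protacfold` implements the NMR- and descriptor-based pipeline used to
characterize that behavior, end to end, with a synthetic-data module that
provides exact ground truth for every stage.

## What it computes

**NOE distances.** Normalized NOESY intensities
`I = sqrt((c1*c2)/(d1*d2))`, initial-rate buildup fitting (longest window of
≥ 4 consecutive mixing times with r² > 0.95), and distances by the isolated
spin-pair approximation `r_ij = r_ref * (sigma_ref/sigma_ij)^(1/6)` against
the geminal methylene reference (1.78 Å). NH temperature coefficients
classify as shielded/strong-IMHB at |Δδ/ΔT| < 3 ppb/K.

**NAMFIS deconvolution.** Simplex-constrained least squares

    min_w  Σ_j ( d_exp,j − Σ_i w_i d_ij )²,   w_i ≥ 0,  Σ_i w_i = 1

(linear or r⁻⁶ ensemble averaging; CH2/CH3 pseudo-atoms via r⁻⁶ member
averaging), with AIC = n·ln(SSE/n) + 2k model comparison, degeneracy
reporting, and validation by 10% multiplicative-noise refits plus
per-restraint jackknife.

**Ensemble descriptors.** Mass-weighted radius of gyration; Shrake–Rupley
SASA (1.4 Å probe, deterministic point set); solvent-accessible 3D polar
surface area (SASA over polar atoms, |q| > 0.1 e or N/O/S + attached H);
geometric IMHB counts (3.5 Å, 135°, ≥ 4 bonds); population-weighted means.

**Shape and clustering.** NPR1/NPR2 principal-moment ratios, Kabsch
superposition, Cartesian PCA, seeded K-means (k = 5) with size-canonical
labels, greedy max–min diverse subsets (26 per cluster), automated
folded/semi-folded/linear classification by normalized end-to-end extension,
and per-atom RMSF.

**Permeability surrogates.** Cell/biochemical IC50 ratio (low = permeable),
geometric-mean Caco-2 passive permeability, and a Spearman rank report of
low polar surface vs high permeability.

## Worked example

Generate a model compound whose ensemble is 60% folded / 30% semi-folded /
10% linear, simulate its NOE experiment at 1% noise, and reconstruct the
ensemble from the data alone:

```r
library(protacfold)

p <- synthetic_preset("protac1", n_conformers = 100, seed = 7)
pairs <- default_restraint_pairs(p$molecule)
sim <- simulate_noe_buildups(p$bundle, pairs,
                             mixing_times = seq(0.005, 0.035, by = 0.005),
                             anchor_time = 0.7, noise_fraction = 0.01, seed = 7)
restraints <- derive_restraints(sim$curves, pairs, "ref")
head(restraints[, c("pair_id", "distance", "kind", "r_squared")], 3)
#>   pair_id distance kind r_squared
#> 1   H1_H4 4.768999  CH2 0.9999916
#> 2   H2_H5 4.906073  CH2 0.9999824
#> 3   H4_H7 4.734015  CH2 0.9999556

lib <- deduplicate_conformers(p$bundle$library, rmsd_cutoff = 3)
fit <- fit_populations(back_calculate(lib, restraints), restraints$distance)
fit
#> ensemble_fit (linear averaging): 3 of 3 conformers selected; fit RMSD 0.12 A; AIC -70.43
round(fit$weights, 2)
#> [1] 0.63 0.29 0.07
p$bundle$fold_labels[attr(lib, "kept")]
#> [1] "folded"      "semi_folded" "linear"
```

The 3 Å redundancy filter collapses the 100 conformers to the three fold
templates, and the fitted populations (0.63/0.29/0.07) recover the
generating fold mixture (0.6/0.3/0.1) from the simulated NMR data. The
ensemble descriptors quantify the chameleonic character:

```r
ensemble_descriptors(p$bundle$library)
#> descriptor_table: 100 conformers
#> population-weighted means: Rgyr 4.356 A; SASA 574.4 A2; SA 3D PSA 38.26 A2; #IMHB 0.44

r <- cell_bio_ratio(0.924, 0.244)   # published IC50s, uM
sprintf("cell/bio ratio %.2f (displays %d)", r$ratio, r$display)
#> [1] "cell/bio ratio 3.79 (displays 4)"
```

Across the three presets (`protac1` folded-shifted → `protac3`
extended-shifted) the weighted mean SA 3D PSA rises monotonically while the
IMHB count falls, and the ranking against the published passive
permeabilities (30, 11, 6 nm/s) is perfectly concordant — the package's
operational form of "folded, low-polarity ensembles are the permeable ones".

## Analysis workflow

The `analysis/` directory holds the numbered drivers that run the full
study on the synthetic compounds and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_ensembles.R` | generate the three compounds + NOE buildups |
| `02_noe_distances.R` | buildups → distance restraints |
| `03_namfis_fit.R` | dedupe → population fit → validation |
| `04_descriptors.R` | Rgyr / SASA / SA 3D PSA / IMHB tables and means |
| `05_shape_clustering.R` | NPR, PCA, K-means, subsets, fold classes, RMSF |
| `06_permeability.R` | surrogates + descriptor-permeability ranking |

Run them in order from the repository root: `Rscript analysis/01_...` etc.

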