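---
title: "Conformational ensembles and degrader permeability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensembles and degrader permeability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protacfold)
```

## The problem

Bifunctional degraders (PROTACs) live far beyond the rule-of-5: they are
large, flexible, and carry more polarity than a passively permeable molecule
should. Some of them nevertheless cross membranes well. The working
explanation is *chameleonicity*: in an apolar environment the molecule folds,
forms intramolecular hydrogen bonds (IMHBs), and buries its polar surface; in
water it unfolds and exposes that surface. Whether a given linker chemistry
permits such folding is therefore a design question, and answering it requires
a description of the *solution conformational ensemble*, not a single
structure.

`protacfold` implements the analysis chain used to build that description:

1. **NOE buildup analysis** — NOESY cross-peak intensities as a function of
   mixing time give interproton distances via the initial-rate approximation.
2. **NAMFIS-style deconvolution** — time-averaged distances are decomposed
   into a population-weighted set of discrete conformers.
3. **Ensemble descriptors** — radius of gyration, solvent-accessible surface
   area (SASA), solvent-accessible 3D polar surface area (SA 3D PSA), and
   IMHB counts, per conformer and population-weighted.
4. **Shape and clustering** — principal-moment ratios (NPR1/NPR2), Cartesian
   PCA, K-means clustering, diverse-subset selection, and an automated
   folded / semi-folded / linear classification.
5. **Permeability surrogates** — the cellular/biochemical potency ratio and
   the Caco-2 geometric-mean passive permeability, ranked against the
   ensemble descriptors.

A synthetic-data module generates model bifunctional molecules and NOE data
with exact ground truth, so every stage is testable without proprietary
conformational searches or spectrometer time.

## NOE distances

Normalized NOE intensities use the symmetric two-peak normalization
$I = \sqrt{(c_1 c_2)/(d_1 d_2)}$ over cross peaks $c$ and diagonal peaks
$d$. The buildup rate $\sigma$ is the slope of the *initial linear regime*
of $I(\tau_m)$: the fitter scans all windows of at least 4 consecutive
mixing times, requires $r^2 > 0.95$, and takes the longest qualifying
window, breaking ties toward the earliest start. The regression carries a
free intercept: forcing the line through the origin is an extra assumption
the data need not satisfy, and with it small zero-offsets would bias the
slope. Distances follow the isolated spin-pair approximation,

$$ r_{ij} = r_\mathrm{ref}\,(\sigma_\mathrm{ref}/\sigma_{ij})^{1/6}, $$

with the geminal methylene pair ($r_\mathrm{ref} = 1.78$ Å) as internal
standard. Restraints outside 1.5–6.0 Å (configurable) are flagged, not
discarded: distances beyond ~6 Å are not NOE-observable in practice, so an
out-of-window value signals a problem upstream. Amide NH temperature
coefficients classify as shielded/strong-IMHB when $|\Delta\delta/\Delta T| <
3$ ppb/K (strict inequality, matching the conventional cut-off).

## NAMFIS deconvolution

Given a library of $N$ conformers and $n$ experimental distances, the fit
solves

$$ \min_{w}\; \sum_j \left( d^\mathrm{exp}_j - d^\mathrm{ens}_j(w) \right)^2
   \quad \text{s.t. } w_i \ge 0,\; \textstyle\sum_i w_i = 1 $$

with $d^\mathrm{ens}_j = \sum_i w_i d_{ij}$ (linear averaging, the default)
or $d^\mathrm{ens}_j = (\sum_i w_i d_{ij}^{-6})^{-1/6}$ ($r^{-6}$
averaging). The literature phrase "population-weighted distances" does not
fix the convention, so it is a switch and both paths are tested. Pseudo-atom
distances (CH2, CH3) are combined by the $r^{-6}$ mean over member-proton
pairs, which reduces to the standard two- and three-term formulas.

The linear problem is convex; it is solved by Lawson–Hanson non-negative
least squares on a penalty-augmented system (a heavily weighted
$\sum_i w_i = 1$ row, followed by exact renormalization). The dual-feasibility
stopping test is scaled by the data block, not the penalty row — scaling it by
the full gradient would stop the active-set iteration several orders of
magnitude too early. The $r^{-6}$ problem is non-convex in $w$; it is
minimized by BFGS on a softmax parameterization, started both from the
linearized solution (NNLS on $d^{-6}$) and from uniform weights.

Model parsimony uses the least-squares information criterion
$\mathrm{AIC} = n \ln(\mathrm{SSE}/n) + 2k$ with $k$ the number of weights at
or above the 1% report threshold; fits within $|\Delta\mathrm{AIC}| < 2$ are
reported as equivalent. Near-duplicate conformer columns (profile correlation
> 0.999) make weight splits non-identifiable; they are reported, never
silently merged.

**Validation.** Two perturbation schemes: (a) refits with every distance
multiplied by $(1+u)$, $u \sim U(-0.1, 0.1)$; (b) leave-one-out refits per
restraint. Each refit's drift is the largest absolute weight change. The
ensemble is *stable* when the **mean** drift over noise trials and the
**maximum** jackknife drift both stay below 0.10. The mean — not the maximum
— summarizes the stochastic scheme deliberately: the maximum over trials is
an extreme-value statistic that grows with the number of trials, and
simulation shows it sits at 0.10–0.22 even for ideally conditioned systems
(random 40×5 distance matrices), where the mean drift is well below 0.10.
The jackknife set is finite and deterministic, so its maximum is meaningful.

## Descriptors

* $R_\mathrm{gyr}$ is mass-weighted about the center of mass.
* SASA uses Shrake–Rupley sphere sampling with a 1.4 Å water probe, Bondi
  radii, and a deterministic Fibonacci-lattice point set (default 960 points
  per atom, ~1% accuracy on an isolated sphere), so values reproduce
  bit-for-bit.
* SA 3D PSA is the SASA summed over polar atoms. An atom is polar when its
  partial charge magnitude exceeds 0.1 e, or — with the element fallback, or
  whenever the structure carries no charges — when it is N, O, S, or an H
  bonded to one. The 0.1 e threshold follows the per-atom-charge PSA
  protocols in the literature; a threshold of 1.0 e would classify
  essentially no atom as polar. Absolute SA 3D PSA values depend on this
  choice, so cross-compound *orderings*, not absolute areas, are the robust
  output.
* IMHBs are counted as donor-H···acceptor triples with D···A ≤ 3.5 Å,
  D–H···A ≥ 135°, and at least 4 bonds between donor and acceptor along the
  molecular graph (excluding, e.g., an amide NH against its own carbonyl).
  All three criteria are configurable; trajectory tools differ in their
  defaults and the source protocols do not print theirs.

## Shape, clustering, fold classes

Superposition is Kabsch (proper rotations only). PCA runs on flattened
Cartesian coordinates after iterative superposition onto the mean structure
(tolerance $10^{-4}$ Å), the convention of the standard trajectory-analysis
tools. K-means uses $k = 5$, 10 restarts, seeded, with labels renumbered by
descending cluster size so runs are comparable. Diverse subsets (up to 26
per cluster) use deterministic greedy max–min selection in PC space, seeded
from the member nearest the cluster centroid — the published analyses used a
commercial tool whose algorithm is unpublished, so a deterministic
re-implementation is the reproducible choice.

Fold classification is automated: with ligand centroids $A$, $B$ and the
contour length $L$ of the shortest bonded path between the ligand anchor
atoms, the normalized extension is $e = \lVert A - B \rVert / L$. Conformers
with $e < 0.35$ are *folded*, $e > 0.65$ *linear*, otherwise *semi-folded*.
The thresholds are configurable; the defaults separate the three synthetic
templates by a wide margin (template extensions ≈ 0.23, 0.44–0.47, 0.94–1.0)
and the classifier is invariant to rigid motion. The published analyses
classified conformers visually; the acceptance surface here is recovery of
by-construction labels, not reproduction of manual calls.

RMSF superposes all frames onto their mean structure and reports
$\sqrt{\langle |r_i - \bar r_i|^2 \rangle}$ per atom.

## Permeability surrogates

For an intracellularly acting degrader, the ratio
$\mathrm{IC}_{50}^\mathrm{cell} / \mathrm{IC}_{50}^\mathrm{bio}$ measures the
potency lost crossing the membrane — a low ratio means high permeability.
Display values round to the nearest integer, ties away from zero, matching
the published table (3.79 → 4, 11.99 → 12, 26.99 → 27). Passive permeability
across Caco-2 monolayers is the geometric mean
$(P_\mathrm{app}^{AB} \cdot P_\mathrm{app}^{BA})^{1/2}$. The ranking report
computes Spearman concordance between $-$SA 3D PSA and the permeability
ordering (sign agreement for two compounds) and lists discordant pairs.

## The synthetic generator

The model molecule is geometric, not physical: two planar 6-rings joined by
a saturated linker with standard 1.5 Å bonds. Ring A carries a ring nitrogen
with the only NH donor; ring B carries a ring oxygen acceptor; the linker
carries two ether oxygens at fixed positions 3 and 6 (charges −0.4 e on
N/O, +0.4 e on the NH hydrogen). Keeping the polar payload fixed across
linker lengths means that in a compound series the fold mixture, not the
atom count, drives the SA 3D PSA contrast — the synthetic analog of a series
sharing its warheads. Every linker carbon carries geminal hydrogens exactly
1.78 Å apart: the internal NOE reference is part of the molecule by
construction.

Three templates realize the fold classes: a two-turn serpentine whose
termini approach within ~5 Å and whose NH points at the acceptor (so the
folded class genuinely hydrogen-bonds), a single-turn V with a 45° apex, and
an all-anti zig-zag. Two geometric rules keep the templates honest: turn
corners and the V apex are convex, fully exposed positions, so the
construction shifts them off the ether oxygens (otherwise a "folded" or
"semi-folded" template would *expose* extra polarity and invert the intended
ordering). Ensembles perturb heavy atoms with isotropic Gaussian noise
(default 0.1 Å) and rebuild hydrogens from the perturbed frame — noising
hydrogens directly would inflate the rigid geminal distance and corrupt the
1.78 Å calibration — then apply a random rigid rotation and translation per
conformer. Fold-class counts follow the requested fractions exactly
(largest-remainder allocation), and everything is seeded.

NOE buildups are simulated from the ensemble-averaged distances with
$\sigma_j = \sigma_\mathrm{ref} (r_\mathrm{ref}/d_j)^6$ and intensities
$\sigma t (1 - \sigma t / 2)$ — a mild saturation that exercises the linear
window rule — plus multiplicative uniform noise per cross peak.
$\sigma_\mathrm{ref}$ is calibrated so the reference intensity reaches 0.3
at `anchor_time`. The anchor defaults to the last mixing time (the standard
0.1–0.7 s experiment); passing short mixing times against the 0.7 s anchor
samples only the strictly linear regime, which is how the zero-noise
round-trip recovers distances to better than 0.02 Å. At the full 0.1–0.7 s
grid the saturation biases the reference slope by design, and recovery
degrades to ~0.3 Å — the quantitative reason the field fits initial rates
only.

**What the generator does not emulate:** force-field energetics, torsional
correlations, solvent structure, spin diffusion, peak overlap, or real
linker chemistry. Passing tests therefore demonstrate that the *analysis
chain* is correct and self-consistent, not that any real PROTAC folds.

## Problem sizes and presets

The three presets mirror a permeability series: `protac1` (12-atom linker,
fold fractions 0.6/0.3/0.1), `protac2` (8-atom linker, 0.3/0.4/0.3),
`protac3` (8-atom linker, 0.1/0.2/0.7). The analysis scripts and the
acceptance script run them at 100 conformers each with SASA at 960 points
per atom — sizes at which every stage's output statistics are stable across
seeds while a full run stays interactive. The parameter-recovery study uses
100 random systems of 5–20 conformers and 15–40 restraints at 1%
multiplicative distance noise, with sparse truth supports of 2–5 conformers.

## Known limitations

* Restraint residuals are unweighted; per-restraint error bars are not
  modeled (the source protocols publish none).
* The $r^{-6}$ averaging fit is non-convex; the two documented starts have
  always reached the basin of the linearized solution in testing, but a
  global optimum is not guaranteed.
* SA 3D PSA absolute values track the polar-atom definition; only orderings
  are portable across definitions.
* The fold classifier needs the two ligand atom sets and a bonded path
  between them; it is undefined for disconnected topologies.
* NAMFIS weight splits between conformers with back-calculated profiles
  correlated above 0.999 are non-identifiable and are only reported.
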