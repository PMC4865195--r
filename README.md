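# dockscore

Empirical protein–ligand scoring functions of the Vina/Vinardo family,
with the machinery to use and to develop them at desk scale, in R.

Docking engines need a scoring function that (a) correlates with measured
binding affinities and (b) keeps an energy minimum near the
crystallographic pose — two properties that do not come together for free.
`dockscore` is aimed at people who study, teach, or prototype such
functions: it implements the pairwise potential exactly, exposes every
parameter in editable text files, and ships the evaluation and training
machinery (pose minimization, symmetry-corrected RMSD, CASF-style power
statistics, enrichment metrics, constrained parameter-grid screens)
together with deterministic synthetic fixtures so everything is testable
without external datasets.

## The model

Binding affinity is a sum over heavy-atom pairs, each evaluated on the
surface distance *d* = *r* − *R<sub>i</sub>* − *R<sub>j</sub>*:

> e(d) = w₁·Gauss1(d) + w₂·Gauss2(d) + w₃·Repulsion(d)
> + w₄·Hydrophobic(d) + w₅·HBond(d)

with Gaussian steric attraction(s) `exp(−((d−o)/s)²)`, quadratic overlap
repulsion `d²` for d ≤ 0, a hydrophobic linear ramp (hydrophobic pairs
only) and a non-directional H-bond ramp (donor–acceptor pairs only; metals
act as donors). Two presets ship as flat parameter files: `vina`
(two-Gaussian steric term, whose aromatic-carbon profile has a second
"long-range" minimum at 6.8 Å interatomic distance) and `vinardo`
(single Gaussian, w₂ = 0, hydrophobic onset at contact, revised C/N/O
radii — one steric minimum, at the sum of the pair radii). An optional
generic m–n Lennard-Jones term supports custom functions. The reported
affinity divides the intermolecular energy by `1 + 0.05846 · n_rot`
(configurable).

Structures are read and written in AutoDock PDBQT, including the ligand
ROOT/BRANCH torsion tree; poses are minimized by BFGS over translation,
quaternion orientation and torsions; pose distances use
Hungarian-assignment symmetry-corrected RMSD.

## Worked example

Score a synthetic six-carbon pocket with a one-carbon ligand at exact
contact under the `vinardo` preset:

```r
library(dockscore)
ps <- scoring_params("vinardo")
pk <- make_toy_pocket(6, ligand_type = "C", receptor_type = "C", params = ps)
sc <- score_complex(pk$ligand, pk$receptor, ps)
print(sc$breakdown)
#> <score_breakdown> total -0.4800 over 6 pair(s)
#>             raw weighted percent
#> gauss1        6    -0.27   56.25
#> gauss2        0     0.00    0.00
#> repulsion     0     0.00    0.00
#> hydrophobic   6    -0.21   43.75
#> hbond         0     0.00    0.00
#> lj            0     0.00    0.00
```

Each of the six contacts sits at surface distance 0: Gauss1 is exactly 1
per pair (raw 6), the hydrophobic ramp is fully engaged, and repulsion is
zero, so the total is 6 × (−0.045 − 0.035) = −0.48. With no rotatable
bonds the affinity equals the total. The steric-profile scan reproduces
the two minima of the `vina` aromatic-carbon curve — contact and the
long-range one:

```r
find_steric_minima(scoring_params("vina"), "CA", "CA", r_range = c(3, 12))
#> [1] 3.802874 6.800000
```

Decoy poses and screening tables come with exact annotations:

```r
lig <- make_toy_ligand(2)                      # 5-atom chain, 2 torsions
dec <- make_pose_decoys(lig, n = 4, rmsd_bins = list(c(0, 0.5), c(1, 2)),
                        seed = 1)
round(dec$rmsd, 3)
#> [1] 0.000 1.497 0.197 1.311

tab <- make_screening_table(25, 200, separation = 1.5, seed = 42)
cat("AUC:", round(roc_auc(tab$predicted, tab$label), 3),
    " BEDROC:", round(bedroc(tab$predicted, tab$label), 3), "\n")
#> AUC: 0.781  BEDROC: 0.608
```

AUC is overall enrichment (0.5 = random); BEDROC(α = 20) weights early
recognition (≈ 0.05 random at small active fractions). A thin command-line
wrapper over the same functions lives at
`system.file("scripts", "dockscore", package = "dockscore")` with
`score`, `minimize`, `search`, `rmsd`, `evaluate`, `grid` and `fixtures`
subcommands.

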