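---
title: "Empirical pair-potential scoring: model, machinery and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical pair-potential scoring: model, machinery and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscore)
```

## The model

`dockscore` predicts protein–ligand binding affinity as a sum of
distance-dependent heavy-atom pair interactions. Every pair is evaluated on
its *surface distance*

$$ d = r - R_i - R_j, $$

the interatomic distance minus the two atomic radii, so that $d = 0$ means
van der Waals contact and $d < 0$ overlap. The weighted pair energy is

$$ e_{pair}(d) = w_1\,G_1(d) + w_2\,G_2(d) + w_3\,\mathrm{Rep}(d)
   + w_4\,\mathrm{Phob}(d) + w_5\,\mathrm{HB}(d), $$

with

* $G_k(d) = \exp\!\big(-((d - o_k)/s_k)^2\big)$ — Gaussian steric
  attraction(s). The first Gaussian sits at contact ($o_1 = 0$); the
  optional second sits 3 Å outside contact and produces a long-range
  attraction.
* $\mathrm{Rep}(d) = d^2$ for $d \le 0$, else 0 — quadratic overlap
  repulsion. Gaussian attraction plus quadratic repulsion reproduces the
  familiar Lennard-Jones-like well without its stiffness.
* $\mathrm{Phob}(d)$ — a linear ramp from 1 at $d \le p_1$ to 0 at
  $d \ge p_2$, applied only when **both** atoms are hydrophobic (carbon
  bonded to no heteroatom, or a halogen).
* $\mathrm{HB}(d)$ — a linear ramp from 1 at $d \le h_1 < 0$ to 0 at
  $d \ge 0$, applied only to donor–acceptor pairs. It is non-directional:
  distance is the only variable. Metals count as donors.

A generic $m$–$n$ Lennard-Jones term (`lj_mn_term()`) is available for
user-defined parameter sets (e.g. a soft 4–8 steric alternative); neither
shipped preset uses it.

Two presets ship as editable key–value files (`scoring_params("vina")`,
`scoring_params("vinardo")`). Their scientific difference is the steric
term: the `vina` preset combines two Gaussians, which gives the
aromatic-carbon pair potential a second, physically hard-to-justify minimum
about 3 Å outside contact (at 6.8 Å interatomic distance;
`find_steric_minima()` locates it); the `vinardo` preset removes the second
Gaussian ($w_2 = 0$), widens the remaining one ($s_1 = 0.8$ Å), starts the
hydrophobic ramp at contact ($p_1 = 0$) with an offset of 2.5 Å — roughly a
water diameter — and revises the C/N/O radii (C 2.0, aromatic C 1.9, N 1.7,
O 1.6 Å). Radii are the most sensitive parameters of the family: they move
every term at once through $d$.

The reported affinity applies a conformational-entropy scaling,
`inter / (1 + c·n_rot)` with $c = 0.05846$ by default and `n_rot` the
rotatable-bond count. The published equations are silent on this point, but
the scores the family is known for were produced by engines that apply it;
it is configurable and can be set to 0. Intramolecular (self) energy is
used only to penalize self-clash during minimization and never enters the
reported affinity — a second point on which the literature is silent and a
defensible default had to be chosen.

### Piecewise normalization

As commonly printed, the hydrophobic middle branch reads $p_2 - d$ and the
H-bond branch $d - h_1$. The first equals 1 at $d = p_1$ only when
$p_2 - p_1 = 1$ (true for the `vina` parameters, false for `vinardo`'s
$p_1 = 0, p_2 = 2.5$); the second is 0 at the onset and *rises* toward
contact, and is discontinuous at $h_1$. Both are implemented as normalized
interpolations — $(p_2 - d)/(p_2 - p_1)$ and $d/h_1$ — which restore
continuity everywhere and reduce to the printed forms exactly where those
are self-consistent. Continuity at every joint is asserted by tests.

## Atom typing

PDBQT input supplies AutoDock types; interaction classes are derived from
the type plus distance-perceived bonds (bond when
$r < 1.2\,(c_i + c_j)$ over single-bond covalent radii — PDBQT carries no
connectivity). Carbon bonded only to C/H is hydrophobic, carbon touching a
heteroatom is polar; NA/OA are acceptors; N/O holding a polar hydrogen (HD)
are donors; halogens hydrophobic; metals a class of their own, scored as
donors. Aromatic carbon means AutoDock type `A` as written in the file; no
ring perception is attempted. Hydrogens are parsed but excluded from every
pair sum — HD's only job is to mark its heavy neighbor as a donor.
Vanadium, unsupported by common preparation tools, is typed as sulfur.
Fluorine's class is not settled by the published parameter tables; the Vina
convention (hydrophobic) is adopted and lives in the editable parameter
file. Radii absent from the published tables (S, P, halogens, metals) keep
their Vina-heritage values in the same files, never in code.

## Pose minimization

The minimization variables are a rigid translation, an orientation
quaternion, and one angle per rotatable bond (`pose_dof()`). Torsions are
applied root-outward along the BRANCH tree, then the whole molecule is
rotated about its reference centroid and translated. The orientation
gradient is taken in the quaternion's 3-D tangent space (the torque about
the rotation center), torsion gradients are the classic serial-chain
Jacobian projections onto the final-frame bond axes, and the quaternion is
renormalized after every update — no Euler angles, no gimbal lock.
`energy_and_gradient()` is verified against central finite differences to
better than $10^{-4}$ relative error away from the piecewise joints.

`local_minimize()` is BFGS with a backtracking Armijo line search
(sufficient-decrease constant $10^{-4}$), gradient-norm tolerance $10^{-6}$
and an iteration cap of 10,000 by default. Three numerical guards matter in
this landscape:

* the curvature update is skipped unless $s^\top y$ exceeds a *relative*
  threshold ($10^{-8}\,\lVert s\rVert\,\lVert y\rVert$) — near-linear
  stretches of the ramps otherwise blow up the inverse Hessian;
* the first accepted update rescales the initial inverse Hessian by
  $s^\top y / y^\top y$;
* trial steps are capped at norm 10 — the repulsive wall otherwise proposes
  basin-hopping teleports.

The objective is only piecewise smooth (kinks at $d = 0$, $p_1$, $p_2$,
$h_1$), so the line search never interpolates curvature across a joint.
One consequence worth knowing: with the `vinardo` hydrophobic onset at
$p_1 = 0$, an exactly-at-contact hydrophobic pair sits *on* a kink; the
one-sided gradient there is zero and a pose can legitimately terminate on
it. The test fixtures that need analytically displaced minima therefore use
polar contacts, whose steric term is smooth at contact.

`random_restart_search()` is a deliberate desk-scale stand-in for a full
docking search: uniform random starts (translation in a box, orientation
uniform on the rotation group via normalized Gaussian quaternions, torsions
uniform in $(-\pi, \pi]$), each locally minimized, ranked by affinity,
fully reproducible from its seed. It makes no global-optimality claim.

## Symmetry-corrected RMSD

Chemically equivalent atoms make the naive index-matched RMSD overestimate
pose distances. `hungarian_rmsd()` minimizes the RMSD over assignments that
only pair atoms of identical (element, AutoDock type), solving each block
as a linear assignment problem on squared distances; tests verify it equals
the exhaustive permutation minimum on every block of ≤ 8 atoms. Blocks are
keyed on type, not bond environment — the pragmatic behavior of the
established implementations; graph-aware matching would be an extension.
Poses are compared in the receptor frame without superposition, as
re-docking evaluation requires, and heavy atoms only. Success means RMSD
≤ 2 Å, inclusive.

## Evaluation statistics

The score-table statistics follow the standard comparative-assessment
definitions: **scoring power** (Pearson R between predicted and
experimental affinities, energies negated so that better predictions give
positive R), **ranking power** over three-ligand-per-protein groups (high:
all three ordered correctly; low: best binder first), **docking power**
(a ≤ 2 Å pose among the top 1/2/3 scored poses), and **screening power**
(known binder within the top 1/3/5 % of the ranked pool,
$\lceil x \cdot \text{pool} \rceil$ — with a 195-compound pool, top 1 %
means rank ≤ 2). Ties are broken by input order, deterministically. One
nuance: the rank-based powers are invariant under any strictly monotone
transformation of the scores, but scoring power, being a Pearson
correlation, is only invariant under positive affine maps; the tests state
it that way.

**ROC AUC** is computed as the Mann–Whitney statistic (ties count ½), which
equals trapezoidal integration of the ROC curve; the test suite checks both
routes and `pROC` as a third. **BEDROC** uses the Truchon–Bayly
exponential-weight formulation with $\alpha = 20$. Its random-selection
null is *not* universally $1/\alpha$: for active fraction $R_a$ the exact
null mean is

$$ \mathbb{E}[\mathrm{BEDROC}_{rand}] =
   \frac{R_a\,\sinh(\alpha/2)}{\cosh(\alpha/2) -
   \cosh(\alpha/2 - \alpha R_a)} + \frac{1}{1 - e^{\alpha(1 - R_a)}}
   \;\approx\; \frac{R_a}{1 - e^{-\alpha R_a}}
   \;\xrightarrow{R_a \to 0}\; \frac{1}{\alpha}, $$

implemented as `bedroc_random_expectation()`. At a 5 % active fraction the
null is ≈ 0.078, not 0.05; the nominal 0.05 belongs to the small-fraction
regime typical of screening libraries. The null-calibration studies in this
package therefore use a 0.5 % active fraction (10 actives, 2000 decoys),
where the closed-form null is 0.0525, and the acceptance run averages
10,000 replicates; the AUC null (0.5 at any composition) is calibrated with
100 actives and 2000 decoys over a few hundred replicates in the tests.

## The training screen

The screen reproduces, at desk scale, a scoring-function development
strategy built on a simple observation: a function can correlate well with
experimental affinities and still dock poorly, because regression on
crystal poses never asks whether the crystal geometry is near a *minimum*
of the function. Average post-minimization RMSD — minimize each crystal
ligand in its receptor, measure how far it moved, average — is cheap and
is a necessary-condition proxy for docking ability.

`generate_grid()` enumerates a constrained Cartesian parameter grid (axes
named in the parameter-file vocabulary; radii respect C ≥ C$_A$, N > O,
N − O ≤ 0.10 Å). `minimization_screen()` ranks candidates by average
post-minimization RMSD (scoring R is computed on the crystal poses, as
regression-style training would) and short-lists `top_k = 20`;
`docking_screen()` re-docks a short-list (convention: refine the best 5)
with seeded reproducibility; `predictor_diagnostics()` quantifies the
punchline as two correlations. The packaged recapitulation builds a
candidate family on synthetic pockets in which radius inflation displaces
every minimum analytically (hurting docking, invisible to crystal scoring)
while the H-bond weight re-balances scores between pocket families
(changing scoring R, hardly touching geometry); the observed pattern —
docking ability strongly anti-correlated with average RMSD, essentially
uncorrelated with scoring R — is asserted directionally, not numerically.

## What the synthetic fixtures do and do not emulate

`make_toy_pocket()` builds shell receptors whose optimum is known by
construction; `make_toy_ligand()` builds idealized zig-zag chains (1.5 Å
bonds, tetrahedral angles) with working torsion trees;
`make_pose_decoys()` perturbs a pose into requested RMSD bins with exact
annotations; `make_screening_table()` draws actives and decoys from
normal score distributions with a chosen separation (0 = the null). All are
pure functions of their arguments and seed.

These fixtures exercise every code path — geometry, typing, gradients,
assignment, ranking — but they are not chemistry: no conformer realism, no
decoy property matching, no solvation, no charged interactions, and pocket
sizes of a dozen atoms rather than thousands. Green tests on them certify
the machinery and the model's stated mathematical properties, not
benchmark performance on real complexes; reproducing published benchmark
numbers would require the external curated datasets those benchmarks are
defined on, which this package deliberately does not bundle.

Problem sizes used by the shipped tests and the acceptance run: steric
scans at $10^{-3}$ Å over (3, 12) Å; 300–10,000 screening-table replicates;
pockets of 3–8 atoms with ligands of 1–7 atoms; candidate grids of ≤ 16
parameter sets over ≤ 6 complexes with 2–3 restarts each.

## Known limitations

* The search is local-restart only; no Monte Carlo chain, no exhaustiveness
  semantics, no pose clustering. Receptors are rigid.
* Electrostatics and desolvation are not modeled (explored historically by
  this function family but absent from both shipped presets).
* Bond perception is purely distance-based; exotic coordination geometries
  may misclassify donors.
* The 8 Å surface-distance cutoff truncates the Gaussians at ~$10^{-7}$ of
  their peak; energies are reproducible to that level, not beyond.
* Assignment-based RMSD ignores bond topology within a type block, which
  can under-report the distance between poses of molecules with many
  equivalent atoms.
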