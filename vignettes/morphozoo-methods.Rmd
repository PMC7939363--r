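---
title: "Morphological complexity and the genotype-phenotype map: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological complexity and the genotype-phenotype map: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

morphozoo asks a developmental-systems question with a simulation pipeline:
when random gene networks are wired to cell behaviors and tissue mechanics
and allowed to run development from a simple flat epithelium, how does the
morphological complexity of the outcome relate to its frequency, its
robustness to developmental noise, and the structure of its
genotype-phenotype map (GPM)?  This vignette documents the model, every
tunable that matters, the numerical choices, and what the desk-scale
analyses can and cannot show.

## The developmental model

**Tissue representation.**  Cells are point particles ("nodes") in 3D.
Mesenchymal cells and extracellular matrix (ECM) are single spheres;
epithelial cells are cylinders made of an apical and a basal node joined by
an unbreakable spring.  Each node carries mechanical radii — an adhesion
radius `p_ADD` and an equilibrium (repulsion) radius `p_EQD` — plus the
spring half-rest-length `p_EQS`, two bending resistances `p_ERP` and
`p_EST`, and a cell-cycle phase rate `p_PHA`.  Every node also carries a
vector of gene-product concentrations.

**Mechanics.**  Two nodes interact when closer than the sum of their
adhesion radii.  The radial force is piecewise in the distance $d$:
repulsive with magnitude $k_{rep}(d_{EQD}-d)$ inside the summed equilibrium
radius, and adhesive with the tent form
$k_{adh}(d-d_{EQD})(d_{ADD}-d)/(d_{ADD}-d_{EQD})$ between $d_{EQD}$ and
$d_{ADD}$ — zero at both ends and continuous at the crossover.  The tent is
the simplest law with the right sign structure whose force vanishes at the
edge of the adhesion range; `pair_potential()` gives the corresponding
scalar potential, which the test suite differentiates numerically against
the implemented forces.  Interaction directions respect cell shape:
center-to-center for sphere pairs, parallel to the apical-basal axis for
face contacts with an epithelial node, and perpendicular to it for lateral
epithelial contacts.  Epithelia additionally feel (i) the apical-basal
spring, (ii) a `p_ERP`-scaled bending force that drives same-side neighbor
connections toward right angles with the apical-basal axis, and (iii) a
`p_EST`-scaled torsional force along the same-side connection that
penalizes shear between apical and basal spacings.  The bending forces use
a quasi-static axis approximation (the axis is treated as fixed while
differentiating), standard for cell-center models; pairwise contributions
remain equal and opposite, so momentum is conserved exactly.

Dynamics are overdamped: node velocity equals total force.  This is the
usual regime for tissue mechanics, where inertia is negligible against
friction.

**Gene regulation.**  Expression follows
$\dot g_{ik} = \phi\!\big(\sum_l t_{lk}\, g_{il}\big) - \mu_k g_{ik}$,
with $t_{lk}$ the signed regulatory strength of product $l$ on product $k$
and $\phi(x) = \max(0,x)/(1+\max(0,x))$ a non-negative saturating
activation.  Because $\phi$ vanishes for non-positive input, subtractive
inhibition creates genuine expression thresholds — this is what lets
hand-wired cascades carve the maintained gradient into discrete
territories (`make_fixture("threshold_cascade")`).  Diffusible products
additionally exchange between contacting nodes by a discrete Laplacian
weighted by the inverse squared pair distance; the exchange is
antisymmetric, so the total amount is conserved up to degradation.  ECM
nodes carry no gene dynamics.

**The maintained gradient.**  Every simulation starts from a flat
centered-hexagonal epithelial sheet (one apical and one basal node per
cell, a mesenchymal layer one cell diameter beneath) with gene 1 expressed
in a linear gradient across the sheet.  Gene 1 is clamped: it is a
maternal-style positional input, not a dynamical variable.  Without
clamping, the gradient would decay under degradation and no temporally
stable spatial pattern could anchor to it; with clamping, signaling-only
dynamics admit stable pattern transformations, which is the property the
ensemble screen selects for.  The flag `maintained_gradient` turns this
off.

**Behaviors.**  A developmental mechanism couples genes to behaviors and
mechanical properties.  Continuous couplings (contraction/growth of
`p_EQD`, apical, basal or mesenchymal; adhesion `p_ADD`; the stiffnesses
`p_EQS`, `p_ERP`, `p_EST`; the division rate `p_PHA`; apoptotic shrinkage)
change node properties at a rate equal to coupling strength times local
gene concentration and are integrated with the rest of the continuous
state.  Discrete events fire between integration steps: cells divide when
their accumulated cycle phase reaches one (one daughter keeps the lineage
label, the other gets a fresh one, chosen at random); apoptotic cells are
eliminated once shrunk to the minimal radius; epithelial-mesenchymal
transition collapses a cylinder into a sphere; ECM secretion spawns an
inert ECM node beneath the basal surface.

**Noise.**  Development is noisy: after every accepted step each cell node
is displaced by an isotropic Gaussian with standard deviation
`noise_amplitude` (default 0.005 length units, i.e. one half-percent of a
cell diameter per step).  The per-step displacements are centered across
cells, so noise perturbs relative positions without imposing a random walk
on the embryo's center of mass; twin distances then measure shape
divergence rather than bulk drift.

**Integration and stopping.**  The continuous state advances by classical
4th-order Runge-Kutta with step-doubling error control at tolerance
`rk_tolerance` (the error check runs every `control_every`-th step, with
plain RK4 at the last accepted step size in between).  Runs halt at
`max_steps`, at the node cap (`max_nodes`, the published cap is 5000),
when aberrant, or at a steady state (deterministic motion and expression
change below tolerance over a window).  Aberrant morphologies — the ones a
screen discards — are broken epithelia (disconnected same-side contact
graph), ruptured apical-basal springs (beyond `rupture_multiple` times
rest length), or interpenetrating sheets (same-side node pairs deep inside
their repulsion core with nearly anti-parallel axes,
`antialign_threshold`).  The anti-alignment test is deliberately
conservative: legitimate deep folds press cells together with substantially
tilted axes, and an aggressive threshold would discard exactly the complex
morphologies of interest.

## Complexity measures and distances

*Angle variation (AV)* scores how unpredictable a cell's orientation is
from cells at a given distance: for each epithelial cell, the angles
between its apical-basal vector and the vectors to all other cells are
binned into seven distance categories spanning 3 to 10 average adhesion
diameters, and the per-cell, per-category population variances are
averaged.  A flat sheet and a perfect sphere score near zero.  AV is
invariant under rigid motions.

*Orientation patch count (OPC)* assigns each cell an octant by the signs
of its apical-to-basal vector (zero components count positive, a
deterministic tie-break) and counts connected same-octant patches of at
least four cells on the contact graph.  OPC is translation- but not
rotation-invariant; that asymmetry is asserted in the tests.

*Distances.*  EMD is the symmetrized mean nearest-node distance between
two node clouds — homology-free, defined for unequal node counts, and not
guaranteed to satisfy the triangle inequality (it is a similarity score,
not a metric).  Lineage labels give node-level homology for the other two:
CMD is the mean absolute difference in local convexity over homologous
epithelial nodes, where a node's convexity is the mean dot product between
the unit vector to its cell partner and the unit vectors to its same-type
neighbors (0 in a plane, approaching ±1 at sharp folds; following the
published formula the vector points from the node to its partner, so the
apical nodes of an evagination score positive).  HMD is the
Procrustes-style root-sum-of-squares over homologous node positions after
centroid translation and optimal rotation (`align = FALSE` disables the
superimposition).  All homology-based normalizers use the actual initial
node count of the sheet in use, never a hard-coded constant, because sheet
size is configurable.

## The ensemble protocol

`sample_network()` draws a 10-gene network: each ordered pair (self-loops
included, so the expected efferent count is exactly
`n_genes * p_interact = 2`) gets an interaction with probability 0.2, sign
fair, magnitude uniform on $(0, t_{max})$; each gene is diffusible with
probability one half; gene 1 is constrained to activate a diffusible
product.  `signaling_only_screen()` then freezes all motion and asks for a
*temporally stable pattern transformation*: the expression dynamics must
settle, differ from the initial pattern, and leave spatial structure in
some non-input gene.  Only passing networks receive behavior couplings
(`attach_behaviors()`: probability 0.5 per gene, uniform over the
behavior/property menu, log-uniform magnitudes for rate-like targets and
signed uniform for property targets) and are simulated in full.  Aberrant
outcomes are discarded.  The `broad_ensemble` flag skips the screen,
mirroring the less productive variant protocol.

Values that only appear in unpublished supplementary material (the
interaction-strength bound, rate ranges, noise amplitude, force constants)
are package defaults chosen once for this model scale and documented in
`sim_config()`; they are config constants, not claims of parity with any
other implementation.

## Screens and GPM statistics

Developmental instability is the mean pairwise distance between twins
(replicates differing only in noise seed).  Pruning deletes superfluous
interactions: a deletion is kept when the mean CMD between candidate twins
and parent twins stays within the parent's CMD instability plus a 0.01
margin, stopping after 40 consecutive rejections (both published values;
configurable).  Aberrant candidates always count as changed.  The IS
one-mutant neighborhood perturbs each parameter by ±20/40/60/80% of its
parental value, 8 mutants per parameter, each simulated as a twin set.
T-neighborhoods delete each interaction once and add one random
interaction per existing interaction (drawn like the ensemble samplers,
resampling on collision).  Iso-morphological random walks perturb one
uniformly chosen parameter per step by ±2 times its *parental* value,
accept steps that preserve the morphology under the same CMD criterion,
and report accepted counts as the proxy for the size of the morphology's
neutral parameter-space region; walks run only for very stable parents
(twin EMD below 0.3).  Steps compound along the walk — the alternative
reading, resetting to parental values each step, is available as
`walk_mode = "reset"`, but a compounding walk is what makes the accepted
count measure a connected region.

GPM regressions follow the screen geometry: the members of a parameter's
series are its 8 mutants plus the unmutated parent at 0% perturbation; the
x-axis is the absolute difference in perturbation percent between members
(so parent-vs-mutant pairs appear at intermediate distances), and the
y-axis the mean cross-twin distance (EMD/CMD) or the distance between mean
morphologies (HMD, which therefore has no 0% level).  The regression
coefficient is the unweighted OLS slope; aberrant members drop their pairs
rather than being imputed.  The mutational-asymmetry histogram bins
offspring complexity change against parent complexity (0.03 AV / 1 OPC
bins) and normalizes within parent-complexity columns before taking the
natural log; empty cells are absent, not $-\infty$.

## Desk-scale study conditions

The published-scale experiment (20,000 mechanisms, 700 parents, sheets of
542 epithelial nodes grown to 5000, 10 twins everywhere, 10×200-step
walks) is replaced by two reduced configurations, chosen once in
`study_config()`:

* **smoke** — a 5-ring sheet (91 epithelial cells), 260 integration steps,
  500-node cap, 2 twins, pruning patience 4 with single candidate twins,
  one 8-step walk with 2 twins per step; a 50-mechanism study finishes in
  roughly a quarter hour.
* **scaled** — the same sheet, 300 steps, 800-node cap, and the full
  published screen protocol (10 twins, patience 40, 10 walks of 200
  steps); a 150-200-mechanism study takes CPU-hours.

The sheet is 5 rings rather than smaller for two reasons.  First, the AV
measure's smallest distance category begins at three average adhesion
diameters: a sheet much less than ten cells across leaves the categories
nearly empty and compact folded morphologies would score exactly zero.
Second, the mutational asymmetry needs headroom: on smaller sheets with
shorter runs the most complex reachable morphologies are capped by
geometry and time rather than by mechanism structure, and their parents
sit on rising complexity slopes where perturbations move complexity both
ways.  Desk-scale spectrum statistics use the orientation-patch-count
measure with its natural one-patch bins (the desk-scale AV distribution
is a spike plus isolated outliers and has no non-arbitrary binning); the
asymmetry analysis sign-tests raw complexity differences, which needs no
binning at all.

What the desk-scale ensemble reproduces is the *qualitative* structure:
complex morphologies are rare, unstable, mutationally fragile (more
offspring lose than gain complexity), have steeper GPM regressions, and
occupy smaller neutral regions.  What it cannot reproduce are
published-scale magnitudes (Spearman coefficients at n in the thousands,
complexities up to 1.2 AV) — the morphologies reachable by a 91-cell sheet
in a few hundred steps are far simpler, and most random mechanisms remain
near-flat, so
rank statistics lean heavily on the minority of morphologically active
members.  One consequence deserves emphasis: at desk scale the ceiling on
complexity is set by run length and sheet size, not by mechanism
structure, so the very most complex parents in a small ensemble can sit on
a rising slope of the complexity landscape where symmetric parameter
perturbations move complexity both up and down; the mutational asymmetry
is therefore clearest in the upper-middle of the desk-scale complexity
range and strengthens with ensemble scale, whereas at publication scale
the complex parents press against what the mechanism itself can encode.  The synthetic generator also does not emulate several features
of real development at any scale: one cylinder per cell (no planar
polarization), a sphere-node ECM (no basal lamina sheet), no mesenchymal
morphology in the complexity scores, and no evolution — mechanisms are
random, not selected.

## Numerical choices and degenerate inputs

Expression is clamped at zero after each step (RK4 can undershoot an
invariant boundary); radii are floored (`p_EQD` at 0.05) and `p_ADD` is
kept at least `p_EQD`.  Zero-length apical-basal axes are rejected in the
morphometrics rather than silently normalized.  OPC octant ties go to the
positive sign.  Convexity is `NA` for isolated nodes, which are excluded
from CMD with the normalizer reduced accordingly.  Empty AV distance
categories and categories with fewer than two pairs contribute zero
variance.  Walk perturbations of degradation/diffusion rates are floored
at zero (a negative rate is not physical); interaction strengths may
change sign.  All stochastic stages derive per-twin/per-mutant seeds by
counter from the base seed, so results are independent of evaluation
order and exactly replayable.

## Known limitations

Beyond the scale limits above: the force law and activation function are
the simplest forms consistent with the qualitative published behavior, not
calibrated fits; the torsional term uses a spacing-difference penalty
rather than a full rotational spring; EMD at small scales retains a
rotational-drift component that the centered noise does not remove; and
the interpenetration detector errs on the side of keeping tightly folded
morphologies, so a rare true self-intersection may survive screening.
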