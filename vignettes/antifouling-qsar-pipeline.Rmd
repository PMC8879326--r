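---
title: "A ligand-based QSAR pipeline for antifouling activity: models, descriptors and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A ligand-based QSAR pipeline for antifouling activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Biofouling — the settlement of barnacles, mussels, bryozoans and algae
on submerged surfaces — is fought today mostly with biocidal coatings.
A ligand-based alternative is to learn, from molecules with measured
antifouling activity, a function from chemical structure to an
active/inactive call, and to use it to triage large marine
natural-product libraries before any experiment. `afqsar` implements
that workflow end to end: molecule curation, descriptor computation,
class-balanced random-forest classification with descriptor selection,
a fixed evaluation protocol (SE/SP/Q/MCC) and probability-threshold
screening triage.

The curated benchmark this protocol comes from contains 141 molecules
(57 active / 70 inactive in training, 6/8 in test; imbalance 1:1.22);
activity is defined per endpoint: percent inhibition > 52% or an
EC50/IC50 of at most 25 ug/mL counts as active. Those numbers —
thresholds, class sizes, the selection sweep {12, 25, 50, 100, 150,
200, 250} and the screening thresholds 0.59/0.68 — are treated as
fixed protocol constants throughout the package.

# The model stack

**Balanced random forest.** The central classifier is a random forest
in which every tree is grown on a per-class bootstrap of the
minority-class size (`sampsize = c(m, m)` with `m` = number of
actives). Out-of-bag (OOB) votes give both an internal validation
estimate and a per-molecule `Prob_active` (fraction of tree votes for
the active class). Descriptor importance is permutation importance
(mean decrease in accuracy), and descriptor selection retrains on the
top-k descriptors for each k in the sweep, choosing k by (Q, then MCC)
— the tie-break rule is this package's own choice, since the protocol
does not state one.

**Comparators.** An RBF support vector machine (C = 1e7, gamma = 1e-8,
minority-class replication, pairwise-coupling probabilities) and a
two-hidden-layer perceptron (200 relu units per layer, 2 sigmoid
outputs, Glorot-uniform initialization, binary cross-entropy, Adadelta,
batch 36, 100 epochs). The perceptron is implemented in-package with
plain matrix arithmetic; both comparators standardize features
internally (the protocol leaves scaling unstated, so it is a documented
package choice). Majority voting over RF/SVM/MLP is available but, as
in the original protocol, is not expected to beat the best member.

**Metrics.** SE = TP/(TP+FN), SP = TN/(TN+FP), Q = (TP+TN)/n and the
Matthews correlation coefficient, with explicit undefined flags when a
denominator vanishes (single-class clusters render "-"). A deliberate
note: the benchmark's table footnotes *describe* SE as a
precision-like ratio, but its printed numbers are consistent only with
standard sensitivity (41/57 = 0.719, not 41/60 = 0.683); the standard
definitions are used. `counts_from_rates()` inverts printed 3-decimal
SE/SP back to integer confusion counts given class sizes; two printed
test-set sensitivities (0.830 and 0.670) are mis-rounded relative to
the only feasible integer counts (5/6, 4/6) and are audited at a
relaxed 0.005 rate tolerance, at which the inversion is still unique
and their printed Q/MCC verify exactly.

# The descriptor engine

All 2D descriptors operate on the hydrogen-suppressed graph; atomic
weights are mass, partial charge, van der Waals volume, Sanderson
electronegativity, polarizability, first ionization potential and the
Kier–Hall intrinsic state (codes m, c, v, e, p, i, s).

* **Autocorrelations** (Broto–Moreau ATS/ATSC, averaged AATS/AATSC,
  Moran, Geary) over lags 1–8 — 336 columns.
* **Burden-modified eigenvalues**: diagonal = carbon-relative atom
  weight; bonded off-diagonal 0.1 x bond order (aromatic 1.5), +0.01
  for terminal partners; 0.001 elsewhere; SpMin1–5/SpMax1–5 per weight
  — 70 columns.
* **E-state atom types**: intrinsic state
  $I = ((2/L)^2\,\delta^v + 1)/\delta$ and
  $S_i = I_i + \sum_j (I_i - I_j)/(d_{ij}+1)^2$; shipped types are
  ssssC (quaternary carbon; sum and max), ssCH2 (sum), saturated-CH
  hydrogens (min, using the package's hydrogen E-state convention
  $I_H = 5$ on the hydrogen-included graph) and weak hydrogen-bond
  acceptors (sum).
* **WTPT-5**: for each nitrogen, 1 plus the sum over simple paths
  starting there of the product of Randic bond weights
  $1/\sqrt{\deg_i \deg_j}$ — the self-term-plus-path convention is a
  declared package decision, the source gives only prose.
* **Galvez topological charge indices** JGI1–3 and Mannhold LogP.
* **3D RDF descriptors**:
  $\mathrm{RDF}(r) = \sum_{i<j} p_i p_j e^{-B (r - r_{ij})^2}$ with
  B = 100 1/A^2, sampled at 128 grid points. "128 equally distributed
  values between 0 and 12.8 A" is ambiguous at the endpoints; the grid
  is fixed to $r_g = 0.1 g$, $g = 1..128$ (r = 0 is chemically
  meaningless for pairs, and 128 x 0.1 A = 12.8 A). Pairs are
  partitioned by charge sign into set a (+,−), b (+,+) and c (−,−);
  products are signed (set a is non-positive), atoms with exactly zero
  charge belong to no set, and an absolute-value mode exists for
  sensitivity checks. Hydrogens are included by default
  (`heavy_only = FALSE`); the protocol is silent on this and the
  charges exist for hydrogens.

Partial charges default to iterative partial equalization of orbital
electronegativity (Gasteiger–Marsili; 6 damped iterations seeded from
formal charges, which conserves total charge to machine precision).
The original protocol used a web-based NBO-charge estimator that is
not reproducible offline; the charge provider is therefore pluggable
(`from_file` injects external charges per atom). Phosphorus is given
interpolated parameters — it is absent from the original PEOE table.

Missing descriptor values (no pair at a lag, no matching atom type, a
zero-variance Moran/Geary denominator) are imputed to 0 and recorded
in a mask; a strict mode errors instead. Random forests tolerate
constant imputation and the mask preserves auditability.

# The synthetic study system

The package validates itself on generated libraries, because the
curated 141-molecule set lives in a publication appendix and the
screening library behind it is a moving external resource. The
generator is first-class, tested code; its defaults are the study
conditions and are not tuned per experiment.

**Molecules.** Seven templated scaffold families mirror the benchmark's
structural clusters in role only (acyclic, O-heterocycle,
N-heterocycle, fused bicyclic, diketopiperazine-like, chalcone-like,
macrocycle). Graphs grow to a drug-like size profile (normal around 28
heavy atoms, truncated to the configured 10–60 range) over a
C/N/O/S/Cl/Br palette, with growth capped so no carbon exceeds three
heavy neighbours — the quaternary-carbon motif below must occur only
where planted. Explicit hydrogens fill standard valences. 3D
coordinates come from a distance-geometry embedding (breadth-first
initial placement, L-BFGS on bond springs at 1.5 A and a 2.0 A
non-bonded repulsion floor, compiled in C++), accepted only when all
bonded distances fall in [1.2, 1.9] A and non-bonded pairs exceed
1.5 A.

**The planted rule.** A molecule is active iff it carries a quaternary
carbon *and* a strong (+,−) charge pair separated by 4.5–5.5 A; the
label then flips with probability 0.05. The two halves are deliberately
heterogeneous: the motif is a 2D, E-state-visible feature; the charge
pair is a 3D, RDF-set-a-visible feature, so recovering the rule
requires both halves of the descriptor engine.

Several design decisions make this planted signal realistic to recover
yet hard to shortcut, and they were chosen by inspecting which
descriptor families could impersonate the rule:

* The strong charge pair is a zwitterion appendage
  (iminium =N+H2 ... alkoxide O−): under the equalization charge
  model its hydrogens (+0.44 e) and oxygen (−0.81 e) are the only
  atoms beyond the rule thresholds (+0.40/−0.50 e), so ordinary polar
  decoration cannot fire the rule.
* The pair's realized separation is steered by a soft distance
  restraint during embedding (in-window targets 4.7–5.3 A; off-window
  targets near 3 A or 7 A). The spacer length echoes the geometry
  class only loosely; the decisive in/out-of-window distinction lives
  in the conformation, which only the 3D descriptors see.
* The planted quaternary carbon carries an ether oxygen substituent.
  The high-intrinsic-state neighbour pushes the carbon's E-state
  decisively negative, well away from the zero that the missing
  policy imputes for motif-free molecules — without it, quaternary
  E-states straddle zero and the motif indicator degrades.
* Inactives populate the three off-rule cells of the motif-by-geometry
  2x2 (no-motif/in-window, motif/off-window, neither at 20/20/60%),
  so neither rule half separates the classes alone; half of the
  motif-free molecules carry a tertiary-carbon decoy so branching
  descriptors cannot stand in for the motif.
* A stratified rejection loop drives the realized pre-noise class
  ratio to the configured active fraction (0.45, i.e. imbalance near
  1:1.22).

**What passing does and does not show.** On these libraries the
balanced RF reaches OOB Q >= 0.85 at n = 200 across seeds, with the
ssssC E-state and in-window RDF set-a bins inside the top-25
importance ranking, and selection improves accuracy further — the same
qualitative pattern as the benchmark tables. This demonstrates that
the descriptor engine, the balancing device, the importance ranking
and the threshold logic work as designed. It does not demonstrate
chemical realism: generated conformers are single restrained
embeddings rather than optimized geometries, charges are equalization
charges rather than quantum-chemical ones, and scaffold "clusters" are
role labels, not chemotypes. Conclusions about real antifouling
chemistry still require the real data.

# Numerical choices and degenerate inputs

* Library sizes in the shipped analyses and validation runs are 200
  molecules (training) and 300 (screening), with descriptor matrices
  of 800 columns — sizes chosen so a complete run of every stage stays
  comfortable on a laptop core.
* Tie-breaks: standardization keeps the heaviest of equally sized
  fragments, then the lowest atom index; screening reports order ties
  by molecule id; selection ties resolve to the smaller k via the
  (Q, MCC) ordering.
* Degenerate inputs: single-atom molecules give all-zero RDF vectors;
  molecules without nitrogen score WTPT-5 = 0 (a defined zero, not a
  missing value); single-class training labels error; empty libraries
  return empty hit tables; a cluster with one class yields undefined
  SE or SP flags rather than NaN.
* Determinism: every stochastic stage (splitting, forests, embedding,
  generation, the MLP) takes an explicit seed; regenerating a library
  from the same configuration is byte-identical.

# Known limitations

* The InChI-based deduplication key delegates stereo perception to
  OpenBabel from 3D coordinates; the constitution-only graph key
  ignores stereo entirely. Which InChI flavour the original curation
  used is unknowable, hence the pluggable provider.
* The charge model is a fast classical approximation; descriptor
  values weighted by charge will not numerically match NBO-weighted
  ones (the contract is a consistent per-atom charge, not parity).
* Descriptor-catalogue parity with PaDEL (1376 descriptors,
  fingerprint families) is out of scope; the engine covers the
  families that the benchmark's top-20 importance list draws from.
* Molecular docking, ADMET prediction and tautomer/mesomer
  normalization are outside the package's scope.
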