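---
title: "Methods: benchmarking amide-coupling yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking amide-coupling yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `amideml`: what each
stage computes, the assumptions it makes, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The reaction model

Every record describes one carbodiimide-mediated amide coupling
`acid + amine -> amide + H2O`, with one of three coupling agents (EDC, DCC,
DIC). Validation is purely stoichiometric: the product's molecular formula
must equal formula(acid) + formula(amine) − H2O, the yield must lie in
[0, 100] and the coupling agent must be recognized. Yields outside [0, 100]
in input files are rejected as row-level violations rather than clamped —
failing loudly beats silently repairing questionable literature rows.

SMILES handling (parsing, canonicalization, format conversion) is delegated
to OpenBabel through ChemmineOB; all downstream chemistry operates on an
explicit-hydrogen molecular graph parsed from V2000 molblocks, so hydrogen
counts and formula arithmetic need no implicit-valence rules. OpenBabel
accepts some malformed SMILES by silently truncating them, so
`canonicalize()` pre-validates the syntax (balanced delimiters, paired ring
closures) and raises a parse error naming the offending string.

## Mechanism-derived augmentation

The O-acylisourea intermediate is built by adding the carboxylic acid across
one C=N bond of the carbodiimide: the acyl oxygen bonds to the central
carbon, and the carboxyl proton transfers to a nitrogen. For the
asymmetric EDC this leaves a tautomer choice; the package assigns the proton
to the nitrogen whose substituent has the smaller heavy-atom count (the
ethyl side for EDC), with ties broken by canonical atom order, which makes
the output a deterministic function of the inputs. Mass balance — the
intermediate's formula equals the exact sum of the reactant formulas — is an
enforced invariant.

Reaction centers are defined as the atoms whose bond incidence differs
between reactant and product side: the carboxyl carbon and the departing
hydroxyl oxygen in the acid, the nucleophilic nitrogen in the amine, the
amide C and N in the product. Rather than a maximum-common-substructure
search, the product's amide bond is identified by an exact fragment
criterion: deleting a candidate C(=O)–N bond must split the product into
fragments whose formulas equal formula(acid) − OH and formula(amine) − H.
For the condensation chemistry in scope this criterion is necessary and
sufficient, it is invariant to atom renumbering (all indices refer to the
canonical-SMILES atom order), and it resolves products that contain other
amide bonds in their substituents.

Amine classification follows the nitrogen's substitution: two carbon
substituents and one H is secondary; one or zero carbon substituents with
two or more H is primary, aromatic if the carbon neighbor is an aromatic
ring atom and aliphatic otherwise. Nitrogens embedded in amides are never
counted as reactive sites. Aromaticity is perceived structurally (ring atom
with an in-ring double bond on the kekulized graph), which is adequate for
the benzenoid and simple heteroaromatic rings this package's chemical space
contains; exotic aromatic systems would need a full Hückel treatment.

## Descriptors

**Morgan fingerprints.** Circular environments of radius 0–2 hashed onto
2048 bits (binary). The hash is a deterministic integer polynomial over the
atom invariant (atomic number, heavy degree, hydrogen count, formal charge,
ring membership) and the sorted (bond order, neighbor id) list, so
fingerprints are bit-exact across platforms. Radius 2 / 2048 bits is the
conventional reaction-ML default.

**2D battery.** Around 230 named descriptors: constitutional counts,
ring/rotor/H-bond counts, topological indices (Wiener, Zagreb, Randić chi,
Balaban J, kappa shape), Kier–Hall electrotopological-state summaries,
functional-group counts, and Moreau–Broto / Moran / Geary autocorrelations
(lags 1–8) over atomic mass, electronegativity, covalent radius, hydrogen
count, degree and a heteroatom indicator. Descriptors that are undefined
for a molecule (autocorrelation of a constant property, shape indices of a
single-atom graph) are `NaN` and are removed by the variance filter rather
than imputed.

**Conformers.** A seeded distance-geometry embedder: harmonic restraints on
bonded distances (reference bond lengths by element pair and order) and on
1–3 distances (ideal angles by hybridization), plus a soft lower-bound
repulsion between nonbonded pairs at 0.75 × the summed van der Waals radii,
minimized with BFGS from several seeded random starts; the lowest-objective
geometry wins and its final objective is stored as the surrogate energy.
The contract is a *single low-energy conformer per molecule*, deterministic
under a fixed seed. `embed_conformer()` defaults to 10 restarts; the
featurization pipeline uses 4, which on this chemical space changes AEV
blocks negligibly while keeping large-scale featurization tractable.
Torsional preferences and ring puckering are not modeled; the geometries
are plausible rather than spectroscopic, which is sufficient for
environment-vector and buried-volume descriptors.

**Atomic environment vectors.** Standard radial and angular symmetry
functions with the smooth cosine cutoff `fc(R) = 0.5 cos(pi R / Rc) + 0.5`:
radial cutoff 5.2 Å with 16 Gaussian shells (η = 16 Å⁻²), angular cutoff
3.5 Å with 4 radial × 8 angle sections (ζ = 32), element channels
{H, C, N, O, F, Si, P, S, Cl}; per-atom vectors are sum-pooled into the
molecular representation. All parameters are config-overridable through
`aev_params()`. Invariance to rigid motion and to permutation of identical
atoms is asserted by tests at 1e-8.

**Buried volume.** `%V_bur` on a 0.1 Å grid inside a 3.5 Å probe sphere
centered on a reaction-center atom, with Bondi van der Waals radii and
hydrogens included — the common convention for steric descriptors. The
steric block reports the buried volume at the acid's carboxyl carbon and at
the amine's nitrogen (both, since the literature does not always agree on
which center carries the steric signal).

**Surrogate QM features.** A pluggable provider contract supplies
per-molecule electronic energies, per-atom charges and Fukui indices, and
molecular IP/EA, restricted to the element set {H, C, N, O, F, Si, P, S,
Cl}; molecules outside the set raise a coverage error and are excluded from
QM experiments. Two providers ship with the package: a deterministic
heuristic (additive atomic energies with bond corrections,
electronegativity-difference charges, Fukui scores emphasizing carbonyl
carbons and amine nitrogens with the nucleophilic score attenuated by local
crowding) and an oracle backed by the synthetic generator's latent energies.
Derived reaction features include `dE_rxn = E(product) + E(water) −
E(acid) − E(amine)`, the Fukui difference `df_rxn` signed acid-minus-amine,
center charges, IP/EA per reactant, and per-molecule charge/Fukui summary
statistics.

## The benchmark

Evaluation uses five fixed seeded 90/10 train/test splits; R² (about the
test-set mean) and MAE are reported per cell as mean ± standard deviation
over splits (the ± is a standard deviation, and is labeled as such). All
fold-dependent state — the variance filter, recursive feature elimination,
and the context vocabulary — is fitted on training rows only. The benchmark
default variance threshold is 1e-8, which also removes train-constant
columns: a feature constant in training carries no usable signal, and a
canary test asserts that a column constant in train but varying in test is
dropped. Context one-hot columns for labels unseen in training are
train-constant (all zero) and are removed by the same mechanism, which makes
full-data context encoding equivalent to training-fold encoding.

Model families and their fixed defaults: ridge/lasso (glmnet, λ by internal
cross-validation on the training fold; binary-dominated blocks are handled
as sparse matrices), RBF-SVM on standardized inputs, random forest (500
trees, regression mtry = p/3), gradient boosting (500 rounds, depth 3,
learning rate 0.05), and an MLP. The MLP uses a single hidden layer of 64
units (weight decay 1e-3) because the underlying engine (`nnet`) supports
one hidden layer; a deeper two-layer configuration would need a different
backend and did not seem worth an extra dependency for a reference
implementation. Hyperparameter sweeping is out of scope; every default is
config-overridable. All predictions are clipped to [0, 100] — yields are
physical percentages.

**Stacking.** Four base models, one per descriptor block (fingerprint, 2D
battery, AEV, QM), combined by an exact arithmetic mean. Defaults: ridge
for the three wide blocks, gradient boosting for the compact QM table whose
signal lives in nonlinear combinations of a few dozen columns. Each block
carries the context slice, so every base model sees the reaction
conditions. The mean meta-rule guarantees stack MAE ≤ the worst base MAE
(convexity); both laws are asserted per fold in tests. By default the
per-molecule blocks cover the acid and amine; the product role is available
as a configuration knob but is redundant for condensations — the product is
a deterministic function of the reactant pair — and multiplies featurization
cost by the number of unique products.

**Recursive feature elimination.** Per block, a seeded 100-tree forest is
refit each round and the lowest-importance 10% of remaining columns are
dropped until the target width remains; blocks are then merged column-wise.
The ranking model and step size are free choices; a seeded forest with
impurity importance is the common default.

## Reactivity cliffs and uncertain records

Two records are *the same reaction* when their canonical reactant/product
SMILES, coupling agent and normalized context agree (label lists compared
order-insensitively). Uncertain groups are signature groups of two or more
records whose yield spread exceeds a tolerance (default 0: any difference).
Reactivity cliffs are unordered record pairs with cosine similarity above
0.9 in the concatenated acid+amine fingerprint + context space, a yield gap
of at least 30 points (read as percentage points, consistent with how
yields are tabulated throughout), and *different* signatures —
signature-identical pairs are routed to the uncertainty detector instead,
which keeps the two sets disjoint by construction. The scan is exact (the
blocked matrix implementation is tested for equality against a brute-force
O(n²) loop); threshold monotonicity is asserted as a property. Removal
takes every member of a flagged pair or group — conservative, since keeping
a "median" record would require deciding which report to trust — and the
identical benchmark configuration (same split seeds) is re-run on the
reduced dataset.

## The synthetic data generator

The generator emulates a literature amide-coupling corpus at desk scale:
5000 reactions by default over 60 acids and 60 amines (20 per class),
10 solvents, 8 reagents, 5 condition labels. The latent noiseless yield is
a squashed linear model over interpretable terms — amine class offsets
(aliphatic +7, aromatic −9, secondary −2), steric crowding near the amine
nitrogen (−2.2 per heavy atom within two bonds), acid halogen/nitrile count
(−3.6 each), acid size (−0.35 per heavy atom) and per-label context effects
(Gaussian with s.d. 6/4/3 points for solvent/reagent/condition) — mapped to
(0, 100) by a logistic of width 16 points. The intercept is calibrated by
root-finding so that the mean latent yield hits the configured target
(64.1% by default, matching the high-yield reporting bias of literature
data); observed yields add Gaussian noise (s.d. 8 points, clipped to
[0, 100]). These choices keep most yields in the 30–95 band, make
P(yield > 50) ≈ 0.75, and give a latent variance around 200–300 so the
noise ceiling 1 − σ²/(V + σ²) sits near 0.75 — comfortable for
recovery tests without being trivial.

Planted structure: cliff pairs duplicate a reaction with a *remote methyl
edit* on a drug-like benzyl-ether acid (the edit site is ≥ 4 bonds from the
carboxyl carbon) and force the observed yields at least the configured gap
(30 points) apart; each planted pair is verified at construction to exceed
cosine similarity 0.9 in the detector's feature space, and generation fails
loudly if not enough verified pairs can be planted. The editable acids are
deliberately large: a one-atom edit on a small molecule perturbs too much
of its fingerprint to stay above the similarity threshold, exactly as real
cliffs live among elaborated, drug-like structures. Uncertain groups are
exact signature duplicates with distinct yields drawn uniformly over
30–90%. Latent per-molecule electronic energies are assigned so that
`dE_rxn` correlates with the observed yield at a configurable target
(−0.12 by default): the product energy is the mass-balance value plus a
perturbation mixing the standardized pair-level structure term with
independent noise, with the mixing weight solved from the realized sample
correlations. Everything is a deterministic function of the configuration
seed.

What the generator does *not* emulate: real reagent chemistry beyond
categorical label effects, multi-step or competing reactions, condition-
dependent mechanism changes, the long tail of rare fragments in literature
data, or its 41k-reaction scale. Tests passing on synthetic data therefore
validate the *machinery* (featurization, splitting, stacking, detection,
bookkeeping) and the recoverability of a known signal under known noise;
they are not evidence about predictive accuracy on proprietary literature
corpora.

## Numerical choices and degenerate inputs

* CSV numerics are serialized at full precision (`%.17g`) so round-trips
  are exact; missing time/temperature are empty fields, never imputed.
* The variance filter at threshold 0 removes only missing-value columns;
  any positive threshold also removes constants. It is idempotent.
* Single-atom molecules embed at the origin; their AEVs are all-zero by the
  no-neighbor convention.
* The angular AEV term uses the conventional 0.95 factor inside `acos` to
  keep gradients finite at collinearity; the radial term is the textbook
  closed form (hand-checked to 1e-12 in tests).
* Zero feature vectors make cosine similarity undefined and raise an error
  rather than returning 0.
* R² is undefined for a zero-variance test fold and raises an error.
* Problem sizes used by the test suite — 5000-reaction recovery runs with
  20 seeded splits, 10-seed removal experiments at n = 1000, a 200-reaction
  brute-force cliff oracle — are desk-scale choices: large enough for tight
  Monte-Carlo bands on the asserted properties, small enough to run
  comfortably on a laptop.

## Known limitations

* Aromaticity perception is structural (kekulized ring double bonds), not
  electron-counting; adequate in scope, wrong for, e.g., azulenes.
* The conformer embedder ignores torsional strain and stereochemistry.
* The heuristic QM provider is a deterministic surrogate with plausible
  trends, not an electronic-structure method; its absolute values are
  meaningless outside the package's own comparisons.
* The EDC tautomer rule is a convention; both tautomers exist in solution.
* Duplicate input rows with identical yields are kept (deduplication is the
  cliffs module's job, and identical-yield duplicates are by definition not
  "uncertain").
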