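---
title: "Methods: tuple-tensor molecular descriptors and GA-MLR model building"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tuple-tensor molecular descriptors and GA-MLR model building}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensormol)
```

This vignette documents the model behind the package, the conventions we
fixed where the design was genuinely open, the numerical choices, and
what the test-suite evidence does and does not establish.

## 1. The descriptor model

A molecule is an ordered list of atoms with 3D Cartesian coordinates
(Å). For tensor order N ∈ {2, 3, 4} we build a dense n^N array whose
entry at an index tuple is a (dis)similarity value over the
corresponding atom tuple, with every repeated-index entry fixed at 0.
Atom contributions come from multi-linear forms: for order 2,
`L_a = x' G^a y`, where `G^a` keeps exactly the entries of `G` with at
least one index equal to `a`; orders 3 and 4 generalize with tri- and
quadrilinear sums. The scalar descriptor is an aggregation operator
applied to the vector `L`.

Because each off-diagonal entry is incident to two (three, four) atoms,
the atom-level tensors of a zero-diagonal tensor sum to N times it; with
the plain-sum aggregator `ES` the order-2 quadratic unit-property
descriptor therefore equals **twice** the tensor grand total. We treat
the any-index split and the plain multi-index contraction as the defining
primitives (both are pinned to brute-force loop oracles in the tests)
and accept this factor as a consequence rather than renormalizing.

### Pairwise metrics (order 2)

Codes `M1`–`M7` are Minkowski `(Σ|Δ|^p)^{1/p}` with the exponent grid
0.25, 0.5, 1, 1.5, 2, 2.5, 3 attached to the codes in that order (an
explicit `p` overrides); `M8` is Chebyshev, the p → ∞ limit, and the two
agree numerically for large p. For p < 1 the quantity is a quasimetric —
the triangle inequality can fail — which the suite documents with an
explicit counterexample; descriptor computation does not rely on
metricity.

`M10`–`M16` (Canberra, Lance–Williams, Clark, Soergel, Bhattacharyya,
Wave-Edges, angular separation) operate on the **raw coordinates**, not
on displacements. They are therefore *not* rigid-motion invariant: their
values depend on the coordinate frame of the input file. We keep the
file frame by default (`origin = "as-read"`) and offer
`origin = "nonnegative"`, which translates the molecule so all
coordinates are ≥ 0 — required for Bhattacharyya, whose square roots
need a non-negative domain (`policy = "strict"` errors on violations,
`"clip"` clamps). Because reference example matrices for these metrics
depend on an unstated frame, only the frame-independent Euclidean
quantities serve as numeric anchors.

Two term-level conventions, both continuity-motivated: any term with a
zero denominator (Canberra, Clark, Soergel, Wave-Edges) contributes 0,
and a zero-norm vector in angular separation yields distance 0. The
Soergel formula is implemented **without** the 1/n prefactor by default:
the prefactor is inconsistent with reference Soergel values exceeding 1
(e.g. 2.235 for the worked example), so it is exposed as the
`soergel_1_over_n` flag instead. The per-metric "average" normalizations
(d/n^{1/p} and kin) are documented here but deliberately not applied in
descriptor computation.

### Multi-metrics (orders 3 and 4)

Perimeter (`M19`/`M20`), triangle area via Heron's formula
(`M21`/`M22`), and ordered sides summation (`M25`/`M26`) take their edge
lengths from a configurable base metric (Euclidean by default). Bond
angle (`M27`/`M28`), tetrahedron volume (`M23`/`M24`) and dihedral angle
(`M29`/`M30`) are purely Cartesian. Conventions:

* **Bond-angle vertex at the first index.** Tensor entry (i, j, l)
  stores the angle at atom i between the directions to j and l. This was
  validated against the reference three-tuple tensor of the worked
  example: all eleven distinct printed angles (0.163 … 2.682 rad) match
  the vertex-at-row-atom reading via the law of cosines on the printed
  distances.
* **Volume is absolute**, `|det(b−a, c−a, d−a)|/6`, so descriptors do
  not inherit a sign from arbitrary atom enumeration.
* **Dihedral** uses the planes (a, b, c) and (d, b, c) with normals
  `(a−b)×(c−b)` and `(d−b)×(c−b)`.
* Degenerate inputs (coincident vertex, collinear plane atoms) return 0;
  Heron's radicand is clipped at 0 for near-collinear triples; arccos
  arguments are clamped to [−1, 1].

Paired codes (e.g. `M19`/`M20`) are treated as one measure selectable at
either arity where defined, since no finer dichotomy is documented.

### Fragments, normalizations, powers, splitting

The pipeline order is fixed: build NS k = 1 → fragment projection →
probabilistic transform → Hadamard power → atom-level split/contract.
Fragments precede normalization so that the stochastic matrices of a
fragment-restricted tensor are normalized over the restricted mass.

The fragment rule — keep an entry fully when all tuple atoms are in the
fragment, halve it when at least one is, zero it otherwise — was
reverse-engineered from the reference local-fragment matrices (e.g. the
halogen matrix halves the C1–Cl4 distance 3.939 to 1.969 while the
heteroatom matrix keeps O3–Cl4 = 2.598 intact) and is asserted by tests.

Simple-stochastic normalization divides each leading-index slice by its
sum; at order 2 this is row normalization, and the generalization to
orders 3/4 (normalize over all trailing indices per fixed leading index)
is our documented interpretation. Double-stochastic normalization is
Sinkhorn–Knopp, order 2 only, tolerance 1e−8 on row/column sums, 10,000
iteration cap, with a symmetric two-sided update (`D A D`) for symmetric
inputs so the output is exactly symmetric; non-convergence is an error
that names the remaining slack. Mutual probability divides by the grand
total. All-zero slices/tensors pass through unchanged.

Hadamard power k > 0 is the entrywise power; k < 0 is the entrywise
reciprocal (with 0 ↦ 0, preserving structural and fragment zeros) raised
to |k|. Powers apply after the probabilistic transform of the k = 1
tensor: the scheme order is explicit in the pipeline even though the
alternative (power first) would not commute.

Tensors are dense. Order-4 construction carries a size guard at 120
atoms: a 120⁴ double array is ≈ 1.7 GB, the practical ceiling, and the
guard exists to fail fast rather than thrash — typical order-4 use sits
at tens of atoms.

### Aggregation operators

The operator registry is fixed by this package (the historical
definitions are not public): `N1` Σ|L|, `N2` Euclidean norm, `N3`
cubic-norm, `ES` ΣL, `AM` mean, `GM` geometric mean of |L| (0 if any
entry is 0), `P` sign-preserving geometric mean, `SD`/`V` sample
sd/variance (0 for n < 2), `S` adjusted skewness, `K` excess kurtosis,
`RA` max−min, `i50` median, `MX`/`MN`, `PN` sum of negative entries;
lag operators over input atom order `AC[k]` (autocorrelation, 0 at zero
variance), `TS[k]` (Σ L_a L_{a+k}), `GV[k]` (Σ L_a L_b / d²_ab over
|a−b| = k, Euclidean d). A two-element chain (`AC[3]_K`) evaluates the
lag operator at lags 1..k to form a profile, then applies the scalar
statistic to that profile. Lag operators depend on atom order by
construction; permutation invariance is asserted only for the
order-free operators. Name collisions with other descriptor software
are possible and accepted.

### Naming grammar

`STATEk-OP-FORM[props]-METRIC[-FRAGMENT]`, e.g.
`SS2-RA-B[a,c]-M1-total`, with `m|k|` for negative powers, `M20(M4)`
for a multi-metric's base metric and `M1{p=1}` for an exponent
override. The grammar is bijective (`parse_descriptor_name()` inverts
`descriptor_name()`), and descriptor tables use canonical names as
column headers in a deterministic order.

## 2. Structures and properties

SDF/MOL V2000 parsing is delegated to ChemmineR; the file is chunked on
`$$$$` by the package so one malformed record is skipped with a warning
instead of failing the file. Formal charges are read from the ctab
atom-block charge code (`M  CHG` property blocks are not surfaced by the
parser and are therefore not supported; fixtures use atom-block codes).
Descriptors are computed on hydrogen-suppressed skeletons by default —
the reference worked-example matrices are 4×4 for CH3–O–CH2–Cl, i.e.
heavy atoms only — with removed explicit hydrogens credited to their
heavy neighbour and the balance implied by default valences (C 4, N 3,
O 2, S 2, P 3, halogens 1, aromatic bonds counting 1.5).

Fragment detection: halogens and heteroatoms need only elements;
acceptors (N/O, not positively charged), donors (N/O with ≥ 1 H),
terminal methyls (C with one heavy neighbour and ≥ 3 H) and
aromatic/aliphatic carbons need connectivity and are flagged unavailable
without bonds. Aromaticity trusts input aromatic bond orders (4) and
falls back to a ring single/double alternation test over DFS-detected
ring bonds; full aromaticity perception is out of scope.

Atomic properties come from a versioned element table
(`atomic_properties_v1.tsv`): masses, Bondi van der Waals radii (volume
= 4/3 π r³), static dipole polarizabilities, Pauling
electronegativities, atomic refractivities, absolute hardness (softness
= 1/hardness), and deliberately simplified per-element log P and polar
surface-area contributions (full fragment schemes are atom-type
resolved; the table documents exactly what is used). Gasteiger-type
partial charges are **never defaulted**: they must arrive as per-atom
annotations (`ATOM_PROP_c` SDF data field).

## 3. The QSAR workflow

Thinning runs entropy → magnitude → correlation, each a pure function
of its input table. Shannon entropy uses an equal-width histogram with
one bin per molecule by default; constant columns get entropy 0; ties
break by name for determinism. The magnitude filter removes any
descriptor with |value| > 1e5 or 0 < |value| < 1e−5 (exact zeros are
kept — zero is not a small-exponent value). The correlation filter drops
columns with standardized entropy H/log₂(bins) < 0.3, then greedily
prunes |r| ≥ 0.95 pairs keeping the higher-entropy member.

The regression core is OLS with intercept via QR. Leave-one-out Q² uses
the hat-matrix identity e_i/(1 − h_ii), which the suite pins to explicit
n-refit PRESS at 1e−9; a leverage of 1 is an error (the LOO residual is
undefined). The GA is steady-state: binary chromosomes are descriptor
supports clamped to 3–9 variables; each iteration produces one offspring
by union-style crossover (probability = the reproduction/mutation
trade-off, 0.5) or a one-gene mutation (add/remove/swap within the size
band); the offspring replaces the worst member when fitter and not a
duplicate; elitism is implicit in worst-replacement. Parent selection is
uniform-random while the selection bias is 0 and binary-tournament after
80% of the iterations. Reference-scale defaults are 500,000 iterations
and population 100; fitness values are memoized per support, which makes
the effective cost proportional to the number of *distinct* supports
visited.

Bootstrap validation resamples n rows with replacement, refits, predicts
the out-of-bag rows, and pools squared errors across replicates
(reference default 5000; replicates with empty out-of-bag sets or
singular refits are skipped, with a warning above 1%). Y-scrambling
(reference default 300 replicates) permutes the response, records each
permuted Q²loo against r = |cor(y_perm, y)|, and reports a(Q²) as the
intercept of the regression of Q²loo on r — the r → 0 extrapolation of
chance correlation. The intercept definition (rather than the mean of
scrambled Q², available via `method = "mean"`) was chosen because it is
the standard in the MLR-GA lineage this workflow follows and is the
form consistent with uniformly negative reference values. Model choice
minimizes f(x) = (1 − Q²boot) + |a(Q²)| over the top-50 models by
Q²loo; the winner is externally validated with the training-mean
denominator, `Q²ext = 1 − Σ(y_t − ŷ)²/Σ(y_t − ȳ_train)²`, which is what
allows negative external scores for worse-than-mean predictors.

Stepwise pre-selection and the multi-population merging protocol
("retain descriptors of the top models until one 100-descriptor
population remains") are not reimplemented; the package searches a
single thinned population, which at desk scale is the same regime.

## 4. Synthetic data and what the tests show

`synthetic_regression()` plants a sparse linear signal: independent
standard-normal descriptor columns (optionally with 0.99-correlated
copies and exact duplicates to exercise the correlation filter) and
y = Xβ + ε. The default study conditions are n = 60 molecules, p = 100
descriptors, support {3, 7, 12} with β = (2, −1, 0.5) and noise sd =
0.1 × sd(signal). These emulate the *statistical* shape of a thinned
descriptor table — they do not emulate the heavy pairwise correlation,
heteroscedasticity or activity-cliff structure of real descriptor/
activity data, so a passing recovery study shows the selector works
when a low-noise sparse linear truth exists, not that real activities
are modelled well.

Problem sizes in the suite are the package's own desk-scale choices:
GA recovery uses 5,000 iterations across 20 seeds (recovery in ≥ 18/20
runs is the pass line), null-behavior studies use 20 seeds with n = 50,
p = 4, bootstrap 60–100 replicates and scrambling 40–60 replicates.
Reference-scale defaults (500,000 iterations, 5000/300 replicates)
remain the function defaults.

`worked_example()` carries the reference matrices and coordinates
*embedded from the printed distance matrix* by classical MDS
(`embed_from_distances()`, deterministic eigen-based with a fixed sign
convention). Printed distances have 3-decimal rounding, so matrix
entries are asserted at ±0.002 Å and derived angles at ±0.005 rad (the
propagated rounding bound); the absolute coordinate frame is not
recoverable from distances, which is also why the frame-dependent
metric matrices are not numeric anchors and why the shipped fixture SDF
is labelled synthetic.

## 5. Known limitations

* No conformer generation, V3000, SMILES, stereo or protonation
  handling — structures must arrive with 3D coordinates.
* Frame-dependent metrics (M10–M16) are only meaningful under a
  documented coordinate policy; cross-software numeric agreement is not
  expected for them.
* The aggregation-operator registry and descriptor nomenclature are
  this package's own; values for operators beyond the documented
  formulas are not comparable across implementations.
* Dense tensors bound order-4 computation to small molecules by design.
* log P and PSA atomic contributions are simplified element-level
  tables, adequate for exercising the algebra, not for property
  prediction per se.
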