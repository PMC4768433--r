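# tensormol

Alignment-free 3D molecular descriptors from N-linear algebraic forms,
with a complete GA-MLR QSAR model-building workflow.

## What problem this solves

Most 3D-QSAR methods (CoMFA-style grids, pharmacophore overlays) require
superposing every molecule onto a reference, which restricts them to
congeneric series. An alternative is to encode each molecule's own 3D
geometry directly: build, for every molecule, order-N tensors over its
atoms whose entries are spatial (dis)similarity values — interatomic
distances under a family of metrics for atom pairs, and bond angles,
triangle areas, perimeters, dihedral angles or tetrahedron volumes for
atom triples and quadruples — and contract those tensors with vectors of
atomic properties (mass, electronegativity, polarizability, ...) through
multi-linear algebraic forms. The result is a large family of scalar
molecular descriptors computable from a single conformer, usable as
predictors in ordinary regression models of biological activity.

`tensormol` implements the descriptor engine and the accompanying model
pipeline for practitioners building such QSAR models in R.

## The core machinery

For a molecule with *n* atoms, the order-2 contribution of atom *a* is
the bilinear form

    L_a = x' G^a y = sum_ij g_ij^a x_i y_j

where `G^a` is the atom-level matrix (entries of the total matrix `G`
incident to atom *a*, all others zero), and `x`, `y` are atomic-property
vectors; trilinear and quadrilinear forms over order-3/4 tensors `GT`,
`GQ` are the direct generalizations. The tensor pipeline is

1. **build** the non-stochastic (`NS`) k = 1 tensor from a metric
   (`M1`–`M8`, `M10`–`M16`: Minkowski family, Chebyshev, Canberra,
   Lance–Williams, Clark, Soergel, Bhattacharyya, Wave-Edges, angular
   separation) or multi-metric (`M19`–`M30`: perimeter, area, sides
   summation, bond angle, volume, dihedral);
2. optionally **project** onto a local fragment (halogens, heteroatoms,
   H-bond acceptors/donors, terminal methyls, aromatic or aliphatic
   carbons) — entries fully inside the fragment are kept, boundary
   entries halved, outside entries zeroed;
3. apply a probabilistic **normalization**: simple-stochastic (`SS`,
   leading-slice sums 1), double-stochastic (`DS`, Sinkhorn–Knopp), or
   mutual-probability (`MP`, grand total 1);
4. raise to an entrywise Hadamard **power** k (±1..±12);
5. **split** into atom-level tensors, **contract** with property
   vectors, and **aggregate** the n atom contributions with a registered
   operator (norms, statistics, lag operators, and two-step chains such
   as `AC[3]_K`).

On top of the descriptor table, the QSAR side provides Shannon-entropy /
magnitude / correlation descriptor thinning, genetic-algorithm variable
selection for multiple linear regression with leave-one-out Q² as the
fitness, bootstrap (Q²boot) and Y-scrambling (a(Q²)) validation, the
model-choice score f(x) = (1 − Q²boot) + |a(Q²)|, and external-test
statistics (Q²ext, SDEP).

## Worked example

The 4-heavy-atom molecule CH3–O–CH2–Cl ships as a fixture (coordinates
recovered from its interatomic distances, hence the `_synthetic` file
name):

```r
library(tensormol)
sdf <- system.file("extdata", "chloromethoxymethane_synthetic.sdf",
                   package = "tensormol")
mol <- read_structures(sdf)[[1]]
t2 <- build_total_matrix(mol, 2, metric_spec("M5"))   # Euclidean
print(t2)
#> <tuple_matrix> order 2, 4 atoms, state NS, k = 1, metric M5
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.000 2.408 1.439 3.939
#> [2,] 2.408 0.000 1.438 1.757
#> [3,] 1.439 1.438 0.000 2.598
#> [4,] 3.939 1.757 2.598 0.000
round(simple_stochastic(t2)$values, 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.000 0.309 0.185 0.506
#> [2,] 0.430 0.000 0.257 0.314
#> [3,] 0.263 0.263 0.000 0.475
#> [4,] 0.475 0.212 0.313 0.000
```

Row 1 of the simple-stochastic matrix says: of the total dissimilarity
atom C1 accumulates against the other atoms, 50.6% comes from the
distant chlorine and 18.5% from the adjacent ether oxygen. A complete
descriptor — simple-stochastic state, Hadamard power 2, bilinear in
atomic mass and electronegativity, aggregated by the range operator —
is one call:

```r
cfg <- descriptor_config("B", c("m", "e"), "M5", state = "SS", k = 2,
                         operator = "RA")
descriptor_name(cfg)
#> [1] "SS2-RA-B[m,e]-M5-total"
compute_descriptor(mol, cfg)
#> [1] 39.33306
```

i.e. the spread (max − min) across the four atoms of their mass-by-
electronegativity bilinear contributions is 39.3. A shell front end
(`inst/cli/tensormol`) wraps `cmd_compute()`/`cmd_model()` for batch
descriptor tables and end-to-end model reports.

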