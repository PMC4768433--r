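# N-linear contraction, aggregation operators, naming grammar and the
# composed descriptor pipeline.

test_that("contraction matches hand-derivable cases", {
  idm <- tensormol:::new_tuple_matrix(diag(4), 2L)
  x <- c(1, 2, 3, 4); y <- c(2, 0, -1, 5)
  expect_equal(contract(idm, list(x, y)), x * y)
  z <- tensormol:::new_tuple_matrix(matrix(0, 4, 4), 2L)
  expect_equal(contract(z, list(x, y)), rep(0, 4))
  expect_error(contract(idm, list(x)), "property vectors")
  expect_error(contract(idm, list(x, y[1:3])), "length")
})

test_that("contraction equals the brute-force index-loop oracle", {
  set.seed(23)
  for (ord in 2:4) {
    n <- 4
    arr <- array(rnorm(n^ord), rep(n, ord))
    t <- tensormol:::new_tuple_matrix(arr, ord)
    props <- replicate(ord, rnorm(n), simplify = FALSE)
    L <- contract(t, props)
    for (a in seq_len(n))
      expect_equal(L[a], brute_contract_atom(arr, props, a),
                   tolerance = 1e-10)
  }
})

test_that("contraction is multilinear and scales with property vectors", {
  set.seed(29)
  n <- 5
  arr <- array(rnorm(n^3), rep(n, 3))
  t <- tensormol:::new_tuple_matrix(arr, 3L)
  x <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
  expect_equal(contract(t, list(x + x2, y, z)),
               contract(t, list(x, y, z)) + contract(t, list(x2, y, z)),
               tolerance = 1e-10)
  cc <- -2.5
  expect_equal(contract(t, list(cc * x, y, z)),
               cc * contract(t, list(x, y, z)), tolerance = 1e-10)
})

test_that("scalar aggregation operators follow their registered formulas", {
  v <- c(1, -2, 3)
  expect_equal(aggregate_contributions(v, "N1"), 6)
  expect_equal(aggregate_contributions(v, "N2"), sqrt(14))
  expect_equal(aggregate_contributions(v, "N3"), 36^(1 / 3))
  expect_equal(aggregate_contributions(v, "ES"), 2)
  expect_equal(aggregate_contributions(v, "AM"), 2 / 3)
  expect_equal(aggregate_contributions(v, "RA"), 5)
  expect_equal(aggregate_contributions(v, "i50"), 1)
  expect_equal(aggregate_contributions(v, "MX"), 3)
  expect_equal(aggregate_contributions(v, "MN"), -2)
  expect_equal(aggregate_contributions(v, "PN"), -2)
  expect_equal(aggregate_contributions(v, "GM"), 6^(1 / 3))
  expect_equal(aggregate_contributions(v, "P"), -6^(1 / 3))
  expect_equal(aggregate_contributions(v, "SD"), sd(v))
  expect_equal(aggregate_contributions(v, "V"), var(v))
  expect_equal(aggregate_contributions(c(5), "SD"), 0)  # n < 2 convention
  expect_error(aggregate_contributions(v, "XX"), "unknown")
})

test_that("lag operators and chains behave as documented", {
  expect_equal(aggregate_contributions(rep(3, 6), "AC[1]"), 0)
  v <- c(1, 2, 3, 4)
  expect_equal(aggregate_contributions(v, "TS[1]"), 1 * 2 + 2 * 3 + 3 * 4)
  expect_equal(aggregate_contributions(v, "TS[3]"), 4)
  expect_equal(aggregate_contributions(v, "TS[9]"), 0)
  m <- mean(v)
  expect_equal(aggregate_contributions(v, "AC[2]"),
               sum((v[1:2] - m) * (v[3:4] - m)) / sum((v - m)^2))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(6, 0, 0))
  expect_equal(aggregate_contributions(v, "GV[1]", mol = coords),
               1 * 2 / 1 + 2 * 3 / 4 + 3 * 4 / 9)
  expect_error(aggregate_contributions(v, "GV[1]"), "coordinates")
  # chain: lag profile 1..k then scalar statistic
  prof <- vapply(1:3, function(k) aggregate_contributions(v, paste0("TS[", k, "]")),
                 numeric(1))
  expect_equal(aggregate_contributions(v, "TS[3]_SD"), sd(prof))
  expect_error(aggregate_contributions(v, "SD_K"), "lag operator")
  expect_error(aggregate_contributions(v, "AC[1]_TS[2]"), "scalar")
  expect_error(aggregate_contributions(v, "AC"), "needs a lag")
})

test_that("descriptor names round-trip and are injective", {
  cfg <- descriptor_config("B", c("a", "c"), "M1", state = "SS", k = 2,
                           operator = "RA")
  expect_equal(descriptor_name(cfg), "SS2-RA-B[a,c]-M1-total")
  sweep <- list(
    descriptor_config("Q", "m", "M5"),
    descriptor_config("L", "e", "M5", state = "MP", k = -2, operator = "N2"),
    descriptor_config("B", c("m", "e"), "M1", k = 3, operator = "AC[2]_K"),
    descriptor_config("Tr", c("m", "e", "v"), "M20", base_metric = "M4",
                      operator = "SD"),
    descriptor_config("Qu", rep("p", 4), "M29", state = "SS", fragment = "G"),
    descriptor_config("B", c("m", "m"), "M1", p = 1))
  nms <- vapply(sweep, descriptor_name, "")
  expect_equal(anyDuplicated(nms), 0L)
  for (i in seq_along(sweep)) {
    back <- parse_descriptor_name(nms[i])
    expect_equal(descriptor_name(back), nms[i])
  }
  expect_error(descriptor_config("Q", "m", "M5", state = "DS", k = 0))
  expect_error(descriptor_config("Tr", c("m", "e"), "M20"), "3 property")
  expect_error(descriptor_config("Tr", c("m", "e", "v"), "M20", state = "DS"),
               "order 2")
})

test_that("composed descriptor equals the staged pipeline", {
  mol <- random_molecule(5, seed = 55)
  cfg <- descriptor_config("B", c("m", "e"), "M5", state = "SS", k = 2,
                           operator = "N1")
  staged <- {
    t <- build_total_matrix(mol, 2, metric_spec("M5"))
    t <- hadamard_power(simple_stochastic(t), 2)
    L <- contract(t, list(property_vector(mol, "m"),
                          property_vector(mol, "e")))
    aggregate_contributions(L, "N1")
  }
  expect_equal(compute_descriptor(mol, cfg), staged, tolerance = 1e-12)
})

test_that("ES-aggregated quadratic unit descriptor doubles the grand total", {
  # each off-diagonal entry is incident to two atoms, so summing the
  # atom-level contributions counts it twice
  mol <- we_fixture$molecule
  cfg <- descriptor_config("Q", "u", "M5", operator = "ES")
  grand <- sum(build_total_matrix(mol, 2, metric_spec("M5"))$values)
  expect_equal(compute_descriptor(mol, cfg), 2 * grand, tolerance = 1e-9)
  expect_equal(grand, 2 * sum(we_fixture$euclidean[upper.tri(diag(4))]),
               tolerance = 0.01)
})

test_that("multilinear descriptors vanish for an all-zero property", {
  mol <- random_molecule(4, seed = 61)
  mol$annotations$zz <- rep(0, 4)
  cfg <- descriptor_config("B", c("zz", "m"), "M5", operator = "N1")
  expect_equal(compute_descriptor(mol, cfg), 0)
})

test_that("order-independent aggregates are invariant under atom relabeling", {
  mol <- random_molecule(6, seed = 71)
  perm <- c(4, 2, 6, 1, 5, 3)
  molp <- molecule3d(mol$elements[perm], mol$coords[perm, ],
                     id = "perm")
  for (op in c("N1", "N2", "ES", "AM", "SD", "RA", "i50", "MX", "MN")) {
    cfg <- descriptor_config("Q", "m", "M5", state = "SS", operator = op)
    expect_equal(compute_descriptor(mol, cfg), compute_descriptor(molp, cfg),
                 tolerance = 1e-9)
  }
})

test_that("Euclidean descriptors are rigid-motion invariant", {
  mol <- we_fixture$molecule
  moved <- molecule3d(mol$elements, rigid_motion(mol$coords, seed = 81),
                      bonds = mol$bonds, id = "moved")
  cfg <- descriptor_config("Q", "m", "M5", operator = "N1")
  expect_equal(compute_descriptor(mol, cfg), compute_descriptor(moved, cfg),
               tolerance = 1e-9)
})

test_that("descriptor tables are deterministic with canonical columns", {
  mols <- lapply(1:3, function(s) random_molecule(5, seed = 100 + s))
  cfgs <- list(descriptor_config("Q", "m", "M5", operator = "N1"),
               "SS1-RA-B[m,e]-M3-total")
  tab1 <- compute_descriptor_table(mols, cfgs)
  tab2 <- compute_descriptor_table(mols, cfgs)
  expect_identical(tab1, tab2)
  expect_equal(names(tab1), c("molecule", "NS1-N1-Q[m]-M5-total",
                              "SS1-RA-B[m,e]-M3-total"))
})
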