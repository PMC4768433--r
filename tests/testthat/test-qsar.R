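# Descriptor thinning, MLR/Q2loo, GA selection and resampling validation.

test_that("entropy filter ranks by histogram entropy with name tie-breaks", {
  set.seed(1)
  n <- 32
  tab <- data.frame(molecule = sprintf("m%02d", 1:n),
                    const = rep(2.5, n),
                    unif = seq_len(n),             # one value per bin
                    check.names = FALSE)
  expect_equal(tensormol:::.shannon_entropy(tab$const, n), 0)
  expect_equal(tensormol:::.shannon_entropy(tab$unif, n), log2(n))
  kept <- entropy_filter(tab, top_k = 1)
  expect_equal(names(kept), c("molecule", "unif"))
  # constants are excluded when informative columns are available
  big <- data.frame(molecule = sprintf("m%02d", 1:40),
                    matrix(rnorm(40 * 100), 40,
                           dimnames = list(NULL, sprintf("r%03d", 1:100))),
                    matrix(1, 40, 5,
                           dimnames = list(NULL, sprintf("k%d", 1:5))),
                    check.names = FALSE)
  kept100 <- entropy_filter(big, top_k = 100)
  expect_false(any(sprintf("k%d", 1:5) %in% names(kept100)))
})

test_that("magnitude filter drops extreme exponents but keeps zeros", {
  tab <- data.frame(molecule = c("a", "b"),
                    huge = c(1, 3.2e6), tiny = c(1e-7, 1),
                    zero = c(0, 0), ok = c(1.5, -2),
                    check.names = FALSE)
  out <- magnitude_filter(tab)
  expect_equal(names(out), c("molecule", "zero", "ok"))
})

test_that("correlation filter prunes duplicated and collinear columns", {
  set.seed(2)
  n <- 200
  base <- rnorm(n)
  tab <- data.frame(molecule = sprintf("m%03d", 1:n),
                    a = base, dup = base, twice = 2 * base,
                    b = rnorm(n), c = rnorm(n), check.names = FALSE)
  out <- correlation_filter(tab)
  kept <- setdiff(names(out), "molecule")
  expect_length(intersect(kept, c("a", "dup", "twice")), 1)
  expect_true(all(c("b", "c") %in% kept))
  # independent columns at n = 200 all survive
  ind <- data.frame(molecule = sprintf("m%03d", 1:n),
                    matrix(rnorm(n * 20), n,
                           dimnames = list(NULL, sprintf("x%02d", 1:20))),
                    check.names = FALSE)
  expect_length(setdiff(names(correlation_filter(ind)), "molecule"), 20)
})

test_that("MLR fit matches a normal-equations solve", {
  set.seed(3)
  n <- 40; p <- 4
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(1, -2, 0.5, 3)
  y <- 2 + X %*% beta + rnorm(n, sd = 0.3)
  m <- fit_mlr(X, y)
  Xc <- cbind(1, X)
  ref <- solve(crossprod(Xc), crossprod(Xc, y))   # independent solver
  expect_equal(unname(coef(m)), as.vector(ref), tolerance = 1e-8)
  # exact linear response
  yz <- 1 + X %*% beta
  mz <- fit_mlr(X, yz)
  expect_equal(mz$r_squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(residuals(mz))), 0, tolerance = 1e-9)
  expect_equal(q2_loo(X, yz), 1, tolerance = 1e-10)
  expect_error(fit_mlr(cbind(X, X[, 1]), y), "singular")
  expect_equal(predict(m, as.data.frame(X)), m$fitted)
})

test_that("hat-matrix Q2loo equals explicit leave-one-out refits", {
  set.seed(4)
  for (trial in 1:10) {
    n <- sample(20:60, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    press <- brute_press(X, y)
    expect_equal(q2_loo(X, y), 1 - press / sum((y - mean(y))^2),
                 tolerance = 1e-9)
  }
})

test_that("Q2loo is non-positive in expectation under the null", {
  set.seed(5)
  vals <- vapply(1:20, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(50 * 3), 50)
    q2_loo(X, rnorm(50))
  }, numeric(1))
  expect_lt(mean(vals), 0)
})

test_that("GA with no search freedom returns the full model", {
  set.seed(6)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% c(1, 1, 1, 1, 1) + rnorm(30, sd = 0.1)
  pop <- ga_select(X, y, ga_config(iterations = 50, population_size = 5,
                                   size_min = 5, size_max = 5, seed = 9))
  expect_equal(sort(pop[[1]]$support), paste0("x", 1:5))
  expect_error(ga_select(X, y, ga_config(size_min = 6, size_max = 6)),
               "size_min exceeds")
})

test_that("GA fitness is self-consistent with Q2loo on each support", {
  syn <- synthetic_regression(n = 40, p = 20, support = c(2L, 5L),
                              beta = c(2, -1), seed = 7)
  X <- as.matrix(syn$table[, -1])
  pop <- ga_select(syn$table, syn$y,
                   ga_config(iterations = 300, population_size = 20,
                             size_min = 2, size_max = 4, seed = 8))
  for (m in pop[1:5]) {
    expect_equal(m$q2_loo, q2_loo(X[, m$support, drop = FALSE], syn$y),
                 tolerance = 1e-10)
    expect_gte(length(m$support), 2)
    expect_lte(length(m$support), 4)
  }
})

test_that("GA recovers a strongly planted support", {
  hits <- vapply(1:3, function(s) {
    syn <- synthetic_regression(n = 60, p = 60, seed = 200 + s)
    pop <- ga_select(syn$table, syn$y,
                     ga_config(iterations = 2000, population_size = 50,
                               seed = 200 + s))
    all(syn$truth$support %in% pop[[1]]$support)
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("bootstrap Q2 is deterministic per seed and exact for linear data", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("x", 1:3)))
  y <- 1 + X %*% c(1, 2, 3)
  expect_equal(q2_bootstrap(X, y, reps = 50, seed = 1), 1, tolerance = 1e-10)
  yn <- y + rnorm(40)
  expect_identical(q2_bootstrap(X, yn, reps = 100, seed = 42),
                   q2_bootstrap(X, yn, reps = 100, seed = 42))
})

test_that("Y-scrambling separates informative from null designs", {
  set.seed(11)
  X <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X %*% c(2, -1, 1) + rnorm(50, sd = 0.3)
  a <- y_scrambling(X, y, reps = 60, seed = 12)
  expect_lt(a, q2_loo(X, y))
  am <- y_scrambling(X, y, reps = 60, seed = 12, method = "mean")
  expect_lt(am, 0.5)
})

test_that("model quality f(x) follows its formula and monotonicity", {
  expect_equal(model_quality_f(q2_boot = 0.765, a_q2 = -0.169), 0.404)
  expect_equal(model_quality_f(q2_boot = 1, a_q2 = 0), 0)
  expect_lt(model_quality_f(q2_boot = 0.9, a_q2 = -0.1),
            model_quality_f(q2_boot = 0.8, a_q2 = -0.1))
  expect_lt(model_quality_f(q2_boot = 0.8, a_q2 = -0.1),
            model_quality_f(q2_boot = 0.8, a_q2 = -0.3))
  expect_error(model_quality_f(q2_boot = 0.5), "required")
})

test_that("external validation anchors at its definitional cases", {
  set.seed(13)
  X <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("x1", "x2")))
  y <- 1 + X %*% c(1, -1)
  m <- fit_mlr(X, y)
  Xt <- matrix(rnorm(10 * 2), 10, dimnames = list(NULL, c("x1", "x2")))
  yt <- 1 + Xt %*% c(1, -1)
  ev <- external_validation(m, Xt, yt)
  expect_equal(ev$q2_ext, 1, tolerance = 1e-10)
  expect_equal(ev$sdep_ext, 0, tolerance = 1e-6)
  # a model predicting exactly the training mean scores Q2_ext = 0
  mean_model <- m
  mean_model$coefficients[] <- c(m$y_mean, 0, 0)
  yt2 <- rnorm(10, mean = m$y_mean, sd = 1)
  ev0 <- external_validation(mean_model, Xt, yt2)
  expect_equal(ev0$q2_ext, 0, tolerance = 1e-12)
  # worse-than-mean predictions go negative
  bad_model <- m
  bad_model$coefficients[] <- c(m$y_mean + 50, 0, 0)
  expect_lt(external_validation(bad_model, Xt, yt2)$q2_ext, 0)
  expect_error(external_validation(m, Xt, rep(m$y_mean, 10)), "undefined")
})

test_that("qsar workflow recovers a planted model end to end", {
  syn <- synthetic_regression(n = 50, p = 30, support = c(3L, 7L, 12L),
                              seed = 17, n_duplicates = 2L)
  ids <- syn$table$molecule
  act <- data.frame(molecule = ids, activity = syn$y)
  rep <- qsar_workflow(syn$table, act, train_ids = ids[1:40],
                       test_ids = ids[41:50],
                       cfg = ga_config(iterations = 1500,
                                       population_size = 30, seed = 19),
                       top_n = 5, boot_reps = 60, scramble_reps = 30,
                       entropy_top_k = 30)
  expect_s3_class(rep, "qsar_report")
  expect_true(all(syn$truth$support %in% rep$model$descriptors))
  expect_gt(rep$statistics$q2_ext, 0.5)
  expect_equal(rep$statistics$f_value,
               (1 - rep$statistics$q2_boot) + abs(rep$statistics$a_q2))
  f <- file.path(tempdir(), "report.json")
  write_qsar_report(rep, f)
  back <- read_qsar_report(f)
  expect_equal(back$statistics$q2_loo, rep$statistics$q2_loo,
               tolerance = 1e-12)
  expect_equal(back$descriptors, rep$model$descriptors)
})
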