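# QSAR model building on a molecules x descriptors table: descriptor
# thinning (Shannon entropy, magnitude, correlation), multiple linear
# regression with leave-one-out Q2, genetic-algorithm variable selection,
# bootstrap and Y-scrambling validation, and external test-set statistics.

# ---- descriptor thinning -----------------------------------------------

.desc_cols <- function(table) {
  nm <- names(table)
  setdiff(nm, "molecule")
}

.shannon_entropy <- function(x, bins) {
  r <- range(x)
  if (!all(is.finite(r)) || r[1] == r[2]) return(0)
  cuts <- seq(r[1], r[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Keep the descriptors with highest Shannon entropy
#'
#' Per-descriptor entropy over an equal-width histogram; ties are broken
#' by descriptor name so the selection is deterministic.
#'
#' @param table descriptor data frame (first column `molecule`).
#' @param top_k number of descriptors to keep.
#' @param bins histogram bin count; defaults to the number of molecules.
#' @return the filtered table.
#' @export
entropy_filter <- function(table, top_k = 1000L, bins = NULL) {
  cols <- .desc_cols(table)
  if (is.null(bins)) bins <- nrow(table)
  stopifnot(bins >= 2L, top_k >= 1L)
  top_k <- min(top_k, length(cols))
  H <- vapply(cols, function(cn) .shannon_entropy(table[[cn]], bins),
              numeric(1))
  if (all(H == 0))
    message("all descriptor entropies are zero; keeping the first ",
            top_k, " by name")
  keep <- cols[order(-H, cols)][seq_len(top_k)]
  table[, c("molecule", keep), drop = FALSE]
}

#' Drop descriptors with extreme magnitudes
#'
#' Removes any descriptor holding a value whose scientific-notation
#' exponent exceeds `exp_limit` in either direction, i.e. |value| >
#' 10^exp_limit or 0 < |value| < 10^-exp_limit.  Exact zeros are retained.
#'
#' @param table descriptor data frame.
#' @param exp_limit exponent bound (default 5).
#' @return the filtered table.
#' @export
magnitude_filter <- function(table, exp_limit = 5) {
  cols <- .desc_cols(table)
  hi <- 10^exp_limit; lo <- 10^(-exp_limit)
  bad <- vapply(cols, function(cn) {
    v <- abs(table[[cn]])
    any(!is.finite(v)) || any(v > hi) || any(v > 0 & v < lo)
  }, logical(1))
  table[, c("molecule", cols[!bad]), drop = FALSE]
}

#' Drop low-entropy and pairwise-correlated descriptors
#'
#' First removes descriptors whose standardized entropy (H / log2(bins))
#' falls below `entropy_floor`; then greedily prunes pairs with absolute
#' Pearson correlation at or above `r_threshold`, keeping the
#' higher-entropy member of each offending pair.
#'
#' @param table descriptor data frame.
#' @param r_threshold correlation threshold (default 0.95).
#' @param entropy_floor standardized-entropy floor (default 0.3).
#' @param bins histogram bin count for the entropy; defaults to the number
#'   of molecules.
#' @return the filtered table.
#' @export
correlation_filter <- function(table, r_threshold = 0.95,
                               entropy_floor = 0.3, bins = NULL) {
  stopifnot(nrow(table) >= 2L)
  cols <- .desc_cols(table)
  if (is.null(bins)) bins <- nrow(table)
  H <- vapply(cols, function(cn) .shannon_entropy(table[[cn]], bins),
              numeric(1))
  Hstd <- H / log2(bins)
  cols <- cols[Hstd >= entropy_floor]
  H <- H[cols]
  if (length(cols) <= 1L)
    return(table[, c("molecule", cols), drop = FALSE])
  ord <- cols[order(-H, cols)]        # greedy from the highest entropy down
  X <- as.matrix(table[, ord, drop = FALSE])
  keep <- logical(length(ord))
  for (j in seq_along(ord)) {
    xj <- X[, j]
    ok <- TRUE
    for (i in which(keep)) {
      r <- suppressWarnings(stats::cor(xj, X[, i]))
      if (!is.na(r) && abs(r) >= r_threshold) { ok <- FALSE; break }
    }
    keep[j] <- ok
  }
  kept <- ord[keep]
  table[, c("molecule", cols[cols %in% kept]), drop = FALSE]
}

# ---- MLR core -----------------------------------------------------------

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares with intercept.  Returns a classed model object
#' with `print`, `summary`, `coef`, `predict` and `residuals` methods and
#' the fit statistics used throughout the workflow.
#'
#' @param X numeric matrix / data frame of descriptors (columns named).
#' @param y numeric response (activity) vector.
#' @return an object of class `"mlr_model"` with elements `coefficients`,
#'   `se`, `r_squared`, `q2_loo`, `fitted`, `residuals`, `descriptors`,
#'   `y_mean`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y))
  if (n <= p + 1L) stop("need more rows than descriptors plus intercept")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  Xc <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) stop("singular design matrix")
  beta <- qr.coef(qrX, y)
  fitted <- as.vector(Xc %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1L)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- names(beta)
  structure(list(coefficients = beta, se = se,
                 r_squared = 1 - rss / tss,
                 q2_loo = .q2_loo_qr(qrX, y, res, tss),
                 fitted = fitted, residuals = res,
                 descriptors = colnames(X), y_mean = mean(y),
                 n = n, qr = qrX),
            class = "mlr_model")
}

# hat-matrix shortcut: LOO residual e_i / (1 - h_ii)
.q2_loo_qr <- function(qrX, y, res, tss) {
  h <- rowSums(qr.Q(qrX)^2)
  if (any(h >= 1 - 1e-12))
    stop("leverage 1 encountered: leave-one-out residual undefined")
  press <- sum((res / (1 - h))^2)
  1 - press / tss
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2_loo = 1 - PRESS / SS_tot`, with PRESS from the leave-one-out
#' residuals computed through the hat-matrix identity
#' `e_i / (1 - h_ii)` (algebraically equal to n explicit refits).
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @return scalar Q2 (at most 1; may be arbitrarily negative).
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < ncol(X) + 2L) stop("need at least p + 2 rows for Q2_loo")
  Xc <- cbind(1, X)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) stop("singular design matrix")
  res <- qr.resid(qrX, y)
  .q2_loo_qr(qrX, y, res, sum((y - mean(y))^2))
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d descriptors, n = %d, R2 = %.4f, Q2loo = %.4f\n",
              length(x$descriptors), x$n, x$r_squared, x$q2_loo))
  invisible(x)
}

#' @export
summary.mlr_model <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std.Error` = object$se)
  cat("Multiple linear regression QSAR model\n")
  print(round(tab, 4))
  cat(sprintf("R2 = %.4f   Q2loo = %.4f   n = %d\n",
              object$r_squared, object$q2_loo, object$n))
  for (f in c("q2_boot", "a_q2", "f_value", "q2_ext", "sdep_ext"))
    if (!is.null(object[[f]]))
      cat(sprintf("%s = %.4f\n", f, object[[f]]))
  invisible(object)
}

#' @export
coef.mlr_model <- function(object, ...) object$coefficients

#' @export
residuals.mlr_model <- function(object, ...) object$residuals

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  nd <- as.matrix(as.data.frame(newdata)[, object$descriptors, drop = FALSE])
  as.vector(cbind(1, nd) %*% object$coefficients)
}

# ---- genetic-algorithm variable selection -------------------------------

#' Genetic-algorithm configuration
#'
#' Defaults mirror the reference search settings: 500000 iterations,
#' population 100, reproduction/mutation trade-off 0.5 (probability that
#' an offspring comes from crossover rather than mutation), selection bias
#' 0 (uniform-random parent selection) until 80% of the iterations and 1
#' (tournament selection) thereafter, and model sizes from 3 to 9
#' descriptors.  Tests and examples pass far smaller `iterations`.
#'
#' @param iterations number of offspring evaluations.
#' @param population_size population size.
#' @param crossover_prob reproduction/mutation trade-off.
#' @param bias_switch fraction of iterations after which tournament
#'   selection replaces random selection.
#' @param size_min,size_max model size bounds.
#' @param seed integer RNG seed.
#' @return an object of class `"ga_config"`.
#' @export
ga_config <- function(iterations = 500000L, population_size = 100L,
                      crossover_prob = 0.5, bias_switch = 0.8,
                      size_min = 3L, size_max = 9L, seed = 1L) {
  stopifnot(iterations >= 1L, population_size >= 2L,
            crossover_prob >= 0, crossover_prob <= 1,
            bias_switch >= 0, bias_switch <= 1,
            size_min >= 1L, size_max >= size_min)
  structure(list(iterations = as.integer(iterations),
                 population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 bias_switch = bias_switch,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Q2loo fitness of a support, -Inf when infeasible/singular
.support_fitness <- function(X, y, supp, tss, n) {
  Xc <- cbind(1, X[, supp, drop = FALSE])
  if (n < ncol(Xc) + 1L) return(-Inf)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) return(-Inf)
  h <- rowSums(qr.Q(qrX)^2)
  if (any(h >= 1 - 1e-12)) return(-Inf)
  res <- qr.resid(qrX, y)
  1 - sum((res / (1 - h))^2) / tss
}

# clamp a support to the size band by random additions/deletions
.clamp_support <- function(supp, p, smin, smax) {
  supp <- unique(supp)
  while (length(supp) > smax) supp <- supp[-sample.int(length(supp), 1L)]
  while (length(supp) < smin) {
    pool <- setdiff(seq_len(p), supp)
    supp <- c(supp, pool[sample.int(length(pool), 1L)])
  }
  sort(supp)
}

#' Genetic-algorithm descriptor-subset search for MLR
#'
#' Steady-state GA over descriptor subsets (supports) of size
#' `size_min..size_max`, with leave-one-out Q2 as the fitness.  Each
#' iteration creates one offspring by single-point-style crossover of two
#' parents (with probability `crossover_prob`) or by mutation of one
#' parent (swap one selected descriptor for an unselected one, or grow /
#' shrink by one within the size band); the offspring replaces the worst
#' population member when fitter.  Parents are drawn uniformly at random
#' while the selection bias is 0 and by binary tournament after
#' `bias_switch` of the iterations.  Fitnesses are memoized per support.
#'
#' @param table descriptor data frame (first column `molecule`) or plain
#'   matrix.
#' @param y response vector.
#' @param cfg a [ga_config()].
#' @return object of class `"ga_population"`: list of models sorted by
#'   decreasing Q2loo, each with `support` (descriptor names), `q2_loo`,
#'   and a fitted [fit_mlr()] model.
#' @export
ga_select <- function(table, y, cfg = ga_config()) {
  X <- if (is.data.frame(table))
    as.matrix(table[, .desc_cols(table), drop = FALSE]) else as.matrix(table)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y))
  if (cfg$size_min > p)
    stop("size_min exceeds the number of available descriptors")
  smax <- min(cfg$size_max, p, n - 3L)
  if (smax < cfg$size_min) stop("infeasible model size range")
  tss <- sum((y - mean(y))^2)
  set.seed(cfg$seed)

  cache <- new.env(parent = emptyenv())
  fit_of <- function(supp) {
    key <- paste(supp, collapse = ",")
    f <- cache[[key]]
    if (is.null(f)) {
      f <- .support_fitness(X, y, supp, tss, n)
      cache[[key]] <- f
    }
    f
  }

  npop <- cfg$population_size
  pop <- vector("list", npop)
  fit <- numeric(npop)
  for (i in seq_len(npop)) {
    sz <- sample(cfg$size_min:smax, 1L)
    pop[[i]] <- sort(sample.int(p, sz))
    fit[i] <- fit_of(pop[[i]])
  }

  switch_at <- ceiling(cfg$bias_switch * cfg$iterations)
  pick_parent <- function(tournament) {
    if (!tournament) return(sample.int(npop, 1L))
    cand <- sample.int(npop, 2L)
    cand[which.max(fit[cand])]
  }
  for (it in seq_len(cfg$iterations)) {
    tournament <- it > switch_at
    if (stats::runif(1) < cfg$crossover_prob) {
      pa <- pop[[pick_parent(tournament)]]
      pb <- pop[[pick_parent(tournament)]]
      shared <- intersect(pa, pb)
      pool <- setdiff(union(pa, pb), shared)
      sz <- sample(c(length(pa), length(pb)), 1L)
      extra <- max(0L, min(length(pool), sz - length(shared)))
      child <- c(shared, if (extra > 0L) sample(pool, extra))
    } else {
      pa <- pop[[pick_parent(tournament)]]
      child <- pa
      pool <- setdiff(seq_len(p), child)
      move <- sample.int(3L, 1L)
      if (move == 1L && length(child) < smax && length(pool)) {
        child <- c(child, pool[sample.int(length(pool), 1L)])
      } else if (move == 2L && length(child) > cfg$size_min) {
        child <- child[-sample.int(length(child), 1L)]
      } else if (length(pool)) {
        out <- sample.int(length(child), 1L)
        child[out] <- pool[sample.int(length(pool), 1L)]
      }
    }
    child <- .clamp_support(child, p, cfg$size_min, smax)
    f <- fit_of(child)
    worst <- which.min(fit)
    key_present <- any(vapply(pop, function(s) identical(s, child), TRUE))
    if (!key_present && f > fit[worst]) {
      pop[[worst]] <- child
      fit[worst] <- f
    }
  }

  ord <- order(-fit)
  models <- lapply(ord, function(i) {
    supp <- pop[[i]]
    m <- tryCatch(fit_mlr(X[, supp, drop = FALSE], y),
                  error = function(e) NULL)
    list(support = colnames(X)[supp], q2_loo = fit[i], model = m)
  })
  structure(models, class = "ga_population")
}

#' @export
print.ga_population <- function(x, ...) {
  cat("<ga_population>", length(x), "models; best Q2loo =",
      round(x[[1]]$q2_loo, 4), "\n")
  best <- x[[1]]$support
  cat("best support:", paste(best, collapse = ", "), "\n")
  invisible(x)
}

# ---- resampling validation ---------------------------------------------

#' Bootstrap-validated Q2
#'
#' Each replicate resamples n training rows with replacement, refits, and
#' predicts the out-of-bag rows; the statistic pools squared out-of-bag
#' errors over replicates: `Q2_boot = 1 - sum(e_oob^2) /
#' sum((y_oob - mean(y_train_rep))^2)`.  Replicates with an empty
#' out-of-bag set or a singular refit are skipped (a warning is raised
#' when more than 1% are).
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param reps bootstrap replicates (reference default 5000).
#' @param seed integer RNG seed; fixed seed gives bit-identical results.
#' @return scalar Q2_boot.
#' @export
q2_bootstrap <- function(X, y, reps = 5000L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(reps >= 1L, n == length(y))
  set.seed(seed)
  sse <- 0; sst <- 0; skipped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (!length(oob)) { skipped <- skipped + 1L; next }
    Xc <- cbind(1, X[idx, , drop = FALSE])
    qrX <- qr(Xc)
    if (qrX$rank < ncol(Xc)) { skipped <- skipped + 1L; next }
    beta <- qr.coef(qrX, y[idx])
    pred <- as.vector(cbind(1, X[oob, , drop = FALSE]) %*% beta)
    sse <- sse + sum((y[oob] - pred)^2)
    sst <- sst + sum((y[oob] - mean(y[idx]))^2)
  }
  if (skipped > 0.01 * reps)
    warning(skipped, " of ", reps, " bootstrap replicates were skipped")
  if (sst == 0) stop("no usable bootstrap replicate")
  1 - sse / sst
}

#' Y-scrambling chance-correlation intercept a(Q2)
#'
#' Each replicate permutes the response, refits, and records the permuted
#' Q2_loo together with `r = |cor(y_perm, y)|`.  The default statistic is
#' the intercept of the least-squares line of Q2_loo on r — the r -> 0
#' extrapolation of chance correlation.  `method = "mean"` returns the
#' mean scrambled Q2_loo instead.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param reps permutation replicates (reference default 300).
#' @param seed integer RNG seed.
#' @param method `"intercept"` (default) or `"mean"`.
#' @return scalar a(Q2).
#' @export
y_scrambling <- function(X, y, reps = 300L, seed = 1L,
                         method = c("intercept", "mean")) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(reps >= 2L)
  set.seed(seed)
  q2 <- numeric(reps); rr <- numeric(reps)
  for (i in seq_len(reps)) {
    yp <- sample(y)
    q2[i] <- tryCatch(q2_loo(X, yp), error = function(e) NA_real_)
    rr[i] <- abs(stats::cor(yp, y))
  }
  ok <- is.finite(q2)
  if (sum(ok) < 2L) stop("too few usable scrambling replicates")
  if (method == "mean") return(mean(q2[ok]))
  unname(stats::coef(stats::lm(q2[ok] ~ rr[ok]))[1])
}

#' Model-quality score f(x)
#'
#' `f(x) = (1 - Q2_boot) + |a(Q2)|`; smaller is better.  Used to choose
#' the single reported model among the top candidates by Q2_loo.
#'
#' @param model an `mlr_model` carrying `q2_boot` and `a_q2`, or a list /
#'   numeric with those two values.
#' @param q2_boot,a_q2 alternatively, pass the two statistics directly.
#' @return scalar score.
#' @export
model_quality_f <- function(model = NULL, q2_boot = NULL, a_q2 = NULL) {
  if (!is.null(model)) {
    q2_boot <- q2_boot %||% model$q2_boot
    a_q2 <- a_q2 %||% model$a_q2
  }
  if (is.null(q2_boot) || is.null(a_q2))
    stop("both q2_boot and a_q2 are required")
  (1 - q2_boot) + abs(a_q2)
}

#' External validation on a held-out test set
#'
#' `Q2_ext = 1 - sum((y_test - yhat)^2) / sum((y_test - y_train_mean)^2)`
#' (the denominator is centred on the *training* mean, so values below 0
#' indicate predictions worse than predicting that mean), and
#' `SDEP_ext = sqrt(mean((y_test - yhat)^2))`.
#'
#' @param model a fitted `mlr_model`.
#' @param X_test test descriptor matrix / data frame.
#' @param y_test test responses.
#' @param y_train_mean training-set response mean; taken from the model by
#'   default.
#' @return list with `q2_ext` and `sdep_ext`.
#' @export
external_validation <- function(model, X_test, y_test,
                                y_train_mean = model$y_mean) {
  y_test <- as.numeric(y_test)
  stopifnot(length(y_test) >= 1L)
  pred <- predict(model, X_test)
  den <- sum((y_test - y_train_mean)^2)
  if (den == 0) stop("zero test variance about the training mean: Q2_ext undefined")
  sse <- sum((y_test - pred)^2)
  list(q2_ext = 1 - sse / den, sdep_ext = sqrt(sse / length(y_test)))
}

# ---- end-to-end workflow ------------------------------------------------

#' Full QSAR model-building workflow
#'
#' Thinning (entropy -> magnitude -> correlation) on the training block,
#' GA-MLR search, retention of the `top_n` models by Q2_loo, bootstrap and
#' Y-scrambling validation of each, selection of the single model with the
#' smallest `f(x) = (1 - Q2_boot) + |a(Q2)|`, and external validation on
#' the test block.
#'
#' @param table descriptor data frame with a `molecule` id column.
#' @param activity named numeric vector (names = molecule ids) or data
#'   frame with columns `molecule` and `activity`.
#' @param train_ids,test_ids disjoint molecule id vectors.
#' @param cfg a [ga_config()].
#' @param top_n candidate models validated (default 50).
#' @param boot_reps,scramble_reps validation replicate counts (reference
#'   defaults 5000 and 300).
#' @param entropy_top_k entropy-filter retention count.
#' @return object of class `"qsar_report"`: the chosen model plus the
#'   Table-style statistics block (size, R2, Q2loo, Q2boot, a(Q2), f,
#'   Q2ext, SDEPext) and the ranked candidate summaries.
#' @export
qsar_workflow <- function(table, activity, train_ids, test_ids,
                          cfg = ga_config(), top_n = 50L,
                          boot_reps = 5000L, scramble_reps = 300L,
                          entropy_top_k = 1000L) {
  if (is.data.frame(activity)) {
    act <- stats::setNames(activity$activity, activity$molecule)
  } else act <- activity
  if (length(intersect(train_ids, test_ids)))
    stop("train and test ids overlap")
  miss <- setdiff(c(train_ids, test_ids), table$molecule)
  if (length(miss)) stop("ids absent from the descriptor table: ",
                         paste(miss, collapse = ", "))
  tr <- table[match(train_ids, table$molecule), , drop = FALSE]
  te <- table[match(test_ids, table$molecule), , drop = FALSE]
  ytr <- as.numeric(act[train_ids]); yte <- as.numeric(act[test_ids])
  if (anyNA(ytr) || anyNA(yte)) stop("activity missing for some ids")

  thin <- entropy_filter(tr, top_k = entropy_top_k)
  thin <- magnitude_filter(thin)
  thin <- correlation_filter(thin)
  if (length(.desc_cols(thin)) < cfg$size_min)
    stop("thinning left fewer descriptors than size_min")

  pop <- ga_select(thin, ytr, cfg)
  top <- pop[seq_len(min(top_n, length(pop)))]
  Xtr <- as.matrix(thin[, .desc_cols(thin), drop = FALSE])
  cand <- lapply(seq_along(top), function(i) {
    supp <- top[[i]]$support
    Xi <- Xtr[, supp, drop = FALSE]
    qb <- q2_bootstrap(Xi, ytr, reps = boot_reps, seed = cfg$seed + i)
    aq <- y_scrambling(Xi, ytr, reps = scramble_reps, seed = cfg$seed + i)
    list(support = supp, q2_loo = top[[i]]$q2_loo, q2_boot = qb, a_q2 = aq,
         f_value = model_quality_f(q2_boot = qb, a_q2 = aq))
  })
  best <- cand[[which.min(vapply(cand, `[[`, 0, "f_value"))]]
  model <- fit_mlr(Xtr[, best$support, drop = FALSE], ytr)
  model$q2_boot <- best$q2_boot
  model$a_q2 <- best$a_q2
  model$f_value <- best$f_value
  ext <- external_validation(model, te, yte)
  model$q2_ext <- ext$q2_ext
  model$sdep_ext <- ext$sdep_ext

  structure(list(
    model = model,
    statistics = list(size = length(best$support),
                      r_squared = model$r_squared, q2_loo = model$q2_loo,
                      q2_boot = best$q2_boot, a_q2 = best$a_q2,
                      f_value = best$f_value, q2_ext = ext$q2_ext,
                      sdep_ext = ext$sdep_ext),
    candidates = cand,
    train_ids = train_ids, test_ids = test_ids),
    class = "qsar_report")
}

#' @export
print.qsar_report <- function(x, ...) {
  s <- x$statistics
  cat("<qsar_report>\n")
  cat(sprintf("  size %d | R2 %.4f | Q2loo %.4f | Q2boot %.4f | a(Q2) %.4f | f %.4f\n",
              s$size, s$r_squared, s$q2_loo, s$q2_boot, s$a_q2, s$f_value))
  cat(sprintf("  external: Q2ext %.4f | SDEPext %.4f\n", s$q2_ext, s$sdep_ext))
  cat("  descriptors:", paste(x$model$descriptors, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a QSAR model report as JSON
#'
#' The report round-trips through JSON: statistics, selected descriptors,
#' coefficients with standard errors, and the candidate summaries.
#'
#' @param report a `qsar_report`.
#' @param path output path.
#' @return `path` invisibly (writer); the parsed report list (reader).
#' @export
write_qsar_report <- function(report, path) {
  stopifnot(inherits(report, "qsar_report"))
  out <- list(statistics = report$statistics,
              descriptors = report$model$descriptors,
              coefficients = as.list(report$model$coefficients),
              standard_errors = as.list(report$model$se),
              candidates = report$candidates,
              train_ids = report$train_ids, test_ids = report$test_ids)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_qsar_report
#' @export
read_qsar_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
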