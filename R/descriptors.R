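# N-linear algebraic contraction of atom-tuple tensors with atomic-property
# vectors, aggregation of atom-level contributions into scalar molecular
# descriptors, and the canonical descriptor-naming grammar
#
#   STATEk-OP[chain]-FORM[props]-METRIC[-FRAGMENT]
#   e.g. "SS2-RA-B[a,c]-M1-total",  "NS3-AC[3]_K-Tr[c,c,c]-M20(M16)-total"
#
# Forms: L linear (one property, remaining slots filled with the unit
# vector), Q quadratic (one property repeated), B bilinear, Tr trilinear,
# Qu quadrilinear (property tuple of the tensor order).

#' Contract a tensor with property vectors into atom contributions
#'
#' For each atom a, the contribution `L_a` is the full multi-index sum of
#' the atom-level tensor entries times the matching property components,
#' i.e. the N-linear form `sum_ij... t[i,j,...] x_i y_j ...` restricted to
#' entries with at least one index equal to a (each qualifying entry is
#' counted exactly once, whatever the number of indices equal to a).
#'
#' @param t a `tuple_matrix` (total, i.e. not yet split; the atom-level
#'   splitting is performed internally for every atom at once).
#' @param props list of numeric property vectors, one per tensor slot
#'   (length must equal the tensor order).
#' @return numeric vector of per-atom contributions.
#' @export
contract <- function(t, props) {
  stopifnot(inherits(t, "tuple_matrix"), is.list(props))
  if (length(props) != t$order)
    stop("need ", t$order, " property vectors, got ", length(props))
  n <- dim(t$values)[1]
  for (p in props) {
    stopifnot(is.numeric(p), all(is.finite(p)))
    if (length(p) != n)
      stop("property vector length ", length(p),
           " does not match atom count ", n)
  }
  w <- t$values
  for (pos in seq_len(t$order)) {
    shape <- rep(1L, t$order); shape[pos] <- n
    w <- w * array(rep(props[[pos]], each = prod(dim(w)[seq_len(pos - 1L)])),
                   dim(w))
  }
  # atom-level split: entry belongs to atom a when ANY of its indices is a
  si <- lapply(seq_len(t$order), function(p) slice.index(w, p))
  L <- numeric(n)
  for (a in seq_len(n)) {
    mask <- si[[1]] == a
    for (p in seq_len(t$order)[-1]) mask <- mask | (si[[p]] == a)
    L[a] <- sum(w[mask])
  }
  L
}

# ---- aggregation operators ---------------------------------------------

# central moments with the zero-variance -> 0 convention
.skewness <- function(x) {
  n <- length(x); if (n < 2L) return(0)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - m) / s)^3)
}
.kurtosis <- function(x) {
  n <- length(x); if (n < 2L) return(0)
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}
.autocorr <- function(x, k) {
  n <- length(x)
  if (k >= n) return(0)
  m <- mean(x); den <- sum((x - m)^2)
  if (den == 0) return(0)
  sum((x[1:(n - k)] - m) * (x[(k + 1):n] - m)) / den
}
.lagsum <- function(x, k) {
  n <- length(x)
  if (k >= n) return(0)
  sum(x[1:(n - k)] * x[(k + 1):n])
}
.gravitational <- function(x, k, coords) {
  if (is.null(coords))
    stop("operator GV needs atomic coordinates; pass the molecule")
  n <- length(x)
  if (k >= n) return(0)
  tot <- 0
  for (a in seq_len(n - k)) {
    b <- a + k
    d2 <- sum((coords[a, ] - coords[b, ])^2)
    if (d2 > 0) tot <- tot + x[a] * x[b] / d2
  }
  tot
}

.SCALAR_OPS <- c("N1", "N2", "N3", "ES", "AM", "GM", "P", "SD", "V", "S",
                 "K", "RA", "i50", "MX", "MN", "PN")
.LAG_OPS <- c("AC", "TS", "GV")

.apply_scalar_op <- function(op, x) {
  n <- length(x)
  switch(op,
    N1 = sum(abs(x)),
    N2 = sqrt(sum(x^2)),
    N3 = sum(abs(x)^3)^(1 / 3),
    ES = sum(x),
    AM = mean(x),
    GM = if (any(x == 0)) 0 else exp(mean(log(abs(x)))),
    P  = {  # sign-preserving geometric mean
      if (any(x == 0)) 0
      else sign(prod(sign(x))) * exp(mean(log(abs(x))))
    },
    SD = if (n < 2L) 0 else stats::sd(x),
    V  = if (n < 2L) 0 else stats::var(x),
    S  = .skewness(x),
    K  = .kurtosis(x),
    RA = max(x) - min(x),
    i50 = stats::median(x),
    MX = max(x),
    MN = min(x),
    PN = sum(x[x < 0]),
    stop("unknown aggregation operator '", op, "'"))
}

# parse "AC[3]" -> list(op = "AC", lag = 3); "RA" -> list(op = "RA", lag = NA)
.parse_op <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Za-z]+[0-9]*?)(\\[([0-9]+)\\])?$", tok))[[1]]
  if (!length(m)) stop("malformed operator token '", tok, "'")
  op <- m[2]; lag <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  if (op %in% .LAG_OPS && is.na(lag))
    stop("operator ", op, " needs a lag, e.g. \"", op, "[2]\"")
  if (!(op %in% c(.SCALAR_OPS, .LAG_OPS)))
    stop("unknown aggregation operator '", op, "'")
  list(op = op, lag = lag)
}

#' Aggregate atom contributions into a scalar descriptor
#'
#' Registered scalar operators: `N1` (Manhattan norm, sum of |L_a|), `N2`
#' (Euclidean norm), `N3` (Minkowski-3 norm), `ES` (plain sum), `AM`
#' (mean), `GM` (geometric mean of |L_a|, 0 if any entry is 0), `P`
#' (sign-preserving geometric mean), `SD` (sample standard deviation), `V`
#' (variance), `S` (skewness), `K` (excess kurtosis), `RA` (range), `i50`
#' (median), `MX`, `MN`, `PN` (sum of negative entries).  Lag operators
#' over input atom order: `AC[k]` (lag-k autocorrelation, 0 for constant
#' vectors), `TS[k]` (lag-k cross-sum `sum L_a L_{a+k}`), `GV[k]`
#' (`sum_{|a-b| = k} L_a L_b / d_ab^2`, Euclidean d, needs coordinates).
#'
#' A two-element chain such as `"AC[3]_K"` first evaluates the lag
#' operator at every lag `1..k` (the lag profile) and then applies the
#' scalar statistic to that profile.
#'
#' @param L numeric vector of atom contributions.
#' @param operator operator id, possibly a `_`-separated chain of length 2.
#' @param mol optional `molecule3d` (or n x 3 coordinate matrix), required
#'   by `GV`.
#' @return scalar descriptor value.
#' @export
aggregate_contributions <- function(L, operator, mol = NULL) {
  stopifnot(is.numeric(L), length(L) >= 1L)
  coords <- if (inherits(mol, "molecule3d")) mol$coords
            else if (!is.null(mol)) as.matrix(mol)
  toks <- strsplit(operator, "_", fixed = TRUE)[[1]]
  if (!length(toks) || length(toks) > 2L)
    stop("operator chain must have one or two elements: '", operator, "'")
  p1 <- .parse_op(toks[1])
  lag_eval <- function(op, k) switch(op,
    AC = .autocorr(L, k), TS = .lagsum(L, k), GV = .gravitational(L, k, coords))
  if (length(toks) == 1L) {
    if (p1$op %in% .LAG_OPS) return(lag_eval(p1$op, p1$lag))
    return(.apply_scalar_op(p1$op, L))
  }
  if (!(p1$op %in% .LAG_OPS))
    stop("the first element of a chain must be a lag operator (AC/TS/GV)")
  p2 <- .parse_op(toks[2])
  if (p2$op %in% .LAG_OPS)
    stop("the second element of a chain must be a scalar statistic")
  profile <- vapply(seq_len(p1$lag), function(k) lag_eval(p1$op, k),
                    numeric(1))
  .apply_scalar_op(p2$op, profile)
}

# ---- descriptor configuration and naming --------------------------------

.FORM_CODES <- c(L = 1L, Q = 1L, B = 2L, Tr = 3L, Qu = 4L)

#' Describe one molecular descriptor
#'
#' A full recipe: tensor order and algebraic form, matrix state, metric (or
#' multi-metric with base metric), Hadamard power, optional fragment,
#' property tuple and aggregation operator (chain).
#'
#' Forms and property tuples: `"L"` linear (one property; the other slot
#' takes the unit vector), `"Q"` quadratic (one property used twice),
#' `"B"` bilinear (two properties), `"Tr"` trilinear (three), `"Qu"`
#' quadrilinear (four).  `L`, `Q` and `B` imply order 2; `Tr` order 3;
#' `Qu` order 4.
#'
#' @param form one of `"L"`, `"Q"`, `"B"`, `"Tr"`, `"Qu"`.
#' @param props character vector of property ids (length per the form).
#' @param metric metric code (order 2) or multi-metric code (orders 3-4).
#' @param state matrix state `"NS"`, `"SS"`, `"DS"` or `"MP"`.
#' @param k Hadamard power.
#' @param operator aggregation operator (chain) id.
#' @param base_metric base metric code for multi-metrics (default `"M5"`,
#'   Euclidean).
#' @param fragment fragment code (`"A"`, `"C"`, `"D"`, `"G"`, `"M"`,
#'   `"P"`, `"X"`) or `NULL` for the total descriptor.
#' @param p optional Minkowski exponent override.
#' @return an object of class `"descriptor_config"`.
#' @export
descriptor_config <- function(form, props, metric, state = "NS", k = 1L,
                              operator = "ES", base_metric = "M5",
                              fragment = NULL, p = NULL) {
  form <- match.arg(form, names(.FORM_CODES))
  order <- if (form %in% c("L", "Q", "B")) 2L else .FORM_CODES[[form]]
  nprops <- switch(form, L = 1L, Q = 1L, B = 2L, Tr = 3L, Qu = 4L)
  props <- as.character(props)
  if (length(props) != nprops)
    stop("form ", form, " takes ", nprops, " property id(s)")
  state <- match.arg(toupper(state), c("NS", "SS", "DS", "MP"))
  if (state == "DS" && order != 2L)
    stop("double-stochastic state is only defined for order 2")
  k <- as.integer(k)
  if (k == 0L || abs(k) > 12L) stop("k must satisfy 1 <= |k| <= 12")
  if (order == 2L) {
    spec <- metric_spec(metric, p = p)
  } else {
    spec <- multimetric_spec(metric, base_metric = metric_spec(base_metric))
  }
  if (!is.null(fragment))
    fragment <- match.arg(fragment, c("A", "C", "D", "G", "M", "P", "X"))
  .parse_op_chain_check(operator)
  structure(list(form = form, order = order, props = props, spec = spec,
                 state = state, k = k, operator = operator,
                 fragment = fragment),
            class = "descriptor_config")
}

.parse_op_chain_check <- function(operator) {
  toks <- strsplit(operator, "_", fixed = TRUE)[[1]]
  lapply(toks, .parse_op)
  invisible(TRUE)
}

#' @export
print.descriptor_config <- function(x, ...) {
  cat("<descriptor_config>", descriptor_name(x), "\n")
  invisible(x)
}

#' Canonical descriptor name
#'
#' The grammar `STATEk-OP-FORM[props]-METRIC[-FRAGMENT]`, e.g.
#' `"SS2-RA-B[a,c]-M1-total"`.  Multi-metrics carry their base metric as
#' `"M20(M4)"`; a non-default Minkowski exponent is appended as
#' `"M1{p=1}"`; a negative Hadamard power is written `m|k|` (`"NSm2"` for
#' k = -2).  Parsing round-trips: see [parse_descriptor_name()].
#'
#' @param cfg a [descriptor_config()].
#' @return character scalar.
#' @export
descriptor_name <- function(cfg) {
  stopifnot(inherits(cfg, "descriptor_config"))
  spec <- cfg$spec
  met <- if (inherits(spec, "metric_spec")) {
    code <- spec$code
    if (!is.null(spec$p) && spec$p != .MINKOWSKI_P[[code]])
      code <- sprintf("%s{p=%g}", code, spec$p)
    code
  } else {
    sprintf("%s(%s)", spec$code, spec$base_metric$code)
  }
  kstr <- if (cfg$k < 0) paste0("m", -cfg$k) else as.character(cfg$k)
  sprintf("%s%s-%s-%s[%s]-%s-%s", cfg$state, kstr, cfg$operator, cfg$form,
          paste(cfg$props, collapse = ","), met,
          cfg$fragment %||% "total")
}

#' Parse a canonical descriptor name
#'
#' Inverse of [descriptor_name()].
#'
#' @param name character scalar in the canonical grammar.
#' @return a [descriptor_config()].
#' @export
parse_descriptor_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) < 4L) stop("malformed descriptor name: ", name)
  frag <- parts[length(parts)]
  met <- parts[length(parts) - 1L]
  statek <- parts[1]
  formpart <- parts[length(parts) - 2L]
  op <- paste(parts[seq(2L, length(parts) - 3L)], collapse = "-")
  m <- regmatches(statek, regexec("^(NS|SS|DS|MP)(m)?([0-9]+)$", statek))[[1]]
  if (!length(m)) stop("malformed state/power prefix: ", statek)
  state <- m[2]
  k <- as.integer(m[4]) * if (nzchar(m[3])) -1L else 1L
  fm <- regmatches(formpart,
                   regexec("^(L|Q|B|Tr|Qu)\\[([^]]*)\\]$", formpart))[[1]]
  if (!length(fm)) stop("malformed form part: ", formpart)
  form <- fm[2]
  props <- strsplit(fm[3], ",", fixed = TRUE)[[1]]
  mm <- regmatches(met, regexec("^(M[0-9]+)(\\((M[0-9]+)\\))?(\\{p=([0-9.]+)\\})?$",
                                met))[[1]]
  if (!length(mm)) stop("malformed metric part: ", met)
  metric <- mm[2]
  base <- if (nzchar(mm[4])) mm[4] else "M5"
  p <- if (nzchar(mm[6])) as.numeric(mm[6]) else NULL
  descriptor_config(form = form, props = props, metric = metric,
                    state = state, k = k, operator = op,
                    base_metric = base,
                    fragment = if (frag == "total") NULL else frag, p = p)
}

#' Compute one molecular descriptor
#'
#' Composes the full pipeline: build the non-stochastic k = 1 tensor,
#' optionally project onto the configured fragment, apply the
#' probabilistic transform, raise to the Hadamard power, contract with the
#' property vectors (atom-level splitting included in the contraction) and
#' aggregate the atom contributions.
#'
#' @param mol a `molecule3d`.
#' @param cfg a [descriptor_config()].
#' @return scalar descriptor value.
#' @export
compute_descriptor <- function(mol, cfg) {
  stopifnot(inherits(mol, "molecule3d"), inherits(cfg, "descriptor_config"))
  t <- build_total_matrix(mol, cfg$order, cfg$spec)
  if (!is.null(cfg$fragment)) {
    masks <- assign_fragments(mol)
    mask <- masks[[cfg$fragment]]
    if (!isTRUE(attr(mask, "available")))
      stop("fragment ", cfg$fragment, " needs bond connectivity, which ",
           mol$id, " lacks")
    t <- apply_fragment(t, mask)
  }
  t <- .apply_state(t, cfg$state)
  if (cfg$k != 1L) t <- hadamard_power(t, cfg$k)
  props <- switch(cfg$form,
    L  = list(property_vector(mol, cfg$props[1]), rep(1, length(mol$elements))),
    Q  = rep(list(property_vector(mol, cfg$props[1])), 2L),
    lapply(cfg$props, function(p) property_vector(mol, p)))
  L <- contract(t, props)
  aggregate_contributions(L, cfg$operator, mol = mol)
}

#' Compute a molecules x descriptors table
#'
#' @param mols list of `molecule3d` objects.
#' @param configs list of [descriptor_config()]s (or canonical names).
#' @return data frame: first column `molecule`, remaining columns one per
#'   descriptor in canonical name order of `configs`.
#' @export
compute_descriptor_table <- function(mols, configs) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  configs <- lapply(configs, function(cf)
    if (is.character(cf)) parse_descriptor_name(cf) else cf)
  nms <- vapply(configs, descriptor_name, "")
  if (anyDuplicated(nms)) stop("duplicate descriptor configurations")
  vals <- matrix(NA_real_, length(mols), length(configs),
                 dimnames = list(NULL, nms))
  for (i in seq_along(mols)) for (j in seq_along(configs)) {
    vals[i, j] <- tryCatch(compute_descriptor(mols[[i]], configs[[j]]),
                           error = function(e) {
                             warning("descriptor ", nms[j], " failed for ",
                                     mols[[i]]$id, ": ",
                                     conditionMessage(e))
                             NA_real_
                           })
  }
  data.frame(molecule = vapply(mols, function(m) m$id, ""), vals,
             check.names = FALSE)
}
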