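# Order-N (N = 2, 3, 4) total spatial (dis)similarity tensors over the atoms
# of a molecule, plus the transformations applied to them before descriptor
# contraction: local-fragment projection, probabilistic normalizations
# (simple-stochastic, double-stochastic, mutual-probability), Hadamard
# powers and atom-level splitting.
#
# Pipeline order (fixed): build non-stochastic k = 1 tensor -> optional
# fragment projection -> probabilistic transform -> Hadamard power ->
# atom-level split.  Matrix state codes "NS", "SS", "DS", "MP" and the
# power k are public identifiers embedded in descriptor names.

.ORDER4_ATOM_LIMIT <- 120L

new_tuple_matrix <- function(values, order, state = "ns", power = 1L,
                             fragment = NULL, metric_tag = "") {
  stopifnot(is.array(values) || is.matrix(values))
  structure(list(values = values, order = as.integer(order), state = state,
                 power = as.integer(power), fragment = fragment,
                 metric_tag = metric_tag),
            class = "tuple_matrix")
}

#' @export
print.tuple_matrix <- function(x, ...) {
  n <- dim(x$values)[1]
  cat(sprintf("<tuple_matrix> order %d, %d atoms, state %s, k = %d%s%s\n",
              x$order, n, toupper(x$state), x$power,
              if (nzchar(x$metric_tag)) paste0(", metric ", x$metric_tag) else "",
              if (!is.null(x$fragment)) paste0(", fragment ", x$fragment) else ""))
  if (x$order == 2L) print(round(x$values, 3))
  invisible(x)
}

#' Build an order-N total spatial (dis)similarity tensor
#'
#' For `order = 2` with a [metric_spec()], entry (i, j) is the pairwise
#' (dis)similarity of atoms i and j.  For `order = 3` (`order = 4`) with a
#' [multimetric_spec()], entry (i, j, l) (resp. (i, j, l, h)) is the ternary
#' (quaternary) measure of the atom tuple in index order; for bond angles
#' the vertex therefore sits at the *row* (first-index) atom.  Entries with
#' any repeated atom index are 0.
#'
#' Coordinate-dependent metrics honour the spec's `origin` policy: with
#' `origin = "nonnegative"` the molecule is first translated so all
#' coordinates are >= 0.
#'
#' @param mol a `molecule3d` (see [read_structures()]) or a plain numeric
#'   n x 3 coordinate matrix.
#' @param order tensor order, 2, 3 or 4.
#' @param spec [metric_spec()] (order 2) or [multimetric_spec()] (orders
#'   3-4).
#' @return a `tuple_matrix` in the non-stochastic state with k = 1.
#' @export
build_total_matrix <- function(mol, order, spec) {
  xyz <- if (inherits(mol, "molecule3d")) mol$coords else as.matrix(mol)
  stopifnot(is.numeric(xyz), ncol(xyz) == 3L, all(is.finite(xyz)))
  order <- as.integer(order)
  n <- nrow(xyz)
  if (!order %in% 2:4) stop("order must be 2, 3 or 4")
  if (n < order) stop("molecule has ", n, " atoms; order ", order,
                      " needs at least ", order)
  if (order == 2L) {
    if (!inherits(spec, "metric_spec"))
      stop("order 2 requires a metric_spec")
  } else {
    if (!inherits(spec, "multimetric_spec"))
      stop("orders 3 and 4 require a multimetric_spec")
    if (order == 4L && n > .ORDER4_ATOM_LIMIT)
      stop("order-4 tensors are limited to ", .ORDER4_ATOM_LIMIT, " atoms")
  }
  origin <- if (inherits(spec, "metric_spec")) spec$origin
            else spec$base_metric$origin
  if (identical(origin, "nonnegative"))
    xyz <- sweep(xyz, 2, apply(xyz, 2, min), "-")
  tag <- if (inherits(spec, "metric_spec")) spec$code
         else paste0(spec$code, "(", spec$base_metric$code, ")")

  if (order == 2L) {
    v <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v[i, j] <- pairwise_distance(spec, xyz[i, ], xyz[j, ])
      v[j, i] <- pairwise_distance(spec, xyz[j, ], xyz[i, ])
    }
  } else if (order == 3L) {
    v <- array(0, c(n, n, n))
    idx <- seq_len(n)
    for (i in idx) for (j in idx) for (l in idx) {
      if (i == j || j == l || i == l) next
      v[i, j, l] <- ternary_measure(spec, xyz[i, ], xyz[j, ], xyz[l, ])
    }
  } else {
    v <- array(0, c(n, n, n, n))
    idx <- seq_len(n)
    for (i in idx) for (j in idx) for (l in idx) for (h in idx) {
      if (anyDuplicated(c(i, j, l, h))) next
      v[i, j, l, h] <- quaternary_measure(spec, xyz[i, ], xyz[j, ],
                                          xyz[l, ], xyz[h, ])
    }
  }
  new_tuple_matrix(v, order, metric_tag = tag)
}

# membership weight array: 1 when all tuple atoms are in the fragment,
# 1/2 when at least one (but not all) is, 0 when none are
.fragment_weights <- function(member, order) {
  m <- as.numeric(member)
  allin <- m; anyin <- m
  for (o in seq_len(order - 1)) {
    allin <- outer(allin, m)
    anyin <- 1 - outer(1 - anyin, 1 - m)
  }
  allin + 0.5 * (anyin - allin)
}

#' Project a tensor onto a local fragment
#'
#' Entries whose atoms all belong to the fragment are kept in full, entries
#' with at least one (but not all) member atom are halved, and entries with
#' no member atom are zeroed.  Fragment projection precedes any
#' probabilistic normalization, so the input must be in the non-stochastic
#' state.
#'
#' @param t a `tuple_matrix` with state `"ns"`.
#' @param mask logical membership vector (one flag per atom), or a
#'   `fragment_mask` from [assign_fragments()].
#' @param fragment_id optional label stored on the result.
#' @return the projected `tuple_matrix`.
#' @export
apply_fragment <- function(t, mask, fragment_id = NULL) {
  stopifnot(inherits(t, "tuple_matrix"))
  if (t$state != "ns")
    stop("fragment projection must precede normalization (state must be 'ns')")
  if (inherits(mask, "fragment_mask")) {
    if (is.null(fragment_id)) fragment_id <- attr(mask, "fragment_id")
    mask <- as.logical(mask)
  }
  n <- dim(t$values)[1]
  if (length(mask) != n)
    stop("mask length ", length(mask), " does not match atom count ", n)
  w <- .fragment_weights(mask, t$order)
  out <- t
  out$values <- t$values * w
  out$fragment <- fragment_id %||% "F"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simple-stochastic normalization
#'
#' Divides every leading-index slice (the row for order 2; the (j), (j, l)
#' or (j, l, h) block for fixed first index i) by its sum.  All-zero slices
#' are left at zero.  This is the generalization of row-stochastic
#' normalization to higher tensor orders.
#'
#' @param t a `tuple_matrix` with state `"ns"`.
#' @return the normalized `tuple_matrix`, state `"ss"`.
#' @export
simple_stochastic <- function(t) {
  stopifnot(inherits(t, "tuple_matrix"), t$state == "ns")
  v <- t$values
  n <- dim(v)[1]
  flat <- matrix(v, nrow = n)            # leading index runs over rows
  s <- rowSums(flat)
  s[s == 0] <- 1
  flat <- flat / s
  out <- t
  out$values <- array(flat, dim(v), dimnames = dimnames(v))
  out$state <- "ss"
  out
}

#' Double-stochastic (Sinkhorn-Knopp) normalization
#'
#' Iteratively rescales a non-negative order-2 matrix until every row and
#' column sum is within `tol` of 1.  Symmetric inputs use the symmetric
#' two-sided scaling `D A D`, whose output is exactly symmetric; general
#' inputs use alternating row/column normalization.
#'
#' @param t a `tuple_matrix` with `order = 2`, state `"ns"`, non-negative
#'   entries and total support.
#' @param tol convergence tolerance on row/column sums (default `1e-8`).
#' @param max_iter iteration cap (default 10000).
#' @return the normalized `tuple_matrix`, state `"ds"`.
#' @export
double_stochastic <- function(t, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(t, "tuple_matrix"), t$state == "ns")
  if (t$order != 2L)
    stop("double-stochastic normalization is defined for order 2 only")
  A <- t$values
  if (any(A < 0)) stop("matrix must be non-negative")
  n <- nrow(A)
  slack <- function(M) max(abs(c(rowSums(M), colSums(M)) - 1))
  if (isTRUE(all.equal(A, base::t(A), tolerance = 1e-12))) {
    d <- rep(1 / sqrt(sum(A) / n), n)
    for (it in seq_len(max_iter)) {
      Ad <- as.vector(A %*% d)
      if (any(Ad == 0)) stop("matrix lacks total support (zero row scaling)")
      d <- sqrt(d / Ad)
      M <- A * outer(d, d)
      if (slack(M) < tol) break
    }
  } else {
    M <- A
    for (it in seq_len(max_iter)) {
      rs <- rowSums(M); rs[rs == 0] <- 1
      M <- M / rs
      cs <- colSums(M); cs[cs == 0] <- 1
      M <- sweep(M, 2, cs, "/")
      if (slack(M) < tol) break
    }
  }
  if (slack(M) >= tol)
    stop(sprintf(paste0("Sinkhorn-Knopp did not converge in %d iterations ",
                        "(remaining slack %.3g > tol %.3g)"),
                 max_iter, slack(M), tol))
  out <- t
  out$values <- M
  out$state <- "ds"
  out
}

#' Mutual-probability normalization
#'
#' Divides every entry by the grand total of the tensor so that the output
#' sums to 1.  An all-zero tensor is returned unchanged.
#'
#' @param t a `tuple_matrix` with state `"ns"`.
#' @return the normalized `tuple_matrix`, state `"mp"`.
#' @export
mutual_probability <- function(t) {
  stopifnot(inherits(t, "tuple_matrix"), t$state == "ns")
  out <- t
  g <- sum(t$values)
  if (g != 0) out$values <- t$values / g
  out$state <- "mp"
  out
}

#' Entrywise (Hadamard) power
#'
#' Raises every entry to the k-th power.  Negative k means the entrywise
#' reciprocal raised to |k|, with zero entries mapped to zero so the sparse
#' structure (repeated-index zeros, fragment zeros) is preserved.  The
#' power is applied after the probabilistic transform of the k = 1 tensor.
#'
#' @param t a `tuple_matrix`.
#' @param k integer power, |k| in 1..12, k != 0.
#' @return the powered `tuple_matrix`.
#' @export
hadamard_power <- function(t, k) {
  stopifnot(inherits(t, "tuple_matrix"))
  k <- as.integer(k)
  if (k == 0L) stop("k = 0 is not a valid Hadamard power")
  if (abs(k) > 12L) stop("|k| must be in 1..12")
  out <- t
  if (k > 0L) {
    out$values <- t$values^k
  } else {
    v <- t$values
    r <- ifelse(v == 0, 0, 1 / v)
    out$values <- r^abs(k)
  }
  out$power <- k
  out
}

#' Atom-level splitting
#'
#' Retains exactly the entries having at least one index equal to `atom`
#' and zeroes all others, yielding the atom-level tensor whose contraction
#' with property vectors gives that atom's contribution.
#'
#' @param t a `tuple_matrix`.
#' @param atom atom index (1-based).
#' @return the atom-level `tuple_matrix`.
#' @export
atom_level_split <- function(t, atom) {
  stopifnot(inherits(t, "tuple_matrix"))
  n <- dim(t$values)[1]
  atom <- as.integer(atom)
  if (atom < 1L || atom > n) stop("atom index ", atom, " out of range 1..", n)
  keep <- array(FALSE, dim(t$values))
  for (p in seq_len(t$order))
    keep <- keep | (slice.index(t$values, p) == atom)
  out <- t
  out$values <- ifelse(keep, t$values, 0)
  out
}

# apply the configured probabilistic transform to an ns tensor
.apply_state <- function(t, state, ds_tol = 1e-8, ds_max_iter = 10000L) {
  switch(tolower(state),
         ns = t,
         ss = simple_stochastic(t),
         ds = double_stochastic(t, tol = ds_tol, max_iter = ds_max_iter),
         mp = mutual_probability(t),
         stop("unknown matrix state: ", state))
}
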