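# Reference fixtures: the chloro(methoxy)methane worked example (printed
# two-tuple matrices, their probabilistic transforms, fragment projections
# and the bond-angle three-tuple tensor, plus 3D coordinates recovered from
# the printed Euclidean distances), synthetic regression tables with a
# planted sparse signal, and random test molecules.

.WE_ATOMS <- c("C1", "C2", "O3", "Cl4")

.we_mat <- function(v) matrix(v, 4, 4, byrow = TRUE,
                              dimnames = list(.WE_ATOMS, .WE_ATOMS))

# two-tuple Euclidean total matrix (3-decimal reference values)
.WE_EUCLIDEAN <- .we_mat(c(
  0.000, 2.408, 1.439, 3.939,
  2.408, 0.000, 1.438, 1.757,
  1.439, 1.438, 0.000, 2.598,
  3.939, 1.757, 2.598, 0.000))

.WE_SS <- .we_mat(c(
  0.000, 0.309, 0.185, 0.506,
  0.430, 0.000, 0.257, 0.314,
  0.263, 0.263, 0.000, 0.475,
  0.475, 0.212, 0.313, 0.000))

.WE_DS <- .we_mat(c(
  0.000, 0.387, 0.246, 0.368,
  0.387, 0.000, 0.368, 0.246,
  0.246, 0.368, 0.000, 0.387,
  0.368, 0.246, 0.387, 0.000))

.WE_MP <- .we_mat(c(
  0.000, 0.089, 0.053, 0.145,
  0.089, 0.000, 0.053, 0.065,
  0.053, 0.053, 0.000, 0.096,
  0.145, 0.065, 0.096, 0.000))

.WE_FRAG_G <- .we_mat(c(     # halogens {Cl4}
  0.000, 0.000, 0.000, 1.969,
  0.000, 0.000, 0.000, 0.878,
  0.000, 0.000, 0.000, 1.299,
  1.969, 0.878, 1.299, 0.000))

.WE_FRAG_M <- .we_mat(c(     # terminal methyl {C1}
  0.000, 1.204, 0.719, 1.969,
  1.204, 0.000, 0.000, 0.000,
  0.719, 0.000, 0.000, 0.000,
  1.969, 0.000, 0.000, 0.000))

.WE_FRAG_X <- .we_mat(c(     # heteroatoms {O3, Cl4}
  0.000, 0.000, 0.719, 1.969,
  0.000, 0.000, 0.719, 0.878,
  0.719, 0.719, 0.000, 2.598,
  1.969, 0.878, 2.598, 0.000))

# bond-angle three-tuple tensor slices (third index = slide); entry
# (i, j, l) is the angle at vertex i between the directions to j and l
.WE_ANGLE_SLIDES <- list(
  .we_mat(c(0.000, 0.000, 0.000, 0.000,
            0.000, 0.000, 0.578, 2.470,
            0.000, 1.985, 0.000, 2.682,
            0.000, 0.390, 0.163, 0.000)),
  .we_mat(c(0.000, 0.000, 0.578, 0.281,
            0.000, 0.000, 0.000, 0.000,
            1.985, 0.000, 0.000, 0.697,
            0.390, 0.000, 0.553, 0.000)),
  .we_mat(c(0.000, 0.578, 0.000, 0.297,
            0.578, 0.000, 0.000, 1.892,
            0.000, 0.000, 0.000, 0.000,
            0.163, 0.553, 0.000, 0.000)),
  .we_mat(c(0.000, 0.281, 0.297, 0.000,
            2.470, 0.000, 1.892, 0.000,
            2.682, 0.697, 0.000, 0.000,
            0.000, 0.000, 0.000, 0.000)))

#' Embed points from a distance matrix (classical MDS)
#'
#' Classical (Torgerson) multidimensional scaling of a symmetric
#' zero-diagonal distance matrix into 3D Cartesian coordinates.  The
#' output is deterministic: axes follow decreasing eigenvalue order and
#' each axis's sign is fixed so that its first nonzero coordinate is
#' positive.  When the Gram form has more than three significantly
#' positive eigenvalues the matrix is not exactly 3D-embeddable; a warning
#' reports the residual.
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @return n x 3 coordinate matrix (rows named like `D`).
#' @export
embed_from_distances <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D), all(D >= 0),
            max(abs(diag(D))) == 0,
            isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = min(3L, n - 1L), eig = TRUE))
  eig <- fit$eig
  scale0 <- max(abs(eig))
  if (sum(eig > 1e-8 * scale0) > 3L) {
    rec <- as.matrix(stats::dist(fit$points))
    warning(sprintf(paste0("distance matrix is not exactly embeddable in 3D ",
                           "(%d positive eigenvalues); max distance residual %.3g"),
                    sum(eig > 1e-8 * scale0), max(abs(rec - D))))
  }
  P <- fit$points
  if (ncol(P) < 3L) P <- cbind(P, matrix(0, n, 3L - ncol(P)))
  for (j in 1:3) {
    nz <- which(abs(P[, j]) > 1e-12)
    if (length(nz) && P[nz[1], j] < 0) P[, j] <- -P[, j]
  }
  rownames(P) <- rownames(D)
  colnames(P) <- c("x", "y", "z")
  P
}

#' The chloro(methoxy)methane worked example
#'
#' Packages the reference 4 x 4 heavy-atom matrices of CH3-O-CH2-Cl used
#' across the test-suite: the Euclidean two-tuple total matrix and its
#' simple-stochastic, double-stochastic and mutual-probability transforms,
#' the halogen / terminal-methyl / heteroatom local-fragment projections,
#' the bond-angle three-tuple tensor, 3D coordinates embedded from the
#' distance matrix (the absolute frame is not recoverable from distances,
#' so coordinates are exact only up to rigid motion), and the molecule
#' itself (atoms C1, C2, O3, Cl4; bonds C1-O3, O3-C2, C2-Cl4).
#'
#' Reference entries carry 3-decimal rounding; distances reproduce to
#' 0.002 A and angles to 0.005 rad.
#'
#' @return list with elements `euclidean`, `ss`, `ds`, `mp`, `fragments`
#'   (list `G`, `M`, `X` of matrices), `angle_tensor` (4 x 4 x 4 array),
#'   `fragment_members`, `coords`, `molecule`.
#' @export
worked_example <- function() {
  ang <- array(0, c(4, 4, 4), dimnames = list(.WE_ATOMS, .WE_ATOMS, .WE_ATOMS))
  for (l in 1:4) ang[, , l] <- .WE_ANGLE_SLIDES[[l]]
  coords <- embed_from_distances(.WE_EUCLIDEAN)
  mol <- molecule3d(c("C", "C", "O", "Cl"), coords,
                    bonds = data.frame(a1 = c(1L, 3L, 2L),
                                       a2 = c(3L, 2L, 4L),
                                       order = c(1L, 1L, 1L)),
                    id = "chloro(methoxy)methane")
  list(euclidean = .WE_EUCLIDEAN, ss = .WE_SS, ds = .WE_DS, mp = .WE_MP,
       fragments = list(G = .WE_FRAG_G, M = .WE_FRAG_M, X = .WE_FRAG_X),
       angle_tensor = ang,
       fragment_members = list(G = "Cl4", M = "C1", X = c("O3", "Cl4")),
       coords = coords, molecule = mol)
}

#' Synthetic regression data with a planted sparse signal
#'
#' Generates a descriptor table whose columns mix independent standard
#' normal draws, pairwise-correlated pairs (to exercise the correlation
#' filter) and exact duplicates, with a response
#' `y = X[, support] %*% beta + N(0, noise_sd)`.
#'
#' @param n molecules (rows).
#' @param p descriptors (columns, named `"d001"`...).
#' @param support integer indices of the informative descriptors.
#' @param beta coefficients, one per support element.
#' @param noise_sd noise standard deviation; `noise_frac` instead scales
#'   it to `noise_frac * sd(signal)` when given.
#' @param noise_frac optional noise level as a fraction of the signal sd.
#' @param n_correlated number of columns generated as 0.99-correlated
#'   copies of earlier columns.
#' @param n_duplicates number of exact duplicate columns appended.
#' @param seed integer RNG seed (deterministic tables).
#' @return list with `table` (data frame incl. `molecule` ids), `y`,
#'   and `truth` (support names, beta, noise_sd, achievable R2).
#' @export
synthetic_regression <- function(n = 60L, p = 100L, support = c(3L, 7L, 12L),
                                 beta = c(2, -1, 0.5), noise_sd = NULL,
                                 noise_frac = 0.1, n_correlated = 0L,
                                 n_duplicates = 0L, seed = 1L) {
  stopifnot(length(support) == length(beta), all(support >= 1L),
            all(support <= p))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (n_correlated > 0L) {
    src <- sample(setdiff(seq_len(p), support), n_correlated)
    for (k in seq_len(n_correlated)) {
      j <- src[k]
      tgt <- p - n_duplicates - n_correlated + k
      X[, tgt] <- 0.99 * X[, j] + sqrt(1 - 0.99^2) * stats::rnorm(n)
    }
  }
  dup_of <- integer(0)
  if (n_duplicates > 0L) {
    dup_of <- sample(setdiff(seq_len(p - n_duplicates), support), n_duplicates)
    for (k in seq_len(n_duplicates)) X[, p - n_duplicates + k] <- X[, dup_of[k]]
  }
  colnames(X) <- sprintf("d%03d", seq_len(p))
  signal <- as.vector(X[, support, drop = FALSE] %*% beta)
  if (is.null(noise_sd)) noise_sd <- noise_frac * stats::sd(signal)
  y <- signal + stats::rnorm(n, sd = noise_sd)
  r2_achievable <- stats::var(signal) / (stats::var(signal) + noise_sd^2)
  list(table = data.frame(molecule = sprintf("mol%03d", seq_len(n)), X,
                          check.names = FALSE),
       y = y,
       truth = list(support = colnames(X)[support], beta = beta,
                    noise_sd = noise_sd, r2_achievable = r2_achievable,
                    duplicate_of = if (length(dup_of))
                      stats::setNames(colnames(X)[dup_of],
                                      colnames(X)[p - n_duplicates +
                                                    seq_len(n_duplicates)])
                    else NULL))
}

#' Random chain molecule
#'
#' Elements drawn from C, N, O, S, F, Cl; coordinates uniform in a 10 A
#' box, rejection-sampled to a minimum pairwise separation of 1 A; bonds
#' form a simple chain in atom order.  Deterministic per seed.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param seed integer RNG seed.
#' @return a `molecule3d`.
#' @export
random_molecule <- function(n_atoms, seed = 1L) {
  stopifnot(n_atoms >= 2L)
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S", "F", "Cl"), n_atoms,
                     replace = TRUE)
  coords <- matrix(NA_real_, n_atoms, 3)
  placed <- 0L
  while (placed < n_atoms) {
    cand <- stats::runif(3, 0, 10)
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(coords[seq_len(placed), , drop = FALSE],
                               2, cand)^2))) >= 1.0) {
      placed <- placed + 1L
      coords[placed, ] <- cand
    }
  }
  bonds <- if (n_atoms >= 2L)
    data.frame(a1 = seq_len(n_atoms - 1L), a2 = 2:n_atoms, order = 1L)
  molecule3d(elements, coords, bonds, id = paste0("random", seed))
}
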