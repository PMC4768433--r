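# Pairwise (dis)similarity metrics on atomic 3D coordinates, and ternary /
# quaternary multi-metrics on atom triples and quadruples.  Metric codes
# "M1".."M16" and multi-metric codes "M19".."M30" are the stable public
# identifiers used in descriptor configurations and names.

.MINKOWSKI_P <- c(M1 = 0.25, M2 = 0.5, M3 = 1, M4 = 1.5, M5 = 2, M6 = 2.5,
                  M7 = 3)

#' Specify a pairwise atomic (dis)similarity metric
#'
#' Codes `"M1"`..`"M7"` are the Minkowski family with default exponents
#' p = 0.25, 0.5, 1 (Manhattan), 1.5, 2 (Euclidean), 2.5 and 3; `"M8"` is
#' Chebyshev (the p -> Inf limit); `"M10"` Canberra, `"M11"`
#' Lance-Williams/Bray-Curtis, `"M12"` Clark, `"M13"` Soergel, `"M14"`
#' Bhattacharyya, `"M15"` Wave-Edges and `"M16"` angular separation
#' (1 - cosine).  Codes M9, M17 and M18 are unassigned.
#'
#' M10-M16 operate on the raw coordinate values, not on coordinate
#' differences, so they are *not* invariant under rigid motion of the
#' molecule; their value depends on the coordinate frame of the input file
#' (`origin = "as-read"`).  `origin = "nonnegative"` first translates the
#' molecule so every coordinate is >= 0, which is required for the
#' Bhattacharyya metric under `policy = "strict"`.
#'
#' @param code metric code, one of `"M1"`..`"M8"`, `"M10"`..`"M16"`.
#' @param p Minkowski exponent, only for M1-M7; defaults to the exponent
#'   conventionally attached to the code.
#' @param soergel_1_over_n logical; include the 1/n prefactor in the Soergel
#'   formula.  Off by default (see the methods vignette).
#' @param origin coordinate-frame policy for the coordinate-dependent
#'   metrics M10-M16: `"as-read"` (default) or `"nonnegative"`.
#' @param policy `"strict"` errors when Bhattacharyya sees a negative
#'   coordinate; `"clip"` clamps negatives to zero.
#' @return an object of class `"metric_spec"`.
#' @examples
#' pairwise_distance(metric_spec("M3"), c(0, 0, 0), c(3, 4, 0))  # 7
#' pairwise_distance(metric_spec("M5"), c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
metric_spec <- function(code, p = NULL, soergel_1_over_n = FALSE,
                        origin = c("as-read", "nonnegative"),
                        policy = c("strict", "clip")) {
  code <- match.arg(code, c(paste0("M", 1:8), paste0("M", 10:16)))
  origin <- match.arg(origin)
  policy <- match.arg(policy)
  if (code %in% names(.MINKOWSKI_P)) {
    if (is.null(p)) p <- .MINKOWSKI_P[[code]]
    stopifnot(is.numeric(p), length(p) == 1L, p > 0)
  } else if (!is.null(p)) {
    stop("exponent 'p' only applies to Minkowski codes M1-M7")
  }
  structure(list(code = code, p = p, soergel_1_over_n = soergel_1_over_n,
                 origin = origin, policy = policy),
            class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  cat("<metric_spec>", x$code,
      if (!is.null(x$p)) paste0("(p=", x$p, ")") else "", "\n")
  invisible(x)
}

#' Specify a ternary/quaternary multi-metric
#'
#' Ternary measures (atom triples): `"M19"`/`"M20"` perimeter, `"M21"`/
#' `"M22"` triangle area (Heron), `"M25"`/`"M26"` sides summation, `"M27"`/
#' `"M28"` bond angle (vertex at the first atom).  Quaternary measures
#' (atom quadruples): `"M19"`/`"M20"` perimeter, `"M23"`/`"M24"` tetrahedron
#' volume, `"M25"`/`"M26"` sides summation, `"M29"`/`"M30"` dihedral angle.
#' Paired codes denote one measure usable at either arity where defined.
#' Perimeter, area and sides summation take their edge lengths from
#' `base_metric`; angles, dihedrals and volumes are purely Cartesian and
#' ignore it.
#'
#' @param code multi-metric code `"M19"`..`"M30"`.
#' @param base_metric a [metric_spec()] supplying edge lengths; defaults to
#'   Euclidean (`"M5"`).
#' @return an object of class `"multimetric_spec"`.
#' @export
multimetric_spec <- function(code, base_metric = metric_spec("M5")) {
  code <- match.arg(code, paste0("M", 19:30))
  stopifnot(inherits(base_metric, "metric_spec"))
  structure(list(code = code, base_metric = base_metric),
            class = "multimetric_spec")
}

#' @export
print.multimetric_spec <- function(x, ...) {
  cat("<multimetric_spec>", x$code, "base:", x$base_metric$code, "\n")
  invisible(x)
}

.mm_kind <- function(code) {
  switch(code,
         M19 = , M20 = "perimeter",
         M21 = , M22 = "area",
         M23 = , M24 = "volume",
         M25 = , M26 = "sides",
         M27 = , M28 = "angle",
         M29 = , M30 = "dihedral",
         stop("unknown multi-metric code: ", code))
}

# ratio with the 0/0 -> 0 continuity convention
.safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Pairwise atomic (dis)similarity
#'
#' Evaluates the metric `spec` between two 3D points.  All metrics are
#' symmetric and vanish when `a == b` (for angular separation, parallel
#' vectors have cosine 1, hence distance 0).  Terms with a zero denominator
#' (Canberra, Clark, Soergel, Wave-Edges) contribute 0.
#'
#' @param spec a [metric_spec()].
#' @param a,b numeric length-3 coordinate vectors (Angstrom).
#' @return non-negative scalar.
#' @export
pairwise_distance <- function(spec, a, b) {
  stopifnot(inherits(spec, "metric_spec"))
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(c(a, b))))
  code <- spec$code
  if (code %in% names(.MINKOWSKI_P))
    return(sum(abs(a - b)^spec$p)^(1 / spec$p))
  switch(code,
    M8  = max(abs(a - b)),
    M10 = sum(.safe_div(abs(a - b), abs(a) + abs(b))),
    M11 = .safe_div(sum(abs(a - b)), sum(abs(a) + abs(b))),
    M12 = sqrt(sum(.safe_div(a - b, abs(a) + abs(b))^2)),
    M13 = {
      d <- sum(.safe_div(abs(a - b), pmax(a, b)))
      if (spec$soergel_1_over_n) d / length(a) else d
    },
    M14 = {
      if (any(c(a, b) < 0)) {
        if (spec$policy == "strict")
          stop("Bhattacharyya metric (M14) requires non-negative ",
               "coordinates; use origin = \"nonnegative\" or policy = \"clip\"")
        a <- pmax(a, 0); b <- pmax(b, 0)
      }
      sqrt(sum((sqrt(a) - sqrt(b))^2))
    },
    M15 = sum(1 - .safe_div(pmin(a, b), pmax(a, b))),
    M16 = {
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den == 0) 0 else 1 - sum(a * b) / den
    })
}

# Euclidean helpers on bare coordinates
.enorm <- function(v) sqrt(sum(v^2))

.angle_at <- function(v, e1, e2) {
  u1 <- e1 - v; u2 <- e2 - v
  n1 <- .enorm(u1); n2 <- .enorm(u2)
  if (n1 == 0 || n2 == 0) return(0)        # degenerate: coincident atoms
  acos(min(1, max(-1, sum(u1 * u2) / (n1 * n2))))
}

#' Ternary multi-metric on an atom triple
#'
#' For the bond angle the vertex is the *first* argument: the returned
#' value is the angle at `a` between the directions to `b` and `c`, in
#' radians within \[0, pi\].  Perimeter is `d(a,b) + d(b,c) + d(c,a)`,
#' sides summation the ordered `d(a,b) + d(b,c)`, and the triangle area is
#' Heron's formula on those three edge lengths (radicand clipped at 0 for
#' near-collinear triples).  Degenerate angle configurations return 0.
#'
#' @param spec a [multimetric_spec()] with a ternary-capable code.
#' @param a,b,c numeric length-3 coordinate vectors.
#' @return scalar measure value.
#' @export
ternary_measure <- function(spec, a, b, c) {
  stopifnot(inherits(spec, "multimetric_spec"))
  kind <- .mm_kind(spec$code)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  bm <- spec$base_metric
  switch(kind,
    perimeter = pairwise_distance(bm, a, b) + pairwise_distance(bm, b, c) +
                pairwise_distance(bm, c, a),
    sides     = pairwise_distance(bm, a, b) + pairwise_distance(bm, b, c),
    area      = {
      dab <- pairwise_distance(bm, a, b)
      dbc <- pairwise_distance(bm, b, c)
      dca <- pairwise_distance(bm, c, a)
      s <- (dab + dbc + dca) / 2
      sqrt(max(0, s * (s - dab) * (s - dbc) * (s - dca)))
    },
    angle     = .angle_at(a, b, c),
    stop("multi-metric ", spec$code, " (", kind,
         ") is not defined for atom triples"))
}

#' Quaternary multi-metric on an atom quadruple
#'
#' Volume is the absolute tetrahedron volume `|det(b-a, c-a, d-a)|/6`
#' (absolute so the measure does not depend on atom enumeration order).
#' The dihedral angle is between the planes `(a, b, c)` and `(d, b, c)`,
#' via the normals `(a-b) x (c-b)` and `(d-b) x (c-b)`, in \[0, pi\];
#' collinear plane-defining atoms give a zero normal and return 0.
#' Perimeter is `d(a,b) + d(b,c) + d(c,d) + d(d,a)`; sides summation is
#' `d(a,b) + d(b,c) + d(c,d)`.
#'
#' @param spec a [multimetric_spec()] with a quaternary-capable code.
#' @param a,b,c,d numeric length-3 coordinate vectors.
#' @return scalar measure value.
#' @export
quaternary_measure <- function(spec, a, b, c, d) {
  stopifnot(inherits(spec, "multimetric_spec"))
  kind <- .mm_kind(spec$code)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  bm <- spec$base_metric
  switch(kind,
    perimeter = pairwise_distance(bm, a, b) + pairwise_distance(bm, b, c) +
                pairwise_distance(bm, c, d) + pairwise_distance(bm, d, a),
    sides     = pairwise_distance(bm, a, b) + pairwise_distance(bm, b, c) +
                pairwise_distance(bm, c, d),
    volume    = abs(det(cbind(b - a, c - a, d - a))) / 6,
    dihedral  = {
      ua <- .cross(a - b, c - b)
      ub <- .cross(d - b, c - b)
      na <- .enorm(ua); nb <- .enorm(ub)
      if (na == 0 || nb == 0) return(0)    # collinear plane atoms
      acos(min(1, max(-1, sum(ua * ub) / (na * nb))))
    },
    stop("multi-metric ", spec$code, " (", kind,
         ") is not defined for atom quadruples"))
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
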