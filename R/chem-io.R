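# Molecular structure input/output (SDF/MOL V2000 via ChemmineR, XYZ),
# atom-type fragment detection, and per-atom property vectors.
#
# Atom indexing is 0-based nowhere: indices are 1-based throughout, matching
# the chemical-table convention of numbering atoms from 1.

.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

# ctab atom-block charge codes (field 6): 1 = +3 ... 7 = -3, 4 = radical
.CTAB_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                  `6` = -2, `7` = -3)

#' Construct a molecule from elements, coordinates and bonds
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param bonds data frame / matrix with columns `a1`, `a2`, `order`
#'   (1-based atom indices; order 4 flags an aromatic bond).  May be empty.
#' @param id molecule identifier.
#' @param charges integer formal charges (default all 0).
#' @param n_hydrogens explicit/implicit hydrogen counts attached to each
#'   (heavy) atom; computed from default valences when `NULL`.
#' @param annotations named list of per-atom numeric vectors (e.g. partial
#'   charges carried in SDF `ATOM_PROP_*` data fields).
#' @return an object of class `"molecule3d"`.
#' @export
molecule3d <- function(elements, coords, bonds = NULL, id = "mol",
                       charges = NULL, n_hydrogens = NULL,
                       annotations = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  stopifnot(n >= 1L, nrow(coords) == n, ncol(coords) == 3L,
            all(is.finite(coords)))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("a1", "a2", "order")
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n))
      stop("bond atom index out of range")
  }
  if (is.null(charges)) charges <- integer(n)
  mol <- structure(list(id = id, elements = as.character(elements),
                        coords = coords, bonds = bonds,
                        charges = as.integer(charges),
                        n_hydrogens = n_hydrogens,
                        annotations = annotations),
                   class = "molecule3d")
  if (is.null(mol$n_hydrogens)) mol$n_hydrogens <- .implicit_hydrogens(mol)
  mol
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d atoms (%s), %d bonds\n", x$id,
              length(x$elements), paste(x$elements, collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

# hydrogens implied by default valence minus the sum of bond orders
# (aromatic bonds count 1.5); added to any explicitly recorded count
.implicit_hydrogens <- function(mol, explicit = integer(length(mol$elements))) {
  n <- length(mol$elements)
  bsum <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + ord[k]
      bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + ord[k]
    }
  }
  val <- .DEFAULT_VALENCE[mol$elements]
  val[is.na(val)] <- 0
  as.integer(explicit + pmax(0, round(val - bsum - explicit)))
}

# drop explicit hydrogens, remapping bonds and crediting heavy neighbours
.suppress_hydrogens <- function(mol) {
  isH <- mol$elements == "H"
  if (!any(isH)) return(mol)
  keep <- which(!isH)
  if (!length(keep)) stop("molecule contains only hydrogens")
  newidx <- integer(length(mol$elements))
  newidx[keep] <- seq_along(keep)
  expH <- integer(length(keep))
  b <- mol$bonds
  hb <- isH[b$a1] | isH[b$a2]
  if (any(hb)) {
    for (k in which(hb)) {
      heavy <- if (isH[b$a1[k]]) b$a2[k] else b$a1[k]
      if (!isH[heavy]) expH[newidx[heavy]] <- expH[newidx[heavy]] + 1L
    }
  }
  b <- b[!hb, , drop = FALSE]
  b$a1 <- newidx[b$a1]; b$a2 <- newidx[b$a2]
  out <- molecule3d(mol$elements[keep], mol$coords[keep, , drop = FALSE],
                    b, id = mol$id, charges = mol$charges[keep],
                    n_hydrogens = NULL,
                    annotations = lapply(mol$annotations, `[`, keep))
  out$n_hydrogens <- .implicit_hydrogens(out, explicit = expH)
  out
}

.sdfset_to_molecules <- function(sdfset, suppress_h) {
  out <- list()
  for (i in seq_along(sdfset)) {
    s <- sdfset[[i]]
    ab <- ChemmineR::atomblock(s)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    chgcode <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
    charges <- .CTAB_CHARGE[as.character(chgcode)]
    charges[is.na(charges)] <- 0
    bb <- ChemmineR::bondblock(s)
    bonds <- if (NROW(bb)) data.frame(a1 = bb[, 1], a2 = bb[, 2],
                                      order = bb[, 3]) else NULL
    db <- tryCatch(ChemmineR::datablock(s), error = function(e) character(0))
    ann <- list()
    if (length(db)) {
      propfields <- grep("^ATOM_PROP_", names(db), value = TRUE)
      for (f in propfields) {
        vals <- suppressWarnings(as.numeric(strsplit(trimws(db[[f]]),
                                                     "[[:space:]]+")[[1]]))
        ann[[sub("^ATOM_PROP_", "", f)]] <- vals
      }
    }
    hdr <- ChemmineR::header(s)
    id <- trimws(hdr[["Molecule_Name"]])
    if (!nzchar(id)) id <- paste0("mol", i)
    mol <- molecule3d(elements, coords, bonds, id = id, charges = charges,
                      annotations = ann)
    if (length(mol$annotations))
      mol$annotations <- lapply(mol$annotations, function(v) {
        if (length(v) != length(elements))
          stop("ATOM_PROP field length does not match atom count in ", id)
        v
      })
    if (suppress_h) mol <- .suppress_hydrogens(mol)
    out[[length(out) + 1L]] <- mol
  }
  out
}

.read_xyz <- function(path, suppress_h) {
  lines <- readLines(path)
  mols <- list(); i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    rec <- rec + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L || i + 1L + n > length(lines) + 1L) {
      warning("skipping malformed XYZ record ", rec, " in ", path)
      i <- i + 1L; next
    }
    title <- if (i + 1L <= length(lines)) trimws(lines[i + 1L]) else ""
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    ok <- vapply(tok, length, 1L) >= 4L
    if (!all(ok)) {
      warning("skipping malformed XYZ record ", rec, " in ", path)
      i <- i + 2L + n; next
    }
    elements <- vapply(tok, `[[`, "", 1L)
    coords <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      warning("skipping malformed XYZ record ", rec, " in ", path)
      i <- i + 2L + n; next
    }
    mol <- molecule3d(elements, coords,
                      id = if (nzchar(title)) title else paste0("mol", rec))
    if (suppress_h) mol <- .suppress_hydrogens(mol)
    mols[[length(mols) + 1L]] <- mol
    i <- i + 2L + n
  }
  mols
}

#' Read molecular structures
#'
#' Reads an SDF/MOL file (V2000) or a (multi-)XYZ file into a list of
#' `molecule3d` objects in file order.  Hydrogens are suppressed by default
#' (descriptors are conventionally computed on the hydrogen-depleted
#' skeleton); explicit hydrogens removed this way are credited to their
#' heavy neighbour's hydrogen count, which fragment detection uses.
#' Records that fail to parse are skipped with a warning; the call only
#' errors when no record is readable.
#'
#' Per-atom numeric annotations (e.g. precomputed partial charges) may be
#' supplied in SDF data fields named `ATOM_PROP_<id>` holding
#' whitespace-separated per-atom values.
#'
#' @param path file path.
#' @param format `"sdf"`, `"mol"` or `"xyz"`; guessed from the extension
#'   by default.
#' @param suppress_hydrogens drop explicit hydrogens (default `TRUE`).
#' @return list of `molecule3d` objects.
#' @export
read_structures <- function(path, format = c("auto", "sdf", "mol", "xyz"),
                            suppress_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "mol", xyz = "xyz",
                     stop("cannot guess format of '", path,
                          "'; pass format explicitly"))
  mols <- if (format == "xyz") {
    .read_xyz(path, suppress_hydrogens)
  } else {
    lines <- readLines(path)
    if (format == "mol" && !any(grepl("^\\$\\$\\$\\$", lines)))
      lines <- c(lines, "$$$$")
    ends <- grep("^\\$\\$\\$\\$", lines)
    starts <- c(1L, head(ends, -1L) + 1L)
    if (!length(ends)) { starts <- 1L; ends <- length(lines) }
    out <- list()
    for (r in seq_along(starts)) {
      chunk <- lines[starts[r]:ends[r]]
      if (!any(nzchar(trimws(chunk)))) next
      m <- tryCatch({
        sdfstr <- ChemmineR::read.SDFstr(chunk)
        sdfset <- suppressWarnings(methods::as(sdfstr, "SDFset"))
        if (!all(suppressWarnings(ChemmineR::validSDF(sdfset))))
          stop("invalid SDF record")
        .sdfset_to_molecules(sdfset, suppress_hydrogens)
      }, error = function(e) {
        warning("skipping unparsable SDF record ", r, " in ", path, ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(m)) out <- c(out, m)
    }
    out
  }
  if (!length(mols)) stop("no valid records in ", path)
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a `molecule3d` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  revchg <- c(`3` = 1, `2` = 2, `1` = 3, `-1` = 5, `-2` = 6, `-3` = 7)
  for (mol in mols) {
    n <- length(mol$elements); nb <- nrow(mol$bonds)
    writeLines(c(mol$id, "  tensormol", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (i in seq_len(n)) {
      code <- revchg[as.character(mol$charges[i])]
      if (is.na(code)) code <- 0
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                         mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3],
                         mol$elements[i], code), con)
    }
    if (nb) for (k in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$a1[k], mol$bonds$a2[k],
                         mol$bonds$order[k]), con)
    writeLines("M  END", con)
    for (nm in names(mol$annotations)) {
      writeLines(sprintf(">  <ATOM_PROP_%s>", nm), con)
      writeLines(paste(mol$annotations[[nm]], collapse = " "), con)
      writeLines("", con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

# atoms participating in any ring, by DFS over the bond graph
.ring_atoms_and_bonds <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  ring <- rep(FALSE, n)
  # an edge is a ring edge iff removing it leaves its endpoints connected
  for (k in seq_len(nrow(b))) {
    u <- b$a1[k]; v <- b$a2[k]
    seen <- rep(FALSE, n); seen[u] <- TRUE; stack <- u; found <- FALSE
    while (length(stack) && !found) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (nb in adj[[cur]]) {
        if (cur == u && nb == v) next
        if (cur == v && nb == u) next
        if (nb == v) { found <- TRUE; break }
        if (!seen[nb]) { seen[nb] <- TRUE; stack <- c(stack, nb) }
      }
    }
    if (found) ring[c(u, v)] <- TRUE
  }
  ring
}

# aromatic carbons: input aromatic bond flags (order 4) trusted first;
# fallback marks ring carbons whose ring bonds alternate single/double
.aromatic_atoms <- function(mol) {
  n <- length(mol$elements)
  arom <- rep(FALSE, n)
  b <- mol$bonds
  if (!nrow(b)) return(arom)
  fl <- b$order == 4
  if (any(fl)) {
    arom[unique(c(b$a1[fl], b$a2[fl]))] <- TRUE
    return(arom)
  }
  ring <- .ring_atoms_and_bonds(mol)
  if (!any(ring)) return(arom)
  # alternation test: every ring atom carrying both a single and a double
  # ring bond is flagged aromatic-like
  for (i in which(ring)) {
    kb <- which((b$a1 == i & ring[b$a2]) | (b$a2 == i & ring[b$a1]))
    ords <- b$order[kb]
    if (any(ords == 1) && any(ords == 2)) arom[i] <- TRUE
  }
  arom
}

#' Detect atom-type fragments
#'
#' Returns one logical membership mask per fragment code:
#' * `G` halogens (F, Cl, Br, I);
#' * `X` heteroatoms (neither C nor H);
#' * `A` hydrogen-bond acceptors (N/O not positively charged);
#' * `D` hydrogen-bond donors (N/O bearing at least one hydrogen, explicit
#'   or implied by default valence);
#' * `M` terminal methyls (carbon bonded to exactly one heavy atom,
#'   carrying >= 3 hydrogens);
#' * `P` aromatic carbons (input aromatic bond flags, else a ring
#'   single/double alternation test);
#' * `C` aliphatic (non-aromatic, sp3-like) carbons.
#'
#' Connectivity-dependent masks (`A`, `D`, `M`, `P`, `C`) are flagged
#' unavailable (`NA` attribute) when the molecule carries no bonds.
#'
#' @param mol a `molecule3d`.
#' @return named list of `fragment_mask` logical vectors with attributes
#'   `fragment_id` and `available`.
#' @export
assign_fragments <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  el <- mol$elements
  n <- length(el)
  has_bonds <- nrow(mol$bonds) > 0L || n == 1L
  nH <- mol$n_hydrogens %||% integer(n)
  heavy_deg <- integer(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      heavy_deg[mol$bonds$a1[k]] <- heavy_deg[mol$bonds$a1[k]] + 1L
      heavy_deg[mol$bonds$a2[k]] <- heavy_deg[mol$bonds$a2[k]] + 1L
    }
  }
  arom <- .aromatic_atoms(mol)
  masks <- list(
    G = el %in% c("F", "Cl", "Br", "I"),
    X = !(el %in% c("C", "H")),
    A = el %in% c("N", "O") & mol$charges <= 0,
    D = el %in% c("N", "O") & nH >= 1L,
    M = el == "C" & heavy_deg <= 1L & nH >= 3L,
    P = el == "C" & arom,
    C = el == "C" & !arom
  )
  avail <- c(G = TRUE, X = TRUE, A = has_bonds, D = has_bonds,
             M = has_bonds, P = has_bonds, C = has_bonds)
  out <- lapply(names(masks), function(f)
    structure(masks[[f]], class = "fragment_mask", fragment_id = f,
              available = unname(avail[f])))
  names(out) <- names(masks)
  out
}

.prop_table_env <- new.env(parent = emptyenv())

#' Atomic property lookup table
#'
#' The versioned element-keyed table shipped with the package (file
#' `atomic_properties_v1.tsv`): atomic mass, van der Waals radius (Bondi,
#' Angstrom), static dipole polarizability (Angstrom^3), Pauling
#' electronegativity, atomic refractivity, absolute hardness (eV), and the
#' simplified per-element contributions used for log P and polar surface
#' area.
#'
#' @return data frame keyed by element symbol.
#' @export
atomic_property_table <- function() {
  if (is.null(.prop_table_env$tab)) {
    f <- system.file("extdata", "atomic_properties_v1.tsv",
                     package = "tensormol", mustWork = TRUE)
    .prop_table_env$tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  }
  .prop_table_env$tab
}

#' Per-atom property vector
#'
#' Property ids: `m` mass, `v` van der Waals volume (from the Bondi
#' radius, 4/3 pi r^3), `p` polarizability, `e` Pauling electronegativity,
#' `r` refractivity, `h` hardness, `s` softness (1/hardness), `a` log P
#' contribution, `psa` polar-surface-area contribution, `u` the unit
#' vector, `c` Gasteiger-Marsili partial charge, which is never defaulted:
#' it must be supplied as a per-atom annotation (SDF field `ATOM_PROP_c`)
#' or via `mol$annotations$c`.  Any other id is looked up in
#' `mol$annotations`.
#'
#' @param mol a `molecule3d`.
#' @param property property id string.
#' @return numeric vector aligned with atom order.
#' @export
property_vector <- function(mol, property) {
  stopifnot(inherits(mol, "molecule3d"))
  el <- mol$elements
  if (property == "u") return(rep(1, length(el)))
  builtin <- c("m", "v", "p", "e", "r", "h", "s", "a", "psa")
  if (!(property %in% builtin)) {
    v <- mol$annotations[[property]]
    if (is.null(v))
      stop("property '", property, "' requires per-atom annotations ",
           "(e.g. SDF data field ATOM_PROP_", property,
           "); none found in molecule ", mol$id)
    return(as.numeric(v))
  }
  tab <- atomic_property_table()
  idx <- match(el, tab$element)
  if (anyNA(idx))
    stop("element ", el[which(is.na(idx))[1]], " (atom ",
         which(is.na(idx))[1], ") has no tabulated value for property '",
         property, "'")
  switch(property,
         m   = tab$mass[idx],
         v   = 4 / 3 * pi * tab$vdw_radius[idx]^3,
         p   = tab$polarizability[idx],
         e   = tab$electronegativity[idx],
         r   = tab$refractivity[idx],
         h   = tab$hardness[idx],
         s   = 1 / tab$hardness[idx],
         a   = tab$logp_contrib[idx],
         psa = tab$psa_contrib[idx])
}
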