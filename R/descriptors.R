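#' Molecular descriptors
#'
#' The default descriptor block has 25 entries: 4 global descriptors —
#' `gmin` (minimum electrotopological state over the atoms), `idwbar`
#' (Bonchev–Trinajstic mean information content of the topological distance
#' distribution), `alogp` (atom-contribution octanol/water logP) and `nrings`
#' (cyclomatic number) — plus 21 atom-type counts of Kier–Hall E-state
#' fragments (an element together with its bonding environment, e.g. `sCH3`
#' counts -CH3 groups). The atom-type list is a runtime configuration; the
#' shipped default covers common C/N/O/halogen environments.
#'
#' @name descriptors
NULL

# coerce SMILES / molecule_set element to mol_graph
.as_graph <- function(x) {
  if (inherits(x, "mol_graph")) return(x)
  if (is.character(x) && length(x) == 1L) {
    p <- .parse_smiles_vec(x)
    if (!p$ok) stop("could not parse structure: ", x, call. = FALSE)
    return(p$graphs[[1]])
  }
  stop("expected a mol_graph or a single SMILES string", call. = FALSE)
}

#' Electrotopological-state indices
#'
#' For every heavy atom i the intrinsic state is
#' \eqn{I_i = ((2/N_i)^2 \delta^v_i + 1)/\delta_i} with \eqn{\delta_i} the
#' number of sigma bonds to heavy atoms, \eqn{\delta^v_i} the valence-electron
#' count minus attached hydrogens and \eqn{N_i} the principal quantum number.
#' The E-state is \eqn{S_i = I_i + \sum_j (I_i - I_j)/r_{ij}^2} with
#' \eqn{r_{ij}} = topological distance + 1, summed over heavy atoms of the
#' same fragment. An isolated heavy atom has \eqn{\delta = 0}; it is handled
#' by substituting \eqn{\delta = 1} and flagging the result.
#'
#' @param mol a `mol_graph` or a SMILES string.
#' @return data frame with columns `atom`, `element`, `I`, `S`; attribute
#'   `single_atom` is `TRUE` when the delta substitution was applied.
#' @examples
#' estate_indices("CCC")$S  # 2.125, 1.25, 2.125
#' @export
estate_indices <- function(mol) {
  g <- .as_graph(mol)
  unknown <- setdiff(unique(g$element), names(.zv))
  if (length(unknown))
    stop("cannot compute E-state for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  deg <- integer(g$n_atoms)
  if (nrow(g$bonds)) {
    tb <- table(factor(c(g$bonds$a1, g$bonds$a2), levels = seq_len(g$n_atoms)))
    deg <- as.integer(tb)
  }
  single <- any(deg == 0L)
  deg_eff <- pmax(deg, 1L)
  dv <- .zv[g$element] - g$nh
  N <- .pqn[g$element]
  I <- ((2 / N)^2 * dv + 1) / deg_eff
  S <- I
  if (g$n_atoms > 1L) {
    r2 <- (.dist_matrix(g) + 1)^2
    for (i in seq_len(g$n_atoms)) {
      j <- which(is.finite(r2[i, ]) & seq_len(g$n_atoms) != i)
      if (length(j)) S[i] <- I[i] + sum((I[i] - I[j]) / r2[i, j])
    }
  }
  structure(data.frame(atom = seq_len(g$n_atoms), element = g$element,
                       I = unname(I), S = unname(S)),
            single_atom = single)
}

#' Minimum E-state value
#' @inheritParams estate_indices
#' @return `min(S)` over the heavy atoms.
#' @export
gmin <- function(mol) min(estate_indices(mol)$S)

#' Bonchev–Trinajstic mean information content of the distance distribution
#'
#' With \eqn{g_k} the number of unordered heavy-atom pairs at topological
#' distance k and \eqn{W = \sum_k k g_k} (the Wiener number), the
#' magnitude-based mean information content is
#' \eqn{\bar{I} = (W \log_2 W - \sum_k g_k k \log_2 k)/W}.
#' Computed on the largest fragment; a single-atom graph yields 0. The
#' equality-based variant \eqn{-\sum_k (g_k/P) \log_2(g_k/P)} (P = number of
#' pairs) is available behind `variant = "equality"`.
#'
#' @inheritParams estate_indices
#' @param variant `"magnitude"` (default) or `"equality"`.
#' @return a non-negative real number.
#' @examples
#' idwbar("CCC")      # 1.5
#' @export
idwbar <- function(mol, variant = c("magnitude", "equality")) {
  variant <- match.arg(variant)
  g <- .as_graph(mol)
  if (g$n_atoms < 2L) return(0)
  main <- which(g$fragment == which.max(tabulate(g$fragment)))
  if (length(main) < 2L) return(0)
  D <- .dist_matrix(g)[main, main, drop = FALSE]
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) return(0)
  gk <- table(d)
  k <- as.numeric(names(gk))
  gk <- as.numeric(gk)
  if (variant == "magnitude") {
    W <- sum(k * gk)
    (W * log2(W) - sum(gk * k * log2(k))) / W
  } else {
    p <- gk / sum(gk)
    -sum(p * log2(p))
  }
}

#' Cyclomatic number (ring count)
#'
#' The smallest number of bonds whose removal leaves an acyclic graph:
#' bonds - atoms + connected components, on the hydrogen-depleted graph.
#'
#' @inheritParams estate_indices
#' @return non-negative integer.
#' @export
nrings <- function(mol) {
  g <- .as_graph(mol)
  as.integer(nrow(g$bonds) - g$n_atoms + max(g$fragment))
}

# ---- atom-type (E-state fragment) counts ------------------------------------

# bonding-environment signature of every atom in a graph:
# element | aromatic | nH | charge | #single | #double | #triple | #aromatic
.atom_signatures <- function(g) {
  n <- g$n_atoms
  s <- d <- t3 <- a <- integer(n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      b <- g$bonds[i, ]
      for (at in c(b$a1, b$a2)) {
        if (b$aromatic) a[at] <- a[at] + 1L
        else if (b$order == 1) s[at] <- s[at] + 1L
        else if (b$order == 2) d[at] <- d[at] + 1L
        else if (b$order == 3) t3[at] <- t3[at] + 1L
      }
    }
  }
  sprintf("%s|%d|%d|%d|%d|%d|%d|%d",
          g$element, as.integer(g$aromatic), g$nh, g$charge, s, d, t3, a)
}

.type_signature <- function(ty) {
  sprintf("%s|%d|%d|%d|%d|%d|%d|%d", ty$element,
          as.integer(isTRUE(ty$aromatic)), ty$nh,
          if (is.null(ty$charge)) 0L else as.integer(ty$charge),
          if (is.null(ty$single)) 0L else as.integer(ty$single),
          if (is.null(ty$double)) 0L else as.integer(ty$double),
          if (is.null(ty$triple)) 0L else as.integer(ty$triple),
          if (is.null(ty$aromatic_bonds)) 0L else as.integer(ty$aromatic_bonds))
}

#' Load an atom-type table
#'
#' The table is a YAML list of entries with fields `name`, `element`,
#' `aromatic`, `nh`, and bond-environment counts `single`, `double`, `triple`,
#' `aromatic_bonds` (and optionally `charge`). Types must be pairwise
#' disjoint: two entries with the same bonding signature are a configuration
#' error.
#'
#' @param path YAML file; default is the table shipped with the package.
#' @return data frame with columns `name` and `signature`.
#' @export
load_atom_types <- function(path = system.file("extdata", "estate_atom_types.yaml",
                                               package = "amescade")) {
  raw <- yaml::read_yaml(path)
  nm <- vapply(raw, function(ty) ty$name, "")
  if (anyDuplicated(nm))
    stop("duplicate atom-type name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sig <- vapply(raw, .type_signature, "")
  if (anyDuplicated(sig))
    stop("overlapping atom-type definitions: ",
         paste(nm[duplicated(sig) | duplicated(sig, fromLast = TRUE)],
               collapse = ", "), call. = FALSE)
  data.frame(name = nm, signature = sig, stringsAsFactors = FALSE)
}

#' Count atom-type occurrences
#'
#' @inheritParams estate_indices
#' @param type_table a table from [load_atom_types()].
#' @return named integer vector, one entry per configured type; each atom
#'   contributes to at most one type.
#' @examples
#' atom_type_counts("CCC")[["sCH3"]]  # 2
#' @export
atom_type_counts <- function(mol, type_table = load_atom_types()) {
  g <- .as_graph(mol)
  sig <- .atom_signatures(g)
  counts <- vapply(type_table$signature, function(s) sum(sig == s), 0L)
  names(counts) <- type_table$name
  counts
}

# ---- descriptor matrix ------------------------------------------------------

#' Default descriptor configuration
#'
#' @param atom_types_path optional path to a custom atom-type YAML.
#' @return a list with the ordered descriptor names and the atom-type table.
#' @export
default_descriptor_config <- function(atom_types_path = NULL) {
  tt <- if (is.null(atom_types_path)) load_atom_types()
        else load_atom_types(atom_types_path)
  list(names = c("gmin", "idwbar", "alogp", "nrings", tt$name),
       type_table = tt)
}

#' Compute the descriptor matrix for a molecule set
#'
#' One row per record in input order. A record whose structure failed to
#' parse, or for which any descriptor fails (e.g. an element outside the
#' atom-contribution tables), gets `computed_ok = FALSE` and `NA` values;
#' such rows propagate to "unpredicted" in the cascade.
#'
#' @param ms a `molecule_set`.
#' @param config a configuration from [default_descriptor_config()].
#' @return data frame: `mol_id`, one column per descriptor, `computed_ok`.
#' @export
compute_descriptors <- function(ms, config = default_descriptor_config()) {
  stopifnot(inherits(ms, "molecule_set"))
  n <- nrow(ms$records)
  mat <- matrix(NA_real_, n, length(config$names),
                dimnames = list(NULL, config$names))
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!ms$records$parse_ok[i]) next
    g <- ms$graphs[[i]]
    row <- tryCatch({
      c(gmin = gmin(g), idwbar = idwbar(g), alogp = alogp(g),
        nrings = as.numeric(nrings(g)),
        as.numeric(atom_type_counts(g, config$type_table)))
    }, error = function(e) NULL)
    if (!is.null(row) && !anyNA(row)) {
      mat[i, ] <- row
      ok[i] <- TRUE
    }
  }
  out <- data.frame(mol_id = ms$records$mol_id, mat,
                    computed_ok = ok, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract the numeric matrix from a descriptor table
#' @param desc a data frame from [compute_descriptors()].
#' @return numeric matrix with mol_id rownames.
#' @export
descriptor_matrix <- function(desc) {
  cols <- setdiff(names(desc), c("mol_id", "computed_ok"))
  m <- as.matrix(desc[, cols, drop = FALSE])
  rownames(m) <- desc$mol_id
  m
}

# ---- max-abs scaling --------------------------------------------------------

#' Fit max-abs scaling factors on a training matrix
#'
#' Each descriptor column is later divided by the maximum absolute value it
#' attains in the training set, mapping the training matrix into \[-1, 1\].
#' All-zero columns get factor 1 (identity).
#'
#' @param mat numeric training matrix (no failed rows).
#' @return named positive numeric vector of per-column factors.
#' @export
fit_scaling <- function(mat) {
  mat <- as.matrix(mat)
  f <- apply(abs(mat), 2, max, na.rm = TRUE)
  f[!is.finite(f) | f == 0] <- 1
  f
}

#' Apply stored scaling factors to a matrix
#'
#' Prediction-time matrices are always scaled with the factors fitted on the
#' training set, never re-fit.
#'
#' @param mat numeric matrix whose columns match `names(factors)`.
#' @param factors output of [fit_scaling()].
#' @return the scaled matrix.
#' @export
apply_scaling <- function(mat, factors) {
  mat <- as.matrix(mat)
  if (!all(colnames(mat) %in% names(factors)))
    stop("matrix has columns without scaling factors", call. = FALSE)
  sweep(mat, 2, factors[colnames(mat)], "/")
}
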