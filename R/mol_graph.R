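# Internal molecular-graph layer.
#
# Structures are parsed by OpenBabel (via ChemmineOB): one conversion to SDF
# (kekule bond orders + formal charges), one to MOL2 (SYBYL atom/bond types,
# which carry OpenBabel's aromaticity perception), one to canonical SMILES.
# Atom order is preserved across the three outputs, so the graphs can be
# zipped together positionally.

#' @importFrom ChemmineOB convertFormat
#' @importFrom utils read.table
NULL

# principal quantum number by element (heavy atoms we classify)
.pqn <- c(B = 2, C = 2, N = 2, O = 2, F = 2,
          Si = 3, P = 3, S = 3, Cl = 3,
          Br = 4, I = 5)

# valence electrons (Zv)
.zv <- c(B = 3, C = 4, N = 5, O = 6, F = 7,
         Si = 4, P = 5, S = 6, Cl = 7,
         Br = 7, I = 7)

# MDL ctab old-style charge codes -> formal charge
.chg_code <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
               `5` = -1L, `6` = -2L, `7` = -3L)

# implicit hydrogen count from element, formal charge and bond-order sum
.implicit_h <- function(element, charge, bosum) {
  std <- switch(element,
    C = 4L + (if (charge < 0) charge else -abs(charge)),
    N = 3L + charge,
    O = 2L + charge,
    B = 3L,
    P = if (bosum > 3) 5L else 3L,
    S = if (bosum > 4) 6L else if (bosum > 2) 4L else 2L + charge,
    F = , Cl = , Br = , I = 1L + (if (charge != 0) -1L else 0L),
    0L)
  max(0L, as.integer(std) - as.integer(bosum))
}

# run an OpenBabel conversion quietly (OB chats on stderr for bad input)
.ob_convert <- function(from, to, source, options = NULL) {
  out <- tryCatch(
    suppressWarnings(
      if (is.null(options)) ChemmineOB::convertFormat(from, to, source)
      else ChemmineOB::convertFormat(from, to, source, options = options)),
    error = function(e) "")
  if (length(out) == 0L) "" else out
}

# Split a multi-molecule SDF text into blocks keyed by the title line.
.split_sdf <- function(txt) {
  if (!nzchar(txt)) return(list())
  blocks <- strsplit(txt, "\\$\\$\\$\\$\r?\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- list()
  for (b in blocks) {
    b <- sub("^\r?\n+", "", b)
    title <- strsplit(b, "\r?\n")[[1]][1]
    out[[trimws(title)]] <- paste0(b, "\n$$$$\n")
  }
  out
}

# Split a multi-molecule MOL2 text into blocks keyed by molecule name.
.split_mol2 <- function(txt) {
  if (!nzchar(txt)) return(list())
  blocks <- strsplit(txt, "(?m)^@<TRIPOS>MOLECULE", perl = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- list()
  for (b in blocks) {
    lines <- strsplit(b, "\r?\n")[[1]]
    lines <- lines[cumsum(nzchar(lines)) > 0L | nzchar(lines)]
    name <- trimws(lines[which(nzchar(trimws(lines)))[1]])
    out[[name]] <- paste0("@<TRIPOS>MOLECULE", b)
  }
  out
}

# Parse one SDF V2000 block into atoms/bonds (counts line + fixed-width fields).
.parse_molblock <- function(block) {
  lines <- strsplit(block, "\r?\n")[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) return(NULL)
  atom_lines <- lines[5:(4 + na)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- .chg_code[as.character(as.integer(substr(atom_lines, 37, 39)))]
  charge[is.na(charge)] <- 0L
  if (nb > 0L) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    ord <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- ord <- integer(0)
  }
  # M  CHG overrides the old-style atom-line codes when present
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  list(element = element, charge = as.integer(charge),
       bonds = data.frame(a1 = a1, a2 = a2, order = ord))
}

# Extract aromatic atom/bond flags from one MOL2 block.
.parse_mol2_arom <- function(block) {
  lines <- strsplit(block, "\r?\n")[[1]]
  sec <- grep("^@<TRIPOS>", lines)
  get_section <- function(tag) {
    i <- which(lines == paste0("@<TRIPOS>", tag))
    if (!length(i)) return(character(0))
    after <- sec[sec > i[1]]
    end <- if (length(after)) min(after) - 1L else length(lines)
    lines[(i[1] + 1L):end]
  }
  at <- get_section("ATOM"); at <- at[nzchar(trimws(at))]
  bd <- get_section("BOND"); bd <- bd[nzchar(trimws(bd))]
  elety <- vapply(strsplit(trimws(at), "\\s+"), `[`, "", 6L)
  atom_ar <- grepl("\\.ar$", elety)
  bond_ar <- logical(0); b1 <- b2 <- integer(0)
  if (length(bd)) {
    bf <- strsplit(trimws(bd), "\\s+")
    b1 <- as.integer(vapply(bf, `[`, "", 2L))
    b2 <- as.integer(vapply(bf, `[`, "", 3L))
    bond_ar <- vapply(bf, `[`, "", 4L) == "ar"
  }
  # an atom on an aromatic bond is aromatic even if typed e.g. N.pl3
  atom_ar[unique(c(b1[bond_ar], b2[bond_ar]))] <- TRUE
  list(atom_ar = atom_ar, b1 = b1, b2 = b2, bond_ar = bond_ar)
}

# Assemble an internal mol_graph from aligned SDF + MOL2 blocks.
.build_graph <- function(sdf_block, mol2_block) {
  mb <- .parse_molblock(sdf_block)
  if (is.null(mb)) return(NULL)
  n <- length(mb$element)
  arom <- rep(FALSE, n)
  bond_ar <- rep(FALSE, nrow(mb$bonds))
  if (!is.null(mol2_block)) {
    m2 <- .parse_mol2_arom(mol2_block)
    if (length(m2$atom_ar) == n) {
      if (length(m2$b1)) {
        key <- function(a, b) paste(pmin(a, b), pmax(a, b))
        ar_keys <- key(m2$b1, m2$b2)[m2$bond_ar]
        bond_ar <- key(mb$bonds$a1, mb$bonds$a2) %in% ar_keys
        # SYBYL also types delocalised acyclic bonds (carboxyl, amidinium)
        # "ar"; true aromatic bonds must lie in a ring, i.e. not be bridges
        if (any(bond_ar)) {
          g0 <- igraph::make_empty_graph(n = n, directed = FALSE)
          g0 <- igraph::add_edges(g0, rbind(mb$bonds$a1, mb$bonds$a2))
          br <- rep(FALSE, nrow(mb$bonds))
          br[as.integer(igraph::bridges(g0))] <- TRUE
          bond_ar <- bond_ar & !br
        }
      }
      arom <- m2$atom_ar
      arom[unique(c(mb$bonds$a1[bond_ar], mb$bonds$a2[bond_ar]))] <- TRUE
      # .ar-typed atoms not on any surviving ring ar bond are spurious too
      on_ar <- seq_len(n) %in% c(mb$bonds$a1[bond_ar], mb$bonds$a2[bond_ar])
      arom[m2$atom_ar & !on_ar] <- FALSE
    }
  }
  bosum <- numeric(n)
  if (nrow(mb$bonds)) {
    for (i in seq_len(nrow(mb$bonds))) {
      o <- mb$bonds$order[i]
      bosum[mb$bonds$a1[i]] <- bosum[mb$bonds$a1[i]] + o
      bosum[mb$bonds$a2[i]] <- bosum[mb$bonds$a2[i]] + o
    }
  }
  nh <- mapply(.implicit_h, mb$element, mb$charge, bosum)
  bonds <- mb$bonds
  bonds$aromatic <- bond_ar
  frag <- .fragment_ids(n, bonds)
  structure(list(
    n_atoms = n,
    element = mb$element,
    aromatic = arom,
    charge = mb$charge,
    nh = as.integer(nh),
    bonds = bonds,
    fragment = frag
  ), class = "mol_graph")
}

.fragment_ids <- function(n, bonds) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  as.integer(igraph::components(g)$membership)
}

# adjacency list (heavy neighbours) for a mol_graph
.neighbors <- function(g) {
  nb <- vector("list", g$n_atoms)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  nb
}

# topological distance matrix over heavy atoms (Inf across fragments)
.dist_matrix <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_atoms, directed = FALSE)
  if (nrow(g$bonds)) ig <- igraph::add_edges(ig, rbind(g$bonds$a1, g$bonds$a2))
  igraph::distances(ig)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph: %d heavy atoms, %d bonds, %d fragment(s)>\n",
              x$n_atoms, nrow(x$bonds), max(x$fragment)))
  invisible(x)
}

# Parse a vector of SMILES strings. Returns aligned lists:
#   graphs (mol_graph or NULL), smiles_canonical (NA on failure), ok (logical)
# `largest_fragment` switches on OpenBabel's salt stripping (-r).
.parse_smiles_vec <- function(smiles, largest_fragment = FALSE) {
  n <- length(smiles)
  graphs <- vector("list", n)
  can <- rep(NA_character_, n)
  ok <- rep(FALSE, n)
  live <- which(!is.na(smiles) & nzchar(trimws(smiles)) &
                  !grepl("[ \t]", trimws(smiles)))
  if (!length(live)) return(list(graphs = graphs, smiles = can, ok = ok))
  opts <- if (largest_fragment) data.frame(names = "r", args = "") else NULL
  sdf_blocks <- list(); mol2_blocks <- list(); can_map <- character(0)
  # OpenBabel stops a batch at the first unparseable entry, so convert in
  # rounds: whatever title is missing first is marked bad and skipped.
  remaining <- live
  while (length(remaining)) {
    titles <- sprintf("amescadeM%06d", remaining)
    src <- paste(trimws(smiles[remaining]), titles, collapse = "\n")
    sdf_blocks <- c(sdf_blocks, .split_sdf(.ob_convert("SMI", "SDF", src, options = opts)))
    mol2_blocks <- c(mol2_blocks, .split_mol2(.ob_convert("SMI", "MOL2", src, options = opts)))
    can_txt <- .ob_convert("SMI", "CAN", src, options = opts)
    if (nzchar(can_txt)) {
      can_lines <- strsplit(can_txt, "\r?\n")[[1]]
      can_lines <- can_lines[nzchar(trimws(can_lines))]
      parts <- strsplit(trimws(can_lines), "[ \t]+")
      cm_names <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
      cm <- vapply(parts, `[`, "", 1L)
      names(cm) <- cm_names
      can_map <- c(can_map, cm)
    }
    done <- titles %in% names(sdf_blocks)
    miss <- which(!done)
    if (!length(miss)) break
    # first missing entry is the one OpenBabel choked on; drop it, retry rest
    remaining <- remaining[-seq_len(miss[1])]
  }
  for (i in live) {
    tt <- sprintf("amescadeM%06d", i)
    sb <- sdf_blocks[[tt]]
    if (is.null(sb)) next
    gr <- tryCatch(.build_graph(sb, mol2_blocks[[tt]]), error = function(e) NULL)
    if (is.null(gr) || gr$n_atoms < 1L) next
    graphs[[i]] <- gr
    can[i] <- if (!is.na(can_map[tt])) unname(can_map[tt]) else NA_character_
    ok[i] <- !is.na(can[i])
  }
  list(graphs = graphs, smiles = can, ok = ok)
}
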