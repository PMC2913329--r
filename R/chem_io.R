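#' Molecule sets: reading, standardizing and writing chemical structures
#'
#' A `molecule_set` holds a batch of molecule records: identifier, canonical
#' SMILES, optional experimental Ames label, optional train/test tag, and the
#' parsed molecular graph. Records that fail to parse are retained with
#' `parse_ok = FALSE` and are carried through the pipeline as "unpredicted" —
#' they are never silently dropped.
#'
#' @name molecule_set
NULL

.label_map <- c(
  "mutagen" = "mutagen", "mutagenic" = "mutagen", "1" = "mutagen",
  "positive" = "mutagen",
  "nonmutagen" = "nonmutagen", "non-mutagen" = "nonmutagen",
  "nonmutagenic" = "nonmutagen", "non-mutagenic" = "nonmutagen",
  "0" = "nonmutagen", "negative" = "nonmutagen")

.parse_labels <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep("unknown", length(x))
  known <- nzchar(x) & !is.na(x) & x != "na" & x != "unknown"
  mapped <- .label_map[x[known]]
  if (anyNA(mapped)) {
    bad <- which(known)[is.na(mapped)]
    stop("unrecognised ames_label value(s) at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out[known] <- mapped
  out
}

.new_molecule_set <- function(records, graphs) {
  stopifnot(nrow(records) == length(graphs))
  structure(list(records = records, graphs = graphs), class = "molecule_set")
}

#' Construct a molecule set from SMILES strings
#'
#' @param smiles character vector of SMILES strings.
#' @param mol_id optional identifiers (default `M1`, `M2`, ...).
#' @param ames_label optional label vector; accepted spellings (case
#'   insensitive) are `mutagen`/`mutagenic`/`1`/`positive` and
#'   `nonmutagen`/`non-mutagenic`/`0`/`negative`; empty or `NA` means unknown.
#'   Any other string is an error naming the offending row.
#' @param set_tag optional `train`/`test`/`none` assignment.
#' @param standardize if `TRUE` (default) apply [standardize_molecules()].
#' @return a `molecule_set`.
#' @examples
#' ms <- molecules_from_smiles(c("CCO", "c1ccccc1"))
#' ms$records$smiles
#' @export
molecules_from_smiles <- function(smiles, mol_id = NULL, ames_label = NULL,
                                  set_tag = NULL, standardize = TRUE) {
  n <- length(smiles)
  if (is.null(mol_id)) mol_id <- paste0("M", seq_len(n))
  if (anyDuplicated(mol_id)) stop("mol_id values must be unique", call. = FALSE)
  labels <- if (is.null(ames_label)) rep("unknown", n) else .parse_labels(ames_label)
  tags <- if (is.null(set_tag)) rep("none", n) else {
    t <- trimws(tolower(as.character(set_tag)))
    t[is.na(t) | !nzchar(t)] <- "none"
    if (!all(t %in% c("train", "test", "none")))
      stop("set_tag must be train/test/none", call. = FALSE)
    t
  }
  parsed <- .parse_smiles_vec(as.character(smiles))
  records <- data.frame(
    mol_id = as.character(mol_id),
    input_structure = as.character(smiles),
    smiles = parsed$smiles,
    ames_label = labels,
    set_tag = tags,
    parse_ok = parsed$ok,
    standardized = rep(FALSE, n),
    stringsAsFactors = FALSE)
  ms <- .new_molecule_set(records, parsed$graphs)
  if (standardize) standardize_molecules(ms) else ms
}

#' Read a molecule dataset from disk
#'
#' Supported formats: `csv` (header `mol_id,smiles,ames_label[,set_tag]`),
#' `smiles` (one `SMILES[ id]` per line, optionally `SMILES id label`), and
#' `sdf` (MDL V2000; an `ames_label` data field is honoured when present).
#'
#' @param path input file.
#' @param format one of `"csv"`, `"smiles"`, `"sdf"`; default guesses from the
#'   file extension.
#' @param standardize passed to [molecules_from_smiles()].
#' @return a `molecule_set`, one record per input entry in input order.
#' @export
read_molecules <- function(path, format = c("auto", "csv", "smiles", "sdf"),
                           standardize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", smi = "smiles", smiles = "smiles", txt = "smiles",
      sdf = "sdf", mol = "sdf",
      stop("cannot guess format from extension '", ext,
           "'; pass format= explicitly", call. = FALSE))
  }
  switch(format,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
      need <- c("mol_id", "smiles")
      if (!all(need %in% names(df)))
        stop("csv must have columns mol_id, smiles", call. = FALSE)
      molecules_from_smiles(df$smiles, mol_id = df$mol_id,
                            ames_label = df[["ames_label"]],
                            set_tag = df[["set_tag"]],
                            standardize = standardize)
    },
    smiles = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[ \t]+")
      smi <- vapply(parts, `[`, "", 1L)
      ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
      lab <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
      if (anyNA(ids)) ids <- paste0("M", seq_along(smi))
      molecules_from_smiles(smi, mol_id = ids, ames_label = lab,
                            standardize = standardize)
    },
    sdf = .read_sdf_molecules(path, standardize = standardize))
}

.read_sdf_molecules <- function(path, standardize = TRUE) {
  sdfset <- ChemmineR::read.SDFset(path)
  n <- length(sdfset)
  smi <- rep(NA_character_, n)
  ids <- character(n)
  labs <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sdf_i <- sdfset[[i]]
    hd <- ChemmineR::header(sdf_i)
    ids[i] <- if (nzchar(trimws(hd[1]))) trimws(hd[1]) else paste0("M", i)
    db <- ChemmineR::datablock(sdf_i)
    if ("ames_label" %in% names(db)) labs[i] <- db[["ames_label"]]
    block <- paste(c(ChemmineR::sdf2str(sdf_i), ""), collapse = "\n")
    s <- .ob_convert("SDF", "CAN", block)
    s <- strsplit(trimws(s), "[ \t]+")[[1]][1]
    if (length(s) == 1L && !is.na(s) && nzchar(s)) smi[i] <- s
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  molecules_from_smiles(smi, mol_id = ids, ames_label = labs,
                        standardize = standardize)
}

#' Standardize molecule records
#'
#' Keeps the largest covalent fragment of multi-fragment structures (salts,
#' mixtures), collapses explicit hydrogens into attached-H counts, re-perceives
#' aromaticity, and rewrites the canonical SMILES. Charges are kept as drawn
#' (no neutralization pass), so e.g. charge-separated nitro groups survive.
#' The operation is deterministic and idempotent.
#'
#' @param ms a `molecule_set`.
#' @return the standardized `molecule_set`.
#' @export
standardize_molecules <- function(ms) {
  stopifnot(inherits(ms, "molecule_set"))
  idx <- which(ms$records$parse_ok)
  if (length(idx)) {
    parsed <- .parse_smiles_vec(ms$records$smiles[idx], largest_fragment = TRUE)
    ms$records$smiles[idx] <- parsed$smiles
    ms$records$parse_ok[idx] <- parsed$ok
    for (k in seq_along(idx)) ms$graphs[[idx[k]]] <- parsed$graphs[[k]]
  }
  ms$records$standardized <- ms$records$parse_ok
  ms
}

#' @export
print.molecule_set <- function(x, ...) {
  r <- x$records
  cat(sprintf("<molecule_set: %d records (%d parsed ok)>\n",
              nrow(r), sum(r$parse_ok)))
  lab <- table(factor(r$ames_label, c("mutagen", "nonmutagen", "unknown")))
  cat(sprintf("  labels: %d mutagen / %d nonmutagen / %d unknown\n",
              lab[1], lab[2], lab[3]))
  invisible(x)
}

#' @export
length.molecule_set <- function(x) nrow(x$records)

#' Subset a molecule set
#' @param x a `molecule_set`.
#' @param i index vector (integer or logical).
#' @param ... ignored.
#' @export
`[.molecule_set` <- function(x, i, ...) {
  idx <- seq_len(nrow(x$records))[i]
  .new_molecule_set(x$records[idx, , drop = FALSE], x$graphs[idx])
}

#' Combine molecule sets
#' @param ... `molecule_set` objects.
#' @export
c.molecule_set <- function(...) {
  parts <- list(...)
  recs <- do.call(rbind, lapply(parts, function(p) p$records))
  rownames(recs) <- NULL
  .new_molecule_set(recs, do.call(c, lapply(parts, function(p) p$graphs)))
}

#' Write a molecule set to a CSV dataset
#'
#' Emits the same `mol_id,smiles,ames_label,set_tag` dialect that
#' [read_molecules()] consumes, so datasets round-trip.
#'
#' @param ms a `molecule_set`.
#' @param path output CSV path.
#' @export
write_molecules <- function(ms, path) {
  stopifnot(inherits(ms, "molecule_set"))
  r <- ms$records
  out <- data.frame(mol_id = r$mol_id,
                    smiles = ifelse(r$parse_ok, r$smiles, r$input_structure),
                    ames_label = r$ames_label,
                    set_tag = r$set_tag,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cascade predictions to CSV
#'
#' Layout: `mol_id,smiles,predicted_class,decision_stage,fired_alerts` with
#' alert ids semicolon-joined, plus a `binary_<policy>` column when the
#' prediction table carries one.
#'
#' @param pred a prediction data frame from [predict.ames_cascade()].
#' @param path output CSV path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(pred, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
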