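#' Structural-alert rulebase and substructure screening
#'
#' A structural alert (toxicophore) is a substructure whose presence signals
#' potential mutagenic reactivity — aromatic nitro, epoxide, nitrosamine and
#' so on. Each alert carries one or more SMARTS patterns (the alert fires if
#' ANY pattern matches) and optional exception SMARTS (a match vetoes the
#' alert). The shipped rulebase encodes 30 mutagenicity rules in the
#' Benigni/Bossa (Toxtree) lineage; fidelity to the original SMARTS is
#' best-effort and the file is editable. Alerts are partitioned into
#' `enhancing` / `suspicious` / `unused` — either by an explicit `partition`
#' block in the file or by [partition_rules()] at training time.
#'
#' Matching is delegated to OpenBabel's SMARTS engine and is invariant to
#' atom numbering and SMILES writing order.
#'
#' @name alerts
NULL

#' Load a structural-alert rulebase
#'
#' @param path YAML file with a list `alerts:` of entries
#'   (`alert_id`, `name`, `patterns`, optional `exceptions`,
#'   `literature_fp_rate_zero`, `provenance`) and an optional `partition:`
#'   block with `enhancing:` and `suspicious:` id lists. Default is the
#'   rulebase shipped with the package.
#' @return an `alert_rulebase` object. Every SMARTS is compile-checked at
#'   load; a malformed pattern is an error naming the alert, as is a
#'   duplicated id.
#' @export
load_rulebase <- function(path = system.file("extdata",
                                             "benigni_bossa_mutagenicity.yaml",
                                             package = "amescade")) {
  raw <- yaml::read_yaml(path)
  alerts <- raw$alerts
  if (is.null(alerts) || !length(alerts))
    stop("rulebase file has no alerts", call. = FALSE)
  ids <- vapply(alerts, function(a) a$alert_id, "")
  if (anyDuplicated(ids))
    stop("duplicate alert_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  probe <- .smarts_probe_sdf()
  for (a in alerts) {
    pats <- unlist(a$patterns)
    if (!length(pats))
      stop("alert ", a$alert_id, " has no patterns", call. = FALSE)
    for (p in c(pats, unlist(a$exceptions))) {
      okc <- tryCatch({
        ChemmineOB::smartsSearch_OB(probe, p, uniqueMatches = TRUE); TRUE
      }, error = function(e) FALSE)
      if (!okc)
        stop("alert ", a$alert_id, ": SMARTS does not compile: ", p,
             call. = FALSE)
    }
  }
  partition <- stats::setNames(rep("unused", length(ids)), ids)
  if (!is.null(raw$partition)) {
    enh <- unlist(raw$partition$enhancing)
    sus <- unlist(raw$partition$suspicious)
    bad <- setdiff(c(enh, sus), ids)
    if (length(bad))
      stop("partition names unknown alert(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (length(intersect(enh, sus)))
      stop("alert(s) in both enhancing and suspicious sets", call. = FALSE)
    partition[enh] <- "enhancing"
    partition[sus] <- "suspicious"
  }
  structure(list(alerts = alerts, partition = partition),
            class = "alert_rulebase")
}

# tiny single-molecule SDFset used only to exercise the SMARTS compiler
.smarts_probe_sdf <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tf <- tempfile(fileext = ".sdf")
      writeLines(.ob_convert("SMI", "SDF", "CC amescade_probe"), tf)
      cache <<- ChemmineR::obmol(suppressWarnings(ChemmineR::read.SDFset(tf)))
    }
    cache
  }
})

#' @export
print.alert_rulebase <- function(x, ...) {
  p <- table(factor(x$partition, c("enhancing", "suspicious", "unused")))
  cat(sprintf("<alert_rulebase: %d alerts (%d enhancing, %d suspicious, %d unused)>\n",
              length(x$alerts), p[1], p[2], p[3]))
  invisible(x)
}

#' Assign the enhancing/suspicious partition of a rulebase
#'
#' @param rulebase an `alert_rulebase`.
#' @param enhancing,suspicious disjoint character vectors of alert ids; all
#'   remaining alerts become `unused`.
#' @return the rulebase with its partition replaced.
#' @export
set_partition <- function(rulebase, enhancing = character(0),
                          suspicious = character(0)) {
  stopifnot(inherits(rulebase, "alert_rulebase"))
  ids <- names(rulebase$partition)
  bad <- setdiff(c(enhancing, suspicious), ids)
  if (length(bad))
    stop("unknown alert id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(intersect(enhancing, suspicious)))
    stop("enhancing and suspicious sets must be disjoint", call. = FALSE)
  part <- stats::setNames(rep("unused", length(ids)), ids)
  part[enhancing] <- "enhancing"
  part[suspicious] <- "suspicious"
  rulebase$partition <- part
  rulebase
}

# SDFset for the parseable records of a molecule set (plus the index map)
.molset_sdf <- function(ms) {
  idx <- which(ms$records$parse_ok)
  if (!length(idx)) return(list(sdf = NULL, idx = idx))
  src <- paste(ms$records$smiles[idx], sprintf("amescadeS%06d", idx),
               collapse = "\n")
  txt <- .ob_convert("SMI", "SDF", src)
  tf <- tempfile(fileext = ".sdf")
  writeLines(txt, tf)
  on.exit(unlink(tf))
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ok <- suppressWarnings(ChemmineR::validSDF(sdf))
  sdf <- sdf[ok]                       # e.g. single-atom records cannot host a match
  got <- as.integer(sub("amescadeS", "", ChemmineR::sdfid(sdf)))
  # one OBMol conversion, reused across every SMARTS pattern
  refs <- if (length(got)) ChemmineR::obmol(sdf) else NULL
  list(sdf = sdf, idx = got, refs = refs)
}

# count matrix: molecules x patterns (0 when no match); `mols` holds OBMol refs
.smarts_counts <- function(mols, patterns) {
  out <- matrix(0L, length(mols), length(patterns))
  for (j in seq_along(patterns)) {
    hits <- tryCatch(
      ChemmineOB::smartsSearch_OB(mols, patterns[j], uniqueMatches = TRUE),
      error = function(e) stop("SMARTS failed at screen time: ", patterns[j],
                               call. = FALSE))
    out[, j] <- as.integer(hits > 0)
  }
  out
}

#' Screen a molecule set against a rulebase
#'
#' @param rulebase an `alert_rulebase`.
#' @param ms a `molecule_set` (standardized).
#' @param subset which alerts to consider: `"all"`, `"enhancing"` or
#'   `"suspicious"` (per the rulebase partition).
#' @return a list, one element per record in input order, each a character
#'   vector of fired alert ids in rulebase order (empty when nothing fires or
#'   the record failed to parse).
#' @export
screen_alerts <- function(rulebase, ms,
                          subset = c("all", "enhancing", "suspicious")) {
  stopifnot(inherits(rulebase, "alert_rulebase"),
            inherits(ms, "molecule_set"))
  subset <- match.arg(subset)
  keep <- if (subset == "all") names(rulebase$partition)
          else names(rulebase$partition)[rulebase$partition == subset]
  fired <- .alert_fire_matrix(rulebase, ms, only = keep)
  lapply(seq_len(nrow(ms$records)), function(i) {
    colnames(fired)[fired[i, ]]
  })
}

# logical matrix records x alert_ids of raw alert firing (partition ignored);
# `only` restricts the screen to a subset of alert ids
.alert_fire_matrix <- function(rulebase, ms, only = NULL) {
  alerts <- rulebase$alerts
  if (!is.null(only))
    alerts <- Filter(function(a) a$alert_id %in% only, alerts)
  ids <- vapply(alerts, function(a) a$alert_id, "")
  out <- matrix(FALSE, nrow(ms$records), length(ids),
                dimnames = list(NULL, ids))
  if (!length(alerts)) return(out)
  sm <- .molset_sdf(ms)
  if (is.null(sm$refs) || !length(sm$idx)) return(out)
  for (a in alerts) {
    pats <- unlist(a$patterns)
    hit <- rowSums(.smarts_counts(sm$refs, pats)) > 0
    exc <- unlist(a$exceptions)
    if (length(exc)) {
      veto <- rowSums(.smarts_counts(sm$refs, exc)) > 0
      hit <- hit & !veto
    }
    out[sm$idx, a$alert_id] <- hit
  }
  out
}

#' Does a single alert fire on a structure?
#'
#' @param alert one element of `rulebase$alerts` (or a list with `patterns` /
#'   `exceptions` fields).
#' @param mol a SMILES string or `mol_graph`... any single structure accepted
#'   by [molecules_from_smiles()].
#' @return `TRUE` iff some pattern matches and no exception matches.
#' @export
alert_matches <- function(alert, mol) {
  smi <- if (is.character(mol)) mol else stop("pass a SMILES string")
  ms <- molecules_from_smiles(smi, standardize = TRUE)
  if (!ms$records$parse_ok[1]) stop("structure did not parse: ", smi)
  rb <- structure(list(alerts = list(c(alert,
                                       list(alert_id = alert$alert_id %||% "q"))),
                       partition = stats::setNames("unused",
                                                   alert$alert_id %||% "q")),
                  class = "alert_rulebase")
  fired <- .alert_fire_matrix(rb, ms)
  unname(fired[1, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
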