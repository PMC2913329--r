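#' Evaluation: stratified splitting, three-output confusion matrices, and
#' policy statistics
#'
#' The cascade emits three labels (mutagenic / suspicious / non-mutagenic),
#' so test-set performance is tallied in a 2x3 confusion matrix with an extra
#' "unpredicted" column for compounds whose descriptors could not be
#' computed. Binary statistics are derived under either of the two end-user
#' policies for the suspicious class: `max_accuracy` folds suspicious into
#' the non-mutagen prediction, `min_fn` folds it into the mutagen
#' prediction. Unpredicted compounds are excluded from all denominators.
#'
#' @name evaluation
NULL

#' Binarization policy for the suspicious class
#'
#' @param name `"max_accuracy"` (suspicious counts as non-mutagen) or
#'   `"min_fn"` (suspicious counts as mutagen).
#' @return a `cascade_policy` list with `name` and `suspicious_maps_to`.
#' @export
policy <- function(name = c("max_accuracy", "min_fn")) {
  name <- match.arg(name)
  structure(list(name = name,
                 suspicious_maps_to = if (name == "min_fn") "mutagen"
                                      else "nonmutagen"),
            class = "cascade_policy")
}

# internal alias so methods with a `policy` argument can still build one
.policy <- policy

#' Binarize three-way cascade labels
#'
#' @param labels character vector of `mutagenic` / `suspicious` /
#'   `nonmutagenic` / `unpredicted`.
#' @param pol a [policy()] or policy name.
#' @return character vector of `mutagen` / `nonmutagen` / `unpredicted`.
#' @export
binarize_labels <- function(labels, pol = policy("max_accuracy")) {
  if (is.character(pol)) pol <- policy(pol)
  out <- c(mutagenic = "mutagen", nonmutagenic = "nonmutagen",
           suspicious = pol$suspicious_maps_to,
           unpredicted = "unpredicted")[labels]
  if (anyNA(out)) stop("unknown cascade label(s)", call. = FALSE)
  unname(out)
}

#' Stratified train/test split
#'
#' Strata are the combination of the true label and a fired-alert profile
#' key (the sorted ids of the alerts each compound fires, when a rulebase is
#' supplied) — a reproducible proxy for splitting by major functional group.
#' Within each stratum the test share is within one compound of
#' `test_fraction`.
#'
#' @param ms labelled `molecule_set`.
#' @param test_fraction fraction held out for testing (default 0.2).
#' @param seed integer seed.
#' @param rulebase optional `alert_rulebase` used to build the alert-profile
#'   part of the stratum key.
#' @return list with `train` and `test` molecule sets (with `set_tag` filled
#'   in), disjoint and exhaustive.
#' @export
stratified_split <- function(ms, test_fraction = 0.2, seed = 1,
                             rulebase = NULL) {
  stopifnot(inherits(ms, "molecule_set"),
            test_fraction > 0, test_fraction < 1)
  key <- ms$records$ames_label
  if (!is.null(rulebase)) {
    prof <- vapply(screen_alerts(rulebase, ms, "all"),
                   function(f) paste(sort(f), collapse = "+"), "")
    key <- paste(key, prof, sep = "|")
  }
  n <- nrow(ms$records)
  test <- logical(n)
  .with_seed(seed, {
    for (s in unique(key)) {
      idx <- which(key == s)
      k <- round(test_fraction * length(idx))
      if (k > 0) test[sample(idx, k)] <- TRUE
    }
  })
  ms$records$set_tag <- ifelse(test, "test", "train")
  list(train = ms[!test], test = ms[test])
}

#' Three-output confusion matrix
#'
#' @param truths character vector of true labels (`mutagen` / `nonmutagen`).
#' @param predictions aligned cascade labels (`mutagenic` / `nonmutagenic` /
#'   `suspicious` / `unpredicted`).
#' @return a `confusion3` object: 2x3 `counts` matrix plus per-class
#'   `unpredicted` tallies.
#' @export
confusion3 <- function(truths, predictions) {
  if (length(truths) != length(predictions))
    stop("truths and predictions misaligned", call. = FALSE)
  if (!all(truths %in% c("mutagen", "nonmutagen")))
    stop("true labels must be mutagen/nonmutagen", call. = FALSE)
  if (!all(predictions %in% c("mutagenic", "nonmutagenic", "suspicious",
                              "unpredicted")))
    stop("unknown prediction label(s)", call. = FALSE)
  counts <- matrix(0L, 2, 3, dimnames = list(
    c("mutagen", "nonmutagen"),
    c("mutagenic", "nonmutagenic", "suspicious")))
  unpred <- c(mutagen = 0L, nonmutagen = 0L)
  for (i in seq_along(truths)) {
    if (predictions[i] == "unpredicted")
      unpred[truths[i]] <- unpred[truths[i]] + 1L
    else counts[truths[i], predictions[i]] <- counts[truths[i], predictions[i]] + 1L
  }
  structure(list(counts = counts, unpredicted = unpred), class = "confusion3")
}

#' Build a confusion3 object from printed counts
#'
#' Convenience for re-deriving statistics from a published 2x3 table.
#'
#' @param mutagen,nonmutagen length-3 integer vectors of
#'   (mutagenic, non-mutagenic, suspicious) predictions for each true class.
#' @param unpredicted optional length-2 vector (mutagen, nonmutagen).
#' @export
confusion3_from_counts <- function(mutagen, nonmutagen,
                                   unpredicted = c(0L, 0L)) {
  counts <- rbind(mutagen = as.integer(mutagen),
                  nonmutagen = as.integer(nonmutagen))
  colnames(counts) <- c("mutagenic", "nonmutagenic", "suspicious")
  structure(list(counts = counts,
                 unpredicted = stats::setNames(as.integer(unpredicted),
                                               c("mutagen", "nonmutagen"))),
            class = "confusion3")
}

#' @export
print.confusion3 <- function(x, ...) {
  m <- cbind(x$counts, unpredicted = x$unpredicted)
  print(m)
  invisible(x)
}

#' Binary statistics of a three-output matrix under a policy
#'
#' The suspicious column is folded into the policy's binary class, then
#' accuracy \eqn{(tp+tn)/n}, sensitivity \eqn{tp/(tp+fn)}, specificity
#' \eqn{tn/(tn+fp)} and the false-negative rate \eqn{fn/(tp+fn)} are
#' computed. Unpredicted compounds stay out of every denominator; an empty
#' class yields `NaN`, never a silent zero.
#'
#' @param cm a `confusion3`.
#' @param pol a [policy()] or policy name.
#' @return a `binary_stats` object: `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity`, `fn_rate`.
#' @export
stats_under_policy <- function(cm, pol = policy("max_accuracy")) {
  stopifnot(inherits(cm, "confusion3"))
  if (is.character(pol)) pol <- policy(pol)
  k <- cm$counts
  sus_pos <- pol$suspicious_maps_to == "mutagen"
  tp <- k["mutagen", "mutagenic"] + if (sus_pos) k["mutagen", "suspicious"] else 0L
  fn <- k["mutagen", "nonmutagenic"] + if (sus_pos) 0L else k["mutagen", "suspicious"]
  fp <- k["nonmutagen", "mutagenic"] + if (sus_pos) k["nonmutagen", "suspicious"] else 0L
  tn <- k["nonmutagen", "nonmutagenic"] + if (sus_pos) 0L else k["nonmutagen", "suspicious"]
  div <- function(a, b) if (b == 0) NaN else a / b
  structure(list(policy = pol$name,
                 tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp),
                 accuracy = div(tp + tn, tp + fn + tn + fp),
                 sensitivity = div(tp, tp + fn),
                 specificity = div(tn, tn + fp),
                 fn_rate = div(fn, tp + fn)),
            class = "binary_stats")
}

#' @export
print.binary_stats <- function(x, ...) {
  cat(sprintf("policy %-12s tp %d fn %d tn %d fp %d | acc %.1f%% sens %.1f%% spec %.1f%% fn-rate %.1f%%\n",
              x$policy, x$tp, x$fn, x$tn, x$fp, 100 * x$accuracy,
              100 * x$sensitivity, 100 * x$specificity, 100 * x$fn_rate))
  invisible(x)
}

#' Relative false-negative reduction
#'
#' @param reference_stats,cascade_stats `binary_stats` on the same
#'   evaluation set (e.g. bare SVM vs cascade).
#' @return `(reference fn - cascade fn) / reference fn`; `NaN` when the
#'   reference has no false negatives.
#' @export
fn_reduction <- function(reference_stats, cascade_stats) {
  stopifnot(inherits(reference_stats, "binary_stats"),
            inherits(cascade_stats, "binary_stats"))
  if (reference_stats$fn == 0) return(NaN)
  (reference_stats$fn - cascade_stats$fn) / reference_stats$fn
}
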