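#' Alert selection by auditing cross-validated predicted negatives
#'
#' Only compounds the SVM stage predicts *negative* ever reach the alert
#' checkpoints, so each rule is audited on exactly that subset of the
#' training data, using cross-validated (out-of-fold) SVM predictions: for a
#' rule, `caught_fn` counts true mutagens among the predicted negatives that
#' it matches (false negatives it would rescue) and `generated_fp` counts
#' true non-mutagens it matches there (false positives it would create).
#' Rules catching more than they cost become `enhancing`; rules with real
#' catching power but a higher misclassification rate become `suspicious`;
#' the rest stay `unused`. Rules with little data support are not trusted on
#' the audit alone: they are admitted (to the enhancing set) only when their
#' source literature reports a nominal false-positive rate of 0%.
#'
#' @name rule_selection
NULL

#' Audit every alert against cross-validated predicted negatives
#'
#' @param rulebase an `alert_rulebase`.
#' @param ms the training `molecule_set`, carrying true labels.
#' @param cv_predictions character vector aligned with `ms` records:
#'   `mutagen` / `nonmutagen` / `unpredicted` out-of-fold SVM labels.
#' @return data frame with one row per alert: `alert_id`, `caught_fn`,
#'   `generated_fp`, `support`, `literature_fp_rate_zero`.
#' @export
audit_rules <- function(rulebase, ms, cv_predictions) {
  stopifnot(inherits(rulebase, "alert_rulebase"),
            inherits(ms, "molecule_set"))
  if (length(cv_predictions) != nrow(ms$records))
    stop("cv_predictions not aligned with molecule records", call. = FALSE)
  truth <- ms$records$ames_label
  neg <- cv_predictions == "nonmutagen" & truth %in% c("mutagen", "nonmutagen")
  fired <- .alert_fire_matrix(rulebase, ms)
  caught <- colSums(fired[neg & truth == "mutagen", , drop = FALSE])
  gen <- colSums(fired[neg & truth == "nonmutagen", , drop = FALSE])
  fp0 <- vapply(rulebase$alerts,
                function(a) isTRUE(a$literature_fp_rate_zero), TRUE)
  data.frame(alert_id = names(rulebase$partition),
             caught_fn = as.integer(caught),
             generated_fp = as.integer(gen),
             support = as.integer(caught + gen),
             literature_fp_rate_zero = fp0,
             stringsAsFactors = FALSE)
}

#' Partition audited rules into enhancing / suspicious / unused
#'
#' Decision per rule: with adequate support (`support >= min_support`),
#' `enhancing` iff `caught_fn > generated_fp`, otherwise `suspicious` iff
#' `caught_fn >= 1` and `caught_fn >= suspicious_floor * generated_fp`, else
#' `unused`. A low-support rule is admitted to `enhancing` only when it both
#' catches more than it costs and carries the literature zero-FP flag;
#' otherwise it is `unused`. The partition is a pure function of the audit
#' table and the policy knobs.
#'
#' @param audits output of [audit_rules()].
#' @param min_support minimum `caught_fn + generated_fp` for the audit to be
#'   considered reliable (default 5).
#' @param suspicious_floor minimum catch/cost ratio for the suspicious set
#'   (default 0.25).
#' @return named character vector `alert_id -> decision`, with attribute
#'   `audit` holding the audit table completed with `decision` and
#'   `low_support_flag` columns.
#' @export
partition_rules <- function(audits, min_support = 5, suspicious_floor = 0.25) {
  stopifnot(is.data.frame(audits),
            all(c("alert_id", "caught_fn", "generated_fp") %in% names(audits)))
  low <- audits$support < min_support
  dec <- character(nrow(audits))
  for (i in seq_len(nrow(audits))) {
    caught <- audits$caught_fn[i]; gen <- audits$generated_fp[i]
    if (low[i]) {
      dec[i] <- if (audits$literature_fp_rate_zero[i] && caught > gen)
        "enhancing" else "unused"
    } else if (caught > gen) {
      dec[i] <- "enhancing"
    } else if (caught >= 1 && caught >= suspicious_floor * gen) {
      dec[i] <- "suspicious"
    } else {
      dec[i] <- "unused"
    }
  }
  audits$decision <- dec
  audits$low_support_flag <- low
  structure(stats::setNames(dec, audits$alert_id), audit = audits)
}
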