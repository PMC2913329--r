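#' Fit the integrated mutagenicity cascade
#'
#' The cascade couples a statistical C-SVC/RBF classifier with two serial
#' structural-alert checkpoints. At prediction time a compound is routed as
#' follows: descriptors fail → `unpredicted`; SVM says mutagen → `mutagenic`
#' (alerts never consulted); any *enhancing* alert fires → `mutagenic`
#' (checkpoint 1); else any *suspicious* alert fires → `suspicious`
#' (checkpoint 2); else → `nonmutagenic`. The checkpoints can therefore only
#' remove false negatives relative to the bare SVM, never create them; the
#' price is paid in false positives, which is the intended trade for a
#' screening tool.
#'
#' Fitting (1) computes the 25-descriptor matrix, (2) fits max-abs scaling
#' on the training rows, (3) trains the SVM at `(C, gamma)` — default
#' `(8, 16)`, the published grid-search calibration — or re-tunes when
#' `tune = TRUE`, (4) obtains stratified k-fold cross-validated predictions,
#' and (5) audits every rulebase alert against the cross-validated predicted
#' negatives to select the enhancing and suspicious sets
#' (see [partition_rules()]). Supplying a rulebase whose file already
#' carries a `partition:` block and setting `select_rules = FALSE` uses that
#' partition verbatim.
#'
#' @param molecules a labelled, standardized `molecule_set` (both classes
#'   required), or a precomputed descriptor data frame in the
#'   [compute_descriptors()] layout (then `labels` must be given and the
#'   alert layer is skipped: the result is the bare statistical model).
#' @param labels optional labels when `molecules` is a descriptor table.
#' @param C,gamma C-SVC cost and RBF width; defaults (8, 16).
#' @param tune if `TRUE` run [svm_grid_search()] first.
#' @param C_grid,gamma_grid grids for tuning.
#' @param folds cross-validation fold count (default 10, used both for
#'   tuning and for the rule-selection predictions).
#' @param seed integer seed controlling fold draws.
#' @param rulebase an `alert_rulebase` (default: shipped 30-rule file).
#' @param select_rules audit + partition the rulebase (default `TRUE`).
#' @param min_support,suspicious_floor rule-selection knobs, see
#'   [partition_rules()].
#' @param descriptor_config see [default_descriptor_config()].
#' @return an object of class `ames_cascade`.
#' @examples
#' \donttest{
#' ms <- generate_molecules(fixture_spec(n = 120, seed = 3))
#' fit <- ames_cascade(ms, seed = 3)
#' head(predict(fit, ms))
#' }
#' @export
ames_cascade <- function(molecules, labels = NULL, C = 8, gamma = 16,
                         tune = FALSE, C_grid = 2^seq(-5, 15, 2),
                         gamma_grid = 2^seq(-15, 3, 2), folds = 10, seed = 1,
                         rulebase = load_rulebase(), select_rules = TRUE,
                         min_support = 5, suspicious_floor = 0.25,
                         descriptor_config = default_descriptor_config()) {
  cl <- match.call()
  from_molecules <- inherits(molecules, "molecule_set")
  if (from_molecules) {
    desc <- compute_descriptors(molecules, descriptor_config)
    truth <- molecules$records$ames_label
  } else {
    desc <- molecules
    if (!is.data.frame(desc) || !"mol_id" %in% names(desc))
      stop("molecules must be a molecule_set or a descriptor data frame",
           call. = FALSE)
    if (is.null(desc$computed_ok)) desc$computed_ok <- TRUE
    if (is.null(labels))
      stop("labels are required with a precomputed descriptor table",
           call. = FALSE)
    truth <- .parse_labels(labels)
    rulebase <- NULL
    select_rules <- FALSE
  }
  usable <- desc$computed_ok & truth %in% c("mutagen", "nonmutagen")
  if (sum(usable) < 10)
    stop("need at least 10 labelled, descriptor-complete compounds",
         call. = FALSE)
  raw <- descriptor_matrix(desc[usable, , drop = FALSE])
  scaling <- fit_scaling(raw)
  X <- apply_scaling(raw, scaling)
  y <- truth[usable]

  tuning <- NULL
  if (tune) {
    tuning <- svm_grid_search(X, y, C_grid = C_grid, gamma_grid = gamma_grid,
                              k = folds, seed = seed)
    C <- tuning$C; gamma <- tuning$gamma
  }
  svm <- svm_train(X, y, C = C, gamma = gamma)
  cv <- svm_cv_predictions(X, y, C = C, gamma = gamma, k = folds, seed = seed)
  cv_full <- rep("unpredicted", length(truth))
  cv_full[usable] <- cv

  audits <- NULL
  if (!is.null(rulebase) && select_rules) {
    audits_raw <- audit_rules(rulebase, molecules, cv_full)
    part <- partition_rules(audits_raw, min_support = min_support,
                            suspicious_floor = suspicious_floor)
    audits <- attr(part, "audit")
    rulebase <- set_partition(rulebase,
                              enhancing = names(part)[part == "enhancing"],
                              suspicious = names(part)[part == "suspicious"])
  }

  structure(list(
    call = cl,
    svm = svm, C = C, gamma = gamma,
    scaling = scaling,
    descriptor_order = colnames(X),
    descriptor_config = descriptor_config,
    rulebase = rulebase,
    audits = audits,
    tuning = tuning,
    folds = folds, seed = seed,
    min_support = min_support, suspicious_floor = suspicious_floor,
    cv_accuracy = mean(cv == y),
    n_train = sum(usable),
    class_counts = table(factor(y, c("mutagen", "nonmutagen"))),
    version = as.character(utils::packageVersion("amescade"))
  ), class = "ames_cascade")
}

#' Predict with a fitted cascade
#'
#' @param object an `ames_cascade`.
#' @param newdata a `molecule_set`, a character vector of SMILES, or (for a
#'   descriptor-trained model) a descriptor data frame.
#' @param policy optional [policy()] or name; adds a binary column.
#' @param use_alerts set `FALSE` to bypass the checkpoints and report the
#'   bare SVM stage.
#' @param ... unused.
#' @return data frame: `mol_id`, `smiles`, `label` (mutagenic / suspicious /
#'   nonmutagenic / unpredicted), `stage` (svm / checkpoint1 / checkpoint2 /
#'   passthrough / failed), `fired_alerts` (semicolon-joined ids), and
#'   `binary` when a policy is given.
#' @export
predict.ames_cascade <- function(object, newdata, policy = NULL,
                                 use_alerts = TRUE, ...) {
  if (is.character(newdata)) newdata <- molecules_from_smiles(newdata)
  if (inherits(newdata, "molecule_set")) {
    desc <- compute_descriptors(newdata, object$descriptor_config)
    ids <- newdata$records$mol_id
    smiles <- newdata$records$smiles
  } else {
    desc <- newdata
    if (is.null(desc$computed_ok)) desc$computed_ok <- TRUE
    ids <- desc$mol_id
    smiles <- rep(NA_character_, nrow(desc))
    newdata <- NULL
  }
  raw <- descriptor_matrix(desc)
  raw <- raw[, object$descriptor_order, drop = FALSE]
  X <- apply_scaling(raw, object$scaling)
  X[!desc$computed_ok, ] <- NA_real_
  svm_lab <- svm_classify(object$svm, X)

  n <- length(svm_lab)
  label <- character(n); stage <- character(n)
  fired <- rep("", n)
  label[svm_lab == "unpredicted"] <- "unpredicted"
  stage[svm_lab == "unpredicted"] <- "failed"
  label[svm_lab == "mutagen"] <- "mutagenic"
  stage[svm_lab == "mutagen"] <- "svm"

  negs <- which(svm_lab == "nonmutagen")
  rb <- object$rulebase
  use_alerts <- use_alerts && !is.null(rb) && !is.null(newdata) &&
    any(rb$partition != "unused")
  if (use_alerts && length(negs)) {
    enh <- screen_alerts(rb, newdata, "enhancing")
    sus <- screen_alerts(rb, newdata, "suspicious")
    for (i in negs) {
      if (length(enh[[i]])) {
        label[i] <- "mutagenic"; stage[i] <- "checkpoint1"
        fired[i] <- paste(enh[[i]], collapse = ";")
      } else if (length(sus[[i]])) {
        label[i] <- "suspicious"; stage[i] <- "checkpoint2"
        fired[i] <- paste(sus[[i]], collapse = ";")
      } else {
        label[i] <- "nonmutagenic"; stage[i] <- "passthrough"
      }
    }
  } else {
    label[negs] <- "nonmutagenic"
    stage[negs] <- "passthrough"
  }
  out <- data.frame(mol_id = ids, smiles = smiles, label = label,
                    stage = stage, fired_alerts = fired,
                    stringsAsFactors = FALSE)
  if (!is.null(policy)) {
    if (is.character(policy)) policy <- .policy(policy)
    out[[paste0("binary_", policy$name)]] <- binarize_labels(label, policy)
  }
  out
}

#' @export
print.ames_cascade <- function(x, ...) {
  cat("Integrated Ames mutagenicity cascade (C-SVC/RBF + structural alerts)\n")
  cat(sprintf("  SVM: C = %g, gamma = %g on %d descriptors; trained on %d compounds (%d mutagen / %d nonmutagen)\n",
              x$C, x$gamma, length(x$descriptor_order), x$n_train,
              x$class_counts[1], x$class_counts[2]))
  cat(sprintf("  %d-fold CV accuracy of the SVM stage: %.1f%%\n",
              x$folds, 100 * x$cv_accuracy))
  if (!is.null(x$rulebase)) {
    p <- table(factor(x$rulebase$partition,
                      c("enhancing", "suspicious", "unused")))
    cat(sprintf("  Alerts: %d enhancing, %d suspicious (of %d)\n",
                p[1], p[2], length(x$rulebase$partition)))
  } else cat("  Alert layer: none (descriptor-only model)\n")
  invisible(x)
}

#' @export
summary.ames_cascade <- function(object, ...) {
  print(object)
  if (!is.null(object$audits)) {
    cat("\nRule audit on cross-validated predicted negatives:\n")
    a <- object$audits
    print(a[order(match(a$decision, c("enhancing", "suspicious", "unused")),
                  -a$caught_fn), ], row.names = FALSE)
  }
  invisible(object)
}

#' Plot the rule audit of a fitted cascade
#'
#' Bar pairs of false negatives caught vs false positives generated per
#' alert, shaded by the selection decision.
#'
#' @param x an `ames_cascade` fitted with `select_rules = TRUE`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ames_cascade <- function(x, ...) {
  a <- x$audits
  if (is.null(a)) stop("no audit stored (descriptor-only model?)", call. = FALSE)
  keep <- a$support > 0
  a <- a[keep, ]
  if (!nrow(a)) stop("no alert had any support", call. = FALSE)
  m <- t(as.matrix(a[, c("caught_fn", "generated_fp")]))
  colnames(m) <- a$alert_id
  cols <- c(enhancing = "forestgreen", suspicious = "goldenrod",
            unused = "grey70")[a$decision]
  graphics::barplot(m, beside = TRUE, las = 2,
                    col = rbind(cols, grDevices::adjustcolor(cols, 0.45)),
                    ylab = "compounds among CV-predicted negatives",
                    legend.text = c("FNs caught", "FPs generated"), ...)
  invisible(x)
}

#' Save / load a cascade model bundle
#'
#' The bundle is a single serialized file containing the SVM, the scaling
#' factors, the descriptor order, the partitioned rulebase and the audit
#' report, stamped with the package version and a partition hash.
#'
#' @param object an `ames_cascade`.
#' @param path file path.
#' @return `save_cascade` returns `path` invisibly; `load_cascade` the
#'   restored object.
#' @export
save_cascade <- function(object, path) {
  stopifnot(inherits(object, "ames_cascade"))
  bundle <- list(model = object,
                 partition_hash = if (!is.null(object$rulebase))
                   paste(object$rulebase$partition, collapse = "|") else "",
                 version = object$version)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  if (!file.exists(path)) stop("no model bundle at ", path, call. = FALSE)
  bundle <- readRDS(path)
  if (!inherits(bundle$model, "ames_cascade"))
    stop("file is not a cascade bundle", call. = FALSE)
  bundle$model
}

#' Evaluate a fitted cascade on a labelled molecule set
#'
#' Computes the three-output confusion matrix, binary statistics under both
#' policies, the bare-SVM reference statistics, and the relative
#' false-negative reductions.
#'
#' @param object an `ames_cascade`.
#' @param ms a labelled `molecule_set`.
#' @return a `cascade_evaluation` list.
#' @export
evaluate_cascade <- function(object, ms) {
  stopifnot(inherits(object, "ames_cascade"), inherits(ms, "molecule_set"))
  keep <- ms$records$ames_label %in% c("mutagen", "nonmutagen")
  ms <- ms[keep]
  truth <- ms$records$ames_label
  pred <- predict(object, ms)
  pred_svm <- predict(object, ms, use_alerts = FALSE)
  cm <- confusion3(truth, pred$label)
  cm_svm <- confusion3(truth, pred_svm$label)
  st_max <- stats_under_policy(cm, policy("max_accuracy"))
  st_min <- stats_under_policy(cm, policy("min_fn"))
  st_svm <- stats_under_policy(cm_svm, policy("max_accuracy"))
  structure(list(
    confusion = cm, confusion_svm = cm_svm,
    stats = list(max_accuracy = st_max, min_fn = st_min, svm = st_svm),
    fn_reduction = list(max_accuracy = fn_reduction(st_svm, st_max),
                        min_fn = fn_reduction(st_svm, st_min)),
    n = sum(keep)), class = "cascade_evaluation")
}

#' @export
print.cascade_evaluation <- function(x, ...) {
  cat(sprintf("Cascade evaluation on %d labelled compounds\n", x$n))
  cat("\nThree-output confusion matrix:\n")
  print(x$confusion)
  cat("\n")
  print(x$stats$svm); cat("  (bare SVM stage)\n")
  print(x$stats$max_accuracy)
  print(x$stats$min_fn)
  cat(sprintf("\nFN reduction vs bare SVM: %.1f%% (max_accuracy), %.1f%% (min_fn)\n",
              100 * x$fn_reduction$max_accuracy, 100 * x$fn_reduction$min_fn))
  invisible(x)
}
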