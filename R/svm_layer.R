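#' C-SVC statistical layer
#'
#' The statistical stage of the cascade is a soft-margin C-support-vector
#' classifier with a radial basis function kernel
#' \eqn{K(x,z) = \exp(-\gamma \|x-z\|^2)}, fitted on max-abs-scaled
#' descriptor vectors (libsvm, via e1071). The shipped default
#' hyperparameters are \eqn{(C, \gamma) = (8, 16)}, the assignment found by
#' the original 10-fold cross-validated grid calibration on the mutagenicity
#' training set; [svm_grid_search()] re-runs such a calibration on any data.
#'
#' @name svm_layer
NULL

# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.check_xy <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("x and labels misaligned", call. = FALSE)
  if (anyNA(x)) stop("descriptor matrix contains NA rows; drop computed_ok = FALSE records first",
                     call. = FALSE)
  if (!all(labels %in% c("mutagen", "nonmutagen")))
    stop("labels must be mutagen/nonmutagen", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training labels are single-class", call. = FALSE)
  list(x = x, y = factor(labels, levels = c("mutagen", "nonmutagen")))
}

#' Train the C-SVC/RBF classifier
#'
#' @param x scaled numeric descriptor matrix (rows = compounds).
#' @param labels character vector, `mutagen` / `nonmutagen`.
#' @param C cost parameter (default 8).
#' @param gamma RBF width (default 16).
#' @return an `svm_layer` object wrapping the fitted libsvm model.
#' @export
svm_train <- function(x, labels, C = 8, gamma = 16) {
  d <- .check_xy(x, labels)
  fit <- e1071::svm(d$x, d$y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, C = C, gamma = gamma,
                 descriptor_order = colnames(d$x),
                 train_pred = as.character(stats::predict(fit, d$x))),
            class = "svm_layer")
}

#' Predict with a trained SVM layer
#'
#' @param model an `svm_layer`.
#' @param x matrix scaled with the same factors and column order used in
#'   training; rows with any `NA` yield `"unpredicted"` rather than a guess.
#' @return character vector of `mutagen` / `nonmutagen` / `unpredicted`.
#' @export
svm_classify <- function(model, x) {
  stopifnot(inherits(model, "svm_layer"))
  x <- as.matrix(x)
  if (!identical(colnames(x), model$descriptor_order))
    stop("descriptor columns do not match the trained model", call. = FALSE)
  out <- rep("unpredicted", nrow(x))
  ok <- stats::complete.cases(x)
  if (any(ok))
    out[ok] <- as.character(stats::predict(model$fit, x[ok, , drop = FALSE]))
  out
}

#' @export
print.svm_layer <- function(x, ...) {
  cat(sprintf("<svm_layer: C-SVC/RBF, C = %g, gamma = %g, %d support vectors>\n",
              x$C, x$gamma, x$fit$tot.nSV))
  invisible(x)
}

# stratified fold assignment; re-drawn (bounded) if any training part of a
# fold would be single-class
.stratified_folds <- function(y, k, seed, max_retry = 10L) {
  n <- length(y)
  .with_seed(seed, {
    for (try in seq_len(max_retry)) {
      folds <- integer(n)
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[folds != f])) >= 2L, TRUE))
      if (ok) return(folds)
    }
  })
  stop("could not build ", k, "-fold stratified partition with both classes in every training split",
       call. = FALSE)
}

#' Cross-validated SVM predictions
#'
#' Each compound's prediction comes from the fold model that did not train on
#' it. Fold assignment is stratified by label and reproducible from `seed`.
#' These out-of-fold predictions drive structural-alert selection: they are
#' representative of the classifier's general (not resubstitution) behaviour.
#'
#' @inheritParams svm_train
#' @param k number of folds (>= 2; default 10).
#' @param seed integer seed for the fold draw.
#' @return character vector of out-of-fold predictions, aligned with rows.
#' @export
svm_cv_predictions <- function(x, labels, C = 8, gamma = 16, k = 10, seed = 1) {
  d <- .check_xy(x, labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  k <- min(k, nrow(d$x))
  folds <- .stratified_folds(as.character(d$y), k, seed)
  out <- character(nrow(d$x))
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te)) next
    fit <- e1071::svm(d$x[!te, , drop = FALSE], droplevels(d$y[!te]),
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    out[te] <- as.character(stats::predict(fit, d$x[te, , drop = FALSE]))
  }
  out
}

#' Grid-search calibration of (C, gamma)
#'
#' Exhaustive search over exponential grids, scored by stratified k-fold
#' cross-validated accuracy; ties broken towards smaller C, then smaller
#' gamma (favouring regularisation).
#'
#' @inheritParams svm_cv_predictions
#' @param C_grid,gamma_grid positive grids; defaults are the classic
#'   \eqn{2^{-5}..2^{15}} and \eqn{2^{-15}..2^{3}} libsvm search ranges.
#' @return list with `C`, `gamma`, `cv_score`, and the full score `grid`.
#' @export
svm_grid_search <- function(x, labels, C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2), k = 10, seed = 1) {
  if (!length(C_grid) || !length(gamma_grid))
    stop("empty hyperparameter grid", call. = FALSE)
  d <- .check_xy(x, labels)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid$cv_score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    pred <- svm_cv_predictions(d$x, as.character(d$y), C = grid$C[i],
                               gamma = grid$gamma[i], k = k, seed = seed)
    grid$cv_score[i] <- mean(pred == as.character(d$y))
  }
  best <- grid[order(-grid$cv_score, grid$C, grid$gamma), ][1, ]
  list(C = best$C, gamma = best$gamma, cv_score = best$cv_score, grid = grid)
}
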