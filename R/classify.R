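#' Assemble a per-clip feature matrix
#'
#' Builds the classifier input from a per-clip summary: for each code in
#' `codes`, a frequency column and/or a maximum-duration column, in
#' deterministic order (codes sorted alphabetically; the frequency block
#' precedes the duration block). Clips lacking a code contribute zeros.
#' Labels map `baseline` clips to `control` and all other conditions to
#' `intervention`.
#'
#' For "pure" classifier data the summary is typically computed on the raw
#' annotations, i.e. without the ear-flicker adjustment.
#'
#' @param summary output of [summarize_clips()].
#' @param clips clip metadata; defines the rows (sorted by `video_id`).
#' @param codes character vector of codes to use as features; must be
#'   non-empty. Codes absent from the summary grid yield all-zero columns.
#' @param mode `"both"` (default), `"frequency"` or `"max_duration"`.
#' @return object of class `facs_features`: list with numeric matrix `x`
#'   (rows named by `video_id`), factor `label` with levels
#'   `c("control", "intervention")`, and `mode`.
#' @export
build_features <- function(summary, clips, codes,
                           mode = c("both", "frequency", "max_duration")) {
  mode <- match.arg(mode)
  codes <- sort(unique(as.character(codes)))
  if (!length(codes)) stop("empty code set")
  vids <- sort(clips$video_id)
  block <- function(measure) {
    prefix <- c(frequency = "freq", max_duration = "maxd")[[measure]]
    m <- matrix(0, length(vids), length(codes),
                dimnames = list(vids, paste0(prefix, "_", codes)))
    sub <- summary[summary$code %in% codes, , drop = FALSE]
    sub <- sub[sub$video_id %in% vids, , drop = FALSE]
    m[cbind(match(sub$video_id, vids), match(sub$code, codes))] <- sub[[measure]]
    m
  }
  x <- switch(mode,
              frequency = block("frequency"),
              max_duration = block("max_duration"),
              both = cbind(block("frequency"), block("max_duration")))
  cond <- clips$condition[match(vids, clips$video_id)]
  label <- factor(ifelse(cond == "baseline", "control", "intervention"),
                  levels = c("control", "intervention"))
  structure(list(x = x, label = label, mode = mode),
            class = "facs_features")
}

#' @export
print.facs_features <- function(x, ...) {
  cat(sprintf("feature matrix: %d clips x %d features (%s), %d intervention / %d control\n",
              nrow(x$x), ncol(x$x), x$mode,
              sum(x$label == "intervention"), sum(x$label == "control")))
  invisible(x)
}

#' Column standardization fitted on training data only
#'
#' @param x numeric matrix of training rows.
#' @return list with `center`, `scale` and `keep` (columns with non-zero
#'   training variance).
#' @keywords internal
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  list(center = center, scale = scale, keep = scale > 0)
}

#' @keywords internal
standardize_apply <- function(fit, x) {
  x <- sweep(x, 2, fit$center, "-")
  x <- sweep(x, 2, pmax(fit$scale, .Machine$double.eps), "/")
  x[, fit$keep, drop = FALSE]
}

#' Stratified cross-validation folds
#'
#' Assigns rows to `k` folds preserving class proportions; redraws (up to
#' 100 times) if some training partition would miss a class entirely.
#'
#' @keywords internal
stratified_folds <- function(label, k = 5) {
  n <- length(label)
  for (try in 1:100) {
    fold <- integer(n)
    for (cl in levels(label)) {
      idx <- sample(which(label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(label[fold != f])) == nlevels(label)
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build stratified folds with both classes in training")
}

balanced_weights <- function(label) {
  tab <- table(label)
  w <- length(label) / (nlevels(label) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

fit_lsvm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
             class.weights = balanced_weights(y))
}

select_c <- function(x, y, c_grid, k = 5) {
  fold <- stratified_folds(y, k = k)
  acc <- vapply(c_grid, function(cost) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (!any(!tr)) next
      std <- standardize_fit(x[tr, , drop = FALSE])
      model <- fit_lsvm(standardize_apply(std, x[tr, , drop = FALSE]),
                        y[tr], cost)
      pred <- stats::predict(model,
                             standardize_apply(std, x[!tr, , drop = FALSE]))
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  # ties favour the smaller C (stronger regularization)
  c_grid[which.max(acc)]
}

#' Leave-one-out linear-SVM evaluation
#'
#' Evaluates how well the per-clip features discriminate intervention from
#' control clips under the leave-one-out (LOO) protocol: for each held-out
#' clip, features are standardized on the remaining clips, the
#' regularization parameter `C` is chosen by stratified five-fold
#' cross-validation on those clips (accuracy criterion, ties going to the
#' smaller `C`), a linear SVM with balanced class weights is fitted, and
#' the held-out clip is predicted. Predictions are collated over all clips
#' into precision, recall and accuracy with `intervention` as the positive
#' class.
#'
#' Standardization and tuning happen strictly inside each LOO fold, so no
#' information about the held-out clip leaks into training.
#'
#' @param features a [build_features()] object with at least two clips per
#'   class.
#' @param c_grid candidate values of `C` (default `10^(-2:2)`).
#' @param seed integer seed controlling the cross-validation folds.
#' @return object of class `loo_report`: list with `precision`, `recall`,
#'   `accuracy` (percent), `predictions` (data.frame of per-clip truth and
#'   prediction), `c_selected` (per-fold chosen `C`) and `seed`.
#' @export
loo_evaluate <- function(features, c_grid = c(0.01, 0.1, 1, 10, 100),
                         seed = 1) {
  stopifnot(inherits(features, "facs_features"))
  x <- features$x
  y <- features$label
  if (min(table(y)) < 2) stop("need at least two clips per class")
  n <- nrow(x)
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  c_sel <- numeric(n)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (i in seq_len(n)) {
    set.seed(seed + i)
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    cost <- select_c(xtr, ytr, c_grid)
    std <- standardize_fit(xtr)
    model <- fit_lsvm(standardize_apply(std, xtr), ytr, cost)
    pred[i] <- stats::predict(model, standardize_apply(std, x[i, , drop = FALSE]))
    c_sel[i] <- cost
  }
  tp <- sum(pred == "intervention" & y == "intervention")
  fp <- sum(pred == "intervention" & y == "control")
  fn <- sum(pred == "control" & y == "intervention")
  structure(list(
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    recall = 100 * tp / (tp + fn),
    accuracy = 100 * mean(pred == y),
    predictions = data.frame(video_id = rownames(x), truth = y,
                             prediction = pred, stringsAsFactors = FALSE),
    c_selected = c_sel, seed = seed
  ), class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf(paste0("leave-one-out linear SVM (n = %d):\n",
                     "  precision %.2f%%  recall %.2f%%  accuracy %.2f%%\n"),
              nrow(x$predictions), x$precision, x$recall, x$accuracy))
  invisible(x)
}
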