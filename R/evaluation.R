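#' Confusion counts for a binary classification
#'
#' Class 1 is the positive class (high valence / high arousal), class 0 the
#' negative class.  `TP` counts positives recognized as positive, `FP`
#' negatives mistaken for positive, `TN` negatives recognized as negative,
#' `FN` positives missed.
#'
#' @param y_true,y_pred equal-length vectors with values in `{0, 1}`.
#' @return object of class `confusion_counts` (fields `TP`, `FP`, `TN`,
#'   `FN`).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true (", length(y_true), ") and y_pred (", length(y_pred),
         ") differ in length")
  if (length(y_true) < 1L) stop("need at least one prediction")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels and predictions must be binary (0/1)")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (TPR) and specificity (TNR) in percent, plus
#' macro-averaged F1: per-class precision `P_i` and recall `R_i` are averaged
#' over the two classes (class 0's precision/recall come from the
#' class-swapped confusion matrix), giving
#' `macro-F1 = 2 * macroP * macroR / (macroP + macroR)` on the `[0, 1]`
#' scale (also reported x100 as `macro_f1_pct`).  A metric whose denominator
#' is zero is reported as `NA` with a warning, never silently as 0.
#'
#' @param c a [confusion()] object, or a list with fields `TP`, `FP`, `TN`,
#'   `FN`.
#' @return object of class `metrics_report` with fields `acc`, `tpr`, `tnr`
#'   (percent), `macro_p`, `macro_r`, `macro_f1` (0-1), `macro_f1_pct`.
#' @export
metrics <- function(c) {
  TP <- c$TP; FP <- c$FP; TN <- c$TN; FN <- c$FN
  if (any(c(TP, FP, TN, FN) < 0) || TP + FP + TN + FN < 1)
    stop("confusion counts must be non-negative with at least one sample")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator); reporting NA",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- (TP + TN) / (TP + TN + FP + FN) * 100
  tpr <- safe_div(TP, TP + FN, "sensitivity (TPR)") * 100
  tnr <- safe_div(TN, TN + FP, "specificity (TNR)") * 100
  p1 <- safe_div(TP, TP + FP, "precision of class 1")
  p0 <- safe_div(TN, TN + FN, "precision of class 0")
  r1 <- safe_div(TP, TP + FN, "recall of class 1")
  r0 <- safe_div(TN, TN + FP, "recall of class 0")
  macro_p <- (p1 + p0) / 2
  macro_r <- (r1 + r0) / 2
  macro_f1 <- if (is.na(macro_p) || is.na(macro_r) || macro_p + macro_r == 0)
    NA_real_ else 2 * macro_p * macro_r / (macro_p + macro_r)
  structure(list(acc = acc, tpr = tpr, tnr = tnr,
                 macro_p = macro_p, macro_r = macro_r,
                 macro_f1 = macro_f1, macro_f1_pct = 100 * macro_f1,
                 counts = list(TP = TP, FP = FP, TN = TN, FN = FN)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  TPR %.2f%%  TNR %.2f%%  macro-F1 %.4f\n",
              x$acc, x$tpr, x$tnr, x$macro_f1))
  invisible(x)
}

# Stratified k-fold assignment: within each class, a seeded shuffle followed
# by round-robin dealing, so fold class proportions track the pooled ones.
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("smallest class has ", min(table(y)), " trials, fewer than k = ", k,
         " folds; use a smaller k")
  folds <- integer(length(y))
  rng <- local_rng(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[rng$sample_order(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Small deterministic RNG wrapper that never touches .Random.seed of the
# caller: saves/restores global state around seeded draws.
local_rng <- function(seed) {
  list(
    sample_order = function(n) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv()))
      set.seed(seed)
      sample.int(n)
    })
}

#' Stratified k-fold cross-validation of the sequence classifier
#'
#' Splits trials into `k` stratified folds (default tenfold), trains a fresh
#' model on each training fold with fold-derived seeds, tests on the held-out
#' fold, and reports per-fold accuracy/TPR/TNR/macro-F1 together with their
#' across-fold mean and sample standard deviation.  Every trial is tested
#' exactly once; fold assignment is reproducible from `seed`.
#'
#' @param sequences list of [segment()] outputs, one per trial, sharing `E`.
#' @param labels a `trial_labels` data.frame aligned with `sequences`, or a
#'   0/1 vector.
#' @param target `"valence"` or `"arousal"` (ignored when `labels` is
#'   already binary).
#' @param config a [model_config()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and per-fold model
#'   seeds.
#' @return object of class `cv_report`: `per_fold` (data.frame of fold
#'   metrics), `mean`, `sd` (named vectors over `acc`, `tpr`, `tnr`,
#'   `macro_f1`, `macro_f1_pct`), `k`, `seed`, pooled `predictions`.
#' @export
crossval <- function(sequences, labels, target = c("valence", "arousal"),
                     config = model_config(), k = 10L, seed = 1L) {
  target <- match.arg(target)
  y <- binary_targets(labels, target)
  keep <- which(!is.na(y))
  if (length(keep) < length(y)) {
    sequences <- sequences[keep]
    y <- y[keep]
  }
  if (length(unique(y)) < 2L)
    stop("cross-validation needs both classes present after exclusions")
  folds <- stratified_folds(y, k, seed)
  metric_names <- c("acc", "tpr", "tnr", "macro_f1", "macro_f1_pct")
  per_fold <- matrix(NA_real_, nrow = k, ncol = length(metric_names),
                     dimnames = list(NULL, metric_names))
  preds <- rep(NA_integer_, length(y))
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    cfg <- config
    cfg$seed <- (config$seed + 101L * f) %% .Machine$integer.max
    fit <- train(sequences[tr], y[tr], target = target, config = cfg)
    pr <- predict(fit, sequences[te])
    preds[te] <- pr$class
    scores[te] <- pr$score
    m <- suppressWarnings(metrics(confusion(y[te], pr$class)))
    per_fold[f, ] <- c(m$acc, m$tpr, m$tnr, m$macro_f1, m$macro_f1_pct)
  }
  per_fold <- as.data.frame(per_fold)
  per_fold$fold <- seq_len(k)
  structure(list(
    per_fold = per_fold,
    mean = vapply(per_fold[metric_names], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per_fold[metric_names], stats::sd, numeric(1), na.rm = TRUE),
    k = k, seed = seed, target = target,
    predictions = data.frame(y_true = y, y_pred = preds, score = scores)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): ACC %.2f +/- %.2f %%  TPR %.2f  TNR %.2f  macro-F1 %.4f +/- %.4f\n",
              x$k, x$target, x$mean["acc"], x$sd["acc"], x$mean["tpr"],
              x$mean["tnr"], x$mean["macro_f1"], x$sd["macro_f1"]))
  invisible(x)
}

# Accepts a trial_labels data.frame or a plain 0/1 vector; returns 0/1 with
# NA for excluded trials.
binary_targets <- function(labels, target) {
  if (is.numeric(labels) || is.logical(labels)) {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("binary label vector must be 0/1")
    return(y)
  }
  if (!inherits(labels, "data.frame"))
    stop("`labels` must be a trial_labels data.frame or a 0/1 vector")
  col <- if (target == "valence") labels$class_valence else labels$class_arousal
  pos <- if (target == "valence") "positive" else "active"
  neg <- if (target == "valence") "negative" else "passive"
  ifelse(col == pos, 1L, ifelse(col == neg, 0L, NA_integer_))
}
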