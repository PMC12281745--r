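# Performance testing in three regimes: training fit, repeated stratified
# k-fold cross-validation, and bootstrap/independent validation. Every
# headline metric is the mean of the two class-as-positive computations
# (so accuracy is unchanged, averaged sensitivity equals balanced
# accuracy, and PRC-AUC genuinely differs between the two views).

# ROC points with tied scores grouped; trapezoidal AUC over the sweep
# equals the pairwise concordance probability exactly.
roc_points <- function(y01, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y01[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / max(sum(1 - y01), 1)),
             tpr = c(0, tp[last] / max(sum(y01), 1)),
             threshold = c(Inf, s[last]))
}

trapezoid_auc <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# precision-recall AUC by step-wise interpolation (average-precision form)
prc_auc_one <- function(y01, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y01[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); pp <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; pp <- pp[last]
  n_pos <- sum(y01)
  if (n_pos == 0) return(NA_real_)
  rec <- tp / n_pos
  prec <- tp / pp
  sum(diff(c(0, rec)) * prec)
}

#' Class-averaged classification metrics
#'
#' Confusion matrix at the given threshold, then each metric computed
#' twice (L as positive, S as positive with reversed scores) and
#' averaged. ROC-AUC uses the trapezoidal rule on the full score sweep;
#' PRC-AUC uses step-wise interpolation; MCC comes from the confusion
#' matrix. Accuracy is reported in percent. With a single-class truth
#' vector the AUCs are reported missing.
#'
#' @param y_true factor with levels c("S","L").
#' @param scores L-class probability scores in [0, 1].
#' @param threshold decision threshold (predict L when score >=
#'   threshold).
#' @return named list of metrics plus the confusion counts (`tp`, `fp`,
#'   `tn`, `fn`, with L as positive).
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  if (any(scores < -1e-9 | scores > 1 + 1e-9, na.rm = TRUE))
    stop_field("scores", "must lie in [0,1]")
  y01 <- to_y01(y_true)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y01 == 1); fp <- sum(pred == 1 & y01 == 0)
  tn <- sum(pred == 0 & y01 == 0); fn <- sum(pred == 0 & y01 == 1)
  n <- tp + fp + tn + fn
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  # L as positive / S as positive
  sens <- c(rate(tp, fn), rate(tn, fp))
  spec <- c(rate(tn, fp), rate(tp, fn))
  prec <- c(rate(tp, fp), rate(tn, fn))
  acc <- 100 * (tp + tn) / n
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  both <- length(unique(y01)) == 2
  if (both) {
    rl <- roc_points(y01, scores)
    auc_l <- trapezoid_auc(rl$fpr, rl$tpr)
    rs <- roc_points(1 - y01, 1 - scores)
    auc_s <- trapezoid_auc(rs$fpr, rs$tpr)
    prc <- c(prc_auc_one(y01, scores), prc_auc_one(1 - y01, 1 - scores))
  } else {
    auc_l <- auc_s <- NA_real_
    prc <- c(NA_real_, NA_real_)
  }
  list(accuracy = acc,
       sensitivity = mean(sens), specificity = mean(spec),
       precision = mean(prec), mcc = mcc,
       roc_auc = mean(c(auc_l, auc_s)), prc_auc = mean(prc),
       tp = tp, fp = fp, tn = tn, fn = fn, n = n,
       threshold = threshold)
}

#' Youden-optimal decision threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over the finite candidate
#' set of midpoints between sorted distinct scores; ties break to the
#' lowest threshold.
#'
#' @param y_true factor S/L (both classes present).
#' @param scores L-probability scores.
#' @return list with `threshold` and `J`.
#' @export
youden_threshold <- function(y_true, scores) {
  y01 <- to_y01(y_true)
  if (length(unique(y01)) < 2)
    stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2 else s
  n1 <- sum(y01); n0 <- sum(1 - y01)
  J <- vapply(cand, function(t) {
    sum(scores >= t & y01 == 1) / n1 + sum(scores < t & y01 == 0) / n0 - 1
  }, numeric(1))
  best <- which(J >= max(J) - 1e-12)[1]   # lowest threshold on ties
  list(threshold = cand[best], J = max(J))
}

#' Score calibration curve
#'
#' Equal-width bins on the score axis; per bin the mean score, the
#' observed L fraction and the count. Empty bins are kept with a missing
#' observed fraction; bin counts sum to n.
#'
#' @param y_true factor S/L.
#' @param scores L-probability scores.
#' @param n_bins number of bins (>= 2).
#' @return data.frame bin/mean_score/observed/count.
#' @export
calibration_curve <- function(y_true, scores, n_bins = 10) {
  if (n_bins < 2) stop_field("n_bins", "needs >= 2 bins")
  y01 <- to_y01(y_true)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(scores, edges, rightmost.closed = TRUE), 1), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lo = utils::head(edges, -1), hi = utils::tail(edges, -1))
  out$count <- vapply(out$bin, function(b) sum(bin == b), integer(1))
  out$mean_score <- vapply(out$bin, function(b)
    if (any(bin == b)) mean(scores[bin == b]) else NA_real_, numeric(1))
  out$observed <- vapply(out$bin, function(b)
    if (any(bin == b)) mean(y01[bin == b]) else NA_real_, numeric(1))
  out
}

# ---------------------------------------------------------------------------
# regimes

metric_row <- function(m, extra = list()) {
  as.data.frame(c(extra, m[c("accuracy", "sensitivity", "specificity",
                             "precision", "mcc", "roc_auc", "prc_auc",
                             "tp", "fp", "tn", "fn")]))
}

summarize_report <- function(per_rep) {
  cols <- c("accuracy", "sensitivity", "specificity", "precision",
            "mcc", "roc_auc", "prc_auc", "youden_j", "youden_threshold")
  cols <- intersect(cols, names(per_rep))
  do.call(rbind, lapply(cols, function(cn) data.frame(
    metric = cn,
    median = stats::median(per_rep[[cn]], na.rm = TRUE),
    mean = mean(per_rep[[cn]], na.rm = TRUE),
    min = suppressWarnings(min(per_rep[[cn]], na.rm = TRUE)),
    max = suppressWarnings(max(per_rep[[cn]], na.rm = TRUE)))))
}

new_report <- function(regime, per_replicate, extra = list()) {
  structure(c(list(regime = regime, per_replicate = per_replicate,
                   summary = summarize_report(per_replicate)), extra),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Performance report (", x$regime, ", ", nrow(x$per_replicate),
      " replicate(s))\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Repeated stratified k-fold cross-validation
#'
#' The whole model path - missingness filter, median imputation, min-max
#' normalization, classifier fit - is refit inside each training fold;
#' fold test scores are pooled per repeat and metrics computed on the
#' pooled scores (threshold 0.5 plus the per-repeat Youden optimum).
#' Repeats use fresh shuffles. If a shuffle leaves a training fold
#' without both classes it is redrawn once, then an error is raised.
#'
#' @param X_raw raw values matrix (patients x features; the candidate
#'   feature subset, unnormalized).
#' @param y factor S/L.
#' @param spec a [classifier_spec()].
#' @param k folds (>= 2).
#' @param repeats number of repeated CV rounds.
#' @param seed integer seed.
#' @return a `performance_report` (regime `"cv"`) whose `per_replicate`
#'   table has one row per repeat; `pooled_scores` keeps the out-of-fold
#'   scores of the last repeat. The frozen deployment threshold
#'   (`youden_median`) is the median Youden threshold across repeats.
#' @export
repeated_cv <- function(X_raw, y, spec = classifier_spec("klr"),
                        k = 10, repeats = 10, seed = 1L) {
  stopifnot(k >= 2)
  y <- factor(y, levels = c("S", "L"))
  if (min(table(y)) < 2) stop("need >= 2 patients per class", call. = FALSE)
  rows <- list()
  scores_last <- NULL
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, k, derive_seed(seed, r))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds != f])) == 2, logical(1)))
    if (!ok) {
      folds <- stratified_folds(y, k, derive_seed(seed, 1000L + r))
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[folds != f])) == 2, logical(1)))
      if (!ok) stop("a training fold lost a class", call. = FALSE)
    }
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      if (!any(!tr)) next
      prep <- fit_preprocess(X_raw[tr, , drop = FALSE])
      clf <- train_classifier(apply_preprocess(prep, X_raw[tr, , drop = FALSE]),
                              y[tr], spec)
      sc <- predict_score(clf, apply_preprocess(prep, X_raw[!tr, , drop = FALSE]))
      scores[!tr] <- pmin(pmax(sc, 0), 1)
    }
    m <- compute_metrics(y, scores, threshold = 0.5)
    yd <- youden_threshold(y, scores)
    rows[[r]] <- metric_row(m, list(repeat_id = r,
                                    youden_threshold = yd$threshold,
                                    youden_j = yd$J))
    scores_last <- scores
  }
  per <- do.call(rbind, rows)
  new_report("cv", per,
             list(k = k, repeats = repeats, seed = seed,
                  youden_median = stats::median(per$youden_threshold),
                  pooled_scores = scores_last))
}

#' Bootstrap validation of a frozen signature model
#'
#' The model (selected features, imputation values, normalization bounds,
#' classifier, threshold) is applied unchanged to B stratified resamples
#' (with replacement) of a validation set that must be disjoint from the
#' training patients. Metrics are computed per resample and summarized as
#' median (range). A resample missing a class is redrawn (at most 100
#' attempts).
#'
#' @param model a [train_signature_model()] result.
#' @param X_raw_val raw validation values matrix (rownames = patient
#'   ids).
#' @param y_val validation labels, factor S/L.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param train_ids training patient ids for the disjointness audit
#'   (optional; overlap raises an error).
#' @return a `performance_report` (regime `"bootstrap"`).
#' @export
bootstrap_validate <- function(model, X_raw_val, y_val, B = 10, seed = 1L,
                               train_ids = NULL) {
  stopifnot(inherits(model, "signature_model"))
  y_val <- factor(y_val, levels = c("S", "L"))
  if (!is.null(train_ids) && length(intersect(train_ids, rownames(X_raw_val))))
    stop("validation set overlaps the training set", call. = FALSE)
  scores_full <- predict_signature(model, X_raw_val)
  thr <- model$classifier$threshold
  rows <- list()
  for (b in seq_len(B)) {
    idx <- NULL
    for (attempt in seq_len(100)) {
      idx <- withr::with_seed(derive_seed(seed, b * 101L + attempt), {
        unlist(lapply(levels(y_val), function(cl) {
          i <- which(y_val == cl)
          sample(i, length(i), replace = TRUE)
        }))
      })
      if (length(unique(y_val[idx])) == 2) break
    }
    m <- compute_metrics(y_val[idx], scores_full[idx], threshold = thr)
    yd <- youden_threshold(y_val[idx], scores_full[idx])
    rows[[b]] <- metric_row(m, list(repeat_id = b,
                                    youden_threshold = yd$threshold,
                                    youden_j = yd$J))
  }
  new_report("bootstrap", do.call(rbind, rows),
             list(B = B, seed = seed, scores = scores_full))
}

#' Plain evaluation of a frozen model on an external set
#'
#' Applies a frozen signature model unchanged (normalization bounds,
#' threshold and all) to an external table, mirroring the train-once /
#' test-elsewhere generalization protocol. Records the evaluation cohort
#' hash so reports can assert the model was not refit.
#'
#' @inheritParams bootstrap_validate
#' @return a `performance_report` (regime `"external"`, one replicate).
#' @export
evaluate_external <- function(model, X_raw_val, y_val, train_ids = NULL) {
  stopifnot(inherits(model, "signature_model"))
  y_val <- factor(y_val, levels = c("S", "L"))
  if (!is.null(train_ids) && length(intersect(train_ids, rownames(X_raw_val))))
    stop("validation set overlaps the training set", call. = FALSE)
  scores <- predict_signature(model, X_raw_val)
  m <- compute_metrics(y_val, scores, threshold = model$classifier$threshold)
  per <- metric_row(m, list(repeat_id = 1))
  new_report("external", per,
             list(scores = scores, cohort_hash = content_hash(rownames(X_raw_val)),
                  model_hash = model$train_hash))
}
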