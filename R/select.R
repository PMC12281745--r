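# Feature-selection strategies: normality-gated statistical ranking,
# PCA-based ranking on the first principal axis, classifier-driven
# bidirectional wrapper search, and the hybrid (wrapper restricted to the
# statistically significant pool). All selection operates on the training
# split only.

#' Statistical feature ranking
#'
#' Per feature: D'Agostino-Pearson normality on each class gates an
#' unpaired t-test (both normal) versus Mann-Whitney U; the effect size
#' is Cohen's d with pooled SD. The composite score is the min-max
#' normalized mean of rank(|d|) and rank(-log10 p) (equal weights), so it
#' is monotone in both evidence axes and lies in [0, 1]. Features are
#' sorted by score with a deterministic lexicographic tie-break.
#' Benjamini-Hochberg q-values are reported for transparency; selection
#' downstream uses the composite score.
#'
#' @param X values matrix (normalized; missing values tolerated and
#'   dropped pairwise).
#' @param y factor S/L (>= 2 patients per class).
#' @return data.frame (one row per feature, sorted): `feature_id`,
#'   `p_value`, `q_value`, `effect_size`, `score`, `test_used`,
#'   `zero_variance`.
#' @export
rank_statistical <- function(X, y) {
  y <- factor(y, levels = c("S", "L"))
  if (min(table(y)) < 2) stop("need >= 2 patients per class", call. = FALSE)
  feats <- colnames(X)
  res <- lapply(feats, function(f) {
    x <- X[, f]
    x1 <- x[y == "L" & !is.na(x)]; x0 <- x[y == "S" & !is.na(x)]
    if (length(unique(c(x0, x1))) < 2)
      return(data.frame(feature_id = f, p_value = 1, effect_size = 0,
                        test_used = "none", zero_variance = TRUE))
    small <- length(x0) < 8 || length(x1) < 8
    normal <- !small &&
      stats::var(x0) > 0 && stats::var(x1) > 0 &&
      dagostino_pearson(x0)$p_value > 0.05 &&
      dagostino_pearson(x1)$p_value > 0.05
    p <- if (normal) stats::t.test(x1, x0, var.equal = TRUE)$p.value
         else suppressWarnings(stats::wilcox.test(x1, x0)$p.value)
    data.frame(feature_id = f, p_value = p,
               effect_size = cohens_d(x1, x0),
               test_used = if (normal) "t" else "mann_whitney",
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  r_d <- rank(abs(out$effect_size), na.last = FALSE)
  r_p <- rank(-log10(pmax(out$p_value, .Machine$double.xmin)), na.last = FALSE)
  combo <- (r_d + r_p) / 2
  rng <- range(combo)
  out$score <- if (diff(rng) == 0) rep(0, nrow(out)) else
    (combo - rng[1]) / diff(rng)
  out$score[out$zero_variance] <- 0
  out <- out[order(-out$score, out$feature_id), ]
  rownames(out) <- NULL
  out[, c("feature_id", "p_value", "q_value", "effect_size", "score",
          "test_used", "zero_variance")]
}

#' PCA-based feature subset on the first principal axis
#'
#' PCA on standardized features; a feature is retained when the absolute
#' value of its loading on the first axis (its correlation with PC1)
#' exceeds 0.5 and its squared cosine on that axis exceeds the
#' equal-contribution null 1/(number of retained axes). Returned ordered
#' by |loading|. Rank-deficient input reduces the axis count with a
#' warning.
#'
#' @param X values matrix (missing entries median-imputed for the PCA).
#' @return data.frame `feature_id`, `loading`, `cos2`, `retained`,
#'   ordered by |loading| descending, with the retained subset first-class
#'   in the `subset` attribute.
#' @export
rank_pca_f1 <- function(X) {
  if (ncol(X) < 2 || nrow(X) < 3)
    stop("need >= 2 features and >= 3 patients", call. = FALSE)
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  pos <- pc$sdev > 1e-10 * pc$sdev[1]
  n_axes <- sum(pos)
  if (n_axes < ncol(X))
    warning(sprintf("rank-deficient input: %d axes retained", n_axes),
            call. = FALSE)
  # correlation of each (standardized) feature with each component
  corr <- sweep(pc$rotation[, pos, drop = FALSE], 2, pc$sdev[pos], "*")
  cos2 <- corr[, 1]^2 / rowSums(corr^2)
  out <- data.frame(feature_id = rownames(corr), loading = corr[, 1],
                    cos2 = cos2,
                    retained = abs(corr[, 1]) > 0.5 & cos2 > 1 / n_axes,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$loading), out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "subset") <- out$feature_id[out$retained]
  attr(out, "n_axes") <- n_axes
  out
}

# CV criteria used by the wrapper, computed from pooled out-of-fold
# scores over a fixed stratified fold assignment so competing subsets are
# compared on identical partitions. Returns the primary criterion
# (accuracy or ROC-AUC) plus the mean held-out log-likelihood, which the
# search uses as a continuous secondary criterion.
wrapper_criterion <- function(X, y, spec, partitions, metric = "accuracy") {
  y01 <- to_y01(y)
  acc <- numeric(0); ll <- numeric(0)
  for (folds in partitions) {
    k <- max(folds)
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      clf <- train_classifier(X[tr, , drop = FALSE], y[tr], spec)
      scores[!tr] <- predict_score(clf, X[!tr, , drop = FALSE])
    }
    sc <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    ll_r <- mean(y01 * log(sc) + (1 - y01) * log(1 - sc))
    acc <- c(acc, switch(metric,
      roc_auc = {
        rl <- roc_points(y01, scores)
        trapezoid_auc(rl$fpr, rl$tpr)
      },
      logloss = ll_r,
      mean((scores >= 0.5) == (y01 == 1))))
    ll <- c(ll, ll_r)
  }
  c(primary = mean(acc), loglik = mean(ll))
}

#' Bidirectional wrapper feature selection
#'
#' Greedy stepwise search maximizing mean cross-validated accuracy (or
#' ROC-AUC): at every step the best single addition and the best single
#' removal are evaluated and the better move is accepted only if it
#' improves the criterion by at least `tol`. Because the 0/1 accuracy
#' criterion moves on a coarse grid (1/n) and plateaus once CV errors hit
#' zero, the mean held-out log-likelihood serves as a continuous
#' secondary criterion: a move that leaves the primary criterion
#' unchanged is still accepted when it improves the held-out likelihood,
#' so the search keeps absorbing genuinely informative features (which
#' sharpen out-of-fold probabilities) and stops on noise features (which
#' degrade them). The search stops at a local optimum of this
#' lexicographic criterion or when the evaluation budget is exhausted
#' (best-so-far returned, flagged). The fold partition is fixed once per
#' search so all subsets are compared on the same folds; every evaluated
#' subset is recorded in the trace. Deterministic for a fixed seed (ties
#' break to the smaller subset, then lexicographically).
#'
#' @param X normalized values matrix without missing entries (training
#'   split only).
#' @param y factor S/L.
#' @param spec a [classifier_spec()] (the wrapped classifier).
#' @param k CV folds for the criterion.
#' @param seed integer seed (fold assignment).
#' @param budget maximum subset evaluations.
#' @param tol minimal criterion improvement to accept a move.
#' @param pool candidate feature pool (default: all columns).
#' @param metric `"accuracy"` (default), `"roc_auc"`, or `"logloss"` to
#'   maximize the mean held-out log-likelihood directly - the natural
#'   criterion for a probabilistic classifier and the one the stability
#'   consensus uses.
#' @param cv_reps fold partitions averaged per criterion evaluation
#'   (default 1); averaging several partitions damps the variance of the
#'   criterion when the cohort is small.
#' @return object of class `selection_result`: list with `method`,
#'   `selected` (ordered as accepted), `criterion`, `trace` (data.frame),
#'   `budget_exhausted`, `seed`.
#' @export
wrapper_search <- function(X, y, spec = classifier_spec("klr"), k = 10,
                           seed = 1L, budget = Inf, tol = 1e-4,
                           pool = colnames(X), metric = "accuracy",
                           cv_reps = 1) {
  y <- factor(y, levels = c("S", "L"))
  pool <- sort(intersect(pool, colnames(X)))
  if (!length(pool)) stop_field("pool", "no candidate features")
  partitions <- lapply(seq_len(cv_reps), function(r)
    stratified_folds(y, k, derive_seed(seed, r)))
  selected <- character(0)
  # empty-model reference: intercept-only predictor at the class prevalence
  p1 <- mean(to_y01(y))
  current <- c(primary = switch(metric,
                                roc_auc = 0.5,
                                logloss = p1 * log(p1) + (1 - p1) * log(1 - p1),
                                max(p1, 1 - p1)),
               loglik = p1 * log(p1) + (1 - p1) * log(1 - p1))
  n_eval <- 0
  trace <- list()
  evaluate <- function(subset, action, feature) {
    n_eval <<- n_eval + 1
    val <- wrapper_criterion(X[, subset, drop = FALSE], y, spec, partitions, metric)
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1, action = action, feature = feature,
      size = length(subset), criterion = val[["primary"]],
      loglik = val[["loglik"]], stringsAsFactors = FALSE)
    val
  }
  improves <- function(cand, ref) {
    cand[["primary"]] >= ref[["primary"]] + tol ||
      (abs(cand[["primary"]] - ref[["primary"]]) < tol &&
         cand[["loglik"]] >= ref[["loglik"]] + tol)
  }
  repeat {
    cands <- list()
    for (f in setdiff(pool, selected)) {
      if (n_eval >= budget) break
      cands[[length(cands) + 1]] <-
        list(action = "add", feature = f,
             crit = evaluate(c(selected, f), "add", f),
             size = length(selected) + 1)
    }
    if (length(selected) > 1) {
      for (f in selected) {
        if (n_eval >= budget) break
        cands[[length(cands) + 1]] <-
          list(action = "remove", feature = f,
               crit = evaluate(setdiff(selected, f), "remove", f),
               size = length(selected) - 1)
      }
    }
    if (!length(cands)) break
    crit <- vapply(cands, function(cc) cc$crit[["primary"]], numeric(1))
    ll <- vapply(cands, function(cc) cc$crit[["loglik"]], numeric(1))
    sizes <- vapply(cands, `[[`, numeric(1), "size")
    featn <- vapply(cands, `[[`, character(1), "feature")
    best <- order(-crit, -ll, sizes, featn)[1]
    if (improves(cands[[best]]$crit, current)) {
      mv <- cands[[best]]
      selected <- if (mv$action == "add") c(selected, mv$feature)
                  else setdiff(selected, mv$feature)
      current <- mv$crit
      if (n_eval >= budget) break
    } else break
    if (n_eval >= budget) break
  }
  structure(list(method = "wrapper", selected = selected,
                 criterion = current[["primary"]],
                 loglik = current[["loglik"]], metric = metric,
                 trace = do.call(rbind, trace),
                 budget_exhausted = n_eval >= budget,
                 classifier = spec$family, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selection (", x$method, ", ", x$classifier, "): ",
      length(x$selected), " feature(s), criterion ",
      round(x$criterion, 4), "\n  ", paste(x$selected, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Hybrid selection: wrapper restricted to the significant pool
#'
#' Runs [rank_statistical()] and restricts the bidirectional wrapper to
#' features with composite score > 0.5; an empty pool falls back to the
#' top-10 ranked features (flagged).
#'
#' @inheritParams wrapper_search
#' @return a `selection_result` with `method = "hybrid"` and the
#'   `ranking` attached.
#' @export
hybrid_select <- function(X, y, spec = classifier_spec("klr"), k = 10,
                          seed = 1L, budget = Inf, tol = 1e-4,
                          metric = "accuracy", cv_reps = 1) {
  ranking <- rank_statistical(X, y)
  pool <- ranking$feature_id[ranking$score > 0.5]
  fallback <- FALSE
  if (!length(pool)) {
    pool <- utils::head(ranking$feature_id, 10)
    fallback <- TRUE
  }
  res <- wrapper_search(X, y, spec, k = k, seed = seed, budget = budget,
                        tol = tol, pool = pool, metric = metric,
                        cv_reps = cv_reps)
  res$method <- "hybrid"
  res$pool <- pool
  res$fallback_top10 <- fallback
  res$ranking <- ranking
  res
}

#' Consensus signature over repeated hybrid selections
#'
#' Runs the hybrid selection under several seeds and forms the consensus
#' signature by per-feature majority vote: a feature enters the consensus
#' when it is selected in more than half of the runs. This
#' stability-selection step damps the run-to-run variability of greedy
#' wrapper searches: individual runs may carry an occasional noise
#' feature or miss a weak one, but features without real signal rarely
#' repeat across seeds while informative ones almost always do.
#'
#' The default engine is deliberately liberal per run and strict in the
#' vote: a linear-kernel kernel logistic regression wrapped under the
#' held-out log-likelihood criterion with a practical-significance
#' acceptance threshold of 0.005 nats per patient.
#'
#' @inheritParams wrapper_search
#' @param seeds integer vector of seeds (one hybrid run each).
#' @return list with `consensus` (feature ids), `votes` (named counts),
#'   `runs` (list of `selection_result`s).
#' @export
consensus_signature <- function(X, y,
                                spec = classifier_spec("klr", kernel = "linear"),
                                k = 10, seeds = 1:10, tol = 5e-3,
                                metric = "logloss", cv_reps = 1) {
  runs <- lapply(seeds, function(s)
    hybrid_select(X, y, spec, k = k, seed = s, tol = tol, metric = metric,
                  cv_reps = cv_reps))
  votes <- sort(table(unlist(lapply(runs, `[[`, "selected"))),
                decreasing = TRUE)
  consensus <- names(votes)[votes > length(seeds) / 2]
  list(consensus = sort(consensus), votes = votes, runs = runs)
}
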