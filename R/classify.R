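# Classifier bench behind one train/predict contract: kernel logistic
# regression (the signature-model engine), Gaussian naive Bayes, logistic
# regression, and the ZeroR majority baseline. The positive class is L
# (long outcome) throughout; scores are probabilities of L.

#' Specify a classifier
#'
#' @param family `"klr"`, `"nb"`, `"logreg"` or `"zeror"`. Additional
#'   families can be registered with [register_classifier()].
#' @param kernel for KLR: `"rbf"` or `"linear"`.
#' @param gamma RBF kernel scale, `exp(-gamma * ||x - x'||^2)`; NULL means
#'   the median heuristic `1 / (2 * median(pairwise distance)^2)`,
#'   computed at training time.
#' @param lambda ridge penalty on the kernel expansion (>= 0).
#' @param threshold decision threshold on the L-probability scale.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("klr", "nb", "logreg", "zeror"),
                            kernel = c("rbf", "linear"),
                            gamma = NULL, lambda = 1e-2, threshold = 0.5) {
  family <- if (is.character(family) && length(family) == 1 &&
                !family %in% c("klr", "nb", "logreg", "zeror"))
    family else match.arg(family)
  kernel <- match.arg(kernel)
  if (!is.null(gamma) && gamma <= 0) stop_field("gamma", "must be positive")
  if (lambda < 0) stop_field("lambda", "must be non-negative")
  structure(list(family = family, kernel = kernel, gamma = gamma,
                 lambda = lambda, threshold = threshold),
            class = "classifier_spec")
}

# plugin registry (the bench is extensible without touching evaluation code)
.classifier_registry <- new.env(parent = emptyenv())

#' Register a plugin classifier family
#'
#' @param family family name used in [classifier_spec()].
#' @param train function(X, y01, spec) -> arbitrary fit object.
#' @param predict function(fit, X) -> numeric scores in [0,1].
#' @return invisibly, the family name.
#' @export
register_classifier <- function(family, train, predict) {
  assign(family, list(train = train, predict = predict),
         envir = .classifier_registry)
  invisible(family)
}

# ---------------------------------------------------------------------------
# kernels

kernel_matrix <- function(X, Y, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(X, Y))
  # squared Euclidean distances via the Gram expansion
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

median_heuristic_gamma <- function(X) {
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) return(1)
  1 / (2 * m^2)
}

# numerically safe log(1 + exp(f))
log1pexp <- function(f) pmax(f, 0) + log1p(exp(-abs(f)))

# ---------------------------------------------------------------------------
# KLR

#' Train a kernel logistic regression classifier
#'
#' Minimizes the ridge-penalized mean negative log-likelihood over the
#' kernel expansion `f(x) = sum_i a_i k(x, x_i) + b` by Newton iterations
#' (iteratively reweighted least squares) with step halving, so the
#' objective is non-increasing at every step. The mean-loss scaling makes
#' the decision function invariant to duplicating the training set.
#' Converged when the parameter change drops below 1e-8 (200 iterations
#' cap; non-convergence returns the best iterate, flagged).
#'
#' @param X numeric matrix (no missing values), patients x features.
#' @param y factor with levels c("S","L") (or 0/1 with 1 = L).
#' @param spec a [classifier_spec()] with family `"klr"`.
#' @return object of class `trained_classifier`.
#' @export
train_klr <- function(X, y, spec = classifier_spec("klr")) {
  y01 <- to_y01(y)
  check_train_input(X, y01)
  gamma <- spec$gamma %||% if (spec$kernel == "rbf") median_heuristic_gamma(X) else NA
  K <- kernel_matrix(X, X, spec$kernel, gamma)
  n <- nrow(X)
  lambda <- max(spec$lambda, 1e-10)
  a <- rep(0, n); b <- 0
  f <- rep(0, n)
  obj_value <- function(a, b) {
    Ka <- as.vector(K %*% a)
    list(f = Ka + b,
         obj = mean(log1pexp(Ka + b) - y01 * (Ka + b)) + lambda / 2 * sum(a * Ka))
  }
  ov <- obj_value(a, b)
  obj <- ov$obj; f <- ov$f
  obj_trace <- obj
  converged <- FALSE
  for (it in seq_len(200)) {
    p <- stats::plogis(f)
    w <- pmax(p * (1 - p), 1e-10)
    z <- f + (y01 - p) / w
    # Newton step via the fitted-value system:
    #   (I + K W / (n lambda)) u = (K W / (n lambda)) z + b 1,
    #   a = W (z - u) / (n lambda),  b chosen so  w' (z - u) = 0.
    C <- sweep(K, 2, w / (n * lambda), "*")
    lu <- tryCatch(solve(diag(n) + C, cbind(as.vector(C %*% z), 1)),
                   error = function(e) NULL)
    if (is.null(lu)) break
    u0 <- lu[, 1]; v <- lu[, 2]
    b_star <- sum(w * (z - u0)) / sum(w * v)
    u <- u0 + b_star * v
    a_star <- w * (z - u) / (n * lambda)
    # step halving guarantees a non-increasing objective
    step <- 1
    repeat {
      a_new <- a + step * (a_star - a)
      b_new <- b + step * (b_star - b)
      ov <- obj_value(a_new, b_new)
      if (ov$obj <= obj + 1e-14 || step < 1e-8) break
      step <- step / 2
    }
    moved <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new; obj <- ov$obj; f <- ov$f
    obj_trace <- c(obj_trace, obj)
    if (moved < 1e-8) { converged <- TRUE; break }
  }
  structure(list(spec = spec, family = "klr",
                 alpha = a, intercept = b, X_train = X, gamma = gamma,
                 features = colnames(X), threshold = spec$threshold,
                 converged = converged, objective_trace = obj_trace),
            class = "trained_classifier")
}

# ---------------------------------------------------------------------------
# baselines

#' Train a baseline classifier (naive Bayes, logistic regression, ZeroR)
#'
#' Gaussian naive Bayes uses per-class feature means, diagonal variances
#' and empirical priors. Logistic regression is ordinary maximum
#' likelihood. ZeroR stores the training-majority label and predicts it
#' for every case; a tied majority breaks deterministically to L (and is
#' flagged).
#'
#' @inheritParams train_klr
#' @param spec a [classifier_spec()] with family `"nb"`, `"logreg"` or
#'   `"zeror"`.
#' @return object of class `trained_classifier`.
#' @export
train_baselines <- function(X, y, spec) {
  y01 <- to_y01(y)
  fit <- switch(
    spec$family,
    nb = {
      check_train_input(X, y01)
      by_class <- lapply(c(0, 1), function(cl) {
        Xc <- X[y01 == cl, , drop = FALSE]
        list(mean = colMeans(Xc),
             var = apply(Xc, 2, stats::var) + 1e-9,
             prior = nrow(Xc) / nrow(X))
      })
      list(s = by_class[[1]], l = by_class[[2]])
    },
    logreg = {
      check_train_input(X, y01)
      g <- suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y01,
                       family = stats::binomial()))
      list(coef = g$coefficients)
    },
    zeror = {
      n_l <- sum(y01 == 1); n_s <- sum(y01 == 0)
      list(majority = if (n_l >= n_s) "L" else "S", tied = n_l == n_s)
    },
    {
      plugin <- get0(spec$family, envir = .classifier_registry)
      if (is.null(plugin))
        stop(sprintf("unknown classifier family '%s'", spec$family), call. = FALSE)
      list(plugin = plugin$train(X, y01, spec))
    }
  )
  if (identical(spec$family, "zeror") && isTRUE(fit$tied))
    warning("tied majority; breaking to L", call. = FALSE)
  structure(c(list(spec = spec, family = spec$family,
                   features = colnames(X), threshold = spec$threshold),
              fit),
            class = "trained_classifier")
}

#' Train any registered classifier
#'
#' Dispatches on the spec's family; all families obey the same contract
#' (train on X/y, emit L-probability scores, deterministic given spec).
#'
#' @inheritParams train_klr
#' @param spec a [classifier_spec()].
#' @return a `trained_classifier`.
#' @export
train_classifier <- function(X, y, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$family == "klr") train_klr(X, y, spec) else train_baselines(X, y, spec)
}

#' Tune KLR hyperparameters by inner cross-validation
#'
#' Grid search over kernel bandwidth and ridge penalty, scored by the
#' mean held-out log-likelihood of an inner stratified k-fold CV on the
#' training split. The winning spec can be passed to [train_klr()] or
#' frozen into a signature model.
#'
#' @param X normalized training matrix (no missing values).
#' @param y factor S/L.
#' @param gammas candidate RBF bandwidths; default scales the median
#'   heuristic by (0.5, 1, 2). Ignored for the linear kernel.
#' @param lambdas candidate ridge penalties.
#' @param kernel `"rbf"` or `"linear"`.
#' @param k inner folds.
#' @param seed integer seed for the fold assignment.
#' @return list with `spec` (the winning [classifier_spec()]) and `grid`
#'   (data.frame of all combinations with their CV log-likelihood).
#' @export
tune_klr <- function(X, y, gammas = NULL, lambdas = c(1e-3, 1e-2, 1e-1),
                     kernel = "rbf", k = 5, seed = 1L) {
  y <- factor(y, levels = c("S", "L"))
  if (is.null(gammas))
    gammas <- if (kernel == "rbf") median_heuristic_gamma(X) * c(0.5, 1, 2) else NA
  folds <- stratified_folds(y, k, seed)
  y01 <- to_y01(y)
  grid <- expand.grid(gamma = gammas, lambda = lambdas)
  grid$loglik <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- classifier_spec("klr", kernel = kernel,
                            gamma = if (kernel == "rbf") grid$gamma[i] else NULL,
                            lambda = grid$lambda[i])
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- train_klr(X[tr, , drop = FALSE], y[tr], spec)
      scores[!tr] <- predict_score(m, X[!tr, , drop = FALSE])
    }
    sc <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    mean(y01 * log(sc) + (1 - y01) * log(1 - sc))
  }, numeric(1))
  best <- which.max(grid$loglik)
  list(spec = classifier_spec("klr", kernel = kernel,
                              gamma = if (kernel == "rbf") grid$gamma[best] else NULL,
                              lambda = grid$lambda[best]),
       grid = grid)
}

to_y01 <- function(y) {
  if (is.factor(y)) as.integer(y == "L")
  else if (all(y %in% c(0, 1))) as.integer(y)
  else stop_field("y", "must be a factor with levels S/L or a 0/1 vector")
}

check_train_input <- function(X, y01) {
  if (anyNA(X)) stop_field("X", "missing values are not allowed; impute first")
  if (min(table(factor(y01, levels = 0:1))) < 2)
    stop_field("y", "need at least 2 patients per class")
}

#' Predict L-class probability scores
#'
#' @param model a `trained_classifier`.
#' @param X matrix whose columns exactly match the model's training
#'   feature list (same order).
#' @return numeric vector of scores in [0, 1]; thresholding at
#'   `model$threshold` gives class labels (see [predict_class()]).
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model$features)) {
    missing_f <- setdiff(model$features, colnames(X))
    extra_f <- setdiff(colnames(X), model$features)
    if (length(missing_f) || length(extra_f) ||
        !identical(colnames(X), model$features))
      stop(sprintf("feature mismatch (missing: %s; extra: %s; order must match)",
                   paste(missing_f, collapse = ",") %||% "",
                   paste(extra_f, collapse = ",")), call. = FALSE)
  }
  switch(
    model$family,
    klr = {
      Knew <- kernel_matrix(X, model$X_train, model$spec$kernel, model$gamma)
      stats::plogis(as.vector(Knew %*% model$alpha) + model$intercept)
    },
    nb = {
      ll <- function(cls) {
        rowSums(sweep(-0.5 * sweep(sweep(X, 2, cls$mean, "-")^2,
                                   2, cls$var, "/"),
                      2, 0.5 * log(2 * pi * cls$var), "-")) + log(cls$prior)
      }
      stats::plogis(ll(model$l) - ll(model$s))
    },
    logreg = stats::plogis(as.vector(cbind(1, X) %*% model$coef)),
    zeror = rep(if (model$majority == "L") 1 else 0, nrow(X)),
    {
      plugin <- get0(model$family, envir = .classifier_registry)
      plugin$predict(model$plugin, X)
    }
  )
}

#' Predict hard class labels
#'
#' @param model a `trained_classifier`.
#' @param X feature matrix.
#' @param threshold decision threshold (defaults to the model's).
#' @return factor with levels c("S","L").
#' @export
predict_class <- function(model, X, threshold = NULL) {
  thr <- threshold %||% model$threshold
  factor(ifelse(predict_score(model, X) >= thr, "L", "S"),
         levels = c("S", "L"))
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("Trained", toupper(x$family), "classifier on",
      length(x$features), "feature(s); threshold", x$threshold, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# signature model: selected features + frozen preprocessing + classifier

#' Train a signature model (features + preprocessing + classifier)
#'
#' Bundles a selected feature subset with a preprocessing plan fitted on
#' the training split only (missingness filter, median imputation,
#' min-max bounds) and a trained classifier, plus provenance (selection
#' method, seed, training-cohort hash) so external evaluations can assert
#' the model was never refit.
#'
#' @param X_raw raw training values matrix (patients x all features).
#' @param y training labels (factor S/L).
#' @param features selected feature ids.
#' @param spec a [classifier_spec()].
#' @param selection_method,seed provenance fields.
#' @return object of class `signature_model`.
#' @export
train_signature_model <- function(X_raw, y, features,
                                  spec = classifier_spec("klr"),
                                  selection_method = "manual", seed = NA) {
  stopifnot(length(features) >= 1, all(features %in% colnames(X_raw)))
  prep <- fit_preprocess(X_raw[, features, drop = FALSE], max_missing = 0.2)
  Xn <- apply_preprocess(prep, X_raw)
  clf <- train_classifier(Xn, y, spec)
  structure(list(features = prep$features, preprocess = prep,
                 classifier = clf, spec = spec,
                 selection_method = selection_method, seed = seed,
                 train_hash = content_hash(list(rownames(X_raw), features))),
            class = "signature_model")
}

#' Score new patients with a signature model
#'
#' @param model a [train_signature_model()] result.
#' @param X_raw raw values matrix containing the model's features.
#' @return numeric L-probability scores.
#' @export
predict_signature <- function(model, X_raw) {
  stopifnot(inherits(model, "signature_model"))
  Xn <- apply_preprocess(model$preprocess, X_raw)
  predict_score(model$classifier, Xn)
}

#' Serialize a signature model to versioned JSON
#'
#' @param model a `signature_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_signature_model <- function(model, path) {
  clf <- model$classifier
  art <- list(
    format_version = 1L,
    family = clf$family,
    features = model$features,
    selection_method = model$selection_method,
    seed = model$seed,
    threshold = clf$threshold,
    preprocess = list(medians = as.list(model$preprocess$medians),
                      lo = as.list(model$preprocess$lo),
                      hi = as.list(model$preprocess$hi)),
    parameters = switch(clf$family,
      klr = list(kernel = clf$spec$kernel, gamma = clf$gamma,
                 lambda = clf$spec$lambda, alpha = clf$alpha,
                 intercept = clf$intercept,
                 support = as.data.frame(clf$X_train)),
      nb = list(s = clf$s, l = clf$l),
      logreg = list(coef = as.list(clf$coef)),
      zeror = list(majority = clf$majority),
      list())
  )
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
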