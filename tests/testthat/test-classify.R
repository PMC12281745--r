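test_that("linear KLR with vanishing penalty matches logistic regression", {
  set.seed(1)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y01 <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  y <- factor(ifelse(y01 == 1, "L", "S"), levels = c("S", "L"))
  klr <- train_klr(X, y, classifier_spec("klr", kernel = "linear",
                                         lambda = 1e-8))
  glm_fit <- glm(y01 ~ X, family = binomial())
  p_glm <- unname(fitted(glm_fit))
  p_klr <- predict_score(klr, X)
  expect_lt(max(abs(p_klr - p_glm)), 1e-3)
})

test_that("KLR objective is non-increasing and duplication-invariant", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("S", "L"), 10), levels = c("S", "L"))
  m <- train_klr(X, y, classifier_spec("klr", lambda = 1e-2))
  expect_true(all(diff(m$objective_trace) <= 1e-12))
  expect_true(m$converged)
  # duplicating every training point leaves the decision function alone
  Xd <- rbind(X, X); yd <- factor(c(as.character(y), as.character(y)),
                                  levels = c("S", "L"))
  md <- train_klr(Xd, yd, classifier_spec("klr", gamma = m$gamma,
                                          lambda = 1e-2))
  grid <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_score(m, grid), predict_score(md, grid),
               tolerance = 1e-6)
})

test_that("RBF kernel solves XOR where the linear kernel cannot", {
  set.seed(3)
  X <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1)))
  X <- X[rep(1:4, each = 10), ] + matrix(rnorm(80, sd = 0.05), 40, 2)
  colnames(X) <- c("x", "y")
  lab <- factor(ifelse(xor(round(X[, 1]), round(X[, 2])) == 1, "L", "S"),
                levels = c("S", "L"))
  rbf <- train_klr(X, lab, classifier_spec("klr", kernel = "rbf",
                                           gamma = 5, lambda = 1e-4))
  lin <- train_klr(X, lab, classifier_spec("klr", kernel = "linear",
                                           lambda = 1e-4))
  acc <- function(m) mean(predict_class(m, X) == lab)
  expect_equal(acc(rbf), 1)
  expect_lte(acc(lin), 0.75)
})

test_that("label swap reflects KLR scores around one half", {
  set.seed(11)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("S", "L"), 15), levels = c("S", "L"))
  y_sw <- factor(ifelse(y == "L", "S", "L"), levels = c("S", "L"))
  spec <- classifier_spec("klr", gamma = 1, lambda = 1e-2)
  m1 <- train_klr(X, y, spec)
  m2 <- train_klr(X, y_sw, spec)
  expect_equal(predict_score(m1, X) + predict_score(m2, X),
               rep(1, 30), tolerance = 1e-6)
})

test_that("KLR scores rise monotonically toward the long-class centroid", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, -1), 20, 2), matrix(rnorm(40, 1), 20, 2))
  colnames(X) <- c("a", "b")
  y <- factor(rep(c("S", "L"), each = 20), levels = c("S", "L"))
  m <- train_klr(X, y, classifier_spec("klr", gamma = 0.5, lambda = 1e-2))
  path <- sapply(seq(-1, 1, length.out = 9), function(t)
    predict_score(m, matrix(c(t, t), 1, 2,
                            dimnames = list(NULL, c("a", "b")))))
  expect_true(all(diff(path) > -1e-9))
})

test_that("naive Bayes recovers the closed-form decision boundary", {
  set.seed(9)
  n <- 2000
  X <- matrix(c(rnorm(n / 2, 0), rnorm(n / 2, 2)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("S", "L"), each = n / 2), levels = c("S", "L"))
  m <- train_baselines(X, y, classifier_spec("nb"))
  s <- predict_score(m, X)
  # boundary: x where P(L)=0.5, theoretically at 1.0
  bnd <- X[which.min(abs(s - 0.5)), 1]
  expect_lt(abs(bnd - 1), 0.1)
})

test_that("logistic regression separates separable toy data", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), 6, 1, dimnames = list(NULL, "f"))
  y <- factor(c("S", "S", "S", "L", "L", "L"), levels = c("S", "L"))
  m <- train_baselines(X, y, classifier_spec("logreg"))
  expect_equal(as.character(predict_class(m, X)), as.character(y))
})

test_that("ZeroR predicts the training majority, breaking ties to L", {
  y <- factor(rep(c("S", "L"), c(32, 34)), levels = c("S", "L"))
  X <- matrix(0, 66, 1, dimnames = list(NULL, "f"))
  m <- train_baselines(X, y, classifier_spec("zeror"))
  expect_equal(m$majority, "L")
  expect_equal(predict_score(m, matrix(0, 5, 1, dimnames = list(NULL, "f"))),
               rep(1, 5))
  y_tie <- factor(rep(c("S", "L"), 5), levels = c("S", "L"))
  expect_warning(mt <- train_baselines(matrix(0, 10, 1,
                                              dimnames = list(NULL, "f")),
                                       y_tie, classifier_spec("zeror")),
                 "tied")
  expect_equal(mt$majority, "L")
})

test_that("prediction demands the exact training feature list", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("S", "L"), 5), levels = c("S", "L"))
  m <- train_klr(X, y, classifier_spec("klr", lambda = 1e-2))
  bad <- X; colnames(bad) <- c("a", "c")
  expect_error(predict_score(m, bad), "feature mismatch")
  expect_error(predict_score(m, X[, c("b", "a")]), "feature mismatch")
})

test_that("plugin families register into the shared contract", {
  register_classifier("meanvote",
    train = function(X, y01, spec) list(mu1 = colMeans(X[y01 == 1, , drop = FALSE]),
                                        mu0 = colMeans(X[y01 == 0, , drop = FALSE])),
    predict = function(fit, X) {
      d1 <- rowSums(sweep(X, 2, fit$mu1)^2)
      d0 <- rowSums(sweep(X, 2, fit$mu0)^2)
      as.numeric(d1 < d0)
    })
  X <- matrix(c(rnorm(20, -1), rnorm(20, 1)), 40, 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("S", "L"), each = 20), levels = c("S", "L"))
  m <- train_classifier(X, y, classifier_spec("meanvote"))
  expect_gt(mean(predict_score(m, X) == (y == "L")), 0.8)
})

test_that("hyperparameter tuning prefers sensible penalties on real signal", {
  fc <- simulate_feature_cohort(n_patients = 60, n_long = 30,
                                n_informative = 4, n_noise = 2, d = 1.5,
                                seed = 17)
  tn <- tune_klr(fc$X, fc$y, lambdas = c(1e-2, 1e3), k = 5, seed = 1)
  # an absurdly strong penalty (flat scores) must lose to a mild one
  expect_equal(tn$spec$lambda, 1e-2)
  expect_equal(nrow(tn$grid), 6)
  expect_true(all(is.finite(tn$grid$loglik)))
})

test_that("signature models freeze preprocessing and serialize to JSON", {
  fc <- simulate_feature_cohort(n_patients = 40, n_long = 20,
                                n_informative = 3, n_noise = 5, d = 2,
                                seed = 13)
  m <- train_signature_model(fc$X, fc$y, fc$informative,
                             classifier_spec("klr", lambda = 1e-2),
                             selection_method = "manual", seed = 13)
  s <- predict_signature(m, fc$X)
  expect_true(all(s >= 0 & s <= 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(m, path)
  art <- jsonlite::read_json(path)
  expect_equal(art$family, "klr")
  expect_equal(unlist(art$features), fc$informative, ignore_attr = TRUE)
})
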