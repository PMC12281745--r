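test_that("ROC-AUC equals the pairwise concordance oracle exactly", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    y01 <- rbinom(n, 1, 0.5)
    if (length(unique(y01)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    y <- factor(ifelse(y01 == 1, "L", "S"), levels = c("S", "L"))
    m <- compute_metrics(y, scores)
    expect_equal(m$roc_auc, auc_oracle(y01, scores), tolerance = 1e-12)
  }
})

test_that("Youden threshold matches the exhaustive scan oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y01 <- rbinom(n, 1, 0.5)
    if (length(unique(y01)) < 2) next
    scores <- round(runif(n), 2)
    y <- factor(ifelse(y01 == 1, "L", "S"), levels = c("S", "L"))
    yd <- youden_threshold(y, scores)
    expect_equal(yd$J, youden_oracle(y01, scores), tolerance = 1e-12)
  }
  # perfect separation gives J = 1
  y <- factor(rep(c("S", "L"), each = 5), levels = c("S", "L"))
  expect_equal(youden_threshold(y, c(1:5 / 10, 6:10 / 10))$J, 1)
})

test_that("permuted labels keep the Youden index small", {
  set.seed(29)
  Js <- replicate(20, {
    y <- factor(sample(rep(c("S", "L"), 50)), levels = c("S", "L"))
    youden_threshold(y, runif(100))$J
  })
  expect_lt(median(Js), 0.35)
})

test_that("class-averaged metrics reproduce the majority-baseline identity", {
  # majority-L baseline on an imbalanced 20 S / 10 L set
  y <- factor(rep(c("S", "L"), c(20, 10)), levels = c("S", "L"))
  m <- compute_metrics(y, rep(1, 30), threshold = 0.5)
  expect_equal(m$accuracy, 100 * 10 / 30, tolerance = 1e-9)
  expect_equal(m$sensitivity, 0.5)       # balanced accuracy of a constant
  # and on the 17 S / 13 L composition
  y2 <- factor(rep(c("S", "L"), c(17, 13)), levels = c("S", "L"))
  expect_equal(compute_metrics(y2, rep(1, 30))$accuracy, 100 * 13 / 30,
               tolerance = 1e-9)
  # perfect scores: everything 1
  y3 <- factor(rep(c("S", "L"), 5), levels = c("S", "L"))
  s3 <- as.numeric(y3 == "L")
  m3 <- compute_metrics(y3, s3)
  expect_equal(m3$accuracy, 100)
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$mcc, 1)
  expect_equal(m3$roc_auc, 1)
})

test_that("averaged accuracy is plain accuracy and avg sensitivity is balanced accuracy", {
  set.seed(31)
  y <- factor(sample(rep(c("S", "L"), c(30, 20))), levels = c("S", "L"))
  s <- runif(50)
  m <- compute_metrics(y, s, 0.4)
  y01 <- as.integer(y == "L")
  pred <- as.integer(s >= 0.4)
  expect_equal(m$accuracy, 100 * mean(pred == y01))
  bal <- (mean(pred[y01 == 1] == 1) + mean(pred[y01 == 0] == 0)) / 2
  expect_equal(m$sensitivity, bal)
  # AUC symmetry: treating S as positive without reversing scores
  # complements the L-positive AUC (scores are tie-free here)
  rl <- pbmcsig:::roc_points(y01, s)
  rs <- pbmcsig:::roc_points(1 - y01, s)
  expect_equal(pbmcsig:::trapezoid_auc(rl$fpr, rl$tpr) +
                 pbmcsig:::trapezoid_auc(rs$fpr, rs$tpr), 1,
               tolerance = 1e-12)
})

test_that("calibration bins conserve counts and track simulated truth", {
  set.seed(37)
  n <- 2000
  s <- runif(n)
  y <- factor(ifelse(rbinom(n, 1, s) == 1, "L", "S"), levels = c("S", "L"))
  cal <- calibration_curve(y, s, n_bins = 10)
  expect_equal(sum(cal$count), n)
  expect_lt(max(abs(cal$mean_score - cal$observed), na.rm = TRUE), 0.1)
  # constant score occupies a single bin near its value
  cal2 <- calibration_curve(factor(rep(c("S", "L"), 50), levels = c("S", "L")),
                            rep(0.5, 100), n_bins = 10)
  expect_equal(sum(cal2$count > 0), 1)
  expect_equal(cal2$observed[cal2$count > 0], 0.5)
})

test_that("repeated CV is calibrated on null data and perfect on separable data", {
  # separable
  fc <- simulate_feature_cohort(n_patients = 40, n_long = 20,
                                n_informative = 2, n_noise = 2, d = 8,
                                seed = 41)
  cv <- repeated_cv(fc$X, fc$y, classifier_spec("klr", lambda = 1e-3),
                    k = 5, repeats = 3, seed = 1)
  expect_equal(cv$per_replicate$accuracy, rep(100, 3))
  # label permutation: median ROC-AUC near chance
  fc0 <- simulate_feature_cohort(n_patients = 60, n_long = 30,
                                 n_informative = 0, n_noise = 10, d = 0,
                                 seed = 43)
  cv0 <- repeated_cv(fc0$X, fc0$y, classifier_spec("klr"), k = 5,
                     repeats = 10, seed = 2)
  med_auc <- cv0$summary$median[cv0$summary$metric == "roc_auc"]
  expect_gt(med_auc, 0.35)
  expect_lt(med_auc, 0.65)
})

test_that("bootstrap validation concentrates near plain validation", {
  fc <- simulate_feature_cohort(n_patients = 82, n_long = 42,
                                n_informative = 5, n_noise = 20, d = 1.2,
                                seed = 47)
  classes <- fc$y; names(classes) <- rownames(fc$X)
  sp <- split_train_validation(classes, 0.8, seed = 3)
  m <- train_signature_model(fc$X[sp$train, ], classes[sp$train],
                             fc$informative, classifier_spec("klr"),
                             seed = 3)
  m$train_ids <- sp$train
  plain <- evaluate_external(m, fc$X[sp$validation, ],
                             classes[sp$validation], train_ids = sp$train)
  boot <- bootstrap_validate(m, fc$X[sp$validation, ],
                             classes[sp$validation], B = 10, seed = 5,
                             train_ids = sp$train)
  acc_plain <- plain$per_replicate$accuracy
  acc_boot <- boot$summary$median[boot$summary$metric == "accuracy"]
  expect_lt(abs(acc_boot - acc_plain), 15)
  # constant-score degenerate model: AUC 0.5 every resample
  z <- train_signature_model(fc$X[sp$train, ], classes[sp$train],
                             fc$informative, classifier_spec("zeror"))
  bz <- bootstrap_validate(z, fc$X[sp$validation, ],
                           classes[sp$validation], B = 5, seed = 7)
  expect_true(all(bz$per_replicate$roc_auc == 0.5))
  # leakage audit: overlapping patients are rejected
  expect_error(bootstrap_validate(m, fc$X[sp$train[1:10], ],
                                  classes[sp$train[1:10]], B = 2, seed = 1,
                                  train_ids = sp$train),
               "overlaps")
})

test_that("external evaluation never refits the frozen model", {
  fc <- simulate_feature_cohort(n_patients = 50, n_long = 25,
                                n_informative = 3, n_noise = 5, d = 1.5,
                                seed = 53)
  classes <- fc$y; names(classes) <- rownames(fc$X)
  m <- train_signature_model(fc$X[1:40, ], classes[1:40], fc$informative,
                             classifier_spec("klr"))
  before <- m$preprocess
  r <- evaluate_external(m, fc$X[41:50, ], classes[41:50])
  expect_identical(m$preprocess, before)
  expect_equal(r$model_hash, m$train_hash)
  expect_equal(sum(r$per_replicate[, c("tp", "fp", "tn", "fn")]), 10)
})
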