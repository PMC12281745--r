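test_that("arcsinh transform is exact, channel-selective and invertible", {
  em <- simulate_events(c(popA = 0.5, popB = 0.5), tiny_panel(), 500,
                        populations = tiny_populations(), seed = 1)
  expect_error(transform_arcsinh(em, cofactor = 0), "cofactor")
  emt <- transform_arcsinh(em, 150)
  # closed forms
  expect_equal(asinh(0), 0)
  expect_equal(asinh(150 / 150), 0.881373587, tolerance = 1e-8)
  # scatter untouched, fluorescence transformed
  expect_identical(unclass(emt)[, "FSC-A"], unclass(em)[, "FSC-A"])
  expect_equal(unclass(emt)[, "M1"], asinh(unclass(em)[, "M1"] / 150))
  # round trip
  back <- inverse_arcsinh(emt)
  expect_equal(unclass(back), unclass(em), tolerance = 1e-9)
})

test_that("sequential pre-gating removes injected junk and reports steps", {
  em <- simulate_events(c(popA = 0.5, popB = 0.5), tiny_panel(), 20000,
                        populations = tiny_populations(),
                        doublet_rate = 0.05, seed = 3)
  pg <- pregate(em)
  surv <- nrow(pg$events) / nrow(em)
  expect_lt(abs(surv - 0.95), 0.02)
  expect_equal(pg$report$step, c("debris_exclusion", "doublet_exclusion"))
  # rules disabled: identity
  pg0 <- pregate(em, pregate_rules(debris = NULL, doublet = NULL))
  expect_equal(nrow(pg0$events), nrow(em))
  # all-debris sample: empty gate flagged, no error
  junk <- simulate_events(c(popA = 1, popB = 0), tiny_panel(), 200,
                          populations = tiny_populations(), seed = 4)
  junk_m <- unclass(junk)
  junk_m[, "FSC-A"] <- 100; junk_m[, "SSC-A"] <- 50
  pg_j <- pregate(event_matrix(junk_m, tiny_panel()))
  expect_equal(nrow(pg_j$events), 0)
  expect_true(attr(pg_j$report, "empty"))
})

test_that("manual gates emit parent-relative frequencies and medians", {
  em <- simulate_events(c(popA = 0.3, popB = 0.7), tiny_panel(), 20000,
                        populations = tiny_populations(), seed = 6)
  emt <- transform_arcsinh(em, 150)
  # gate at the true boundary between the planted means (1 vs 4)
  tree <- gating_tree(
    gate_node("all", NULL, "M1", lo = -Inf, hi = Inf),
    gate_node("A_like", "all", "M1", lo = -Inf, hi = 2.5, terminal = TRUE),
    gate_node("B_like", "all", "M1", lo = 2.5, hi = Inf))
  fr <- apply_manual_gates(emt, tree)
  freqs <- fr$value[fr$kind == "frequency"]
  expect_equal(freqs[fr$gate[fr$kind == "frequency"] == "all"], 100)
  expect_lt(abs(freqs[2] - 30), 1.5)
  expect_lt(abs(freqs[3] - 70), 1.5)
  # child never exceeds parent; event order irrelevant
  expect_true(all(freqs <= 100))
  perm <- pbmcsig:::em_keep(emt, sample(nrow(emt)))
  fr2 <- apply_manual_gates(perm, tree)
  expect_equal(fr2$value, fr$value)
  # median features reported on the transformed scale for terminal gates
  expect_true(any(fr$kind == "median_intensity"))
  med_m1 <- fr$value[fr$feature_id == "PPEP.MG.T1.A_like.med_M1"]
  expect_equal(med_m1, 1, tolerance = 0.1)
})

test_that("empty parents propagate missing frequencies, not zeros", {
  em <- simulate_events(c(popA = 1, popB = 0), tiny_panel(), 500,
                        populations = tiny_populations(), seed = 2)
  emt <- transform_arcsinh(em, 150)
  tree <- gating_tree(
    gate_node("none", NULL, "M1", lo = 100, hi = Inf),
    gate_node("child", "none", "M2", lo = -Inf, hi = Inf))
  fr <- apply_manual_gates(emt, tree)
  expect_equal(fr$value[fr$gate == "none"], 0)
  expect_true(is.na(fr$value[fr$gate == "child"]))
})

test_that("HyperGating recovers planted components and stays deterministic", {
  samples <- lapply(1:4, function(i)
    transform_arcsinh(simulate_events(c(popA = 0.4, popB = 0.6),
                                      tiny_panel(), 1500,
                                      populations = tiny_populations(),
                                      seed = i), 150))
  m <- fit_hypergates(samples, k_grid = 2:5, seed = 7,
                      events_per_sample = 1000)
  expect_equal(m$k, 2)
  m2 <- fit_hypergates(samples, k_grid = 2:5, seed = 7,
                       events_per_sample = 1000)
  expect_equal(m$parameters$mean, m2$parameters$mean, tolerance = 1e-12)
  # down-sampling fairness: pooled fit uses equal counts per sample
  expect_equal(m$events_per_sample, 1000)
  # assignment: frequencies partition to 100 and match planted weights
  fr <- assign_hypergates(samples[[1]], m)
  freqs <- fr$value[fr$kind == "frequency"]
  expect_equal(sum(freqs), 100, tolerance = 1e-9)
  expect_equal(sort(freqs), c(40, 60), tolerance = 0.04 * 100)
  # sample drawn purely from one component concentrates in one cluster
  pure <- transform_arcsinh(simulate_events(c(popA = 1, popB = 0),
                                            tiny_panel(), 2000,
                                            populations = tiny_populations(),
                                            seed = 11), 150)
  frp <- assign_hypergates(pure, m)
  expect_gt(max(frp$value[frp$kind == "frequency"]), 95)
})

test_that("model selection finds four well-separated planted populations", {
  pops4 <- list(
    p1 = list(channel_means = c(M1 = 0.3, M2 = 0.3), channel_sds = c(M1 = 0.3, M2 = 0.3),
              base_frequency = 0.25, scatter_profile = c(fsc = 5e4, ssc = 3e4)),
    p2 = list(channel_means = c(M1 = 4, M2 = 0.3), channel_sds = c(M1 = 0.3, M2 = 0.3),
              base_frequency = 0.25, scatter_profile = c(fsc = 5e4, ssc = 3e4)),
    p3 = list(channel_means = c(M1 = 0.3, M2 = 4), channel_sds = c(M1 = 0.3, M2 = 0.3),
              base_frequency = 0.25, scatter_profile = c(fsc = 5e4, ssc = 3e4)),
    p4 = list(channel_means = c(M1 = 4, M2 = 4), channel_sds = c(M1 = 0.3, M2 = 0.3),
              base_frequency = 0.25, scatter_profile = c(fsc = 5e4, ssc = 3e4)))
  prof <- c(p1 = 0.25, p2 = 0.25, p3 = 0.25, p4 = 0.25)
  hits <- vapply(1:5, function(s) {
    samples <- lapply(1:3, function(i)
      transform_arcsinh(simulate_events(prof, tiny_panel(), 1200,
                                        populations = pops4,
                                        seed = 50 * s + i), 150))
    fit_hypergates(samples, k_grid = 2:8, seed = s,
                   events_per_sample = 800)$k
  }, numeric(1))
  expect_gte(mean(hits == 4), 0.8)
})

test_that("HyperGating agrees with an independent EM oracle on 1D mixtures", {
  # 2-component, 1-channel mixture; oracle: hand-coded EM
  set.seed(31)
  n <- 4000
  z <- rbinom(n, 1, 0.35)
  x <- ifelse(z == 1, rnorm(n, 3, 0.5), rnorm(n, 0, 0.5))
  em_oracle <- function(x, iters = 300) {
    mu <- c(min(x), max(x)); s <- c(sd(x), sd(x)); pi1 <- 0.5
    for (i in seq_len(iters)) {
      d1 <- pi1 * dnorm(x, mu[2], s[2])
      d0 <- (1 - pi1) * dnorm(x, mu[1], s[1])
      r <- d1 / (d1 + d0)
      pi1 <- mean(r)
      mu <- c(sum((1 - r) * x) / sum(1 - r), sum(r * x) / sum(r))
      s <- sqrt(c(sum((1 - r) * (x - mu[1])^2) / sum(1 - r),
                  sum(r * (x - mu[2])^2) / sum(r)))
    }
    mean(r > 0.5)
  }
  frac_oracle <- em_oracle(x)
  # wrap x as a one-fluorescence-channel event matrix
  pan <- panel_schema("X", data.frame(
    name = c("FSC-A", "FSC-H", "SSC-A", "M1"),
    role = c("scatter_a", "scatter_h", "side_scatter", "fluorescence"),
    marker = c(NA, NA, NA, "M1"), stringsAsFactors = FALSE))
  mat <- cbind(`FSC-A` = 5e4, `FSC-H` = 5e4, `SSC-A` = 3e4, M1 = x)
  ems <- list(event_matrix(mat[1:2000, ], pan), event_matrix(mat[2001:4000, ], pan))
  ems <- lapply(ems, function(e) { attr(e, "transformed") <- TRUE; e })
  m <- fit_hypergates(ems, k_grid = 2, seed = 1, events_per_sample = 2000)
  fr <- assign_hypergates(ems[[1]], m)
  freqs <- sort(fr$value[fr$kind == "frequency"]) / 100
  expect_lt(abs(freqs[1] - min(frac_oracle, 1 - frac_oracle)), 0.01)
})

test_that("panel and event-matrix validation catch malformed input", {
  expect_error(panel_schema("P", data.frame(name = c("a", "a"),
                                            role = c("scatter_a", "side_scatter"),
                                            marker = NA)), "unique")
  bad <- matrix(1, 2, 5, dimnames = list(NULL, c("x", "y", "z", "u", "v")))
  expect_error(event_matrix(bad, tiny_panel()), "channels")
})
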