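# Synthetic PBMC cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# per-patient event-level cytometry mixtures containing the signature
# populations (CXCR3+ pDC-like, CD62P-bright platelet-aggregate-like,
# exhausted-CD8-like, activated-CXCR3+-T-like, CD4/CD8/CXCR3+CD8 T cells),
# class-dependent population frequencies with configurable standardized
# effect sizes, Ct tables with a reference gene, log-normal clinical
# covariates, and outcome times drawn from a proportional-hazards model
# tied to the planted frequencies.

# ---------------------------------------------------------------------------
# panel / population defaults

#' Default reduced cytometry panel
#'
#' A single stand-in panel with three scatter channels and ten fluorescence
#' markers covering the populations the generator plants. Real studies use
#' several panels of ~19 markers; this schema is a deliberately reduced
#' stand-in, not a replication of any published panel table.
#'
#' @return a [panel_schema()] object.
#' @export
default_panel <- function() {
  panel_schema(
    panel_id = "P1",
    channels = data.frame(
      name = c("FSC-A", "FSC-H", "SSC-A",
               "CD45", "CD3", "CD4", "CD8", "CXCR3",
               "CD62P", "CD303", "CD69", "CD38", "PD1"),
      role = c("scatter_a", "scatter_h", "side_scatter",
               rep("fluorescence", 10)),
      marker = c(NA, NA, NA,
                 "CD45", "CD3", "CD4", "CD8", "CXCR3",
                 "CD62P", "CD303", "CD69", "CD38", "PD1"),
      stringsAsFactors = FALSE
    )
  )
}

# channel mean helper: named defaults (arcsinh scale), overridden per marker
.pop_means <- function(...) {
  m <- c(CD45 = 4.5, CD3 = 0.3, CD4 = 0.3, CD8 = 0.3, CXCR3 = 0.3,
         CD62P = 0.3, CD303 = 0.3, CD69 = 0.3, CD38 = 0.3, PD1 = 0.3)
  ov <- c(...)
  m[names(ov)] <- ov
  m
}

#' Default planted population specifications
#'
#' Eight leukocyte populations on the arcsinh intensity scale (cofactor
#' 150): roughly 0.3 for negative, 4 for positive and 6.5 for bright
#' markers. The CD62P-bright platelet-aggregate-like population has larger
#' scatter; all base frequencies sum to 1.
#'
#' @return named list of population specs (fields `channel_means`,
#'   `channel_sds`, `base_frequency`, `scatter_profile`).
#' @export
default_populations <- function() {
  sds <- function() rep(0.35, 10)
  mk <- function(means, freq, fsc, ssc) {
    list(channel_means = means,
         channel_sds = stats::setNames(sds(), names(means)),
         base_frequency = freq,
         scatter_profile = c(fsc = fsc, ssc = ssc))
  }
  list(
    HG1_pDC_CXCR3        = mk(.pop_means(CD303 = 4, CXCR3 = 4), 0.04, 55000, 35000),
    HG2_platelet_aggregate = mk(.pop_means(CD62P = 6.5, CD38 = 2.5), 0.06, 90000, 70000),
    HG3_exhausted_CD8    = mk(.pop_means(CD3 = 4, CD8 = 4, PD1 = 4), 0.07, 52000, 30000),
    HG4_activated_T      = mk(.pop_means(CD3 = 4, CD69 = 4, CD38 = 4, CXCR3 = 4), 0.08, 54000, 32000),
    CD4_T                = mk(.pop_means(CD3 = 4, CD4 = 4), 0.25, 50000, 28000),
    CD8_T                = mk(.pop_means(CD3 = 4, CD8 = 4), 0.15, 50000, 28000),
    CXCR3pos_CD8_T       = mk(.pop_means(CD3 = 4, CD8 = 4, CXCR3 = 4), 0.10, 51000, 29000),
    background           = mk(.pop_means(CD38 = 1.5), 0.25, 60000, 45000)
  )
}

#' Default planted class effect sizes
#'
#' Cohen's d of the long-class frequency shift per population. Directions
#' follow the biology the pipeline is built to detect: inflammatory
#' CXCR3-positive subsets and T cells up in long-outcome patients,
#' platelet-leukocyte aggregates and exhausted CD8 cells up in
#' short-outcome patients.
#'
#' @param d magnitude of the standardized shift (default 1.2).
#' @return named numeric vector (one entry per informative population).
#' @export
default_effect_sizes <- function(d = 1.2) {
  c(HG1_pDC_CXCR3 = d, HG2_platelet_aggregate = -d, HG3_exhausted_CD8 = -d,
    HG4_activated_T = d, CD4_T = d, CD8_T = d, CXCR3pos_CD8_T = d)
}

#' Default planted log hazard ratios
#'
#' Per unit min-max-normalized population frequency. The pDC-like
#' population is protective (hazard ratio 0.58); aggregates and exhausted
#' CD8 cells are adverse.
#'
#' @return named numeric vector of log hazard ratios.
#' @export
default_hazard_coefs <- function() {
  c(HG1_pDC_CXCR3 = log(0.58), HG2_platelet_aggregate = log(1.6),
    HG3_exhausted_CD8 = log(1.4), HG4_activated_T = log(0.7))
}

# ---------------------------------------------------------------------------
# spec

#' Specify a synthetic cohort
#'
#' Collects every generative parameter of the synthetic cohort: sample
#' size, class balance, population mixture, planted class effect sizes
#' (Cohen's d of the frequency shift), proportional-hazards coefficients,
#' censoring, qPCR and clinical table sizes, and the root seed.
#'
#' @param n_patients number of patients.
#' @param class_balance fraction of long-class patients, in (0,1).
#' @param populations named list of population specs
#'   (see [default_populations()]).
#' @param panels list of [panel_schema()] objects.
#' @param effect_sizes named vector, population -> Cohen's d of the
#'   long-class frequency shift.
#' @param hazard_coefs named vector, population -> log hazard ratio per
#'   unit min-max-normalized frequency.
#' @param baseline_hazard events per day for the failure-time model.
#' @param censor_rate independent censoring fraction, in [0,1).
#' @param n_events_per_sample cytometry events per patient and panel.
#' @param n_genes qPCR genes including the reference gene (>= 2).
#' @param n_clinical clinical covariates (>= 4: LDH, albumin, leukocyte
#'   count and CA19-9 plus fillers).
#' @param freq_sigma log-scale between-patient spread of population
#'   frequencies (the scale on which effect sizes are planted).
#' @param doublet_rate fraction of injected debris/doublet events.
#' @param cofactor arcsinh cofactor of the intensity scale.
#' @param ca19_9_direction sign of the weak CA19-9 class association
#'   (+1: higher in long class, -1: higher in short class, the default).
#' @param seed integer root seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 82,
                        class_balance = 42 / 82,
                        populations = default_populations(),
                        panels = list(default_panel()),
                        effect_sizes = default_effect_sizes(),
                        hazard_coefs = default_hazard_coefs(),
                        baseline_hazard = 1 / 150,
                        censor_rate = 0.15,
                        n_events_per_sample = 5000,
                        n_genes = 11,
                        n_clinical = 10,
                        freq_sigma = 0.25,
                        doublet_rate = 0.05,
                        cofactor = 150,
                        ca19_9_direction = -1,
                        seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop_field("n_patients", "must be a count >= 2")
  if (!(class_balance > 0 && class_balance < 1))
    stop_field("class_balance", "must lie strictly in (0,1)")
  if (!(censor_rate >= 0 && censor_rate < 1))
    stop_field("censor_rate", "must lie in [0,1)")
  if (baseline_hazard <= 0)
    stop_field("baseline_hazard", "must be positive")
  if (n_events_per_sample < 1)
    stop_field("n_events_per_sample", "must be a positive count")
  if (n_genes < 2)
    stop_field("n_genes", "needs at least a reference plus one target gene")
  if (n_clinical < 4)
    stop_field("n_clinical", "needs at least LDH, albumin, leukocyte, CA19-9")
  base <- vapply(populations, function(p) p$base_frequency, numeric(1))
  if (abs(sum(base) - 1) > 1e-8)
    stop_field("populations", "base frequencies must sum to 1")
  unknown <- setdiff(names(effect_sizes), names(populations))
  if (length(unknown))
    stop_field("effect_sizes", paste("unknown population(s):",
                                     paste(unknown, collapse = ", ")))
  unknown <- setdiff(names(hazard_coefs), names(populations))
  if (length(unknown))
    stop_field("hazard_coefs", paste("unknown population(s):",
                                     paste(unknown, collapse = ", ")))
  structure(list(
    n_patients = as.integer(n_patients), class_balance = class_balance,
    populations = populations, panels = panels,
    effect_sizes = effect_sizes, hazard_coefs = hazard_coefs,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    n_events_per_sample = as.integer(n_events_per_sample),
    n_genes = as.integer(n_genes), n_clinical = as.integer(n_clinical),
    freq_sigma = freq_sigma, doublet_rate = doublet_rate,
    cofactor = cofactor, ca19_9_direction = sign(ca19_9_direction),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_patients, "patients,",
      round(x$class_balance * 100), "% long class,",
      length(x$populations), "populations,",
      x$n_events_per_sample, "events/sample, seed", x$seed, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# frequencies

# Per-patient true population frequencies. Effects are planted on the log
# scale with spread `freq_sigma`; closing the composition (renormalizing
# to the simplex) adds shared denominator noise that would dilute the
# realized standardized difference by about
# sqrt(1 + sum(w^2) - 2*w_p) (w = base frequencies), so the planted
# shift is inflated by that factor and the realized Cohen's d of a
# population's frequency matches the requested value in expectation.
simulate_frequencies <- function(spec, classes, rng_seed) {
  pops <- names(spec$populations)
  base <- vapply(spec$populations, function(p) p$base_frequency, numeric(1))
  d <- stats::setNames(rep(0, length(pops)), pops)
  d[names(spec$effect_sizes)] <- spec$effect_sizes
  n <- length(classes)
  withr::with_seed(rng_seed, {
    z <- matrix(stats::rnorm(n * length(pops)), n, length(pops))
  })
  dilution <- sqrt(pmax(1 + sum(base^2) - 2 * base, 0.25))
  shift <- outer(ifelse(classes == "L", 0.5, -0.5),
                 d * dilution * spec$freq_sigma)
  logf <- matrix(log(base), n, length(pops), byrow = TRUE) +
    shift + z * spec$freq_sigma
  f <- exp(logf)
  f <- f / rowSums(f)
  colnames(f) <- pops
  f
}

# ---------------------------------------------------------------------------
# events

#' Simulate event-level cytometry data for one patient
#'
#' Draws `n_events` events from a Gaussian mixture on the arcsinh intensity
#' scale (component weights equal to the patient's population-frequency
#' profile) and maps fluorescence back to the raw scale; scatter channels
#' are filled from each population's scatter profile. The true component
#' of every event is kept in the `"component"` attribute so tests can
#' check recovery against the generator's truth.
#'
#' @param profile named frequency vector over populations (sums to 1).
#' @param panel a [panel_schema()].
#' @param n_events number of events to draw.
#' @param populations population spec list (see [default_populations()]).
#' @param cofactor arcsinh cofactor used for the raw-scale mapping.
#' @param doublet_rate fraction of events replaced by injected
#'   debris/doublets (distinct scatter signatures; component labels
#'   `"debris"` / `"doublet"`).
#' @param seed integer seed.
#' @return an [event_matrix()] with a `"component"` attribute.
#' @export
simulate_events <- function(profile, panel, n_events,
                            populations = default_populations(),
                            cofactor = 150, doublet_rate = 0, seed = 1L) {
  if (abs(sum(profile) - 1) > 1e-9)
    stop_field("profile", "frequencies must sum to 1")
  pops <- names(profile)
  chan <- panel$channels
  fluo <- chan$name[chan$role == "fluorescence"]
  for (p in pops) {
    missing_ch <- setdiff(fluo, names(populations[[p]]$channel_means))
    if (length(missing_ch))
      stop(sprintf("population %s lacks channel mean(s): %s",
                   p, paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  fsc_a <- chan$name[chan$role == "scatter_a"][1]
  fsc_h <- chan$name[chan$role == "scatter_h"][1]
  ssc   <- chan$name[chan$role == "side_scatter"][1]

  withr::with_seed(seed, {
    n_junk <- stats::rbinom(1, n_events, doublet_rate)
    n_real <- n_events - n_junk
    comp <- sample(pops, n_real, replace = TRUE, prob = profile)
    X <- matrix(NA_real_, n_events, nrow(chan),
                dimnames = list(NULL, chan$name))
    for (p in unique(comp)) {
      idx <- which(comp == p)
      ps <- populations[[p]]
      mu <- ps$channel_means[fluo]
      sd <- ps$channel_sds[fluo]
      Z <- matrix(stats::rnorm(length(idx) * length(fluo)),
                  length(idx), length(fluo))
      Z <- sweep(sweep(Z, 2, sd, "*"), 2, mu, "+")
      X[idx, fluo] <- cofactor * sinh(Z)
      sp <- ps$scatter_profile
      if (!is.na(fsc_a))
        X[idx, fsc_a] <- pmax(stats::rnorm(length(idx), sp["fsc"], 0.08 * sp["fsc"]), 1)
      if (!is.na(fsc_h)) # singlets: height tracks area closely
        X[idx, fsc_h] <- X[idx, fsc_a] * stats::rnorm(length(idx), 1, 0.03)
      if (!is.na(ssc))
        X[idx, ssc] <- pmax(stats::rnorm(length(idx), sp["ssc"], 0.1 * sp["ssc"]), 1)
    }
    comp_all <- c(comp, rep(NA_character_, n_junk))
    if (n_junk > 0) {
      jidx <- n_real + seq_len(n_junk)
      is_debris <- stats::runif(n_junk) < 0.5
      comp_all[jidx] <- ifelse(is_debris, "debris", "doublet")
      Z <- matrix(stats::rnorm(n_junk * length(fluo), 0.2, 0.3), n_junk, length(fluo))
      X[jidx, fluo] <- cofactor * sinh(Z)
      fa <- ifelse(is_debris,
                   stats::rnorm(n_junk, 5000, 1500),
                   stats::rnorm(n_junk, 110000, 10000))
      X[jidx, fsc_a] <- pmax(fa, 1)
      # doublets: area roughly twice height; debris keeps singlet ratio
      X[jidx, fsc_h] <- X[jidx, fsc_a] /
        ifelse(is_debris, stats::rnorm(n_junk, 1, 0.03), stats::rnorm(n_junk, 2, 0.1))
      X[jidx, ssc] <- pmax(ifelse(is_debris,
                                  stats::rnorm(n_junk, 3000, 1000),
                                  stats::rnorm(n_junk, 60000, 8000)), 1)
    }
    # shuffle event order so component blocks are not contiguous
    ord <- sample(n_events)
  })
  em <- event_matrix(X[ord, , drop = FALSE], panel)
  attr(em, "component") <- comp_all[ord]
  em
}

# ---------------------------------------------------------------------------
# outcomes

#' Simulate proportional-hazards outcome times
#'
#' Failure times are exponential with rate
#' `baseline_hazard * exp(sum(coef * feature))` where features are the
#' min-max-normalized planted frequencies; overall survival is the failure
#' time plus an independent Gamma-distributed follow-on so the two
#' endpoints correlate positively. Censoring is independent at the stated
#' rate (a censored patient is observed at a uniform fraction of the true
#' time).
#'
#' @param frequencies patients x populations matrix of true frequencies.
#' @param hazard_coefs named log hazard ratios (names must be populations).
#' @param baseline_hazard events/day.
#' @param censor_rate fraction in [0,1).
#' @param seed integer seed.
#' @return data.frame with `patient_id`, `ttf2_days`, `ttf2_event`,
#'   `os_days`, `os_event`.
#' @export
simulate_outcomes <- function(frequencies, hazard_coefs, baseline_hazard,
                              censor_rate = 0, seed = 1L) {
  if (baseline_hazard <= 0)
    stop_field("baseline_hazard", "must be positive")
  bad <- setdiff(names(hazard_coefs), colnames(frequencies))
  if (length(bad))
    stop_field("hazard_coefs", paste("unknown feature(s):",
                                     paste(bad, collapse = ", ")))
  n <- nrow(frequencies)
  Z <- apply(frequencies, 2, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  })
  lp <- if (length(hazard_coefs))
    as.vector(Z[, names(hazard_coefs), drop = FALSE] %*% hazard_coefs)
  else rep(0, n)
  withr::with_seed(seed, {
    ttf2 <- stats::rexp(n, rate = baseline_hazard * exp(lp))
    ext <- stats::rgamma(n, shape = 2, scale = 60)
    cens <- stats::runif(n) < censor_rate
    frac <- stats::runif(n)
  })
  os <- ttf2 + ext
  ttf2_obs <- ifelse(cens, ttf2 * frac, ttf2)
  os_obs <- ifelse(cens, ttf2_obs, os)
  data.frame(
    patient_id = rownames(frequencies) %||% sprintf("PT%03d", seq_len(n)),
    ttf2_days = ttf2_obs, ttf2_event = !cens,
    os_days = os_obs, os_event = !cens,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# qPCR and clinical tables

#' Simulate an RT-qPCR Ct table
#'
#' Gene-specific Ct baselines with one invariant reference gene (`"REF"`).
#' A subset of target genes is coupled to planted population frequencies:
#' a positive loading lowers Ct (more transcript) when the coupled
#' population's log frequency is high, so `2^-dCt` correlates positively
#' with that frequency.
#'
#' @param frequencies patients x populations true-frequency matrix.
#' @param n_genes total genes including the reference (>= 2).
#' @param couplings named list gene -> list(population, loading); defaults
#'   couple the first targets to activated-T and CXCR3+ CD8 populations.
#' @param seed integer seed.
#' @return data.frame `patient_id` + one Ct column per gene.
#' @export
simulate_qpcr <- function(frequencies, n_genes = 11, couplings = NULL,
                          seed = 1L) {
  if (n_genes < 2)
    stop_field("n_genes", "needs a reference plus one target")
  genes <- c("REF", sprintf("G%02d", seq_len(n_genes - 1)))
  if (is.null(couplings)) {
    couplings <- list()
    cand <- intersect(c("HG4_activated_T", "CXCR3pos_CD8_T", "HG1_pDC_CXCR3"),
                      colnames(frequencies))
    for (i in seq_along(cand))
      if (n_genes - 1 >= i)
        couplings[[genes[i + 1]]] <- list(population = cand[i], loading = 1.5)
  }
  n <- nrow(frequencies)
  withr::with_seed(seed, {
    base <- stats::setNames(stats::runif(n_genes, 20, 30), genes)
    base["REF"] <- 18
    ct <- matrix(stats::rnorm(n * n_genes, sd = 0.3), n, n_genes,
                 dimnames = list(NULL, genes))
  })
  ct <- sweep(ct, 2, base, "+")
  for (g in names(couplings)) {
    cp <- couplings[[g]]
    z <- scale(log(frequencies[, cp$population]))[, 1]
    ct[, g] <- ct[, g] - cp$loading * z
  }
  data.frame(patient_id = rownames(frequencies) %||% sprintf("PT%03d", seq_len(n)),
             ct, check.names = FALSE, stringsAsFactors = FALSE)
}

# Log-normal clinical covariates; CA19-9 gets a weak class association
# whose direction is configurable.
simulate_clinical <- function(classes, n_clinical = 10,
                              ca19_9_direction = -1, seed = 1L) {
  n <- length(classes)
  withr::with_seed(seed, {
    ldh <- stats::rlnorm(n, log(250), 0.3)
    alb <- stats::rlnorm(n, log(40), 0.1)
    leuk <- stats::rlnorm(n, log(7), 0.3)
    ca <- stats::rlnorm(n, log(500) + 0.3 * ca19_9_direction *
                          ifelse(classes == "L", 0.5, -0.5), 1)
    extra <- matrix(stats::rlnorm(n * max(0, n_clinical - 4), 0, 0.5),
                    nrow = n)
  })
  out <- data.frame(patient_id = names(classes) %||% sprintf("PT%03d", seq_len(n)),
                    LDH = ldh, albumin = alb, leukocyte = leuk, CA19_9 = ca,
                    stringsAsFactors = FALSE)
  if (ncol(extra) > 0) {
    colnames(extra) <- sprintf("covar%02d", seq_len(ncol(extra)))
    out <- cbind(out, extra)
  }
  out
}

# ---------------------------------------------------------------------------
# whole cohort

#' Simulate a complete synthetic cohort
#'
#' Generates, for each patient: a class label (long/short), true population
#' frequencies shifted by the planted effect sizes, one event matrix per
#' panel, a qPCR Ct row, a clinical row and proportional-hazards outcomes.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `patients`,
#'   `classes`, `events` (patient -> panel -> [event_matrix()]), `ct`,
#'   `clinical`, `outcomes`, `truth` (true frequency matrix) and
#'   `spec_used`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  n_long <- round(n * spec$class_balance)
  classes <- rep(c("S", "L"), c(n - n_long, n_long))
  withr::with_seed(derive_seed(spec$seed, 1L), classes <- sample(classes))
  ids <- sprintf("PT%03d", seq_len(n))
  names(classes) <- ids

  freq <- simulate_frequencies(spec, classes, derive_seed(spec$seed, 2L))
  rownames(freq) <- ids

  events <- vector("list", n)
  names(events) <- ids
  for (i in seq_len(n)) {
    events[[i]] <- lapply(spec$panels, function(pn)
      simulate_events(freq[i, ], pn, spec$n_events_per_sample,
                      populations = spec$populations,
                      cofactor = spec$cofactor,
                      doublet_rate = spec$doublet_rate,
                      seed = derive_seed(spec$seed, 100L + i)))
    names(events[[i]]) <- vapply(spec$panels, function(p) p$panel_id, character(1))
    for (pn in names(events[[i]]))
      attr(events[[i]][[pn]], "patient_id") <- ids[i]
  }

  outcomes <- simulate_outcomes(freq, spec$hazard_coefs, spec$baseline_hazard,
                                spec$censor_rate, derive_seed(spec$seed, 3L))
  ct <- simulate_qpcr(freq, spec$n_genes, seed = derive_seed(spec$seed, 4L))
  clinical <- simulate_clinical(classes, spec$n_clinical,
                                spec$ca19_9_direction,
                                derive_seed(spec$seed, 5L))

  structure(list(patients = ids, classes = classes, events = events,
                 ct = ct, clinical = clinical, outcomes = outcomes,
                 truth = freq, spec_used = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$patients), "patients (",
      sum(x$classes == "S"), "S /", sum(x$classes == "L"), "L ),",
      length(x$events[[1]]), "panel(s),",
      x$spec_used$n_events_per_sample, "events/sample\n")
  invisible(x)
}

#' Simulate a feature-level cohort with planted informative features
#'
#' A lightweight generator for studying the selection and classification
#' stages directly at the feature-table level: standard-normal noise
#' features plus `n_informative` features whose long-class mean is shifted
#' by `d` standard deviations (so the population Cohen's d equals `d`).
#'
#' @param n_patients,n_long cohort size and long-class count.
#' @param n_informative,n_noise planted and noise feature counts.
#' @param d Cohen's d of each planted feature.
#' @param seed integer seed.
#' @return list with `X` (patients x features matrix), `y` (factor S/L)
#'   and `informative` (planted feature names).
#' @export
simulate_feature_cohort <- function(n_patients = 82, n_long = 42,
                                    n_informative = 7, n_noise = 100,
                                    d = 1.2, seed = 1L) {
  stopifnot(n_long > 0, n_long < n_patients, n_informative >= 0, n_noise >= 0)
  p <- n_informative + n_noise
  feat <- c(if (n_informative) sprintf("info_%02d", seq_len(n_informative)),
            if (n_noise) sprintf("noise_%03d", seq_len(n_noise)))
  withr::with_seed(seed, {
    y <- sample(rep(c("S", "L"), c(n_patients - n_long, n_long)))
    X <- matrix(stats::rnorm(n_patients * p), n_patients, p,
                dimnames = list(sprintf("PT%03d", seq_len(n_patients)), feat))
  })
  if (n_informative)
    X[, seq_len(n_informative)] <- X[, seq_len(n_informative), drop = FALSE] +
      ifelse(y == "L", d / 2, -d / 2)
  list(X = X, y = factor(y, levels = c("S", "L")),
       informative = feat[seq_len(n_informative)])
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes per-patient event CSVs (`events_<patient>_<panel>.csv`, header =
#' channel names) plus cohort-level `ct.csv`, `clinical.csv`,
#' `outcomes.csv` and a `truth.json` with the planted parameters.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param events whether to write the (large) per-patient event CSVs.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, events = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(cohort$ct, "ct.csv")
  wr(cohort$clinical, "clinical.csv")
  wr(cohort$outcomes, "outcomes.csv")
  truth <- list(classes = as.list(cohort$classes),
                frequencies = as.data.frame(cohort$truth),
                effect_sizes = as.list(cohort$spec_used$effect_sizes),
                hazard_coefs = as.list(cohort$spec_used$hazard_coefs),
                seed = cohort$spec_used$seed)
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  files <- c(files, tj)
  if (events) {
    for (id in cohort$patients)
      for (pn in names(cohort$events[[id]]))
        wr(as.data.frame(unclass(cohort$events[[id]][[pn]])),
           sprintf("events_%s_%s.csv", id, pn))
  }
  invisible(files)
}
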