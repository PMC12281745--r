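# Survival and group-comparison statistics used for cohort stratification
# and feature interpretation. Kaplan-Meier, log-rank and Cox models are
# delegated to the survival package behind this module's interface;
# the D'Agostino-Pearson normality test and the univariate ROUT-style
# outlier filter are implemented here.

#' Kaplan-Meier curves with log-rank test and hazard ratio
#'
#' Product-limit estimates per group, a two-sided log-rank test, and the
#' between-group hazard ratio from a univariate Cox model.
#'
#' @param times event/censoring times.
#' @param events logical/0-1 event indicators.
#' @param groups group labels (2+ groups; the HR is reported for 2).
#' @return list with `fits` (per-group data.frame: time, surv, n_risk),
#'   `medians` (first time survival drops to <= 0.5; NA if never, flagged
#'   via `all_censored`), `logrank_p`, `hr`, `hr_ci`.
#' @export
km_logrank <- function(times, events, groups) {
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  groups <- as.factor(droplevels(as.factor(groups)))
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata_id <- rep(names(sf$strata) %||% levels(groups)[1], sf$strata %||% length(sf$time))
  fits <- split(data.frame(time = sf$time, surv = sf$surv,
                           n_risk = sf$n.risk, n_event = sf$n.event),
                sub("^groups=", "", strata_id))
  medians <- vapply(fits, function(f) {
    i <- which(f$surv <= 0.5)
    if (length(i)) f$time[min(i)] else NA_real_
  }, numeric(1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  hr <- hr_ci <- NA
  if (nlevels(groups) == 2) {
    # groups defined by an outcome split can order times almost
    # perfectly; the monotone-likelihood warning is expected there
    cx <- suppressWarnings(survival::coxph(survival::Surv(times, events) ~ groups))
    s <- summary(cx)
    hr <- unname(s$conf.int[1, "exp(coef)"])
    hr_ci <- unname(s$conf.int[1, c("lower .95", "upper .95")])
  }
  all_cens <- tapply(events, groups, function(e) !any(e))
  list(fits = fits, medians = medians, logrank_p = p,
       hr = hr, hr_ci = hr_ci, all_censored = all_cens)
}

#' Cox proportional-hazards regression
#'
#' Newton-Raphson on the partial likelihood via `survival::coxph`. Tie
#' handling follows the "exact for small tie groups, Efron for larger
#' ones" convention: with `ties = "auto"`, the exact method is used
#' unless some tied event time has more than `tie_threshold` events (or
#' there are no ties at all, where the methods coincide and Efron is
#' used). Perfect separation (monotone likelihood) is flagged and refit
#' with a ridge penalty as a fallback.
#'
#' @param covariates numeric matrix/data.frame of covariates (no missing).
#' @param times,events survival outcome.
#' @param ties `"auto"`, `"efron"`, `"exact"` or `"breslow"`.
#' @param mode `"joint"` (one model with all covariates) or
#'   `"per_feature"` (one univariate model per covariate); the result
#'   records which was run.
#' @param tie_threshold maximum tie-group size for the exact method.
#' @return object of class `cox_result`: data.frame with per-covariate
#'   `coef`, `hr`, `ci_lo`, `ci_hi`, `p`, plus attributes `ties_used`,
#'   `mode`, `flagged` (separation) and `penalized`.
#' @export
cox_fit <- function(covariates, times, events, ties = "auto",
                    mode = c("joint", "per_feature"), tie_threshold = 5) {
  mode <- match.arg(mode)
  X <- as.matrix(covariates)
  if (anyNA(X)) stop_field("covariates", "missing values are not allowed")
  if (sum(events) < ncol(X) && mode == "joint")
    stop("fewer events than covariates", call. = FALSE)
  if (ties == "auto") {
    ev_times <- times[as.logical(events)]
    tie_sizes <- table(ev_times)
    ties <- if (!any(tie_sizes > 1)) "efron"
            else if (max(tie_sizes) > tie_threshold) "efron" else "exact"
  }
  fit_one <- function(Xs) {
    df <- data.frame(Xs, check.names = FALSE)
    fml <- stats::as.formula(paste("survival::Surv(times, events) ~",
                                   paste(sprintf("`%s`", colnames(df)),
                                         collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = df, ties = ties),
      warning = function(w) {
        if (grepl("infinite|converge|beta may be", conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    pen <- FALSE
    if (sep || any(!is.finite(stats::coef(fit))) ||
        any(abs(stats::coef(fit)) > 15)) {
      pen <- TRUE
      fml_r <- stats::as.formula(paste(
        "survival::Surv(times, events) ~ survival::ridge(",
        paste(sprintf("`%s`", colnames(df)), collapse = ", "),
        ", theta = 1)"))
      fit <- suppressWarnings(survival::coxph(fml_r, data = df, ties = ties))
    }
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    data.frame(feature = colnames(df), coef = unname(co),
               hr = exp(unname(co)),
               ci_lo = exp(unname(co) - 1.96 * se),
               ci_hi = exp(unname(co) + 1.96 * se),
               p = 2 * stats::pnorm(-abs(unname(co) / se)),
               separation = sep, penalized = pen,
               stringsAsFactors = FALSE)
  }
  out <- if (mode == "joint") fit_one(X)
  else do.call(rbind, lapply(colnames(X), function(f)
    fit_one(X[, f, drop = FALSE])))
  rownames(out) <- NULL
  structure(out, ties_used = ties, mode = mode, class = c("cox_result", "data.frame"))
}

#' Spearman correlation matrix with pairwise p-values
#'
#' Rank correlation with average ranks for ties; symmetric with unit
#' diagonal. Constant columns give missing entries and are flagged.
#'
#' @param table numeric matrix/data.frame (>= 3 complete pairs per cell).
#' @return list with `rho`, `p` (symmetric matrices) and
#'   `constant_columns`.
#' @export
spearman_matrix <- function(table) {
  X <- as.matrix(table)
  const <- apply(X, 2, function(x) stats::var(x, na.rm = TRUE) == 0)
  rho <- suppressWarnings(stats::cor(X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  p <- matrix(NA_real_, ncol(X), ncol(X), dimnames = dimnames(rho))
  diag(p) <- 0
  for (i in seq_len(ncol(X) - 1)) for (j in (i + 1):ncol(X)) {
    if (const[i] || const[j]) next
    ok <- stats::complete.cases(X[, i], X[, j])
    if (sum(ok) < 3) next
    ct <- suppressWarnings(stats::cor.test(X[ok, i], X[ok, j],
                                           method = "spearman"))
    p[i, j] <- p[j, i] <- ct$p.value
  }
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- ifelse(const, NA, 1)
  list(rho = rho, p = p, constant_columns = names(const)[const])
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines z-transformed sample skewness and kurtosis into the K-squared
#' statistic, chi-squared with 2 degrees of freedom under normality.
#' Requires n >= 8.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test needs n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("constant sample", call. = FALSE)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness z (D'Agostino 1970, as in common implementations)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- if (y == 0) 0 else delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- (1 - 2 / (9 * a) - term2) / sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Normality-gated group comparisons
#'
#' The test battery used throughout the analysis: two-group comparisons
#' use an unpaired t-test when both groups pass D'Agostino-Pearson
#' normality (p > 0.05), otherwise Mann-Whitney U; groups smaller than 8
#' default to the nonparametric branch (flagged). Multi-group designs use
#' one-way ANOVA with Sidak-adjusted pairwise contrasts; paired designs
#' the Wilcoxon signed-rank test; 2x2 categorical tables Fisher's exact
#' test (hypergeometric enumeration via `stats::fisher.test`).
#'
#' @param values numeric vector (two_group/multi_group), list of two
#'   paired vectors (paired), or a 2x2 table/matrix (categorical).
#' @param groups group labels (two_group/multi_group only).
#' @param design one of `"two_group"`, `"multi_group"`, `"paired"`,
#'   `"categorical"`.
#' @return list with at least `p_value` and `test`; multi_group adds a
#'   `pairwise` data.frame with Sidak-adjusted p-values.
#' @export
compare_groups <- function(values, groups = NULL,
                           design = c("two_group", "multi_group",
                                      "paired", "categorical")) {
  design <- match.arg(design)
  switch(design,
    two_group = {
      g <- droplevels(as.factor(groups))
      stopifnot(nlevels(g) == 2)
      xs <- split(values, g)
      small <- any(vapply(xs, length, integer(1)) < 8)
      normal <- if (small) FALSE else
        all(vapply(xs, function(x) dagostino_pearson(x)$p_value > 0.05,
                   logical(1)))
      if (normal) {
        tt <- stats::t.test(xs[[1]], xs[[2]], var.equal = TRUE)
        list(test = "t", p_value = tt$p.value, statistic = unname(tt$statistic),
             normal = TRUE, small_sample = small)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(xs[[1]], xs[[2]]))
        list(test = "mann_whitney", p_value = wt$p.value,
             statistic = unname(wt$statistic),
             normal = FALSE, small_sample = small)
      }
    },
    multi_group = {
      g <- droplevels(as.factor(groups))
      fit <- stats::aov(values ~ g)
      p_global <- summary(fit)[[1]][["Pr(>F)"]][1]
      pw <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
      comps <- which(!is.na(pw), arr.ind = TRUE)
      m <- nrow(comps)
      pairwise <- data.frame(
        group1 = rownames(pw)[comps[, 1]],
        group2 = colnames(pw)[comps[, 2]],
        p_raw = pw[comps],
        p_sidak = pmin(1, 1 - (1 - pw[comps])^m),
        stringsAsFactors = FALSE)
      list(test = "anova_sidak", p_value = p_global, pairwise = pairwise)
    },
    paired = {
      stopifnot(is.list(values), length(values) == 2)
      wt <- suppressWarnings(
        stats::wilcox.test(values[[1]], values[[2]], paired = TRUE))
      list(test = "wilcoxon_signed_rank", p_value = wt$p.value,
           statistic = unname(wt$statistic))
    },
    categorical = {
      tab <- as.matrix(values)
      ft <- stats::fisher.test(tab)
      list(test = "fisher_exact", p_value = ft$p.value,
           odds_ratio = unname(ft$estimate))
    })
}

#' ROUT-style robust outlier detection (univariate)
#'
#' The robust-regression-plus-outlier-removal idea specialized to the
#' univariate location case: residuals from the median are scaled by a
#' robust spread estimate (the 68.27th percentile of absolute residuals,
#' small-sample adjusted), converted to t-like statistics, and selected
#' by Benjamini-Hochberg false-discovery control at rate Q.
#'
#' @param values numeric vector (n >= 5).
#' @param Q target false-discovery rate, in (0, 0.1].
#' @return logical mask, TRUE = outlier.
#' @export
rout_outliers <- function(values, Q = 0.02) {
  x <- values
  n <- sum(!is.na(x))
  if (n < 5) stop("ROUT needs n >= 5", call. = FALSE)
  if (!(Q > 0 && Q <= 0.1)) stop_field("Q", "must lie in (0, 0.1]")
  resid <- x - stats::median(x, na.rm = TRUE)
  s <- stats::quantile(abs(resid), 0.6827, na.rm = TRUE, names = FALSE) *
    n / (n - 1)
  if (s == 0) return(rep(FALSE, length(x)))
  tstat <- abs(resid) / s
  p <- 2 * stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  mask <- stats::p.adjust(p, method = "BH") < Q
  mask[is.na(mask)] <- FALSE
  mask
}

#' Fold separation of two group medians
#'
#' @param median_long,median_short group medians (short must be > 0).
#' @return list with `raw` ratio and `fold` (rounded to one decimal, the
#'   reporting convention).
#' @export
median_fold_separation <- function(median_long, median_short) {
  if (median_short == 0) stop("zero denominator", call. = FALSE)
  r <- median_long / median_short
  list(raw = r, fold = round(r, 1))
}
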