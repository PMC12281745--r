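# Feature-table assembly: qPCR delta-Ct normalization, gene and clinical
# ratios, min-max normalization, outcome dichotomization and the
# stratified train/validation split.

# ---------------------------------------------------------------------------
# qPCR

#' Normalize a Ct table to relative expression
#'
#' Standard delta-Ct normalization against a reference (housekeeping)
#' gene: `dCt = Ct_gene - Ct_reference`, relative expression
#' `2^-dCt`. A patient with a missing reference Ct gets a fully missing
#' expression row.
#'
#' @param ct data.frame with `patient_id` plus one Ct column per gene.
#' @param reference_gene reference gene column name.
#' @return data.frame `patient_id` plus `PGEP.<gene>` relative-expression
#'   columns (reference excluded).
#' @export
normalize_qpcr <- function(ct, reference_gene = "REF") {
  if (!reference_gene %in% names(ct))
    stop_field("reference_gene", sprintf("'%s' not found in Ct table", reference_gene))
  genes <- setdiff(names(ct), c("patient_id", reference_gene))
  ref <- ct[[reference_gene]]
  out <- data.frame(patient_id = ct$patient_id, stringsAsFactors = FALSE)
  for (g in genes) out[[paste0("PGEP.", g)]] <- 2^(-(ct[[g]] - ref))
  out[is.na(ref), -1] <- NA_real_
  out
}

#' Compute gene-ratio features
#'
#' One ratio feature per configured pair of relative-expression columns,
#' named `PGEP.<a>_<b>.ratio`. A zero or missing denominator yields a
#' missing value.
#'
#' @param expr output of [normalize_qpcr()].
#' @param pairs list of length-2 character vectors (gene names without the
#'   `PGEP.` prefix).
#' @return `expr` with ratio columns appended.
#' @export
compute_gene_ratios <- function(expr, pairs) {
  for (pr in pairs) {
    a <- paste0("PGEP.", pr[1]); b <- paste0("PGEP.", pr[2])
    if (!a %in% names(expr) || !b %in% names(expr))
      stop(sprintf("ratio pair (%s, %s): gene not found", pr[1], pr[2]),
           call. = FALSE)
    den <- expr[[b]]
    den[!is.na(den) & den == 0] <- NA_real_
    expr[[sprintf("PGEP.%s_%s.ratio", pr[1], pr[2])]] <- expr[[a]] / den
  }
  expr
}

# ---------------------------------------------------------------------------
# clinical

#' Append standard clinical ratio features
#'
#' Adds `LdAR = LDH/albumin`, `LeAR = leukocyte/albumin` and
#' `LdLeR = LDH/leukocyte`. Zero or missing denominators give missing
#' values.
#'
#' @param clinical data.frame with at least `LDH`, `albumin`, `leukocyte`.
#' @return the table with the three ratio columns appended.
#' @export
compute_clinical_ratios <- function(clinical) {
  need <- c("LDH", "albumin", "leukocyte")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop_field("clinical", paste("missing column(s):", paste(miss, collapse = ", ")))
  safe_div <- function(a, b) { b[!is.na(b) & b == 0] <- NA_real_; a / b }
  clinical$LdAR <- safe_div(clinical$LDH, clinical$albumin)
  clinical$LeAR <- safe_div(clinical$leukocyte, clinical$albumin)
  clinical$LdLeR <- safe_div(clinical$LDH, clinical$leukocyte)
  clinical
}

# ---------------------------------------------------------------------------
# feature table

#' Assemble the unified patient-by-feature table
#'
#' Joins PPEP (cytometry), PGEP (qPCR) and clinical blocks on
#' `patient_id` and tags every feature with its provenance. Clinical
#' columns are renamed `CLIN.<name>`.
#'
#' @param ppep wide data.frame: `patient_id` + `PPEP.*` columns (may be
#'   NULL).
#' @param pgep output of [normalize_qpcr()]/[compute_gene_ratios()] (may
#'   be NULL).
#' @param clinical clinical data.frame incl. ratios (may be NULL).
#' @return object of class `feature_table`: list with `values` (patients x
#'   features numeric matrix), `source` (named vector: PPEP-MG / PPEP-HG /
#'   PGEP / Clin) and `state = "raw"`.
#' @export
feature_table <- function(ppep = NULL, pgep = NULL, clinical = NULL) {
  blocks <- Filter(Negate(is.null), list(ppep = ppep, pgep = pgep, clinical = clinical))
  if (!length(blocks)) stop("no feature blocks supplied", call. = FALSE)
  ids <- blocks[[1]]$patient_id
  vals <- list(); src <- character(0)
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    b <- b[match(ids, b$patient_id), , drop = FALSE]
    cols <- setdiff(names(b), "patient_id")
    m <- as.matrix(b[, cols, drop = FALSE])
    if (bn == "clinical") {
      colnames(m) <- paste0("CLIN.", cols)
      s <- rep("Clin", ncol(m))
    } else if (bn == "pgep") {
      s <- rep("PGEP", ncol(m))
    } else {
      s <- ifelse(grepl("^PPEP\\.MG\\.", cols), "PPEP-MG", "PPEP-HG")
    }
    vals[[bn]] <- m
    src <- c(src, stats::setNames(s, colnames(m)))
  }
  values <- do.call(cbind, vals)
  rownames(values) <- ids
  if (anyDuplicated(colnames(values)))
    stop_field("features", "feature ids must be unique across blocks")
  storage.mode(values) <- "double"
  structure(list(values = values, source = src, state = "raw",
                 dropped_constant = character(0)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$values), "patients x", ncol(x$values),
      "features (", paste(sprintf("%s:%d", names(table(x$source)),
                                  table(x$source)), collapse = ", "),
      "),", x$state, "state\n")
  invisible(x)
}

#' Min-max normalize a feature table
#'
#' Per feature, `(x - min) / (max - min)` over non-missing entries, so
#' every non-constant feature spans exactly [0, 1]. Constant features are
#' dropped and recorded. Ranks (and hence Spearman correlations) are
#' unchanged.
#'
#' @param ft a raw-state [feature_table()].
#' @return the normalized `feature_table` (state `"minmax"`, dropped
#'   constants listed in `$dropped_constant`).
#' @export
minmax_normalize <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$state != "raw") stop("table is already normalized", call. = FALSE)
  v <- ft$values
  rng <- apply(v, 2, function(x) range(x, na.rm = TRUE))
  const <- rng[1, ] == rng[2, ] | !is.finite(rng[1, ]) | !is.finite(rng[2, ])
  if (any(const))
    warning(sprintf("dropping %d constant feature(s)", sum(const)), call. = FALSE)
  keep <- which(!const)
  v <- v[, keep, drop = FALSE]
  rng <- rng[, keep, drop = FALSE]
  v <- sweep(sweep(v, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
  structure(list(values = v, source = ft$source[keep], state = "minmax",
                 dropped_constant = names(const)[const],
                 bounds = rng), class = "feature_table")
}

# ---------------------------------------------------------------------------
# preprocessing path (fit on training data only, frozen for validation)

#' Fit the missing-data and normalization path on training data
#'
#' Drops features with more than `max_missing` missingness, freezes
#' per-feature training medians for imputation and training min-max
#' bounds for normalization. Applying the result to new data
#' ([apply_preprocess()]) never recomputes any statistic, which is what
#' keeps validation data out of the model path.
#'
#' @param X training values matrix (raw scale).
#' @param max_missing maximum tolerated missing fraction per feature.
#' @return object of class `preprocess_plan`.
#' @export
fit_preprocess <- function(X, max_missing = 0.2) {
  miss <- colMeans(is.na(X))
  keep <- names(miss)[miss <= max_missing]
  X <- X[, keep, drop = FALSE]
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in seq_along(keep)) X[is.na(X[, j]), j] <- med[j]
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  const <- hi - lo == 0
  keep <- keep[!const]
  structure(list(features = keep, medians = med[keep],
                 lo = lo[keep], hi = hi[keep]),
            class = "preprocess_plan")
}

#' Apply a frozen preprocessing plan
#'
#' @param plan a [fit_preprocess()] result.
#' @param X values matrix containing at least the plan's features.
#' @return imputed, min-max-scaled matrix restricted to the plan's
#'   features (values from new data may fall outside [0, 1]; bounds are
#'   the training bounds by design).
#' @export
apply_preprocess <- function(plan, X) {
  stopifnot(inherits(plan, "preprocess_plan"))
  miss <- setdiff(plan$features, colnames(X))
  if (length(miss))
    stop(paste("missing feature(s):", paste(miss, collapse = ", ")), call. = FALSE)
  X <- X[, plan$features, drop = FALSE]
  for (j in seq_along(plan$features))
    X[is.na(X[, j]), j] <- plan$medians[j]
  sweep(sweep(X, 2, plan$lo, "-"), 2, plan$hi - plan$lo, "/")
}

# ---------------------------------------------------------------------------
# outcome classes

#' Dichotomize outcome times into short/long classes
#'
#' The median is computed on the full cohort. Censored cases below the
#' median are excluded (their true class is uncertain); censored cases
#' above the median are long by construction. From the eligible cases the
#' bottom and top `percentile_band` fractions are retained as S and L;
#' the middle is excluded, which maximizes class separation while keeping
#' a workable sample size.
#'
#' @param outcomes data.frame with `patient_id`, `<endpoint>_days`,
#'   `<endpoint>_event`.
#' @param endpoint `"ttf2"` or `"os"`.
#' @param percentile_band fraction in (0, 0.5] retained on each side
#'   (0.5 = plain median split).
#' @return list with `classes` (named factor S/L over retained patients)
#'   and `report` (data.frame patient_id/class/reason covering everyone).
#' @export
dichotomize_outcomes <- function(outcomes, endpoint = c("ttf2", "os"),
                                 percentile_band = 0.45) {
  endpoint <- match.arg(endpoint)
  if (!(percentile_band > 0 && percentile_band <= 0.5))
    stop_field("percentile_band", "must lie in (0, 0.5]")
  times <- outcomes[[paste0(endpoint, "_days")]]
  events <- outcomes[[paste0(endpoint, "_event")]]
  id <- outcomes$patient_id
  med <- stats::median(times)
  cls <- rep(NA_character_, length(times))
  reason <- rep("", length(times))
  below <- times <= med
  cls[below & events] <- "S"
  cls[!below] <- "L"                      # censored above median still L
  reason[below & !events] <- "censored_below_median"
  elig <- !is.na(cls)
  q_lo <- stats::quantile(times[elig], percentile_band, names = FALSE)
  q_hi <- stats::quantile(times[elig], 1 - percentile_band, names = FALSE)
  drop_mid <- elig & ((cls == "S" & times > q_lo) | (cls == "L" & times < q_hi))
  reason[drop_mid] <- "middle_band"
  cls[drop_mid] <- NA_character_
  keep <- !is.na(cls)
  if (sum(cls[keep] == "S") < 2 || sum(cls[keep] == "L") < 2)
    stop("fewer than 2 eligible patients in a class", call. = FALSE)
  classes <- factor(cls[keep], levels = c("S", "L"))
  names(classes) <- id[keep]
  reason[keep] <- "retained"
  list(classes = classes,
       report = data.frame(patient_id = id, class = cls, reason = reason,
                           median = med, stringsAsFactors = FALSE))
}

#' Stratified train/validation split
#'
#' Splits patients by class so both sides keep near-balanced classes;
#' deterministic for a fixed seed. The same partition should be reused
#' for every endpoint labelling of the same cohort.
#'
#' @param classes named factor of class labels (names = patient ids).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `validation` patient-id vectors.
#' @export
split_train_validation <- function(classes, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop_field("train_fraction", "must lie strictly in (0,1)")
  if (any(table(classes) < 2))
    stop("each class needs at least 2 members to split", call. = FALSE)
  train <- character(0)
  withr::with_seed(seed, {
    for (cl in levels(classes)) {
      idx <- names(classes)[classes == cl]
      n_tr <- max(1, min(length(idx) - 1, round(length(idx) * train_fraction)))
      train <- c(train, sample(idx, n_tr))
    }
  })
  list(train = sort(train),
       validation = sort(setdiff(names(classes), train)))
}
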