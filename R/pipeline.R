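# End-to-end orchestration: simulate -> gate -> features -> classes ->
# select -> train -> evaluate -> survival -> report, under one config and
# one root seed fanned out to named substreams.

#' Default manual gating tree for the bundled panel
#'
#' A small conventional hierarchy on the arcsinh scale: T cells (CD3+),
#' their CD4+ and CD8+ children, and CXCR3+ CD8 T cells as a terminal
#' grandchild; plus a CD62P-bright gate for platelet-aggregate-like
#' events. Thresholds sit between the generator's negative (~0.3) and
#' positive (~4) population locations.
#'
#' @return a [gating_tree()].
#' @export
default_gating_tree <- function() {
  gating_tree(
    gate_node("T_cells", NULL, "CD3", lo = 2, hi = Inf),
    gate_node("CD4_T", "T_cells", "CD4", lo = 2, hi = Inf, terminal = TRUE),
    gate_node("CD8_T", "T_cells", "CD8", lo = 2, hi = Inf),
    gate_node("CXCR3_CD8_T", "CD8_T", "CXCR3", lo = 2, hi = Inf, terminal = TRUE),
    gate_node("CD62P_bright", NULL, "CD62P", lo = 5.5, hi = Inf, terminal = TRUE)
  )
}

#' Assemble a pipeline configuration
#'
#' Defaults follow the study design the pipeline implements: 80/20
#' stratified split, 10x tenfold cross-validation, bootstrapping 10x with
#' replacement, 45th-percentile outcome bands.
#'
#' @param cohort named list of [cohort_spec()] arguments for the
#'   simulation stage.
#' @param k_grid HyperGating cluster-count grid.
#' @param hg_events_per_sample events per sample in the pooled
#'   HyperGating fit.
#' @param classifier a [classifier_spec()].
#' @param selection `"hybrid"`, `"wrapper"`, `"rank_top5"` or `"pca_f1"`.
#' @param cv_k,cv_repeats cross-validation geometry.
#' @param bootstrap_B bootstrap resamples for validation.
#' @param train_fraction training share of the stratified split.
#' @param percentile_band outcome-class band (see
#'   [dichotomize_outcomes()]).
#' @param endpoint `"ttf2"` or `"os"`.
#' @param seed root seed.
#' @param outdir optional output directory for JSON/CSV artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), k_grid = 4:10,
                            hg_events_per_sample = 500,
                            classifier = classifier_spec("klr"),
                            selection = "hybrid",
                            cv_k = 10, cv_repeats = 10, bootstrap_B = 10,
                            train_fraction = 0.8, percentile_band = 0.45,
                            endpoint = "ttf2", seed = 1L, outdir = NULL) {
  stopifnot(selection %in% c("hybrid", "wrapper", "rank_top5", "pca_f1"),
            inherits(classifier, "classifier_spec"))
  structure(list(cohort = cohort, k_grid = k_grid,
                 hg_events_per_sample = hg_events_per_sample,
                 classifier = classifier, selection = selection,
                 cv_k = cv_k, cv_repeats = cv_repeats,
                 bootstrap_B = bootstrap_B,
                 train_fraction = train_fraction,
                 percentile_band = percentile_band,
                 endpoint = endpoint, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [pipeline_config()]
#'   arguments (`classifier` given as a named list).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$classifier))
    raw$classifier <- do.call(classifier_spec, raw$classifier)
  do.call(pipeline_config, raw)
}

#' Run the end-to-end pipeline
#'
#' Executes simulation, gating/feature extraction, feature-table
#' assembly, outcome dichotomization, the stratified split, feature
#' selection (training split only), signature-model training with a
#' CV-median Youden threshold, repeated-CV and bootstrap evaluation, and
#' per-feature Cox interpretation. Returns a manifest holding every
#' stage's output and content hashes; with `outdir` set, also writes the
#' main artifacts as JSON/CSV.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  # --- simulate
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = derive_seed(seed, 10L))))
  cohort <- simulate_cohort(spec)
  # --- gate
  ppep <- extract_ppep_features(cohort, tree = default_gating_tree(),
                                k_grid = config$k_grid,
                                seed = derive_seed(seed, 20L),
                                events_per_sample = config$hg_events_per_sample,
                                cofactor = spec$cofactor)
  # --- features
  pgep <- normalize_qpcr(cohort$ct, reference_gene = "REF")
  genes <- sub("^PGEP\\.", "", grep("^PGEP\\.", names(pgep), value = TRUE))
  if (length(genes) >= 2)
    pgep <- compute_gene_ratios(pgep, list(genes[1:2]))
  clin <- compute_clinical_ratios(cohort$clinical)
  ft <- feature_table(ppep = ppep$features, pgep = pgep, clinical = clin)
  # --- classes
  dich <- dichotomize_outcomes(cohort$outcomes, endpoint = config$endpoint,
                               percentile_band = config$percentile_band)
  classes <- dich$classes
  ids <- intersect(rownames(ft$values), names(classes))
  X_raw <- ft$values[ids, , drop = FALSE]
  y <- classes[ids]
  split <- split_train_validation(y, config$train_fraction,
                                  seed = derive_seed(seed, 30L))
  X_tr <- X_raw[split$train, , drop = FALSE]
  y_tr <- y[split$train]
  # --- select (training split only)
  prep <- fit_preprocess(X_tr)
  X_trn <- apply_preprocess(prep, X_tr)
  sel_seed <- derive_seed(seed, 40L)
  sel <- switch(config$selection,
    hybrid = hybrid_select(X_trn, y_tr, config$classifier, k = config$cv_k,
                           seed = sel_seed),
    wrapper = wrapper_search(X_trn, y_tr, config$classifier, k = config$cv_k,
                             seed = sel_seed),
    rank_top5 = {
      rk <- rank_statistical(X_trn, y_tr)
      structure(list(method = "rank_top5",
                     selected = utils::head(rk$feature_id, 5),
                     criterion = NA, trace = NULL, seed = sel_seed,
                     ranking = rk), class = "selection_result")
    },
    pca_f1 = {
      rk <- rank_pca_f1(X_trn)
      structure(list(method = "pca_f1", selected = attr(rk, "subset"),
                     criterion = NA, trace = NULL, seed = sel_seed,
                     ranking = rk), class = "selection_result")
    })
  if (!length(sel$selected))
    stop("selection returned no features", call. = FALSE)
  # --- evaluate (CV on the training split, full path inside folds)
  cv <- repeated_cv(X_tr[, sel$selected, drop = FALSE], y_tr,
                    config$classifier, k = config$cv_k,
                    repeats = config$cv_repeats,
                    seed = derive_seed(seed, 50L))
  # --- train frozen model with the CV-median Youden threshold
  spec_frozen <- config$classifier
  spec_frozen$threshold <- cv$youden_median
  model <- train_signature_model(X_tr, y_tr, sel$selected, spec_frozen,
                                 selection_method = sel$method, seed = seed)
  model$train_ids <- split$train
  boot <- bootstrap_validate(model,
                             X_raw[split$validation, , drop = FALSE],
                             y[split$validation], B = config$bootstrap_B,
                             seed = derive_seed(seed, 60L),
                             train_ids = split$train)
  # --- survival interpretation on the analyzed cohort
  out_rows <- cohort$outcomes[match(ids, cohort$outcomes$patient_id), ]
  prep_all <- fit_preprocess(X_raw[, sel$selected, drop = FALSE])
  Xn_all <- apply_preprocess(prep_all, X_raw)
  cox <- cox_fit(Xn_all, out_rows[[paste0(config$endpoint, "_days")]],
                 out_rows[[paste0(config$endpoint, "_event")]],
                 mode = "per_feature")
  km <- km_logrank(out_rows[[paste0(config$endpoint, "_days")]],
                   out_rows[[paste0(config$endpoint, "_event")]], y)
  manifest <- structure(list(
    config = config,
    cohort_hash = content_hash(cohort$truth),
    split = split,
    class_report = dich$report,
    selection = sel,
    cv = cv, bootstrap = boot,
    model = model, cox = cox, km = km,
    stage_hashes = list(
      features = content_hash(ft$values),
      selection = content_hash(sel$selected),
      model = model$train_hash)
  ), class = "pipeline_manifest")
  if (!is.null(config$outdir)) write_manifest(manifest, config$outdir)
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  analyzed patients:", length(x$split$train) + length(x$split$validation),
      "(", length(x$split$train), "train /", length(x$split$validation),
      "validation )\n")
  cat("  signature (", x$selection$method, "): ",
      paste(x$selection$selected, collapse = ", "), "\n", sep = "")
  cat("  CV median accuracy:",
      round(x$cv$summary$median[x$cv$summary$metric == "accuracy"], 1), "%\n")
  cat("  bootstrap median accuracy:",
      round(x$bootstrap$summary$median[x$bootstrap$summary$metric == "accuracy"], 1),
      "%\n")
  invisible(x)
}

write_manifest <- function(manifest, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest$cv$per_replicate,
                   file.path(outdir, "report_cv.csv"), row.names = FALSE)
  utils::write.csv(manifest$bootstrap$per_replicate,
                   file.path(outdir, "report_bootstrap.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(manifest$cox),
                   file.path(outdir, "cox_features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = manifest$config$seed,
         selected = manifest$selection$selected,
         method = manifest$selection$method,
         threshold = manifest$model$classifier$threshold,
         stage_hashes = manifest$stage_hashes,
         split = manifest$split),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  write_signature_model(manifest$model, file.path(outdir, "model.json"))
  invisible(outdir)
}

#' Compare performance reports side by side
#'
#' Medians (and ranges) for every metric across models, with the best
#' model flagged per metric. Reports carrying cohort hashes must come
#' from the same evaluation cohort.
#'
#' @param reports named list of `performance_report`s.
#' @return data.frame: metric x model medians plus a `best` column.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  hashes <- unlist(lapply(reports, function(r) r$cohort_hash))
  if (length(unique(hashes)) > 1)
    stop("reports come from different evaluation cohorts", call. = FALSE)
  metrics <- Reduce(union, lapply(reports, function(r) r$summary$metric))
  out <- data.frame(metric = metrics)
  for (nm in names(reports)) {
    s <- reports[[nm]]$summary
    out[[nm]] <- s$median[match(metrics, s$metric)]
  }
  dirn <- ifelse(metrics == "youden_threshold", NA, 1)
  out$best <- vapply(seq_along(metrics), function(i) {
    vals <- unlist(out[i, names(reports)])
    if (all(is.na(vals)) || is.na(dirn[i])) return(NA_character_)
    names(reports)[which.max(vals)]
  }, character(1))
  out
}
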