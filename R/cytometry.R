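# Event-level cytometry processing: arcsinh transform, sequential
# pre-gating, manual rule gates (MG) and automated Gaussian-mixture
# meta-clustering ("HyperGating", HG).

# ---------------------------------------------------------------------------
# schema and containers

#' Define a cytometry panel schema
#'
#' @param panel_id panel label.
#' @param channels data.frame with columns `name`, `role` (one of
#'   `scatter_a`, `scatter_h`, `side_scatter`, `fluorescence`) and
#'   `marker` (NA for scatter channels).
#' @return object of class `panel_schema`.
#' @export
panel_schema <- function(panel_id, channels) {
  stopifnot(is.data.frame(channels),
            all(c("name", "role", "marker") %in% names(channels)))
  if (anyDuplicated(channels$name))
    stop_field("channels", "channel names must be unique within a panel")
  if (!any(channels$role == "scatter_a") || !any(channels$role == "side_scatter"))
    stop_field("channels", "need at least one scatter_a and one side_scatter channel")
  structure(list(panel_id = panel_id, channels = channels),
            class = "panel_schema")
}

#' Wrap an events-by-channels matrix as an event matrix
#'
#' @param values numeric matrix, events x channels; column names must
#'   match the panel's channel names.
#' @param panel a [panel_schema()].
#' @return object of class `event_matrix` (a matrix carrying `panel` and
#'   `transformed` attributes).
#' @export
event_matrix <- function(values, panel) {
  stopifnot(inherits(panel, "panel_schema"))
  values <- as.matrix(values)
  if (!identical(colnames(values), panel$channels$name))
    stop_field("values", "columns must equal the panel's channels, in order")
  if (any(!is.finite(values)))
    stop_field("values", "intensities must be finite")
  structure(values, panel = panel, transformed = FALSE,
            class = c("event_matrix", "matrix"))
}

em_panel <- function(em) attr(em, "panel")
fluor_channels <- function(panel) {
  panel$channels$name[panel$channels$role == "fluorescence"]
}
# keep event_matrix attributes through row subsetting
em_keep <- function(em, keep) {
  out <- unclass(em)[keep, , drop = FALSE]
  attr(out, "panel") <- attr(em, "panel")
  attr(out, "transformed") <- attr(em, "transformed")
  comp <- attr(em, "component")
  if (!is.null(comp)) attr(out, "component") <- comp[keep]
  attr(out, "patient_id") <- attr(em, "patient_id")
  class(out) <- c("event_matrix", "matrix")
  out
}

#' @export
print.event_matrix <- function(x, ...) {
  p <- em_panel(x)
  cat("Event matrix:", nrow(x), "events x", ncol(x), "channels (panel",
      p$panel_id, if (attr(x, "transformed")) ", arcsinh scale" else ", raw scale",
      ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# transform

#' Arcsinh-transform fluorescence channels
#'
#' Applies `asinh(x / cofactor)` to fluorescence channels only; scatter
#' channels are untouched. Monotone and invertible per channel
#' (see [inverse_arcsinh()]).
#'
#' @param em an [event_matrix()] on the raw scale.
#' @param cofactor positive scalar (default 150, a common cytometry
#'   choice).
#' @return transformed [event_matrix()].
#' @export
transform_arcsinh <- function(em, cofactor = 150) {
  if (!is.numeric(cofactor) || cofactor <= 0)
    stop_field("cofactor", "must be a positive scalar")
  if (isTRUE(attr(em, "transformed")))
    stop("event matrix is already transformed", call. = FALSE)
  fl <- fluor_channels(em_panel(em))
  out <- em
  out[, fl] <- asinh(unclass(em)[, fl, drop = FALSE] / cofactor)
  attr(out, "transformed") <- TRUE
  attr(out, "cofactor") <- cofactor
  out
}

#' Invert the arcsinh transform
#'
#' @param em a transformed [event_matrix()].
#' @param cofactor cofactor used in the forward transform (taken from the
#'   matrix if omitted).
#' @return raw-scale [event_matrix()].
#' @export
inverse_arcsinh <- function(em, cofactor = NULL) {
  if (!isTRUE(attr(em, "transformed")))
    stop("event matrix is not transformed", call. = FALSE)
  cofactor <- cofactor %||% attr(em, "cofactor")
  fl <- fluor_channels(em_panel(em))
  out <- em
  out[, fl] <- cofactor * sinh(unclass(em)[, fl, drop = FALSE])
  attr(out, "transformed") <- FALSE
  attr(out, "cofactor") <- NULL
  out
}

# ---------------------------------------------------------------------------
# pre-gating

#' Configure the sequential pre-gating strategy
#'
#' Three optional steps applied in order: debris exclusion (lower bounds
#' on forward/side scatter), doublet exclusion (band on the
#' scatter-A/scatter-H ratio; singlets have ratio near 1, doublets near
#' 2), and a CD45-positive leukocyte gate on the arcsinh scale.
#'
#' @param debris NULL to disable, or list(fsc_min=, ssc_min=).
#' @param doublet NULL to disable, or list(ratio_min=, ratio_max=).
#' @param cd45 NULL to disable, or list(channel=, min=) with `min` on the
#'   transformed scale.
#' @return object of class `pregate_rules`.
#' @export
pregate_rules <- function(debris = list(fsc_min = 20000, ssc_min = 8000),
                          doublet = list(ratio_min = 0.8, ratio_max = 1.35),
                          cd45 = NULL) {
  structure(list(debris = debris, doublet = doublet, cd45 = cd45),
            class = "pregate_rules")
}

#' Sequential pre-gating of an event matrix
#'
#' Applies debris exclusion, doublet exclusion and an optional CD45+
#' leukocyte gate in sequence, recording the events surviving each step.
#' An empty result does not raise an error; it sets a warning flag in the
#' report so downstream code can record a missing sample.
#'
#' @param em an [event_matrix()] (raw or transformed; scatter channels
#'   are on the raw scale either way).
#' @param rules a [pregate_rules()].
#' @return list with `events` (pre-gated [event_matrix()]) and `report`
#'   (data.frame step/n_in/n_out plus an `empty` flag attribute).
#' @export
pregate <- function(em, rules = pregate_rules()) {
  stopifnot(inherits(rules, "pregate_rules"))
  panel <- em_panel(em)
  fsc_a <- panel$channels$name[panel$channels$role == "scatter_a"][1]
  fsc_h <- panel$channels$name[panel$channels$role == "scatter_h"][1]
  ssc <- panel$channels$name[panel$channels$role == "side_scatter"][1]
  cur <- em
  report <- data.frame(step = character(0), n_in = integer(0), n_out = integer(0))
  add <- function(step, n_in, n_out)
    rbind(report, data.frame(step = step, n_in = n_in, n_out = n_out))
  if (!is.null(rules$debris)) {
    keep <- unclass(cur)[, fsc_a] >= rules$debris$fsc_min &
      unclass(cur)[, ssc] >= rules$debris$ssc_min
    report <- add("debris_exclusion", nrow(cur), sum(keep))
    cur <- em_keep(cur, keep)
  }
  if (!is.null(rules$doublet) && !is.na(fsc_h)) {
    ratio <- unclass(cur)[, fsc_a] / unclass(cur)[, fsc_h]
    keep <- ratio >= rules$doublet$ratio_min & ratio <= rules$doublet$ratio_max
    report <- add("doublet_exclusion", nrow(cur), sum(keep))
    cur <- em_keep(cur, keep)
  }
  if (!is.null(rules$cd45)) {
    ch <- rules$cd45$channel
    if (!ch %in% panel$channels$name)
      stop(sprintf("unknown CD45 channel '%s'", ch), call. = FALSE)
    keep <- unclass(cur)[, ch] >= rules$cd45$min
    report <- add("cd45_gate", nrow(cur), sum(keep))
    cur <- em_keep(cur, keep)
  }
  attr(report, "empty") <- nrow(cur) == 0
  list(events = cur, report = report)
}

# ---------------------------------------------------------------------------
# manual gating

#' Define a manual gate node
#'
#' Predicates over one (interval) or two (rectangle) transformed channels.
#' Quadrant gates are rectangles with infinite bounds.
#'
#' @param name gate name (unique within a tree).
#' @param parent parent gate name, or NULL for a root child.
#' @param channels one or two channel names.
#' @param lo,hi numeric bounds per channel (use -Inf/Inf for open sides).
#' @param terminal whether median-intensity features are emitted for this
#'   gate.
#' @return a gate node list.
#' @export
gate_node <- function(name, parent = NULL, channels, lo, hi, terminal = FALSE) {
  stopifnot(length(channels) %in% 1:2,
            length(lo) == length(channels), length(hi) == length(channels))
  list(name = name, parent = parent, channels = channels,
       lo = lo, hi = hi, terminal = terminal)
}

#' Assemble a gating tree
#'
#' @param ... [gate_node()]s. Parents must be declared before children;
#'   the implicit root is the full pre-gated event set.
#' @return object of class `gating_tree`.
#' @export
gating_tree <- function(...) {
  nodes <- list(...)
  nm <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_field("nodes", "gate names must be unique")
  for (nd in nodes)
    if (!is.null(nd$parent) && !nd$parent %in% nm)
      stop(sprintf("gate '%s' references undeclared parent '%s'",
                   nd$name, nd$parent), call. = FALSE)
  structure(stats::setNames(nodes, nm), class = "gating_tree")
}

#' Apply manual gates and extract population features
#'
#' Emits one frequency feature per gate (percent of the immediate parent's
#' events) and one median-intensity feature per terminal gate and
#' fluorescence channel. A parent with zero events yields missing
#' frequencies for its children (never 0, to avoid fabricating signal).
#' Event order does not affect any feature.
#'
#' @param em transformed, pre-gated [event_matrix()].
#' @param tree a [gating_tree()].
#' @return data.frame with `feature_id`, `value`, `kind`, `gate`,
#'   `parent`, `source = "MG"`. Frequency features are named
#'   `PPEP.MG.<panel>.<gate>.freq`, medians
#'   `PPEP.MG.<panel>.<gate>.med_<marker>`.
#' @export
apply_manual_gates <- function(em, tree) {
  stopifnot(inherits(tree, "gating_tree"))
  if (!isTRUE(attr(em, "transformed")))
    stop("events must be arcsinh-transformed before manual gating", call. = FALSE)
  panel <- em_panel(em)
  for (nd in tree) {
    bad <- setdiff(nd$channels, panel$channels$name)
    if (length(bad))
      stop(sprintf("gate '%s' uses unknown channel(s): %s",
                   nd$name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  X <- unclass(em)
  member <- list(.root = rep(TRUE, nrow(X)))
  rows <- list()
  fl <- fluor_channels(panel)
  markers <- stats::setNames(panel$channels$marker, panel$channels$name)
  for (nd in tree) {
    pm <- member[[nd$parent %||% ".root"]]
    inside <- pm
    for (j in seq_along(nd$channels)) {
      v <- X[, nd$channels[j]]
      inside <- inside & v >= nd$lo[j] & v <= nd$hi[j]
    }
    member[[nd$name]] <- inside
    n_parent <- sum(pm)
    freq <- if (n_parent == 0) NA_real_ else 100 * sum(inside) / n_parent
    rows[[length(rows) + 1]] <- data.frame(
      feature_id = sprintf("PPEP.MG.%s.%s.freq", panel$panel_id, nd$name),
      value = freq, kind = "frequency", gate = nd$name,
      parent = nd$parent %||% ".root", source = "MG",
      stringsAsFactors = FALSE)
    if (isTRUE(nd$terminal)) {
      for (ch in fl) {
        med <- if (sum(inside) == 0) NA_real_ else stats::median(X[inside, ch])
        rows[[length(rows) + 1]] <- data.frame(
          feature_id = sprintf("PPEP.MG.%s.%s.med_%s",
                               panel$panel_id, nd$name, markers[[ch]]),
          value = med, kind = "median_intensity", gate = nd$name,
          parent = nd$parent %||% ".root", source = "MG",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# HyperGating

#' Fit a HyperGating model by pooled Gaussian-mixture meta-clustering
#'
#' Events are down-sampled to equal counts per sample (fairness across
#' patients), pooled over samples, and clustered with a Gaussian mixture
#' on the transformed fluorescence channels. The number of clusters is
#' chosen by the Bayesian information criterion over `k_grid`.
#' Deterministic given the data, seed and grid.
#'
#' @param samples list of transformed, pre-gated [event_matrix()]s from
#'   one panel (>= 2 samples).
#' @param k_grid candidate cluster counts.
#' @param seed integer seed.
#' @param events_per_sample cap on events contributed per sample; the
#'   actual count is `min(events_per_sample, min(sample sizes))`, equal
#'   for every sample.
#' @param model_names mclust covariance structure(s); NULL (default)
#'   chooses `"VVI"` (diagonal, per-cluster volume/shape - a robust
#'   choice for arcsinh-scale cytometry data), or `"V"` for
#'   single-channel panels.
#' @return object of class `hypergate_model` with cluster parameters,
#'   the per-k BIC table and the selected `k`.
#' @import mclust
#' @export
fit_hypergates <- function(samples, k_grid = 2:8, seed = 1L,
                           events_per_sample = 2000, model_names = NULL) {
  if (length(samples) < 2)
    stop_field("samples", "need at least two samples to meta-cluster")
  panel <- em_panel(samples[[1]])
  fl <- fluor_channels(panel)
  n_each <- min(events_per_sample, vapply(samples, nrow, integer(1)))
  if (n_each < 1) stop_field("samples", "a sample has zero pre-gated events")
  pooled <- withr::with_seed(seed, {
    do.call(rbind, lapply(samples, function(s) {
      idx <- sample(nrow(s), n_each)
      unclass(s)[idx, fl, drop = FALSE]
    }))
  })
  if (max(k_grid) > nrow(pooled))
    stop_field("k_grid", "contains k larger than the pooled event count")
  model_names <- model_names %||% if (ncol(pooled) == 1) "V" else "VVI"
  fit <- withr::with_seed(seed, {
    bic <- mclust::mclustBIC(pooled, G = k_grid, modelNames = model_names,
                             verbose = FALSE)
    mclust::Mclust(pooled, x = bic, verbose = FALSE)
  })
  if (is.null(fit)) stop("mixture fit failed for every candidate k", call. = FALSE)
  structure(list(
    panel_id = panel$panel_id, channels = fl,
    k = fit$G, model_name = fit$modelName,
    parameters = fit$parameters,
    bic_table = fit$BIC, seed = seed,
    events_per_sample = n_each, n_samples = length(samples)
  ), class = "hypergate_model")
}

#' @export
print.hypergate_model <- function(x, ...) {
  cat("HyperGating model: panel", x$panel_id, "-", x$k, "clusters (",
      x$model_name, "),", length(x$channels), "channels, seed", x$seed, "\n")
  invisible(x)
}

#' Assign events to HyperGates and extract population features
#'
#' Each event goes to its maximum-posterior cluster. Emits one frequency
#' feature per cluster (percent of all pre-gated events, so frequencies
#' partition to 100) and one median-intensity feature per cluster and
#' channel. Empty clusters yield frequency 0 and missing medians.
#'
#' @param em transformed, pre-gated [event_matrix()] from the model's
#'   panel.
#' @param model a [fit_hypergates()] result.
#' @return data.frame in the same shape as [apply_manual_gates()], with
#'   feature ids `PPEP.HG.<panel>.HG<k>.freq` / `.med_<marker>` and
#'   `source = "HG"`.
#' @export
assign_hypergates <- function(em, model) {
  stopifnot(inherits(model, "hypergate_model"))
  panel <- em_panel(em)
  if (!identical(panel$panel_id, model$panel_id))
    stop("event matrix and model come from different panels", call. = FALSE)
  X <- unclass(em)[, model$channels, drop = FALSE]
  z <- mclust::estep(modelName = model$model_name, data = X,
                     parameters = model$parameters)$z
  cl <- max.col(z, ties.method = "first")
  markers <- stats::setNames(panel$channels$marker, panel$channels$name)
  n <- nrow(X)
  rows <- list()
  for (k in seq_len(model$k)) {
    idx <- cl == k
    rows[[length(rows) + 1]] <- data.frame(
      feature_id = sprintf("PPEP.HG.%s.HG%d.freq", panel$panel_id, k),
      value = 100 * sum(idx) / n, kind = "frequency",
      gate = sprintf("HG%d", k), parent = ".pregated", source = "HG",
      stringsAsFactors = FALSE)
    for (ch in model$channels) {
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = sprintf("PPEP.HG.%s.HG%d.med_%s",
                             panel$panel_id, k, markers[[ch]]),
        value = if (any(idx)) stats::median(X[idx, ch]) else NA_real_,
        kind = "median_intensity", gate = sprintf("HG%d", k),
        parent = ".pregated", source = "HG", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cluster") <- cl
  out
}

#' Extract PPEP features for a whole cohort
#'
#' Convenience driver: pre-gates and transforms every sample, applies the
#' manual gating tree, fits one HyperGating model per panel on the pooled
#' cohort and assigns every sample to it.
#'
#' @param cohort a [simulate_cohort()] result (or any list with `events`
#'   shaped patient -> panel -> [event_matrix()]).
#' @param tree a [gating_tree()] (applied to every panel whose channels it
#'   references; pass NULL to skip manual gating).
#' @param rules a [pregate_rules()].
#' @param k_grid,seed,events_per_sample passed to [fit_hypergates()].
#' @param cofactor arcsinh cofactor.
#' @return list with `features` (patients x feature_id data.frame, wide),
#'   `models` (per-panel HyperGating models) and `pregate_reports`.
#' @export
extract_ppep_features <- function(cohort, tree = NULL,
                                  rules = pregate_rules(),
                                  k_grid = 2:8, seed = 1L,
                                  events_per_sample = 1000,
                                  cofactor = 150) {
  ids <- names(cohort$events)
  panels <- names(cohort$events[[1]])
  prepped <- list()
  reports <- list()
  for (pn in panels) {
    prepped[[pn]] <- lapply(ids, function(id) {
      pg <- pregate(cohort$events[[id]][[pn]], rules)
      reports[[paste(id, pn, sep = ".")]] <<- pg$report
      transform_arcsinh(pg$events, cofactor)
    })
    names(prepped[[pn]]) <- ids
  }
  models <- lapply(panels, function(pn)
    fit_hypergates(prepped[[pn]], k_grid = k_grid, seed = seed,
                   events_per_sample = events_per_sample))
  names(models) <- panels
  rows <- list()
  for (pn in panels) {
    for (id in ids) {
      fr <- assign_hypergates(prepped[[pn]][[id]], models[[pn]])
      fr$patient_id <- id
      rows[[length(rows) + 1]] <- fr[, c("patient_id", "feature_id", "value")]
      if (!is.null(tree)) {
        fr2 <- apply_manual_gates(prepped[[pn]][[id]], tree)
        fr2$patient_id <- id
        rows[[length(rows) + 1]] <- fr2[, c("patient_id", "feature_id", "value")]
      }
    }
  }
  long <- do.call(rbind, rows)
  wide <- stats::reshape(long, idvar = "patient_id", timevar = "feature_id",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- wide$patient_id
  wide <- wide[ids, , drop = FALSE]
  list(features = wide, models = models, pregate_reports = reports)
}
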