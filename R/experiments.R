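# Scenario runners reproducing the experimental designs on (synthetic)
# cohorts: within-cohort k-fold CV for {MIL, patch} x {all-tissue,
# tumor-only}, cross-cohort transfer, combined-cohort training, and the
# visualization-case / attention-heatmap exports.

fit_paradigm <- function(paradigm, bags, survival, config) {
  if (paradigm == "mil") {
    fit_mil(bags, survival, config)
  } else {
    fit_patch_cox(expand_labels(bags, survival), config)
  }
}

predict_paradigm <- function(paradigm, model, bags, fold) {
  if (paradigm == "mil") predict_mil(model, bags, fold = fold)
  else predict_patch_cox(model, bags, fold = fold)
}

apply_tissue_mode <- function(bags, tissue, qc_model = NULL) {
  mode <- switch(tissue, all = "all_tissue", tumor = "tumor_only",
                 stop_param("tissue must be 'all' or 'tumor'"))
  lapply(bags, select_patches, mode = mode, qc_model = qc_model)
}

# Pooled metrics for standardized predictions + survival.
pooled_metrics <- function(predictions, survival, horizons = c(12, 36, 60)) {
  m <- match(predictions$slide_id, survival$slide_id)
  tt <- survival$time[m]; dd <- survival$event[m]
  z <- predictions$risk_std
  names(tt) <- names(dd) <- predictions$slide_id
  cidx <- harrell_c(z, tt, dd)
  hrs <- lapply(c(q25 = 0.25, q50 = 0.50, q75 = 0.75), function(q) {
    tryCatch({
      gr <- stratify_quantile(stats::setNames(z, predictions$slide_id), q)
      hr <- cox_hr_binary(gr, tt, dd)
      list(hr = hr$hr, diverged = hr$diverged)
    }, error = function(e) list(hr = NA_real_, diverged = NA))
  })
  auc <- tryCatch(timepoint_auc_panel(z, tt, dd, horizons),
                  error = function(e) stats::setNames(
                    rep(NA_real_, length(horizons)), paste0("t", horizons)))
  list(c_index = cidx, hr = hrs, auc = auc, n = length(z),
       n_events = sum(dd))
}

#' Within-cohort k-fold cross-validation
#'
#' The main experimental design: slide-level folds stratified by event
#' status, a model fit per training fold, each slide predicted exactly
#' once by the model that never saw it, fold-wise z-scoring, and pooled
#' metrics (C-index, quantile hazard ratios, time-dependent AUC panel).
#'
#' @param cohort a `wsi_cohort`.
#' @param paradigm `"mil"` or `"patch"`.
#' @param tissue `"all"` or `"tumor"` patch selection.
#' @param k folds (default 5).
#' @param seed seed for fold assignment and model training (per-fold model
#'   seeds derive from it).
#' @param config a [train_config()]; its seed is overridden per fold.
#' @param qc_model optional QC model used in all-tissue mode.
#' @return list with `predictions` (pooled, standardized; attention or
#'   patch risks attached for single-paradigm downstream use) and `report`
#'   (an `experiment_report`).
#' @export
run_cv <- function(cohort, paradigm = c("mil", "patch"),
                   tissue = c("all", "tumor"), k = 5L, seed = 1L,
                   config = train_config(), qc_model = NULL) {
  paradigm <- match.arg(paradigm); tissue <- match.arg(tissue)
  check_number(k, "k", min = 2)
  if (!inherits(cohort, "wsi_cohort")) stop_param("cohort must be a wsi_cohort")
  bags <- apply_tissue_mode(cohort$bags, tissue, qc_model)
  sv <- match_survival(bags, cohort$survival)
  set.seed(seed)
  fold <- stratified_folds(paste0("event", sv$event), k)
  preds <- vector("list", k)
  attn <- list()
  for (f in seq_len(k)) {
    tr <- which(fold != f); va <- which(fold == f)
    if (sum(sv$event[tr]) < 1) stop_param("training fold %d has no events", f)
    cfg <- config; cfg$seed <- seed * 1000L + f
    model <- fit_paradigm(paradigm, bags[tr], sv, cfg)
    pf <- predict_paradigm(paradigm, model, bags[va], fold = f)
    if (paradigm == "mil") attn <- c(attn, attr(pf, "attention"))
    preds[[f]] <- pf
  }
  pooled <- do.call(rbind, preds)
  pooled <- zscore_by_fold(pooled)
  met <- pooled_metrics(pooled, sv)
  report <- structure(list(scenario = "cv", cohort_id = cohort$cohort_id,
                           paradigm = paradigm, tissue = tissue, k = k,
                           seed = seed, metrics = met,
                           fold_sizes = as.integer(table(fold))),
                      class = "experiment_report")
  if (length(attn)) attr(pooled, "attention") <- attn
  list(predictions = pooled, report = report)
}

#' Cross-cohort transfer evaluation
#'
#' Fits one model on the full training cohort, predicts the full test
#' cohort, standardizes over the test set as a single fold, and reports
#' pooled metrics. Mirrors the leave-one-dataset-out design that exposes
#' domain shift between cohorts.
#'
#' @param train_cohort,test_cohort `wsi_cohort`s with matching embedding
#'   dimension.
#' @inheritParams run_cv
#' @return list with `predictions` and `report` (records both cohort ids).
#' @export
run_transfer <- function(train_cohort, test_cohort,
                         paradigm = c("mil", "patch"),
                         tissue = c("all", "tumor"), seed = 1L,
                         config = train_config(), qc_model = NULL) {
  paradigm <- match.arg(paradigm); tissue <- match.arg(tissue)
  if (train_cohort$config$embed_dim != test_cohort$config$embed_dim)
    stop_param("embedding dimensions differ (%d vs %d)",
               train_cohort$config$embed_dim, test_cohort$config$embed_dim)
  bags_tr <- apply_tissue_mode(train_cohort$bags, tissue, qc_model)
  bags_te <- apply_tissue_mode(test_cohort$bags, tissue, qc_model)
  sv_tr <- match_survival(bags_tr, train_cohort$survival)
  sv_te <- match_survival(bags_te, test_cohort$survival)
  cfg <- config; cfg$seed <- seed
  model <- fit_paradigm(paradigm, bags_tr, sv_tr, cfg)
  pred <- predict_paradigm(paradigm, model, bags_te, fold = 1L)
  pred <- zscore_by_fold(pred)
  met <- pooled_metrics(pred, sv_te)
  report <- structure(list(scenario = "transfer",
                           train_cohort = train_cohort$cohort_id,
                           test_cohort = test_cohort$cohort_id,
                           paradigm = paradigm, tissue = tissue, seed = seed,
                           metrics = met),
                      class = "experiment_report")
  list(predictions = pred, report = report, model = model)
}

#' Combined-cohort training
#'
#' Pools several cohorts, builds folds stratified by cohort x event (every
#' fold sees every cohort), runs the usual CV, and reports metrics per
#' source cohort on the pooled standardized predictions.
#'
#' @param cohorts named list of >= 2 `wsi_cohort`s (names become cohort
#'   ids; slide ids are prefixed to stay unique).
#' @inheritParams run_cv
#' @return list with `predictions` (with a `cohort` column) and `reports`,
#'   one `experiment_report` per cohort.
#' @export
run_combined <- function(cohorts, paradigm = c("mil", "patch"),
                         tissue = c("all", "tumor"), k = 5L, seed = 1L,
                         config = train_config(), qc_model = NULL) {
  paradigm <- match.arg(paradigm); tissue <- match.arg(tissue)
  if (length(cohorts) < 2) stop_param("need at least 2 cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  bags <- list(); sv <- list(); origin <- character(0)
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    bs <- apply_tissue_mode(co$bags, tissue, qc_model)
    bs <- lapply(bs, function(b) { b$slide_id <- paste0(nm, ":", b$slide_id); b })
    s <- co$survival
    s$slide_id <- paste0(nm, ":", s$slide_id)
    bags <- c(bags, bs); sv[[nm]] <- s
    origin <- c(origin, rep(nm, length(bs)))
  }
  sv <- do.call(rbind, sv)
  svm <- match_survival(bags, sv)
  set.seed(seed)
  fold <- stratified_folds(paste0(origin, "_event", svm$event), k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); va <- which(fold == f)
    if (sum(svm$event[tr]) < 1) stop_param("training fold %d has no events", f)
    cfg <- config; cfg$seed <- seed * 1000L + f
    model <- fit_paradigm(paradigm, bags[tr], svm, cfg)
    preds[[f]] <- predict_paradigm(paradigm, model, bags[va], fold = f)
  }
  pooled <- do.call(rbind, preds)
  pooled <- zscore_by_fold(pooled)
  pooled$cohort <- origin[match(pooled$slide_id,
                                vapply(bags, `[[`, "", "slide_id"))]
  reports <- lapply(names(cohorts), function(nm) {
    sub <- pooled[pooled$cohort == nm, , drop = FALSE]
    structure(list(scenario = "combined", cohort_id = nm,
                   paradigm = paradigm, tissue = tissue, k = k, seed = seed,
                   metrics = pooled_metrics(sub, svm)),
              class = "experiment_report")
  })
  names(reports) <- names(cohorts)
  list(predictions = pooled, reports = reports)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s | %s/%s | C = %.4f (n = %d, events = %d)\n",
              x$scenario, x$paradigm, x$tissue, x$metrics$c_index,
              x$metrics$n, x$metrics$n_events))
  invisible(x)
}

#' Select accurately predicted low-/high-risk visualization cases
#'
#' Picks the cases whose predicted risk and observed outcome agree, for
#' downstream patch visualization: among below-median-risk slides, the
#' `n_low` lowest risks whose outcome is consistent with low risk
#' (censored with follow-up at or beyond the median observed time, or
#' death after the 75th percentile of event times); symmetrically, among
#' above-median-risk slides, the `n_high` highest risks that died by the
#' median event time. The two sets are disjoint by construction.
#'
#' @param predictions standardized prediction data.frame.
#' @param survival survival table keyed by `slide_id`.
#' @param n_low,n_high cases per side (default 25 + 25).
#' @param low_event_q,high_event_q quantiles of the event-time
#'   distribution used in the consistency rules (configurable
#'   operationalization).
#' @return list with `low_ids`, `high_ids`.
#' @export
select_visualization_cases <- function(predictions, survival, n_low = 25L,
                                       n_high = 25L, low_event_q = 0.75,
                                       high_event_q = 0.50) {
  m <- match(predictions$slide_id, survival$slide_id)
  if (anyNA(m)) stop_param("predictions reference unknown slides")
  tt <- survival$time[m]; dd <- survival$event[m]
  z <- predictions$risk_std
  if (all(is.na(z))) z <- predictions$risk_raw
  med_risk <- stats::median(z)
  ev_t <- tt[dd == 1]
  if (length(ev_t) == 0) stop_param("no events: cannot define consistency")
  med_fu <- stats::median(tt)
  low_ok <- z < med_risk &
    ((dd == 0 & tt >= med_fu) |
       (dd == 1 & tt >= stats::quantile(ev_t, low_event_q)))
  high_ok <- z >= med_risk & dd == 1 &
    tt <= stats::quantile(ev_t, high_event_q)
  if (sum(low_ok) < n_low || sum(high_ok) < n_high)
    stop_param("insufficient qualifying cases: %d low (need %d), %d high (need %d)",
               sum(low_ok), n_low, sum(high_ok), n_high)
  ids <- predictions$slide_id
  low_ids <- ids[low_ok][order(z[low_ok])][seq_len(n_low)]
  high_ids <- ids[high_ok][order(-z[high_ok])][seq_len(n_high)]
  list(low_ids = low_ids, high_ids = high_ids)
}

#' Export an attention heatmap
#'
#' Writes the per-patch attention of one slide as a CSV (`row`, `col`,
#' `weight`, weights summing to 1) and, optionally, a rendered PNG raster
#' on the slide's tile grid.
#'
#' @param bag a `slide_bag`.
#' @param weights attention weights aligned to the bag's patch order.
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.png`.
#' @param png render the raster too (default TRUE).
#' @return invisibly, the CSV path.
#' @export
export_heatmap <- function(bag, weights, path, png = TRUE) {
  if (!inherits(bag, "slide_bag")) stop_param("bag must be a slide_bag")
  n <- nrow(bag$coords)
  if (length(weights) != n)
    stop_param("weights (%d) misaligned with patches (%d)", length(weights), n)
  w <- weights / sum(weights)
  df <- data.frame(row = bag$coords[, 1], col = bag$coords[, 2], weight = w)
  csv <- paste0(path, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  if (png) {
    nr <- max(df$row) + 1L; nc <- max(df$col) + 1L
    grid <- matrix(NA_real_, nr, nc)
    grid[cbind(df$row + 1L, df$col + 1L)] <- df$weight
    grDevices::png(paste0(path, ".png"), width = 64 * nc, height = 64 * nr)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(grid)[, nr:1, drop = FALSE], axes = FALSE,
                    col = grDevices::hcl.colors(64, "inferno"),
                    useRaster = TRUE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(csv)
}
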