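# Plain-text serialization. A cohort directory holds: embeddings.csv (one
# row per patch: slide_id, row, col, tissue_class, archetype, e1..ed),
# survival.csv (slide_id, time, event), truth.csv and config.json.
# Predictions use the shared CSV schema (slide_id, fold, risk_raw,
# risk_std).

#' Write / read a cohort as a plain-text directory
#'
#' @param cohort a `wsi_cohort`.
#' @param dir target directory (created if missing).
#' @return `write_cohort` the directory invisibly; `read_cohort` a
#'   `wsi_cohort` (truth/config restored when present).
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "wsi_cohort")) stop_param("cohort must be a wsi_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$config$embed_dim
  rows <- lapply(cohort$bags, function(b) {
    data.frame(slide_id = b$slide_id, row = b$coords[, 1], col = b$coords[, 2],
               tissue_class = b$tissue_class,
               archetype = b$archetype %||% NA_character_,
               b$embeddings, stringsAsFactors = FALSE)
  })
  emb <- do.call(rbind, rows)
  names(emb)[-(1:5)] <- paste0("e", seq_len(d))
  utils::write.csv(emb, file.path(dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(c(unclass(cohort$config),
                         list(cohort_id = cohort$cohort_id)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  emb <- utils::read.csv(file.path(dir, "embeddings.csv"),
                         stringsAsFactors = FALSE)
  surv <- utils::read.csv(file.path(dir, "survival.csv"),
                          stringsAsFactors = FALSE)
  cfg_path <- file.path(dir, "config.json")
  cj <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path,
                                                       simplifyVector = TRUE)
        else NULL
  ecols <- grep("^e\\d+$", names(emb))
  cohort_id <- cj$cohort_id %||% "imported"
  bags <- lapply(split(emb, factor(emb$slide_id, levels = unique(emb$slide_id))),
                 function(df) {
    arch <- if (all(is.na(df$archetype))) NULL else df$archetype
    slide_bag(df$slide_id[1], as.matrix(df[, ecols, drop = FALSE]),
              cbind(row = df$row, col = df$col), df$tissue_class,
              cohort_id = cohort_id, archetype = arch)
  })
  names(bags) <- NULL
  config <- if (!is.null(cj)) {
    cj$cohort_id <- NULL
    do.call(cohort_config, cj[setdiff(names(cj), "nontumor_mix")])
  } else {
    cohort_config(n_slides = length(bags), embed_dim = length(ecols))
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  structure(list(bags = bags, survival = surv, truth = truth,
                 config = config, archetypes = NULL, cohort_id = cohort_id),
            class = "wsi_cohort")
}

#' Write / read predictions in the shared CSV schema
#'
#' @param predictions prediction data.frame.
#' @param path CSV path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions[, c("slide_id", "fold", "risk_raw", "risk_std")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Flatten an experiment report for JSON export.
report_to_list <- function(report) {
  m <- report$metrics
  list(scenario = report$scenario,
       cohort_id = report$cohort_id %||% NULL,
       train_cohort = report$train_cohort %||% NULL,
       test_cohort = report$test_cohort %||% NULL,
       paradigm = report$paradigm, tissue = report$tissue,
       seed = report$seed, c_index = m$c_index,
       hr = lapply(m$hr, `[[`, "hr"),
       auc = as.list(m$auc), n = m$n, n_events = m$n_events)
}

#' Write an experiment report as JSON
#'
#' @param report an `experiment_report` (or list of them).
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  x <- if (inherits(report, "experiment_report")) report_to_list(report)
       else lapply(report, report_to_list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
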