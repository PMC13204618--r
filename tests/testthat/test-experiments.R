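test_that("run_cv: every slide predicted exactly once, k = 5 default, reproducible", {
  co <- tiny_cohort()
  res <- run_cv(co, "mil", "all", seed = 17, config = fast_config())
  expect_setequal(res$predictions$slide_id, co$survival$slide_id)
  expect_equal(anyDuplicated(res$predictions$slide_id), 0L)
  expect_equal(res$report$k, 5L)
  expect_length(res$report$fold_sizes, 5)
  expect_false(any(is.na(res$predictions$risk_std)))
  res2 <- run_cv(co, "mil", "all", seed = 17, config = fast_config())
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$report$metrics, res2$report$metrics)
  # patch paradigm emits the same schema
  resp <- run_cv(co, "patch", "tumor", seed = 17, config = fast_config())
  expect_named(resp$predictions,
               c("slide_id", "fold", "risk_raw", "risk_std"))
})

test_that("run_transfer: self-transfer consistency and provenance", {
  co <- tiny_cohort()
  cfg <- fast_config()
  res <- run_transfer(co, co, "mil", "all", seed = 5, config = cfg)
  expect_identical(res$report$train_cohort, res$report$test_cohort)
  # same seed, same data: transfer C equals a full refit evaluated in-cohort
  model <- fit_mil(co$bags, co$survival,
                   { c2 <- cfg; c2$seed <- 5L; c2 })
  pr <- predict_mil(model, co$bags)
  m <- match(pr$slide_id, co$survival$slide_id)
  expect_equal(res$report$metrics$c_index,
               harrell_c(pr$risk_raw, co$survival$time[m], co$survival$event[m]))
})

test_that("run_combined: cohort bookkeeping and homogeneous-pooling sanity", {
  coA <- make_cohort(cohort_config(n_slides = 36, patches_min = 10,
                                   patches_max = 16, embed_dim = 8, beta = 2,
                                   seed = 61))
  coB <- make_cohort(cohort_config(n_slides = 36, patches_min = 10,
                                   patches_max = 16, embed_dim = 8, beta = 2,
                                   seed = 62))
  res <- run_combined(list(A = coA, B = coB), "mil", "all", k = 3, seed = 7,
                      config = fast_config())
  expect_named(res$reports, c("A", "B"))
  expect_setequal(unique(res$predictions$cohort), c("A", "B"))
  expect_equal(sum(res$predictions$cohort == "A"), 36)
  expect_error(run_combined(list(coA), "mil"), "at least 2")
})

test_that("select_visualization_cases: counts, disjointness, insufficiency error", {
  set.seed(31)
  n <- 200
  eta <- rnorm(n)
  tt <- rexp(n, 0.02 * exp(eta)); dd <- rbinom(n, 1, 0.75)
  pr <- data.frame(slide_id = sprintf("s%03d", 1:n), fold = 1,
                   risk_raw = eta, risk_std = NA_real_)
  pr <- zscore_by_fold(pr)
  sv <- data.frame(slide_id = pr$slide_id, time = tt, event = dd)
  cs <- select_visualization_cases(pr, sv, n_low = 10, n_high = 10)
  expect_length(cs$low_ids, 10)
  expect_length(cs$high_ids, 10)
  expect_length(intersect(cs$low_ids, cs$high_ids), 0)
  # high-risk cases really are accurately predicted: all died
  m <- match(cs$high_ids, sv$slide_id)
  expect_true(all(sv$event[m] == 1))
  expect_error(select_visualization_cases(pr, sv, n_low = 190, n_high = 10),
               "insufficient")
})

test_that("export_heatmap: alignment, normalization, flat raster", {
  co <- tiny_cohort()
  bag <- co$bags[[1]]
  n <- nrow(bag$coords)
  w <- rep(1 / n, n)
  path <- file.path(tempdir(), "hm_test")
  csv <- export_heatmap(bag, w, path)
  df <- read.csv(csv)
  expect_equal(nrow(df), n)
  expect_equal(sum(df$weight), 1, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".png")))
  # uniform attention stays uniform after normalization
  expect_true(all(abs(df$weight - 1 / n) < 1e-12))
  expect_error(export_heatmap(bag, w[-1], path), "misaligned")
  unlink(paste0(path, c(".csv", ".png")))
})

test_that("cohort and prediction serialization round-trips", {
  co <- make_cohort(cohort_config(n_slides = 5, patches_min = 4,
                                  patches_max = 7, embed_dim = 5, seed = 19))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$bags), 5)
  for (i in 1:5) {
    expect_equal(unname(back$bags[[i]]$embeddings),
                 unname(co$bags[[i]]$embeddings), tolerance = 1e-12)
    expect_identical(back$bags[[i]]$tissue_class, co$bags[[i]]$tissue_class)
  }
  expect_equal(back$survival$time, co$survival$time, tolerance = 1e-12)
  expect_equal(back$config$beta, co$config$beta)
  pr <- data.frame(slide_id = c("a", "b"), fold = 1L, risk_raw = c(0.5, -1),
                   risk_std = c(1, -1))
  f <- file.path(tempdir(), "pred.csv")
  write_predictions(pr, f)
  expect_equal(read_predictions(f), pr)
  unlink(dir, recursive = TRUE); unlink(f)
})

test_that("CLI: simulate and cv subcommands produce outputs and a manifest", {
  out1 <- file.path(tempdir(), "cli_sim")
  wsisurv_cli(c("simulate", "--seed", "3", "--out", out1,
                "--config", {
                  cfgf <- file.path(tempdir(), "cli_cfg.json")
                  jsonlite::write_json(list(cohort = list(
                    n_slides = 8, patches_min = 6, patches_max = 9,
                    embed_dim = 5)), cfgf, auto_unbox = TRUE)
                  cfgf
                }))
  expect_true(file.exists(file.path(out1, "embeddings.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  out2 <- file.path(tempdir(), "cli_cv")
  wsisurv_cli(c("cv", "--seed", "3", "--cohort", out1, "--paradigm", "patch",
                "--tissue", "all", "--folds", "2", "--out", out2,
                "--config", {
                  cfgf <- file.path(tempdir(), "cli_cfg2.json")
                  jsonlite::write_json(list(train = list(
                    epochs = 10, hidden = 4, attn_dim = 2, patience = 2)),
                    cfgf, auto_unbox = TRUE)
                  cfgf
                }))
  met <- jsonlite::read_json(file.path(out2, "metrics.json"))
  expect_true(is.numeric(met$c_index))
  expect_true(file.exists(file.path(out2, "predictions.csv")))
  unlink(c(out1, out2), recursive = TRUE)
})
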