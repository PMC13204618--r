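# Patch-level Cox baseline: every patch inherits its slide's survival
# label, a small per-patch scorer (2-layer perceptron on embeddings,
# standing in for a full CNN trunk) is trained with the Cox objective at
# instance level — instances treated as independent, a stated
# approximation — and the slide risk is the mean patch risk.

#' Expand slide labels to patch instances
#'
#' Every patch of a slide becomes one instance carrying the slide's
#' survival time and event indicator verbatim; the instance count is the
#' total patch count.
#'
#' @param bags list of non-empty `slide_bag`.
#' @param survival data.frame `slide_id`, `time`, `event` covering all bags.
#' @return object of class `patch_instances`: list with `embeddings`
#'   (sum(N_i) x d), `slide_id`, `time`, `event` per instance.
#' @export
expand_labels <- function(bags, survival) {
  if (length(bags) == 0) stop_param("no bags supplied")
  for (b in bags) if (!inherits(b, "slide_bag") || nrow(b$embeddings) < 1)
    stop_param("every element must be a non-empty slide_bag")
  sv <- match_survival(bags, survival)
  n_per <- vapply(bags, function(b) nrow(b$embeddings), 0L)
  structure(list(embeddings = do.call(rbind, lapply(bags, `[[`, "embeddings")),
                 slide_id = rep(sv$slide_id, n_per),
                 time = rep(sv$time, n_per),
                 event = rep(sv$event, n_per)),
            class = "patch_instances")
}

patch_init <- function(d, hidden) {
  list(W1 = glorot(d, hidden), b1 = numeric(hidden),
       w2 = stats::runif(hidden, -0.3, 0.3), b2 = 0)
}

patch_scores <- function(p, X) {
  Hm <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  list(r = drop(Hm %*% p$w2) + p$b2, Hm = Hm)
}

#' Fit the patch-level Cox scorer
#'
#' Minimises [cox_npll()] over per-patch risks with risk sets built over
#' instances (global across slides, not slide-stratified). Early stopping
#' monitors the slide-level C-index (mean patch risk per slide) on a
#' held-out, event-stratified 20% of slides. `config$max_instances_per_slide`
#' caps the instances drawn per slide to bound the risk-set size.
#' Deterministic given `config$seed`.
#'
#' @param instances a [expand_labels()] result.
#' @param config a [train_config()].
#' @return object of class `patch_cox_model`.
#' @export
fit_patch_cox <- function(instances, config = train_config()) {
  if (!inherits(instances, "patch_instances"))
    stop_param("instances must come from expand_labels()")
  if (sum(instances$event[!duplicated(instances$slide_id)]) < 1)
    stop_param("no events among instances")
  set.seed(config$seed)
  d <- ncol(instances$embeddings)
  slides <- unique(instances$slide_id)
  sl_event <- instances$event[match(slides, instances$slide_id)]
  sl_time <- instances$time[match(slides, instances$slide_id)]
  sp <- make_val_split(sl_event, config$val_frac)
  keep <- instances$slide_id %in% slides[sp$train]
  idx_tr <- which(keep)
  if (is.finite(config$max_instances_per_slide)) {
    by_slide <- split(idx_tr, instances$slide_id[idx_tr])
    idx_tr <- sort(unlist(lapply(by_slide, function(ix)
      if (length(ix) > config$max_instances_per_slide)
        sample(ix, config$max_instances_per_slide) else ix), use.names = FALSE))
  }
  Xtr <- instances$embeddings[idx_tr, , drop = FALSE]
  t_tr <- instances$time[idx_tr]; e_tr <- instances$event[idx_tr]
  va_sl <- slides[sp$val]
  idx_va <- which(instances$slide_id %in% va_sl)
  params <- patch_init(d, config$hidden)
  state <- adam_init(params)
  nev <- sum(e_tr)
  best <- list(c = -Inf, params = params, epoch = 0L)
  bad <- 0L; hist <- list(); best_loss <- Inf; ckpt <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    fw <- patch_scores(params, Xtr)
    loss <- cox_npll(fw$r, t_tr, e_tr) / nev
    dr <- cox_grad(fw$r, t_tr, e_tr) / nev
    dpre <- (outer(dr, params$w2)) * (1 - fw$Hm^2)
    grads <- list(W1 = crossprod(Xtr, dpre) + config$weight_decay * params$W1,
                  b1 = colSums(dpre),
                  w2 = drop(crossprod(fw$Hm, dr)) + config$weight_decay * params$w2,
                  b2 = sum(dr))
    up <- adam_step(params, grads, state, config$lr)
    params <- up$params; state <- up$state
    if (loss < best_loss) { best_loss <- loss; ckpt <- c(ckpt, loss) }
    if (ep %% config$eval_every == 0L || ep == config$epochs) {
      val_c <- NA_real_
      if (length(idx_va)) {
        rv <- patch_scores(params, instances$embeddings[idx_va, , drop = FALSE])$r
        sl_r <- tapply(rv, instances$slide_id[idx_va], mean)
        m <- match(names(sl_r), slides)
        val_c <- tryCatch(harrell_c(as.numeric(sl_r), sl_time[m], sl_event[m]),
                          error = function(e) NA_real_)
      }
      score <- if (is.na(val_c)) -loss else val_c
      hist[[length(hist) + 1L]] <- c(epoch = ep, loss = loss, val_c = val_c)
      if (score > best$c + 1e-9) {
        best <- list(c = score, params = params, epoch = ep); bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  }
  structure(list(params = best$params, d = d, config = config,
                 best_epoch = best$epoch,
                 history = list(trace = do.call(rbind, hist),
                                checkpoint_losses = ckpt)),
            class = "patch_cox_model")
}

#' @export
print.patch_cox_model <- function(x, ...) {
  cat(sprintf("<patch_cox_model> d=%d, hidden=%d, best epoch %d\n",
              x$d, x$config$hidden, x$best_epoch))
  invisible(x)
}

#' Mean patch risk per slide
#'
#' The slide-level risk of the patch paradigm: the arithmetic mean of the
#' patch risk scores of each slide. Linear and order-invariant.
#'
#' @param patch_risks named list of per-slide numeric risk vectors.
#' @return named numeric vector of slide risks.
#' @export
slide_risk_mean <- function(patch_risks) {
  if (length(patch_risks) == 0) stop_param("no risk vectors supplied")
  vapply(patch_risks, function(r) {
    if (length(r) < 1) stop_param("empty patch risk vector")
    mean(r)
  }, numeric(1))
}

#' Predict slide risks with the patch-level model
#'
#' Scores every patch and averages within slides ([slide_risk_mean()]).
#'
#' @param model a fitted `patch_cox_model`.
#' @param bags list of `slide_bag`.
#' @param fold optional fold id recorded on the predictions.
#' @return data.frame with the shared prediction schema (`slide_id`,
#'   `fold`, `risk_raw`, `risk_std` = NA); per-patch risks in
#'   `attr(, "patch_risks")`.
#' @export
predict_patch_cox <- function(model, bags, fold = NA_integer_) {
  if (!inherits(model, "patch_cox_model"))
    stop_param("model must be a patch_cox_model")
  if (length(bags) == 0)
    return(structure(data.frame(slide_id = character(), fold = integer(),
                                risk_raw = numeric(), risk_std = numeric()),
                     patch_risks = list()))
  ids <- vapply(bags, `[[`, "", "slide_id")
  pr <- lapply(bags, function(b)
    patch_scores(model$params, b$embeddings)$r)
  names(pr) <- ids
  structure(data.frame(slide_id = ids, fold = fold,
                       risk_raw = unname(slide_risk_mean(pr)),
                       risk_std = NA_real_, stringsAsFactors = FALSE),
            patch_risks = pr)
}
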