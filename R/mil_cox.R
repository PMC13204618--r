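# Attention-based multiple-instance Cox model. Per slide i with patch
# embeddings x_ik: h_ik = phi(x_ik) (one tanh layer), gated-attention
# scores s_ik = w' (tanh(h V) * sigmoid(h U)), a_i = softmax(s_i), pooled
# representation z_i = sum_k a_ik h_ik, risk r_i = w_r' z_i + b_r. Trained
# end-to-end by full-batch Adam on the Cox negative partial log-likelihood
# over slide risks. All patch math is batched: patches of all bags are
# stacked into one matrix with a slide index, and per-slide softmax /
# pooling use grouped reductions.

#' Training configuration for the neural survival models
#'
#' Shared by [fit_mil()] and [fit_patch_cox()]. The paper's appendix
#' hyperparameters are not available; these defaults are desk-scale choices
#' tuned for the synthetic embedding world (d ~ 32) and documented in the
#' vignette.
#'
#' @param epochs maximum training epochs (>= 1).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on weight matrices (not biases).
#' @param hidden width of the feature transform phi.
#' @param attn_dim width of the gated-attention branch.
#' @param patience early-stopping patience, counted in evaluations of the
#'   held-out C-index (evaluated every `eval_every` epochs).
#' @param val_frac share of training slides held out for early stopping.
#' @param eval_every epochs between early-stopping evaluations.
#' @param max_instances_per_slide patch-level baseline only: cap on
#'   instances drawn per slide (bounds the Cox risk-set size); `Inf` keeps
#'   every patch.
#' @param seed RNG seed (initialisation and validation split).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 250L, lr = 5e-3, weight_decay = 1e-4,
                         hidden = 16L, attn_dim = 8L, patience = 12L,
                         val_frac = 0.2, eval_every = 5L,
                         max_instances_per_slide = Inf, seed = 1L) {
  check_number(epochs, "epochs", min = 1)
  check_number(lr, "lr", positive = TRUE)
  check_number(weight_decay, "weight_decay", min = 0)
  check_number(hidden, "hidden", min = 1)
  check_number(attn_dim, "attn_dim", min = 1)
  check_number(patience, "patience", min = 1)
  check_number(val_frac, "val_frac", min = 0)
  check_number(eval_every, "eval_every", min = 1)
  check_number(seed, "seed")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, hidden = as.integer(hidden),
                 attn_dim = as.integer(attn_dim),
                 patience = as.integer(patience), val_frac = val_frac,
                 eval_every = as.integer(eval_every),
                 max_instances_per_slide = max_instances_per_slide,
                 seed = as.integer(seed)),
            class = "train_config")
}

mil_init <- function(d, hidden, attn_dim) {
  list(W1 = glorot(d, hidden), b1 = numeric(hidden),
       V = glorot(hidden, attn_dim), U = glorot(hidden, attn_dim),
       w_att = stats::runif(attn_dim, -0.3, 0.3),
       w_r = stats::runif(hidden, -0.3, 0.3), b_r = 0)
}

# Stack a list of bags into one patch matrix + slide index.
stack_bags <- function(bags) {
  X <- do.call(rbind, lapply(bags, `[[`, "embeddings"))
  group <- rep(seq_along(bags),
               vapply(bags, function(b) nrow(b$embeddings), 0L))
  list(X = X, group = group,
       split = split(seq_len(nrow(X)), group))
}

# Batched forward pass. Returns risks, attention, pooled reps and caches.
mil_forward_batch <- function(p, X, group, split_idx) {
  n <- length(split_idx)
  Hm <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  Tm <- tanh(Hm %*% p$V)
  Um <- sigmoid(Hm %*% p$U)
  TU <- Tm * Um
  s <- drop(TU %*% p$w_att)
  a <- numeric(length(s))
  for (g in seq_len(n)) {
    idx <- split_idx[[g]]
    e <- exp(s[idx] - max(s[idx]))
    a[idx] <- e / sum(e)
  }
  Z <- rowsum(a * Hm, group, reorder = TRUE)
  r <- unname(drop(Z %*% p$w_r)) + p$b_r
  list(r = r, a = a, Z = Z, Hm = Hm, Tm = Tm, Um = Um, TU = TU, s = s)
}

mil_backward <- function(p, X, group, split_idx, fw, dr, weight_decay) {
  a <- fw$a; Hm <- fw$Hm
  dZ <- outer(dr, p$w_r)                       # n x H
  dw_r <- drop(crossprod(fw$Z, dr)); db_r <- sum(dr)
  dZg <- dZ[group, , drop = FALSE]             # expand to patches
  da <- rowSums(Hm * dZg)
  dH <- a * dZg
  Sg <- drop(rowsum(a * da, group, reorder = TRUE))
  ds <- a * (da - Sg[group])
  dw_att <- drop(crossprod(fw$TU, ds))
  dTU <- outer(ds, p$w_att)
  dpreT <- dTU * fw$Um * (1 - fw$Tm^2)
  dpreU <- dTU * fw$Tm * fw$Um * (1 - fw$Um)
  dV <- crossprod(Hm, dpreT)
  dU <- crossprod(Hm, dpreU)
  dH <- dH + dpreT %*% t(p$V) + dpreU %*% t(p$U)
  dpreH <- dH * (1 - Hm^2)
  dW1 <- crossprod(X, dpreH)
  db1 <- colSums(dpreH)
  g <- list(W1 = dW1 + weight_decay * p$W1, b1 = db1,
            V = dV + weight_decay * p$V, U = dU + weight_decay * p$U,
            w_att = dw_att + weight_decay * p$w_att,
            w_r = dw_r + weight_decay * p$w_r, b_r = db_r)
  g
}

#' Forward pass of the attention-MIL model on one bag
#'
#' Computes the attention weights (softmax over the bag, summing to one),
#' the pooled slide representation \eqn{z_i = \sum_k a_{ik} \phi(x_{ik})}
#' and the scalar risk \eqn{r_i = f_\theta(z_i)}; higher risk means higher
#' hazard by training convention. Invariant to patch order.
#'
#' @param bag a `slide_bag` (non-empty, dimension matching the model).
#' @param model a fitted or initialised `mil_model`.
#' @return list with `risk` (scalar), `weights` (per patch, sums to 1) and
#'   `representation` (pooled feature vector).
#' @export
mil_forward <- function(bag, model) {
  if (!inherits(model, "mil_model")) stop_param("model must be a mil_model")
  if (!inherits(bag, "slide_bag")) stop_param("bag must be a slide_bag")
  if (ncol(bag$embeddings) != model$d)
    stop_param("bag dimension %d does not match model dimension %d",
               ncol(bag$embeddings), model$d)
  fw <- mil_forward_batch(model$params, bag$embeddings,
                          rep(1L, nrow(bag$embeddings)),
                          list(seq_len(nrow(bag$embeddings))))
  list(risk = fw$r[1], weights = fw$a, representation = drop(fw$Z))
}

#' Fit the attention-MIL Cox model
#'
#' Jointly learns the patch feature transform, gated-attention pooling and
#' risk head by full-batch Adam on [cox_npll()] over slide-level risks
#' (risk sets are global over the training slides). Early stopping
#' monitors Harrell's C on a held-out 20% split of the training slides,
#' stratified by event status; the best-scoring parameters are returned.
#' Deterministic given `config$seed`.
#'
#' @param bags list of `slide_bag` (>= 2, at least one event).
#' @param survival data.frame with `slide_id`, `time`, `event` covering
#'   every bag.
#' @param config a [train_config()].
#' @return object of class `mil_model` with fields `params`, `d`, `config`
#'   and a training `history` (epoch, train loss, validation C at
#'   evaluations, and the running-best checkpoint losses).
#' @export
fit_mil <- function(bags, survival, config = train_config()) {
  sv <- match_survival(bags, survival)
  if (length(bags) < 2) stop_param("need at least 2 slides")
  if (sum(sv$event) < 1) stop_param("no events in the training data")
  set.seed(config$seed)
  d <- ncol(bags[[1]]$embeddings)
  params <- mil_init(d, config$hidden, config$attn_dim)
  sp <- make_val_split(sv$event, config$val_frac)
  tr <- sp$train; va <- sp$val
  st_tr <- stack_bags(bags[tr])
  st_va <- if (length(va)) stack_bags(bags[va]) else NULL
  state <- adam_init(params)
  nev <- sum(sv$event[tr])
  best <- list(c = -Inf, params = params, epoch = 0L)
  bad <- 0L
  hist <- list()
  best_loss <- Inf; ckpt_losses <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    fw <- mil_forward_batch(params, st_tr$X, st_tr$group, st_tr$split)
    loss <- cox_npll(fw$r, sv$time[tr], sv$event[tr]) / nev
    dr <- cox_grad(fw$r, sv$time[tr], sv$event[tr]) / nev
    grads <- mil_backward(params, st_tr$X, st_tr$group, st_tr$split, fw, dr,
                          config$weight_decay)
    up <- adam_step(params, grads, state, config$lr)
    params <- up$params; state <- up$state
    if (loss < best_loss) { best_loss <- loss; ckpt_losses <- c(ckpt_losses, loss) }
    if (ep %% config$eval_every == 0L || ep == config$epochs) {
      val_c <- if (!is.null(st_va)) {
        fv <- mil_forward_batch(params, st_va$X, st_va$group, st_va$split)
        tryCatch(harrell_c(fv$r, sv$time[va], sv$event[va]),
                 error = function(e) NA_real_)
      } else NA_real_
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
                                checkpoint_losses = ckpt_losses)),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> d=%d, hidden=%d, attn=%d, best epoch %d\n",
              x$d, x$config$hidden, x$config$attn_dim, x$best_epoch))
  invisible(x)
}

# 80/20 event-stratified split of slide indices; degenerate cases (val
# would lack events or hold < 2 slides) fall back to loss-based stopping.
make_val_split <- function(event, val_frac) {
  n <- length(event)
  n_val <- floor(n * val_frac)
  if (n_val >= 2) {
    idx_e <- which(event == 1); idx_c <- which(event == 0)
    k_e <- round(n_val * length(idx_e) / n)
    k_c <- n_val - k_e
    va <- c(if (k_e > 0) sample(idx_e, min(k_e, length(idx_e))),
            if (k_c > 0) sample(idx_c, min(k_c, length(idx_c))))
    tr <- setdiff(seq_len(n), va)
    if (sum(event[tr]) >= 1 && length(va) >= 2 && sum(event[va]) >= 1)
      return(list(train = tr, val = va))
  }
  list(train = seq_len(n), val = integer(0))
}

# Align a survival table to a bag list; errors on missing slides.
match_survival <- function(bags, survival) {
  ids <- vapply(bags, `[[`, "", "slide_id")
  m <- match(ids, survival$slide_id)
  if (anyNA(m))
    stop_param("missing survival records for: %s",
               paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  data.frame(slide_id = ids, time = survival$time[m],
             event = survival$event[m], stringsAsFactors = FALSE)
}

#' Predict slide risks with a fitted MIL model
#'
#' One prediction per bag; attention weights are returned aligned to each
#' bag's patch order as an attribute.
#'
#' @param model a fitted `mil_model`.
#' @param bags list of `slide_bag`.
#' @param fold optional fold id to record on the predictions.
#' @return data.frame (`slide_id`, `fold`, `risk_raw`, `risk_std` = NA
#'   until [zscore_by_fold()]) with `attr(, "attention")`: a named list of
#'   per-slide weight vectors.
#' @export
predict_mil <- function(model, bags, fold = NA_integer_) {
  if (!inherits(model, "mil_model")) stop_param("model must be a mil_model")
  if (length(bags) == 0)
    return(structure(data.frame(slide_id = character(), fold = integer(),
                                risk_raw = numeric(), risk_std = numeric()),
                     attention = list()))
  st <- stack_bags(bags)
  fw <- mil_forward_batch(model$params, st$X, st$group, st$split)
  ids <- vapply(bags, `[[`, "", "slide_id")
  att <- lapply(seq_along(bags), function(g) fw$a[st$split[[g]]])
  names(att) <- ids
  structure(data.frame(slide_id = ids, fold = fold, risk_raw = fw$r,
                       risk_std = NA_real_, stringsAsFactors = FALSE),
            attention = att)
}

#' Select the highest-attention patches of a slide
#'
#' Keeps `k = min(cap, max(1, ceil(frac * N)))` patches with the largest
#' attention weights — the top 10% by default, capped at 200 patches.
#' Ties break toward the lower patch index.
#'
#' @param weights per-patch attention weights (non-empty).
#' @param frac fraction of patches to keep, in (0, 1].
#' @param cap hard cap on the number kept.
#' @return integer indices of the selected patches, highest weight first.
#' @export
top_attention_patches <- function(weights, frac = 0.10, cap = 200L) {
  n <- length(weights)
  if (n < 1) stop_param("weights must be non-empty")
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop_param("frac must be in (0, 1]")
  check_number(cap, "cap", min = 1)
  k <- min(cap, max(1L, ceiling(frac * n)))
  order(-weights, seq_len(n))[seq_len(k)]
}
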