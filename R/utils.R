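# Internal numerical helpers shared by the trainers.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) stats::plogis(x)

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_param("`%s` must be > 0", name)
  if (x < min) stop_param("`%s` must be >= %s", name, format(min))
  invisible(x)
}

# Glorot-uniform initialisation for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Adam over a named list of numeric arrays. State carries first/second
# moments and the step counter; shapes mirror the parameter list.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stratified assignment of n items to k folds, balancing a categorical
# stratum (event status, or cohort x event). Returns integer fold ids.
stratified_folds <- function(strata, k, max_tries = 25L) {
  n <- length(strata)
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    ok <- TRUE
    ev <- grepl("event1$", strata) | strata == "1"
    if (any(ev)) {
      for (f in seq_len(k)) {
        if (sum(ev & fold != f) < 1) { ok <- FALSE; break }
      }
    }
    if (ok) return(fold)
  }
  stop_param("could not build %d folds with events in every training fold", k)
}
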