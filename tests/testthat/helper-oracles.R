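# Independent brute-force oracles. These are deliberately naive (direct
# summation, full pair enumeration) and share no code with the package's
# implementation paths.

oracle_cox_npll <- function(risks, times, events) {
  s <- 0
  for (i in seq_along(risks)) {
    if (events[i] == 1) {
      rset <- which(times >= times[i])
      s <- s - (risks[i] - log(sum(exp(risks[rset]))))
    }
  }
  s
}

oracle_harrell_c <- function(risks, times, events) {
  conc <- ties <- comp <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[i] < times[j]) {
        comp <- comp + 1
        if (risks[i] > risks[j]) conc <- conc + 1
        else if (risks[i] == risks[j]) ties <- ties + 1
      }
    }
  }
  stopifnot(comp > 0)
  (conc + 0.5 * ties) / comp
}

# Grid maximizer of the binary-covariate Cox partial log-likelihood
# (Breslow ties), used as the oracle for cox_hr_binary.
oracle_binary_cox_beta <- function(x, times, events, grid = seq(-6, 6, by = 1e-4)) {
  ev_times <- sort(unique(times[events == 1]))
  d_all <- sapply(ev_times, function(t) sum(times == t & events == 1))
  d_high <- sapply(ev_times, function(t) sum(times == t & events == 1 & x == 1))
  n1 <- sapply(ev_times, function(t) sum(times >= t & x == 1))
  n0 <- sapply(ev_times, function(t) sum(times >= t & x == 0))
  ll <- vapply(grid, function(b) sum(d_high * b - d_all * log(n0 + n1 * exp(b))),
               numeric(1))
  grid[which.max(ll)]
}

# Shared fixtures, built once per test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_cohort <- function() fixture("tiny_cohort", function() {
  make_cohort(cohort_config(n_slides = 40, patches_min = 12, patches_max = 20,
                            embed_dim = 8, beta = 2, seed = 401))
})

fast_config <- function(...) {
  do.call(train_config,
          utils::modifyList(list(epochs = 60, eval_every = 5, patience = 6,
                                 hidden = 8, attn_dim = 4), list(...)))
}
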