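#' Cox negative partial log-likelihood
#'
#' Computes the negative partial log-likelihood of the Cox proportional
#' hazards model for a vector of risk scores,
#' \deqn{-\sum_{i: \delta_i = 1} \left[ r_i - \log \sum_{j \in R(t_i)} e^{r_j} \right],}
#' where the risk set \eqn{R(t) = \{j : t_j \ge t\}} includes ties and tied
#' event times share one Breslow denominator. The log-sum-exp is stabilised
#' by a max shift before exponentiation, so large risk scores are safe.
#'
#' This is the training objective of both the attention-MIL model
#' ([fit_mil()]) and the patch-level baseline ([fit_patch_cox()]); there it
#' is applied to slide-level and patch-level risk vectors respectively.
#'
#' @param risks numeric vector of risk scores (higher = higher hazard).
#' @param times numeric vector of follow-up times, same length.
#' @param events 0/1 vector of event indicators (1 = death).
#' @return The scalar loss (a sum over events, not an average).
#' @examples
#' cox_npll(c(0, 0), c(1, 2), c(1, 1))  # log(2)
#' @export
cox_npll <- function(risks, times, events) {
  cx <- cox_prepare(risks, times, events)
  -sum(cx$r_event - cx$log_denom)
}

# Shared bookkeeping for the loss and its gradient. Sorts ascending by
# time, locates tie blocks, and computes Breslow denominators
# D_block = sum_{t_j >= t_block} exp(r_j) with a max shift.
cox_prepare <- function(risks, times, events) {
  n <- length(risks)
  if (length(times) != n || length(events) != n)
    stop_param("risks, times and events must have equal length")
  if (n < 1L) stop_param("need at least one observation")
  if (any(!is.finite(times)) || any(times <= 0))
    stop_param("times must be finite and positive")
  if (!all(events %in% c(0, 1)))
    stop_param("events must be 0/1")
  if (sum(events) < 1)
    stop_param("no events: the Cox partial likelihood is undefined")
  o <- order(times)
  t_s <- times[o]; r_s <- risks[o]; d_s <- events[o]
  M <- max(r_s)
  e_s <- exp(r_s - M)
  # reverse cumulative sum: S[k] = sum_{j >= k} e_s[j]
  S <- rev(cumsum(rev(e_s)))
  # tie blocks: positions sharing one observed time
  first_idx <- which(!duplicated(t_s))
  block <- findInterval(seq_len(n), first_idx)      # block id per position
  last_idx <- c(first_idx[-1] - 1L, n)              # last index per block
  log_D <- log(S[first_idx[block]]) + M             # per-position Breslow log-denominator
  ev_pos <- which(d_s == 1)
  list(order = o, n = n, t_s = t_s, r_s = r_s, d_s = d_s,
       block = block, block_last = last_idx[block], log_D = log_D,
       r_event = r_s[ev_pos], log_denom = log_D[ev_pos], ev_pos = ev_pos)
}

# Gradient of cox_npll with respect to the risk vector (original order):
# dL/dr_j = -delta_j + exp(r_j) * sum_{events i: t_i <= t_j} 1 / D_i.
cox_grad <- function(risks, times, events) {
  cx <- cox_prepare(risks, times, events)
  contrib <- ifelse(cx$d_s == 1, exp(-cx$log_D), 0)
  A_cum <- cumsum(contrib)
  # events tied with t_j count (risk set uses t_j >= t_i): take the
  # cumulative sum at the LAST index of each tie block
  A <- A_cum[cx$block_last]
  g_sorted <- -cx$d_s + exp(cx$r_s) * A
  g <- numeric(cx$n)
  g[cx$order] <- g_sorted
  g
}
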