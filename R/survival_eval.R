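# Evaluation layer: fold-wise standardization, Harrell's C, Kaplan-Meier,
# quantile stratification, binary-group Cox hazard ratios, IPCW
# cumulative/dynamic AUC, bootstrap model comparison. Input is the shared
# prediction schema (slide_id, fold, risk_raw, risk_std) plus a survival
# table keyed by slide_id.

#' Fold-wise z-score standardization of risk scores
#'
#' Models trained in different cross-validation folds produce risks on
#' incomparable scales. Within each fold f the raw risks are standardized,
#' \eqn{z_i = (r_i - \mu_f) / \sigma_f}, using the population standard
#' deviation (scale alignment, not inference), and the folds are pooled
#' into one unified validation set. Ranks within a fold are preserved. A
#' zero-variance fold yields all-zero scores with a warning.
#'
#' @param predictions data.frame with `fold` and `risk_raw` (>= 2 rows per
#'   fold).
#' @return the same data.frame with `risk_std` filled in.
#' @export
zscore_by_fold <- function(predictions) {
  if (!all(c("fold", "risk_raw") %in% names(predictions)))
    stop_param("predictions need columns fold, risk_raw")
  for (f in unique(predictions$fold)) {
    idx <- which(predictions$fold == f)
    if (length(idx) < 2)
      stop_param("fold '%s' has fewer than 2 predictions", f)
    r <- predictions$risk_raw[idx]
    mu <- mean(r)
    sigma <- sqrt(mean((r - mu)^2))
    if (sigma == 0) {
      warning(sprintf("fold '%s' has zero risk variance; scores set to 0", f))
      predictions$risk_std[idx] <- 0
    } else {
      predictions$risk_std[idx] <- (r - mu) / sigma
    }
  }
  predictions
}

#' Harrell's concordance index
#'
#' The proportion of comparable pairs whose predicted risks order
#' consistently with survival: pair (i, j) is comparable iff
#' \eqn{t_i < t_j} and subject i had the event; it is concordant iff
#' \eqn{r_i > r_j}; risk ties count 0.5.
#'
#' @param risks,times,events aligned vectors; `events` 0/1.
#' @return c in \[0, 1\]; errors when no pair is comparable.
#' @export
harrell_c <- function(risks, times, events) {
  n <- length(risks)
  if (length(times) != n || length(events) != n)
    stop_param("risks, times, events must have equal length")
  # comparable[i, j]: t_i < t_j and delta_i = 1
  comp <- outer(times, times, "<") & (events == 1)
  n_comp <- sum(comp)
  if (n_comp == 0) stop_param("no comparable pairs")
  rd <- outer(risks, risks, "-")
  conc <- sum(comp & (rd > 0))
  ties <- sum(comp & (rd == 0))
  (conc + 0.5 * ties) / n_comp
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous step estimate of the survival function; censored
#' subjects leave the risk set after their observed time. With zero
#' censoring it equals the empirical survival function exactly.
#'
#' @param times,events aligned vectors; `events` 0/1.
#' @return object of class `km_curve`: data.frame-backed list with `time`
#'   (unique observed times), `surv`, `n_risk`, `n_event`, `n_censor`.
#' @export
km_estimate <- function(times, events) {
  n <- length(times)
  if (n < 1) stop_param("need at least one observation")
  if (length(events) != n) stop_param("times and events must align")
  ut <- sort(unique(times))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 0)
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), 0)
  n_risk <- vapply(ut, function(t) sum(times >= t), 0)
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, surv = surv, n_risk = n_risk,
                 n_event = n_event, n_censor = n_censor),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, final S = %.3f\n",
              length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

# Evaluate a km_curve at time t (right-continuous); t before the first
# jump gives 1.
km_eval <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
}

#' Quantile-based risk stratification
#'
#' Splits subjects into low- and high-risk groups at a predefined quantile
#' of the (standardized) risk scores: cutoff = the empirical q-quantile
#' (linear interpolation, type 7); risk <= cutoff is low-risk. Used at
#' q = 0.25, 0.50, 0.75 for KM curves and group hazard ratios; applied to a
#' subject subset (e.g. a grade subgroup) it partitions only that subset.
#'
#' @param risks numeric (optionally named; names become ids).
#' @param q quantile in (0, 1).
#' @param ids subject ids (default names of `risks`, else indices).
#' @return object of class `risk_groups`: list with `q`, `cutoff`,
#'   `low_ids`, `high_ids` (a partition of `ids`).
#' @export
stratify_quantile <- function(risks, q, ids = NULL) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop_param("q must be in (0, 1)")
  n <- length(risks)
  if (n < 2) stop_param("need at least 2 subjects")
  if (is.null(ids)) ids <- names(risks) %||% as.character(seq_len(n))
  if (length(unique(risks)) == 1)
    stop_param("all risks identical: quantile split is degenerate")
  cutoff <- unname(stats::quantile(risks, q, type = 7))
  low <- risks <= cutoff
  structure(list(q = q, cutoff = cutoff, low_ids = ids[low],
                 high_ids = ids[!low]),
            class = "risk_groups")
}

#' Hazard ratio of high- vs low-risk group
#'
#' Maximizes the Cox partial likelihood with the single binary covariate
#' "high-risk" (low-risk is the reference) by safeguarded Newton ascent
#' with step halving and Breslow tie handling. Monotone likelihood
#' (perfect separation, e.g. all early deaths in one group) is flagged and
#' the hazard ratio reported as `Inf` (or 0).
#'
#' @param groups a [stratify_quantile()] result.
#' @param times,events named or id-aligned survival vectors: either named
#'   by subject id, or aligned with `c(groups$low_ids, groups$high_ids)`
#'   order via `ids`.
#' @param ids subject ids aligning `times`/`events` with the groups
#'   (default: `names(times)`).
#' @return object of class `cox_hr`: list with `hr`, `beta`, `se`,
#'   `diverged`, `n_low`, `n_high`.
#' @export
cox_hr_binary <- function(groups, times, events, ids = NULL) {
  if (!inherits(groups, "risk_groups")) stop_param("groups must be risk_groups")
  if (is.null(ids)) ids <- names(times)
  if (is.null(ids)) stop_param("supply ids or named times")
  if (length(groups$low_ids) == 0 || length(groups$high_ids) == 0)
    stop_param("both groups must be non-empty")
  m <- match(c(groups$low_ids, groups$high_ids), ids)
  if (anyNA(m)) stop_param("groups reference unknown subject ids")
  x <- c(rep(0, length(groups$low_ids)), rep(1, length(groups$high_ids)))
  tt <- times[m]; dd <- events[m]
  if (sum(dd) < 1) stop_param("no events")
  # risk-set counts per event time (Breslow)
  ev_times <- sort(unique(tt[dd == 1]))
  d_all <- vapply(ev_times, function(t) sum(tt == t & dd == 1), 0)
  d_high <- vapply(ev_times, function(t) sum(tt == t & dd == 1 & x == 1), 0)
  n1 <- vapply(ev_times, function(t) sum(tt >= t & x == 1), 0)
  n0 <- vapply(ev_times, function(t) sum(tt >= t & x == 0), 0)
  loglik <- function(b) sum(d_high * b - d_all * log(n0 + n1 * exp(b)))
  beta <- 0; cap <- 15
  diverged <- FALSE
  for (it in 1:60) {
    eb <- exp(beta)
    pi1 <- n1 * eb / (n0 + n1 * eb)
    score <- sum(d_high - d_all * pi1)
    info <- sum(d_all * pi1 * (1 - pi1))
    if (info < 1e-12) { diverged <- TRUE; break }
    step <- score / info
    ll0 <- loglik(beta)
    # step halving safeguard
    for (h in 0:30) {
      cand <- beta + step / 2^h
      if (loglik(cand) >= ll0 - 1e-12) { beta <- cand; break }
    }
    if (abs(beta) > cap) { diverged <- TRUE; break }
    if (abs(score) < 1e-10) break
  }
  if (abs(beta) > cap) diverged <- TRUE
  eb <- exp(beta); pi1 <- n1 * eb / (n0 + n1 * eb)
  info <- sum(d_all * pi1 * (1 - pi1))
  hr <- if (diverged) { if (beta > 0) Inf else 0 } else exp(beta)
  structure(list(hr = hr, beta = if (diverged) sign(beta) * Inf else beta,
                 se = if (diverged || info < 1e-12) NA_real_ else 1 / sqrt(info),
                 diverged = diverged,
                 n_low = length(groups$low_ids),
                 n_high = length(groups$high_ids)),
            class = "cox_hr")
}

#' @export
print.cox_hr <- function(x, ...) {
  cat(sprintf("<cox_hr> HR = %s (n_low = %d, n_high = %d)%s\n",
              format(x$hr, digits = 4), x$n_low, x$n_high,
              if (x$diverged) " [monotone likelihood]" else ""))
  invisible(x)
}

# Kaplan-Meier of the censoring distribution G(t). Tied event and censor
# times: events precede censorings, so deaths at t have already left the
# risk set of censorings at t.
censoring_km <- function(times, events) {
  ut <- sort(unique(times))
  n_cens <- vapply(ut, function(t) sum(times == t & events == 0), 0)
  n_risk <- vapply(ut, function(t) sum(times >= t) - sum(times == t & events == 1), 0)
  surv <- cumprod(ifelse(n_risk > 0, 1 - n_cens / n_risk, 1))
  list(time = ut, surv = surv, n_cens = n_cens)
}

# G evaluated with a left limit: only censorings strictly before t count.
censor_g <- function(ckm, t, left = FALSE) {
  vapply(t, function(ti) {
    if (left) idx <- which(ckm$time < ti) else idx <- which(ckm$time <= ti)
    if (length(idx) == 0) 1 else ckm$surv[max(idx)]
  }, numeric(1))
}

#' IPCW cumulative/dynamic time-dependent AUC
#'
#' Discrimination at horizon t: cases are subjects with an observed event
#' by t, controls are subjects still at risk beyond t. Censoring is
#' compensated by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution: case i weighs
#' \eqn{1/\hat G(t_i^-)}, controls \eqn{1/\hat G(t)}. Risk ties count 0.5.
#' With zero censoring this reduces exactly to the rank-sum AUC of the
#' indicator time <= t against the risk score.
#'
#' @param risks,times,events aligned vectors.
#' @param horizon evaluation time t.
#' @return AUC in \[0, 1\]; errors when there is no case or no control at t.
#' @export
ipcw_auc <- function(risks, times, events, horizon) {
  n <- length(risks)
  if (length(times) != n || length(events) != n)
    stop_param("risks, times, events must have equal length")
  check_number(horizon, "horizon", positive = TRUE)
  case <- which(times <= horizon & events == 1)
  ctrl <- which(times > horizon)
  if (length(case) == 0) stop_param("no cases (events by t = %g)", horizon)
  if (length(ctrl) == 0) stop_param("no controls (at risk beyond t = %g)", horizon)
  ckm <- censoring_km(times, events)
  w_case <- 1 / censor_g(ckm, times[case], left = TRUE)
  w_ctrl <- rep(1 / censor_g(ckm, horizon), length(ctrl))
  rd <- outer(risks[case], risks[ctrl], "-")
  wm <- outer(w_case, w_ctrl)
  num <- sum(wm * ((rd > 0) + 0.5 * (rd == 0)))
  num / sum(wm)
}

#' Time-dependent AUC panel at fixed horizons
#'
#' [ipcw_auc()] at the standard 1-, 3- and 5-year horizons (12/36/60
#' months); per-horizon precondition failures are reported with the
#' horizon in the error.
#'
#' @param risks,times,events aligned vectors.
#' @param horizons numeric vector of months.
#' @return named numeric vector of AUCs.
#' @export
timepoint_auc_panel <- function(risks, times, events,
                                horizons = c(12, 36, 60)) {
  out <- vapply(horizons, function(h) {
    tryCatch(ipcw_auc(risks, times, events, h),
             error = function(e)
               stop_param("horizon %g: %s", h, conditionMessage(e)))
  }, numeric(1))
  names(out) <- paste0("t", horizons)
  out
}

#' Bootstrap comparison of two models' C-indices
#'
#' Resamples subjects with replacement `n_iter` times; each iteration
#' recomputes \eqn{\Delta C = C_A - C_B}. The 95% CI is the 2.5/97.5
#' percentile of the bootstrap distribution and the two-sided p-value is
#' \eqn{2 \min(P(\Delta \le 0), P(\Delta \ge 0))} clipped to \[0, 1\].
#' Resamples without comparable pairs are redrawn (counted, capped at
#' 100 x `n_iter`). Deterministic given `seed`.
#'
#' @param risks_a,risks_b the two models' risk scores, subject-aligned.
#' @param times,events survival data.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return object of class `bootstrap_result`: `delta` (point estimate on
#'   the full data), `ci`, `p_value`, `n_iter`, `n_redrawn`, `deltas`.
#' @export
bootstrap_delta_c <- function(risks_a, risks_b, times, events,
                              n_iter = 1000L, seed = 1L, conf = 0.95) {
  n <- length(times)
  if (length(risks_a) != n || length(risks_b) != n || length(events) != n)
    stop_param("all vectors must be subject-aligned")
  if (n < 2) stop_param("need at least 2 subjects")
  check_number(n_iter, "n_iter", min = 1)
  set.seed(seed)
  delta_hat <- harrell_c(risks_a, times, events) -
    harrell_c(risks_b, times, events)
  deltas <- numeric(n_iter)
  redrawn <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      d <- tryCatch(harrell_c(risks_a[idx], times[idx], events[idx]) -
                      harrell_c(risks_b[idx], times[idx], events[idx]),
                    error = function(e) NA_real_)
      if (!is.na(d)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_iter)
        stop_param("too many degenerate bootstrap resamples")
    }
    deltas[i] <- d
  }
  alpha <- 1 - conf
  ci <- unname(stats::quantile(deltas, c(alpha / 2, 1 - alpha / 2), type = 7))
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  structure(list(delta = delta_hat, ci = ci, p_value = p,
                 n_iter = as.integer(n_iter), n_redrawn = redrawn,
                 deltas = deltas),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> dC = %.4f, %d iters, CI [%.4f, %.4f], p = %.4g\n",
              x$delta, x$n_iter, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}
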