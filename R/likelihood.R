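# Likelihood internals operate on "prepared" sessions: the IRT start times
# and durations are fixed by the data, so they are extracted once and reused
# across thousands of MCMC evaluations.

.prepare_session <- function(record, include_first_latency = TRUE) {
  times <- record$response_times
  if (length(times) && any(diff(times) <= 0)) {
    stop_data("response times must be strictly increasing")
  }
  if (include_first_latency) {
    taus <- diff(c(0, times))
    starts <- c(0, times[-length(times)])[seq_along(taus)]
  } else {
    taus <- diff(times)
    starts <- times[-length(times)]
  }
  t_last <- if (length(times)) times[length(times)] else 0
  list(starts = starts, taus = taus, t_last = t_last,
       rem = record$session_duration - t_last,
       min_irt = if (length(taus)) min(taus) else Inf)
}

# Log-likelihood of one prepared session for a natural-scale parameter
# vector ordered as .param_names. Returns -Inf when delta exceeds an
# observed interval; no validation beyond that (callers enforce orderings).
.ll_session <- function(prep, nat, censor_tail = TRUE) {
  L0 <- nat[1]; w0 <- nat[2]; b0 <- nat[3]
  ga <- nat[4]; al <- nat[5]; be <- nat[6]
  de <- nat[7]; om <- nat[8]
  if (prep$min_irt < de) return(-Inf)
  ll <- 0
  if (length(prep$taus)) {
    L <- L0 * exp(-ga * prep$starts)
    p <- L / (1 + L)
    w <- (w0 - om) * exp(-al * prep$starts) + om
    b <- (b0 - om) * exp(-be * prep$starts) + om
    u <- prep$taus - de
    la <- log(p) + log(w) - w * u
    lb <- log1p(-p) + log(b) - b * u
    ll <- sum(log_sum_exp(la, lb))
  }
  if (censor_tail && prep$rem > de) {
    tl <- prep$t_last
    L <- L0 * exp(-ga * tl)
    p <- L / (1 + L)
    w <- (w0 - om) * exp(-al * tl) + om
    b <- (b0 - om) * exp(-be * tl) + om
    uc <- prep$rem - de
    ll <- ll + log_sum_exp(log(p) - w * uc, log1p(-p) - b * uc)
  }
  ll
}

.nat_vector <- function(params) {
  unlist(params[.param_names], use.names = FALSE)
}

# Session-2 naturals from session-1 naturals and recovery coefficients
# (ordered as .recovery_names: half-life coefficients divide the rates).
.recovered_nat <- function(nat, coef) {
  c(nat[1] * coef[1], nat[2] * coef[2], nat[3] * coef[3],
    nat[4] / coef[4], nat[5] / coef[5], nat[6] / coef[6],
    nat[7] * coef[7], nat[8] * coef[8])
}

# Ordering/positivity constraints on a natural-scale vector; rate_min is
# the decay-rate floor implied by the half-life cap.
.nat_valid <- function(nat, rate_min = log(2) / HALF_LIFE_CAP) {
  all(is.finite(nat)) &&
    nat[2] > nat[3] && nat[3] >= nat[8] &&
    nat[6] >= nat[5] &&
    nat[4] >= rate_min && nat[5] >= rate_min && nat[6] >= rate_min &&
    nat[7] > 0 && nat[8] > 0 && nat[1] > 0
}

#' Log-likelihood of one rat's extinction data
#'
#' Sums the IRT mixture log-density over every interval of the first (and
#' optionally second) session, with the dynamic parameters evaluated at each
#' interval's start time. Second-session intervals use the recovery-adjusted
#' parameters with the session clock restarted at zero. Two flags control
#' data handling: `include_first_latency` treats the latency from session
#' start to the first response as an ordinary model interval, and
#' `censor_tail` adds a right-censored survival term for the pause from the
#' last response to the end of the session.
#'
#' A refractory period exceeding any observed interval yields `-Inf` (an
#' impossible dataset), not an error.
#'
#' @param record_ext1 `session_record` for session 1.
#' @param record_ext2 Optional `session_record` for session 2 (requires
#'   `coeffs`).
#' @param params Valid `dberm_params` for session 1.
#' @param coeffs `dberm_recovery` mapping session 1 to session 2.
#' @param include_first_latency,censor_tail Logical flags (default `TRUE`).
#' @return Log-likelihood (scalar; may be `-Inf`).
#' @export
rat_log_likelihood <- function(record_ext1, record_ext2 = NULL, params,
                               coeffs = NULL, include_first_latency = TRUE,
                               censor_tail = TRUE) {
  bad <- validate_constraints(params)
  if (length(bad)) {
    stop_constraint(paste0("invalid DBERM parameters: ",
                           paste(bad, collapse = "; ")))
  }
  nat <- .nat_vector(params)
  prep1 <- .prepare_session(record_ext1, include_first_latency)
  ll <- .ll_session(prep1, nat, censor_tail)
  if (!is.null(record_ext2)) {
    if (is.null(coeffs)) {
      stop_data("coeffs required when a second session is supplied")
    }
    nat2 <- .nat_vector(apply_recovery(params, coeffs))
    prep2 <- .prepare_session(record_ext2, include_first_latency)
    ll <- ll + .ll_session(prep2, nat2, censor_tail)
  }
  ll
}

# Flat hyperprior supports on the log-scale location mu, per parameter.
# Decay rates extend down to the floor implied by the half-life cap; all
# other parameters span [1e-4, 1e4] in canonical units (minutes).
.mu_support <- function(param) {
  lo <- if (param %in% c("gamma", "alpha", "beta")) {
    log(log(2) / HALF_LIFE_CAP)
  } else {
    log(1e-4)
  }
  c(lo, log(1e4))
}

#' Hierarchical log-posterior density
#'
#' Evaluates, up to a constant, the joint log-posterior of a cohort: the sum
#' of every rat's [rat_log_likelihood()], plus Gaussian log-densities of the
#' rats' log-scale parameters given their strain's `(mu, sd)`, plus the flat
#' hyperprior (0 inside the declared supports, `-Inf` outside). Locations
#' `mu` are uniform on `[log 1e-4, log 1e4]` in canonical units -- decay
#' rates extend down to the floor implied by the half-life cap -- and
#' population SDs are uniform on `(0, 5]`.
#'
#' @param dataset A `cohort_dataset`.
#' @param individual_params Named list (by rat id) with elements `params`
#'   (`dberm_params`) and optionally `coeffs` (`dberm_recovery`).
#' @param group_hyperparams Named list (by strain) with named numeric
#'   vectors `mu` and `sd` over the eight parameters, and, for two-session
#'   data, `mu_recovery` and `sd_recovery` over the eight coefficients.
#' @param include_first_latency,censor_tail Likelihood flags, as in
#'   [rat_log_likelihood()].
#' @param sd_max Upper bound of the flat prior on population SDs.
#' @return Unnormalised log-posterior (scalar; may be `-Inf`).
#' @export
log_posterior <- function(dataset, individual_params, group_hyperparams,
                          include_first_latency = TRUE, censor_tail = TRUE,
                          sd_max = 5) {
  idx <- cohort_index(dataset)
  lp <- 0
  # flat hyperprior support
  for (s in names(group_hyperparams)) {
    h <- group_hyperparams[[s]]
    for (j in .param_names) {
      sup <- .mu_support(j)
      if (h$mu[[j]] < sup[1] || h$mu[[j]] > sup[2]) return(-Inf)
      if (h$sd[[j]] <= 0 || h$sd[[j]] > sd_max) return(-Inf)
    }
    if (!is.null(h$mu_recovery)) {
      if (any(h$mu_recovery < log(1e-4)) || any(h$mu_recovery > log(1e4))) {
        return(-Inf)
      }
      if (any(h$sd_recovery <= 0) || any(h$sd_recovery > sd_max)) {
        return(-Inf)
      }
    }
  }
  for (rat in names(individual_params)) {
    ind <- individual_params[[rat]]
    recs <- dataset$sessions[vapply(dataset$sessions, function(x)
      x$rat_id == rat, logical(1))]
    if (!length(recs)) stop_data(sprintf("no sessions for rat '%s'", rat))
    ord <- order(vapply(recs, `[[`, 0L, "session_index"))
    recs <- recs[ord]
    strain <- recs[[1]]$strain
    h <- group_hyperparams[[strain]]
    if (is.null(h)) stop_data(sprintf("no hyperparameters for strain '%s'",
                                      strain))
    ll <- rat_log_likelihood(
      recs[[1]], if (length(recs) > 1) recs[[2]] else NULL,
      params = ind$params, coeffs = ind$coeffs,
      include_first_latency = include_first_latency,
      censor_tail = censor_tail)
    th <- log(.nat_vector(ind$params))
    pr <- sum(stats::dnorm(th, unlist(h$mu[.param_names]),
                           unlist(h$sd[.param_names]), log = TRUE))
    if (!is.null(ind$coeffs)) {
      cth <- log(unlist(ind$coeffs[.recovery_names], use.names = FALSE))
      pr <- pr + sum(stats::dnorm(cth, unlist(h$mu_recovery[.recovery_names]),
                                  unlist(h$sd_recovery[.recovery_names]),
                                  log = TRUE))
    }
    lp <- lp + ll + pr
  }
  lp
}
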