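#' Evaluate the dynamic parameters at a session time
#'
#' Computes the exponentially decaying state of the model at time `t`
#' (minutes since session start):
#' `L_t = L0 exp(-gamma t)`,
#' `w_t = (w0 - omega) exp(-alpha t) + omega`,
#' `b_t = (b0 - omega) exp(-beta t) + omega`, and the within-bout mixing
#' probability `p_t = L_t / (1 + L_t)`.
#'
#' @param params A valid `dberm_params` object.
#' @param t Time(s) since session start, minutes, `>= 0`.
#' @return A data frame of class `dberm_state` with columns `t`, `L_t`,
#'   `w_t`, `b_t`, `p_t`, one row per element of `t`.
#' @export
evaluate_dynamics <- function(params, t) {
  bad <- validate_constraints(params)
  if (length(bad)) {
    stop_constraint(paste0("invalid DBERM parameters: ",
                           paste(bad, collapse = "; ")))
  }
  if (any(t < 0)) stop_constraint("t must be >= 0")
  L <- params$L0 * exp(-params$gamma * t)
  w <- (params$w0 - params$omega) * exp(-params$alpha * t) + params$omega
  b <- (params$b0 - params$omega) * exp(-params$beta * t) + params$omega
  structure(
    data.frame(t = t, L_t = L, w_t = w, b_t = b, p_t = L / (1 + L)),
    class = c("dberm_state", "data.frame")
  )
}

#' Probability of remaining within a bout
#'
#' `p = L / (1 + L)` for mean bout length `L`: the chance that the next
#' response is produced by the fast within-bout process rather than by a new
#' bout initiation.
#'
#' @param L Mean bout length(s), `>= 0`.
#' @return Probabilities in `[0, 1)`.
#' @export
bout_stay_probability <- function(L) {
  if (any(L < 0)) stop_constraint("L must be >= 0")
  L / (1 + L)
}

.check_state <- function(state) {
  if (is.null(state$p_t) || is.null(state$w_t) || is.null(state$b_t)) {
    stop_data("state must have fields p_t, w_t and b_t")
  }
  if (any(state$w_t <= state$b_t)) {
    stop_constraint("mixture components not ordered: requires w_t > b_t")
  }
  if (any(state$p_t < 0 | state$p_t >= 1)) {
    stop_constraint("p_t must lie in [0, 1)")
  }
}

#' Log-density of an inter-response time
#'
#' The IRT that starts at session time `t` has density zero below the
#' refractory period and, for `tau >= delta`,
#' `p_t w_t exp(-w_t (tau - delta)) + (1 - p_t) b_t exp(-b_t (tau - delta))`
#' with the state frozen at the IRT's start. Mixing is done in log space
#' (log-sum-exp), so very long IRTs yield large negative but finite values;
#' only `tau < delta` returns `-Inf`.
#'
#' @param state A `dberm_state` row set (or list with `p_t`, `w_t`, `b_t`);
#'   recycled against `tau`.
#' @param delta Refractory period, minutes.
#' @param tau IRT duration(s), minutes, `>= 0`.
#' @return Log-density values (per minute).
#' @export
irt_log_density <- function(state, delta, tau) {
  .check_state(state)
  if (any(delta <= 0)) stop_constraint("delta must be > 0")
  if (any(tau < 0)) stop_constraint("tau must be >= 0")
  u <- tau - delta
  la <- log(state$p_t) + log(state$w_t) - state$w_t * u
  lb <- log1p(-state$p_t) + log(state$b_t) - state$b_t * u
  out <- log_sum_exp(la, lb)
  out[tau < delta] <- -Inf
  out
}

#' Survivor function of the IRT mixture
#'
#' `Pr(IRT > tau)` with the state frozen at the IRT's start: 1 below the
#' refractory period and
#' `p_t exp(-w_t (tau - delta)) + (1 - p_t) exp(-b_t (tau - delta))`
#' thereafter.
#'
#' @inheritParams irt_log_density
#' @return Survivor probabilities in `(0, 1]`.
#' @export
irt_survivor <- function(state, delta, tau) {
  .check_state(state)
  u <- pmax(tau - delta, 0)
  state$p_t * exp(-state$w_t * u) + (1 - state$p_t) * exp(-state$b_t * u)
}

#' @rdname irt_survivor
#' @return `irt_cdf()` returns `1 - irt_survivor()`.
#' @export
irt_cdf <- function(state, delta, tau) {
  1 - irt_survivor(state, delta, tau)
}

#' Mean IRT of the mixture frozen at a state
#'
#' Closed-form expectation `delta + p_t / w_t + (1 - p_t) / b_t`, used as an
#' independent oracle for the Monte-Carlo simulator.
#'
#' @inheritParams irt_log_density
#' @return Expected IRT duration(s), minutes.
#' @export
expected_irt <- function(state, delta) {
  if (is.null(state$p_t) || is.null(state$w_t) || is.null(state$b_t)) {
    stop_data("state must have fields p_t, w_t and b_t")
  }
  if (any(state$w_t <= 0) || any(state$b_t <= 0)) {
    stop_constraint("rates must be > 0")
  }
  delta + state$p_t / state$w_t + (1 - state$p_t) / state$b_t
}
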