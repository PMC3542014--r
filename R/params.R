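#' Half-life cap for decay-rate parameters
#'
#' Decay rates indistinguishable from zero imply unbounded half-lives, which
#' can make posterior summaries of half-lives improper. Half-life estimates
#' are therefore truncated at 5.6e6 minutes (roughly ten years), and decay
#' rates are bounded below by `log(2) / HALF_LIFE_CAP`.
#'
#' @format A numeric scalar, minutes.
#' @export
HALF_LIFE_CAP <- 5.6e6

.param_names <- c("L0", "w0", "b0", "gamma", "alpha", "beta", "delta", "omega")
.recovery_names <- c("L0", "w0", "b0", "H_L", "H_w", "H_b", "delta", "omega")

#' DBERM parameter set for one rat-session
#'
#' Bundles the eight model parameters governing one session: baseline mean
#' bout length `L0` (responses beyond the bout-initiating response), baseline
#' within-bout rate `w0` and bout-initiation rate `b0` (per minute), their
#' exponential decay rates `gamma`, `alpha`, `beta` (per minute), the
#' refractory period `delta` (minutes internally; see
#' [dberm_params_hl()] for second-based input) and the asymptotic rate
#' `omega` (per minute) toward which both `w_t` and `b_t` decay.
#'
#' The model requires `w0 > b0 >= omega >= 0`, `beta >= alpha >= 0`,
#' `gamma >= 0`, `L0 >= 0` and `delta > 0`.
#'
#' @param L0,w0,b0,gamma,alpha,beta,delta,omega Numeric scalars as described
#'   above; all times/rates in minutes.
#' @param check Validate constraints and fail on violation (default `TRUE`).
#' @return An object of class `dberm_params` (a named list).
#' @seealso [validate_constraints()], [dberm_params_hl()]
#' @export
dberm_params <- function(L0, w0, b0, gamma, alpha, beta, delta, omega,
                         check = TRUE) {
  p <- structure(
    list(L0 = as.numeric(L0), w0 = as.numeric(w0), b0 = as.numeric(b0),
         gamma = as.numeric(gamma), alpha = as.numeric(alpha),
         beta = as.numeric(beta), delta = as.numeric(delta),
         omega = as.numeric(omega)),
    class = "dberm_params"
  )
  if (check) {
    bad <- validate_constraints(p)
    if (length(bad)) {
      stop_constraint(paste0("invalid DBERM parameters: ",
                             paste(bad, collapse = "; ")))
    }
  }
  p
}

#' Build DBERM parameters from half-lives and a refractory period in seconds
#'
#' Convenience constructor in reporting units: half-lives of `L`, `w`, `b` in
#' minutes and the refractory period in seconds. Infinite half-lives map to
#' decay rate zero.
#'
#' @param L0,w0,b0,omega As in [dberm_params()].
#' @param H_L,H_w,H_b Half-lives in minutes (positive; may be `Inf`).
#' @param delta_s Refractory period in seconds.
#' @inheritParams dberm_params
#' @return A `dberm_params` object.
#' @export
dberm_params_hl <- function(L0, w0, b0, H_L, H_w, H_b, delta_s, omega,
                            check = TRUE) {
  dberm_params(L0, w0, b0,
               gamma = half_life_to_rate(H_L),
               alpha = half_life_to_rate(H_w),
               beta  = half_life_to_rate(H_b),
               delta = delta_s / 60, omega = omega, check = check)
}

#' @export
print.dberm_params <- function(x, ...) {
  cat("DBERM parameters (one rat-session)\n")
  cat(sprintf("  L0 = %.4g resp   w0 = %.4g /min   b0 = %.4g /min\n",
              x$L0, x$w0, x$b0))
  hl <- half_lives(x)
  cat(sprintf("  half-lives: H_L = %.4g  H_w = %.4g  H_b = %.4g min%s\n",
              hl$half_life[1], hl$half_life[2], hl$half_life[3],
              if (any(hl$capped)) " (capped)" else ""))
  cat(sprintf("  delta = %.4g s   omega = %.4g /min\n",
              x$delta * 60, x$omega))
  invisible(x)
}

#' List violated DBERM parameter constraints
#'
#' Checks the ordering and positivity constraints of the model and names
#' every violated inequality. An empty character vector means the parameter
#' set is valid.
#'
#' @param params A `dberm_params` object (or named list with the same
#'   fields).
#' @return Character vector of violated constraints (possibly empty).
#' @export
validate_constraints <- function(params) {
  v <- character(0)
  p <- params
  vals <- unlist(p[.param_names])
  if (any(!is.finite(vals))) v <- c(v, "all parameters must be finite")
  if (!isTRUE(p$w0 > p$b0)) v <- c(v, "w0 > b0")
  if (!isTRUE(p$b0 >= p$omega)) v <- c(v, "b0 >= omega")
  if (!isTRUE(p$omega >= 0)) v <- c(v, "omega >= 0")
  if (!isTRUE(p$beta >= p$alpha)) v <- c(v, "beta >= alpha")
  if (!isTRUE(p$alpha >= 0)) v <- c(v, "alpha >= 0")
  if (!isTRUE(p$gamma >= 0)) v <- c(v, "gamma >= 0")
  if (!isTRUE(p$L0 >= 0)) v <- c(v, "L0 >= 0")
  if (!isTRUE(p$delta > 0)) v <- c(v, "delta > 0")
  v
}

#' Convert a decay rate to a (capped) half-life
#'
#' `H = log(2) / rate`, truncated at `cap`; a rate of zero maps to the cap.
#' The inverse transform is [half_life_to_rate()]; the pair compose to the
#' identity whenever the half-life is uncapped.
#'
#' @param rate Nonnegative decay rate(s), per minute.
#' @param cap Maximum reportable half-life in minutes
#'   (default [HALF_LIFE_CAP]).
#' @return A list with numeric `half_life` (minutes) and logical `capped`,
#'   each the length of `rate`.
#' @export
rate_to_half_life <- function(rate, cap = HALF_LIFE_CAP) {
  if (any(rate < 0)) stop_constraint("decay rate must be >= 0")
  h <- ifelse(rate == 0, Inf, log(2) / rate)
  capped <- h > cap
  list(half_life = pmin(h, cap), capped = capped)
}

#' @rdname rate_to_half_life
#' @param half_life Half-life (minutes); `Inf` maps to rate 0.
#' @export
half_life_to_rate <- function(half_life) {
  if (any(half_life <= 0)) stop_constraint("half-life must be > 0")
  ifelse(is.infinite(half_life), 0, log(2) / half_life)
}

#' Truncate a half-life summary at the reporting cap
#'
#' @param value Nonnegative half-life value(s), minutes.
#' @inheritParams rate_to_half_life
#' @return List with `value` (capped) and logical `capped`.
#' @export
cap_half_life <- function(value, cap = HALF_LIFE_CAP) {
  if (any(value < 0)) stop_constraint("half-life must be >= 0")
  list(value = pmin(value, cap), capped = value > cap)
}

#' Half-lives of the three decaying parameters
#'
#' @param params A `dberm_params` object.
#' @inheritParams rate_to_half_life
#' @return A data frame with columns `parameter` (`H_L`, `H_w`, `H_b`),
#'   `half_life` (minutes) and `capped`.
#' @export
half_lives <- function(params, cap = HALF_LIFE_CAP) {
  rates <- c(params$gamma, params$alpha, params$beta)
  h <- rate_to_half_life(rates, cap)
  data.frame(parameter = c("H_L", "H_w", "H_b"),
             half_life = h$half_life, capped = h$capped)
}

#' Between-session recovery coefficients
#'
#' One positive multiplicative factor per model parameter relating a rat's
#' second extinction session to its first: the coefficient for a baseline
#' parameter multiplies the baseline, and the coefficient for a half-life
#' multiplies the half-life (so the decay rate is divided by it). A
#' coefficient of 1 means the parameter carried over unchanged; e.g. a
#' session-2 baseline bout length half the session-1 value corresponds to a
#' coefficient of 0.5 on `L0`.
#'
#' @param L0,w0,b0,delta,omega Coefficients on the directly scaled
#'   parameters.
#' @param H_L,H_w,H_b Coefficients on the three half-lives.
#' @return An object of class `dberm_recovery` (a named list).
#' @seealso [apply_recovery()]
#' @export
recovery_coefficients <- function(L0 = 1, w0 = 1, b0 = 1, H_L = 1, H_w = 1,
                                  H_b = 1, delta = 1, omega = 1) {
  x <- list(L0 = L0, w0 = w0, b0 = b0, H_L = H_L, H_w = H_w, H_b = H_b,
            delta = delta, omega = omega)
  x <- lapply(x, as.numeric)
  if (any(!is.finite(unlist(x))) || any(unlist(x) <= 0)) {
    stop_constraint("recovery coefficients must be finite and > 0")
  }
  structure(x, class = "dberm_recovery")
}

#' Map first-session parameters to second-session parameters
#'
#' Applies the multiplicative recovery model: baselines, the refractory
#' period and the asymptotic rate are multiplied by their coefficients, and
#' decay rates are divided by the corresponding half-life coefficients. The
#' result is validated; coefficients that break the parameter orderings
#' raise a constraint violation naming the broken inequality.
#'
#' @param params_ext1 `dberm_params` for the first session.
#' @param coeffs `dberm_recovery` coefficients.
#' @return `dberm_params` for the second session.
#' @export
apply_recovery <- function(params_ext1, coeffs) {
  p <- params_ext1
  dberm_params(
    L0 = p$L0 * coeffs$L0,
    w0 = p$w0 * coeffs$w0,
    b0 = p$b0 * coeffs$b0,
    gamma = p$gamma / coeffs$H_L,
    alpha = p$alpha / coeffs$H_w,
    beta  = p$beta / coeffs$H_b,
    delta = p$delta * coeffs$delta,
    omega = p$omega * coeffs$omega
  )
}

#' Recovery coefficient implied by a pair of parameter values
#'
#' Under the multiplicative between-session model the coefficient for a
#' parameter is simply the ratio of its session-2 to session-1 value.
#'
#' @param x1 Session-1 value (positive).
#' @param x2 Session-2 value (positive).
#' @return `x2 / x1`.
#' @export
recovery_coefficient <- function(x1, x2) {
  if (any(x1 <= 0) || any(x2 <= 0)) {
    stop_constraint("parameter values must be > 0")
  }
  x2 / x1
}

#' Time at which two bout-length trajectories cross
#'
#' Solves `L0_a exp(-gamma_a t) = L0_b exp(-gamma_b t)` in closed form:
#' `t = log(L0_a / L0_b) / (gamma_a - gamma_b)`. Used, for instance, to find
#' when the median bout length of a slowly decaying strain falls below that
#' of a persistent strain.
#'
#' @param params_a,params_b `dberm_params` for the two groups.
#' @return Crossing time in minutes (may be negative if the trajectories
#'   crossed before session start); `NA` if the curves are parallel.
#' @export
bout_length_crossing_time <- function(params_a, params_b) {
  dg <- params_a$gamma - params_b$gamma
  if (dg == 0) return(NA_real_)
  log(params_a$L0 / params_b$L0) / dg
}

#' Maximum instantaneous response rate implied by a refractory period
#'
#' Responses cannot be spaced more closely than the refractory period, so a
#' refractory period of `delta_s` seconds caps the instantaneous rate at
#' `60 / delta_s` responses per minute (e.g. 0.1 s implies 600 resp/min).
#'
#' @param delta_s Refractory period in seconds (> 0).
#' @return Ceiling rate, responses per minute.
#' @export
refractory_rate_ceiling <- function(delta_s) {
  if (any(delta_s <= 0)) stop_constraint("delta must be > 0")
  60 / delta_s
}

#' Reference strain parameter medians
#'
#' Built-in median parameter estimates representative of spontaneously
#' hypertensive (SHR) and Wistar-Kyoto (WKY) rats in a first extinction
#' session after extended variable-interval training. They are the package's
#' default generative values for simulation experiments: SHR shows a higher
#' bout-initiation rate and an essentially non-decaying bout length, WKY a
#' longer baseline bout length whose half-life is about 19 minutes.
#'
#' @param strain `"SHR"` or `"WKY"`.
#' @return A `dberm_params` object.
#' @seealso [reference_recovery()]
#' @export
reference_medians <- function(strain = c("SHR", "WKY")) {
  strain <- match.arg(strain)
  switch(strain,
    SHR = dberm_params_hl(L0 = 0.91, w0 = 253.71, b0 = 42.74,
                          H_L = 2794.48, H_w = 42.94, H_b = 7.77,
                          delta_s = 0.11, omega = 2.37),
    WKY = dberm_params_hl(L0 = 2.81, w0 = 175.68, b0 = 14.70,
                          H_L = 19.37, H_w = 21.28, H_b = 4.69,
                          delta_s = 0.12, omega = 1.64)
  )
}

#' Reference between-session recovery coefficient medians
#'
#' Companion to [reference_medians()]: median recovery coefficients for the
#' same two strains between their first and second extinction sessions.
#'
#' @inheritParams reference_medians
#' @return A `dberm_recovery` object.
#' @export
reference_recovery <- function(strain = c("SHR", "WKY")) {
  strain <- match.arg(strain)
  switch(strain,
    SHR = recovery_coefficients(L0 = 1.44, w0 = 0.85, b0 = 0.73,
                                H_L = 0.15, H_w = 0.52, H_b = 0.44,
                                delta = 1.00, omega = 0.37),
    WKY = recovery_coefficients(L0 = 0.50, w0 = 0.93, b0 = 1.24,
                                H_L = 1.27, H_w = 1.51, H_b = 0.43,
                                delta = 1.09, omega = 0.70)
  )
}
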