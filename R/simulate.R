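#' One rat-session of response times
#'
#' @param response_times Strictly increasing response times since lever
#'   extension, minutes, all within `[0, session_duration]`.
#' @param rat_id,strain Labels.
#' @param session_index 1-based extinction session number.
#' @param session_duration Session length in minutes (default 65).
#' @param first_latency_included Whether the latency from session start to
#'   the first response is treated as an ordinary model interval.
#' @return An object of class `session_record`.
#' @export
session_record <- function(response_times, rat_id, strain, session_index = 1,
                           session_duration = 65,
                           first_latency_included = TRUE) {
  response_times <- as.numeric(response_times)
  if (length(response_times)) {
    if (any(diff(response_times) <= 0)) {
      stop_data("response times must be strictly increasing")
    }
    if (any(response_times < 0) ||
        any(response_times > session_duration)) {
      stop_data("response times must lie in [0, session_duration]")
    }
  }
  structure(
    list(rat_id = as.character(rat_id), strain = as.character(strain),
         session_index = as.integer(session_index),
         response_times = response_times,
         session_duration = as.numeric(session_duration),
         first_latency_included = isTRUE(first_latency_included)),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("session_record: %s (%s) session %d, %d responses in %g min\n",
              x$rat_id, x$strain, x$session_index,
              length(x$response_times), x$session_duration))
  invisible(x)
}

#' Log-normal population distribution of a strain's parameters
#'
#' Individual rats' parameters are modelled as log-normally distributed
#' within a strain: each of the eight model parameters (and, optionally,
#' each of the eight recovery coefficients) has a log-scale location `mu`
#' and log-scale standard deviation. The exponentiated location is the
#' strain's median parameter vector.
#'
#' @param medians A valid `dberm_params` object of strictly positive strain
#'   medians (`exp(mu)`).
#' @param sdlog Log-scale SD: a scalar recycled across parameters or a named
#'   vector over `L0, w0, b0, gamma, alpha, beta, delta, omega`.
#' @param strain Strain label.
#' @param recovery_medians Optional `dberm_recovery` of median coefficients;
#'   required when two-session rats are to be generated.
#' @param recovery_sdlog Log-scale SD for the coefficients (scalar or named
#'   vector); defaults to `sdlog`.
#' @return An object of class `dberm_group`.
#' @export
group_distribution <- function(medians, sdlog = 0.2, strain = "strain",
                               recovery_medians = NULL,
                               recovery_sdlog = sdlog) {
  vals <- unlist(medians[.param_names])
  if (any(vals <= 0)) {
    stop_constraint("log-normal medians must be strictly positive")
  }
  expand_sd <- function(s, nm) {
    if (length(s) == 1) s <- stats::setNames(rep(as.numeric(s), length(nm)), nm)
    if (is.null(names(s)) || !all(nm %in% names(s))) {
      stop_data("sdlog must be a scalar or named over all parameters")
    }
    s <- s[nm]
    if (any(s < 0)) stop_constraint("sdlog must be >= 0")
    s
  }
  g <- list(strain = as.character(strain),
            mu = log(vals),
            sdlog = expand_sd(sdlog, .param_names),
            mu_recovery = NULL, sdlog_recovery = NULL)
  if (!is.null(recovery_medians)) {
    cv <- unlist(recovery_medians[.recovery_names])
    g$mu_recovery <- log(cv)
    g$sdlog_recovery <- expand_sd(recovery_sdlog, .recovery_names)
  }
  structure(g, class = "dberm_group")
}

.params_from_log <- function(theta, check = TRUE) {
  dberm_params(exp(theta[["L0"]]), exp(theta[["w0"]]), exp(theta[["b0"]]),
               exp(theta[["gamma"]]), exp(theta[["alpha"]]),
               exp(theta[["beta"]]), exp(theta[["delta"]]),
               exp(theta[["omega"]]), check = check)
}

#' Draw one rat's parameters from its strain distribution
#'
#' Each parameter is an exponentiated Gaussian draw on the log scale. Draws
#' violating the model's ordering constraints (including constraints on the
#' implied second-session parameters when recovery coefficients are drawn)
#' are rejected and redrawn, up to `max_tries` attempts.
#'
#' @param group A `dberm_group`.
#' @param seed Optional integer seed (RNG state is restored afterwards); if
#'   `NULL`, the current RNG stream is used.
#' @param max_tries Retry budget for constraint rejection (default 1000).
#' @return A list with `params` (`dberm_params`) and `coeffs`
#'   (`dberm_recovery` or `NULL` when the group has no recovery part).
#' @export
sample_individual_params <- function(group, seed = NULL, max_tries = 1000) {
  draw <- function() {
    for (i in seq_len(max_tries)) {
      th <- stats::rnorm(length(group$mu), group$mu, group$sdlog)
      names(th) <- .param_names
      p <- try(.params_from_log(th), silent = TRUE)
      if (inherits(p, "try-error")) next
      if (is.null(group$mu_recovery)) {
        return(list(params = p, coeffs = NULL))
      }
      cth <- stats::rnorm(length(group$mu_recovery), group$mu_recovery,
                          group$sdlog_recovery)
      names(cth) <- .recovery_names
      cf <- do.call(recovery_coefficients, as.list(exp(cth)))
      p2 <- try(apply_recovery(p, cf), silent = TRUE)
      if (inherits(p2, "try-error")) next
      return(list(params = p, coeffs = cf))
    }
    stop_constraint(
      "retry budget exhausted: group distribution incompatible with the parameter constraints")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate one extinction session by sequential Monte Carlo sampling
#'
#' Generates response times by iterating from session time 0: (1) update the
#' dynamic parameters at the current time, (2) sample the bout state
#' (within-bout with probability `p_t`), (3) sample an exponential pause
#' with mean `1/w_t` or `1/b_t` accordingly, (4) add the refractory period
#' to obtain the IRT and advance the clock. The loop stops once the clock
#' exceeds the session duration; the overshooting response is discarded.
#'
#' @param params A valid `dberm_params`.
#' @param duration Session length, minutes (default 65).
#' @param seed Optional integer seed; RNG state is restored afterwards.
#' @param rat_id,strain,session_index Labels stored on the record.
#' @return A `session_record`. The first response time is itself the first
#'   model interval (latency from session start).
#' @export
simulate_session <- function(params, duration = 65, seed = NULL,
                             rat_id = "rat1", strain = "synthetic",
                             session_index = 1) {
  bad <- validate_constraints(params)
  if (length(bad)) {
    stop_constraint(paste0("invalid DBERM parameters: ",
                           paste(bad, collapse = "; ")))
  }
  if (duration <= 0) stop_constraint("duration must be > 0")
  run <- function() {
    L0 <- params$L0; w0 <- params$w0; b0 <- params$b0
    ga <- params$gamma; al <- params$alpha; be <- params$beta
    de <- params$delta; om <- params$omega
    cap <- 1024L
    times <- numeric(cap)
    n <- 0L
    t <- 0
    repeat {
      L <- L0 * exp(-ga * t)
      p <- L / (1 + L)
      rate <- if (stats::runif(1) < p) {
        (w0 - om) * exp(-al * t) + om
      } else {
        (b0 - om) * exp(-be * t) + om
      }
      t <- t + stats::rexp(1, rate) + de
      if (t > duration) break
      n <- n + 1L
      if (n > cap) {
        times <- c(times, numeric(cap))
        cap <- cap * 2L
      }
      times[n] <- t
    }
    session_record(times[seq_len(n)], rat_id = rat_id, strain = strain,
                   session_index = session_index, session_duration = duration)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a rat across extinction sessions
#'
#' The first session is generated from `params_ext1`; each later session
#' re-applies the recovery coefficients to the previous session's parameters
#' and restarts the session clock at zero.
#'
#' @param params_ext1 `dberm_params` for session 1.
#' @param coeffs `dberm_recovery`, required when more than one session is
#'   requested.
#' @param durations Session durations in minutes, one per session.
#' @param seed Optional root seed; per-session streams are derived from it.
#' @param rat_id,strain Labels.
#' @return List of `session_record`, one per session.
#' @export
simulate_rat <- function(params_ext1, coeffs = NULL, durations = c(65, 65),
                         seed = NULL, rat_id = "rat1", strain = "synthetic") {
  n_sessions <- length(durations)
  if (n_sessions > 1 && is.null(coeffs)) {
    stop_data("recovery coefficients are required for multi-session rats")
  }
  p <- params_ext1
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    if (s > 1) p <- apply_recovery(p, coeffs)
    s_seed <- if (is.null(seed)) NULL else derive_seed(seed, s)
    out[[s]] <- simulate_session(p, duration = durations[s], seed = s_seed,
                                 rat_id = rat_id, strain = strain,
                                 session_index = s)
  }
  out
}

#' Simulate a multi-strain cohort
#'
#' Draws each rat's parameters from its strain's log-normal population and
#' simulates every session. Substream seeds are derived deterministically
#' per rat and session from the root seed, so enlarging the cohort never
#' reshuffles existing rats and the dataset is reproducible byte-for-byte
#' from `(groups, sizes, seed)`.
#'
#' @param groups List of `dberm_group`, one per strain.
#' @param n_rats_per_strain Rats per strain (default 6).
#' @param n_sessions 1 or 2 extinction sessions (default 2; recovery
#'   coefficients are only consumed when `n_sessions == 2`).
#' @param duration Session duration, minutes (default 65).
#' @param seed Root integer seed (default 1).
#' @return An object of class `cohort_dataset`: a list with `sessions` (flat
#'   list of `session_record`) and `metadata` (seed, design, generative
#'   groups and every rat's true parameters).
#' @export
simulate_cohort <- function(groups, n_rats_per_strain = 6, n_sessions = 2,
                            duration = 65, seed = 1) {
  if (n_rats_per_strain < 1) stop_data("need at least one rat per strain")
  if (!n_sessions %in% c(1L, 2L)) stop_data("n_sessions must be 1 or 2")
  if (!is.list(groups) || !length(groups)) stop_data("groups must be a list")
  if (inherits(groups, "dberm_group")) groups <- list(groups)
  sessions <- list()
  truth <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (n_sessions == 2 && is.null(g$mu_recovery)) {
      stop_data(sprintf(
        "group '%s' has no recovery distribution but n_sessions = 2",
        g$strain))
    }
    for (ri in seq_len(n_rats_per_strain)) {
      rat_id <- paste0(g$strain, ri)
      ind <- sample_individual_params(g, seed = derive_seed(seed, gi, ri))
      coeffs <- if (n_sessions == 2) ind$coeffs else NULL
      recs <- simulate_rat(ind$params, coeffs,
                           durations = rep(duration, n_sessions),
                           seed = derive_seed(seed, gi, ri, 7L),
                           rat_id = rat_id, strain = g$strain)
      sessions <- c(sessions, recs)
      truth[[rat_id]] <- list(params = ind$params, coeffs = coeffs)
    }
  }
  structure(
    list(sessions = sessions,
         metadata = list(seed = as.integer(seed),
                         n_rats_per_strain = as.integer(n_rats_per_strain),
                         n_sessions = as.integer(n_sessions),
                         duration = duration,
                         strains = vapply(groups, `[[`, "", "strain"),
                         groups = groups,
                         truth = truth)),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  idx <- cohort_index(x)
  cat(sprintf("cohort_dataset: %d rats (%s), %d session records, %d responses\n",
              length(unique(idx$rat_id)),
              paste(unique(idx$strain), collapse = "/"),
              nrow(idx), sum(idx$n_responses)))
  invisible(x)
}

#' Tabulate the sessions of a cohort
#'
#' @param dataset A `cohort_dataset`.
#' @return Data frame with one row per session record: `rat_id`, `strain`,
#'   `session_index`, `n_responses`, `session_duration`.
#' @export
cohort_index <- function(dataset) {
  do.call(rbind, lapply(dataset$sessions, function(s) {
    data.frame(rat_id = s$rat_id, strain = s$strain,
               session_index = s$session_index,
               n_responses = length(s$response_times),
               session_duration = s$session_duration,
               stringsAsFactors = FALSE)
  }))
}
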