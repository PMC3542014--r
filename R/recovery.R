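#' Generative overrides for preconfigured recovery scenarios
#'
#' Two stress-test scenarios probe whether a short-bout strain's bout-length
#' half-life can be recovered without bias: `"hl_swap"` keeps the SHR
#' reference medians but sources the bout-length decay rate from the WKY
#' reference value (swapping `H_L` between strains), and
#' `"hl_swap_l0_third"` additionally shortens the generative SHR `L0` by a
#' factor of 3. `"none"` returns no overrides.
#'
#' @param scenario Scenario name.
#' @return A named list (by strain) of named numeric vectors of replacement
#'   generative medians, suitable for [recovery_experiment()]'s `overrides`.
#' @export
recovery_scenario <- function(scenario = c("none", "hl_swap",
                                           "hl_swap_l0_third")) {
  scenario <- match.arg(scenario)
  if (scenario == "none") return(list())
  wky_gamma <- reference_medians("WKY")$gamma
  ov <- list(SHR = c(gamma = wky_gamma))
  if (scenario == "hl_swap_l0_third") {
    ov$SHR <- c(ov$SHR, L0 = reference_medians("SHR")$L0 / 3)
  }
  ov
}

.apply_overrides <- function(groups, overrides) {
  for (s in names(overrides)) {
    gi <- which(vapply(groups, `[[`, "", "strain") == s)
    if (!length(gi)) stop_data(sprintf("override for unknown strain '%s'", s))
    for (p in names(overrides[[s]])) {
      if (!p %in% .param_names) {
        stop_data(sprintf("override for unknown parameter '%s'", p))
      }
      groups[[gi]]$mu[[p]] <- log(overrides[[s]][[p]])
    }
  }
  groups
}

#' Parameter-recovery simulation experiment
#'
#' Repeatedly simulates cohorts from known group distributions, fits the
#' hierarchical model to each, and compares the recovered group-level
#' posteriors with the generative medians. For every replicate, strain and
#' parameter the report records the generative median, the posterior median
#' and 95% credible interval of the back-transformed group location, a
#' coverage flag (generative value inside the interval) and the log-scale
#' bias. Aggregate coverage near 95% on well-specified simulations is the
#' calibration benchmark.
#'
#' @param generative List of `dberm_group` generative distributions (one per
#'   strain), e.g. built from [reference_medians()].
#' @param overrides Optional named list (by strain) of named replacement
#'   medians, or the output of [recovery_scenario()].
#' @param n_reps Number of replicate simulate-fit cycles (default 20).
#' @param n_rats_per_strain,n_sessions,duration Cohort design passed to
#'   [simulate_cohort()].
#' @param fit_config [mcmc_config()] used for every fit.
#' @param seed Root seed; replicate streams are derived from it.
#' @return A data frame of class `recovery_report`: columns `replicate`,
#'   `strain`, `parameter`, `generative`, `median`, `lower`, `upper`
#'   (linear scale), `covered`, `log_bias`.
#' @export
recovery_experiment <- function(generative, overrides = list(), n_reps = 20,
                                n_rats_per_strain = 6, n_sessions = 1,
                                duration = 65,
                                fit_config = mcmc_config(n_retain = 2000,
                                                         burn_in = 1000),
                                seed = 1) {
  groups <- .apply_overrides(generative, overrides)
  out <- list()
  for (rep in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, rep)
    cohort <- simulate_cohort(groups,
                              n_rats_per_strain = n_rats_per_strain,
                              n_sessions = n_sessions, duration = duration,
                              seed = rep_seed)
    chains <- run_mcmc(cohort, config = fit_config,
                       seed = derive_seed(seed, rep, 2L))
    for (g in groups) {
      s <- g$strain
      for (p in .param_names) {
        logs <- chains$samples[, paste("mu", s, p, sep = ".")]
        q <- stats::quantile(logs, c(0.5, 0.025, 0.975), names = FALSE)
        gen <- exp(g$mu[[p]])
        out[[length(out) + 1]] <- data.frame(
          replicate = rep, strain = s, parameter = p,
          generative = gen, median = exp(q[1]), lower = exp(q[2]),
          upper = exp(q[3]),
          covered = q[2] <= g$mu[[p]] && g$mu[[p]] <= q[3],
          log_bias = q[1] - g$mu[[p]],
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, out),
            class = c("recovery_report", "data.frame"),
            seed = seed, n_reps = n_reps)
}

#' Aggregate a recovery report
#'
#' @param report A `recovery_report`.
#' @return Data frame per strain and parameter: coverage proportion and mean
#'   log-scale bias across replicates.
#' @export
recovery_coverage <- function(report) {
  agg <- stats::aggregate(cbind(covered, log_bias) ~ strain + parameter,
                          data = report, FUN = mean)
  names(agg)[names(agg) == "covered"] <- "coverage"
  names(agg)[names(agg) == "log_bias"] <- "mean_log_bias"
  agg
}
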