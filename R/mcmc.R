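#' Sampler configuration
#'
#' Defaults mirror the package's standard analysis: 20,100 retained samples
#' after a 5,000-sample burn-in, the first latency included as a model
#' interval, and the terminal pause entering as a right-censored term.
#' Proposal scales adapt toward a 0.44 acceptance rate during burn-in and
#' are frozen afterwards.
#'
#' @param n_retain Retained (post burn-in) samples.
#' @param burn_in Discarded initial samples, during which proposal scales
#'   adapt.
#' @param include_first_latency,censor_tail Likelihood flags; see
#'   [rat_log_likelihood()].
#' @param target_accept Target acceptance rate for the scalar random-walk
#'   updates.
#' @param adapt_batch Batch length (iterations) between adaptation steps.
#' @param sd_max Upper bound of the flat prior on population SDs.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_retain = 20100, burn_in = 5000,
                        include_first_latency = TRUE, censor_tail = TRUE,
                        target_accept = 0.44, adapt_batch = 50, sd_max = 5) {
  stopifnot(n_retain >= 1, burn_in >= 0, adapt_batch >= 1,
            target_accept > 0, target_accept < 1, sd_max > 0)
  structure(
    list(n_retain = as.integer(n_retain), burn_in = as.integer(burn_in),
         include_first_latency = isTRUE(include_first_latency),
         censor_tail = isTRUE(censor_tail),
         target_accept = target_accept,
         adapt_batch = as.integer(adapt_batch), sd_max = sd_max),
    class = "mcmc_config"
  )
}

# Crude data-driven starting values for one rat: classify IRTs as short
# (within-bout) or long by their geometric midpoint, then method-of-moments.
# Burn-in adaptation does the fine work; this only needs to be finite.
.init_params <- function(preps, durations) {
  taus <- unlist(lapply(preps, `[[`, "taus"))
  total_t <- sum(durations)
  rmin <- log(2) / HALF_LIFE_CAP
  if (!length(taus)) {
    nat <- c(1, 60, 2, log(2) / 30, log(2) / 60, log(2) / 10, 0.002, 0.2)
  } else {
    dmin <- min(taus)
    de <- 0.9 * dmin
    cut <- exp(mean(range(log(taus))))
    short <- taus[taus <= cut]
    frac <- length(short) / length(taus)
    frac <- min(max(frac, 0.02), 0.95)
    L0 <- frac / (1 - frac)
    w0 <- 1 / max(mean(short) - de, 1e-4)
    b0 <- max(length(taus) * (1 - frac) / total_t, 0.5)
    if (w0 <= 2 * b0) w0 <- 3 * b0
    d1 <- durations[1]
    nat <- c(L0, w0, b0,
             log(2) / d1,          # gamma: halves over one session
             log(2) / d1,          # alpha
             log(2) / (d1 / 4),    # beta: bout rate decays faster
             de, 0.2 * b0)
  }
  nat[4:6] <- pmax(nat[4:6], rmin)
  names(nat) <- .param_names
  nat
}

# One adaptive random-walk Metropolis step on a scalar, given the
# log-target difference callback. Used for every scalar in the Gibbs sweep.
.rw_adapt_factor <- function(batch) min(0.05, 1 / sqrt(batch))

#' Hierarchical MCMC estimation of the bout model
#'
#' Fits the hierarchical model by adaptive Metropolis-within-Gibbs: each
#' rat's eight log-scale parameters (and eight log recovery coefficients
#' when the rat has a second session) and each strain's log-normal
#' hyperparameters `(mu, sd)` are updated one scalar at a time by Gaussian
#' random walks. Proposals violating the model's ordering constraints
#' (`w0 > b0 >= omega`, `beta >= alpha`, decay rates above the floor implied
#' by the half-life cap) are rejected, so every retained sample is a valid
#' parameter set. Flat hyperpriors are bounded as described in
#' [log_posterior()]. Runs are exactly reproducible from the seed.
#'
#' @param dataset A `cohort_dataset` with at least one rat per strain.
#' @param config An [mcmc_config()].
#' @param seed Integer seed.
#' @return An object of class `dberm_chains`: retained samples (matrix, one
#'   named column per scalar; individual parameters on the log scale),
#'   per-column acceptance rates, split-half R-hat diagnostics for the
#'   hyperparameters, the rat/strain layout, the config and the seed.
#' @export
run_mcmc <- function(dataset, config = mcmc_config(), seed = 1) {
  with_seed(seed, .run_mcmc_impl(dataset, config, seed))
}

.run_mcmc_impl <- function(dataset, config, seed) {
  rmin <- log(2) / HALF_LIFE_CAP
  idx <- cohort_index(dataset)
  rat_ids <- unique(idx$rat_id)
  n_rats <- length(rat_ids)
  if (!n_rats) stop_data("dataset has no sessions")
  rat_strain <- vapply(rat_ids, function(r)
    idx$strain[idx$rat_id == r][1], "")
  strains <- unique(rat_strain)

  # prepared data per rat (sessions ordered by index)
  preps <- list(); durations <- list()
  for (r in rat_ids) {
    recs <- dataset$sessions[vapply(dataset$sessions, function(x)
      x$rat_id == r, logical(1))]
    recs <- recs[order(vapply(recs, `[[`, 0L, "session_index"))]
    if (length(recs) > 2) stop_data("at most two sessions per rat")
    preps[[r]] <- lapply(recs, .prepare_session,
                         include_first_latency = config$include_first_latency)
    durations[[r]] <- vapply(recs, `[[`, 0, "session_duration")
  }
  n_sess <- vapply(preps, length, 0L)
  has2 <- n_sess == 2L

  npar <- length(.param_names)
  # state: log-scale individual parameters and coefficients
  theta <- matrix(0, n_rats, npar,
                  dimnames = list(rat_ids, .param_names))
  for (ri in seq_len(n_rats)) {
    theta[ri, ] <- log(.init_params(preps[[ri]], durations[[ri]]))
  }
  ctheta <- matrix(0, n_rats, npar,
                   dimnames = list(rat_ids, .recovery_names))
  nat <- exp(theta)
  cnat <- exp(ctheta)

  mu <- matrix(0, length(strains), npar, dimnames = list(strains, .param_names))
  sdv <- matrix(0.4, length(strains), npar,
                dimnames = list(strains, .param_names))
  cmu <- matrix(0, length(strains), npar,
                dimnames = list(strains, .recovery_names))
  csd <- matrix(0.4, length(strains), npar,
                dimnames = list(strains, .recovery_names))
  for (s in strains) {
    rows <- which(rat_strain == s)
    m <- if (length(rows) > 1) colMeans(theta[rows, , drop = FALSE]) else
      theta[rows, ]
    sup_lo <- vapply(.param_names, function(j) .mu_support(j)[1], 0)
    sup_hi <- vapply(.param_names, function(j) .mu_support(j)[2], 0)
    mu[s, ] <- pmin(pmax(m, sup_lo), sup_hi)
  }

  # cached log-likelihood per rat-session
  ll <- matrix(0, n_rats, 2)
  sess_nat <- function(ri, s) {
    if (s == 1) nat[ri, ] else .recovered_nat(nat[ri, ], cnat[ri, ])
  }
  for (ri in seq_len(n_rats)) {
    for (s in seq_len(n_sess[ri])) {
      ll[ri, s] <- .ll_session(preps[[ri]][[s]], sess_nat(ri, s),
                               config$censor_tail)
    }
    if (!all(is.finite(ll[ri, seq_len(n_sess[ri])]))) {
      stop_dberm(sprintf(
        "non-finite log-likelihood at initialization for rat '%s'",
        rat_ids[ri]), "dberm_init_error")
    }
  }

  # proposal scales and acceptance bookkeeping
  sc_th <- matrix(0.15, n_rats, npar); sc_cth <- matrix(0.15, n_rats, npar)
  sc_mu <- matrix(0.25, length(strains), npar)
  sc_sd <- matrix(0.15, length(strains), npar)
  sc_cmu <- matrix(0.25, length(strains), npar)
  sc_csd <- matrix(0.15, length(strains), npar)
  acc <- list(th = 0 * sc_th, cth = 0 * sc_cth, mu = 0 * sc_mu,
              sd = 0 * sc_sd, cmu = 0 * sc_cmu, csd = 0 * sc_csd)
  bat <- lapply(acc, function(x) x)  # per-batch acceptance counts
  acc_total <- lapply(acc, function(x) x)

  mu_lo <- vapply(.param_names, function(j) .mu_support(j)[1], 0)
  mu_hi <- vapply(.param_names, function(j) .mu_support(j)[2], 0)

  n_iter <- config$burn_in + config$n_retain
  keep_cols <- c(
    as.vector(outer(rat_ids, .param_names,
                    function(r, p) paste("theta", r, p, sep = "."))),
    if (any(has2)) as.vector(outer(rat_ids[has2], .recovery_names,
                    function(r, p) paste("ctheta", r, p, sep = "."))),
    as.vector(outer(strains, .param_names,
                    function(s, p) paste("mu", s, p, sep = "."))),
    as.vector(outer(strains, .param_names,
                    function(s, p) paste("sd", s, p, sep = "."))),
    if (any(has2)) c(
      as.vector(outer(strains, .recovery_names,
                      function(s, p) paste("mu", s, "C", p, sep = "."))),
      as.vector(outer(strains, .recovery_names,
                      function(s, p) paste("sd", s, "C", p, sep = "."))))
  )
  samples <- matrix(NA_real_, config$n_retain, length(keep_cols),
                    dimnames = list(NULL, keep_cols))

  snapshot <- function() {
    c(as.vector(theta),
      if (any(has2)) as.vector(ctheta[has2, , drop = FALSE]),
      as.vector(mu), as.vector(sdv),
      if (any(has2)) c(as.vector(cmu), as.vector(csd)))
  }
  # column order check: outer() varies rats fastest, as does as.vector()
  stopifnot(length(snapshot()) == length(keep_cols))

  nat_ok <- function(v) {
    all(is.finite(v)) && v[2] > v[3] && v[3] >= v[8] &&
      v[6] >= v[5] && v[4] >= rmin && v[5] >= rmin && v[6] >= rmin
  }

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= config$burn_in
    # --- individual base parameters -------------------------------------
    for (ri in seq_len(n_rats)) {
      s <- rat_strain[ri]
      for (j in seq_len(npar)) {
        prop <- theta[ri, j] + stats::rnorm(1, 0, sc_th[ri, j])
        v <- nat[ri, ]; v[j] <- exp(prop)
        if (!nat_ok(v)) next
        ll1 <- .ll_session(preps[[ri]][[1]], v, config$censor_tail)
        ll2 <- if (has2[ri]) {
          v2 <- .recovered_nat(v, cnat[ri, ])
          if (!nat_ok(v2)) next
          .ll_session(preps[[ri]][[2]], v2, config$censor_tail)
        } else 0
        cur_ll2 <- if (has2[ri]) ll[ri, 2] else 0
        lr <- (ll1 + ll2) - (ll[ri, 1] + cur_ll2) +
          stats::dnorm(prop, mu[s, j], sdv[s, j], log = TRUE) -
          stats::dnorm(theta[ri, j], mu[s, j], sdv[s, j], log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          theta[ri, j] <- prop; nat[ri, j] <- v[j]
          ll[ri, 1] <- ll1
          if (has2[ri]) ll[ri, 2] <- ll2
          bat$th[ri, j] <- bat$th[ri, j] + 1
          if (!adapting) acc_total$th[ri, j] <- acc_total$th[ri, j] + 1
        }
      }
      # --- recovery coefficients --------------------------------------
      if (has2[ri]) {
        for (j in seq_len(npar)) {
          prop <- ctheta[ri, j] + stats::rnorm(1, 0, sc_cth[ri, j])
          cv <- cnat[ri, ]; cv[j] <- exp(prop)
          v2 <- .recovered_nat(nat[ri, ], cv)
          if (!nat_ok(v2)) next
          ll2 <- .ll_session(preps[[ri]][[2]], v2, config$censor_tail)
          lr <- ll2 - ll[ri, 2] +
            stats::dnorm(prop, cmu[s, j], csd[s, j], log = TRUE) -
            stats::dnorm(ctheta[ri, j], cmu[s, j], csd[s, j], log = TRUE)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            ctheta[ri, j] <- prop; cnat[ri, j] <- cv[j]
            ll[ri, 2] <- ll2
            bat$cth[ri, j] <- bat$cth[ri, j] + 1
            if (!adapting) acc_total$cth[ri, j] <- acc_total$cth[ri, j] + 1
          }
        }
      }
    }
    # --- hyperparameters ------------------------------------------------
    for (si in seq_along(strains)) {
      rows <- which(rat_strain == strains[si])
      for (j in seq_len(npar)) {
        th_j <- theta[rows, j]
        # location
        prop <- mu[si, j] + stats::rnorm(1, 0, sc_mu[si, j])
        if (prop >= mu_lo[j] && prop <= mu_hi[j]) {
          lr <- sum(stats::dnorm(th_j, prop, sdv[si, j], log = TRUE)) -
            sum(stats::dnorm(th_j, mu[si, j], sdv[si, j], log = TRUE))
          if (log(stats::runif(1)) < lr) {
            mu[si, j] <- prop
            bat$mu[si, j] <- bat$mu[si, j] + 1
            if (!adapting) acc_total$mu[si, j] <- acc_total$mu[si, j] + 1
          }
        }
        # scale (flat prior on the SD itself)
        prop <- sdv[si, j] + stats::rnorm(1, 0, sc_sd[si, j])
        if (prop > 0 && prop <= config$sd_max) {
          lr <- sum(stats::dnorm(th_j, mu[si, j], prop, log = TRUE)) -
            sum(stats::dnorm(th_j, mu[si, j], sdv[si, j], log = TRUE))
          if (log(stats::runif(1)) < lr) {
            sdv[si, j] <- prop
            bat$sd[si, j] <- bat$sd[si, j] + 1
            if (!adapting) acc_total$sd[si, j] <- acc_total$sd[si, j] + 1
          }
        }
        if (any(has2[rows])) {
          cth_j <- ctheta[rows[has2[rows]], j]
          prop <- cmu[si, j] + stats::rnorm(1, 0, sc_cmu[si, j])
          if (prop >= log(1e-4) && prop <= log(1e4)) {
            lr <- sum(stats::dnorm(cth_j, prop, csd[si, j], log = TRUE)) -
              sum(stats::dnorm(cth_j, cmu[si, j], csd[si, j], log = TRUE))
            if (log(stats::runif(1)) < lr) {
              cmu[si, j] <- prop
              bat$cmu[si, j] <- bat$cmu[si, j] + 1
              if (!adapting) acc_total$cmu[si, j] <- acc_total$cmu[si, j] + 1
            }
          }
          prop <- csd[si, j] + stats::rnorm(1, 0, sc_csd[si, j])
          if (prop > 0 && prop <= config$sd_max) {
            lr <- sum(stats::dnorm(cth_j, cmu[si, j], prop, log = TRUE)) -
              sum(stats::dnorm(cth_j, cmu[si, j], csd[si, j], log = TRUE))
            if (log(stats::runif(1)) < lr) {
              csd[si, j] <- prop
              bat$csd[si, j] <- bat$csd[si, j] + 1
              if (!adapting) acc_total$csd[si, j] <- acc_total$csd[si, j] + 1
            }
          }
        }
      }
    }
    # --- adaptation (burn-in only, diminishing) -------------------------
    if (adapting && iter %% config$adapt_batch == 0) {
      f <- .rw_adapt_factor(iter / config$adapt_batch)
      adj <- function(sc, b) {
        rate <- b / config$adapt_batch
        sc * exp(ifelse(rate > config$target_accept, f, -f))
      }
      sc_th <- adj(sc_th, bat$th); sc_cth <- adj(sc_cth, bat$cth)
      sc_mu <- adj(sc_mu, bat$mu); sc_sd <- adj(sc_sd, bat$sd)
      sc_cmu <- adj(sc_cmu, bat$cmu); sc_csd <- adj(sc_csd, bat$csd)
      bat <- lapply(bat, function(x) 0 * x)
    }
    if (iter > config$burn_in) {
      samples[iter - config$burn_in, ] <- snapshot()
    }
  }

  accept_rate <- lapply(acc_total, function(x) x / config$n_retain)
  chains <- structure(
    list(samples = samples,
         rats = data.frame(rat_id = rat_ids, strain = rat_strain,
                           n_sessions = as.integer(n_sess),
                           stringsAsFactors = FALSE, row.names = NULL),
         strains = strains,
         config = config, seed = as.integer(seed),
         accept = accept_rate),
    class = "dberm_chains"
  )
  chains$diagnostics <- list(rhat = .split_rhat(chains))
  chains
}

# Split-half potential-scale-reduction for the hyperparameter columns: a
# cheap single-chain stationarity check.
.split_rhat <- function(chains) {
  cols <- grep("^(mu|sd)\\.", colnames(chains$samples), value = TRUE)
  n <- nrow(chains$samples)
  h <- floor(n / 2)
  vapply(cols, function(cn) {
    x1 <- chains$samples[seq_len(h), cn]
    x2 <- chains$samples[seq_len(h) + h, cn]
    w <- (stats::var(x1) + stats::var(x2)) / 2
    bm <- h * (mean(x1) - mean(x2))^2 / 2
    if (w == 0) return(1)
    sqrt(((h - 1) / h * w + bm / h) / w)
  }, 0)
}

#' @export
print.dberm_chains <- function(x, ...) {
  cat(sprintf(
    "dberm_chains: %d retained samples (burn-in %d), %d rats, strains: %s\n",
    nrow(x$samples), x$config$burn_in, nrow(x$rats),
    paste(x$strains, collapse = ", ")))
  rh <- x$diagnostics$rhat
  cat(sprintf("  max split R-hat (hyperparameters): %.3f\n", max(rh)))
  invisible(x)
}

# Generic adaptive scalar random-walk sampler for a univariate log-target.
# Shares the adaptation rule of the hierarchical sampler; used to validate
# the Metropolis machinery against conjugate closed forms.
.sample_scalar_chain <- function(log_target, init, n_retain, burn_in = 500,
                                 scale = 0.5, target_accept = 0.44,
                                 adapt_batch = 50, seed = 1) {
  with_seed(seed, {
    x <- init
    lx <- log_target(x)
    if (!is.finite(lx)) stop_dberm("non-finite target at init",
                                   "dberm_init_error")
    out <- numeric(n_retain)
    nb <- 0L
    for (iter in seq_len(burn_in + n_retain)) {
      prop <- x + stats::rnorm(1, 0, scale)
      lp <- log_target(prop)
      if (is.finite(lp) && log(stats::runif(1)) < lp - lx) {
        x <- prop; lx <- lp; nb <- nb + 1L
      }
      if (iter <= burn_in && iter %% adapt_batch == 0) {
        f <- .rw_adapt_factor(iter / adapt_batch)
        scale <- scale * exp(if (nb / adapt_batch > target_accept) f else -f)
        nb <- 0L
      }
      if (iter > burn_in) out[iter - burn_in] <- x
    }
    out
  })
}
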