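test_that("empty sessions contribute nothing without censoring", {
  rec <- session_record(numeric(0), "r1", "WKY", session_duration = 65)
  p <- reference_medians("WKY")
  expect_identical(
    rat_log_likelihood(rec, params = p, censor_tail = FALSE), 0)
  # with censoring the whole silent session is one survival term
  # (log-space mixture: the direct survivor underflows at 65 min)
  ll <- rat_log_likelihood(rec, params = p, censor_tail = TRUE)
  st <- evaluate_dynamics(p, 0)
  uc <- 65 - p$delta
  expect_equal(ll, dberm:::log_sum_exp(log(st$p_t) - st$w_t * uc,
                                       log1p(-st$p_t) - st$b_t * uc))
  expect_true(is.finite(ll))
})

test_that("an IRT shorter than the refractory period is impossible", {
  p <- static_params(delta = 0.01)
  rec <- session_record(c(0.005), "r1", "X", session_duration = 1)
  expect_identical(rat_log_likelihood(rec, params = p), -Inf)
})

test_that("single-process likelihood matches the shifted-exponential oracle", {
  p <- static_params(L0 = 0, w0 = 60, b0 = 8, delta = 0.003)
  rec <- simulate_session(p, duration = 15, seed = 21)
  irts <- record_irts(rec)
  expect_gt(length(irts), 50)
  oracle <- sum(log(p$b0) - p$b0 * (irts - p$delta)) -
    p$b0 * (rec$session_duration - max(rec$response_times) - p$delta)
  got <- rat_log_likelihood(rec, params = p)
  expect_equal(got, oracle, tolerance = 1e-10)
  # excluding the first latency removes exactly its term
  got2 <- rat_log_likelihood(rec, params = p,
                             include_first_latency = FALSE)
  expect_equal(got - got2,
               log(p$b0) - p$b0 * (irts[1] - p$delta), tolerance = 1e-10)
})

test_that("two-session likelihood applies the recovery map with its own clock", {
  p <- static_params(L0 = 1, w0 = 60, b0 = 10, delta = 0.002)
  cf <- recovery_coefficients(b0 = 0.5, L0 = 0.8)
  r1 <- simulate_session(p, duration = 10, seed = 31, session_index = 1)
  r2 <- simulate_session(apply_recovery(p, cf), duration = 10, seed = 32,
                         session_index = 2)
  both <- rat_log_likelihood(r1, r2, params = p, coeffs = cf)
  separate <- rat_log_likelihood(r1, params = p) +
    rat_log_likelihood(r2, params = apply_recovery(p, cf))
  expect_equal(both, separate, tolerance = 1e-12)
  expect_error(rat_log_likelihood(r1, r2, params = p),
               class = "dberm_data_error")
})

test_that("identical rats contribute identical likelihood terms", {
  p <- reference_medians("SHR")
  rec <- simulate_session(p, duration = 5, seed = 41)
  expect_identical(rat_log_likelihood(rec, params = p),
                   rat_log_likelihood(rec, params = p))
})

test_that("the joint posterior equals likelihood plus population density", {
  groups <- reference_groups(sdlog = 0.2)
  co <- simulate_cohort(groups[2], n_rats_per_strain = 1, n_sessions = 1,
                        duration = 5, seed = 51)
  truth <- co$metadata$truth$WKY1
  hyper <- list(WKY = list(
    mu = setNames(log(unlist(reference_medians("WKY"))),
                  names(unlist(reference_medians("WKY")))),
    sd = setNames(rep(0.2, 8), names(unlist(reference_medians("WKY"))))))
  lp <- log_posterior(co, list(WKY1 = truth), hyper)
  ll <- rat_log_likelihood(co$sessions[[1]], params = truth$params)
  pr <- sum(dnorm(log(unlist(truth$params)), hyper$WKY$mu, 0.2, log = TRUE))
  expect_equal(lp, ll + pr, tolerance = 1e-10)

  # flat hyperprior support boundaries
  hyper_bad <- hyper
  hyper_bad$WKY$mu[["b0"]] <- log(1e5)
  expect_identical(log_posterior(co, list(WKY1 = truth), hyper_bad), -Inf)
  hyper_bad <- hyper
  hyper_bad$WKY$sd[["b0"]] <- 6
  expect_identical(log_posterior(co, list(WKY1 = truth), hyper_bad), -Inf)
})

test_that("adaptive Metropolis reproduces a conjugate Gamma posterior", {
  # p = 0, known delta, flat prior on log rate: the rate posterior for n
  # shifted-exponential IRTs with total excess time T is Gamma(n, T)
  set.seed(61)
  n <- 80
  rate <- 5
  x <- rexp(n, rate)
  T_ <- sum(x)
  logpost <- function(lb) n * lb - exp(lb) * T_
  chain <- exp(dberm:::.sample_scalar_chain(logpost, init = log(1),
                                            n_retain = 6000, burn_in = 1000,
                                            seed = 62))
  expect_equal(mean(chain), n / T_, tolerance = 0.05)
  expect_equal(sd(chain), sqrt(n) / T_, tolerance = 0.25)
})

test_that("short chains are deterministic, sized and constraint-respecting", {
  groups <- reference_groups(sdlog = 0.2)
  co <- simulate_cohort(groups, n_rats_per_strain = 2, n_sessions = 1,
                        duration = 6, seed = 71)
  cfg <- mcmc_config(n_retain = 120, burn_in = 60)
  ch1 <- run_mcmc(co, cfg, seed = 72)
  ch2 <- run_mcmc(co, cfg, seed = 72)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(nrow(ch1$samples), 120L)

  # every retained sample satisfies the model orderings
  for (r in ch1$rats$rat_id) {
    nat <- exp(ch1$samples[, paste("theta", r, dberm:::.param_names,
                                   sep = ".")])
    expect_true(all(nat[, 2] > nat[, 3]))          # w0 > b0
    expect_true(all(nat[, 3] >= nat[, 8]))         # b0 >= omega
    expect_true(all(nat[, 6] >= nat[, 5]))         # beta >= alpha
    expect_true(all(nat[, 4:6] >= log(2) / HALF_LIFE_CAP))
  }
  expect_named(ch1$diagnostics, "rhat")
})

test_that("a two-session fit estimates recovery coefficients", {
  groups <- reference_groups(sdlog = 0.15, with_recovery = TRUE)
  co <- simulate_cohort(groups, n_rats_per_strain = 2, n_sessions = 2,
                        duration = 6, seed = 81)
  ch <- run_mcmc(co, mcmc_config(n_retain = 150, burn_in = 80), seed = 82)
  expect_true(any(grepl("^ctheta\\.", colnames(ch$samples))))
  tab <- summarize_posterior(ch)
  expect_true("C(L0)" %in% tab$parameter)
  eff <- strain_effect(ch, "C(b0)")
  expect_s3_class(eff, "dberm_effect")
})

test_that("posterior summaries respect quantile transforms and units", {
  # hand-built chains: constant and symmetric columns
  cols <- c(paste("mu", "WKY", dberm:::.param_names, sep = "."),
            paste("sd", "WKY", dberm:::.param_names, sep = "."))
  n <- 401
  sm <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  sm[, "mu.WKY.b0"] <- log(14.7)                       # point mass
  sm[, "mu.WKY.L0"] <- log(2) + seq(-1, 1, length.out = n)  # symmetric
  sm[, "mu.WKY.gamma"] <- log(log(2) / 19.37)
  sm[, "mu.WKY.delta"] <- log(0.12 / 60)
  sm[, "mu.WKY.w0"] <- log(100); sm[, "mu.WKY.alpha"] <- log(0.01)
  sm[, "mu.WKY.beta"] <- log(0.1); sm[, "mu.WKY.omega"] <- log(1)
  ch <- structure(list(samples = sm,
                       rats = data.frame(rat_id = "WKY1", strain = "WKY",
                                         n_sessions = 1L),
                       strains = "WKY",
                       config = mcmc_config(n_retain = n, burn_in = 0),
                       seed = 1L),
                  class = "dberm_chains")
  tab <- summarize_posterior(ch)
  b0 <- tab[tab$parameter == "b0", ]
  expect_equal(c(b0$median, b0$lower, b0$upper), rep(14.7, 3))
  expect_equal(tab$median[tab$parameter == "L0"], 2)   # e^mu at symmetry
  expect_equal(tab$median[tab$parameter == "H_L"], 19.37, tolerance = 1e-9)
  expect_equal(tab$median[tab$parameter == "delta"], 0.12)
  expect_identical(tab$unit[tab$parameter == "delta"], "s")
})

test_that("strain effects flag ratios whose interval excludes one", {
  p_names <- dberm:::.param_names
  cols <- c(paste("mu", rep(c("SHR", "WKY"), each = 8),
                  rep(p_names, 2), sep = "."))
  set.seed(91)
  n <- 2000
  sm <- matrix(rnorm(n * length(cols), 0, 0.01), n, length(cols),
               dimnames = list(NULL, cols))
  sm[, "mu.SHR.b0"] <- rnorm(n, log(42.74), 0.05)
  sm[, "mu.WKY.b0"] <- rnorm(n, log(14.70), 0.05)
  sm[, "mu.SHR.gamma"] <- rnorm(n, log(log(2) / 2794.48), 0.05)
  sm[, "mu.WKY.gamma"] <- rnorm(n, log(log(2) / 19.37), 0.05)
  ch <- structure(list(samples = sm,
                       rats = data.frame(rat_id = c("SHR1", "WKY1"),
                                         strain = c("SHR", "WKY"),
                                         n_sessions = c(1L, 1L)),
                       strains = c("SHR", "WKY"),
                       config = mcmc_config(n_retain = n, burn_in = 0),
                       seed = 1L),
                  class = "dberm_chains")
  eff <- strain_effect(ch, "b0")
  expect_true(eff$significant)
  expect_equal(eff$ratio_median, 42.74 / 14.70, tolerance = 0.02)
  expect_equal(exp(median(eff$samples)), eff$ratio_median)

  # null parameter: interval straddles a ratio of one
  eff0 <- strain_effect(ch, "w0")
  expect_false(eff0$significant)

  # half-life labels flip the sign of the rate effect
  ehl <- strain_effect(ch, "H_L")
  expect_true(ehl$significant)
  expect_equal(ehl$ratio_median, 2794.48 / 19.37, tolerance = 0.05)

  expect_error(strain_effect(ch, "nonesuch"), class = "dberm_data_error")
})
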