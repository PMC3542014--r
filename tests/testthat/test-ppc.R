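test_that("binned rates partition the session and conserve counts", {
  empty <- session_record(numeric(0), "r", "X", session_duration = 65)
  br <- binned_response_rates(empty)
  expect_equal(br$rate, rep(0, 8))
  expect_equal(attr(br, "bin_width"), 8.125)

  uniform <- session_record(seq(0.5, 64.5, by = 1), "r", "X",
                            session_duration = 65)
  bu <- binned_response_rates(uniform)
  # 65 evenly spaced responses over 8 bins: 8 per bin, 9 in the one that
  # straddles an extra grid point
  expect_equal(bu$count, c(8L, 8L, 8L, 8L, 9L, 8L, 8L, 8L))
  expect_equal(bu$rate, rep(1, 8), tolerance = 0.15)
  expect_equal(sum(bu$rate) * 8.125, 65)           # exact reconstruction
  expect_equal(bu$midpoint[1], 8.125 / 2)

  # boundary responses: left-closed bins, last bin closed at the end
  edge <- session_record(c(0, 8.125, 65), "r", "X", session_duration = 65)
  be <- binned_response_rates(edge)
  expect_equal(be$count, c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L))

  mangled <- structure(list(response_times = c(1, 70), rat_id = "r",
                            strain = "X", session_index = 1L,
                            session_duration = 65,
                            first_latency_included = TRUE),
                       class = "session_record")
  expect_error(binned_response_rates(mangled), class = "dberm_data_error")
})

test_that("survivor curves are nonincreasing and start at probability one", {
  one <- session_record(0.4, "r", "X", session_duration = 1)
  sc <- log_survivor_curve(one, c(0, 1))
  expect_equal(sc$survivor, c(1, 0))
  expect_equal(sc$duration, c(0, 0.4))

  p <- static_params(L0 = 1, w0 = 60, b0 = 6, delta = 0.002)
  rec <- simulate_session(p, duration = 60, seed = 7)
  sc <- log_survivor_curve(rec, c(0, 60))
  expect_true(all(diff(sc$survivor) <= 0))
  expect_equal(sc$survivor[1], 1)
  expect_identical(attr(sc, "n_irts"), length(record_irts(rec)))

  late <- log_survivor_curve(session_record(0.1, "r", "X",
                                            session_duration = 65),
                             c(50, 65))
  expect_true(attr(late, "empty"))
  expect_error(log_survivor_curve(rec, c(10, 5)),
               class = "dberm_data_error")
})

test_that("exponential IRTs give a log-linear survivor tail", {
  set.seed(8)
  irts <- rexp(1e4, 10)
  rec <- session_record(cumsum(irts), "r", "X",
                        session_duration = sum(irts) + 1)
  sc <- log_survivor_curve(rec, c(0, sum(irts)))
  mid <- sc$survivor > 0.01 & sc$survivor < 0.9
  fit <- lm(log_survivor ~ duration, data = sc[mid, ])
  expect_equal(unname(coef(fit)[2]), -10, tolerance = 0.05)
})

test_that("mixture IRTs show the broken-stick slope ordering", {
  p <- static_params(L0 = 2, w0 = 150, b0 = 5, delta = 0.001)
  rec <- simulate_session(p, duration = 400, seed = 9)
  sc <- log_survivor_curve(rec, c(0, 400))
  early <- sc$duration > 0 & sc$duration < 1.5 / p$w0
  late <- sc$duration > 3 / p$b0 & sc$survivor > 0
  s_early <- coef(lm(log_survivor ~ duration, data = sc[early, ]))[2]
  s_late <- coef(lm(log_survivor ~ duration, data = sc[late, ]))[2]
  expect_lt(s_early, 3 * s_late)  # early limb at least 3x steeper
  expect_lt(s_early, 0)
  expect_lt(s_late, 0)
})

# chains concentrated at one parameter set, for degenerate-posterior checks
point_mass_chains <- function(params, rat_id = "WKY1", strain = "WKY",
                              n = 150) {
  logs <- log(unlist(params[dberm:::.param_names]))
  cols <- c(paste("theta", rat_id, dberm:::.param_names, sep = "."),
            paste("mu", strain, dberm:::.param_names, sep = "."),
            paste("sd", strain, dberm:::.param_names, sep = "."))
  sm <- matrix(rep(c(logs, logs, rep(0.01, 8)), each = n), n,
               dimnames = list(NULL, cols))
  structure(list(samples = sm,
                 rats = data.frame(rat_id = rat_id, strain = strain,
                                   n_sessions = 1L),
                 strains = strain,
                 config = mcmc_config(n_retain = n, burn_in = 0),
                 seed = 1L),
            class = "dberm_chains")
}

test_that("degenerate posterior predictive equals replicate simulation", {
  p <- reference_medians("WKY")
  ch <- point_mass_chains(p)
  co <- list(sessions = list(simulate_session(p, 65, seed = 10,
                                              rat_id = "WKY1",
                                              strain = "WKY")))
  class(co) <- "cohort_dataset"
  ppr <- posterior_predictive_rates(ch, co, n_draws = 120, seed = 11)
  direct <- rowMeans(vapply(1:120, function(i) {
    binned_response_rates(simulate_session(p, 65, seed = 1000 + i))$rate
  }, numeric(8)))
  expect_equal(ppr$rate, direct, tolerance = 0.12)
  expect_true(all(ppr$lower <= ppr$rate & ppr$rate <= ppr$upper))
  # decaying rates: predictive curve declines after the first bin
  expect_true(all(diff(ppr$rate) < 0))
})

test_that("survivor envelopes bracket the generative curve", {
  # static parameters so the window-pooled IRTs share one closed-form law
  p <- static_params(L0 = 2.81, w0 = 175, b0 = 14.7, delta = 0.002)
  ch <- point_mass_chains(p)
  co <- list(sessions = list(simulate_session(p, 65, seed = 12,
                                              rat_id = "WKY1",
                                              strain = "WKY")))
  class(co) <- "cohort_dataset"
  env <- ppc_survivor_envelope(ch, co, "WKY1", window = c(0, 10),
                               n_draws = 80, seed = 13)
  expect_true(all(diff(env$median) <= 1e-12))
  expect_true(all(env$lower <= env$median + 1e-12))
  expect_true(all(env$median <= env$upper + 1e-12))
  # closed-form early-session survivor lies inside the central band
  st <- evaluate_dynamics(p, 0)
  theo <- irt_survivor(st, p$delta, env$duration)
  inside <- mean(theo >= env$lower & theo <= env$upper)
  expect_gt(inside, 0.85)
  # reproducible from the seed
  env2 <- ppc_survivor_envelope(ch, co, "WKY1", window = c(0, 10),
                                n_draws = 80, seed = 13)
  expect_identical(as.data.frame(env), as.data.frame(env2))
})

test_that("recovery scenarios rewrite the generative medians", {
  ov <- recovery_scenario("hl_swap")
  expect_equal(ov$SHR[["gamma"]], log(2) / 19.37, tolerance = 1e-12)
  ov2 <- recovery_scenario("hl_swap_l0_third")
  expect_equal(ov2$SHR[["L0"]], 0.91 / 3)
  groups <- dberm:::.apply_overrides(reference_groups(0.2), ov2)
  shr <- groups[[which(vapply(groups, `[[`, "", "strain") == "SHR")]]
  expect_equal(exp(shr$mu[["gamma"]]), log(2) / 19.37, tolerance = 1e-12)
  expect_equal(exp(shr$mu[["L0"]]), 0.91 / 3, tolerance = 1e-12)
  expect_identical(recovery_scenario("none"), list())
})
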