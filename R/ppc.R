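#' Binned response rates for one session
#'
#' Counts responses in consecutive equal-width bins (half-open on the
#' right, last bin closed) and divides by the bin width. With the default 8
#' bins over a 65-min session the bins are 8.125 min wide, and
#' `sum(rate) * width` reconstructs the total response count exactly.
#'
#' @param record A `session_record`.
#' @param n_bins Number of equal bins (default 8).
#' @return A data frame of class `binned_rates` with columns `bin`,
#'   `midpoint` (minutes), `count` and `rate` (responses per minute);
#'   attributes `bin_width`, `rat_id`, `strain`, `session_index`.
#' @export
binned_response_rates <- function(record, n_bins = 8) {
  times <- record$response_times
  dur <- record$session_duration
  if (length(times) && (any(times < 0) || any(times > dur))) {
    stop_data("responses outside [0, session_duration]")
  }
  w <- dur / n_bins
  edges <- seq(0, dur, length.out = n_bins + 1)
  # half-open [lo, hi), last bin closed
  counts <- as.integer(table(cut(times, edges, right = FALSE,
                                 include.lowest = FALSE,
                                 labels = FALSE)) [as.character(1:n_bins)])
  counts[is.na(counts)] <- 0L
  counts[n_bins] <- counts[n_bins] + sum(times == dur)
  structure(
    data.frame(bin = seq_len(n_bins), midpoint = edges[-1] - w / 2,
               count = counts, rate = counts / w),
    class = c("binned_rates", "data.frame"),
    bin_width = w, rat_id = record$rat_id, strain = record$strain,
    session_index = record$session_index
  )
}

#' Empirical log-survivor curve of IRTs in a time window
#'
#' Collects the IRTs whose start times fall in `[window[1], window[2])` and
#' returns, at each sorted duration, the proportion of IRTs strictly
#' exceeding it. Bi-exponential mixtures produce the characteristic
#' "broken-stick" shape: a steep early limb (within-bout IRTs) bending into
#' a shallow tail (between-bout pauses). The first model interval (latency
#' from session start) is included when the record flags it.
#'
#' @param record A `session_record`.
#' @param window Numeric `c(start, end)` in minutes, within the session.
#' @return A data frame of class `survivor_curve` with columns `duration`
#'   (minutes), `survivor` and `log_survivor` (natural log), starting at
#'   `(0, 1, 0)`; attributes `window`, `n_irts`, `empty`.
#' @export
log_survivor_curve <- function(record, window = c(0, 10)) {
  if (length(window) != 2 || window[1] >= window[2] ||
      window[1] < 0 || window[2] > record$session_duration) {
    stop_data("window must be an increasing pair within the session")
  }
  times <- record$response_times
  if (record$first_latency_included) {
    taus <- diff(c(0, times))
    starts <- c(0, times[-length(times)])[seq_along(taus)]
  } else {
    taus <- diff(times)
    starts <- times[-length(times)]
  }
  sel <- starts >= window[1] & starts < window[2]
  irts <- sort(taus[sel])
  n <- length(irts)
  if (!n) {
    out <- data.frame(duration = 0, survivor = 1, log_survivor = 0)
  } else {
    surv <- (n - seq_len(n)) / n
    out <- data.frame(duration = c(0, irts), survivor = c(1, surv),
                      log_survivor = log(c(1, surv)))
  }
  structure(out, class = c("survivor_curve", "data.frame"),
            window = window, n_irts = n, empty = n == 0)
}

# Extract one posterior draw's parameter set (and coefficients) for a rat.
.draw_params <- function(chains, rat, draw) {
  th <- chains$samples[draw, paste("theta", rat, .param_names, sep = ".")]
  names(th) <- .param_names
  params <- .params_from_log(th, check = FALSE)
  ccols <- paste("ctheta", rat, .recovery_names, sep = ".")
  coeffs <- NULL
  if (all(ccols %in% colnames(chains$samples))) {
    cv <- exp(chains$samples[draw, ccols])
    names(cv) <- .recovery_names
    coeffs <- do.call(recovery_coefficients, as.list(cv))
  }
  list(params = params, coeffs = coeffs)
}

.select_draws <- function(chains, n_draws, replace_note = TRUE) {
  n <- nrow(chains$samples)
  if (n_draws <= n) {
    sample.int(n, n_draws, replace = FALSE)
  } else {
    if (replace_note) {
      warning("n_draws exceeds chain length; sampling with replacement")
    }
    sample.int(n, n_draws, replace = TRUE)
  }
}

#' Posterior-predictive binned response rates
#'
#' For each of `n_draws` joint posterior samples (drawn without replacement
#' when the chain is long enough), every rat's sessions are re-simulated
#' from that draw's parameters and binned; the per-draw rates are averaged
#' over the rats of each strain. Returns, per strain, session and bin, the
#' mean simulated rate together with the central 95% band over draws --
#' directly comparable to the observed binned rates.
#'
#' @param chains A `dberm_chains`.
#' @param dataset The `cohort_dataset` the chains were fitted to (supplies
#'   the rat/session layout and durations).
#' @param n_draws Number of posterior draws (default 10000).
#' @param seed Integer seed for draw selection and simulation.
#' @param n_bins Bins per session (default 8).
#' @return A data frame with columns `strain`, `session_index`, `bin`,
#'   `midpoint`, `rate` (mean over draws), `lower`, `upper` (2.5 and 97.5
#'   percentiles over draws).
#' @export
posterior_predictive_rates <- function(chains, dataset, n_draws = 10000,
                                       seed = 1, n_bins = 8) {
  idx <- cohort_index(dataset)
  with_seed(seed, {
    draws <- .select_draws(chains, n_draws)
    out <- list()
    for (s in unique(idx$strain)) {
      rats <- unique(idx$rat_id[idx$strain == s])
      for (sess in sort(unique(idx$session_index[idx$strain == s]))) {
        dur <- idx$session_duration[idx$strain == s &
                                      idx$session_index == sess][1]
        acc <- matrix(NA_real_, length(draws), n_bins)
        for (di in seq_along(draws)) {
          per_rat <- matrix(NA_real_, length(rats), n_bins)
          for (ri in seq_along(rats)) {
            dp <- .draw_params(chains, rats[ri], draws[di])
            p <- dp$params
            if (sess > 1) {
              for (k in seq_len(sess - 1)) p <- apply_recovery(p, dp$coeffs)
            }
            rec <- simulate_session(p, duration = dur,
                                    rat_id = rats[ri], strain = s,
                                    session_index = sess)
            per_rat[ri, ] <- binned_response_rates(rec, n_bins)$rate
          }
          acc[di, ] <- colMeans(per_rat)
        }
        q <- apply(acc, 2, stats::quantile, c(0.025, 0.975), names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          strain = s, session_index = sess, bin = seq_len(n_bins),
          midpoint = (seq_len(n_bins) - 0.5) * dur / n_bins,
          rate = colMeans(acc), lower = q[1, ], upper = q[2, ],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Posterior-predictive log-survivor envelope for one rat
#'
#' Simulates the rat's session from `n_draws` posterior draws, computes the
#' empirical survivor curve of the IRTs starting in `window`, interpolates
#' each curve onto a common duration grid, and returns the pointwise median
#' and central 95% band -- the predictive envelope against which the
#' observed log-survivor curve is compared. Durations beyond a draw's
#' largest IRT have empirical survivor probability zero; draws with no IRT
#' in the window are dropped (their count is reported).
#'
#' @inheritParams posterior_predictive_rates
#' @param rat_id Rat label.
#' @param session_index Session to simulate (1 or 2).
#' @param window `c(start, end)` minutes, as in [log_survivor_curve()].
#' @param grid_n Number of grid points (default 200).
#' @return A data frame of class `ppc_envelope` with columns `duration`,
#'   `median`, `lower`, `upper` (survivor scale) and their natural-log
#'   counterparts; attributes `window`, `n_draws_used`, `n_empty`.
#' @export
ppc_survivor_envelope <- function(chains, dataset, rat_id, session_index = 1,
                                  window = c(0, 10), n_draws = 1000,
                                  seed = 1, grid_n = 200) {
  idx <- cohort_index(dataset)
  row <- idx[idx$rat_id == rat_id & idx$session_index == session_index, ]
  if (!nrow(row)) stop_data("rat/session not present in dataset")
  dur <- row$session_duration[1]
  strain <- row$strain[1]
  with_seed(seed, {
    draws <- .select_draws(chains, n_draws)
    curves <- vector("list", length(draws))
    for (di in seq_along(draws)) {
      dp <- .draw_params(chains, rat_id, draws[di])
      p <- dp$params
      if (session_index > 1) {
        for (k in seq_len(session_index - 1)) {
          p <- apply_recovery(p, dp$coeffs)
        }
      }
      rec <- simulate_session(p, duration = dur, rat_id = rat_id,
                              strain = strain,
                              session_index = session_index)
      sc <- log_survivor_curve(rec, window)
      curves[[di]] <- if (attr(sc, "empty")) NULL else sc
    }
    keep <- !vapply(curves, is.null, logical(1))
    if (!any(keep)) stop_data("no posterior draw produced IRTs in the window")
    curves <- curves[keep]
    dmax <- max(vapply(curves, function(cv) max(cv$duration), 0))
    grid <- seq(0, dmax, length.out = grid_n)
    mat <- vapply(curves, function(cv) {
      stats::approx(cv$duration, cv$survivor, xout = grid,
                    method = "constant", f = 0, yleft = 1, yright = 0,
                    ties = "ordered")$y
    }, numeric(grid_n))
    q <- apply(mat, 1, stats::quantile, c(0.5, 0.025, 0.975), names = FALSE)
    structure(
      data.frame(duration = grid, median = q[1, ], lower = q[2, ],
                 upper = q[3, ],
                 log_median = log(q[1, ]), log_lower = log(q[2, ]),
                 log_upper = log(q[3, ])),
      class = c("ppc_envelope", "data.frame"),
      window = window, n_draws_used = sum(keep), n_empty = sum(!keep))
  })
}
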