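.linear_summary <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  c(median = q[1], lower = q[2], upper = q[3])
}

# Transform log-scale samples of a canonical parameter into reporting
# units: rates become half-lives (minutes, capped), delta becomes seconds.
.report_samples <- function(param, logs, cap) {
  if (param %in% c("gamma", "alpha", "beta")) {
    h <- cap_half_life(log(2) / exp(logs), cap)
    list(name = c(gamma = "H_L", alpha = "H_w", beta = "H_b")[[param]],
         x = h$value, capped = any(h$capped),
         unit = "min")
  } else if (param == "delta") {
    list(name = "delta", x = exp(logs) * 60, capped = FALSE, unit = "s")
  } else {
    list(name = param, x = exp(logs), capped = FALSE,
         unit = if (param == "L0") "resp" else "min^-1")
  }
}

#' Summarise posterior chains on the reporting scale
#'
#' Back-transforms the log-scale group locations (and, at
#' `level = "individual"`, each rat's parameters) to the linear scale and
#' reports the posterior median with a central 95% credible interval.
#' Decay rates are reported as half-lives (minutes, truncated at the
#' half-life cap) and the refractory period in seconds; baselines are
#' responses and per-minute rates. Recovery-coefficient summaries are
#' labelled `C(x)`.
#'
#' @param chains A `dberm_chains` object.
#' @param level `"group"` (strain medians, the back-transformed `mu`) or
#'   `"individual"` (per-rat parameters).
#' @param cap Half-life reporting cap, minutes.
#' @return A data frame with columns `strain` (or `rat_id`), `parameter`,
#'   `median`, `lower`, `upper`, `unit`, `capped`.
#' @export
summarize_posterior <- function(chains, level = c("group", "individual"),
                                cap = HALF_LIFE_CAP) {
  level <- match.arg(level)
  sm <- chains$samples
  if (!nrow(sm)) stop_data("chains are empty")
  out <- list()
  emit <- function(label_col, label, param, logs, coef = FALSE) {
    r <- .report_samples(param, logs, cap)
    s <- .linear_summary(r$x)
    row <- data.frame(label = label,
                      parameter = if (coef) paste0("C(", r$name, ")") else
                        r$name,
                      median = s[["median"]], lower = s[["lower"]],
                      upper = s[["upper"]],
                      unit = if (coef) "" else r$unit, capped = r$capped,
                      stringsAsFactors = FALSE)
    names(row)[1] <- label_col
    row
  }
  if (level == "group") {
    for (s in chains$strains) {
      for (j in .param_names) {
        out[[length(out) + 1]] <-
          emit("strain", s, j, sm[, paste("mu", s, j, sep = ".")])
      }
      ccol <- paste("mu", s, "C", .recovery_names, sep = ".")
      if (all(ccol %in% colnames(sm))) {
        for (k in seq_along(.recovery_names)) {
          logs <- sm[, ccol[k]]
          q <- .linear_summary(exp(logs))
          out[[length(out) + 1]] <- data.frame(
            strain = s, parameter = paste0("C(", .recovery_names[k], ")"),
            median = q[["median"]], lower = q[["lower"]],
            upper = q[["upper"]], unit = "", capped = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    for (r in chains$rats$rat_id) {
      for (j in .param_names) {
        out[[length(out) + 1]] <-
          emit("rat_id", r, j, sm[, paste("theta", r, j, sep = ".")])
      }
      ccol <- paste("ctheta", r, .recovery_names, sep = ".")
      if (all(ccol %in% colnames(sm))) {
        for (k in seq_along(.recovery_names)) {
          q <- .linear_summary(exp(sm[, ccol[k]]))
          out[[length(out) + 1]] <- data.frame(
            rat_id = r, parameter = paste0("C(", .recovery_names[k], ")"),
            median = q[["median"]], lower = q[["lower"]],
            upper = q[["upper"]], unit = "", capped = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Strain effect size for one parameter
#'
#' Computes, sample by sample, the difference of the two strains' log-scale
#' group locations, `E = mu(strain 1) - mu(strain 2)`. On the linear scale
#' `exp(E)` estimates the ratio of the strains' parameter medians. The
#' difference is declared significant when the central 95% credible interval
#' of `E` excludes 0 (equivalently, the ratio interval excludes 1).
#'
#' Half-life labels (`H_L`, `H_w`, `H_b`) are accepted and map to the
#' corresponding decay rate with the sign flipped, so a ratio above 1 always
#' means "larger in strain 1". Recovery coefficients are addressed as
#' `C(L0)`, `C(H_b)`, etc.
#'
#' @param chains A `dberm_chains` containing both strains.
#' @param parameter Parameter label.
#' @param strains Character vector of two strains, `c(strain1, strain2)`;
#'   defaults to the chains' strain order.
#' @return An object of class `dberm_effect`: list with `parameter`,
#'   `strains`, `samples` (log-scale effect), `median`, `lower`, `upper`
#'   (log scale), `ratio_median`, `ratio_lower`, `ratio_upper` and
#'   `significant`.
#' @export
strain_effect <- function(chains, parameter, strains = NULL) {
  if (is.null(strains)) strains <- chains$strains
  if (length(strains) != 2 || !all(strains %in% chains$strains)) {
    stop_data("chains must contain the two requested strains")
  }
  flip <- FALSE
  par_in <- parameter
  if (grepl("^C\\((.+)\\)$", parameter)) {
    cname <- sub("^C\\((.+)\\)$", "\\1", parameter)
    if (!cname %in% .recovery_names) {
      stop_data(sprintf("unknown parameter '%s'", parameter))
    }
    cols <- paste("mu", strains, "C", cname, sep = ".")
  } else {
    hl_map <- c(H_L = "gamma", H_w = "alpha", H_b = "beta")
    if (parameter %in% names(hl_map)) {
      flip <- TRUE                      # H = log(2)/rate: log H = const - log rate
      parameter <- hl_map[[parameter]]
    }
    if (!parameter %in% .param_names) {
      stop_data(sprintf("unknown parameter '%s'", par_in))
    }
    cols <- paste("mu", strains, parameter, sep = ".")
  }
  if (!all(cols %in% colnames(chains$samples))) {
    stop_data(sprintf("chains lack columns for parameter '%s'", par_in))
  }
  e <- chains$samples[, cols[1]] - chains$samples[, cols[2]]
  if (flip) e <- -e
  q <- stats::quantile(e, c(0.5, 0.025, 0.975), names = FALSE)
  structure(
    list(parameter = par_in, strains = strains, samples = e,
         median = q[1], lower = q[2], upper = q[3],
         ratio_median = exp(q[1]), ratio_lower = exp(q[2]),
         ratio_upper = exp(q[3]),
         significant = !(q[2] <= 0 && 0 <= q[3])),
    class = "dberm_effect"
  )
}

#' @export
print.dberm_effect <- function(x, ...) {
  cat(sprintf(
    "effect %s [%s vs %s]: ratio %.3f (95%% CI %.3f-%.3f)%s\n",
    x$parameter, x$strains[1], x$strains[2],
    x$ratio_median, x$ratio_lower, x$ratio_upper,
    if (x$significant) " *" else ""))
  invisible(x)
}
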