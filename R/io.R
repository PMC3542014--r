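# Event-time interchange format: comma-separated UTF-8 text with '.'
# decimals, a '#'-prefixed metadata preamble, a header row, and one row per
# response. Times are seconds from lever extension at the file boundary and
# minutes internally.

.events_header <- "rat_id,strain,session_index,response_time_s"

#' Write a cohort to the event-time text format
#'
#' One row per response (`rat_id,strain,session_index,response_time_s`),
#' preceded by `#` metadata lines carrying the session duration and the
#' first-latency flag. Rows are ordered by strain, rat, session and time, so
#' output is deterministic. When the dataset carries generative truth
#' metadata it can be written to a JSON sidecar for recovery experiments.
#'
#' @param dataset A `cohort_dataset`.
#' @param path Output file path.
#' @param truth_path Optional path for the generative-truth JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_events <- function(dataset, path, truth_path = NULL) {
  idx <- cohort_index(dataset)
  durs <- unique(idx$session_duration)
  if (length(durs) != 1) {
    stop_data("event files require a single session duration")
  }
  flags <- unique(vapply(dataset$sessions, `[[`, TRUE,
                         "first_latency_included"))
  if (length(flags) != 1) {
    stop_data("event files require a single first-latency convention")
  }
  ord <- order(idx$strain, idx$rat_id, idx$session_index)
  rows <- character(0)
  for (i in ord) {
    s <- dataset$sessions[[i]]
    if (length(s$response_times)) {
      rows <- c(rows, sprintf("%s,%s,%d,%.6f", s$rat_id, s$strain,
                              s$session_index, s$response_times * 60))
    }
  }
  lines <- c("# dberm-events v1",
             sprintf("# session_duration_min: %.10g", durs),
             sprintf("# first_latency_included: %s", flags),
             .events_header, rows)
  writeLines(lines, path)
  if (!is.null(truth_path) && !is.null(dataset$metadata$truth)) {
    .write_truth(dataset, truth_path)
  }
  invisible(path)
}

.write_truth <- function(dataset, path) {
  md <- dataset$metadata
  truth <- lapply(md$truth, function(x) {
    out <- list(params = as.list(unlist(x$params[.param_names])))
    if (!is.null(x$coeffs)) {
      out$coeffs <- as.list(unlist(x$coeffs[.recovery_names]))
    }
    out
  })
  groups <- lapply(md$groups, function(g) {
    out <- list(strain = g$strain, mu = as.list(g$mu),
                sdlog = as.list(g$sdlog))
    if (!is.null(g$mu_recovery)) {
      out$mu_recovery <- as.list(g$mu_recovery)
      out$sdlog_recovery <- as.list(g$sdlog_recovery)
    }
    out
  })
  jsonlite::write_json(
    list(seed = md$seed, duration = md$duration,
         n_sessions = md$n_sessions, groups = groups, truth = truth),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from the event-time text format
#'
#' Parses and validates an event file written by [write_events()] (or any
#' file in the same dialect). Violations -- non-increasing or duplicate
#' timestamps within a rat-session, negative times, times beyond the session
#' duration, more than two strain labels -- are rejected with the offending
#' data row number.
#'
#' @param path Input file path.
#' @param strains Optional declared strain pair; labels outside it are
#'   rejected.
#' @return A `cohort_dataset` (times converted to minutes).
#' @export
read_events <- function(path, strains = NULL) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NULL) {
    hit <- grep(paste0("^# ", key, ": "), meta_lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  duration <- as.numeric(get_meta("session_duration_min", "65"))
  flag <- as.logical(get_meta("first_latency_included", "TRUE"))
  body_start <- which(!grepl("^#", lines))[1]
  if (is.na(body_start) || lines[body_start] != .events_header) {
    stop_data("missing or malformed header row")
  }
  data_lines <- lines[-seq_len(body_start)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) stop_data("file contains no response rows")
  df <- utils::read.csv(text = c(.events_header, data_lines),
                        stringsAsFactors = FALSE)
  df$row <- seq_len(nrow(df)) + body_start  # 1-based line numbers in file
  if (any(is.na(df$response_time_s))) {
    stop_data(sprintf("unparseable time at line %d",
                      df$row[which(is.na(df$response_time_s))[1]]))
  }
  if (any(df$response_time_s < 0)) {
    stop_data(sprintf("negative time at line %d",
                      df$row[which(df$response_time_s < 0)[1]]))
  }
  too_late <- df$response_time_s > duration * 60
  if (any(too_late)) {
    stop_data(sprintf(
      "time %.6g s exceeds the %.6g-min session at line %d",
      df$response_time_s[which(too_late)[1]], duration,
      df$row[which(too_late)[1]]))
  }
  lab <- unique(df$strain)
  if (!is.null(strains)) {
    bad <- setdiff(lab, strains)
    if (length(bad)) {
      stop_data(sprintf("unknown strain label '%s'", bad[1]))
    }
  } else if (length(lab) > 2) {
    stop_data(sprintf("more than two strain labels: %s",
                      paste(lab, collapse = ", ")))
  }
  strain_of <- tapply(df$strain, df$rat_id, function(x) x[1])
  mismatch <- tapply(df$strain, df$rat_id, function(x) length(unique(x)) > 1)
  if (any(mismatch)) {
    stop_data(sprintf("rat '%s' appears under multiple strains",
                      names(which(mismatch))[1]))
  }
  sessions <- list()
  for (r in sort(unique(df$rat_id))) {
    for (sx in sort(unique(df$session_index[df$rat_id == r]))) {
      sub <- df[df$rat_id == r & df$session_index == sx, ]
      if (any(diff(sub$response_time_s) <= 0)) {
        k <- which(diff(sub$response_time_s) <= 0)[1]
        stop_data(sprintf(
          "non-increasing timestamps for rat '%s' session %d at line %d",
          r, sx, sub$row[k + 1]))
      }
      sessions[[length(sessions) + 1]] <- session_record(
        sub$response_time_s / 60, rat_id = r,
        strain = strain_of[[r]], session_index = sx,
        session_duration = duration, first_latency_included = flag)
    }
  }
  structure(
    list(sessions = sessions,
         metadata = list(source = path, duration = duration,
                         strains = sort(lab),
                         first_latency_included = flag)),
    class = "cohort_dataset")
}

#' Persist and restore posterior chains as portable text
#'
#' The sample matrix is written as a CSV (`<prefix>.samples.csv`) and the
#' layout, sampler configuration, seed, acceptance summary, diagnostics and
#' package version as JSON (`<prefix>.meta.json`), so a chain store can be
#' inspected or reloaded anywhere.
#'
#' @param chains A `dberm_chains`.
#' @param prefix Path prefix for the two files.
#' @return `prefix`, invisibly.
#' @export
write_chains <- function(chains, prefix) {
  utils::write.csv(as.data.frame(chains$samples),
                   paste0(prefix, ".samples.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(rats = chains$rats, strains = chains$strains,
         config = unclass(chains$config), seed = chains$seed,
         accept = lapply(chains$accept, function(m)
           if (is.matrix(m)) as.vector(m) else m),
         rhat = as.list(chains$diagnostics$rhat),
         package_version = as.character(utils::packageVersion("dberm"))),
    paste0(prefix, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_chains
#' @export
read_chains <- function(prefix) {
  sm <- as.matrix(utils::read.csv(paste0(prefix, ".samples.csv"),
                                  check.names = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(mcmc_config, meta$config[names(meta$config) %in%
                                            names(formals(mcmc_config))])
  chains <- structure(
    list(samples = sm,
         rats = as.data.frame(meta$rats),
         strains = meta$strains,
         config = cfg, seed = meta$seed, accept = meta$accept),
    class = "dberm_chains")
  chains$diagnostics <- list(rhat = unlist(meta$rhat))
  chains
}
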