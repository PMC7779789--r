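# End-to-end orchestration: ingest -> filter -> score -> aggregate ->
# correlations -> six moderated regressions + simple slopes, with a
# serializable report and full determinism under a master seed.

#' Assemble a pipeline run configuration
#'
#' @param posts path to the post file (JSONL or CSV).
#' @param emotion_lexicon,prosocial_lexicon lexicon TSV paths.
#' @param severity severity CSV path.
#' @param out_dir output directory (created if absent).
#' @param window_start,window_end study window dates; \code{NULL} means
#'   use the post date range.
#' @param negation_window preceding-token window for negation reversal.
#' @param n_boot bootstrap resamples per model.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param emotions emotion categories to model (default all six).
#' @param keyword optional ingest keyword prefilter (\code{NULL} = off).
#' @param negators path to a negator list file, or a character vector.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(posts, emotion_lexicon, prosocial_lexicon, severity,
                       out_dir, window_start = NULL, window_end = NULL,
                       negation_window = 1L, n_boot = 5000L, seed = 1L,
                       emotions = EMOTION_CATEGORIES, keyword = NULL,
                       negators = read_negators()) {
  stopifnot(all(emotions %in% EMOTION_CATEGORIES))
  if (!is.null(window_start) && !is.null(window_end)) {
    stopifnot(as.Date(window_start) <= as.Date(window_end))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading (flag-style precedence).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, list(...))
  if (is.character(y$negators) && length(y$negators) == 1 &&
      file.exists(y$negators)) {
    y$negators <- read_negators(y$negators)
  }
  do.call(run_config, y)
}

#' Run the full scoring and moderation pipeline
#'
#' Executes filter -> tokenize/score -> daily aggregation ->
#' descriptives/correlations -> one moderated regression per requested
#' emotion (outcome: daily mean prosocial score; moderator: daily newly
#' confirmed cases) with simple slopes at the high (M + 1SD) and low
#' (M - 1SD or observed minimum) severity levels. All outputs are
#' written under \code{config$out_dir}: the daily panel, a
#' descriptives-and-correlations CSV, a coefficient CSV (one block per
#' model), a simple-slopes CSV, and a JSON report carrying every number
#' plus provenance (config hash, seed, package version). Identical
#' (config, seed) runs produce byte-identical reports.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return the report, invisibly (class \code{run_report}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$posts, config$emotion_lexicon,
              config$prosocial_lexicon, config$severity)) {
    if (!file.exists(p)) stop_named("input file not found: %s", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  msg <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  posts <- read_posts(config$posts)
  elex <- read_lexicon(config$emotion_lexicon, kind = "emotion")
  plex <- read_lexicon(config$prosocial_lexicon, kind = "prosocial")
  sev <- read_severity(config$severity)
  negs <- if (is.character(config$negators) && length(config$negators) == 1 &&
              file.exists(config$negators)) read_negators(config$negators)
          else config$negators
  msg("ingest", "%d posts, %d emotion terms, %d prosocial terms",
      nrow(posts), nrow(elex), nrow(plex))

  kept <- filter_posts(posts, keyword = config$keyword)
  drops <- attr(kept, "drop_counts")
  msg("filter", "retained %d posts (dropped: %s)", nrow(kept),
      paste(names(drops), drops, sep = "=", collapse = ", "))

  scored <- score_posts(kept, elex, plex, negators = negs,
                        window = config$negation_window)
  msg("score", "scored %d posts", nrow(scored))

  ws <- config$window_start %||% min(scored$date)
  we <- config$window_end %||% max(scored$date)
  panel <- aggregate_daily(scored, sev, ws, we)
  msg("aggregate", "panel of %d days (%s..%s)", nrow(panel),
      format(min(panel$date)), format(max(panel$date)))

  corr <- correlation_report(panel)

  m_raw <- panel$new_cases
  level_high <- mean(m_raw) + stats::sd(m_raw)
  level_low <- low_level_rule(m_raw)
  models <- list()
  for (emo in config$emotions) {
    fit <- fit_moderation(panel$prosocial, panel[[emo]], m_raw,
                          n_boot = config$n_boot,
                          seed = derive_seed(config$seed,
                                             paste0("boot_", emo)))
    sl <- simple_slopes(fit, c(level_high, level_low))
    sl$level <- c("high", "low")
    models[[emo]] <- list(fit = fit, slopes = sl)
  }
  msg("analyze", "%d moderation models fitted (n_boot = %d)",
      length(models), config$n_boot)

  report <- build_run_report(config, drops, panel, corr, models)
  write_run_report(report, panel, config$out_dir)
  msg("report", "written to %s", config$out_dir)
  invisible(report)
}

config_hash <- function(config) {
  # FNV-1a over the canonical JSON of the analysis config; the output
  # directory is excluded so reruns into a different directory hash alike
  cfg <- config[setdiff(names(config), "out_dir")]
  s <- jsonlite::toJSON(lapply(cfg, function(x)
    if (inherits(x, "Date")) as.character(x) else x),
    auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

build_run_report <- function(config, drops, panel, corr, models) {
  coef_rows <- do.call(rbind, lapply(names(models), function(emo) {
    cf <- models[[emo]]$fit$coefficients
    cbind(tibble::tibble(emotion = emo,
                         r_squared = models[[emo]]$fit$r_squared,
                         f = models[[emo]]$fit$f_statistic), cf)
  }))
  slope_rows <- do.call(rbind, lapply(names(models), function(emo) {
    cbind(tibble::tibble(emotion = emo), models[[emo]]$slopes)
  }))
  structure(list(
    provenance = list(
      package_version = as.character(utils::packageVersion("affectpanel")),
      seed = config$seed,
      n_boot = config$n_boot,
      config_hash = config_hash(config)
    ),
    drop_counts = as.list(drops),
    panel_summary = list(
      n_days = nrow(panel),
      window = c(format(min(panel$date)), format(max(panel$date))),
      total_posts = sum(panel$n_posts),
      posts_per_day = range(panel$n_posts)
    ),
    descriptives = corr$descriptives,
    correlations = list(r = corr$r, p = corr$p),
    coefficients = tibble::as_tibble(coef_rows),
    simple_slopes = tibble::as_tibble(slope_rows)
  ), class = "run_report")
}

write_run_report <- function(report, panel, out_dir) {
  write_panel(panel, file.path(out_dir, "panel.csv"))
  desc <- as.data.frame(report$descriptives)
  rmat <- round(report$correlations$r, 6)
  corr_df <- cbind(desc, as.data.frame(rmat, check.names = FALSE))
  utils::write.csv(corr_df, file.path(out_dir, "descriptives_correlations.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(report$coefficients),
                   file.path(out_dir, "moderation_coefficients.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(report$simple_slopes),
                   file.path(out_dir, "simple_slopes.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(unclass_report(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

unclass_report <- function(report) {
  r <- unclass(report)
  r$descriptives <- as.data.frame(r$descriptives)
  r$coefficients <- as.data.frame(r$coefficients)
  r$simple_slopes <- as.data.frame(r$simple_slopes)
  r$correlations$r <- as.data.frame(r$correlations$r)
  r$correlations$p <- as.data.frame(r$correlations$p)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %d-day panel, %d posts, %d models\n",
              x$panel_summary$n_days, x$panel_summary$total_posts,
              nrow(x$coefficients) / 4))
  cat("Interaction terms:\n")
  ix <- x$coefficients[x$coefficients$term == "x:m", ]
  print(as.data.frame(ix[, c("emotion", "estimate", "se", "t", "p")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}
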