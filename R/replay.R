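# Desk-scale reconstruction of conditional slopes from printed
# standardized regression coefficients: when the raw panel is not
# redistributable, published B1 (focal) and B3 (interaction) together
# with the moderator's published moments are enough to recover every
# pick-a-point simple slope via slope = B1 + B3 * z.

#' Read a table of published moderation coefficients
#'
#' CSV with one row per fitted model and columns \code{model},
#' \code{emotion}, \code{b_intercept}, \code{b_emotion},
#' \code{b_severity}, \code{b_interaction} and optionally \code{r2},
#' \code{f}. Coefficients are standardized regression weights.
#'
#' @param path CSV path; defaults to the coefficient table bundled with
#'   the package, reported by a published 41-day Weibo study of emotion,
#'   prosocial tendency and COVID-19 epidemic severity.
#' @return tibble of coefficients.
#' @export
read_coefficients <- function(path = system.file(
    "extdata", "covid_weibo_coefficients.csv", package = "affectpanel")) {
  df <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  need <- c("model", "emotion", "b_emotion", "b_interaction")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_named("coefficient table missing column(s): %s",
                                  paste(missing, collapse = ", "))
  df
}

#' Read published moderator moments
#'
#' CSV with columns \code{variable}, \code{mean}, \code{sd}, \code{min};
#' defaults to the bundled severity (daily newly confirmed cases) moments
#' matching the bundled coefficient table.
#'
#' @param path CSV path.
#' @return one-row tibble.
#' @export
read_moments <- function(path = system.file(
    "extdata", "covid_weibo_moments.csv", package = "affectpanel")) {
  df <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  need <- c("variable", "mean", "sd", "min")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_named("moments table missing column(s): %s",
                                  paste(missing, collapse = ", "))
  df
}

#' Reconstruct simple slopes from printed coefficients
#'
#' For each model row, computes the conditional slope of the emotion on
#' the outcome at a high moderator level (M + 1SD, i.e. z = +1) and a
#' low level (M - 1SD, substituted by the published raw minimum when
#' M - 1SD falls below it), using slope = B1 + B3 z. No standard errors
#' are produced: the coefficient covariance is not printed.
#'
#' @param coefficients tibble from [read_coefficients()].
#' @param moments one-row moments table from [read_moments()] (moderator
#'   mean, sd and raw minimum). An error is raised if absent.
#' @return tibble: \code{model}, \code{emotion}, \code{level}
#'   (\code{"high"}/\code{"low"}), \code{moderator_raw},
#'   \code{moderator_z}, \code{slope}.
#' @export
#' @examples
#' replay_slopes(read_coefficients(), read_moments())
replay_slopes <- function(coefficients = read_coefficients(),
                          moments = read_moments()) {
  if (is.null(moments) || !nrow(moments)) {
    stop_named("moderator moments are required to locate the slope levels")
  }
  mu <- moments$mean[1]; sdev <- moments$sd[1]; mn <- moments$min[1]
  if (anyNA(c(mu, sdev, mn))) stop_named("moments table has missing values")
  raw_high <- mu + sdev
  raw_low <- max(mu - sdev, mn)
  levels <- tibble::tibble(level = c("high", "low"),
                           moderator_raw = c(raw_high, raw_low),
                           moderator_z = (c(raw_high, raw_low) - mu) / sdev)
  out <- do.call(rbind, lapply(seq_len(nrow(coefficients)), function(i) {
    ci <- coefficients[i, ]
    tibble::tibble(
      model = ci$model, emotion = ci$emotion,
      level = levels$level,
      moderator_raw = levels$moderator_raw,
      moderator_z = levels$moderator_z,
      slope = ci$b_emotion + ci$b_interaction * levels$moderator_z
    )
  }))
  tibble::as_tibble(out)
}
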