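# Moderated multiple regression on the standardized daily panel:
# y ~ 1 + x + m + x*m with percentile bootstrap CIs and simple slopes
# at pick-a-point moderator levels.

#' Standardize a series, keeping its source moments
#'
#' z = (x - mean) / sd with the sample (n-1) standard deviation. The
#' source mean and sd are stored so raw moderator levels can be mapped
#' onto the standardized scale later.
#'
#' @param x numeric vector, length >= 2, nonzero variance.
#' @return object of class \code{standardized_series}: list with
#'   \code{values}, \code{source_mean}, \code{source_sd}.
#' @export
#' @examples
#' standardize(c(1, 2, 3))$values
standardize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  s <- stats::sd(x)
  if (s == 0) stop_named("zero variance: cannot standardize")
  structure(list(values = (x - mean(x)) / s,
                 source_mean = mean(x), source_sd = s),
            class = "standardized_series")
}

#' Fit a moderated regression with bootstrap intervals
#'
#' Standardizes \code{y}, \code{x} (focal predictor) and \code{m}
#' (moderator), forms the product term from the standardized factors
#' (the product itself is not re-standardized), and fits the
#' ordinary-least-squares model \code{y ~ 1 + x + m + x:m}. Analytic
#' standard errors, t statistics (df = n - 4) and p values are reported
#' alongside nonparametric case-resampling percentile bootstrap 95\%
#' intervals; the bootstrap resamples whole standardized rows and is
#' reproducible bit-for-bit under a fixed seed.
#'
#' @param y,x,m numeric vectors of equal length n >= 5 (outcome, focal
#'   predictor, moderator), on their raw scales.
#' @param n_boot number of bootstrap resamples (default 5000); 0 skips
#'   the bootstrap and reports analytic intervals only.
#' @param seed integer seed for the bootstrap RNG.
#' @param conf confidence level (default 0.95).
#' @return object of class \code{moderation_fit}: list with
#'   \code{coefficients} (tibble: term, estimate, se, t, p, ci_low,
#'   ci_high, boot_low, boot_high), \code{r_squared}, \code{f_statistic},
#'   \code{df}, \code{n}, \code{n_boot}, \code{seed}, \code{vcov},
#'   \code{moments} (source mean/sd of y, x, m).
#' @export
fit_moderation <- function(y, x, m, n_boot = 5000L, seed = 1L,
                           conf = 0.95) {
  n <- length(y)
  stopifnot(length(x) == n, length(m) == n, n >= 5)
  zy <- standardize(y); zx <- standardize(x); zm <- standardize(m)
  X <- cbind(`(Intercept)` = 1, x = zx$values, m = zm$values,
             `x:m` = zx$values * zm$values)
  if (qr(X)$rank < 4L) stop_named("rank-deficient design matrix")
  fit <- stats::lm.fit(X, zy$values)
  b <- fit$coefficients
  df_res <- n - 4L
  rss <- sum(fit$residuals^2)
  tss <- sum((zy$values - mean(zy$values))^2)
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  vc <- sigma2 * XtXinv
  se <- sqrt(diag(vc))
  tval <- b / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df_res)
  r2 <- 1 - rss / tss
  f <- (tss - rss) / 3 / sigma2

  if (n_boot > 0) {
    set.seed(as.integer(seed))
    bb <- matrix(NA_real_, n_boot, 4L)
    rows <- cbind(zy$values, X)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xi <- rows[idx, -1, drop = FALSE]
      # degenerate resamples (collinear rows) yield NA and are dropped
      cf <- tryCatch(stats::lm.fit(Xi, rows[idx, 1])$coefficients,
                     error = function(e) rep(NA_real_, 4L))
      bb[i, ] <- cf
    }
    alpha <- (1 - conf) / 2
    bq <- apply(bb, 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE)
  } else {
    bq <- matrix(NA_real_, 2L, 4L)  # analytic-only fit
  }

  coefs <- tibble::tibble(
    term = c("intercept", "x", "m", "x:m"),
    estimate = unname(b), se = unname(se), t = unname(tval),
    p = unname(pval),
    ci_low = unname(b - tcrit * se), ci_high = unname(b + tcrit * se),
    boot_low = bq[1, ], boot_high = bq[2, ]
  )
  structure(list(
    coefficients = coefs, r_squared = r2, f_statistic = f,
    f_p = stats::pf(f, 3, df_res, lower.tail = FALSE),
    df = df_res, n = n, n_boot = n_boot, seed = as.integer(seed),
    vcov = vc,
    moments = list(
      y = c(mean = zy$source_mean, sd = zy$source_sd),
      x = c(mean = zx$source_mean, sd = zx$source_sd),
      m = c(mean = zm$source_mean, sd = zm$source_sd))
  ), class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf(
    "Moderated regression (n = %d): R^2 = %.3f, F(3, %d) = %.2f, p = %.4g\n",
    x$n, x$r_squared, x$df, x$f_statistic, x$f_p))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Low moderator level with minimum substitution
#'
#' Pick-a-point rule for the low moderator group: M - 1SD, unless that
#' value falls below the observed minimum of the raw moderator (as it
#' does for a right-skewed case-count series), in which case the
#' observed minimum is used instead.
#'
#' @param m_raw raw moderator values.
#' @return a single raw moderator value.
#' @export
#' @examples
#' low_level_rule(c(77, 500, 4000, 9000))
low_level_rule <- function(m_raw) {
  stopifnot(length(m_raw) >= 1, all(is.finite(m_raw)))
  lvl <- mean(m_raw) - stats::sd(as.numeric(m_raw))
  if (length(m_raw) == 1L || is.na(lvl)) return(m_raw[1])
  max(lvl, min(m_raw))
}

#' Conditional (simple) slopes of the focal predictor
#'
#' For each raw moderator level, maps the level onto the standardized
#' scale, z = (level - mean) / sd, and reports the conditional effect
#' slope = B1 + B3 z with its standard error from the analytic
#' coefficient covariance, SE = sqrt(Var(B1) + z^2 Var(B3) +
#' 2 z Cov(B1, B3)), t = slope / SE on the model residual df, and the
#' two-tailed p value.
#'
#' @param fit a [fit_moderation()] result.
#' @param m_levels_raw numeric vector of raw moderator levels.
#' @param m_moments optional c(mean, sd) of the raw moderator; defaults
#'   to the moments stored in \code{fit}.
#' @return tibble: \code{moderator_raw}, \code{moderator_z},
#'   \code{slope}, \code{se}, \code{t}, \code{p}.
#' @export
simple_slopes <- function(fit, m_levels_raw, m_moments = NULL) {
  stopifnot(inherits(fit, "moderation_fit"))
  mm <- m_moments %||% fit$moments$m
  z <- (m_levels_raw - mm[["mean"]]) / mm[["sd"]]
  b <- fit$coefficients$estimate
  vc <- fit$vcov
  slope <- b[2] + b[4] * z
  se <- sqrt(vc["x", "x"] + z^2 * vc["x:m", "x:m"] + 2 * z * vc["x", "x:m"])
  tval <- slope / se
  tibble::tibble(
    moderator_raw = m_levels_raw, moderator_z = z,
    slope = slope, se = se, t = tval,
    p = 2 * stats::pt(-abs(tval), fit$df)
  )
}

#' Descriptives and correlation matrix of the daily panel
#'
#' Per-variable mean and sample SD, the pairwise Pearson correlation
#' matrix and two-tailed p values (t transform, df = n - 2) over the
#' eight panel variables: epidemic severity, prosocial score and the six
#' emotion scores.
#'
#' @param panel tibble from [aggregate_daily()] (needs \code{new_cases}
#'   and the seven category columns), or any numeric data frame.
#' @param variables columns to include; defaults to severity + the seven
#'   category scores when present, otherwise all numeric columns.
#' @return object of class \code{correlation_report}: list with
#'   \code{descriptives} (tibble variable/mean/sd), \code{r} matrix,
#'   \code{p} matrix, \code{n}.
#' @export
correlation_report <- function(panel, variables = NULL) {
  if (is.null(variables)) {
    preferred <- c("new_cases", "prosocial", EMOTION_CATEGORIES)
    variables <- if (all(preferred %in% names(panel))) preferred else
      names(panel)[vapply(panel, is.numeric, TRUE)]
  }
  dat <- as.data.frame(panel)[, variables, drop = FALSE]
  n <- nrow(dat)
  if (n < 3) stop_named("need at least 3 rows for correlations")
  sds <- vapply(dat, stats::sd, 0)
  const <- names(sds)[sds == 0]
  if (length(const)) stop_named("constant column '%s'", const[1])
  r <- stats::cor(as.matrix(dat))
  tmat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tmat), n - 2)
  diag(p) <- 0
  structure(list(
    descriptives = tibble::tibble(variable = variables,
                                  mean = vapply(dat, mean, 0),
                                  sd = unname(sds)),
    r = r, p = p, n = n
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Panel descriptives and correlations (n = %d)\n", x$n))
  print(as.data.frame(x$descriptives), digits = 4, row.names = FALSE)
  cat("\nPearson r:\n")
  print(round(x$r, 2))
  invisible(x)
}
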