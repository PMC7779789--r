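# Building a weighted prosocial lexicon from a human rating table:
# candidates are rated 1-9 by several raters, low-mean / high-disagreement
# terms are dropped, and retained mean ratings are min-max rescaled to [1, 9].

#' Read a rating table
#'
#' UTF-8 CSV, first column the candidate term, remaining columns one per
#' rater; every cell must be an integer on the 9-point scale.
#'
#' @param path CSV path.
#' @return a tibble with column \code{term} and one numeric column per rater.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop_named("rating table needs a term column plus raters")
  names(df)[1] <- "term"
  df$term <- canonicalize_term(as.character(df$term))
  validate_ratings(df)
  tibble::as_tibble(df)
}

validate_ratings <- function(ratings) {
  r <- as.matrix(ratings[, -1, drop = FALSE])
  if (!nrow(r)) stop_named("rating table has no candidate terms")
  if (anyNA(r)) stop_named("rating table has missing cells")
  if (any(r < 1 | r > 9)) stop_named("ratings must lie on the 1-9 scale")
  invisible(ratings)
}

#' Per-term mean and standard deviation of rater scores
#'
#' The SD uses the sample (n-1) denominator: raters are treated as a
#' sample of possible judges.
#'
#' @param ratings a rating table as returned by [read_ratings()] (column
#'   \code{term} plus one column per rater).
#' @return tibble with columns \code{term}, \code{mean}, \code{sd},
#'   preserving input order.
#' @export
#' @examples
#' tab <- tibble::tibble(term = c("a", "b"), r1 = c(6L, 1L), r2 = c(6L, 9L))
#' aggregate_ratings(tab)
aggregate_ratings <- function(ratings) {
  validate_ratings(ratings)
  r <- as.matrix(ratings[, -1, drop = FALSE])
  tibble::tibble(
    term = ratings$term,
    mean = rowMeans(r),
    sd = apply(r, 1L, stats::sd)
  )
}

#' Filter lexicon candidates on mean and rater agreement
#'
#' Deletion rules: a candidate is dropped when its mean rating is
#' strictly below \code{mean_min} (rated insufficiently prosocial) or its
#' rater SD is strictly above \code{sd_max} (rated inconsistently).
#' Boundary values are therefore retained. Input order is preserved.
#'
#' @param stats tibble with columns \code{term}, \code{mean}, \code{sd}
#'   (as from [aggregate_ratings()]).
#' @param mean_min minimum mean rating retained (default 6).
#' @param sd_max maximum rater SD retained (default 2).
#' @return the retained rows of \code{stats}.
#' @export
filter_candidates <- function(stats, mean_min = 6, sd_max = 2) {
  stopifnot(all(c("term", "mean", "sd") %in% names(stats)))
  if (!nrow(stats)) stop_named("no candidate statistics supplied")
  stats[stats$mean >= mean_min & stats$sd <= sd_max, , drop = FALSE]
}

#' Min-max rescaling of mean ratings onto a target interval
#'
#' Affine map \code{lo + (hi - lo) * (mean - min) / (max - min)}: the
#' lowest-scoring retained term maps exactly to \code{lo}, the highest to
#' \code{hi}, and rank order is preserved.
#'
#' @param means named or unnamed numeric vector of mean ratings.
#' @param lo,hi target interval endpoints (default 1 and 9).
#' @param degenerate_to_mid if all means coincide the map is undefined;
#'   set \code{TRUE} to map every term to \code{(lo + hi) / 2} instead of
#'   erroring.
#' @return numeric vector of weights, same names/order as \code{means}.
#' @export
#' @examples
#' minmax_normalize(c(a = 6, b = 7.5, c = 9))
minmax_normalize <- function(means, lo = 1, hi = 9, degenerate_to_mid = FALSE) {
  stopifnot(is.numeric(means), length(means) >= 1, all(is.finite(means)),
            hi > lo)
  rng <- range(means)
  if (rng[1] == rng[2]) {
    if (degenerate_to_mid) {
      return(setNames(rep((lo + hi) / 2, length(means)), names(means)))
    }
    stop_named("all mean ratings identical: min-max scaling undefined")
  }
  lo + (hi - lo) * (means - rng[1]) / (rng[2] - rng[1])
}

#' Inter-rater reliability of a rating table
#'
#' Two statistics are offered. \code{"icc2k"} (default) is the two-way
#' random-effects, average-measures intraclass correlation
#' ICC(2,k) = (MS_rows - MS_err) / (MS_rows + (MS_cols - MS_err) / n),
#' with terms as rows, raters as columns and n the number of terms.
#' \code{"mean_pairwise_r"} is the mean Pearson correlation over all
#' rater pairs. Both are invariant to rater relabeling and term order.
#'
#' @param ratings rating table (column \code{term} plus rater columns).
#' @param method \code{"icc2k"} or \code{"mean_pairwise_r"}.
#' @return a single number in \[-1, 1\].
#' @export
interrater_reliability <- function(ratings,
                                   method = c("icc2k", "mean_pairwise_r")) {
  method <- match.arg(method)
  validate_ratings(ratings)
  r <- as.matrix(ratings[, -1, drop = FALSE])
  n <- nrow(r); k <- ncol(r)
  if (n < 2 || k < 2) stop_named("need at least 2 terms and 2 raters")
  if (var(rowMeans(r)) == 0) {
    stop_named("zero between-term variance: reliability undefined")
  }
  if (method == "mean_pairwise_r") {
    cm <- stats::cor(r)
    return(mean(cm[upper.tri(cm)]))
  }
  grand <- mean(r)
  ms_rows <- k * sum((rowMeans(r) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(r) - grand)^2) / (k - 1)
  # residual SS of the two-way additive decomposition
  ss_err <- sum((r - outer(rowMeans(r), rep(1, k)) -
                   outer(rep(1, n), colMeans(r)) + grand)^2)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (ms_cols - ms_err) / n)
}

#' Build a prosocial lexicon from a rating table
#'
#' Convenience composition of [aggregate_ratings()],
#' [filter_candidates()] and [minmax_normalize()]: rate, drop low-mean /
#' high-disagreement candidates, then rescale the retained mean ratings
#' onto \[1, 9\].
#'
#' @inheritParams interrater_reliability
#' @inheritParams filter_candidates
#' @inheritParams minmax_normalize
#' @return a prosocial [lexicon()].
#' @export
build_prosocial_lexicon <- function(ratings, mean_min = 6, sd_max = 2,
                                    lo = 1, hi = 9) {
  kept <- filter_candidates(aggregate_ratings(ratings), mean_min, sd_max)
  if (!nrow(kept)) stop_named("no candidates survive filtering")
  w <- minmax_normalize(kept$mean, lo = lo, hi = hi)
  lexicon(kept$term, "prosocial", w, kind = "prosocial")
}
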