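# Per-post scoring: weighted lexicon frequencies with negation reversal,
# then daily averaging against the severity series.

#' Filter a raw post table for scoring
#'
#' Applies the ingest rules: posts from official verified accounts are
#' dropped; reposts keep only the comment attached to the repost (the
#' reposted body does not reflect the reposting user's own opinion), and
#' reposts with an empty comment are dropped; user identifiers are
#' replaced by a one-way anonymization map. Optionally a keyword
#' prefilter retains only posts whose text contains \code{keyword}.
#'
#' @param posts tibble/data.frame with columns \code{post_id},
#'   \code{user_id}, \code{date}, \code{text}, \code{is_official},
#'   \code{is_repost} and optionally \code{repost_comment}.
#' @param keyword optional substring; if non-\code{NULL}, posts not
#'   containing it are dropped (ingest-time topical prefilter).
#' @return the retained posts, with \code{text} rewritten for reposts and
#'   \code{user_id} anonymized; attribute \code{"drop_counts"} carries a
#'   named integer vector of exclusion counts per reason.
#' @export
filter_posts <- function(posts, keyword = NULL) {
  need <- c("post_id", "user_id", "date", "text", "is_official", "is_repost")
  missing <- setdiff(need, names(posts))
  if (length(missing)) stop_named("posts missing column(s): %s",
                                  paste(missing, collapse = ", "))
  posts <- tibble::as_tibble(posts)
  if (!"repost_comment" %in% names(posts)) posts$repost_comment <- NA_character_
  drops <- c(official = 0L, empty_repost_comment = 0L, keyword = 0L)

  keep <- !posts$is_official
  drops["official"] <- sum(!keep)
  posts <- posts[keep, , drop = FALSE]

  is_rep <- posts$is_repost
  cm <- posts$repost_comment
  cm[is.na(cm)] <- ""
  posts$text[is_rep] <- cm[is_rep]
  keep <- !(is_rep & !nzchar(trimws(posts$text)))
  drops["empty_repost_comment"] <- sum(!keep)
  posts <- posts[keep, , drop = FALSE]

  if (!is.null(keyword)) {
    keep <- grepl(keyword, posts$text, fixed = TRUE)
    drops["keyword"] <- sum(!keep)
    posts <- posts[keep, , drop = FALSE]
  }

  # one-way de-identification: opaque serial per first appearance
  posts$user_id <- sprintf("u%06d",
                           match(posts$user_id, unique(posts$user_id)))
  attr(posts, "drop_counts") <- drops
  posts
}

#' Score one token sequence against the lexicons
#'
#' Each occurrence of a lexicon term contributes its weight to the
#' term's category; a term listed under several emotion categories
#' contributes to each of them. The contribution's sign is reversed when
#' any of the \code{window} tokens immediately preceding the occurrence
#' is a negator — reversal is a flag, so several negators in the window
#' still flip the sign exactly once. Tokens absent from every lexicon
#' contribute nothing; a text without lexicon terms scores 0 everywhere.
#'
#' @param tokens character vector of tokens (see [tokenize()]).
#' @param emotion_lex emotion [lexicon()].
#' @param prosocial_lex prosocial [lexicon()].
#' @param negators character vector of negator tokens.
#' @param window how many preceding tokens are checked for a negator
#'   (default 1: only the immediately preceding token).
#' @return named numeric vector of length 7 (six emotions + prosocial).
#' @export
#' @examples
#' plex <- lexicon("帮助", "prosocial", 8.2, kind = "prosocial")
#' elex <- lexicon("高兴", "happiness", 5, kind = "emotion")
#' score_post(c("不", "帮助"), elex, plex, negators = "不")
score_post <- function(tokens, emotion_lex, prosocial_lex,
                       negators = character(0), window = 1L) {
  stopifnot(window >= 1L)
  scores <- setNames(numeric(length(ALL_CATEGORIES)), ALL_CATEGORIES)
  if (!length(tokens)) return(scores)
  lex <- rbind(as.data.frame(emotion_lex)[c("term", "category", "weight")],
               as.data.frame(prosocial_lex)[c("term", "category", "weight")])
  negset <- unique(canonicalize_term(negators))
  is_neg <- tokens %in% negset
  n <- length(tokens)
  for (i in seq_len(n)) {
    rows <- which(lex$term == tokens[i])
    if (!length(rows)) next
    lo <- max(1L, i - window)
    flip <- i > 1L && any(is_neg[lo:(i - 1L)])
    sgn <- if (flip) -1 else 1
    for (r in rows) {
      scores[[lex$category[r]]] <- scores[[lex$category[r]]] +
        sgn * lex$weight[r]
    }
  }
  scores
}

# vectorized scorer used by score_posts(): same semantics as score_post()
# but one pass over all tokens of all posts via lookup tables.
score_token_matrix <- function(token_list, lex, negset, window) {
  cat_idx <- match(lex$category, ALL_CATEGORIES)
  out <- matrix(0, nrow = length(token_list), ncol = length(ALL_CATEGORIES),
                dimnames = list(NULL, ALL_CATEGORIES))
  # group lexicon rows by term for O(1) lookup
  by_term <- split(seq_len(nrow(lex)), lex$term)
  for (p in seq_along(token_list)) {
    toks <- token_list[[p]]
    if (!length(toks)) next
    hits <- which(toks %in% names(by_term))
    if (!length(hits)) next
    is_neg <- toks %in% negset
    for (i in hits) {
      lo <- max(1L, i - window)
      sgn <- if (i > 1L && any(is_neg[lo:(i - 1L)])) -1 else 1
      for (r in by_term[[toks[i]]]) {
        out[p, cat_idx[r]] <- out[p, cat_idx[r]] + sgn * lex$weight[r]
      }
    }
  }
  out
}

#' Score a table of posts
#'
#' Tokenizes each post (default tokenizer [tokenize()] with a vocabulary
#' of all lexicon terms plus negators) and applies [score_post()]
#' semantics to every post.
#'
#' @param posts tibble with at least \code{post_id}, \code{date},
#'   \code{text} (normally the output of [filter_posts()]).
#' @inheritParams score_post
#' @param tokenizer function \code{(text, vocab) -> character()}; defaults
#'   to [tokenize()].
#' @return tibble: \code{post_id}, \code{date}, one numeric column per
#'   category.
#' @export
score_posts <- function(posts, emotion_lex, prosocial_lex,
                        negators = character(0), window = 1L,
                        tokenizer = tokenize) {
  stopifnot(all(c("post_id", "date", "text") %in% names(posts)))
  lex <- rbind(as.data.frame(emotion_lex)[c("term", "category", "weight")],
               as.data.frame(prosocial_lex)[c("term", "category", "weight")])
  negset <- unique(canonicalize_term(negators))
  vocab <- unique(c(lex$term, negset))
  token_list <- lapply(posts$text, tokenizer, vocab = vocab)
  sc <- score_token_matrix(token_list, lex, negset, window)
  out <- tibble::tibble(post_id = posts$post_id, date = as.Date(posts$date))
  for (cat in ALL_CATEGORIES) out[[cat]] <- sc[, cat]
  out
}

#' Aggregate per-post scores into a daily panel
#'
#' Computes the per-day mean of each category score (every post weighted
#' equally), records the per-day post count, and joins the daily severity
#' series (newly confirmed cases). Every day of the study window must
#' have at least one post and a severity value.
#'
#' @param scored output of [score_posts()].
#' @param severity tibble with columns \code{date}, \code{new_cases}.
#' @param window_start,window_end study window (inclusive); defaults to
#'   the range of dates present in \code{scored}.
#' @return tibble with one row per day: \code{date}, \code{n_posts}, the
#'   seven mean category scores, \code{new_cases}.
#' @export
aggregate_daily <- function(scored, severity,
                            window_start = min(scored$date),
                            window_end = max(scored$date)) {
  stopifnot(all(c("date", "new_cases") %in% names(severity)))
  days <- seq(as.Date(window_start), as.Date(window_end), by = "day")
  scored <- scored[scored$date %in% days, , drop = FALSE]
  have <- unique(scored$date)
  miss <- days[!days %in% have]
  if (length(miss)) stop_named("no posts on day %s", format(miss[1]))
  sev <- setNames(severity$new_cases, as.character(as.Date(severity$date)))
  missev <- days[!as.character(days) %in% names(sev)]
  if (length(missev)) stop_named("no severity value for day %s",
                                 format(missev[1]))
  f <- factor(as.character(scored$date), levels = as.character(days))
  out <- tibble::tibble(
    date = days,
    n_posts = as.integer(table(f))
  )
  for (cat in ALL_CATEGORIES) {
    out[[cat]] <- as.numeric(tapply(scored[[cat]], f, mean))
  }
  out$new_cases <- as.numeric(sev[as.character(days)])
  out
}

#' Read posts from JSON-lines or CSV
#'
#' JSONL: one JSON object per line with the post fields; CSV: identical
#' headers. Field types are coerced (\code{date} to \code{Date}, flags to
#' logical).
#'
#' @param path input path; format inferred from the extension
#'   (\code{.jsonl}/\code{.ndjson} vs \code{.csv}).
#' @return tibble of posts.
#' @export
read_posts <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                          colClasses = "character")
  }
  df <- tibble::as_tibble(df)
  df$date <- as.Date(df$date)
  df$is_official <- as.logical(df$is_official)
  df$is_repost <- as.logical(df$is_repost)
  if (!"repost_comment" %in% names(df)) df$repost_comment <- NA_character_
  df$repost_comment[df$repost_comment %in% c("", "NA")] <- NA_character_
  df
}

#' Write posts as JSON-lines
#' @param posts tibble of posts.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_posts <- function(posts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  df <- as.data.frame(posts)
  df$date <- as.character(df$date)
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' Read a daily severity series
#'
#' CSV \code{date,new_cases} with ISO-8601 dates and nonnegative integer
#' case counts.
#'
#' @param path CSV path.
#' @return tibble with \code{date} (Date) and \code{new_cases} (integer).
#' @export
read_severity <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  stopifnot(all(c("date", "new_cases") %in% names(df)))
  out <- tibble::tibble(date = as.Date(df$date),
                        new_cases = as.integer(df$new_cases))
  if (any(out$new_cases < 0)) stop_named("negative case count in '%s'", path)
  out
}

#' Write a daily severity series
#' @param severity tibble with \code{date}, \code{new_cases}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_severity <- function(severity, path) {
  df <- data.frame(date = as.character(as.Date(severity$date)),
                   new_cases = as.integer(severity$new_cases))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read the daily panel CSV
#'
#' Dialect: \code{date,n_posts,happiness,...,surprise,prosocial,new_cases}.
#'
#' @param panel tibble from [aggregate_daily()].
#' @param path CSV path.
#' @return \code{path} (write) or the panel tibble (read).
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$date <- as.character(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' Read a negator list
#'
#' One token per line, UTF-8, \code{#} comment lines ignored. Defaults to
#' the Chinese negator inventory bundled with the package.
#'
#' @param path file path.
#' @return character vector of negator tokens.
#' @export
read_negators <- function(path = system.file(
    "extdata", "negators_zh.txt", package = "affectpanel")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  unique(canonicalize_term(lines[nzchar(lines)]))
}
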