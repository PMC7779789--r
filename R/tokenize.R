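#' Segment text with a lexicon-augmented greedy matcher
#'
#' Default segmenter for scoring. Whitespace is a hard separator; within
#' each non-whitespace run the matcher walks left to right taking the
#' longest vocabulary term starting at the current position (prefix-trie
#' lookup), falling back to a single character where nothing matches.
#' Every vocabulary term occurring contiguously in the text is therefore
#' guaranteed to surface as one token, which is the only property
#' scoring relies on. For real Chinese text a full segmenter (e.g. a
#' jieba port) can be plugged in anywhere a \code{tokenizer} argument is
#' accepted, as long as it maps a string to a character vector of tokens.
#'
#' @param text a single string.
#' @param vocab character vector of vocabulary terms: all lexicon terms
#'   plus the negator list.
#' @return character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("不捐赠", vocab = c("捐赠", "不"))
tokenize <- function(text, vocab) {
  stopifnot(length(text) == 1L, is.character(text), length(vocab) >= 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  trie <- vocab_trie(vocab)
  runs <- strsplit(trimws(text), "\\s+")[[1]]
  runs <- runs[nzchar(runs)]
  out <- vector("list", length(runs))
  for (j in seq_along(runs)) {
    run <- runs[j]
    st <- get0(run, envir = trie, inherits = FALSE)
    if (isTRUE(st)) {       # fast path: the whole run is one vocab term
      out[[j]] <- run
      next
    }
    out[[j]] <- match_run(run, trie)
  }
  unlist(out) %||% character(0)
}

# prefix map: every prefix of every vocab term, TRUE iff a full term.
# Cached on the vocab vector so repeated calls over a corpus reuse it.
vocab_trie <- function(vocab) {
  cached <- attr(vocab, "affectpanel_trie")
  if (!is.null(cached)) return(cached)
  key <- paste(vocab, collapse = "\r")
  hit <- get0(key, envir = .trie_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  vocab <- unique(canonicalize_term(vocab))
  trie <- new.env(parent = emptyenv(), size = 4L * length(vocab))
  for (v in vocab) {
    n <- nchar(v)
    for (l in seq_len(n - 1L)) {
      p <- substr(v, 1L, l)
      if (is.null(get0(p, envir = trie, inherits = FALSE))) {
        assign(p, FALSE, envir = trie)
      }
    }
    assign(v, TRUE, envir = trie)
  }
  assign(key, trie, envir = .trie_cache)
  trie
}
.trie_cache <- new.env(parent = emptyenv())

# greedy longest-match over one whitespace-free run
match_run <- function(run, trie) {
  chars <- strsplit(run, "", fixed = TRUE)[[1]]
  nc <- length(chars)
  toks <- character(nc)  # at most one token per character
  nt <- 0L
  i <- 1L
  while (i <= nc) {
    best <- 0L
    cand <- ""
    l <- 0L
    while (i + l <= nc) {
      cand <- paste0(cand, chars[i + l])
      l <- l + 1L
      st <- get0(cand, envir = trie, inherits = FALSE)
      if (is.null(st)) break          # not even a prefix: stop extending
      if (isTRUE(st)) best <- l       # full term: remember longest so far
    }
    nt <- nt + 1L
    if (best > 0L) {
      toks[nt] <- substr(run, i, i + best - 1L)
      i <- i + best
    } else {
      toks[nt] <- chars[i]
      i <- i + 1L
    }
  }
  toks[seq_len(nt)]
}
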