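#' Construct a weighted lexicon
#'
#' A lexicon is a set of (term, category, weight) entries. The emotion
#' kind admits the six basic-emotion categories (happiness, anger,
#' sadness, fear, disgust, surprise); the prosocial kind admits only the
#' single category \code{"prosocial"}. Weights are intensity (emotion) or
#' prosociality (prosocial) ratings on the 1--9 scale.
#'
#' @param term character vector of terms (canonicalized internally).
#' @param category character vector of categories, recycled if length 1.
#' @param weight numeric vector of weights in \[1, 9\].
#' @param kind \code{"emotion"} or \code{"prosocial"}.
#' @return an object of class \code{lexicon}: a tibble with columns
#'   \code{term}, \code{category}, \code{weight} and attribute \code{kind}.
#' @export
#' @examples
#' lexicon(c("捐赠", "帮助"), "prosocial", c(8.5, 7.9), kind = "prosocial")
lexicon <- function(term, category, weight, kind = c("emotion", "prosocial")) {
  kind <- match.arg(kind)
  term <- canonicalize_term(as.character(term))
  category <- as.character(rep_len(category, length(term)))
  weight <- as.numeric(weight)
  stopifnot(length(category) == length(term), length(weight) == length(term))
  entries <- tibble::tibble(term = term, category = category, weight = weight)
  validate_lexicon_entries(entries, kind)
  structure(entries, class = c("lexicon", class(entries)), kind = kind)
}

validate_lexicon_entries <- function(entries, kind, line = NULL) {
  at <- function(i) if (is.null(line)) "" else sprintf(" (line %d)", line[i])
  allowed <- if (kind == "prosocial") "prosocial" else EMOTION_CATEGORIES
  bad <- which(!entries$category %in% allowed)
  if (length(bad)) {
    stop_named("unknown category '%s' for %s lexicon%s",
               entries$category[bad[1]], kind, at(bad[1]))
  }
  bad <- which(!nzchar(entries$term))
  if (length(bad)) stop_named("empty term%s", at(bad[1]))
  bad <- which(!is.finite(entries$weight) |
                 entries$weight < 1 | entries$weight > 9)
  if (length(bad)) {
    stop_named("weight %s outside [1, 9]%s",
               format(entries$weight[bad[1]]), at(bad[1]))
  }
  key <- paste(entries$term, entries$category, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) {
    stop_named("duplicate (term, category) entry '%s'%s",
               entries$term[bad[1]], at(bad[1]))
  }
  invisible(entries)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %s, %d entries, %d categories>\n",
              attr(x, "kind"), nrow(x), length(unique(x$category))))
  NextMethod()
}

#' Read a lexicon from a tab-separated file
#'
#' The file dialect is UTF-8 TSV with header \code{term<TAB>category<TAB>weight}
#' and \code{#}-prefixed comment lines. Parse errors (weight outside
#' \[1, 9\], unknown category, duplicated (term, category)) name the
#' offending line number.
#'
#' @param path file path.
#' @param kind \code{"emotion"} or \code{"prosocial"}.
#' @return a [lexicon()].
#' @export
read_lexicon <- function(path, kind = c("emotion", "prosocial")) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop_named("no content in lexicon file '%s'", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!identical(trimws(fields[[1]][1:3]), c("term", "category", "weight"))) {
    stop_named("expected header 'term\\tcategory\\tweight' in '%s'", path)
  }
  fields <- fields[-1]
  lineno <- lineno[-1]
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_named("malformed row (need 3 tab-separated fields) (line %d)",
               lineno[which(nf < 3)[1]])
  }
  entries <- tibble::tibble(
    term = canonicalize_term(vapply(fields, `[`, "", 1L)),
    category = trimws(vapply(fields, `[`, "", 2L)),
    weight = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  )
  bad <- which(is.na(entries$weight))
  if (length(bad)) stop_named("non-numeric weight (line %d)", lineno[bad[1]])
  validate_lexicon_entries(entries, kind, line = lineno)
  structure(entries, class = c("lexicon", class(entries)), kind = kind)
}

#' Write a lexicon to a tab-separated file
#'
#' Inverse of [read_lexicon()]: a write followed by a read reproduces the
#' entry set exactly (weights are written with full precision).
#'
#' @param lex a [lexicon()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  rows <- sprintf("%s\t%s\t%s", lex$term, lex$category,
                  formatC(lex$weight, digits = 17, format = "g"))
  writeLines(c("term\tcategory\tweight", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Fraction of one lexicon's terms found in another
#'
#' Computes |terms(a) intersect terms(b)| / |terms(a)| on canonicalized
#' unique terms, the overlap statistic used to compare a newly built
#' lexicon against an established reference dictionary.
#'
#' @param a,b lexicons (or anything coercible to a character term vector
#'   via a \code{term} column).
#' @return a fraction in \[0, 1\].
#' @export
lexicon_overlap <- function(a, b) {
  ta <- unique(canonicalize_term(if (is.character(a)) a else a$term))
  tb <- unique(canonicalize_term(if (is.character(b)) b else b$term))
  if (!length(ta)) stop_named("lexicon 'a' has no terms")
  mean(ta %in% tb)
}
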