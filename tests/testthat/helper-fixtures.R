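# Shared fixture builders: everything is generated in code, nothing on disk.

toy_prosocial_lexicon <- function() {
  lexicon(c("帮助", "捐赠", "志愿", "奉献"), "prosocial",
          c(8.2, 7.0, 5.0, 9.0), kind = "prosocial")
}

toy_emotion_lexicon <- function() {
  lexicon(
    term = c("高兴", "愤怒", "悲伤", "害怕", "厌恶", "惊讶", "激动", "激动"),
    category = c("happiness", "anger", "sadness", "fear", "disgust",
                 "surprise", "happiness", "surprise"),
    weight = c(5, 7, 3, 6, 4, 2, 6.5, 3.5),
    kind = "emotion")
}

toy_negators <- function() c("不", "没有", "很少")

# complete rating table: one row per term, one column per rater
toy_ratings <- function() {
  tibble::tibble(
    term = c("帮助", "捐赠", "志愿", "奉献"),
    r1 = c(9L, 7L, 5L, 8L),
    r2 = c(8L, 6L, 4L, 9L),
    r3 = c(9L, 7L, 6L, 8L)
  )
}

# small simulation config so synthetic tests stay fast
small_sim_config <- function(...) {
  defaults <- list(posts_per_day = c(60L, 120L), emotion_vocab_size = 15L,
                   prosocial_vocab_size = 40L, filler_vocab_size = 80L,
                   fillers_per_post = 6)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Independent scoring oracle: exhaustively enumerates every
# (token occurrence, lexicon entry) pair and accumulates signed weights.
# Deliberately vectorized/merge-based, sharing no code with score_post().
oracle_score <- function(tokens, lex, negators, window = 1L) {
  out <- stats::setNames(numeric(7), c("happiness", "anger", "sadness",
                                       "fear", "disgust", "surprise",
                                       "prosocial"))
  if (!length(tokens)) return(out)
  occ <- data.frame(pos = seq_along(tokens), token = tokens)
  hits <- merge(occ, as.data.frame(lex), by.x = "token", by.y = "term")
  if (!nrow(hits)) return(out)
  is_neg <- tokens %in% negators
  flip <- vapply(hits$pos, function(i) {
    lo <- max(1L, i - window)
    i > 1L && any(is_neg[lo:(i - 1L)])
  }, logical(1))
  contrib <- ifelse(flip, -hits$weight, hits$weight)
  agg <- tapply(contrib, hits$category, sum)
  out[names(agg)] <- agg
  out
}

# random token sequence mixing lexicon terms, negators and noise tokens
random_tokens <- function(lex, negators, max_len = 12L) {
  pool <- c(lex$term, negators, c("x1", "x2", "x3", "的", "了"))
  n <- sample.int(max_len, 1L) - 1L
  if (n == 0) character(0) else sample(pool, n, replace = TRUE)
}

full_toy_lexicon_frame <- function() {
  rbind(as.data.frame(toy_emotion_lexicon())[1:3],
        as.data.frame(toy_prosocial_lexicon())[1:3])
}

# write a small synthetic corpus + lexicons + severity to dir
make_pipeline_inputs <- function(dir, seed = 10, b3 = 0.6,
                                 official_fraction = 0.05,
                                 repost_fraction = 0.1) {
  cfg <- small_sim_config(b3 = b3, posts_per_day = c(80L, 140L),
                          official_fraction = official_fraction,
                          repost_fraction = repost_fraction)
  lx <- generate_lexicons(cfg, seed)
  sv <- generate_severity(cfg, seed)
  gp <- generate_posts(cfg, lx, sv, seed)
  write_posts(gp$posts, file.path(dir, "posts.jsonl"))
  write_lexicon(lx$emotion, file.path(dir, "emotion.tsv"))
  write_lexicon(lx$prosocial, file.path(dir, "prosocial.tsv"))
  write_severity(sv, file.path(dir, "severity.csv"))
  list(cfg = cfg, lx = lx, truth = gp$truth)
}

pipeline_config <- function(dir, out, seed = 1, n_boot = 200) {
  run_config(
    posts = file.path(dir, "posts.jsonl"),
    emotion_lexicon = file.path(dir, "emotion.tsv"),
    prosocial_lexicon = file.path(dir, "prosocial.tsv"),
    severity = file.path(dir, "severity.csv"),
    out_dir = out, n_boot = n_boot, seed = seed,
    negators = generate_lexicons(small_sim_config(), 10)$negators)
}
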