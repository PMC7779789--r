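# Post filtering, tokenization, weighted-frequency scoring with negation
# reversal, and daily aggregation.

test_that("ingest filtering drops official posts and keeps repost comments", {
  posts <- tibble::tibble(
    post_id = c("p1", "p2", "p3", "p4"),
    user_id = c("alice", "bob", "alice", "carol"),
    date = as.Date("2020-01-20") + 0:3,
    text = c("普通原创内容", "官方通告", "转发正文", "转发正文"),
    is_official = c(FALSE, TRUE, FALSE, FALSE),
    is_repost = c(FALSE, FALSE, TRUE, TRUE),
    repost_comment = c(NA, NA, "加油", ""))
  out <- filter_posts(posts)
  drops <- attr(out, "drop_counts")
  expect_equal(out$post_id, c("p1", "p3"))
  expect_equal(out$text, c("普通原创内容", "加油"))
  expect_equal(unname(drops[c("official", "empty_repost_comment")]), c(1L, 1L))
  # one-way anonymization: original handles are gone, same user same alias
  expect_false(any(out$user_id %in% posts$user_id))
  expect_equal(out$user_id[1], "u000001")

  kw <- filter_posts(posts, keyword = "加油")
  expect_equal(kw$post_id, "p3")
})

test_that("greedy longest-match tokenization honors the vocabulary", {
  vocab <- c("捐赠", "不", "捐", "医护人员")
  expect_equal(tokenize("捐赠", vocab), "捐赠")           # whole-term fast path
  expect_equal(tokenize("不捐赠", vocab), c("不", "捐赠")) # longest match wins
  expect_equal(tokenize("", vocab), character(0))
  expect_equal(tokenize("我不捐赠了", vocab), c("我", "不", "捐赠", "了"))
  # a contiguous vocab term always surfaces as one token
  toks <- tokenize("感谢医护人员的付出", vocab)
  expect_true("医护人员" %in% toks)
  # whitespace is a separator and never appears in tokens
  expect_equal(tokenize("neg01 pro0001", c("pro0001", "neg01")),
               c("neg01", "pro0001"))
})

test_that("scoring accumulates signed weighted frequencies per category", {
  elex <- toy_emotion_lexicon()
  plex <- toy_prosocial_lexicon()
  negs <- toy_negators()

  s <- score_post("帮助", elex, plex, negs)
  expect_equal(s[["prosocial"]], 8.2)
  expect_equal(sum(abs(s[names(s) != "prosocial"])), 0)

  expect_equal(score_post(c("不", "帮助"), elex, plex, negs)[["prosocial"]],
               -8.2)
  expect_equal(score_post(c("帮助", "捐赠"), elex, plex, negs)[["prosocial"]],
               8.2 + 7.0)
  # a term listed under two emotion categories feeds both
  s2 <- score_post("激动", elex, plex, negs)
  expect_equal(s2[["happiness"]], 6.5)
  expect_equal(s2[["surprise"]], 3.5)
  # no lexicon content scores zero everywhere
  expect_equal(unname(score_post(c("的", "了"), elex, plex, negs)),
               rep(0, 7))
})

test_that("negation reversal is a flag over the preceding window", {
  elex <- toy_emotion_lexicon()
  plex <- toy_prosocial_lexicon()
  negs <- toy_negators()
  w <- 8.2  # weight of 帮助

  # window 1: only the immediately preceding token counts
  expect_equal(score_post(c("不", "不", "帮助"), elex, plex, negs,
                          window = 1)[["prosocial"]], -w)
  # wider window: two negators still flip exactly once (flag, not product)
  expect_equal(score_post(c("不", "没有", "帮助"), elex, plex, negs,
                          window = 2)[["prosocial"]], -w)
  # negator beyond the window does nothing
  expect_equal(score_post(c("不", "的", "帮助"), elex, plex, negs,
                          window = 1)[["prosocial"]], w)
})

test_that("score_post equals the exhaustive enumeration oracle", {
  elex <- toy_emotion_lexicon()
  plex <- toy_prosocial_lexicon()
  negs <- toy_negators()
  lex <- full_toy_lexicon_frame()
  set.seed(424)
  for (case in seq_len(1000)) {
    toks <- random_tokens(lex, negs)
    win <- sample(1:3, 1)
    expect_equal(score_post(toks, elex, plex, negs, window = win),
                 oracle_score(toks, lex, negs, window = win))
  }
})

test_that("scoring is additive over concatenation away from negators", {
  elex <- toy_emotion_lexicon()
  plex <- toy_prosocial_lexicon()
  negs <- toy_negators()
  lex <- full_toy_lexicon_frame()
  set.seed(77)
  for (case in 1:50) {
    a <- random_tokens(lex, negs)
    b <- random_tokens(lex, negs)
    # pad the boundary so no negator scope can span it
    sep <- c("x1", "x2")
    expect_equal(
      score_post(c(a, sep, b), elex, plex, negs),
      score_post(c(a, sep), elex, plex, negs) + score_post(b, elex, plex, negs))
  }
})

test_that("score_posts matches score_post on whole posts", {
  elex <- toy_emotion_lexicon()
  plex <- toy_prosocial_lexicon()
  negs <- toy_negators()
  posts <- tibble::tibble(
    post_id = c("p1", "p2", "p3"),
    date = as.Date("2020-01-20") + c(0, 0, 1),
    text = c("不帮助", "捐赠 帮助", ""))
  sc <- score_posts(posts, elex, plex, negs)
  vocab <- c(elex$term, plex$term, negs)
  for (i in 1:3) {
    expect_equal(
      unlist(sc[i, -(1:2)]),
      score_post(tokenize(posts$text[i], vocab), elex, plex, negs))
  }
})

test_that("daily aggregation averages posts and conserves mass", {
  elex <- toy_emotion_lexicon()
  plex <- toy_prosocial_lexicon()
  scored <- tibble::tibble(
    post_id = c("p1", "p2", "p3"),
    date = as.Date("2020-01-20") + c(0, 1, 1))
  for (cat in c("happiness", "anger", "sadness", "fear", "disgust",
                "surprise", "prosocial")) scored[[cat]] <- 0
  scored$prosocial <- c(5, 2, 4)
  sev <- tibble::tibble(date = as.Date("2020-01-20") + 0:1,
                        new_cases = c(100L, 200L))
  pan <- aggregate_daily(scored, sev)
  expect_equal(pan$n_posts, c(1L, 2L))
  expect_equal(pan$prosocial, c(5, 3))
  expect_equal(pan$new_cases, c(100, 200))
  # mass conservation: sum(mean * n) equals the total post score
  expect_equal(sum(pan$prosocial * pan$n_posts), sum(scored$prosocial))

  expect_error(aggregate_daily(scored, sev,
                               window_end = as.Date("2020-01-22")),
               "2020-01-22")
  expect_error(aggregate_daily(scored, sev[1, ]), "2020-01-21")
})

test_that("a 41-day synthetic window yields a 41-row panel", {
  cfg <- small_sim_config()
  lx <- generate_lexicons(cfg, 5)
  sv <- generate_severity(cfg, 5)
  gp <- generate_posts(cfg, lx, sv, 5)
  sc <- score_posts(filter_posts(gp$posts), lx$emotion, lx$prosocial,
                    negators = lx$negators)
  pan <- aggregate_daily(sc, sv)
  expect_equal(nrow(pan), 41L)
  expect_true(all(pan$n_posts >= 1))
  expect_equal(pan$date, sv$date)
})

test_that("post and severity files round-trip through the documented dialects", {
  posts <- tibble::tibble(
    post_id = "p1", user_id = "u1", date = as.Date("2020-02-01"),
    text = "捐赠 帮助", is_official = FALSE, is_repost = FALSE,
    repost_comment = NA_character_)
  pj <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(posts, pj)
  back <- read_posts(pj)
  expect_equal(back$text, posts$text)
  expect_equal(back$date, posts$date)
  expect_identical(back$is_official, FALSE)

  sev <- tibble::tibble(date = as.Date("2020-02-01") + 0:2,
                        new_cases = c(77L, 120L, 98L))
  sp <- withr::local_tempfile(fileext = ".csv")
  write_severity(sev, sp)
  expect_equal(as.data.frame(read_severity(sp)), as.data.frame(sev))
})
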