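# Lexicon construction: rating aggregation, candidate filtering,
# min-max rescaling, inter-rater reliability, overlap, file round-trips.

test_that("aggregate_ratings returns rater means and sample SDs", {
  tab <- tibble::tibble(term = c("a", "b", "c"),
                        r1 = c(6L, 1L, 9L), r2 = c(6L, 9L, 9L))
  # pad 'a' to ten constant ratings via a wider table
  const <- tibble::tibble(term = "k")
  for (i in 1:10) const[[paste0("r", i)]] <- 6L
  out_const <- aggregate_ratings(const)
  expect_equal(out_const$mean, 6)
  expect_equal(out_const$sd, 0)

  out <- aggregate_ratings(tab)
  expect_equal(out$term, c("a", "b", "c"))
  expect_equal(out$mean, c(6, 5, 9))
  # hand computation, n-1 denominator: sd(1, 9) = sqrt(32)
  expect_equal(out$sd, c(0, sqrt(32), 0))

  all9 <- tibble::tibble(term = "x")
  for (i in 1:10) all9[[paste0("r", i)]] <- 9L
  expect_equal(aggregate_ratings(all9)$mean, 9)
  expect_equal(aggregate_ratings(all9)$sd, 0)

  expect_error(aggregate_ratings(tibble::tibble(term = character(0),
                                                r1 = integer(0))),
               "no candidate")
})

test_that("candidate filtering deletes on strict inequalities only", {
  stats <- tibble::tibble(
    term = c("low_mean", "boundary", "high_sd", "good"),
    mean = c(5.99, 6.0, 8.0, 7.2),
    sd = c(0.5, 2.0, 2.01, 1.0))
  kept <- filter_candidates(stats)
  expect_setequal(kept$term, c("boundary", "good"))
  # order preserved, and filtering is idempotent
  expect_equal(kept$term, c("boundary", "good"))
  expect_identical(filter_candidates(kept), kept)
})

test_that("min-max normalization maps extremes to the target interval", {
  expect_equal(minmax_normalize(c(a = 6, b = 9)), c(a = 1, b = 9))
  expect_equal(minmax_normalize(c(a = 6, b = 7.5, c = 9))[["b"]], 5)

  set.seed(11)
  for (rep in 1:20) {
    means <- runif(sample(2:50, 1), 1, 9)
    w <- minmax_normalize(means)
    expect_equal(min(w), 1)
    expect_equal(max(w), 9)
    expect_equal(rank(w, ties.method = "first"),
                 rank(means, ties.method = "first"))
  }

  expect_error(minmax_normalize(rep(7, 3)), "identical")
  expect_equal(minmax_normalize(rep(7, 3), degenerate_to_mid = TRUE),
               rep(5, 3))
})

test_that("ICC(2,k) matches a two-way ANOVA mean-squares oracle", {
  tab <- toy_ratings()
  got <- interrater_reliability(tab, method = "icc2k")

  # oracle: mean squares from aov() on the long table
  long <- data.frame(
    rating = c(tab$r1, tab$r2, tab$r3),
    term = factor(rep(tab$term, 3)),
    rater = factor(rep(c("r1", "r2", "r3"), each = nrow(tab))))
  ms <- summary(stats::aov(rating ~ term + rater, data = long))[[1]][["Mean Sq"]]
  n <- nrow(tab)
  want <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(got >= -1 && got <= 1)
})

test_that("reliability is invariant to rater relabeling and term order", {
  tab <- toy_ratings()
  shuffled <- tab[sample(nrow(tab)), c("term", "r3", "r1", "r2")]
  names(shuffled) <- c("term", "rA", "rB", "rC")
  for (m in c("icc2k", "mean_pairwise_r")) {
    expect_equal(interrater_reliability(tab, m),
                 interrater_reliability(shuffled, m))
  }
})

test_that("perfect agreement gives reliability 1, none gives about 0", {
  tab <- tibble::tibble(term = letters[1:6],
                        r1 = c(1L, 3L, 5L, 7L, 9L, 2L))
  tab$r2 <- tab$r1; tab$r3 <- tab$r1
  expect_equal(interrater_reliability(tab, "icc2k"), 1)
  expect_equal(interrater_reliability(tab, "mean_pairwise_r"), 1)

  # destroy agreement: second rater is an independent shuffle, large n
  set.seed(303)
  v <- sample(rep(1:9, length.out = 200))
  big <- tibble::tibble(term = sprintf("t%03d", 1:200),
                        r1 = v, r2 = sample(v))
  expect_lt(abs(interrater_reliability(big, "icc2k")), 0.1)
  expect_lt(abs(interrater_reliability(big, "mean_pairwise_r")), 0.1)

  const <- tibble::tibble(term = c("a", "b"), r1 = c(5L, 5L), r2 = c(5L, 5L))
  expect_error(interrater_reliability(const), "variance")
})

test_that("lexicon overlap counts shared canonical terms", {
  a <- toy_prosocial_lexicon()
  expect_equal(lexicon_overlap(a, a), 1)
  b <- lexicon(c("合作", "分享"), "prosocial", c(7, 7), kind = "prosocial")
  expect_equal(lexicon_overlap(a, b), 0)
  expect_equal(lexicon_overlap(c("x", "y", "z", "w"), c("x", "y", "z", "q")),
               0.75)
  expect_error(lexicon_overlap(character(0), a), "no terms")

  # monotone nondecreasing as b grows
  grown <- c("合作", a$term[1:2])
  expect_gte(lexicon_overlap(a, grown), lexicon_overlap(a, b))
})

test_that("lexicon files round-trip exactly and reject bad rows", {
  cfg <- small_sim_config(prosocial_vocab_size = 155L)
  lex <- generate_lexicons(cfg, 99)$prosocial
  expect_equal(nrow(lex), 155L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  back <- read_lexicon(path, kind = "prosocial")
  expect_equal(as.data.frame(back), as.data.frame(lex))

  bad_cat <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tcategory\tweight", "smile\tjoy\t5"), bad_cat)
  expect_error(read_lexicon(bad_cat, "emotion"), "joy.*line 2")

  bad_w <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tcategory\tweight", "# comment", "smile\thappiness\t9.5"),
             bad_w)
  expect_error(read_lexicon(bad_w, "emotion"), "9.5.*line 3")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tcategory\tweight", "help\tprosocial\t5",
               "help\tprosocial\t6"), dup)
  expect_error(read_lexicon(dup, "prosocial"), "duplicate.*line 3")
})

test_that("build_prosocial_lexicon composes rate, filter and rescale", {
  set.seed(7)
  n <- 30
  tab <- tibble::tibble(term = sprintf("w%02d", 1:n))
  base <- runif(n, 3, 9)
  for (i in 1:10) tab[[paste0("r", i)]] <- pmin(9L, pmax(1L,
    as.integer(round(base + rnorm(n, 0, 1)))))
  lex <- build_prosocial_lexicon(tab)
  st <- filter_candidates(aggregate_ratings(tab))
  expect_equal(nrow(lex), nrow(st))
  expect_equal(range(lex$weight), c(1, 9))
  expect_true(all(lex$category == "prosocial"))
})
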