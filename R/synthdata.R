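# Synthetic corpus generator: lexicons, a severity curve and a post
# stream with a planted emotion x severity interaction on prosocial word
# emission, so every pipeline stage can be tested against known ground
# truth. The synthetic "language" is whitespace-separable and its filler
# vocabulary is disjoint from all lexicons, which keeps the default
# tokenizer and the scoring oracle exact on generated text.

#' Simulation configuration
#'
#' Bundles every knob of the generator with defaults emulating the scale
#' of the study design the package targets: a 41-day window starting
#' 2020-01-20, hundreds to thousands of posts per day, a 155-word
#' prosocial lexicon, a severity pulse floored at 77 daily cases.
#'
#' @param n_days number of panel days (default 41).
#' @param start_date first day of the window.
#' @param posts_per_day integer range c(lo, hi); the per-day post count
#'   is drawn uniformly from it.
#' @param emotion_vocab_size synthetic terms per emotion category.
#' @param prosocial_vocab_size synthetic prosocial terms (default 155).
#' @param filler_vocab_size neutral filler vocabulary size.
#' @param n_negators number of synthetic negator tokens.
#' @param fillers_per_post mean filler tokens per post (Poisson).
#' @param latent_mean,latent_sd per-day latent emotion intensity
#'   distribution (shared across categories; latents are standardized
#'   before entering the structural equation).
#' @param severity_peak_day,severity_peak_height,severity_shape,severity_floor
#'   log-normal-shaped severity pulse parameters and case-count floor.
#' @param severity_noise add Poisson noise to the severity curve.
#' @param b0,b1,b2,b3 structural coefficients of the planted model:
#'   latent prosocial = b0 + b1 emotion + b2 severity +
#'   b3 emotion x severity + noise (all latents standardized).
#' @param noise_sd SD of the structural noise term.
#' @param driving_emotion which emotion category drives prosociality.
#' @param emission_base,emission_gain log-linear Poisson emission of
#'   emotion terms per post: count ~ Poisson(exp(base + gain * latent)).
#' @param emission_base_prosocial base log-rate for prosocial terms.
#' @param negator_fraction fraction of lexicon-term occurrences that get
#'   a negator inserted immediately before them.
#' @param official_fraction,repost_fraction fractions of posts flagged
#'   official / repost (to exercise ingest filtering; default 0).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_days = 41L,
                       start_date = as.Date("2020-01-20"),
                       posts_per_day = c(800L, 2000L),
                       emotion_vocab_size = 40L,
                       prosocial_vocab_size = 155L,
                       filler_vocab_size = 500L,
                       n_negators = 8L,
                       fillers_per_post = 12,
                       latent_mean = 0, latent_sd = 1,
                       severity_peak_day = 15L,
                       severity_peak_height = 4000,
                       severity_shape = 0.6,
                       severity_floor = 77L,
                       severity_noise = TRUE,
                       b0 = 0, b1 = 0.3, b2 = 0.3, b3 = 0.4,
                       noise_sd = 0.3,
                       driving_emotion = "anger",
                       emission_base = log(0.25),
                       emission_gain = 0.5,
                       emission_base_prosocial = log(0.6),
                       negator_fraction = 0.05,
                       official_fraction = 0,
                       repost_fraction = 0) {
  stopifnot(n_days >= 5, length(posts_per_day) == 2,
            posts_per_day[1] >= 1, posts_per_day[2] >= posts_per_day[1],
            driving_emotion %in% EMOTION_CATEGORIES,
            negator_fraction >= 0, negator_fraction <= 1)
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate synthetic emotion and prosocial lexicons plus negators
#'
#' Terms are collision-free synthetic strings (category-prefixed), with
#' weights drawn uniformly in \[1, 9\]; category vocabularies are
#' disjoint by construction, and the negator tokens are disjoint from
#' every lexicon.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; generation is fully deterministic in
#'   (config, seed).
#' @return list with elements \code{emotion} (lexicon), \code{prosocial}
#'   (lexicon), \code{negators} (character vector), \code{fillers}
#'   (character vector of neutral filler tokens).
#' @export
generate_lexicons <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "lexicons"))
  mk <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  terms <- list()
  for (cat in EMOTION_CATEGORIES) {
    terms[[cat]] <- mk(substr(cat, 1, 3), config$emotion_vocab_size)
  }
  emo <- lexicon(
    unlist(terms, use.names = FALSE),
    rep(EMOTION_CATEGORIES, each = config$emotion_vocab_size),
    runif(length(EMOTION_CATEGORIES) * config$emotion_vocab_size, 1, 9),
    kind = "emotion")
  pro <- lexicon(mk("pro", config$prosocial_vocab_size), "prosocial",
                 runif(config$prosocial_vocab_size, 1, 9),
                 kind = "prosocial")
  list(emotion = emo, prosocial = pro,
       negators = mk("ng", config$n_negators),
       fillers = mk("zfil", config$filler_vocab_size))
}

#' Generate a daily severity series
#'
#' A log-normal-shaped pulse peaking at the configured day, riding on a
#' case-count floor, with optional Poisson noise. The floor guarantees
#' the configured minimum.
#'
#' @inheritParams generate_lexicons
#' @return tibble \code{date}, \code{new_cases}.
#' @export
generate_severity <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "severity"))
  d <- seq_len(config$n_days)
  pulse <- exp(-(log(d / config$severity_peak_day))^2 /
                 (2 * config$severity_shape^2))
  base <- config$severity_peak_height * pulse
  cases <- if (config$severity_noise) {
    config$severity_floor + rpois(config$n_days, base)
  } else {
    config$severity_floor + round(base)
  }
  tibble::tibble(
    date = config$start_date + d - 1L,
    new_cases = as.integer(cases)
  )
}

#' Generate a synthetic post stream with known ground truth
#'
#' Per day, latent emotion intensities are drawn per category and
#' standardized across days; the latent prosocial intensity follows the
#' planted structural model b0 + b1 e + b2 s + b3 e s + noise (e the
#' driving emotion, s standardized severity). Each post mixes neutral
#' filler tokens with emotion and prosocial terms emitted
#' Poisson(exp(base + gain * latent)); a configurable fraction of
#' lexicon-term occurrences gets a negator inserted immediately before
#' it. Negator insertion consumes an RNG stream separate from content
#' generation, so runs that differ only in \code{negator_fraction} emit
#' identical term sequences.
#'
#' @inheritParams generate_lexicons
#' @param lexicons output of [generate_lexicons()].
#' @param severity tibble from [generate_severity()]; its dates must be
#'   exactly the configured window.
#' @return list with \code{posts} (tibble of raw posts) and \code{truth}
#'   (tibble per day: standardized latents, severity; coefficients and
#'   noise SD in attribute \code{"coefficients"}).
#' @export
generate_posts <- function(config, lexicons, severity, seed) {
  stopifnot(inherits(config, "sim_config"))
  days <- config$start_date + seq_len(config$n_days) - 1L
  if (!identical(as.character(sort(as.Date(severity$date))),
                 as.character(days))) {
    stop_named("severity dates do not match the configured %d-day window",
               config$n_days)
  }
  sev <- severity$new_cases[order(as.Date(severity$date))]

  set.seed(derive_seed(seed, "latents"))
  e_raw <- matrix(rnorm(config$n_days * length(EMOTION_CATEGORIES),
                        config$latent_mean, config$latent_sd),
                  nrow = config$n_days,
                  dimnames = list(NULL, EMOTION_CATEGORIES))
  e_std <- scale(e_raw)[, , drop = FALSE]
  s_std <- as.numeric(scale(sev))
  e_drive <- e_std[, config$driving_emotion]
  p_lat <- config$b0 + config$b1 * e_drive + config$b2 * s_std +
    config$b3 * e_drive * s_std +
    rnorm(config$n_days, 0, config$noise_sd)

  set.seed(derive_seed(seed, "content"))
  n_posts_day <- sample(posts_range(config), config$n_days, replace = TRUE)
  emo_terms <- split(lexicons$emotion$term, lexicons$emotion$category)
  pro_terms <- lexicons$prosocial$term

  day_posts <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    np <- n_posts_day[d]
    rates <- exp(config$emission_base + config$emission_gain * e_std[d, ])
    rate_pro <- exp(config$emission_base_prosocial +
                      config$emission_gain * p_lat[d])
    counts <- vapply(EMOTION_CATEGORIES,
                     function(cat) rpois(np, rates[[cat]]),
                     integer(np))
    counts <- matrix(counts, nrow = np,
                     dimnames = list(NULL, EMOTION_CATEGORIES))
    count_pro <- rpois(np, rate_pro)
    n_fill <- 1L + rpois(np, config$fillers_per_post)
    texts <- character(np)
    units <- vector("list", np)
    for (i in seq_len(np)) {
      toks <- c(sample(lexicons$fillers, n_fill[i], replace = TRUE),
                unlist(lapply(EMOTION_CATEGORIES, function(cat) {
                  if (counts[i, cat] > 0)
                    sample(emo_terms[[cat]], counts[i, cat], replace = TRUE)
                  else character(0)
                }), use.names = FALSE),
                if (count_pro[i] > 0)
                  sample(pro_terms, count_pro[i], replace = TRUE)
                else character(0))
      units[[i]] <- sample(toks)  # shuffle token order
    }
    day_posts[[d]] <- list(units = units, date = days[d])
  }

  # negator insertion on a dedicated stream: content above is unaffected
  set.seed(derive_seed(seed, "negators"))
  lex_terms <- c(unlist(emo_terms, use.names = FALSE), pro_terms)
  for (d in seq_len(config$n_days)) {
    day_posts[[d]]$units <- lapply(day_posts[[d]]$units, function(toks) {
      is_lex <- toks %in% lex_terms
      if (!any(is_lex) || config$negator_fraction == 0) return(toks)
      neg <- is_lex & runif(length(toks)) < config$negator_fraction
      if (!any(neg)) return(toks)
      out <- vector("list", length(toks))
      ng <- sample(lexicons$negators, sum(neg), replace = TRUE)
      j <- 0L
      for (k in seq_along(toks)) {
        if (neg[k]) { j <- j + 1L; out[[k]] <- c(ng[j], toks[k]) }
        else out[[k]] <- toks[k]
      }
      unlist(out)
    })
  }

  set.seed(derive_seed(seed, "metadata"))
  total <- sum(n_posts_day)
  texts <- unlist(lapply(day_posts, function(dp) {
    vapply(dp$units, paste, "", collapse = " ")
  }), use.names = FALSE)
  posts <- tibble::tibble(
    post_id = sprintf("p%07d", seq_len(total)),
    user_id = sprintf("user%05d", sample.int(max(2L, total %/% 2L),
                                             total, replace = TRUE)),
    date = rep(days, n_posts_day),
    text = texts,
    is_official = runif(total) < config$official_fraction,
    is_repost = FALSE,
    repost_comment = NA_character_
  )
  if (config$repost_fraction > 0) {
    rp <- runif(total) < config$repost_fraction
    posts$is_repost <- rp
    posts$repost_comment[rp] <- posts$text[rp]
    posts$text[rp] <- "reposted body not attributable to the user"
  }

  truth <- tibble::tibble(date = days)
  for (cat in EMOTION_CATEGORIES) truth[[cat]] <- as.numeric(e_std[, cat])
  truth$prosocial_latent <- p_lat
  truth$new_cases <- sev
  truth$severity_z <- s_std
  attr(truth, "coefficients") <- c(b0 = config$b0, b1 = config$b1,
                                   b2 = config$b2, b3 = config$b3,
                                   noise_sd = config$noise_sd)
  list(posts = posts, truth = truth)
}

posts_range <- function(config) {
  seq.int(config$posts_per_day[1], config$posts_per_day[2])
}

#' Simulate a day-level panel with known standardized effects
#'
#' Regression-level generator used for parameter-recovery and coverage
#' studies: x and m are independent standard normals,
#' y = b1 x + b2 m + b3 x m + noise, with the noise SD chosen (by
#' default) so that y has unit population variance — the planted
#' coefficients then live on the standardized scale that
#' [fit_moderation()] estimates.
#'
#' @param n_days panel length (default 41).
#' @param b1,b2,b3 planted standardized effects.
#' @param noise_sd structural noise SD; \code{NULL} (default) solves
#'   sqrt(1 - b1^2 - b2^2 - b3^2) for unit outcome variance.
#' @param seed integer seed.
#' @return tibble \code{y}, \code{x}, \code{m}.
#' @export
simulate_panel <- function(n_days = 41L, b1 = 0.3, b2 = 0.3, b3 = 0.4,
                           noise_sd = NULL, seed = 1L) {
  if (is.null(noise_sd)) {
    v <- 1 - b1^2 - b2^2 - b3^2
    if (v <= 0) stop_named("planted effects leave no room for unit variance")
    noise_sd <- sqrt(v)
  }
  set.seed(as.integer(seed))
  x <- rnorm(n_days); m <- rnorm(n_days)
  tibble::tibble(y = b1 * x + b2 * m + b3 * x * m + rnorm(n_days, 0, noise_sd),
                 x = x, m = m)
}
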