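---
title: "Lexicon-weighted affect scoring and severity-moderated regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexicon-weighted affect scoring and severity-moderated regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`affectpanel` turns a stream of short social-media posts into a daily
panel of emotion and prosociality scores and asks whether an external
stressor — here, epidemic severity measured as daily newly confirmed
cases — moderates the day-level relationship between each emotion and
prosocial tendency. This vignette is the package's own account of the
models and the design decisions behind them.

## 1. The scoring model

Scoring is a weighted bag-of-words ("dictionary presence") model. A
post's text is segmented into tokens; every token that appears in a
lexicon contributes its weight \(w \in [1, 9]\) to that lexicon entry's
category, and per-category contributions are summed:

\[
s_c(\text{post}) \;=\; \sum_{i \,:\, t_i \in L_c} \sigma_i \, w(t_i),
\qquad
\sigma_i = \begin{cases} -1 & \text{a negator precedes } t_i \\ +1 & \text{otherwise.} \end{cases}
\]

Assumptions worth making explicit:

* **Bag of words.** Syntax, sarcasm and long-range context are ignored;
  the model is a population-scale signal extractor, not a per-post
  classifier.
* **Negation as local sign reversal.** The negation scope is a
  preceding-token window (default size 1: only the immediately
  preceding token). Reversal is a *flag*: two negators inside the
  window flip the sign once, not twice. We chose the minimal adjacency
  reading because anything wider requires syntactic commitments a
  segmented bag-of-words model cannot honor. The window is
  configurable (`window` argument throughout).
* **No length normalization.** Post scores are raw weighted sums, then
  averaged per day with each post weighted equally. Whether to divide
  by token count is a judgment call; we default to raw sums and expose
  no hidden rescaling — if you need rate-like scores, divide before
  aggregation.
* **Multi-category terms.** A term listed under two emotion categories
  contributes to both; categories are not competing labels.

The built-in tokenizer is a greedy longest-match over the combined
vocabulary (all lexicon terms plus negators) with single-character
fallback, implemented with a prefix trie. Its contract — any
vocabulary term occurring contiguously in the text surfaces as exactly
one token — is the only property scoring relies on, so a proper Chinese
segmenter can be substituted through the `tokenizer` argument without
touching anything downstream.

## 2. Building a weighted prosocial lexicon

`build_prosocial_lexicon()` composes three steps over a complete
term × rater table of 9-point ratings:

1. `aggregate_ratings()`: per-term mean and **sample (n − 1) SD**.
   Raters are a sample of possible judges, so the sample denominator is
   the defensible default.
2. `filter_candidates()`: delete terms with mean **strictly below** 6
   (insufficiently prosocial) or SD **strictly above** 2 (inconsistent
   raters). The deletion conditions are strict inequalities, so
   boundary values (mean exactly 6, SD exactly 2) are retained.
3. `minmax_normalize()`: affine rescaling of the retained means onto
   [1, 9]. Applied after filtering, so the endpoint weights 1 and 9 are
   attained by the retained extremes. If all means coincide the map is
   undefined; we raise an error rather than guessing, with an explicit
   `degenerate_to_mid` escape hatch.

Inter-rater reliability is reported by `interrater_reliability()`. The
default statistic is ICC(2,k) — two-way random effects, average
measures — computed from the two-way mean squares; mean pairwise
Pearson *r* is available as a simpler alternative. Published analyses
of this kind often report a reliability number without naming the
statistic, so the package offers both and never assumes one.

## 3. The daily panel and the moderation model

`aggregate_daily()` produces one row per calendar day: per-category
means, the post count, and the joined severity value. A day with no
posts or no severity value is an error naming the date — silent gap
interpolation would corrupt the regression n.

For each emotion, `fit_moderation()` estimates

\[ Y = B_0 + B_1 X + B_2 M + B_3 XM + \varepsilon \]

with \(Y\) the daily prosocial mean, \(X\) the emotion, \(M\) severity.
Numerical choices:

* **Standardization.** \(X\), \(M\), \(Y\) are z-scored with the sample
  SD; the product term is the product of the standardized factors and
  is *not* re-standardized (the Aiken–West convention). Source moments
  are retained for mapping raw moderator levels back onto the z scale.
* **Inference.** Analytic SEs, t and p on df = n − 4 accompany a
  nonparametric case-resampling percentile bootstrap (default 5000
  resamples, seed mandatory, bit-for-bit reproducible). The bootstrap
  resamples the already-standardized rows jointly rather than
  re-standardizing inside each replicate: this keeps the product term
  consistent with the convention above and makes replicates cheap. On
  large Gaussian panels the two interval constructions agree (checked
  in the test suite at n = 2000 within 5% relative difference).
* **Simple slopes.** The conditional effect at moderator level z is
  \(B_1 + B_3 z\), with SE from the coefficient covariance,
  \(\sqrt{\operatorname{Var} B_1 + z^2 \operatorname{Var} B_3 + 2z \operatorname{Cov}(B_1, B_3)}\),
  and t on the model residual df (n − 4). The high level is M + 1SD
  (z = +1). The low level is M − 1SD **unless that falls below the
  observed minimum** of the raw moderator, in which case the minimum is
  substituted (`low_level_rule()`): for a right-skewed case-count
  series M − 1SD can be negative and meaningless. The rule is applied
  uniformly to every model.
* **Independent fits, no multiplicity correction.** Each emotion is
  fitted in its own model; the package reports six uncorrected p
  values because the analysis design treats each emotion as a separate
  question. Users wanting familywise control can apply `p.adjust` to
  the reported p values.
* **Degenerate inputs.** Zero-variance series and rank-deficient
  designs (e.g. moderator equal to predictor) are errors, not warnings.

`replay_slopes()` is the desk-scale counterpart: given only *printed*
standardized coefficients (B1, B3 per model) and the moderator's
published mean, SD and minimum, it reconstructs every high/low
conditional slope. The package bundles, as plain-text inputs under
`inst/extdata/`, the six-model coefficient table and severity moments
reported by a published 41-day Weibo analysis of emotion, prosocial
tendency and COVID-19 severity; the test suite checks the
reconstruction of all six published slopes to ±0.02, which is the
precision available from coefficients printed to two decimals.

## 4. The synthetic-data generator

Because a crawled microblog corpus cannot be redistributed, the
package's evidence comes from `sim_config()` / `generate_lexicons()` /
`generate_severity()` / `generate_posts()`, which emulate the study
design the package targets:

* **Scale.** 41 days starting 2020-01-20; per-day post counts drawn
  uniformly from 800–2000 by default (hundreds to thousands — large
  enough for stable daily means, small enough to generate quickly);
  155 prosocial terms; severity floored at 77 daily cases with a
  log-normal-shaped pulse (peak day 15, peak height 4000, shape 0.6 —
  a plausible single-wave outbreak profile) plus Poisson noise.
* **Structure.** Per day, latent emotion intensities are standard
  normal across days; the latent prosocial intensity follows the
  planted structural model
  \(p_d = b_0 + b_1 e_d + b_2 s_d + b_3 e_d s_d + \varepsilon_d\)
  (defaults \(b_1 = b_2 = 0.3\), \(b_3 = 0.4\), noise SD 0.3), with
  \(e\) the driving emotion (anger by default) and \(s\) standardized
  severity. Posts emit category terms as
  \(\text{Poisson}(\exp(a + g \cdot \text{latent}))\) — a log-linear
  link chosen for positivity and simple moment calculations (emission
  base rates 0.25 emotion / 0.6 prosocial terms per post, gain 0.5,
  calibrated once to give daily mean scores of realistic magnitude).
  Negators are inserted immediately before a configurable fraction
  (default 5%) of lexicon-term occurrences, on an RNG stream separate
  from content generation so corpora differing only in negation are
  token-for-token comparable.
* **Determinism.** Every generation call derives stage-specific child
  seeds from one master seed; identical (config, seed) yields
  byte-identical post files.

What the generator deliberately does **not** emulate: real Chinese
orthography (the synthetic language is whitespace-separable, so the
built-in tokenizer is exact on it and segmentation fidelity is
decoupled from statistical testing); user-level structure and repeated
posting habits; temporal autocorrelation beyond the severity curve;
topic drift. Passing tests therefore certify the *pipeline arithmetic
and inference machinery*, not the adequacy of any particular Chinese
segmenter or lexicon on real text.

Because the emission link is nonlinear, the regression coefficient on
the *scored* panel is not numerically equal to the planted latent
\(b_3\); end-to-end tests assert sign recovery and detection power
(power > 0.8 at |b₃| = 0.5, n = 41), while exact coefficient recovery
is tested at the regression level with `simulate_panel()`, which plants
effects directly on the standardized scale (noise SD solved so the
outcome has unit variance).

## 5. Problem sizes used by the test suite

The suite favors many small deterministic checks over few large ones:
the scoring oracle runs 1200 random token sequences against an
independent exhaustive-enumeration scorer; parameter recovery uses 500
simulated 41-day panels (analytic inference only) to bound coefficient
bias at 0.02 and check 95% CI coverage of the interaction within
[0.90, 0.98]; bootstrap/analytic convergence uses one n = 2000 panel
with 2000 resamples; end-to-end corpus tests use 60–300 posts per day.
These sizes are the package's choices for a fast, fully reproducible
suite; all of them can be scaled up through the same interfaces.

## 6. Known limitations

* Negation handling is purely local; scope-bearing constructions
  ("not only … but") are mis-signed.
* The overlap statistic for lexicon validation is term-set containment
  after canonicalization; it does not attempt translation or synonym
  matching.
* The 41-row panel is treated as independent observations, as in the
  analysis design it reproduces; day-to-day autocorrelation is not
  modeled and the reported SEs inherit that assumption.
* `low_level_rule()` encodes one specific pick-a-point convention;
  Johnson–Neyman regions are out of scope.
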