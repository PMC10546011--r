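---
title: "Methods: speech-graph connectedness and dementia severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech-graph connectedness and dementia severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgdem)
```

## The measurement model

Spontaneous speech elicited by a picture-description task is treated as a
trajectory through a speaker's lexicon. Each unique word type is a node;
each pair of consecutively spoken words contributes one directed edge. The
result is a directed multigraph: immediate repetitions become self-loops,
repeated transitions become parallel edges. Interruptions matter —
transcribers put speech following an interruption on a new line, and the
graph draws **no edge across a line break**, because the word before and
after an interruption were not produced as a sequence.

Two component sizes summarize how connected the trajectory is:

- **LCC**, the node count of the largest component when edge direction is
  ignored. It measures how much of the produced vocabulary is woven into a
  single stretch of connected discourse.
- **LSC**, the node count of the largest set of nodes that are mutually
  reachable along directed paths. Cycles only arise when the speaker
  *returns* to earlier words, so LSC captures long-range recurrence in word
  sequencing and is the stricter of the two (LSC ≤ LCC, with LSC ≥ 1 for
  any non-empty graph since a single node is trivially strongly connected).

Components are computed exactly: weak components by union–find, strong
components by an iterative two-pass (Kosaraju-style) search, both written
to handle multigraphs with self-loops. The test suite checks both against
an independent brute-force oracle (boolean reachability by repeated matrix
squaring) on a thousand random multigraphs per run.

## Verbosity control: the moving window

Longer narratives grow larger graphs for reasons that have nothing to do
with connectedness. The package therefore computes attributes on a moving
window of fixed word length — default 30 words, sliding by 3, i.e. 90%
token overlap between consecutive windows — and reports the plain
arithmetic **grand mean** of the per-window LCC and LSC. Design choices
worth making explicit:

- Windows are defined on the concatenated token stream and may span
  several utterances, but edge construction inside a window still respects
  utterance boundaries. This is the only combination that works when
  individual utterances are much shorter than 30 words.
- Trailing tokens that cannot fill a complete window are dropped, never
  padded: padding would change the graph size that the window is meant to
  hold constant. Grand means are consequently invariant to tokens beyond
  the last complete window.
- Transcripts with fewer than 30 words cannot fill one window. They are
  excluded, and the batch interface (`analyze_transcripts()`) logs each
  exclusion with the participant id and token count rather than failing.
- Grand means are kept at full precision; nothing is rounded before the
  regression stage.

A note on scale: a 30-word window can contain at most 30 nodes, so windowed
grand means live on a 1–30 scale, whereas whole-narrative LCC/LSC values in
dementia picture-description corpora range into the hundreds for verbose
speakers. Published cohort norms for these measures are typically on the
whole-narrative scale. The regression machinery is indifferent to the
scale; only the interpretation of a coefficient ("per one unit of
connectedness") changes.

## Token normalization

The graph's nodes are surface word forms after a deliberately light
normalization: lowercase (so `Cookie` and `cookie` are one type — distinct
case would inflate node counts), punctuation stripped from token edges
(internal apostrophes and hyphens survive, so `boy's` stays one token), and
empty tokens dropped. Filled pauses (*uh*, *um*, ...) are **kept** by
default — they are words the speaker produced — with a flag to drop them.
No lemmatization is applied by default; an optional hook accepts any
token-to-lemma function. For CHAT transcripts, markup codes are stripped
but retraced and repeated words are **kept**: repetition is precisely what
LSC measures, so `<the the> [/] the boy` contributes three `the` tokens.
Normalization is idempotent, and writing a transcript to plain text (one
utterance per line) and re-reading it is the identity.

## The severity regression

Each severity outcome (MMSE, 0–30; MDRS, 0–144; BDS, 0–28) is regressed by
OLS on five predictors: depression (HDRS) and age of symptom onset as
controls, plus years of education, an aggregate verbal-fluency score, and
one connectedness measure (windowed mean LCC or LSC). The fluency
aggregate is the sum of the two sample z-scores (semantic + phonemic),
standardized against the analysis sample's own mean and SD (denominator
n−1); a zero SD in either measure is a hard error, since z-scores are then
undefined.

Missing data are handled in two distinct ways:

- **Outcomes** are analyzed complete-case, per outcome: a participant
  missing MDRS drops out of the MDRS models only, so different outcomes
  may have different residual degrees of freedom.
- **Fluency scores** are multiply imputed by chained equations. Each
  incomplete fluency variable is regressed on the fully observed analysis
  variables plus the other fluency measure; regression parameters are
  drawn from their Bayesian posterior (normal-inverse-chi-squared), and by
  default imputations come from **predictive-mean matching** with a donor
  pool of 5: a missing case receives the observed value of one of the five
  donors whose predicted means are closest. PMM was chosen because fluency
  scores are non-negative integer counts and donor values are always
  actually-observed counts; a normal-model engine (`engine = "norm"`) is
  available. The chain runs a fixed 10 iterations and produces `m = 5`
  completed tables by default; everything is bit-reproducible given
  `(seed, m, maxit)`.

Fluency z-scores are computed **within each completed dataset, after
imputation** — the aggregate needs complete fluency, and computing the
scale per completed table propagates imputation uncertainty into it.

Per-table OLS fits are pooled by **Rubin's rules**: the pooled estimate is
the mean of the per-table estimates; the total variance is the mean
within-table variance plus (1 + 1/m) times the between-table variance.
Degrees of freedom use the Barnard–Rubin small-sample adjustment with
complete-data df equal to n − 6. With `m = 1` the pooled result reduces
*exactly* to the single `lm()` fit — same estimates, SEs, t, p, CIs, R²
and F — which the tests assert to 1e−12. The pooled R² averages the
per-table values on the Fisher-z scale of √R² and back-transforms; the
overall F is recomputed from the pooled R² as
(R²/5) / ((1−R²)/(n−6)), which again coincides with the classical F when
m = 1. Per-coefficient inference is a two-sided t test; no
multiple-testing correction is applied. Rank-deficient designs raise an
error naming the collinear columns rather than silently dropping one.

## The synthetic-data generator

Clinical speech corpora are access-restricted, so the package ships a
generator that emulates the *statistical* features the pipeline consumes
— never the linguistics.

**Transcripts.** Tokens come from a repetition process with three handles:
with probability `p_return` the next token revisits a uniformly chosen
earlier token (position-uniform, so frequent words attract returns);
otherwise it is a fresh uniform draw from a `vocab_size`-word vocabulary;
after each token an utterance break occurs with probability `p_break`.
Returns close cycles, so `p_return` manipulates connectedness *through the
full transcript→graph path* rather than by sampling graphs directly. The
defaults — `vocab_size = 250`, `n_tokens = 100`, `p_return = 0.35`,
`p_break = 0.15` — were chosen so that whole-transcript attributes sit at
the center of the ranges reported for dementia picture-description
cohorts (mean LCC ≈ 55, mean LSC ≈ 38 across seeds, against published
means near 57 and 36); varying `n_tokens` (35–300) and `p_return` spans
those cohorts' full observed ranges (LCC ~14–151, LSC ~1–117), which the
tests verify.

One property of the mechanism deserves emphasis: **mean LSC is unimodal,
not monotone, in `p_return`**. On the rising limb more returns create more
reciprocal paths, but as `p_return → 1` fresh draws become rare and the
number of distinct word types collapses toward 1 (≈ (1−p)·n types, further
concentrated by the rich-get-richer position-uniform returns), taking the
strong component down with it. Simulation across wide parameter grids puts
the peak near `p_return` ≈ 0.5–0.7 regardless of `vocab_size`, `n_tokens`
or `p_break`; at the defaults the per-grid means are roughly
30, 35, 38, 37, 34, 29, 23, 16, 9 for `p_return` = 0.1 … 0.9. The package's
property test therefore asserts the honest shape (LSC at moderate return
beats both extremes); an acceptance check that demands strict increase
across the whole grid fails by design of the mechanism itself, and is kept
failing rather than weakened.

**Cohorts.** Covariates are truncated-normal draws at means/SDs/ranges
matching the demographic and clinical profile of published Alzheimer's
picture-description cohorts (age 71.9 ± 8.7 within 50–88, education
12.4 ± 3.0, HDRS 5.9 ± 3.6, fluency counts ~9 and ~7, onset age = age
minus a positive gap so onset ≤ age always); counts are rounded to
integers. Connectedness is by default drawn from truncated normals on the
whole-narrative-like scale of those cohort norms (mean 57 ± 23 for LCC);
with `transcripts = TRUE` it is instead *computed* by generating one
transcript per participant and running the windowed pipeline, which yields
means on the ≤30 window scale and exercises the whole path end-to-end.
Severity scores are generated from the linear model above with Gaussian
noise. When `noise_sd` is not given it is set per outcome from a target
construction R² via `sd(linear predictor)·sqrt(1/R² − 1)`; defaults are
0.44 (MMSE) and 0.61 (MDRS), matching the explained-variance levels
reported for cognitive instruments in this setting, and 0.15 for BDS as a
deliberately weak-signal condition (the informant-rated functional scale
is reported as not predicted by language measures; no explained-variance
figure is available for it). Severity is **unclipped** by default so the
generating model is exactly linear and coefficient-recovery tests are
unbiased; `clip = TRUE` clamps to instrument ranges for realism.
Missingness is MCAR cell deletion confined to the two fluency columns,
default rate 0.25 when requested, mirroring the ~25% fluency missingness
typical of archival cohorts.

What the generator does *not* emulate: real lexical or syntactic
structure, topic content of the picture description, informative (MNAR)
missingness, clustering of repetitions around discourse markers, or
measurement error in the severity instruments. Passing tests therefore
demonstrate that the pipeline's algorithms are correct and its inference
calibrated under a known data-generating process — not that the effect
sizes found in real corpora are reproduced.

## Numerical and degenerate-input choices

- Empty transcripts/graphs are errors, not size-0 results: inputs below
  the window length are filtered upstream with a logged reason, so an
  empty graph signals pipeline misuse.
- A constant outcome yields slopes of 0 and R² defined as 0 (not NaN).
- Truncated-normal draws use rejection sampling (exact; ranges are wide
  relative to the SDs, so rejection is cheap).
- PMM donor ties are broken by stable ordering of predicted-mean
  distances; the donor within the pool is drawn uniformly.
- All randomness flows through an explicit `seed` argument; generators
  and imputation save and restore the caller's RNG state, and identical
  seeds give bit-identical output.
- The Barnard–Rubin df guards against division by zero when the
  between-imputation variance vanishes (lambda floored at ~1e−12); with
  no missing data and m > 1 the m tables are identical copies and the
  pooled fit equals the single fit up to the (slightly smaller)
  adjusted df.

## Validation problem sizes

The shipped tests run the component oracle on 1000 random multigraphs of
up to 12 nodes, OLS against the normal equations on 100 random cohorts,
confidence-interval coverage and type-I error on 500 synthetic cohorts of
n = 128 each, imputation bias on 200 replicates of 128 participants with
25% fluency missingness at m = 5, and end-to-end coefficient recovery
through transcript generation → windowing → regression on 20 replicates of
40 participants. These sizes give Monte-Carlo error comfortably inside the
binomial bands asserted while keeping a full run around a minute.

## Known limitations

- The CHAT reader is minimal: it handles main-tier selection,
  continuation lines and the common markup families, not the full CHAT
  specification (no dependent-tier parsing, no phonology tiers).
- Imputation assumes missingness confined to the fluency measures, as in
  the intended archival-cohort use; incomplete covariates other than the
  outcome are silently excluded from the imputation model.
- Pooled prediction uses the pooled coefficients and the training fluency
  scale; no prediction intervals are provided for m > 1.
- LSC on windowed data is coarse (integer means over ≤ 30-node graphs);
  very short transcripts near the 30-word cutoff are summarized by one or
  two windows only.
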