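# sgdem — speech-graph connectedness and dementia severity

`sgdem` quantifies how *connected* spontaneous speech is and relates that to
dementia severity. It is aimed at researchers in clinical computational
linguistics and neuropsychology who work with picture-description tasks
(e.g. the Cookie Theft scene): transcripts go in, graph-based connectedness
measures come out, and a covariate-adjusted regression relates them to
severity instruments (MMSE, MDRS, BDS).

## The model

A transcript is mapped to a **word-trajectory graph**: a directed multigraph
*G = (V, E)* with one node per unique word type and one directed edge for
every pair of consecutive words spoken *within* an utterance (speech
following an interruption is transcribed on a new line, and no edge crosses
that boundary). Two attributes summarize connectedness:

- **LCC** — the number of nodes in the largest connected component of the
  undirected version of *G* (lexical diversity of connected discourse);
- **LSC** — the number of nodes in the largest *strongly* connected
  component, i.e. the largest set of words that are mutually reachable
  along directed paths (long-range recurrence in word sequencing). A single
  node is trivially strongly connected, so LSC ≥ 1, and LSC ≤ LCC always.

To control verbosity, attributes are not computed on the whole narrative
but on a moving window of 30 words sliding by 3 (90% overlap between
consecutive windows); the **grand means** over all complete windows are the
participant-level measures. Transcripts with fewer than 30 words cannot
fill a single window and are excluded, with a logged reason.

At the cohort level, each severity score *y* is modelled by ordinary least
squares:

    y = β0 + β1·HDRS + β2·onset age + β3·education + β4·fluency-z + β5·connectedness + ε

where fluency-z is the sum of the sample z-scores of semantic and phonemic
fluency counts, and connectedness is the windowed mean LCC or LSC. Missing
fluency scores are multiply imputed by chained equations with
predictive-mean matching; estimates are pooled across the *m* completed
datasets by Rubin's rules with Barnard–Rubin degrees of freedom.

## Worked example

Synthetic data stand in for access-restricted clinical corpora: the
generator produces transcripts with a tunable repetition structure and
cohorts whose severity scores follow a known linear model.

```r
library(sgdem)

tr <- generate_transcript(n_tokens = 120, seed = 7, participant_id = "demo")
windowed_connectedness(tr)
#> <sg_windowed> participant 'demo': 120 tokens, 31 windows (length 30, step 3)
#>   mean LCC 22.81, mean LSC 9.29

coh <- generate_cohort(n = 128, seed = 7, missing_rate = 0.25)
fit <- fit_severity(coh, outcome = "mmse", measure = "lcc", m = 5, seed = 11)
summary(fit)
#> <severity_fit> MMSE ~ HDRS + onset age + education + fluency-z + LCC
#>   n = 128, m = 5 imputation(s); R^2 = 0.404, F(5, 122) = 16.56
#>                Estimate Std. Error     2.5 %    97.5 %  t value       df  Pr(>|t|)
#> (Intercept)   15.864394   3.316645  9.275621 22.453167   4.7833  90.3241 6.678e-06
#> hdrs           0.006322   0.100606 -0.194900  0.207544   0.0628  60.2938  0.950102
#> onset_age     -0.011856   0.044830 -0.102395  0.078683  -0.2645  40.9408  0.792745
#> education      0.283946   0.103809  0.078304  0.489587   2.7353 114.1710  0.007229
#> fluency        1.560039   0.216232  1.127049  1.993030   7.2147  57.0391 1.391e-09
#> connectedness  0.027349   0.018353 -0.010810  0.065509   1.4902  21.0694  0.150993
#> Overall: F(5, 122) = 16.56, p = 1.86e-12
```

The demo transcript's 31 windows average an LCC of 22.8 of a possible 30
(most word types in each window hang together in one component) and an LSC
of 9.3 (a core of ~9 words recurs in loops). In the regression, education
and fluency carry most of the signal at this noise level; the pooled
connectedness coefficient is positive (more connected speech, higher MMSE),
with its inference widened — note the small Barnard–Rubin df — by the 25%
missingness in the fluency scores it is adjusted against.

Transcripts can also be read from files: `read_plaintext()` (one utterance
per line) and `read_chat()` (CHAT `.cha` main tiers, markup stripped,
repetitions kept).

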