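---
title: "Methods: annotation-scheme analytics for depression-related short texts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-scheme analytics for depression-related short texts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsignal)
```

## The problem

Keyword queries against a social-media stream are the cheapest way to
collect posts that *might* mention depression, but most matches are
figurative ("a new economic depression") or otherwise off-topic. Before a
surveillance system can be trained, one needs a manually annotated corpus,
and before trusting that corpus one needs to quantify four things: how
reliably humans apply the label scheme (agreement), how often each query
keyword actually retrieves a relevant post (keyword precision), what the
corpus contains (category frequencies, co-occurrence structure), and which
words the annotated categories make discriminative (feature selection).
`depsignal` implements that full analysis pipeline over a fixed annotation
scheme, and — because real tweet corpora cannot be redistributed — ships a
seeded synthetic-corpus generator whose ground truth is planted and
therefore recoverable, so every stage of the pipeline is testable end to
end.

## The annotation scheme

`sad_scheme()` defines 22 categories in a fixed order: 9 depressive-symptom
parents (DSM-5: depressed mood, anhedonia, weight or appetite change,
disturbed sleep, psychomotor agitation or retardation, fatigue,
worthlessness or guilt, diminished concentration, recurrent thoughts of
death), 12 psychosocial-stressor parents (DSM-IV Axis IV: problems with the
expected life course, primary support group, social environment, education,
occupation, housing, economy, health-care access, the legal system, other
psychosocial problems, plus the corpus-driven categories weather and
media), and one *no evidence of clinical depression* label. A tweet may
carry several evidence categories; `no_evidence` is mutually exclusive with
all others for a given annotator. The scheme order indexes the correlation
matrix and heatmap axes.

## The keyword lexicon and matching semantics

The packaged lexicon (110 rows, 109 distinct patterns — `neglect*` appears
in two blocks) is the LIWC "sad" keyword list augmented with
clinician-selected keywords, each row tagged with the scheme category it
suggests or with the `liwc_sad` block label. A trailing `*` is a prefix
wildcard; everything else is a literal token.

Two deliberate choices:

* **Whole-token matching.** `lose` does not match `loses`, because
  inflections are enumerated as separate patterns; a wildcard matches any
  token beginning with its stem. Creative spellings and missing spaces
  ("sodepressed") are therefore *not* matched — a documented limitation of
  token-level semantics.
* **`divorc` is kept verbatim.** The source list prints it without a star;
  under whole-token semantics it matches almost nothing. We do not silently
  correct the source; `load_lexicon(assume_divorc_wildcard = TRUE)` opts
  into treating it as `divorc*`.

## Inter-annotator agreement

Two annotators are compared on the tweets both annotated, as sets of
(tweet, category) assertions. With `m` matches and `mm` assertions made by
only one side,

$$F = \frac{2m}{2m + mm} \times 100\%$$

— the harmonic-mean F1 of one annotator against the other, with no chance
correction. The *overall* score is micro-averaged: counts are pooled over
all 22 categories (including `no_evidence`, which participates as an
ordinary category) and the formula applied once. A category asserted by
neither annotator is *not observed* and rendered as an em dash.
`adjudicate()` produces gold labels: agreed tweets pass through,
disagreements resolve to the third annotator (three-way splits also
resolve to the adjudicator but are flagged as unresolved-majority events).

## Keyword precision

For each pattern, `tweet_hits` counts distinct matched tweets and a hit is
*relevant* when the tweet's gold labels include any evidence category.
Precision is binned into five equal ranges. The printed convention
(0–19%, 20–39%, …) is realized as half-open real intervals at
20/40/60/80 with the last bin closed at 100, so fractional precisions are
classifiable while integer percentages land in their printed bin. The hit
distribution aggregates *nonmutually exclusive* hits: a tweet matched by k
distinct keywords contributes k to the denominator, but a keyword matching
one tweet at several positions contributes once.

## Frequency and co-occurrence

Category shares are computed over gold annotation instances; the
multi-label distribution over tweets. Pairwise co-occurrence over the 21
evidence categories uses the phi coefficient — the Pearson product-moment
correlation of two binary indicators, computed from the 2×2 table as
$(n_{11}n_{00}-n_{10}n_{01})/\sqrt{n_{1\cdot}n_{0\cdot}n_{\cdot 1}n_{\cdot 0}}$ —
with `NA` when either margin is constant. Magnitudes are classified with
Cohen effect-size bins. The printed convention ("<0.09", "0.1–0.29",
"0.3–0.49", ">0.50") leaves (0.09, 0.1) uncovered; we close the gap at 0.1
and use half-open intervals, so the four bins partition [0, 1]. Negative
correlations are reported with sign but binned by magnitude. Two-sided
p-values from the t transform of r are computed for completeness but never
used for binning: p is driven by sample size, r is not.

## Information-gain word ranking

Words are scored per category by the mutual information (bits) between
binary word presence and the one-vs-rest category indicator,
$IG = H(C) - \sum_v P(W{=}v)\,H(C \mid W{=}v)$, with $0\log 0 \equiv 0$.
Presence, not counts, is the feature — on 15-token texts counts add almost
no information. The corpus is split into 5 near-equal random subsets; the
assignment is seeded and keyed to the *sorted* tweet ids, so permuting
record order cannot change results. Within each subset every vocabulary
word is ranked by descending IG with lexicographic tie-breaks; a word
absent from a subset's vocabulary is assigned rank (vocabulary size + 1).
Words are reported by ascending mean rank. Categories with fewer than
`min_mentions` (default 3) positive tweets are skipped rather than ranked
from noise. Stopwords are deliberately retained: first-person pronouns are
known signal in this domain. The tokenizer lowercases, splits on
whitespace, strips edge punctuation (emoji survive), maps URLs and
@-mentions to placeholders, and keeps `#` on hashtags.

## The synthetic generator

`generator_config()` fixes the study conditions; `generate_corpus()` is
fully determined by the seed.

**Labels.** Each phi-target pair of categories is drawn jointly from the
2×2 cell probabilities implied by the target
($p_{11} = \rho\sqrt{p_iq_ip_jq_j} + p_ip_j$), so empirical phi converges
to the target; construction fails loudly if a target violates the Fréchet
bound for the two prevalences. All other categories are independent
Bernoulli draws. Pairs must be vertex-disjoint — correlation is planted
only where listed, keeping the joint distribution well-defined without a
21-dimensional copula.

**Text.** Token counts are rounded normal (mean 14.56, SD 7.40, truncated
at 1). Tokens come from three pools that are *disjoint by construction*
(validated at config build): Zipf-weighted background pseudo-words, ten
planted discriminative words per category (each present with probability
0.4 in tweets carrying the category and never elsewhere), and injected
lexicon keywords. Each keyword receives Poisson(`hits_rate` × n) hits,
each allocated to an evidence tweet with the keyword's planted relevance
probability, so its empirical precision is an exact binomial draw around
the planted value.

**Defaults.** Prevalences sum to 0.301 and were chosen to mirror the
headline shape of a keyword-sampled depression corpus: about 72% of gold
annotations are `no_evidence` and evidence annotations split roughly 65:35
between symptoms and stressors. The three default phi targets are the
strongest co-occurrences in this domain — fatigue–disturbed sleep (0.60),
depressed mood–guilt (0.55), educational problems–diminished concentration
(0.60). The prevalences of the six pair categories (1.8–5.3%) were fixed
by an up-front power analysis: the sampling SD of empirical phi at
n = 10,000 must stay near 0.02 for ±0.05 recovery to hold in ≥95% of
seeds, which requires expected joint counts of ~150 per pair. This
inflates `educational_problems` and `diminished_ability_to_think` above
their natural prevalence ordering. It also makes the multi-label share
(~6% of tweets with two categories) higher than the <2% seen in real
keyword-sampled corpora: three strongly correlated pairs at recoverable
prevalences necessarily co-occur that often. We chose recoverability over
the multi-label share; the share can be pushed down by lowering the phi
targets or pair prevalences, at the cost of noisier recovery.

**Annotators.** `corrupt_annotations()` deletes each gold evidence
assertion with rate d and adds a spurious category per tweet with rate a;
a tweet left empty becomes `no_evidence`. With deletion only and the F
score pooled over the 21 evidence categories, the expectation is exactly
$2(1-d)^2/(2(1-d)^2 + 2d(1-d)) = 1-d$ per pair — the closed form used in
the recovery tests. Note that the *overall* micro-F (including
`no_evidence`) is higher, because two simultaneous deletions agree on
`no_evidence`; with the default rates it sits near 90%, above the 76–81%
seen in real campaigns, since independent flips are a simpler error
process than structured human disagreement.

**What the generator does not emulate.** Linguistically realistic text
(pseudo-word vocabulary of ~1500 types vs ~20,000 in a real corpus);
corpora in which *every* tweet contains a query keyword; human
disagreement that concentrates on genuinely ambiguous tweets; temporal
structure. Passing recovery tests therefore demonstrates the estimators
are correct and well-calibrated, not that they will behave identically on
real language.

## Test design and numerical choices

* Oracle tests compare `f_score` against an independent set-based F1 and
  `phi_coefficient` against `stats::cor` on randomized fixtures (absolute
  tolerance 1e-12); information gain is checked against brute-force 2×2
  mutual information.
* The keyword-precision recovery test asserts that every planted relevance
  lies in a *family-wise* 99% Clopper-Pearson interval (per-keyword level
  1 − 0.01/109). Requiring 109 individual 99% intervals to hold
  simultaneously would fail roughly 40% of seeds by multiplicity alone —
  about 0.5 keywords per run are expected outside their own interval even
  with a perfectly calibrated generator.
* Recovery runs use n = 10,000 tweets for phi/precision/top-words, 5,000
  for agreement noise, and 400–500 for pipeline determinism; the full
  suite completes in well under a minute on one CPU.
* Degenerate inputs resolve to explicit sentinels rather than numbers:
  not-observed categories give `NA` F scores and phi values (rendered as
  em dashes), under-mentioned categories give a skipped top-words result,
  and empty comparison sets are errors, never zeros.

## A worked run

```{r, eval = FALSE}
demo <- demo_generate_and_analyze(seed = 1)
#> <recovery_summary>
#>   planted vs estimated phi:
#>     fatigue_or_loss_of_energy ~ disturbed_sleep: planted 0.60, estimated 0.611
#>     depressed_mood ~ worthlessness_or_guilt: planted 0.55, estimated 0.563
#>     educational_problems ~ diminished_ability_to_think: planted 0.60, estimated 0.618
#>   keyword precision MAE vs planted relevance: 0.033
#>   planted words recovered in top-10 lists: 77.6%
#>   no-evidence annotation share: 71.95%
```

The planted-word figure averages over *all* categories ranked (recovery is
near-perfect for categories with prevalence above ~1.5% and poor for
rare categories, whose handful of mentions cannot support a stable
ranking — exactly the behaviour the `min_mentions` guard and the skipped
sentinel are there for).

## Known limitations

Recall of the keyword lexicon is not estimable (it would require gold
labels for unmatched tweets, which a keyword-sampled corpus does not
contain). Chance-corrected agreement coefficients (kappa, alpha) are out
of scope by design — the F score is the field's convention for sparse
multi-label span annotation. No multiple-testing correction is applied
across the 210 category pairs, mirroring standard practice of
interpreting r magnitudes rather than p-values.
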