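# depsignal

Analytics for manually annotated corpora of depression-related short
social-media posts, built around a 22-category annotation scheme: 9 DSM-5
depressive-symptom parent categories, 12 DSM-IV Axis IV
psychosocial-stressor parent categories, and a *no evidence of clinical
depression* label. The package is for researchers building or auditing
keyword-collected mental-health corpora: it quantifies how reliably
annotators apply the scheme, how well each query keyword retrieves
relevant posts, and what structure the finished gold annotations contain.

What it computes:

* **Keyword lexicon and matching** — a packaged 110-entry LIWC-derived
  depression keyword list with prefix-wildcard semantics (`jitter*`
  matches `jittery`; literal `lose` matches only `lose`), and a matcher
  reporting every (tweet, keyword, token) hit.
* **Inter-annotator agreement** — pairwise F score over (tweet, category)
  assertions, `F = 2m / (2m + mm) × 100%`, per category and micro-averaged
  overall, with third-annotator adjudication to gold labels.
* **Keyword precision** — per keyword, the share of matched tweets whose
  gold labels include any evidence category, classified into five bins
  (zero-to-poor 0–19% … high-to-excellent 80–100%), plus the tweet-hit
  distribution by bin.
* **Frequency and co-occurrence** — category shares over annotations,
  multi-label distribution over tweets, and the 21×21 phi-coefficient
  matrix `φ = (n11·n00 − n10·n01) / √(n1·n0·n·1n·0)` with Cohen
  effect-size bins and a heatmap export.
* **Characteristic words** — per-category information-gain ranking of
  unigrams (binary presence vs one-vs-rest label, bits), averaged over
  five seeded corpus subsets, with lexicon-coverage annotation.
* **Synthetic corpora** — a seeded generator that plants prevalences,
  pairwise phi targets, per-keyword precision, and discriminative
  vocabulary, so every estimator above can be validated against known
  ground truth.

## Worked example

Match the packaged lexicon against a post — one post can hit several
keywords:

```r
library(depsignal)
find_hits(c(t1 = "I'm so depressed because I got fired today"))
#> # A tibble: 2 × 4
#>   tweet_id pattern  token     token_index
#>   <chr>    <chr>    <chr>           <int>
#> 1 t1       depress* depressed           2
#> 2 t1       fired    fired             6
```

Keyword precision against gold labels: four tweets contain "sobbing", one
of them is gold-labelled with a depressive symptom, so the keyword's
precision is 25% and it falls in the poor-to-low bin:

```r
cp <- corpus(
  tibble::tibble(tweet_id = paste0("t", 1:4),
                 text = c("i could not stop sobbing last night",
                          "sobbing through the movie again",
                          "sobbing with laughter at this",
                          "that scene has everyone sobbing")),
  data.frame(tweet_id = paste0("t", 1:4), annotator_id = "GOLD",
             category = c("depressed_mood", rep("no_evidence", 3))))
keyword_precision(cp)
#> # A tibble: 1 × 5
#>   pattern tweet_hits relevant_hits precision bin
#>   <chr>        <int>         <int>     <dbl> <fct>
#> 1 sobbing          4             1        25 poor-to-low
```

Agreement between two annotators with 3 matching assertions and one
mismatch on each side:

```r
f_score(list(matches = 3, type1_mismatches = 1, type2_mismatches = 1))
#> [1] 75
```

End to end on synthetic data — generate a 10,000-tweet corpus with planted
ground truth, simulate three noisy annotators, run every stage, and
compare estimates against what was planted:

```r
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

The planted correlations come back within a few hundredths, per-keyword
precision tracks the planted relevance, and the corpus reproduces the
intended ~72% no-evidence skew. `run_all()` writes the agreement,
precision, frequency, top-words and phi tables (CSV/JSON), the bin chart
and heatmap (PNG), and a manifest with a checksum of every output, so a
rerun with the same seed is bit-identical.

See `vignettes/depsignal-methods.Rmd` for the statistical details and
design decisions.

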