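# Shared fixtures and independent oracles.

# Build a small corpus from a named list of texts and a data frame of
# (tweet_id, annotator_id, category) triples given as a list of vectors.
mk_corpus <- function(texts, ann = NULL) {
  tw <- tibble::tibble(tweet_id = names(texts), text = unname(texts))
  if (!is.null(ann)) {
    ann <- do.call(rbind, lapply(ann, function(x) {
      data.frame(tweet_id = x[[1]], annotator_id = x[[2]], category = x[[3]],
                 stringsAsFactors = FALSE)
    }))
  }
  corpus(tw, ann)
}

# Corpus where `n` tweets all contain `token`, of which the first
# `n_relevant` carry a depressive-symptom gold label.
mk_keyword_corpus <- function(token, n, n_relevant) {
  ids <- paste0("t", seq_len(n))
  texts <- stats::setNames(paste("i feel", token, "today"), ids[1])
  texts <- stats::setNames(rep(paste("i feel", token, "today"), n), ids)
  ann <- lapply(seq_len(n), function(i) {
    list(ids[i], "GOLD",
         if (i <= n_relevant) "depressed_mood" else "no_evidence")
  })
  mk_corpus(texts, ann)
}

# Independent set-based F1 oracle: treat annotator A's assertion set as
# reference and B's as prediction; harmonic mean of precision and recall.
oracle_f1_pct <- function(set_a, set_b) {
  tp <- length(intersect(set_a, set_b))
  if (length(set_a) == 0 && length(set_b) == 0) return(NA_real_)
  if (tp == 0) return(0)
  prec <- tp / length(set_b)
  rec <- tp / length(set_a)
  100 * 2 * prec * rec / (prec + rec)
}

# Brute-force mutual information oracle (bits): direct summation of
# p(c,w) log2(p(c,w) / (p(c) p(w))) over the 2x2 joint table.
oracle_mutual_information <- function(class01, word01) {
  n <- length(class01)
  mi <- 0
  for (cv in 0:1) for (wv in 0:1) {
    pj <- sum(class01 == cv & word01 == wv) / n
    if (pj > 0) {
      mi <- mi + pj * log2(pj / ((sum(class01 == cv) / n) *
                                   (sum(word01 == wv) / n)))
    }
  }
  mi
}
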