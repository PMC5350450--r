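#' Tokenize tweet text
#'
#' Lowercases, splits on whitespace, strips leading and trailing
#' punctuation from each token (so emoji and other symbol characters
#' survive), replaces URLs and @-mentions by the placeholder tokens
#' `<url>` and `<mention>`, and keeps the `#` on hashtags. Internal
#' apostrophes are preserved (`can't`). No stopword removal: function
#' words such as first-person pronouns are informative for this domain.
#'
#' @param text Character vector of texts.
#' @return For a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @examples
#' tokenize("I can't concentrate")
#' @export
tokenize <- function(text) {
  out <- lapply(text, tokenize_text)
  if (length(text) == 1L) out[[1L]] else out
}

tokenize_text <- function(text) {
  toks <- strsplit(trimws(tolower(text)), "\\s+")[[1L]]
  if (length(toks) == 0L) return(character())
  is_url <- grepl("^(https?://|www\\.)", toks)
  is_mention <- grepl("^@[[:alnum:]_]", toks)
  hash <- startsWith(toks, "#")
  core <- gsub("^\\p{P}+|\\p{P}+$", "", toks, perl = TRUE)
  core[hash & nzchar(core)] <- paste0("#", core[hash & nzchar(core)])
  core[is_url] <- "<url>"
  core[is_mention] <- "<mention>"
  core[nzchar(core)]
}

entropy2 <- function(p) {
  # binary entropy in bits with 0 log 0 = 0
  p <- c(p, 1 - p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

ig_from_counts <- function(n_pos_w, n_pos, n_w, n) {
  # IG of binary word presence about a binary one-vs-rest class label,
  # from the 2x2 table margins: n = tweets, n_pos = positive tweets,
  # n_w = tweets containing the word, n_pos_w = both.
  h_c <- entropy2(n_pos / n)
  p_w <- n_w / n
  h_given <- numeric(length(n_w))
  for (i in seq_along(n_w)) {
    h1 <- if (n_w[i] > 0) entropy2(n_pos_w[i] / n_w[i]) else 0
    h0 <- if (n_w[i] < n) entropy2((n_pos - n_pos_w[i]) / (n - n_w[i])) else 0
    h_given[i] <- p_w[i] * h1 + (1 - p_w[i]) * h0
  }
  h_c - h_given
}

corpus_tokens <- function(corpus) {
  toks <- lapply(corpus$tweets$text, function(t) unique(tokenize_text(t)))
  names(toks) <- corpus$tweets$tweet_id
  toks
}

#' Information gain of a word for a category
#'
#' Mutual information, in bits, between binary word presence and the
#' binary one-vs-rest indicator of a gold category, computed over the
#' gold-annotated tweets: IG = H(C) - sum_v P(W=v) H(C | W=v), log base 2.
#'
#' @param word A token (lowercase).
#' @param category A scheme category id.
#' @param corpus An `annotated_corpus` with `GOLD` annotations.
#' @return Information gain in bits (non-negative).
#' @export
information_gain <- function(word, category, corpus) {
  assert_known_categories(category)
  assert_gold(corpus)
  stopifnot(nrow(corpus$tweets) >= 2L)
  toks <- corpus_tokens(corpus)
  gold <- annotations_of(corpus, "GOLD")
  pos_ids <- unique(gold$tweet_id[gold$category == category])
  ids <- names(toks)
  has_w <- vapply(toks, function(tt) word %in% tt, logical(1))
  is_pos <- ids %in% pos_ids
  ig_from_counts(sum(has_w & is_pos), sum(is_pos), sum(has_w), length(ids))
}

#' Most characteristic words for a category by average-rank information gain
#'
#' The corpus is split into `n_subsets` near-equal random subsets (seeded;
#' the assignment is keyed to sorted tweet ids, so permuting corpus record
#' order does not change results). Within each subset every vocabulary
#' word is ranked by information gain for the one-vs-rest category
#' indicator (descending IG, ties broken lexicographically); a word absent
#' from a subset's vocabulary gets rank = subset vocabulary size + 1. Words
#' are then ordered by ascending mean rank and the top `k` returned.
#'
#' Categories with fewer than `min_mentions` positive tweets are skipped:
#' rankings learned from a handful of mentions are noise.
#'
#' @param corpus An `annotated_corpus` with `GOLD` annotations.
#' @param category A scheme category id.
#' @param k Number of words to return (default 10).
#' @param n_subsets Number of random subsets (default 5).
#' @param seed Integer seed for the subset assignment.
#' @param min_mentions Minimum positive tweets required (default 3).
#' @param tokens Optional precomputed per-tweet unique-token list (from
#'   repeated calls over categories).
#' @return A tibble (rank, word, avg_rank, ig_bits) where `ig_bits` is the
#'   full-corpus information gain of the word; the `rank_per_subset`
#'   attribute carries the per-subset ranks. If the category is skipped, a
#'   zero-row tibble with attribute `skipped = TRUE`.
#' @export
top_words <- function(corpus, category, k = 10, n_subsets = 5, seed = 1,
                      min_mentions = 3, tokens = NULL) {
  assert_known_categories(category)
  assert_gold(corpus)
  if (is.null(tokens)) tokens <- corpus_tokens(corpus)
  gold <- annotations_of(corpus, "GOLD")
  pos_ids <- unique(gold$tweet_id[gold$category == category])
  empty <- tibble::tibble(rank = integer(), word = character(),
                          avg_rank = numeric(), ig_bits = numeric())
  if (length(pos_ids) < min_mentions) {
    attr(empty, "skipped") <- TRUE
    attr(empty, "n_positive") <- length(pos_ids)
    return(empty)
  }
  ids <- sort(names(tokens))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  assign <- sample(rep_len(seq_len(n_subsets), length(ids)))
  names(assign) <- ids
  is_pos <- ids %in% pos_ids

  subset_rank <- list()
  for (s in seq_len(n_subsets)) {
    sel <- ids[assign == s]
    tt <- tokens[sel]
    pos <- is_pos[assign == s]
    all_tok <- unlist(tt, use.names = FALSE)
    tok_pos <- rep(pos, lengths(tt))
    n_w <- table(all_tok)
    vocab <- names(n_w)
    n_pos_w <- table(factor(all_tok[tok_pos], levels = vocab))
    ig <- ig_from_counts(as.integer(n_pos_w), sum(pos),
                         as.integer(n_w), length(sel))
    ord <- order(-ig, vocab)
    rk <- integer(length(vocab))
    rk[ord] <- seq_along(vocab)
    names(rk) <- vocab
    subset_rank[[s]] <- rk
  }
  words <- sort(unique(unlist(lapply(subset_rank, names), use.names = FALSE)))
  rank_mat <- matrix(NA_real_, nrow = length(words), ncol = n_subsets,
                     dimnames = list(words, NULL))
  for (s in seq_len(n_subsets)) {
    rk <- subset_rank[[s]]
    miss_rank <- length(rk) + 1
    rank_mat[, s] <- miss_rank
    rank_mat[names(rk), s] <- rk
  }
  avg <- rowMeans(rank_mat)
  ord <- order(avg, words)
  take <- utils::head(ord, k)
  chosen <- words[take]
  # full-corpus IG of the reported words
  all_tok <- unlist(tokens[ids], use.names = FALSE)
  tok_pos <- rep(is_pos, lengths(tokens[ids]))
  n_w <- vapply(chosen, function(w) sum(all_tok == w), integer(1))
  n_pos_w <- vapply(chosen, function(w) sum(all_tok == w & tok_pos), integer(1))
  ig_full <- ig_from_counts(n_pos_w, sum(is_pos), n_w, length(ids))
  out <- tibble::tibble(rank = seq_along(chosen), word = chosen,
                        avg_rank = avg[take], ig_bits = ig_full)
  attr(out, "skipped") <- FALSE
  attr(out, "rank_per_subset") <- rank_mat[take, , drop = FALSE]
  out
}

#' Lexicon coverage of a ranked word list
#'
#' A word is covered if any lexicon pattern matches it under
#' [match_token()] semantics (so `depressed` is covered by `depress*`).
#'
#' @param words A character vector, or a [top_words()] tibble (its `word`
#'   column is used).
#' @param lexicon A `lexicon`; defaults to the packaged lexicon.
#' @return Tibble (word, in_lexicon); `sum(out$in_lexicon)` is the overlap
#'   count.
#' @export
lexicon_overlap <- function(words, lexicon = load_lexicon()) {
  if (is.data.frame(words)) words <- words$word
  covered <- vapply(words, function(w) any(match_token(lexicon$pattern, w)),
                    logical(1))
  tibble::tibble(word = words, in_lexicon = unname(covered))
}
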