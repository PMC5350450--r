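#' Default per-category prevalences for the synthetic generator
#'
#' Tweet-level probabilities for the 21 evidence categories, chosen so the
#' emitted corpus mirrors the headline shape of a keyword-sampled
#' depression corpus: about 72% of gold annotations are `no_evidence`, and
#' evidence annotations split roughly 65:35 between depressive symptoms
#' and psychosocial stressors. Categories involved in the default planted
#' phi pairs carry prevalences in the few-percent range so that pairwise
#' phi is estimable from a 10,000-tweet corpus.
#'
#' @return Named numeric vector over [scheme_categories()]`("EVIDENCE")`.
#' @export
default_prevalence <- function() {
  c(depressed_mood = 0.053,
    anhedonia = 0.002,
    weight_change_or_appetite = 0.008,
    disturbed_sleep = 0.022,
    psychomotor_agitation_or_retardation = 0.004,
    fatigue_or_loss_of_energy = 0.045,
    worthlessness_or_guilt = 0.018,
    diminished_ability_to_think = 0.030,
    thoughts_of_death_or_suicide = 0.014,
    expected_life_course_problems = 0.003,
    primary_support_group_problems = 0.020,
    social_environment_problems = 0.020,
    educational_problems = 0.035,
    occupational_problems = 0.007,
    housing_problems = 0.004,
    economic_problems = 0.008,
    health_care_access_problems = 0.001,
    legal_system_problems = 0.002,
    other_psychosocial_problems = 0.002,
    weather = 0.002,
    media = 0.001)
}

#' Default planted phi targets
#'
#' Three vertex-disjoint greater-than-large pairs, mirroring the strongest
#' symptom/stressor co-occurrences in this domain: fatigue with disturbed
#' sleep, depressed mood with feelings of worthlessness or guilt, and
#' educational problems with diminished ability to concentrate.
#'
#' @return Tibble with columns `category_a`, `category_b`, `phi`.
#' @export
default_phi_targets <- function() {
  tibble::tibble(
    category_a = c("fatigue_or_loss_of_energy", "depressed_mood",
                   "educational_problems"),
    category_b = c("disturbed_sleep", "worthlessness_or_guilt",
                   "diminished_ability_to_think"),
    phi = c(0.60, 0.55, 0.60))
}

#' Default planted keyword relevance
#'
#' Assigns each distinct lexicon pattern a relevance probability (the
#' chance that a tweet containing the keyword is evidence-labelled),
#' spread over the five precision bins with most mass at the low end —
#' the signature of an ambiguous keyword lexicon, where most matches are
#' figurative or off-topic.
#'
#' @param lexicon A `lexicon`; defaults to the packaged lexicon.
#' @return Named numeric vector over distinct patterns.
#' @export
default_keyword_relevance <- function(lexicon = load_lexicon()) {
  pats <- unique(lexicon$pattern)
  k <- length(pats)
  lv <- c(rep(0.08, 49), rep(0.28, 39), rep(0.48, 12), rep(0.68, 8), 0.90)
  rel <- rep_len(lv, k)
  names(rel) <- pats
  rel
}

make_pseudo_words <- function(n, syllables = 3L) {
  cons <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n",
            "p", "q", "r", "t", "v", "x")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  k <- length(syl)
  idx <- seq_len(n) - 1L
  w <- character(n)
  for (s in seq_len(syllables)) {
    w <- paste0(syl[(idx %% k) + 1L], w)
    idx <- idx %/% k
  }
  w
}

make_planted_words <- function(n_words = 10L) {
  cats <- scheme_categories("EVIDENCE")
  out <- lapply(cats, function(cc) {
    sprintf("z%s%02d", substr(gsub("_", "", cc), 1L, 8L), seq_len(n_words))
  })
  names(out) <- cats
  out
}

#' Synthetic-corpus generator configuration
#'
#' Defines the study conditions a generated corpus emulates: a skewed
#' 22-way label distribution, short texts with a given token-count
#' distribution, lexicon keywords injected with controllable per-keyword
#' relevance, per-category planted discriminative vocabulary, planted
#' pairwise phi targets, and multi-annotator noise. All randomness is
#' governed by a single seed.
#'
#' Validation: probabilities must lie in \[0, 1\] and prevalences sum to
#' at most 1; phi-target pairs must be vertex-disjoint and each target
#' attainable given the two prevalences (the 2x2 cell probabilities
#' implied by the target must all be non-negative — the Frechet bound);
#' and no background or planted word may match a lexicon pattern, so
#' planted keyword precisions stay exact by construction.
#'
#' @param n_tweets Corpus size (default 10000).
#' @param prevalence Named tweet-level probabilities for the 21 evidence
#'   categories ([default_prevalence()]).
#' @param phi_targets Tibble (category_a, category_b, phi) of planted
#'   pairwise correlations ([default_phi_targets()]); unlisted pairs are
#'   independent.
#' @param multilabel_rate Probability that a tweet with exactly one label
#'   receives a second, independently drawn category (default 0; the
#'   planted pairs already induce multi-label tweets).
#' @param keyword_relevance Named per-pattern relevance probabilities
#'   ([default_keyword_relevance()]).
#' @param hits_rate Expected injected tweet hits per keyword, as a
#'   fraction of corpus size (Poisson with mean `hits_rate * n_tweets`;
#'   default 0.009, about 90 hits per keyword in a 10,000-tweet corpus).
#' @param planted_word_rate Probability that each of a category's planted
#'   words appears in a tweet carrying that category (default 0.4).
#' @param n_planted_words Planted discriminative words per category
#'   (default 10).
#' @param background_vocab_size Size of the shared background vocabulary
#'   (default 1200; sampled with Zipf weights).
#' @param length_mean,length_sd Token-count distribution (rounded normal,
#'   truncated at 1); defaults 14.56 and 7.40.
#' @param annotators Named list of per-annotator error rates, each a list
#'   with `deletion` (chance a gold assertion is dropped) and `spurious`
#'   (chance a tweet gains a random extra category).
#' @param lexicon The lexicon whose keywords are injected.
#' @param seed Integer seed.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_tweets = 10000,
                             prevalence = default_prevalence(),
                             phi_targets = default_phi_targets(),
                             multilabel_rate = 0,
                             keyword_relevance = default_keyword_relevance(),
                             hits_rate = 0.009,
                             planted_word_rate = 0.4,
                             n_planted_words = 10L,
                             background_vocab_size = 1200L,
                             length_mean = 14.56,
                             length_sd = 7.40,
                             annotators = list(
                               A1 = list(deletion = 0.15, spurious = 0.02),
                               A2 = list(deletion = 0.15, spurious = 0.02),
                               A3 = list(deletion = 0.15, spurious = 0.02)),
                             lexicon = load_lexicon(),
                             seed = 1L) {
  cats <- scheme_categories("EVIDENCE")
  stopifnot(n_tweets >= 1)
  if (!setequal(names(prevalence), cats)) {
    stop("prevalence must be named over the 21 evidence categories",
         call. = FALSE)
  }
  prevalence <- prevalence[cats]
  if (any(prevalence < 0 | prevalence > 1) || sum(prevalence) > 1) {
    stop("prevalences must be in [0,1] and sum to at most 1", call. = FALSE)
  }
  stopifnot(multilabel_rate >= 0, multilabel_rate <= 1,
            planted_word_rate >= 0, planted_word_rate <= 1,
            all(keyword_relevance >= 0 & keyword_relevance <= 1),
            length_mean > 0, length_sd >= 0, hits_rate >= 0)
  for (a in annotators) {
    stopifnot(a$deletion >= 0, a$deletion <= 1,
              a$spurious >= 0, a$spurious <= 1)
  }
  pair_cats <- c(phi_targets$category_a, phi_targets$category_b)
  assert_known_categories(pair_cats, "phi target")
  if (anyDuplicated(pair_cats)) {
    stop("phi target pairs must be vertex-disjoint (a category may appear in one pair only)",
         call. = FALSE)
  }
  cells <- pair_cells(phi_targets, prevalence)  # Frechet check happens here
  missing_rel <- setdiff(unique(lexicon$pattern), names(keyword_relevance))
  if (length(missing_rel) > 0L) {
    stop("keyword_relevance missing pattern(s): ", missing_rel[1L], call. = FALSE)
  }

  bg <- make_pseudo_words(as.integer(background_vocab_size) * 2L)
  bg <- bg[!vapply(bg, function(w) any(match_token(lexicon$pattern, w)),
                   logical(1))]
  bg <- utils::head(bg, background_vocab_size)
  planted <- make_planted_words(n_planted_words)
  pl <- unlist(planted, use.names = FALSE)
  if (any(vapply(pl, function(w) any(match_token(lexicon$pattern, w)),
                 logical(1)))) {
    stop("planted word collides with a lexicon pattern", call. = FALSE)
  }
  # each keyword's surface token (its stem) must match only its own pattern,
  # so injected hits are attributable to exactly one keyword
  pats <- unique(lexicon[, c("stem", "wildcard", "pattern")])
  n_match <- vapply(pats$stem, function(tok) {
    length(unique(pats$pattern[match_token(pats$pattern, tok)]))
  }, integer(1))
  if (any(n_match != 1L)) {
    stop("keyword token matches multiple patterns: ",
         pats$stem[n_match != 1L][1L], call. = FALSE)
  }

  structure(list(n_tweets = as.integer(n_tweets), prevalence = prevalence,
                 phi_targets = phi_targets, pair_cells = cells,
                 multilabel_rate = multilabel_rate,
                 keyword_relevance = keyword_relevance,
                 hits_rate = hits_rate,
                 planted_word_rate = planted_word_rate,
                 planted_words = planted,
                 background_vocab = bg,
                 length_mean = length_mean, length_sd = length_sd,
                 annotators = annotators, lexicon = lexicon,
                 seed = as.integer(seed)),
            class = "generator_config")
}

pair_cells <- function(phi_targets, prevalence) {
  if (nrow(phi_targets) == 0L) return(phi_targets)
  pi_ <- prevalence[phi_targets$category_a]
  pj <- prevalence[phi_targets$category_b]
  s <- sqrt(pi_ * (1 - pi_) * pj * (1 - pj))
  p11 <- phi_targets$phi * s + pi_ * pj
  p10 <- pi_ - p11
  p01 <- pj - p11
  p00 <- 1 - p11 - p10 - p01
  bad <- p11 < 0 | p10 < 0 | p01 < 0 | p00 < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "phi target %.2f for (%s, %s) violates the Frechet bound for prevalences (%.3f, %.3f)",
      phi_targets$phi[i], phi_targets$category_a[i], phi_targets$category_b[i],
      pi_[i], pj[i]), call. = FALSE)
  }
  cbind(phi_targets, p11 = unname(p11), p10 = unname(p10),
        p01 = unname(p01), p00 = unname(p00))
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> n=%d, sum prevalence=%.3f, %d phi pair(s), %d annotator(s), seed=%d\n",
    x$n_tweets, sum(x$prevalence), nrow(x$phi_targets),
    length(x$annotators), x$seed))
  invisible(x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

#' Generate a synthetic annotated corpus with planted ground truth
#'
#' Drawing is fully determined by `config$seed`. Label indicators for the
#' phi-target pairs are drawn jointly from the 2x2 cell probabilities
#' implied by the target (so empirical phi converges to the target); all
#' other categories are independent Bernoulli draws. Tweet text is
#' assembled from Zipf-weighted background words, the planted
#' discriminative words of the tweet's categories, and injected lexicon
#' keywords whose relevance (probability of landing in an evidence tweet)
#' is planted per keyword. Token counts follow a rounded normal truncated
#' at 1. Tweets with no category receive the gold label `no_evidence`.
#'
#' @param config A `generator_config`.
#' @return A list with `corpus` (an `annotated_corpus` with `GOLD`
#'   annotations) and `truth` (a `ground_truth` list: the planted
#'   prevalences, phi targets, per-keyword relevance and realized hit
#'   allocations, planted words, and the per-tweet latent label matrix).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_tweets
    cats <- scheme_categories("EVIDENCE")
    y <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
    cells <- config$pair_cells
    for (i in seq_len(nrow(cells))) {
      cell <- sample.int(4L, n, replace = TRUE,
                         prob = c(cells$p11[i], cells$p10[i],
                                  cells$p01[i], cells$p00[i]))
      y[, cells$category_a[i]] <- as.integer(cell %in% c(1L, 2L))
      y[, cells$category_b[i]] <- as.integer(cell %in% c(1L, 3L))
    }
    pair_cats <- c(cells$category_a, cells$category_b)
    for (cc in setdiff(cats, pair_cats)) {
      y[, cc] <- stats::rbinom(n, 1L, config$prevalence[[cc]])
    }
    if (config$multilabel_rate > 0) {
      free <- setdiff(cats, pair_cats)
      pr <- config$prevalence[free]
      singles <- which(rowSums(y) == 1L & stats::runif(n) < config$multilabel_rate)
      for (i in singles) {
        open <- free[y[i, free] == 0L]
        if (length(open) == 0L) next
        w <- config$prevalence[open]
        y[i, sample(open, 1L, prob = w / sum(w))] <- 1L
      }
    }

    ids <- sprintf("s%06d", seq_len(n))
    len <- pmax(1L, as.integer(round(stats::rnorm(n, config$length_mean,
                                                  config$length_sd))))
    bg <- config$background_vocab
    zipf <- 1 / seq_along(bg)
    bg_tok <- sample(bg, sum(len), replace = TRUE, prob = zipf / sum(zipf))
    extra_idx <- integer(0)
    extra_tok <- character(0)

    for (cc in cats) {
      pos <- which(y[, cc] == 1L)
      if (length(pos) == 0L) next
      for (w in config$planted_words[[cc]]) {
        sel <- pos[stats::runif(length(pos)) < config$planted_word_rate]
        extra_idx <- c(extra_idx, sel)
        extra_tok <- c(extra_tok, rep(w, length(sel)))
      }
    }

    evid <- which(rowSums(y) > 0L)
    noev <- which(rowSums(y) == 0L)
    pats <- unique(config$lexicon[, c("stem", "wildcard", "pattern")])
    rel_planted <- config$keyword_relevance[pats$pattern]
    hit_alloc <- vector("list", nrow(pats))
    for (i in seq_len(nrow(pats))) {
      m <- stats::rpois(1L, config$hits_rate * n)
      if (m == 0L) { hit_alloc[[i]] <- integer(0); next }
      n_rel <- stats::rbinom(1L, m, rel_planted[i])
      n_rel <- min(n_rel, length(evid))
      n_irr <- min(m - n_rel, length(noev))
      tw <- c(if (n_rel > 0L) evid[sample.int(length(evid), n_rel)],
              if (n_irr > 0L) noev[sample.int(length(noev), n_irr)])
      hit_alloc[[i]] <- tw
      extra_idx <- c(extra_idx, tw)
      extra_tok <- c(extra_tok, rep(pats$stem[i], length(tw)))
    }
    names(hit_alloc) <- pats$pattern

    tok_by_tweet <- split(bg_tok, rep.int(seq_len(n), len))
    extra_by_tweet <- split(extra_tok, factor(extra_idx, levels = seq_len(n)))
    text <- vapply(seq_len(n), function(i) {
      paste(sample(c(tok_by_tweet[[i]], extra_by_tweet[[i]])), collapse = " ")
    }, "")

    hits <- which(y == 1L, arr.ind = TRUE)
    gold <- rbind(
      if (nrow(hits) > 0L)
        data.frame(tweet_id = ids[hits[, 1L]], annotator_id = "GOLD",
                   category = cats[hits[, 2L]], stringsAsFactors = FALSE),
      if (length(noev) > 0L)
        data.frame(tweet_id = ids[noev], annotator_id = "GOLD",
                   category = no_evidence_label(), stringsAsFactors = FALSE))
    cp <- corpus(tibble::tibble(tweet_id = ids, text = text,
                                source = "synthetic"), gold)
    truth <- structure(list(
      prevalence = config$prevalence,
      phi_targets = config$phi_targets,
      keyword_relevance = rel_planted,
      keyword_hit_tweets = lapply(hit_alloc, function(ix) ids[ix]),
      planted_words = config$planted_words,
      labels = y,
      tweet_ids = ids), class = "ground_truth")
    list(corpus = cp, truth = truth)
  })
}

#' Simulate noisy annotators over gold labels
#'
#' Each annotator independently drops each gold evidence assertion with
#' their `deletion` rate and, with their `spurious` rate per tweet, adds
#' one uniformly drawn evidence category not already asserted. A tweet
#' left with no assertion becomes `no_evidence` for that annotator. With
#' deletion rate d and no spurious additions, the expected pairwise F
#' score pooled over evidence categories is 100(1-d) in closed form.
#'
#' @param corpus An `annotated_corpus` with `GOLD` annotations.
#' @param annotators Named list of per-annotator error rates (as in
#'   [generator_config()]).
#' @param seed Integer seed.
#' @return The corpus with the simulated annotators' annotations appended.
#' @export
corrupt_annotations <- function(corpus, annotators, seed = 1L) {
  assert_gold(corpus)
  for (a in annotators) {
    stopifnot(a$deletion >= 0, a$deletion <= 1,
              a$spurious >= 0, a$spurious <= 1)
  }
  gold <- annotations_of(corpus, "GOLD")
  ev <- gold[gold$category != no_evidence_label(), ]
  ids <- unique(gold$tweet_id)
  cats <- scheme_categories("EVIDENCE")
  with_seed(seed, {
    new_rows <- list()
    for (ann in names(annotators)) {
      d <- annotators[[ann]]$deletion
      a <- annotators[[ann]]$spurious
      keep <- ev[stats::runif(nrow(ev)) >= d, c("tweet_id", "category")]
      spur_ids <- ids[stats::runif(length(ids)) < a]
      if (length(spur_ids) > 0L) {
        add <- data.frame(tweet_id = spur_ids,
                          category = sample(cats, length(spur_ids),
                                            replace = TRUE),
                          stringsAsFactors = FALSE)
        keep <- unique(rbind(keep, add))
      }
      labelled <- unique(keep$tweet_id)
      noe <- setdiff(ids, labelled)
      out <- rbind(keep,
                   data.frame(tweet_id = noe,
                              category = no_evidence_label(),
                              stringsAsFactors = FALSE))
      out$annotator_id <- ann
      new_rows[[ann]] <- out[, c("tweet_id", "annotator_id", "category")]
    }
    corpus(corpus$tweets,
           rbind(corpus$annotations, do.call(rbind, new_rows)))
  })
}
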