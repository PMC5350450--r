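test_that("tokenizer lowercases, strips edge punctuation, keeps emoji and hashtags", {
  expect_equal(tokenize("I can't concentrate"), c("i", "can't", "concentrate"))
  expect_equal(tokenize("   "), character(0))
  expect_equal(tokenize("Tiredddd!!! \U0001F634"), c("tiredddd", "\U0001F634"))
  expect_equal(tokenize("see http://x.co/a and @friend #SoSad..."),
               c("see", "<url>", "and", "<mention>", "#sosad"))
  expect_equal(tokenize("'quoted' words"), c("quoted", "words"))
})

ig_fixture <- function() {
  # 6 tweets; word "examweek" in 2 of 3 positives and 1 of 3 negatives
  mk_corpus(
    c(t1 = "examweek is rough", t2 = "examweek again ugh", t3 = "so rough",
      t4 = "examweek whatever", t5 = "nice day", t6 = "nothing here"),
    list(list("t1", "GOLD", "educational_problems"),
         list("t2", "GOLD", "educational_problems"),
         list("t3", "GOLD", "educational_problems"),
         list("t4", "GOLD", "no_evidence"),
         list("t5", "GOLD", "no_evidence"),
         list("t6", "GOLD", "no_evidence")))
}

test_that("information gain matches the brute-force 2x2 oracle", {
  cp <- ig_fixture()
  cls <- c(1, 1, 1, 0, 0, 0)
  wrd <- c(1, 1, 0, 1, 0, 0)
  expect_equal(information_gain("examweek", "educational_problems", cp),
               oracle_mutual_information(cls, wrd), tolerance = 1e-12)
  # word present everywhere carries no information
  expect_equal(information_gain("the", "educational_problems",
                                mk_corpus(c(a = "the x", b = "the y"),
                                          list(list("a", "GOLD", "educational_problems"),
                                               list("b", "GOLD", "no_evidence")))),
               0)
  # perfectly separating word on a balanced class carries exactly 1 bit
  cp2 <- mk_corpus(c(a = "hit x", b = "hit y", c = "miss z", d = "miss w"),
                   list(list("a", "GOLD", "weather"), list("b", "GOLD", "weather"),
                        list("c", "GOLD", "no_evidence"),
                        list("d", "GOLD", "no_evidence")))
  expect_equal(information_gain("hit", "weather", cp2), 1)
})

test_that("information gain is bounded by both marginal entropies on random fixtures", {
  set.seed(12)
  h2 <- function(p) {
    p <- c(p, 1 - p); p <- p[p > 0]; -sum(p * log2(p))
  }
  for (i in 1:100) {
    n <- sample(4:30, 1)
    cls <- stats::rbinom(n, 1, 0.5)
    wrd <- stats::rbinom(n, 1, 0.5)
    ig <- oracle_mutual_information(cls, wrd)
    texts <- stats::setNames(ifelse(wrd == 1, "magic word", "plain stuff"),
                             paste0("t", 1:n))
    ann <- lapply(seq_len(n), function(j) {
      list(paste0("t", j), "GOLD", if (cls[j] == 1) "media" else "no_evidence")
    })
    got <- information_gain("magic", "media", mk_corpus(texts, ann))
    expect_lt(abs(got - ig), 1e-12)
    expect_gte(got, -1e-12)
    expect_lte(got, min(h2(mean(cls)), h2(mean(wrd))) + 1e-12)
  }
})

test_that("top_words finds planted separators and is order-invariant", {
  set.seed(33)
  n <- 60
  pos <- 1:20
  texts <- vapply(1:n, function(i) {
    base <- paste(sample(c("alpha", "beta", "gamma", "delta"), 8, TRUE),
                  collapse = " ")
    if (i %in% pos) paste(base, "examweek") else base
  }, "")
  names(texts) <- paste0("t", sprintf("%02d", 1:n))
  ann <- lapply(1:n, function(i) {
    list(names(texts)[i], "GOLD",
         if (i %in% pos) "educational_problems" else "no_evidence")
  })
  cp <- mk_corpus(texts, ann)
  tw <- top_words(cp, "educational_problems", k = 3, seed = 7)
  expect_equal(tw$word[1], "examweek")
  expect_false(isTRUE(attr(tw, "skipped")))
  # permuting tweet order leaves the ranking unchanged
  perm <- sample(n)
  cp2 <- corpus(cp$tweets[perm, ], cp$annotations)
  tw2 <- top_words(cp2, "educational_problems", k = 3, seed = 7)
  expect_equal(tw, tw2, ignore_attr = TRUE)
  # same seed twice is identical; k larger than vocabulary returns it all
  expect_identical(tw$word,
                   top_words(cp, "educational_problems", k = 3, seed = 7)$word)
  big <- top_words(cp, "educational_problems", k = 10000, seed = 7)
  expect_lte(nrow(big), 10000)
  expect_equal(sort(big$word),
               sort(unique(unlist(lapply(cp$tweets$text, tokenize)))))
})

test_that("categories with too few mentions are skipped", {
  cp <- mk_corpus(c(t1 = "one thing", t2 = "two things", t3 = "three things"),
                  list(list("t1", "GOLD", "weather"),
                       list("t2", "GOLD", "no_evidence"),
                       list("t3", "GOLD", "no_evidence")))
  tw <- top_words(cp, "weather", min_mentions = 3)
  expect_true(attr(tw, "skipped"))
  expect_equal(nrow(tw), 0L)
  expect_equal(attr(tw, "n_positive"), 1L)
})

test_that("lexicon overlap applies wildcard semantics to ranked words", {
  ov <- lexicon_overlap(c("depressed", "examweek", "lonely", "xyzzy"))
  expect_equal(ov$in_lexicon, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(lexicon_overlap(character(0))), 0L)
})
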