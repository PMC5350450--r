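two_annotator_corpus <- function(labels_a, labels_b) {
  ids <- union(names(labels_a), names(labels_b))
  texts <- stats::setNames(rep("some text", length(ids)), ids)
  ann <- list()
  for (id in names(labels_a)) for (cc in labels_a[[id]]) {
    ann[[length(ann) + 1]] <- list(id, "A1", cc)
  }
  for (id in names(labels_b)) for (cc in labels_b[[id]]) {
    ann[[length(ann) + 1]] <- list(id, "A2", cc)
  }
  mk_corpus(texts, ann)
}

test_that("pair counts implement the match / mismatch definitions", {
  ids <- paste0("t", 1:10)
  lab <- stats::setNames(rep(list("depressed_mood"), 10), ids)
  cp <- two_annotator_corpus(lab, lab)
  pc <- pair_counts(cp, "A1", "A2")
  expect_equal(pc$matches, 10L)
  expect_equal(pc$type1_mismatches + pc$type2_mismatches, 0L)

  cp2 <- two_annotator_corpus(list(t1 = "depressed_mood"),
                              list(t1 = "weather"))
  pc2 <- pair_counts(cp2, "A1", "A2")
  expect_equal(c(pc2$matches, pc2$type1_mismatches, pc2$type2_mismatches),
               c(0L, 1L, 1L))
})

test_that("pair counts are symmetric with the mismatch types exchanged", {
  cp <- two_annotator_corpus(
    list(t1 = c("depressed_mood", "weather"), t2 = "no_evidence",
         t3 = "fatigue_or_loss_of_energy"),
    list(t1 = "depressed_mood", t2 = "media", t3 = "no_evidence"))
  ab <- pair_counts(cp, "A1", "A2")
  ba <- pair_counts(cp, "A2", "A1")
  expect_equal(ab$matches, ba$matches)
  expect_equal(ab$type1_mismatches, ba$type2_mismatches)
  expect_equal(ab$type2_mismatches, ba$type1_mismatches)
  expect_equal(f_score(ab), f_score(ba))
})

test_that("tweets not co-annotated by the pair are excluded", {
  cp <- two_annotator_corpus(list(t1 = "depressed_mood", t2 = "weather"),
                             list(t1 = "depressed_mood", t9 = "media"))
  pc <- pair_counts(cp, "A1", "A2")
  expect_equal(pc$n_tweets, 1L)
  expect_equal(pc$matches, 1L)
  expect_equal(pc$type1_mismatches, 0L)
  cp2 <- two_annotator_corpus(list(t1 = "depressed_mood"),
                              list(t2 = "media"))
  expect_error(pair_counts(cp2, "A1", "A2"), "empty comparison set")
})

test_that("f_score reproduces the printed formula and its edge cases", {
  expect_equal(f_score(list(matches = 10, type1_mismatches = 0,
                            type2_mismatches = 0)), 100)
  expect_equal(f_score(list(matches = 0, type1_mismatches = 3,
                            type2_mismatches = 2)), 0)
  expect_equal(f_score(list(matches = 3, type1_mismatches = 1,
                            type2_mismatches = 1)), 75)
  expect_true(is.na(f_score(list(matches = 0, type1_mismatches = 0,
                                 type2_mismatches = 0))))
})

test_that("f_score equals an independent set-based F1 on random fixtures", {
  set.seed(5)
  for (i in 1:200) {
    universe <- paste0("t", 1:8, "+",
                       rep(sample(scheme_categories(), 4), each = 8))
    a <- sample(universe, sample(0:10, 1))
    b <- sample(universe, sample(0:10, 1))
    counts <- list(matches = length(intersect(a, b)),
                   type1_mismatches = length(setdiff(a, b)),
                   type2_mismatches = length(setdiff(b, a)))
    if (length(a) == 0 && length(b) == 0) {
      expect_true(is.na(f_score(counts)) && is.na(oracle_f1_pct(a, b)))
    } else {
      expect_lt(abs(f_score(counts) - oracle_f1_pct(a, b)), 1e-9)
    }
  }
})

test_that("overall counts equal the sum of per-category counts", {
  set.seed(6)
  cats <- scheme_categories()
  lab_a <- lab_b <- list()
  for (id in paste0("t", 1:30)) {
    lab_a[[id]] <- if (stats::runif(1) < 0.3) "no_evidence" else
      sample(setdiff(cats, "no_evidence"), sample(1:2, 1))
    lab_b[[id]] <- if (stats::runif(1) < 0.3) "no_evidence" else
      sample(setdiff(cats, "no_evidence"), sample(1:2, 1))
  }
  cp <- two_annotator_corpus(lab_a, lab_b)
  overall <- pair_counts(cp, "A1", "A2")
  per_cat <- lapply(cats, function(cc) pair_counts(cp, "A1", "A2", cc))
  expect_equal(sum(vapply(per_cat, `[[`, 0, "matches")), overall$matches)
  expect_equal(sum(vapply(per_cat, `[[`, 0, "type1_mismatches")),
               overall$type1_mismatches)
  expect_equal(sum(vapply(per_cat, `[[`, 0, "type2_mismatches")),
               overall$type2_mismatches)
})

test_that("adjudication passes agreement through and lets the third annotator resolve", {
  texts <- c(t1 = "x", t2 = "y", t3 = "z")
  cp <- mk_corpus(texts, list(
    list("t1", "A1", "depressed_mood"), list("t1", "A2", "depressed_mood"),
    list("t2", "A1", "weather"), list("t2", "A2", "media"),
    list("t2", "A3", "media"),
    list("t3", "A1", "no_evidence"), list("t3", "A2", "no_evidence")))
  out <- adjudicate(cp, c("A1", "A2"), "A3")
  gold <- annotations_of(out, "GOLD")
  expect_equal(gold$category[gold$tweet_id == "t1"], "depressed_mood")
  expect_equal(gold$category[gold$tweet_id == "t2"], "media")
  expect_equal(gold$category[gold$tweet_id == "t3"], "no_evidence")
  expect_length(attr(out, "unresolved_majority"), 0L)
})

test_that("adjudication errors on unresolved disagreements and flags 3-way splits", {
  cp <- mk_corpus(c(t1 = "x"), list(
    list("t1", "A1", "weather"), list("t1", "A2", "media")))
  expect_error(adjudicate(cp, c("A1", "A2"), "A3"),
               "without adjudicator label.*t1")
  cp2 <- mk_corpus(c(t1 = "x"), list(
    list("t1", "A1", "weather"), list("t1", "A2", "media"),
    list("t1", "A3", "economic_problems")))
  out <- adjudicate(cp2, c("A1", "A2"), "A3")
  expect_equal(attr(out, "unresolved_majority"), "t1")
  gold <- annotations_of(out, "GOLD")
  # gold never contains an assertion made by none of the three annotators
  expect_true(all(paste(gold$tweet_id, gold$category) %in%
                    paste(cp2$annotations$tweet_id, cp2$annotations$category)))
})

test_that("phase arithmetic: overlap tweets do not add to the unique total", {
  expect_equal(phase_plan(300, 300, 2700, 1200)$total_unique_tweets, 9300)
  expect_equal(phase_plan(0, 0, 0, 0)$total_unique_tweets, 0)
  expect_equal(phase_plan(100, 0, 0, 0)$total_unique_tweets, 100)
  expect_equal(phase_plan(100, 10, 5, 9999)$total_unique_tweets,
               phase_plan(100, 10, 5, 0)$total_unique_tweets)
})
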