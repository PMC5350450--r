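gold_corpus <- function(labels) {
  ids <- names(labels)
  texts <- stats::setNames(rep("text", length(ids)), ids)
  ann <- list()
  for (id in ids) for (cc in labels[[id]]) {
    ann[[length(ann) + 1]] <- list(id, "GOLD", cc)
  }
  mk_corpus(texts, ann)
}

test_that("frequency report counts annotations and tweets correctly", {
  labs <- c(rep(list("no_evidence"), 7),
            list(c("depressed_mood", "educational_problems")),
            list("fatigue_or_loss_of_energy"), list("weather"))
  names(labs) <- paste0("t", 1:10)
  fr <- frequency_report(gold_corpus(labs))
  expect_equal(fr$total_annotations, 11L)
  expect_equal(fr$evidence_split$n, c(7L, 4L))
  expect_equal(fr$multilabel$n_tweets, c(9L, 1L, 0L))
  expect_equal(sum(fr$per_category$n), fr$total_annotations)
  expect_equal(sum(fr$evidence_split$pct), 100)
  expect_equal(fr$group_split$n, c(2L, 2L))
})

test_that("an all-no-evidence corpus reports a 100% no-evidence share", {
  labs <- stats::setNames(rep(list("no_evidence"), 5), paste0("t", 1:5))
  fr <- frequency_report(gold_corpus(labs))
  expect_equal(fr$evidence_split$pct[1], 100)
  expect_equal(fr$multilabel$n_tweets, c(5L, 0L, 0L))
})

test_that("indicator matrix encodes gold labels over the 21 evidence categories", {
  labs <- list(t1 = c("depressed_mood", "educational_problems"),
               t2 = "no_evidence", t3 = "weather")
  m <- indicator_matrix(gold_corpus(labs))
  expect_equal(dim(m), c(3L, 21L))
  expect_equal(sum(m["t1", ]), 2L)
  expect_equal(m["t1", "depressed_mood"], 1L)
  expect_equal(sum(m["t2", ]), 0L)
  # row sums reproduce the evidence-label counts per tweet
  expect_equal(unname(rowSums(m)[c("t1", "t2", "t3")]), c(2, 0, 1))
})

test_that("phi matches the product-moment oracle on random 0/1 vectors", {
  set.seed(8)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    x <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    y <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      expect_true(is.na(phi_coefficient(x, y)))
    } else {
      expect_lt(abs(phi_coefficient(x, y) - stats::cor(x, y)), 1e-12)
    }
  }
})

test_that("phi handles the hand-computed 2x2 table and degenerate inputs", {
  x <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(phi_coefficient(x, y), 0.6)
  expect_equal(phi_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_true(is.na(phi_coefficient(c(1, 1, 1), c(1, 0, 1))))
  expect_error(phi_coefficient(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("phi is invariant under joint relabeling, antisymmetric under single", {
  set.seed(9)
  for (i in 1:50) {
    x <- stats::rbinom(30, 1, 0.5); y <- stats::rbinom(30, 1, 0.5)
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    r <- phi_coefficient(x, y)
    expect_lt(abs(phi_coefficient(1 - x, 1 - y) - r), 1e-12)
    expect_lt(abs(phi_coefficient(1 - x, y) + r), 1e-12)
  }
})

test_that("Cohen bins partition [0, 1] with the 0.1 gap-closing boundary", {
  expect_equal(as.character(cohen_bin(c(0, 0.05, 0.095, 0.1, 0.29, 0.3,
                                        0.49, 0.5, 0.6, 1))),
               c("less-than-small", "less-than-small", "less-than-small",
                 "small-to-medium", "small-to-medium", "medium-to-large",
                 "medium-to-large", "greater-than-large",
                 "greater-than-large", "greater-than-large"))
  expect_equal(as.character(cohen_bin(-0.35)), "medium-to-large")
  expect_error(cohen_bin(1.2), "<= 1")
})

test_that("phi matrix is symmetric with unit diagonal and NA for unobserved", {
  labs <- list(t1 = c("depressed_mood", "fatigue_or_loss_of_energy"),
               t2 = "depressed_mood", t3 = "no_evidence", t4 = "weather")
  pm <- phi_matrix(gold_corpus(labs))
  expect_equal(pm$r, t(pm$r))
  expect_equal(pm$r["depressed_mood", "depressed_mood"], 1)
  expect_true(all(abs(pm$r) <= 1, na.rm = TRUE))
  # anhedonia never occurs: whole row is not observed
  expect_true(all(is.na(pm$r["anhedonia", ])))
  counts <- effect_pair_counts(pm)
  expect_equal(sum(counts$n_pairs), choose(21, 2))
})

test_that("heatmap export writes a deterministic image file", {
  labs <- list(t1 = c("depressed_mood", "fatigue_or_loss_of_energy"),
               t2 = "depressed_mood", t3 = "no_evidence")
  pm <- phi_matrix(gold_corpus(labs))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  phi_heatmap(pm, f1)
  phi_heatmap(pm, f2)
  expect_true(file.exists(f1))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
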