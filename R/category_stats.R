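#' Category frequency and multi-label report
#'
#' Category shares are computed over gold annotation instances (a tweet
#' with two categories contributes two annotations); the multi-label
#' distribution is computed over tweets. The evidence split contrasts
#' `no_evidence` annotations with all others; the group split partitions
#' evidence annotations into depressive symptoms and psychosocial
#' stressors.
#'
#' @param corpus An `annotated_corpus` with `GOLD` annotations.
#' @return A `frequency_report`: list with `total_annotations`,
#'   `per_category` (tibble: category, group, n, pct), `evidence_split`,
#'   `group_split`, and `multilabel` (tibble: n_categories in 1/2/3+, n
#'   tweets, pct).
#' @export
frequency_report <- function(corpus) {
  assert_gold(corpus)
  gold <- annotations_of(corpus, "GOLD")
  if (nrow(gold) == 0L) stop("corpus has no gold annotations", call. = FALSE)
  sc <- sad_scheme()
  total <- nrow(gold)
  n_cat <- vapply(sc$category, function(cc) sum(gold$category == cc), integer(1))
  per_category <- tibble::tibble(category = sc$category, group = sc$group,
                                 n = unname(n_cat),
                                 pct = 100 * unname(n_cat) / total)
  n_noe <- sum(gold$category == no_evidence_label())
  evidence_split <- tibble::tibble(
    class = c("no_evidence", "evidence"),
    n = c(n_noe, total - n_noe),
    pct = 100 * c(n_noe, total - n_noe) / total)
  n_sym <- sum(per_category$n[per_category$group == "SYMPTOM"])
  n_str <- sum(per_category$n[per_category$group == "STRESSOR"])
  group_split <- tibble::tibble(
    group = c("SYMPTOM", "STRESSOR"),
    n = c(n_sym, n_str),
    pct = 100 * c(n_sym, n_str) / total)
  per_tweet <- table(factor(gold$tweet_id))
  ml <- c(sum(per_tweet == 1L), sum(per_tweet == 2L), sum(per_tweet >= 3L))
  multilabel <- tibble::tibble(n_categories = c("1", "2", "3+"),
                               n_tweets = ml,
                               pct = 100 * ml / sum(ml))
  structure(list(total_annotations = total, per_category = per_category,
                 evidence_split = evidence_split, group_split = group_split,
                 multilabel = multilabel),
            class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  noe <- x$evidence_split
  cat(sprintf("<frequency_report> %d gold annotations\n", x$total_annotations))
  cat(sprintf("  no evidence: %.2f%% (%d/%d); evidence: %.2f%%\n",
              noe$pct[1], noe$n[1], x$total_annotations, noe$pct[2]))
  cat(sprintf("  symptoms %.2f%% vs stressors %.2f%% of all annotations\n",
              x$group_split$pct[1], x$group_split$pct[2]))
  ml <- x$multilabel
  cat(sprintf("  tweets with 1/2/3+ categories: %d / %d / %d\n",
              ml$n_tweets[1], ml$n_tweets[2], ml$n_tweets[3]))
  invisible(x)
}

#' Tweet-by-category binary indicator matrix
#'
#' One row per gold-annotated tweet, one column per evidence category (the
#' 21 symptom and stressor categories in scheme order; `no_evidence` is
#' excluded, so a no-evidence tweet is an all-zero row).
#'
#' @param corpus An `annotated_corpus` with `GOLD` annotations.
#' @return Integer matrix with tweet ids as row names.
#' @export
indicator_matrix <- function(corpus) {
  assert_gold(corpus)
  gold <- annotations_of(corpus, "GOLD")
  ids <- unique(gold$tweet_id)
  cats <- scheme_categories("EVIDENCE")
  m <- matrix(0L, nrow = length(ids), ncol = length(cats),
              dimnames = list(ids, cats))
  ev <- gold[gold$category != no_evidence_label(), ]
  if (nrow(ev) > 0L) {
    m[cbind(match(ev$tweet_id, ids), match(ev$category, cats))] <- 1L
  }
  m
}

#' Phi coefficient of two binary vectors
#'
#' The Pearson product-moment correlation specialised to 0/1 variables:
#' phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0), computed from the
#' 2x2 contingency table. When either variable is constant the coefficient
#' is undefined and `NA` is returned ("not observed").
#'
#' @param x,y Binary (0/1 or logical) vectors of equal length >= 2.
#' @return The phi coefficient in \[-1, 1\], or `NA`.
#' @examples
#' phi_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)) # 1
#' @export
phi_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  stopifnot(length(x) >= 2L)
  x <- as.integer(x); y <- as.integer(y)
  stopifnot(all(x %in% 0:1), all(y %in% 0:1))
  n11 <- sum(x == 1L & y == 1L); n10 <- sum(x == 1L & y == 0L)
  n01 <- sum(x == 0L & y == 1L); n00 <- sum(x == 0L & y == 0L)
  r1 <- n11 + n10; r0 <- n01 + n00; c1 <- n11 + n01; c0 <- n10 + n00
  if (r1 == 0L || r0 == 0L || c1 == 0L || c0 == 0L) return(NA_real_)
  (n11 * n00 - n10 * n01) /
    sqrt(as.numeric(r1) * as.numeric(r0) * as.numeric(c1) * as.numeric(c0))
}

#' Classify a correlation magnitude into Cohen effect-size bins
#'
#' Applied to |r|: less-than-small below 0.1, small-to-medium in
#' \[0.1, 0.3), medium-to-large in \[0.3, 0.5), greater-than-large at 0.5
#' and above. The printed convention leaves (0.09, 0.1) uncovered; the
#' boundary is closed here at 0.1 so the four bins partition \[0, 1\].
#' Negative correlations are binned by magnitude.
#'
#' @param r Correlation coefficient(s), |r| <= 1; `NA` passes through.
#' @return Factor of bin labels.
#' @examples
#' cohen_bin(0.6) # greater-than-large
#' @export
cohen_bin <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  labels <- c("less-than-small", "small-to-medium", "medium-to-large",
              "greater-than-large")
  idx <- findInterval(abs(r), c(0, 0.1, 0.3, 0.5))
  factor(labels[idx], levels = labels)
}

#' Pairwise phi-coefficient matrix over the 21 evidence categories
#'
#' Computes the phi coefficient, its two-sided p-value (from the t
#' transform of r; reported but never used for effect binning, since p is
#' driven by sample size while r is not), and the Cohen effect bin for
#' every pair of evidence categories. Pairs involving a category that
#' never (or always) occurs are `NA` ("not observed in the corpus").
#'
#' @param corpus An `annotated_corpus` with `GOLD` annotations, or an
#'   indicator matrix as returned by [indicator_matrix()].
#' @return A `phi_matrix`: list with `labels`, symmetric matrices `r` and
#'   `p_value`, `effect_bin` (character matrix over |r|), and `n` (tweets).
#' @export
phi_matrix <- function(corpus) {
  m <- if (is.matrix(corpus)) corpus else indicator_matrix(corpus)
  cats <- colnames(m)
  k <- ncol(m)
  n <- nrow(m)
  r <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  p <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  for (i in seq_len(k)) {
    for (j in i:k) {
      rij <- if (i == j) {
        if (stats::var(m[, i]) > 0) 1 else NA_real_
      } else {
        phi_coefficient(m[, i], m[, j])
      }
      r[i, j] <- r[j, i] <- rij
      if (!is.na(rij) && i != j && abs(rij) < 1) {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  eb <- matrix(as.character(cohen_bin(as.vector(r))), k, k,
               dimnames = list(cats, cats))
  structure(list(labels = cats, r = r, p_value = p, effect_bin = eb, n = n),
            class = "phi_matrix")
}

#' @export
print.phi_matrix <- function(x, ...) {
  cat(sprintf("<phi_matrix> %d categories, n=%d tweets\n",
              length(x$labels), x$n))
  print(effect_pair_counts(x))
  invisible(x)
}

#' Count category pairs per Cohen effect bin
#'
#' Recomputes, from a phi matrix, how many distinct off-diagonal pairs
#' fall in each effect bin and how many are not observed.
#'
#' @param pm A `phi_matrix`.
#' @return Tibble with columns `bin` and `n_pairs`.
#' @export
effect_pair_counts <- function(pm) {
  ut <- upper.tri(pm$r)
  bins <- c(levels(cohen_bin(0)), "not-observed")
  b <- pm$effect_bin[ut]
  b[is.na(b)] <- "not-observed"
  tibble::tibble(bin = bins,
                 n_pairs = vapply(bins, function(x) sum(b == x), integer(1)))
}

#' Export a phi matrix as long-form CSV rows
#'
#' @param pm A `phi_matrix`.
#' @return Tibble of distinct pairs: `category_a`, `category_b`, `r`,
#'   `p_value`, `effect_bin` (`NA` = not observed).
#' @export
phi_long <- function(pm) {
  ut <- which(upper.tri(pm$r), arr.ind = TRUE)
  tibble::tibble(category_a = pm$labels[ut[, 1L]],
                 category_b = pm$labels[ut[, 2L]],
                 r = pm$r[ut],
                 p_value = pm$p_value[ut],
                 effect_bin = pm$effect_bin[ut])
}

#' Heatmap of pairwise co-occurrence effect sizes
#'
#' Renders the 21x21 matrix with one colour per Cohen effect bin (darker =
#' larger effect), axes indexed by scheme position, deterministic for a
#' given matrix. Not-observed cells use the background colour.
#'
#' @param pm A `phi_matrix`.
#' @param path Output image path (`.png` or `.svg`).
#' @return `path`, invisibly.
#' @export
phi_heatmap <- function(pm, path) {
  k <- length(pm$labels)
  levs <- levels(cohen_bin(0))
  z <- matrix(match(pm$effect_bin, levs), k, k)
  z[is.na(z)] <- 0L
  cols <- c("grey95", "#d0c4e8", "#a188cf", "#6d4fa8", "#2e1a5e")
  open_device(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::image(seq_len(k), seq_len(k), t(z[k:1, , drop = FALSE]),
                  col = cols, breaks = seq(-0.5, 4.5, by = 1),
                  axes = FALSE, xlab = "category index", ylab = "category index",
                  main = "Pairwise co-occurrence (Cohen effect bins)")
  graphics::axis(1, at = seq_len(k), labels = seq_len(k), cex.axis = 0.6)
  graphics::axis(2, at = seq_len(k), labels = rev(seq_len(k)), cex.axis = 0.6)
  graphics::box()
  invisible(path)
}
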