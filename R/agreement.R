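#' Pairwise annotation match/mismatch counts
#'
#' Compares two annotators' (tweet, category) assertion sets on the tweets
#' they both annotated. A match is an assertion made by both; a type-1
#' mismatch is an assertion made by the first annotator only, a type-2
#' mismatch one made by the second only. Tweets not co-annotated by the
#' pair are excluded rather than treated as mismatches. `no_evidence`
#' participates as an ordinary category.
#'
#' @param corpus An `annotated_corpus`.
#' @param annotator_a,annotator_b Annotator ids.
#' @param category `"ALL"` (default) pools every category; otherwise a
#'   character vector of category ids to restrict to.
#' @return An `agreement_counts` object: list with `matches`,
#'   `type1_mismatches`, `type2_mismatches` and the comparison metadata.
#' @seealso [f_score()]
#' @export
pair_counts <- function(corpus, annotator_a, annotator_b, category = "ALL") {
  a <- annotations_of(corpus, annotator_a)
  b <- annotations_of(corpus, annotator_b)
  shared <- intersect(unique(a$tweet_id), unique(b$tweet_id))
  if (length(shared) == 0L) {
    stop(sprintf("empty comparison set: %s and %s share no annotated tweets",
                 annotator_a, annotator_b), call. = FALSE)
  }
  a <- a[a$tweet_id %in% shared, ]
  b <- b[b$tweet_id %in% shared, ]
  if (!identical(category, "ALL")) {
    assert_known_categories(category)
    a <- a[a$category %in% category, ]
    b <- b[b$category %in% category, ]
  }
  sa <- paste(a$tweet_id, a$category)
  sb <- paste(b$tweet_id, b$category)
  structure(list(matches = length(intersect(sa, sb)),
                 type1_mismatches = length(setdiff(sa, sb)),
                 type2_mismatches = length(setdiff(sb, sa)),
                 annotator_a = annotator_a, annotator_b = annotator_b,
                 category = category, n_tweets = length(shared)),
            class = "agreement_counts")
}

#' @export
print.agreement_counts <- function(x, ...) {
  cat(sprintf("<agreement_counts> %s vs %s (%s): matches=%d type1=%d type2=%d\n",
              x$annotator_a, x$annotator_b,
              paste(x$category, collapse = ","),
              x$matches, x$type1_mismatches, x$type2_mismatches))
  invisible(x)
}

#' Inter-annotator agreement F score
#'
#' F score = (2 x matches) / (2 x matches + mismatches) x 100%, where
#' mismatches = type-1 + type-2. This is the harmonic-mean F1 of one
#' annotator's assertions against the other's, expressed as a percentage;
#' no chance correction is applied. When no assertion was made by either
#' annotator the category was not observed and `NA` is returned (rendered
#' as an em dash in reports).
#'
#' @param counts An `agreement_counts` object, or a list/vector with
#'   elements `matches`, `type1_mismatches`, `type2_mismatches`.
#' @return Percentage in \[0, 100\], or `NA` if all counts are zero.
#' @examples
#' f_score(list(matches = 3, type1_mismatches = 1, type2_mismatches = 1)) # 75
#' @export
f_score <- function(counts) {
  m <- counts[["matches"]]
  mm <- counts[["type1_mismatches"]] + counts[["type2_mismatches"]]
  stopifnot(m >= 0, mm >= 0)
  if (m + mm == 0) return(NA_real_)
  100 * 2 * m / (2 * m + mm)
}

#' Per-category and overall agreement report for annotator pairs
#'
#' For each annotator pair, computes the per-category F score for all 22
#' scheme categories plus a micro-averaged overall row (counts pooled
#' across categories, including `no_evidence`, then one application of the
#' F formula). Categories asserted by neither annotator are `NA`
#' ("not observed").
#'
#' @param corpus An `annotated_corpus`.
#' @param pairs A list of length-2 character vectors of annotator ids;
#'   default: all unordered pairs of non-GOLD annotators.
#' @return A tibble with one row per category (plus `"overall"` first) and
#'   one column per pair (named `"A1/A2"` etc.).
#' @export
agreement_report <- function(corpus, pairs = NULL) {
  if (is.null(pairs)) {
    ids <- setdiff(annotators(corpus), "GOLD")
    if (length(ids) < 2L) stop("need at least two annotators", call. = FALSE)
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
  }
  cats <- sad_scheme()$category
  out <- tibble::tibble(category = c("overall", cats))
  for (p in pairs) {
    col <- vapply(c(list("ALL"), as.list(cats)), function(cc) {
      f_score(pair_counts(corpus, p[1L], p[2L], cc))
    }, numeric(1))
    out[[paste(p, collapse = "/")]] <- col
  }
  out
}

#' Format an agreement report for export
#'
#' Rounds scores to whole percentages and renders not-observed cells as an
#' em dash, mirroring the usual tabular presentation.
#'
#' @param report Output of [agreement_report()].
#' @return A character data frame.
#' @export
format_agreement_report <- function(report) {
  out <- report
  for (nm in setdiff(names(out), "category")) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), "—", sprintf("%.0f", v))
  }
  out
}

#' Adjudicate a pair's disagreements with a third annotator
#'
#' Tweets where the two primary annotators agree (identical assertion sets)
#' pass through as gold; tweets where they disagree are resolved to the
#' adjudicator's labels. A disagreement for which the adjudicator supplied
#' no label is an error. Three-way disagreements (adjudicator's labels
#' match neither annotator) are still resolved to the adjudicator but
#' recorded in the `unresolved_majority` attribute of the result.
#'
#' @param corpus An `annotated_corpus`.
#' @param pair Character vector of the two primary annotator ids.
#' @param adjudicator Annotator id of the adjudicator.
#' @return An `annotated_corpus` equal to the input with `GOLD` annotations
#'   added for every tweet the pair co-annotated.
#' @export
adjudicate <- function(corpus, pair, adjudicator) {
  stopifnot(length(pair) == 2L)
  if (has_gold(corpus)) stop("corpus already has GOLD annotations", call. = FALSE)
  a <- annotations_of(corpus, pair[1L])
  b <- annotations_of(corpus, pair[2L])
  c_ <- annotations_of(corpus, adjudicator)
  shared <- intersect(unique(a$tweet_id), unique(b$tweet_id))
  if (length(shared) == 0L) stop("empty comparison set", call. = FALSE)
  la <- split(a$category, a$tweet_id)
  lb <- split(b$category, b$tweet_id)
  lc <- split(c_$category, c_$tweet_id)
  gold <- vector("list", length(shared))
  unresolved <- character()
  missing_adj <- character()
  for (i in seq_along(shared)) {
    id <- shared[i]
    sa <- sort(la[[id]]); sb <- sort(lb[[id]])
    if (identical(sa, sb)) {
      gold[[i]] <- data.frame(tweet_id = id, annotator_id = "GOLD",
                              category = sa, stringsAsFactors = FALSE)
    } else {
      sc <- sort(lc[[id]])
      if (length(sc) == 0L) { missing_adj <- c(missing_adj, id); next }
      if (!identical(sc, sa) && !identical(sc, sb)) unresolved <- c(unresolved, id)
      gold[[i]] <- data.frame(tweet_id = id, annotator_id = "GOLD",
                              category = sc, stringsAsFactors = FALSE)
    }
  }
  if (length(missing_adj) > 0L) {
    stop("disagreement without adjudicator label for tweet(s): ",
         paste(missing_adj, collapse = ", "), call. = FALSE)
  }
  out <- corpus(corpus$tweets,
                rbind(corpus$annotations, do.call(rbind, gold)))
  attr(out, "unresolved_majority") <- unresolved
  out
}

#' Corpus size arithmetic for a phased annotation campaign
#'
#' The campaign model: phase 1, all annotators co-annotate a common pilot
#' set; phase 2, each of the three annotator pairs independently annotates
#' its own block, with the third annotator adjudicating; phase 3, each of
#' the three annotators independently annotates a further block, and an
#' overlap subset (drawn from tweets already counted) is re-annotated by
#' all three for reliability. Unique corpus size is therefore
#' `n_phase1 + 3 * n_phase2_per_pair + 3 * n_phase3_per_annotator`; the
#' overlap adds annotations, not tweets.
#'
#' @param n_phase1 Tweets in the common pilot set.
#' @param n_phase2_per_pair Tweets per annotator pair in phase 2.
#' @param n_phase3_per_annotator Tweets per annotator in phase 3.
#' @param n_overlap Re-annotated overlap tweets (no effect on the total).
#' @return A list with the phase sizes and `total_unique_tweets`.
#' @examples
#' phase_plan(300, 300, 2700, 1200)$total_unique_tweets # 9300
#' @export
phase_plan <- function(n_phase1, n_phase2_per_pair, n_phase3_per_annotator,
                       n_overlap = 0) {
  stopifnot(n_phase1 >= 0, n_phase2_per_pair >= 0,
            n_phase3_per_annotator >= 0, n_overlap >= 0)
  list(n_phase1 = n_phase1,
       n_phase2 = 3 * n_phase2_per_pair,
       n_phase3 = 3 * n_phase3_per_annotator,
       n_overlap = n_overlap,
       total_unique_tweets =
         n_phase1 + 3 * n_phase2_per_pair + 3 * n_phase3_per_annotator)
}
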