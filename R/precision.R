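#' The five keyword-precision bins
#'
#' Printed integer ranges (0-19%, 20-39%, 40-59%, 60-79%, 80-100%) realized
#' as half-open real intervals at 20/40/60/80 (the last closed at 100), so
#' fractional precisions are classifiable.
#'
#' @return Tibble with columns `bin`, `label`, `lower`, `upper`.
#' @export
precision_bins <- function() {
  tibble::tibble(
    bin = 1:5,
    label = c("zero-to-poor", "poor-to-low", "low-to-moderate",
              "moderate-to-high", "high-to-excellent"),
    lower = c(0, 20, 40, 60, 80),
    upper = c(20, 40, 60, 80, 100))
}

#' Classify a precision percentage into its bin
#'
#' @param p Precision percentage(s) in \[0, 100\].
#' @return Factor of bin labels (levels in bin order).
#' @examples
#' bin_precision(25) # poor-to-low
#' @export
bin_precision <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 100)) {
    stop("precision must be in [0, 100]", call. = FALSE)
  }
  bins <- precision_bins()
  idx <- pmin(findInterval(p, bins$lower), 5L)
  factor(bins$label[idx], levels = bins$label)
}

#' Per-keyword retrieval precision against gold labels
#'
#' For each lexicon pattern, `tweet_hits` counts the distinct tweets it
#' matches (a pattern matching one tweet at several token positions counts
#' once), `relevant_hits` counts the matched tweets whose gold labels
#' include at least one category other than `no_evidence`, and precision is
#' `100 * relevant_hits / tweet_hits`. Patterns matching no tweet are
#' reported separately in the `not_found` attribute, mirroring the
#' found / not-found split of a keyword audit.
#'
#' @param corpus An `annotated_corpus` with `GOLD` annotations.
#' @param lexicon A `lexicon`; defaults to the packaged lexicon.
#' @param hits Optional precomputed output of [find_hits()] for `corpus`.
#' @return A `keyword_precision` tibble (pattern, tweet_hits,
#'   relevant_hits, precision, bin), in lexicon order over distinct
#'   patterns, with attributes `not_found` (unmatched patterns) and
#'   `n_patterns` (distinct patterns in the lexicon).
#' @export
keyword_precision <- function(corpus, lexicon = load_lexicon(), hits = NULL) {
  assert_gold(corpus)
  if (is.null(hits)) hits <- find_hits(corpus, lexicon)
  gold <- annotations_of(corpus, "GOLD")
  relevant_ids <- unique(gold$tweet_id[gold$category != no_evidence_label()])
  hits <- hits[!duplicated(paste(hits$tweet_id, hits$pattern)), ]
  pats <- unique(lexicon$pattern)
  tw_hits <- vapply(pats, function(p) sum(hits$pattern == p), integer(1))
  rel_hits <- vapply(pats, function(p) {
    sum(hits$pattern == p & hits$tweet_id %in% relevant_ids)
  }, integer(1))
  found <- tw_hits > 0L
  out <- tibble::tibble(
    pattern = pats[found],
    tweet_hits = unname(tw_hits[found]),
    relevant_hits = unname(rel_hits[found]),
    precision = 100 * unname(rel_hits[found] / tw_hits[found]))
  out$bin <- bin_precision(out$precision)
  attr(out, "not_found") <- pats[!found]
  attr(out, "n_patterns") <- length(pats)
  class(out) <- c("keyword_precision", class(out))
  out
}

#' Tweet-hit distribution by precision bin
#'
#' Aggregates nonmutually exclusive tweet hits over precision bins: the
#' count for a bin is the sum of `tweet_hits` of the keywords falling in
#' it, and proportions are over total hits (a tweet matched by k distinct
#' keywords contributes k hits to the denominator).
#'
#' @param precisions Output of [keyword_precision()] (non-empty).
#' @return Tibble with one row per bin: `bin`, `n_keywords`, `tweet_hits`,
#'   `proportion` (in percent).
#' @export
hit_distribution <- function(precisions) {
  if (nrow(precisions) == 0L) {
    stop("empty precision list: no keyword matched any tweet", call. = FALSE)
  }
  bins <- precision_bins()$label
  counts <- vapply(bins, function(b) {
    sum(precisions$tweet_hits[precisions$bin == b])
  }, numeric(1))
  nk <- vapply(bins, function(b) sum(precisions$bin == b), integer(1))
  tibble::tibble(bin = factor(bins, levels = bins),
                 n_keywords = nk,
                 tweet_hits = counts,
                 proportion = 100 * counts / sum(counts))
}

#' Bar chart of the tweet-hit distribution by precision bin
#'
#' @param distribution Output of [hit_distribution()].
#' @param path Output image path (`.png` or `.svg` by extension).
#' @return `path`, invisibly.
#' @export
plot_hit_distribution <- function(distribution, path) {
  open_device(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(9, 4, 2, 1))
  graphics::barplot(distribution$proportion,
                    names.arg = as.character(distribution$bin),
                    las = 2, col = "grey25",
                    ylab = "share of tweet hits (%)",
                    main = "Tweet hits by keyword precision bin")
  invisible(path)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported image extension: ", ext, call. = FALSE))
}
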