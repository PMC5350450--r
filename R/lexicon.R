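#' Load a keyword lexicon
#'
#' Reads a two-column tab-separated lexicon file (`block_label<TAB>pattern`,
#' UTF-8, `#` comment lines). A trailing `*` on a pattern marks a LIWC-style
#' prefix wildcard; all other patterns are literal whole-token keywords. The
#' packaged default is the 110-keyword depression lexicon: the LIWC "sad"
#' category list augmented with clinician-selected keywords, organised in
#' blocks (one block per keyword-bearing scheme category plus the LIWC "sad"
#' block).
#'
#' Patterns may repeat across blocks (the packaged file carries `neglect*`
#' both under problems with the primary support group and under the LIWC
#' "sad" block), but a duplicate within one block is a parse error, as are
#' embedded whitespace and a non-terminal `*`.
#'
#' @param path Path to a lexicon TSV. `NULL` (default) loads the packaged
#'   lexicon.
#' @param assume_divorc_wildcard The source table prints `divorc` without a
#'   star, which under whole-token semantics matches almost nothing. The
#'   default keeps it verbatim; `TRUE` treats it as the wildcard `divorc*`.
#' @return A tibble of class `lexicon` with columns `block_label`, `stem`,
#'   `wildcard` and `pattern` (the rendered printed form), in file order.
#' @examples
#' lex <- load_lexicon()
#' nrow(lex)            # 110 entries
#' unique_patterns(lex) # 109 distinct patterns
#' @export
load_lexicon <- function(path = NULL, assume_divorc_wildcard = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "liwc_depression_lexicon.tsv",
                        package = "depsignal", mustWork = TRUE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(new_lexicon(tibble::tibble(block_label = character(),
                                      stem = character(),
                                      wildcard = logical(),
                                      pattern = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  if (any(n_col != 2L)) {
    bad <- lineno[which(n_col != 2L)[1L]]
    stop(sprintf("lexicon parse error at line %d: expected 2 tab-separated columns", bad),
         call. = FALSE)
  }
  block <- trimws(vapply(parts, `[[`, "", 1L))
  pat <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(grepl("\\s", pat))) {
    bad <- lineno[which(grepl("\\s", pat))[1L]]
    stop(sprintf("lexicon parse error at line %d: pattern contains whitespace", bad),
         call. = FALSE)
  }
  wildcard <- grepl("\\*$", pat)
  stem <- sub("\\*$", "", pat)
  if (any(grepl("\\*", stem))) {
    bad <- lineno[which(grepl("\\*", stem))[1L]]
    stop(sprintf("lexicon parse error at line %d: '*' only allowed as final character", bad),
         call. = FALSE)
  }
  if (any(!nzchar(stem))) {
    bad <- lineno[which(!nzchar(stem))[1L]]
    stop(sprintf("lexicon parse error at line %d: empty pattern stem", bad),
         call. = FALSE)
  }
  if (assume_divorc_wildcard) {
    wildcard[stem == "divorc" & !wildcard] <- TRUE
  }
  dup <- duplicated(paste(block, stem, wildcard))
  if (any(dup)) {
    bad <- lineno[which(dup)[1L]]
    stop(sprintf("lexicon parse error at line %d: duplicate pattern within block '%s'",
                 bad, block[which(dup)[1L]]), call. = FALSE)
  }
  new_lexicon(tibble::tibble(block_label = block, stem = tolower(stem),
                             wildcard = wildcard,
                             pattern = render_pattern(tolower(stem), wildcard)))
}

new_lexicon <- function(tbl) {
  class(tbl) <- c("lexicon", class(tbl))
  tbl
}

#' Render a keyword pattern in its printed form
#'
#' @param stem Lowercase pattern stem(s).
#' @param wildcard Logical: append the `*` wildcard marker.
#' @return Character vector, e.g. `"jitter*"`.
#' @export
render_pattern <- function(stem, wildcard) {
  paste0(stem, ifelse(wildcard, "*", ""))
}

#' Count distinct patterns in a lexicon
#'
#' Cross-block duplicates (the packaged lexicon repeats `neglect*`) are
#' counted once here, whereas `nrow()` counts lexicon rows.
#'
#' @param lexicon A `lexicon`.
#' @return Integer count of distinct rendered patterns.
#' @export
unique_patterns <- function(lexicon) {
  length(unique(lexicon$pattern))
}

#' Match a keyword pattern against a normalized token
#'
#' Wildcard patterns match any token that starts with the stem; literal
#' patterns require whole-token equality (inflections such as `loses` and
#' `losing` are separate lexicon entries, so `lose` does not match them).
#' Inputs are assumed lowercase (see [tokenize()]).
#'
#' @param pattern Pattern(s) in printed form (`"jitter*"`, `"lose"`), or a
#'   `lexicon` row subset whose `pattern` column is used.
#' @param token Token(s) to test. `pattern` and `token` are recycled to a
#'   common length.
#' @return Logical vector.
#' @examples
#' match_token("jitter*", "jittery")  # TRUE
#' match_token("lose", "loses")       # FALSE
#' @export
match_token <- function(pattern, token) {
  if (inherits(pattern, "lexicon")) pattern <- pattern$pattern
  n <- max(length(pattern), length(token))
  pattern <- rep_len(as.character(pattern), n)
  token <- rep_len(as.character(token), n)
  wildcard <- grepl("\\*$", pattern)
  stem <- sub("\\*$", "", pattern)
  ifelse(wildcard, startsWith(token, stem), token == stem)
}

#' Find all keyword hits in a corpus
#'
#' Tokenizes each tweet (see [tokenize()]) and reports every
#' (pattern, token) match. A tweet may yield multiple hits — from several
#' patterns, or from one pattern at several token positions; hits are
#' nonmutually exclusive. Deduplication to one hit per (tweet, pattern) is
#' performed downstream by [keyword_precision()].
#'
#' @param corpus An `annotated_corpus` (see [corpus()]), or a character
#'   vector of tweet texts (ids are taken from names, or invented).
#' @param lexicon A `lexicon`; defaults to the packaged lexicon.
#' @return A tibble with columns `tweet_id`, `pattern`, `token`,
#'   `token_index` (0-based), ordered by tweet, token position, then
#'   lexicon order.
#' @examples
#' find_hits(c(t1 = "I'm so depressed because I got fired today"))
#' @export
find_hits <- function(corpus, lexicon = load_lexicon()) {
  if (is.character(corpus)) {
    ids <- names(corpus)
    if (is.null(ids)) ids <- paste0("t", seq_along(corpus))
    tweets <- tibble::tibble(tweet_id = ids, text = unname(corpus))
  } else {
    stopifnot(inherits(corpus, "annotated_corpus"))
    tweets <- corpus$tweets
  }
  empty <- tibble::tibble(tweet_id = character(), pattern = character(),
                          token = character(), token_index = integer())
  if (nrow(tweets) == 0L) return(empty)
  toks <- lapply(tweets$text, tokenize_text)
  flat <- tibble::tibble(
    tweet_id = rep(tweets$tweet_id, lengths(toks)),
    token = unlist(toks, use.names = FALSE),
    token_index = unlist(lapply(lengths(toks), function(k) seq_len(k) - 1L),
                         use.names = FALSE))
  if (nrow(flat) == 0L || nrow(lexicon) == 0L) return(empty)
  # match the (small) unique-token vocabulary against each pattern once
  u <- unique(flat$token)
  pats <- unique(lexicon[, c("stem", "wildcard", "pattern")])
  hit_map <- lapply(seq_len(nrow(pats)), function(i) {
    m <- if (pats$wildcard[i]) startsWith(u, pats$stem[i]) else u == pats$stem[i]
    if (!any(m)) return(NULL)
    data.frame(token = u[m], pattern = pats$pattern[i],
               pat_order = i, stringsAsFactors = FALSE)
  })
  hit_map <- do.call(rbind, hit_map)
  if (is.null(hit_map)) return(empty)
  hits <- merge(flat, hit_map, by = "token")
  hits <- hits[order(match(hits$tweet_id, tweets$tweet_id),
                     hits$token_index, hits$pat_order), ]
  tibble::tibble(tweet_id = hits$tweet_id, pattern = hits$pattern,
                 token = hits$token, token_index = hits$token_index)
}
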