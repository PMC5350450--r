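#' Construct an annotated tweet corpus
#'
#' The central container: a set of short texts plus zero or more
#' (annotator, category) labels per text. Annotator ids are free strings
#' (conventionally `A1`, `A2`, `A3`); the reserved id `GOLD` carries
#' adjudicated reference labels. Categories must come from [sad_scheme()].
#'
#' Validity rules: tweet ids are unique and texts non-empty; every
#' annotation references an existing tweet and a scheme category; duplicate
#' (tweet, annotator, category) triples are rejected; and for any annotator
#' the `no_evidence` label is mutually exclusive with every other label on
#' the same tweet. Annotations are stored in canonical order (tweet order,
#' then annotator, then scheme order), so two corpora with the same content
#' compare identical regardless of input record order.
#'
#' @param tweets A data frame with columns `tweet_id`, `text`, and
#'   optionally `source` (defaults to `"synthetic"`).
#' @param annotations A data frame with columns `tweet_id`, `annotator_id`,
#'   `category`; may be empty.
#' @return An object of class `annotated_corpus`: a list with tibbles
#'   `tweets` and `annotations`.
#' @export
corpus <- function(tweets, annotations = NULL) {
  tweets <- tibble::as_tibble(tweets)
  stopifnot(all(c("tweet_id", "text") %in% names(tweets)))
  tweets$tweet_id <- as.character(tweets$tweet_id)
  tweets$text <- as.character(tweets$text)
  if (!"source" %in% names(tweets)) tweets$source <- "synthetic"
  tweets <- tweets[, c("tweet_id", "text", "source")]
  if (anyDuplicated(tweets$tweet_id)) {
    stop("duplicate tweet_id: ",
         tweets$tweet_id[duplicated(tweets$tweet_id)][1L], call. = FALSE)
  }
  if (any(!nzchar(tweets$text))) stop("tweet text must be non-empty", call. = FALSE)
  if (is.null(annotations)) {
    annotations <- tibble::tibble(tweet_id = character(),
                                  annotator_id = character(),
                                  category = character())
  }
  annotations <- tibble::as_tibble(annotations)
  stopifnot(all(c("tweet_id", "annotator_id", "category") %in% names(annotations)))
  annotations <- annotations[, c("tweet_id", "annotator_id", "category")]
  annotations[] <- lapply(annotations, as.character)
  assert_known_categories(annotations$category)
  orphan <- setdiff(annotations$tweet_id, tweets$tweet_id)
  if (length(orphan) > 0L) {
    stop("annotation references unknown tweet_id: ", orphan[1L], call. = FALSE)
  }
  key <- paste(annotations$tweet_id, annotations$annotator_id,
               annotations$category)
  if (anyDuplicated(key)) {
    stop("duplicate (tweet, annotator, category) annotation: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  ta <- paste(annotations$tweet_id, annotations$annotator_id)
  noe <- annotations$category == no_evidence_label()
  mixed <- intersect(ta[noe], ta[!noe])
  if (length(mixed) > 0L) {
    stop("no_evidence combined with another category for (tweet annotator): ",
         mixed[1L], call. = FALSE)
  }
  ord <- order(match(annotations$tweet_id, tweets$tweet_id),
               annotations$annotator_id,
               match(annotations$category, sad_scheme()$category))
  annotations <- annotations[ord, ]
  structure(list(tweets = tweets, annotations = annotations),
            class = "annotated_corpus")
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat(sprintf("<annotated_corpus> %d tweets, %d annotations, %d annotator(s)\n",
              nrow(x$tweets), nrow(x$annotations),
              length(annotators(x))))
  if (length(annotators(x)) > 0L) {
    cat("  annotators:", paste(annotators(x), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotator ids present in a corpus
#' @param corpus An `annotated_corpus`.
#' @return Sorted character vector of annotator ids.
#' @export
annotators <- function(corpus) {
  sort(unique(corpus$annotations$annotator_id))
}

#' Annotations of a single annotator
#'
#' @param corpus An `annotated_corpus`.
#' @param annotator_id Annotator id, e.g. `"A1"` or `"GOLD"`.
#' @return Tibble of (tweet_id, annotator_id, category) rows.
#' @export
annotations_of <- function(corpus, annotator_id) {
  corpus$annotations[corpus$annotations$annotator_id == annotator_id, ]
}

has_gold <- function(corpus) "GOLD" %in% corpus$annotations$annotator_id

assert_gold <- function(corpus) {
  if (!has_gold(corpus)) {
    stop("corpus has no GOLD annotations; adjudicate or generate them first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a corpus from a JSON-lines file
#'
#' One JSON object per line with fields `id`, `text`, optional `source`, and
#' `labels`, a map from annotator id to an array of category ids. Lines
#' starting with `#` are skipped. An annotator mapped to an empty array is
#' interpreted, when `infer_no_evidence` is on, as an explicit
#' `no_evidence` assertion (an annotator who looked and found nothing).
#'
#' @param path File path.
#' @param infer_no_evidence Replace empty label arrays by `no_evidence`
#'   (default `TRUE`).
#' @return An `annotated_corpus`.
#' @export
read_corpus <- function(path, infer_no_evidence = TRUE) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  tweets <- vector("list", length(lines))
  anns <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("corpus parse error at line %d: %s",
                                   lineno[i], conditionMessage(e)), call. = FALSE)
                    })
    if (is.null(rec$id) || is.null(rec$text)) {
      stop(sprintf("corpus parse error at line %d: missing id or text", lineno[i]),
           call. = FALSE)
    }
    tweets[[i]] <- data.frame(
      tweet_id = as.character(rec$id), text = as.character(rec$text),
      source = if (is.null(rec$source)) "synthetic" else as.character(rec$source),
      stringsAsFactors = FALSE)
    labels <- rec$labels
    if (length(labels) > 0L) {
      rows <- lapply(names(labels), function(ann) {
        cats <- as.character(unlist(labels[[ann]]))
        if (length(cats) == 0L) {
          if (!infer_no_evidence) return(NULL)
          cats <- no_evidence_label()
        }
        bad <- setdiff(cats, sad_scheme()$category)
        if (length(bad) > 0L) {
          stop(sprintf("corpus parse error at line %d: unknown category '%s'",
                       lineno[i], bad[1L]), call. = FALSE)
        }
        data.frame(tweet_id = as.character(rec$id), annotator_id = ann,
                   category = cats, stringsAsFactors = FALSE)
      })
      anns[[i]] <- do.call(rbind, rows)
    }
  }
  tw <- do.call(rbind, tweets)
  if (is.null(tw)) {
    tw <- data.frame(tweet_id = character(), text = character(),
                     source = character(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tw$tweet_id)) {
    stop("duplicate tweet_id in corpus file: ",
         tw$tweet_id[duplicated(tw$tweet_id)][1L], call. = FALSE)
  }
  corpus(tw, do.call(rbind, anns))
}

#' Write a corpus to a JSON-lines file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` recovers
#' `x` exactly, including unicode text. An empty corpus yields a file with
#' only the header comment.
#'
#' @param corpus An `annotated_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotated_corpus"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# depsignal annotated corpus (JSON lines)", con, useBytes = TRUE)
  if (nrow(corpus$tweets) == 0L) return(invisible(path))
  ann <- corpus$annotations
  lines <- vapply(seq_len(nrow(corpus$tweets)), function(i) {
    id <- corpus$tweets$tweet_id[i]
    rows <- ann[ann$tweet_id == id, ]
    labels <- lapply(split(rows$category, rows$annotator_id), as.list)
    jsonlite::toJSON(list(id = id, text = corpus$tweets$text[i],
                          source = corpus$tweets$source[i],
                          labels = labels),
                     auto_unbox = TRUE)
  }, "")
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Flat annotation triples
#'
#' @param corpus An `annotated_corpus`.
#' @return Tibble of (tweet_id, annotator_id, category) rows, suitable for
#'   CSV export.
#' @export
flat_annotations <- function(corpus) {
  corpus$annotations
}
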