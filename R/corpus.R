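#' Annotated sentences
#'
#' The corpus unit: a sentence string plus its gold (head, relation, tail)
#' triples with exact character offsets.
#'
#' @param text sentence string.
#' @param triples list of [triple()] objects.
#' @return An `annotated_sentence`.
#' @export
annotated_sentence <- function(text, triples = list()) {
  n <- nchars_of(text)
  for (tr in triples) {
    for (sp in list(tr$head, tr$tail)) {
      if (sp$end > n) stop("span [", sp$start, ",", sp$end,
                           ") beyond text length ", n)
      got <- char_slice(text, sp$start, sp$end)
      if (!identical(got, sp$text)) {
        stop("span text mismatch: annotation says \"", sp$text,
             "\" but text slice is \"", got, "\"")
      }
    }
  }
  structure(list(text = text, triples = triples),
            class = "annotated_sentence")
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(x$text, "\n")
  for (tr in x$triples) cat("  ", format(tr), "\n")
  invisible(x)
}

#' Read a relation schema
#'
#' @param path JSON file holding an array of relation label strings.
#' @return character vector of relation labels.
#' @export
read_relation_schema <- function(path) {
  rel <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.character(rel) || length(rel) == 0L || anyDuplicated(rel)) {
    stop("relation schema must be a non-empty array of unique strings")
  }
  rel
}

#' The default wheat-variety relation schema
#'
#' The 23 attribute relations used by the bundled synthetic variety-report
#' generator (growth period, plant height, unit weight, crude protein
#' content, ...).
#'
#' @return character vector of 23 relation labels.
#' @export
default_relation_schema <- function() {
  read_relation_schema(system.file("extdata", "relations_wheat.json",
                                   package = "lextriple", mustWork = TRUE))
}

span_to_list <- function(sp) {
  list(start = sp$start, end = sp$end, text = sp$text)
}

span_from_list <- function(x) span(x$start, x$end, x$text, is_text = TRUE)

#' Read / write span-annotated corpora as JSONL
#'
#' One JSON object per line:
#' `{"text": ..., "triples": [{"head": {"start", "end", "text"},
#' "relation": ..., "tail": {...}}]}` with 0-based half-open character
#' offsets. Reading validates every span against the sentence text and,
#' when a schema is supplied, every relation against it; errors name the
#' offending line.
#'
#' @param path JSONL file path.
#' @param schema optional character vector of allowed relation labels.
#' @return `read_corpus_jsonl`: list of [annotated_sentence()];
#'   `write_corpus_jsonl`: `path`, invisibly.
#' @export
read_corpus_jsonl <- function(path, schema = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("line ", i, ": malformed JSON (", conditionMessage(e), ")"))
    trs <- lapply(rec$triples %||% list(), function(t) {
      if (!is.null(schema) && !(t$relation %in% schema)) {
        stop("line ", i, ": unknown relation '", t$relation, "'")
      }
      triple(span_from_list(t$head), t$relation, span_from_list(t$tail))
    })
    out[[i]] <- tryCatch(annotated_sentence(rec$text, trs),
                         error = function(e)
                           stop("line ", i, ": ", conditionMessage(e)))
  }
  out
}

#' @rdname read_corpus_jsonl
#' @param sentences list of [annotated_sentence()].
#' @export
write_corpus_jsonl <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    rec <- list(text = s$text,
                triples = lapply(s$triples, function(t)
                  list(head = span_to_list(t$head), relation = t$relation,
                       tail = span_to_list(t$tail))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Convert doccano-style exports
#'
#' Accepts the doccano relation-extraction JSONL dialect
#' (`{"text", "entities": [{"id", "start_offset", "end_offset", ...}],
#' "relations": [{"from_id", "to_id", "type"}]}`) and converts it to
#' [annotated_sentence()] records.
#'
#' @param path doccano JSONL export.
#' @param schema optional allowed relation labels.
#' @return list of [annotated_sentence()].
#' @export
read_doccano_jsonl <- function(path, schema = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    ents <- list()
    for (e in rec$entities %||% list()) {
      ents[[as.character(e$id)]] <-
        span(e$start_offset, e$end_offset, rec$text)
    }
    trs <- lapply(rec$relations %||% list(), function(r) {
      h <- ents[[as.character(r$from_id)]]
      t <- ents[[as.character(r$to_id)]]
      if (is.null(h) || is.null(t)) {
        stop("line ", i, ": relation references unknown entity id")
      }
      if (!is.null(schema) && !(r$type %in% schema)) {
        stop("line ", i, ": unknown relation '", r$type, "'")
      }
      triple(h, r$type, t)
    })
    out[[i]] <- annotated_sentence(rec$text, trs)
  }
  out
}

# ---- "01" pointer labels ------------------------------------------------

#' Convert gold spans to pointer ("01") labels and back
#'
#' `spans_to_labels` marks, for every gold span, a 1 at its first
#' character in the start sequence and a 1 at its last character in the
#' end sequence (all other positions 0). Head labels pool all gold heads;
#' tail labels are kept per gold head and per relation, which is what the
#' cascade trains against. `labels_to_spans` inverts the scheme by
#' proximity decoding; the round trip recovers the original annotation
#' whenever gold spans do not conflict inside a shared label sequence.
#'
#' @param sentence an [annotated_sentence()].
#' @param relations relation label vector fixing the column order of the
#'   tail matrices; defaults to the sorted relations present.
#' @return A `pointer_labels` object: `n`, `relations`, `head_start`,
#'   `head_end` (integer 0/1 vectors), `heads` (list of head [span()]s),
#'   `tail_start`, `tail_end` (per head, n x R integer matrices).
#' @export
spans_to_labels <- function(sentence, relations = NULL) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  n <- nchars_of(sentence$text)
  if (is.null(relations)) {
    relations <- sort(unique(vapply(sentence$triples, function(t) t$relation,
                                    character(1L))))
  }
  head_start <- integer(n)
  head_end <- integer(n)
  heads <- list()
  keys <- character()
  tail_start <- list()
  tail_end <- list()
  for (tr in sentence$triples) {
    h <- tr$head
    head_start[h$start + 1L] <- 1L
    head_end[h$end] <- 1L
    k <- paste(h$start, h$end, sep = ":")
    if (!(k %in% keys)) {
      keys <- c(keys, k)
      heads[[length(heads) + 1L]] <- h
      tail_start[[length(heads)]] <-
        matrix(0L, n, length(relations), dimnames = list(NULL, relations))
      tail_end[[length(heads)]] <-
        matrix(0L, n, length(relations), dimnames = list(NULL, relations))
    }
    ki <- match(k, keys)
    r <- match(tr$relation, relations)
    if (is.na(r)) stop("relation '", tr$relation, "' not in schema")
    tail_start[[ki]][tr$tail$start + 1L, r] <- 1L
    tail_end[[ki]][tr$tail$end, r] <- 1L
  }
  structure(list(n = n, relations = relations,
                 head_start = head_start, head_end = head_end,
                 heads = heads, tail_start = tail_start,
                 tail_end = tail_end),
            class = "pointer_labels")
}

#' @rdname spans_to_labels
#' @param labels a `pointer_labels` object.
#' @param text the sentence string the labels refer to.
#' @export
labels_to_spans <- function(labels, text) {
  stopifnot(inherits(labels, "pointer_labels"))
  if (nchars_of(text) != labels$n) {
    stop("label length ", labels$n, " does not match text length ",
         nchars_of(text))
  }
  triples <- list()
  for (ki in seq_along(labels$heads)) {
    h <- labels$heads[[ki]]
    for (r in seq_along(labels$relations)) {
      tails <- decode_spans_proximity(labels$tail_start[[ki]][, r],
                                      labels$tail_end[[ki]][, r], text)
      for (tl in tails) {
        triples[[length(triples) + 1L]] <-
          triple(h, labels$relations[r], tl)
      }
    }
  }
  annotated_sentence(text, triples)
}
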