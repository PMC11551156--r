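#' Word-vector tables and per-character candidate-word matching
#'
#' A `word_vector_table` maps word strings to fixed-dimension real vectors.
#' It backs the candidate-word matching step of the character-word fusion
#' encoder: for every character of a sentence, the lexicon words that occur
#' in the sentence over that character are retrieved, and their vectors are
#' injected into the character stream by an attention mechanism
#' (see [word_attention_fuse()]).
#'
#' @param words character vector of unique, non-empty word strings.
#' @param vectors numeric matrix with one row per word.
#' @return An object of class `word_vector_table` with fields `words`
#'   (character vector), `vectors` (matrix, rows aligned with `words`),
#'   `dim` (vector dimensionality) and a hashed index for O(1) lookup.
#' @examples
#' tab <- word_vector_table(c("wheat", "grain"), rbind(c(1, 0, 0), c(0, 1, 0)))
#' lookup_word(tab, "wheat")
#' @export
word_vector_table <- function(words, vectors) {
  words <- as.character(words)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = length(words))
  storage.mode(vectors) <- "double"
  if (length(words) != nrow(vectors)) {
    stop("need one vector per word: ", length(words), " words vs ",
         nrow(vectors), " vectors")
  }
  if (anyDuplicated(words)) {
    stop("duplicate words in table: ",
         paste(unique(words[duplicated(words)])[1:3], collapse = ", "))
  }
  if (any(!nzchar(words))) stop("empty word strings are not allowed")
  check_finite(vectors, "word vectors")
  index <- new.env(parent = emptyenv(), size = max(29L, length(words)))
  for (i in seq_along(words)) assign(words[i], i, envir = index)
  structure(
    list(words = words, vectors = vectors, dim = ncol(vectors), index = index),
    class = "word_vector_table"
  )
}

#' @export
print.word_vector_table <- function(x, ...) {
  cat("word_vector_table:", length(x$words), "words, dim", x$dim, "\n")
  invisible(x)
}

#' @export
length.word_vector_table <- function(x) length(x$words)

#' Look up a word's vector
#'
#' Returns `NULL` when the word is absent, so absence is distinguishable
#' from a stored all-zero vector.
#'
#' @param table a [word_vector_table()].
#' @param word a single word string.
#' @return The word's numeric vector, or `NULL` if absent.
#' @export
lookup_word <- function(table, word) {
  stopifnot(inherits(table, "word_vector_table"))
  i <- get0(word, envir = table$index, inherits = FALSE)
  if (is.null(i)) NULL else table$vectors[i, ]
}

#' Read a word-vector table in word2vec text format
#'
#' The file starts with a header line `"<count> <dim>"` followed by one line
#' per word: the word then `dim` space-separated floats. UTF-8 throughout.
#'
#' @param path path to the file.
#' @param expected_dim if given, the file's dimensionality must equal it.
#' @return A [word_vector_table()].
#' @export
read_word_vectors <- function(path, expected_dim = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty word-vector file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed word2vec header at line 1: '", lines[1L], "'")
  }
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  if (!is.null(expected_dim) && d != expected_dim) {
    stop("word-vector dimensionality ", d, " does not match expected ",
         expected_dim)
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("header declares ", n, " vectors but file has ", length(body))
  }
  parts <- strsplit(body, " ", fixed = TRUE)
  words <- character(n)
  vecs <- matrix(0, n, d)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    p <- p[nzchar(p)]
    if (length(p) != d + 1L) {
      stop("ragged row at line ", i + 1L, ": expected ", d + 1L,
           " fields, got ", length(p))
    }
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v)) stop("non-numeric vector components at line ", i + 1L)
    words[i] <- p[1L]
    vecs[i, ] <- v
  }
  if (anyDuplicated(words)) {
    bad <- which(duplicated(words))[1L]
    stop("duplicate word '", words[bad], "' at line ", bad + 1L)
  }
  word_vector_table(words, vecs)
}

#' Write a word-vector table in word2vec text format
#'
#' @param table a [word_vector_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(table, path) {
  stopifnot(inherits(table, "word_vector_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(table$words), table$dim), con)
  rows <- apply(table$vectors, 1L, function(v)
    paste(formatC(v, format = "g", digits = 17), collapse = " "))
  writeLines(paste(table$words, rows), con)
  invisible(path)
}

#' Match candidate lexicon words for every character of a sentence
#'
#' For each character position the lexicon words that occur in the sentence
#' as a contiguous substring covering that position (up to `max_word_len`
#' characters long) are collected. When more than `m` words match, the `m`
#' longest are kept (ties broken by earlier occurrence start, then
#' lexicographically); when fewer match, positions are padded with `PAD`
#' entries carrying the all-zeros vector, so every position holds exactly
#' `m` candidate entries.
#'
#' @param sentence a single string.
#' @param table a [word_vector_table()].
#' @param m number of candidate slots per character (default 3, the value
#'   at which the padded-slot interference/coverage trade-off is best).
#' @param max_word_len longest lexicon word considered (characters).
#' @return An object of class `char_word_matches`: `words` (n x m character
#'   matrix, `NA` for PAD), `is_pad` (n x m logical), `vectors`
#'   ((n*m) x dim matrix, rows grouped by position, zero rows for PAD),
#'   `m`, `dim`, `chars`.
#' @export
match_candidate_words <- function(sentence, table, m = 3L, max_word_len = 8L) {
  stopifnot(inherits(table, "word_vector_table"))
  if (!is.numeric(m) || m < 1) stop("m must be a positive integer")
  m <- as.integer(m)
  ch <- chars_of(sentence)
  n <- length(ch)
  if (n == 0L) stop("sentence must be non-empty")

  # candidate occurrences per position: word index, length, start
  hits <- vector("list", n)
  for (start in seq_len(n)) {
    maxlen <- min(max_word_len, n - start + 1L)
    for (len in seq_len(maxlen)) {
      w <- paste(ch[start:(start + len - 1L)], collapse = "")
      wi <- get0(w, envir = table$index, inherits = FALSE)
      if (!is.null(wi)) {
        for (pos in start:(start + len - 1L)) {
          hits[[pos]] <- c(hits[[pos]], wi, len, start)
        }
      }
    }
  }

  words <- matrix(NA_character_, n, m)
  is_pad <- matrix(TRUE, n, m)
  vecs <- matrix(0, n * m, table$dim)
  for (i in seq_len(n)) {
    h <- hits[[i]]
    if (is.null(h)) next
    h <- matrix(h, ncol = 3L, byrow = TRUE)  # wi, len, start
    # earliest covering occurrence per distinct word
    ord <- order(h[, 1L], h[, 3L])
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(h[, 1L]), , drop = FALSE]
    w <- table$words[h[, 1L]]
    keep <- order(-h[, 2L], h[, 3L], w)[seq_len(min(m, nrow(h)))]
    for (j in seq_along(keep)) {
      k <- keep[j]
      words[i, j] <- w[k]
      is_pad[i, j] <- FALSE
      vecs[(i - 1L) * m + j, ] <- table$vectors[h[k, 1L], ]
    }
  }
  structure(
    list(words = words, is_pad = is_pad, vectors = vecs,
         m = m, dim = table$dim, chars = ch),
    class = "char_word_matches"
  )
}

#' @export
print.char_word_matches <- function(x, ...) {
  cat("char_word_matches:", length(x$chars), "positions, m =", x$m, "\n")
  nshow <- min(length(x$chars), 10L)
  for (i in seq_len(nshow)) {
    w <- x$words[i, ]
    w[is.na(w)] <- "PAD"
    cat(sprintf("  %2d %s: %s\n", i, x$chars[i], paste(w, collapse = ", ")))
  }
  if (length(x$chars) > nshow) cat("  ...\n")
  invisible(x)
}

# Truncate matches to the first n_keep positions (sentence truncation).
truncate_matches <- function(matches, n_keep) {
  n <- length(matches$chars)
  if (n_keep >= n) return(matches)
  m <- matches$m
  matches$words <- matches$words[seq_len(n_keep), , drop = FALSE]
  matches$is_pad <- matches$is_pad[seq_len(n_keep), , drop = FALSE]
  matches$vectors <- matches$vectors[seq_len(n_keep * m), , drop = FALSE]
  matches$chars <- matches$chars[seq_len(n_keep)]
  matches
}

#' Generate a random word-vector table
#'
#' Utility for tests and synthetic corpora: assigns unit-normalised
#' Gaussian random vectors to a vocabulary.
#'
#' @param words character vector of words.
#' @param dim vector dimensionality (default 200).
#' @param seed RNG seed.
#' @return A [word_vector_table()].
#' @export
random_word_vectors <- function(words, dim = 200L, seed = 1L) {
  words <- unique(as.character(words))
  set.seed(seed)
  v <- matrix(stats::rnorm(length(words) * dim), length(words), dim)
  v <- v / sqrt(rowSums(v^2))
  word_vector_table(words, v)
}
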