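#' Spans and triples
#'
#' Spans use 0-based half-open character offsets `[start, end)`; the
#' pointer ("01") label scheme marks the span's first character in the
#' start sequence and its last character in the end sequence.
#'
#' @param start 0-based start offset.
#' @param end exclusive end offset.
#' @param text the sentence the span indexes into, or the span text itself
#'   when `is_text = TRUE`.
#' @param is_text interpret `text` as the span's own text.
#' @return A `span` object (list with `start`, `end`, `text`).
#' @export
span <- function(start, end, text, is_text = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start) stop("invalid span [", start, ", ", end, ")")
  txt <- if (is_text) text else char_slice(text, start, end)
  structure(list(start = start, end = end, text = txt), class = "span")
}

#' @export
format.span <- function(x, ...) {
  sprintf("[%d,%d) \"%s\"", x$start, x$end, x$text)
}

#' @export
print.span <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @rdname span
#' @param head,tail [span()] objects.
#' @param relation relation label string.
#' @export
triple <- function(head, relation, tail) {
  stopifnot(inherits(head, "span"), inherits(tail, "span"),
            is.character(relation), length(relation) == 1L)
  structure(list(head = head, relation = relation, tail = tail),
            class = "triple")
}

#' @export
format.triple <- function(x, ...) {
  sprintf("(%s, %s, %s)", x$head$text, x$relation, x$tail$text)
}

#' @export
print.triple <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

triple_key <- function(tr) {
  paste(tr$head$start, tr$head$end, tr$relation, tr$tail$start, tr$tail$end,
        sep = "|")
}

# ---- pointer scoring ----------------------------------------------------

init_pointer_params <- function(d, relations) {
  r <- length(relations)
  list(head_w_start = stats::rnorm(d, sd = 1 / sqrt(d)), head_b_start = 0,
       head_w_end = stats::rnorm(d, sd = 1 / sqrt(d)), head_b_end = 0,
       tail_W_start = rnorm_mat(d, r), tail_b_start = numeric(r),
       tail_W_end = rnorm_mat(d, r), tail_b_end = numeric(r))
}

#' Head-entity start/end pointer probabilities
#'
#' Per-position sigmoid scores `p_i = sigmoid(w' M2_i + b)` for being the
#' start or the end of a head entity.
#'
#' @param M2 n x d matrix of encoded character vectors.
#' @param params pointer parameter list (fields `head_w_start`,
#'   `head_b_start`, `head_w_end`, `head_b_end`).
#' @return list with numeric vectors `start` and `end`, each length n,
#'   values in (0, 1).
#' @export
head_pointer_probs <- function(M2, params) {
  check_finite(M2, "M2")
  list(start = sigmoid(drop(M2 %*% params$head_w_start) + params$head_b_start),
       end = sigmoid(drop(M2 %*% params$head_w_end) + params$head_b_end))
}

#' Subject representation of a head span
#'
#' The candidate head entity is summarised as the arithmetic mean of the
#' encoded vectors over its character positions; this vector is added to
#' every position before tail tagging.
#'
#' @param M2 n x d encoded matrix.
#' @param head a [span()].
#' @return numeric d-vector.
#' @export
subject_rep <- function(M2, head) {
  rows <- (head$start + 1L):head$end
  if (head$start < 0L || head$end > nrow(M2)) {
    stop("span outside encoded sentence")
  }
  colMeans(M2[rows, , drop = FALSE])
}

#' Relation-specific tail start/end probabilities given a subject
#'
#' For every relation r the subject vector is added to each position and
#' scored with that relation's own start/end affine maps:
#' `p_i = sigmoid(w_r' (M2_i + v_sub) + b_r)`.
#'
#' @param M2 n x d encoded matrix.
#' @param v_sub subject d-vector from [subject_rep()].
#' @param params pointer parameter list (fields `tail_W_start` (d x R),
#'   `tail_b_start`, `tail_W_end`, `tail_b_end`).
#' @param relations character vector of relation labels (columns of the
#'   tail parameter matrices).
#' @return list with `start` and `end`: n x R matrices of probabilities,
#'   columns named by relation.
#' @export
tail_pointer_probs <- function(M2, v_sub, params, relations) {
  if (length(relations) == 0L) stop("relation schema is empty")
  S <- add_bias(M2, v_sub)
  ps <- sigmoid(add_bias(S %*% params$tail_W_start, params$tail_b_start))
  pe <- sigmoid(add_bias(S %*% params$tail_W_end, params$tail_b_end))
  colnames(ps) <- relations
  colnames(pe) <- relations
  list(start = ps, end = pe)
}

#' Threshold pointer probabilities into 0/1 labels
#'
#' @param probs numeric vector/matrix of probabilities in `[0, 1]`.
#' @param threshold detection threshold in (0, 1); a position is labelled
#'   1 iff its probability strictly exceeds the threshold.
#' @return integer 0/1 object of the same shape.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)")
  }
  out <- ifelse(probs > threshold, 1L, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Decode spans from 0/1 start/end labels by the principle of proximity
#'
#' Each start position pairs with the nearest end position at or after it;
#' starts with no following end are dropped, and one end may serve several
#' starts. With starts at "Zhong", "8", "1" and ends at "9", "L", "%" this
#' yields three candidate entities, the start at "8" pairing with the
#' following "L".
#'
#' @param start_labels,end_labels equal-length integer 0/1 vectors.
#' @param text optional sentence string used to fill span texts.
#' @return list of [span()] objects (with `text = NA` when no sentence is
#'   supplied).
#' @export
decode_spans_proximity <- function(start_labels, end_labels, text = NULL) {
  stopifnot(length(start_labels) == length(end_labels))
  starts <- which(start_labels == 1L)
  ends <- which(end_labels == 1L)
  chs <- if (!is.null(text)) chars_of(text) else NULL
  out <- list()
  for (s in starts) {
    e <- ends[ends >= s]
    if (length(e) == 0L) next
    e <- e[1L]
    txt <- if (!is.null(chs)) paste(chs[s:e], collapse = "") else NA_character_
    out[[length(out) + 1L]] <- span(s - 1L, e, txt, is_text = TRUE)
  }
  out
}

#' Extract triples from an encoded sentence with the cascading pointers
#'
#' Heads are decoded first from the head pointer labels; then, conditioned
#' on each decoded head's subject vector, tail spans are decoded per
#' relation and every (head, relation, tail) combination is emitted. The
#' result is duplicate-free. Because tails are tagged separately for each
#' relation conditioned on the head, a single head span can participate in
#' many triples (overlapping relations).
#'
#' @param text the sentence string.
#' @param M2 its encoded n x d matrix.
#' @param params pointer parameter list.
#' @param relations relation labels.
#' @param threshold detection threshold (default 0.5).
#' @return list of [triple()] objects.
#' @export
extract_triples <- function(text, M2, params, relations, threshold = 0.5) {
  hp <- head_pointer_probs(M2, params)
  heads <- decode_spans_proximity(binarize(hp$start, threshold),
                                  binarize(hp$end, threshold), text)
  out <- list()
  seen <- character()
  for (h in heads) {
    v <- subject_rep(M2, h)
    tp <- tail_pointer_probs(M2, v, params, relations)
    ts <- binarize(tp$start, threshold)
    te <- binarize(tp$end, threshold)
    for (r in seq_along(relations)) {
      tails <- decode_spans_proximity(ts[, r], te[, r], text)
      for (tl in tails) {
        tr <- triple(h, relations[r], tl)
        k <- triple_key(tr)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          out[[length(out) + 1L]] <- tr
        }
      }
    }
  }
  out
}
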