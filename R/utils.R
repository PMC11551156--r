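# Small numeric / text helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax, numerically stabilised.
softmax_rows <- function(x) {
  rmax <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - rmax)
  e / rowSums(e)
}

# X + b broadcast over rows (column-major: b[j] fills column j).
add_bias <- function(X, b) X + rep(b, each = nrow(X))

# Split a string into its Unicode characters.
chars_of <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  strsplit(enc2utf8(text), "", fixed = FALSE)[[1L]]
}

# Character count (not bytes).
nchars_of <- function(text) length(chars_of(text))

# Substring by 0-based half-open character offsets.
char_slice <- function(text, start, end) {
  ch <- chars_of(text)
  if (start < 0 || end > length(ch) || start >= end) {
    stop("invalid span [", start, ", ", end, ") for text of length ",
         length(ch))
  }
  paste(ch[(start + 1L):end], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(x)
}
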