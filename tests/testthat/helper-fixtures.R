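# Shared fixtures, built in code.

# A tiny word-vector table over explicit words.
toy_table <- function(words, dim = 4L, seed = 1L) {
  random_word_vectors(words, dim = dim, seed = seed)
}

# The worked overlapping-relations sentence: one variety head carrying a
# unit-weight tail and a crude-protein tail.
overlap_example_sentence <- function() {
  text <- "Zhongmai 159, rongzhong 827 g/L, cudanbai 14.8%."
  head <- span(0, 12, text)                 # "Zhongmai 159"
  tail1 <- span(24, 31, text)               # "827 g/L"
  tail2 <- span(42, 47, text)               # "14.8%"
  annotated_sentence(text, list(
    triple(head, "Unit weight", tail1),
    triple(head, "Crude protein content", tail2)
  ))
}

# Small trained-from-scratch model over a generated corpus.
tiny_setup <- function(n_sentences = 8L, seed = 5L, hidden_dim = 16L,
                       layers = 2L, num_heads = 2L, word_dim = 16L, ...) {
  corp <- generate_corpus(synth_config(n_sentences = n_sentences,
                                       seed = seed, lexicon_size = 60L,
                                       word_dim = word_dim))
  cfg <- encoder_config(layers = layers, hidden_dim = hidden_dim,
                        num_heads = num_heads, word_dim = word_dim,
                        seed = seed, ...)
  model <- new_model(cfg, corp$schema, corp$lexicon,
                     c(corp$train, corp$dev, corp$test))
  list(corpus = corp, model = model)
}

# Brute-force candidate matcher: every window of every length is tested
# against the lexicon; per position the full (untruncated) word set.
oracle_match_sets <- function(sentence, words, max_word_len = 8L) {
  ch <- strsplit(sentence, "")[[1]]
  n <- length(ch)
  sets <- replicate(n, character(0), simplify = FALSE)
  for (s in seq_len(n)) {
    for (len in seq_len(min(max_word_len, n - s + 1L))) {
      w <- paste(ch[s:(s + len - 1L)], collapse = "")
      if (w %in% words) {
        for (pos in s:(s + len - 1L)) {
          sets[[pos]] <- union(sets[[pos]], w)
        }
      }
    }
  }
  sets
}

# Exhaustive nearest-end span pairing: for each start, minimise e - s
# over all ends e >= s.
oracle_decode <- function(start_labels, end_labels) {
  out <- list()
  for (s in which(start_labels == 1L)) {
    es <- which(end_labels == 1L)
    es <- es[es >= s]
    if (length(es) == 0L) next
    e <- es[which.min(es - s)]
    out[[length(out) + 1L]] <- c(start = s - 1L, end = e)
  }
  out
}
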