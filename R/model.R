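#' Build a triple-extraction model
#'
#' Assembles the lexicon-fused encoder and the cascading pointer network
#' into one trainable model. The character vocabulary is collected from
#' the supplied corpus (an `<unk>` slot covers unseen characters at
#' prediction time); weights are initialised from `config$seed`.
#'
#' @param config an [encoder_config()].
#' @param relations relation label vector (the schema; one tail
#'   start/end tagger pair per relation).
#' @param lexicon a [word_vector_table()] backing candidate-word matching;
#'   its dimensionality must equal `config$word_dim`.
#' @param corpus list of [annotated_sentence()] (or plain strings) the
#'   character vocabulary is built from.
#' @return An object of class `lextriple_model`.
#' @export
new_model <- function(config, relations, lexicon, corpus) {
  stopifnot(inherits(config, "encoder_config"),
            inherits(lexicon, "word_vector_table"))
  if (length(relations) == 0L) stop("relation schema is empty")
  if (lexicon$dim != config$word_dim) {
    stop("lexicon dimensionality ", lexicon$dim,
         " does not match config word_dim ", config$word_dim)
  }
  texts <- vapply(corpus, function(s)
    if (inherits(s, "annotated_sentence")) s$text else s, character(1L))
  vocab <- c("<unk>", sort(unique(unlist(lapply(texts, chars_of)))))
  set.seed(config$seed)
  params <- init_encoder_params(config, length(vocab))
  names(params$layers) <- paste0("l", seq_len(config$layers))
  params$ptr <- init_pointer_params(config$hidden_dim, relations)
  structure(list(config = config, relations = relations, lexicon = lexicon,
                 vocab = vocab, params = params, log = NULL),
            class = "lextriple_model")
}

#' @export
print.lextriple_model <- function(x, ...) {
  cfg <- x$config
  cat("lextriple_model: L =", cfg$layers, "(fusion after layer",
      paste0(cfg$fusion_layer, "),"), "d_h =", cfg$hidden_dim,
      ", m =", cfg$m, "\n")
  cat("  relations:", length(x$relations),
      "| char vocab:", length(x$vocab),
      "| lexicon:", length(x$lexicon$words), "words\n")
  cat("  fusion:", if (cfg$use_fusion) "on" else "off",
      "| bilstm:", if (cfg$use_bilstm) "on" else "off", "\n")
  invisible(x)
}

char_ids <- function(model, chars) {
  i <- match(chars, model$vocab)
  i[is.na(i)] <- 1L
  i
}

# Prepare one sentence for the network: truncate, id-encode, match words.
prepare_example <- function(model, sentence) {
  cfg <- model$config
  text <- if (inherits(sentence, "annotated_sentence")) sentence$text else sentence
  ch <- chars_of(text)
  n <- min(length(ch), cfg$max_len)
  ch <- ch[seq_len(n)]
  matches <- truncate_matches(
    match_candidate_words(text, model$lexicon, cfg$m), n)
  ex <- list(text = text, n = n, ids = char_ids(model, ch),
             matches = matches)
  if (inherits(sentence, "annotated_sentence")) {
    kept <- Filter(function(t) t$head$end <= n && t$tail$end <= n,
                   sentence$triples)
    ex$labels <- spans_to_labels(annotated_sentence(text, kept),
                                 model$relations)
    # label vectors must match the truncated length
    ex$labels$head_start <- ex$labels$head_start[seq_len(n)]
    ex$labels$head_end <- ex$labels$head_end[seq_len(n)]
    ex$labels$tail_start <- lapply(ex$labels$tail_start,
                                   function(mm) mm[seq_len(n), , drop = FALSE])
    ex$labels$tail_end <- lapply(ex$labels$tail_end,
                                 function(mm) mm[seq_len(n), , drop = FALSE])
    ex$labels$n <- n
  }
  ex
}

#' Encode a sentence
#'
#' Runs the full encoder: character + position embedding, the Transformer
#' stack with attention word fusion after layer `fusion_layer`, and the
#' BiLSTM. Returns both the deep-fusion representation M1 and the
#' bidirectional representation M2 (equal when `use_bilstm` is off).
#'
#' @param model a [new_model()].
#' @param sentence string or [annotated_sentence()].
#' @return list with `M1`, `M2` (n x hidden_dim matrices) and the
#'   prepared example `ex`.
#' @export
encode_sentence <- function(model, sentence) {
  ex <- prepare_example(model, sentence)
  fw <- encoder_fwd(model$params, model$config, ex$ids, ex$matches)
  list(M1 = fw$M1, M2 = fw$M2, ex = ex, cache = fw$cache)
}

#' Predict triples for a sentence
#'
#' @param model a trained [new_model()].
#' @param text sentence string.
#' @param threshold pointer detection threshold.
#' @return list of [triple()] objects.
#' @export
predict_triples <- function(model, text, threshold = 0.5) {
  enc <- encode_sentence(model, text)
  extract_triples(substr_chars(text, enc$ex$n), enc$M2, model$params$ptr,
                  model$relations, threshold)
}

substr_chars <- function(text, n) {
  ch <- chars_of(text)
  paste(ch[seq_len(min(n, length(ch)))], collapse = "")
}

#' Save / load a model
#'
#' The model (weights, configuration, schema, vocabularies) is serialised
#' to `<dir>/model.rds`; the lexicon is additionally written as
#' `vectors.txt` and the schema as `schema.json` for interoperability.
#'
#' @param model a [new_model()].
#' @param dir target directory.
#' @return `save_model`: `dir` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lex <- model$lexicon
  model$lexicon <- list(words = lex$words, vectors = lex$vectors)
  saveRDS(model, file.path(dir, "model.rds"))
  write_word_vectors(lex, file.path(dir, "vectors.txt"))
  jsonlite::write_json(model$relations, file.path(dir, "schema.json"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  model$lexicon <- word_vector_table(model$lexicon$words,
                                     model$lexicon$vectors)
  model
}
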