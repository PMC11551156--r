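#' Exact-match triple evaluation
#'
#' A predicted triple counts as correct only when its head span, relation
#' label and tail span all exactly equal a gold triple of the same
#' sentence. With N_pred predicted, N_right correct and N_gold gold
#' triples: precision = N_right / N_pred, recall = N_right / N_gold,
#' F1 = 2PR / (P + R). Precision is defined as 0 when nothing is
#' predicted and F1 as 0 when P + R = 0.
#'
#' @param predicted list (one element per sentence) of [triple()] lists.
#' @param gold same structure with the gold triples.
#' @param by `"offsets"` matches on character offsets plus relation;
#'   `"text"` matches on span texts plus relation.
#' @return list with `precision`, `recall`, `f1` and `counts`
#'   (`n_pred`, `n_right`, `n_gold`).
#' @export
evaluate_triples <- function(predicted, gold, by = c("offsets", "text")) {
  by <- match.arg(by)
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must be sentence-aligned lists")
  }
  key <- function(tr) {
    if (by == "offsets") triple_key(tr)
    else paste(tr$head$text, tr$relation, tr$tail$text, sep = "|")
  }
  n_pred <- 0L; n_right <- 0L; n_gold <- 0L
  for (i in seq_along(predicted)) {
    pk <- unique(vapply(predicted[[i]], key, character(1L)))
    gk <- unique(vapply(gold[[i]], key, character(1L)))
    n_pred <- n_pred + length(pk)
    n_gold <- n_gold + length(gk)
    n_right <- n_right + length(intersect(pk, gk))
  }
  p <- if (n_pred == 0L) 0 else n_right / n_pred
  r <- if (n_gold == 0L) 0 else n_right / n_gold
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1,
       counts = list(n_pred = n_pred, n_right = n_right, n_gold = n_gold))
}

#' Evaluate a model on an annotated corpus
#'
#' @param model a trained model.
#' @param corpus list of [annotated_sentence()].
#' @param threshold pointer detection threshold.
#' @param by match mode, see [evaluate_triples()].
#' @return as [evaluate_triples()].
#' @export
evaluate_model <- function(model, corpus, threshold = 0.5,
                           by = c("offsets", "text")) {
  pred <- lapply(corpus, function(s) predict_triples(model, s$text, threshold))
  gold <- lapply(corpus, function(s) s$triples)
  evaluate_triples(pred, gold, by = by)
}
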