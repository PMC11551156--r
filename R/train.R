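#' Training configuration
#'
#' @param learning_rate Adam step size. The default suits the small
#'   from-scratch encoders this package trains; fine-tuning a large
#'   pretrained stack would use a much smaller rate (the full-scale
#'   preset pairs with 1e-5).
#' @param batch_size sentences per optimiser step (default 4).
#' @param epochs passes over the training set.
#' @param threshold pointer detection threshold used for evaluation
#'   during training.
#' @param seed RNG seed for shuffling and gold-subject sampling.
#' @param optimizer only `"adam"` is implemented.
#' @param clip_norm global gradient-norm clip (default 1.0).
#' @param eval_every evaluate exact-match F1 every this many epochs
#'   (0 = never).
#' @param stop_f1 stop early once the monitored F1 reaches this value
#'   (`NULL` = train for the full epoch budget).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 4L, epochs = 10L,
                         threshold = 0.5, seed = 1L, optimizer = "adam",
                         clip_norm = 1.0, eval_every = 0L, stop_f1 = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1L) stop("batch_size must be positive")
  if (epochs < 0L) stop("epochs must be non-negative")
  optimizer <- match.arg(optimizer, "adam")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), threshold = threshold,
                 seed = as.integer(seed), optimizer = optimizer,
                 clip_norm = clip_norm, eval_every = as.integer(eval_every),
                 stop_f1 = stop_f1),
            class = "train_config")
}

#' Binary cross-entropy pointer loss
#'
#' Mean binary cross-entropy between predicted pointer probabilities and
#' gold 0/1 labels, over however many label sequences are supplied
#' (head start/end plus the per-relation tail start/end sequences of the
#' sampled gold subject).
#'
#' @param probs numeric vector/matrix/list of probabilities in (0, 1).
#' @param labels matching 0/1 structure.
#' @param eps clamp applied inside the logs.
#' @return non-negative scalar.
#' @export
pointer_loss <- function(probs, labels, eps = 1e-12) {
  p <- unlist(probs, use.names = FALSE)
  y <- unlist(labels, use.names = FALSE)
  if (length(p) != length(y)) {
    stop("probability/label shape mismatch: ", length(p), " vs ", length(y))
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Forward + loss + full backward for one sentence. Returns flat grads.
# The gold subject for tail supervision is sampled uniformly among the
# sentence's gold heads (teacher forcing).
sentence_grad <- function(params, cfg, ex, relations) {
  lb <- ex$labels
  n <- ex$n
  nr <- length(relations)
  fw <- encoder_fwd(params, cfg, ex$ids, ex$matches)
  M2 <- fw$M2
  ptr <- params$ptr

  hs_logit <- drop(M2 %*% ptr$head_w_start) + ptr$head_b_start
  he_logit <- drop(M2 %*% ptr$head_w_end) + ptr$head_b_end
  ps <- sigmoid(hs_logit)
  pe <- sigmoid(he_logit)

  k <- if (length(lb$heads) > 1L) sample.int(length(lb$heads), 1L) else 1L
  head_k <- lb$heads[[k]]
  v <- subject_rep(M2, head_k)
  S <- add_bias(M2, v)
  ts_logit <- add_bias(S %*% ptr$tail_W_start, ptr$tail_b_start)
  te_logit <- add_bias(S %*% ptr$tail_W_end, ptr$tail_b_end)
  tps <- sigmoid(ts_logit)
  tpe <- sigmoid(te_logit)

  ys <- lb$head_start; ye <- lb$head_end
  Ys <- lb$tail_start[[k]]; Ye <- lb$tail_end[[k]]
  # objective: per-position mean BCE for the head taggers, plus
  # per-position mean of the relation-summed BCE for the tail taggers --
  # the sum over relations keeps the sparse tail positives from being
  # drowned by the |schema| * n negatives
  loss <- pointer_loss(list(ps, pe), list(ys, ye)) +
    nr * pointer_loss(list(tps, tpe), list(Ys, Ye))

  dhs <- (ps - ys) / (2 * n)
  dhe <- (pe - ye) / (2 * n)
  dts <- (tps - Ys) / (2 * n)
  dte <- (tpe - Ye) / (2 * n)

  gr_ptr <- list(
    head_w_start = drop(crossprod(M2, dhs)), head_b_start = sum(dhs),
    head_w_end = drop(crossprod(M2, dhe)), head_b_end = sum(dhe),
    tail_W_start = crossprod(S, dts), tail_b_start = colSums(dts),
    tail_W_end = crossprod(S, dte), tail_b_end = colSums(dte))

  dM2 <- outer(dhs, ptr$head_w_start) + outer(dhe, ptr$head_w_end)
  dS <- dts %*% t(ptr$tail_W_start) + dte %*% t(ptr$tail_W_end)
  dM2 <- dM2 + dS
  dv <- colSums(dS)
  rows <- (head_k$start + 1L):head_k$end
  dM2[rows, ] <- dM2[rows, ] +
    matrix(dv / length(rows), length(rows), length(dv), byrow = TRUE)

  grads <- encoder_bwd(dM2, fw$cache)
  grads$ptr <- gr_ptr
  list(loss = loss, grads = flatten_params(grads))
}

add_flat <- function(a, b) {
  for (k in names(b)) {
    a[[k]] <- if (is.null(a[[k]])) b[[k]] else a[[k]] + b[[k]]
  }
  a
}

#' Train a model
#'
#' Optimises all encoder and pointer parameters with Adam on the pointer
#' binary cross-entropy. Head pointers are supervised on all gold heads
#' of a sentence; tail pointers are supervised for one gold head sampled
#' uniformly per visit (teacher forcing), which over epochs covers all
#' heads. Deterministic for a fixed seed.
#'
#' @param model a [new_model()].
#' @param corpus list of [annotated_sentence()] with at least one triple.
#' @param config a [train_config()].
#' @param dev optional held-out sentences monitored (exact-match F1)
#'   every `eval_every` epochs; when absent the training set is
#'   monitored.
#' @param quiet suppress per-epoch messages.
#' @return The trained model; `$log` holds a data.frame with per-epoch
#'   mean loss and any monitored F1 (NA when not evaluated).
#' @export
train_model <- function(model, corpus, config = train_config(), dev = NULL,
                        quiet = TRUE) {
  stopifnot(inherits(model, "lextriple_model"),
            inherits(config, "train_config"))
  if (length(corpus) == 0L) stop("training corpus is empty")
  n_triples <- sum(vapply(corpus, function(s) length(s$triples), integer(1L)))
  if (n_triples == 0L) stop("training corpus contains no gold triples")

  cfg <- model$config
  exs <- lapply(corpus, function(s) prepare_example(model, s))
  exs <- Filter(function(e) length(e$labels$heads) > 0L, exs)
  if (length(exs) == 0L) stop("no sentence retained a gold head after truncation")

  set.seed(config$seed)
  flat <- flatten_params(model$params)
  state <- adam_state(flat)
  log_loss <- numeric(0)
  log_f1 <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(exs))
    batch_losses <- numeric(0)
    i <- 1L
    while (i <= length(ord)) {
      take <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      acc <- list()
      bl <- 0
      for (j in take) {
        sg <- sentence_grad(model$params, cfg, exs[[j]], model$relations)
        acc <- add_flat(acc, sg$grads)
        bl <- bl + sg$loss
      }
      acc <- lapply(acc, function(g) g / length(take))
      upd <- adam_step(flat, acc, state, lr = config$learning_rate,
                       clip_norm = config$clip_norm)
      flat <- upd$params
      state <- upd$state
      model$params <- assign_flat(model$params, flat)
      batch_losses <- c(batch_losses, bl / length(take))
      i <- i + config$batch_size
    }
    log_loss[epoch] <- mean(batch_losses)
    f1 <- NA_real_
    if (config$eval_every > 0L && epoch %% config$eval_every == 0L) {
      monitor <- dev %||% corpus
      pred <- lapply(monitor, function(s)
        predict_triples(model, s$text, config$threshold))
      gold <- lapply(monitor, function(s) s$triples)
      f1 <- evaluate_triples(pred, gold)$f1
    }
    log_f1[epoch] <- f1
    if (!quiet) {
      message(sprintf("epoch %d  loss %.5f%s", epoch, log_loss[epoch],
                      if (is.na(f1)) "" else sprintf("  f1 %.3f", f1)))
    }
    if (!is.null(config$stop_f1) && !is.na(f1) && f1 >= config$stop_f1) break
  }
  model$log <- data.frame(epoch = seq_along(log_loss), loss = log_loss,
                          f1 = log_f1)
  model
}
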