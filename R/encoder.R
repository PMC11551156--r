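#' Encoder configuration
#'
#' The encoder embeds characters, runs `fusion_layer` Transformer encoder
#' blocks, injects attention-weighted candidate-word vectors at every
#' position (deep character-word fusion), runs the remaining
#' `layers - fusion_layer` blocks to produce the fused representation M1,
#' and finally a bidirectional LSTM produces the contextual representation
#' M2 used by the pointer taggers.
#'
#' @param layers total number of Transformer encoder blocks (L).
#' @param fusion_layer block after which word fusion is applied (N, in
#'   `[1, layers]`). Fusing after the first block gives the deepest
#'   character-word interaction; `fusion_layer = layers` is the shallow
#'   encode-then-fuse-once variant.
#' @param hidden_dim character-stream width d_h; must be divisible by
#'   `num_heads` and by 2 (the BiLSTM runs d_h/2 per direction).
#' @param ff_dim feed-forward inner width (default `2 * hidden_dim`).
#' @param num_heads attention heads per block.
#' @param word_dim lexicon vector dimensionality (default 200).
#' @param m candidate-word slots per character (default 3).
#' @param max_len maximum sentence length in characters; longer input is
#'   truncated (default 256).
#' @param use_fusion disable to skip word fusion entirely (ablation).
#' @param use_bilstm disable to set M2 := M1 (ablation).
#' @param mask_pad when `TRUE`, PAD candidate slots are masked out of the
#'   fusion softmax; by default they participate with a zero vector.
#' @param seed seed for weight initialisation.
#' @param preset `"full"` applies the full-scale preset (12 layers, width
#'   768, 12 heads, max_len 256, m 3, word_dim 200); explicit arguments
#'   still override it.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(layers = 2L, fusion_layer = 1L, hidden_dim = 64L,
                           ff_dim = NULL, num_heads = 4L, word_dim = 200L,
                           m = 3L, max_len = 256L, use_fusion = TRUE,
                           use_bilstm = TRUE, mask_pad = FALSE, seed = 1L,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "full")
    defaults <- list(layers = 12L, fusion_layer = 1L, hidden_dim = 768L,
                     num_heads = 12L, word_dim = 200L, m = 3L,
                     max_len = 256L)
    given <- names(match.call())[-1L]
    for (nm in names(defaults)) {
      if (!(nm %in% given)) assign(nm, defaults[[nm]])
    }
  }
  cfg <- list(layers = as.integer(layers),
              fusion_layer = as.integer(fusion_layer),
              hidden_dim = as.integer(hidden_dim),
              ff_dim = as.integer(ff_dim %||% (2L * hidden_dim)),
              num_heads = as.integer(num_heads),
              word_dim = as.integer(word_dim),
              m = as.integer(m),
              max_len = as.integer(max_len),
              use_fusion = isTRUE(use_fusion),
              use_bilstm = isTRUE(use_bilstm),
              mask_pad = isTRUE(mask_pad),
              seed = as.integer(seed))
  validate_encoder_config(cfg)
  structure(cfg, class = "encoder_config")
}

validate_encoder_config <- function(cfg) {
  with(cfg, {
    if (layers < 1L) stop("layers must be >= 1")
    if (fusion_layer < 1L || fusion_layer > layers) {
      stop("fusion_layer must lie in [1, layers]; got ", fusion_layer,
           " with layers = ", layers)
    }
    if (hidden_dim %% num_heads != 0L) {
      stop("hidden_dim must be divisible by num_heads")
    }
    if (hidden_dim %% 2L != 0L) stop("hidden_dim must be even")
    if (max_len < 1L) stop("max_len must be >= 1")
    if (m < 1L) stop("m must be >= 1")
  })
  invisible(cfg)
}

#' Read an encoder/training configuration from YAML or JSON
#'
#' Recognised keys: `layers`, `fusion_layer`, `hidden_dim`, `ff_dim`,
#' `heads`, `word_dim`, `m`, `max_len`, `use_fusion`, `use_bilstm`,
#' `mask_pad`, `seed`, `preset`, plus the training keys consumed by
#' [train_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A named list with `$encoder` ([encoder_config()]) and `$train`
#'   ([train_config()]).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  enc_keys <- c(layers = "layers", fusion_layer = "fusion_layer",
                hidden_dim = "hidden_dim", ff_dim = "ff_dim",
                num_heads = "heads", word_dim = "word_dim", m = "m",
                max_len = "max_len", use_fusion = "use_fusion",
                use_bilstm = "use_bilstm", mask_pad = "mask_pad",
                seed = "seed", preset = "preset")
  enc_args <- list()
  for (nm in names(enc_keys)) {
    v <- raw[[enc_keys[[nm]]]]
    if (!is.null(v)) enc_args[[nm]] <- v
  }
  tr_keys <- c("learning_rate", "batch_size", "epochs", "threshold", "seed",
               "optimizer", "clip_norm", "eval_every", "stop_f1")
  tr_args <- raw[names(raw) %in% tr_keys]
  list(encoder = do.call(encoder_config, enc_args),
       train = do.call(train_config, tr_args))
}

# ---- model parameters ---------------------------------------------------

init_encoder_params <- function(cfg, vocab_size) {
  d <- cfg$hidden_dim
  p <- list(
    char_emb = rnorm_mat(vocab_size, d),
    pos_emb = rnorm_mat(cfg$max_len, d),
    emb_ln_g = rep(1, d), emb_ln_b = numeric(d),
    fuse_Wattn = rnorm_mat(d, d, sd = 1 / sqrt(d)),
    fuse_proj = rnorm_mat(cfg$word_dim, d, sd = 1 / sqrt(cfg$word_dim))
  )
  p$layers <- lapply(seq_len(cfg$layers), function(i)
    init_transformer_layer(d, cfg$ff_dim))
  p$bilstm <- init_bilstm(d)
  p
}

#' Attention-weighted fusion of one character vector with its candidates
#'
#' Computes attention logits `z W c_j^T` between a character vector and its
#' `m` candidate-word vectors, softmax-normalises them, and adds the
#' weighted candidate sum to the character vector:
#' `fused = z + sum_j a_j c_j`.
#'
#' @param char_vec numeric d-vector (character representation z).
#' @param candidate_vecs m x d matrix of candidate vectors (already
#'   projected to width d; PAD rows are zero).
#' @param W_attn d x d bilinear attention weight matrix.
#' @param mask logical m-vector; `TRUE` entries are excluded from the
#'   softmax (used for PAD masking). Default: none masked.
#' @return list with `fused` (d-vector) and `weights` (m-vector summing
#'   to 1, zeros where masked).
#' @export
word_attention_fuse <- function(char_vec, candidate_vecs, W_attn,
                                mask = NULL) {
  if (!is.matrix(candidate_vecs)) candidate_vecs <- rbind(candidate_vecs)
  check_finite(char_vec, "char_vec")
  check_finite(candidate_vecs, "candidate_vecs")
  logits <- drop(candidate_vecs %*% crossprod(W_attn, char_vec))
  if (!is.null(mask) && any(mask)) logits[mask] <- -Inf
  if (all(!is.finite(logits))) {
    w <- numeric(length(logits))
  } else {
    e <- exp(logits - max(logits[is.finite(logits)]))
    e[!is.finite(logits)] <- 0
    w <- e / sum(e)
  }
  w <- unname(w)
  list(fused = unname(char_vec + drop(w %*% candidate_vecs)), weights = w)
}

# Vectorised fusion over all positions. X: n x d; matches carry raw
# (n*m) x d_w candidate vectors, projected here so the projection trains.
fuse_fwd <- function(X, matches, params, mask_pad = FALSE) {
  n <- nrow(X)
  m <- matches$m
  grp <- rep(seq_len(n), each = m)
  Cp <- matches$vectors %*% params$fuse_proj
  ZW <- X %*% params$fuse_Wattn
  logits <- matrix(rowSums(ZW[grp, , drop = FALSE] * Cp), n, m, byrow = TRUE)
  if (mask_pad) logits[matches$is_pad] <- -Inf
  A <- softmax_rows(logits)
  A[!is.finite(A)] <- 0  # rows where every slot is masked
  Avec <- as.vector(t(A))
  ctilde <- rowsum(Cp * Avec, grp)
  dimnames(ctilde) <- NULL
  list(out = X + ctilde,
       cache = list(X = X, Cp = Cp, ZW = ZW, A = A, grp = grp, m = m,
                    Wattn = params$fuse_Wattn, Vraw = matches$vectors))
}

fuse_bwd <- function(dout, cache) {
  n <- nrow(dout)
  grp <- cache$grp
  Drep <- dout[grp, , drop = FALSE]
  dA <- matrix(rowSums(Drep * cache$Cp), n, cache$m, byrow = TRUE)
  dCp <- as.vector(t(cache$A)) * Drep
  dlog <- cache$A * (dA - rowSums(dA * cache$A))
  dlogvec <- as.vector(t(dlog))
  dZW <- rowsum(cache$Cp * dlogvec, grp)
  dCp <- dCp + dlogvec * cache$ZW[grp, , drop = FALSE]
  dX <- dout + dZW %*% t(cache$Wattn)
  list(dX = dX,
       dWattn = crossprod(cache$X, dZW),
       dproj = crossprod(cache$Vraw, dCp))
}

# ---- full encoder forward/backward -------------------------------------

# ids: integer character ids (1-based into char_emb); matches aligned.
encoder_fwd <- function(params, cfg, ids, matches) {
  n <- length(ids)
  E <- params$char_emb[ids, , drop = FALSE] +
    params$pos_emb[seq_len(n), , drop = FALSE]
  ln <- layernorm_fwd(E, params$emb_ln_g, params$emb_ln_b)
  X <- ln$out
  layer_caches <- vector("list", cfg$layers)
  fuse_cache <- NULL
  for (l in seq_len(cfg$layers)) {
    step <- transformer_layer_fwd(X, params$layers[[l]], cfg$num_heads)
    layer_caches[[l]] <- step$cache
    X <- step$out
    if (l == cfg$fusion_layer && cfg$use_fusion) {
      fs <- fuse_fwd(X, matches, params, cfg$mask_pad)
      fuse_cache <- fs$cache
      X <- fs$out
    }
  }
  M1 <- X
  if (cfg$use_bilstm) {
    bl <- bilstm_fwd(M1, params$bilstm)
    M2 <- bl$out
    bl_cache <- bl$cache
  } else {
    M2 <- M1
    bl_cache <- NULL
  }
  list(M1 = M1, M2 = M2,
       cache = list(ids = ids, emb_ln = ln, layers = layer_caches,
                    fuse = fuse_cache, bilstm = bl_cache, cfg = cfg,
                    vocab_size = nrow(params$char_emb)))
}

encoder_bwd <- function(dM2, cache, dM1_extra = NULL) {
  cfg <- cache$cfg
  grads <- list(layers = stats::setNames(vector("list", cfg$layers),
                                         paste0("l", seq_len(cfg$layers))))
  if (cfg$use_bilstm) {
    bl <- bilstm_bwd(dM2, cache$bilstm)
    dX <- bl$dX
    grads$bilstm <- list(f_W = bl$df_W, f_b = bl$df_b, f_U = bl$df_U,
                         b_W = bl$db_W, b_b = bl$db_b, b_U = bl$db_U)
  } else {
    dX <- dM2
  }
  if (!is.null(dM1_extra)) dX <- dX + dM1_extra
  for (l in rev(seq_len(cfg$layers))) {
    if (l == cfg$fusion_layer && cfg$use_fusion) {
      fb <- fuse_bwd(dX, cache$fuse)
      dX <- fb$dX
      grads$fuse_Wattn <- fb$dWattn
      grads$fuse_proj <- fb$dproj
    }
    tb <- transformer_layer_bwd(dX, cache$layers[[l]])
    dX <- tb$dX
    g <- tb$grads
    names(g) <- sub("^d", "", names(g))
    grads$layers[[l]] <- g
  }
  lb <- layernorm_bwd(dX, cache$emb_ln$cache)
  grads$emb_ln_g <- lb$dg
  grads$emb_ln_b <- lb$db
  dE <- lb$dX
  n <- length(cache$ids)
  demb <- matrix(0, cache$vocab_size, ncol(dE))
  for (i in seq_len(n)) {
    demb[cache$ids[i], ] <- demb[cache$ids[i], ] + dE[i, ]
  }
  grads$char_emb <- demb
  dpos <- matrix(0, cfg$max_len, ncol(dE))
  dpos[seq_len(n), ] <- dE
  grads$pos_emb <- dpos
  grads
}
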