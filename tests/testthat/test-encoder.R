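test_that("equal candidates share attention weight equally", {
  z <- c(0.5, -1, 2)
  v <- c(1, 1, 0)
  C <- rbind(v, v, v)
  W <- diag(3)
  out <- word_attention_fuse(z, C, W)
  expect_equal(out$weights, rep(1 / 3, 3))
  expect_equal(out$fused, z + v)
})

test_that("attention weights always normalise to one", {
  set.seed(12)
  for (case in 1:50) {
    m <- sample(1:5, 1); d <- sample(2:6, 1)
    out <- word_attention_fuse(rnorm(d), matrix(rnorm(m * d), m, d),
                               matrix(rnorm(d * d), d, d))
    expect_equal(sum(out$weights), 1, tolerance = 1e-6)
  }
})

test_that("fusion reproduces the scalar attention oracle", {
  # d = 2, m = 2, identity bilinear form, z = (1, 0),
  # candidates (1, 0) and (0, 1): logits (1, 0)
  z <- c(1, 0)
  C <- rbind(c(1, 0), c(0, 1))
  out <- word_attention_fuse(z, C, diag(2))
  w1 <- exp(1) / (exp(1) + 1)
  w2 <- 1 / (exp(1) + 1)
  expect_equal(out$weights, c(w1, w2), tolerance = 1e-12)
  expect_equal(out$fused, c(1 + w1, w2), tolerance = 1e-12)
})

test_that("non-finite inputs are rejected", {
  expect_error(word_attention_fuse(c(NA, 1), rbind(c(1, 1)), diag(2)),
               "non-finite")
})

test_that("the encoder preserves length and width", {
  ts <- tiny_setup()
  s <- ts$corpus$train[[1]]
  enc <- encode_sentence(ts$model, s)
  n <- nchar(s$text)
  expect_equal(dim(enc$M1), c(n, ts$model$config$hidden_dim))
  expect_equal(dim(enc$M2), c(n, ts$model$config$hidden_dim))
  expect_true(all(is.finite(enc$M1)))
  expect_true(all(is.finite(enc$M2)))
  expect_error(encode_sentence(ts$model, ""), "non-empty")
})

test_that("fusing after the last layer equals encode-then-fuse-once", {
  ts <- tiny_setup(layers = 3, fusion_layer = 3)
  model <- ts$model
  s <- ts$corpus$train[[2]]
  deep <- encode_sentence(model, s)

  plain <- model
  plain$config$use_fusion <- FALSE
  M1_plain <- encode_sentence(plain, s)$M1

  ex <- lextriple:::prepare_example(model, s)
  Cp <- ex$matches$vectors %*% model$params$fuse_proj
  m <- ex$matches$m
  M1_manual <- M1_plain
  for (i in seq_len(nrow(M1_plain))) {
    rows <- ((i - 1) * m + 1):(i * m)
    M1_manual[i, ] <- word_attention_fuse(
      M1_plain[i, ], Cp[rows, , drop = FALSE],
      model$params$fuse_Wattn)$fused
  }
  expect_equal(deep$M1, M1_manual, tolerance = 1e-5)
})

test_that("encoding is deterministic for a fixed seed and config", {
  a <- tiny_setup(seed = 33)
  b <- tiny_setup(seed = 33)
  s <- a$corpus$train[[1]]
  ea <- encode_sentence(a$model, s)
  eb <- encode_sentence(b$model, s)
  expect_identical(ea$M1, eb$M1)
  expect_identical(ea$M2, eb$M2)
})

test_that("the fusion position sweep grid is accepted", {
  for (N in c(1L, 3L, 6L, 9L, 12L)) {
    cfg <- encoder_config(layers = 12L, fusion_layer = N, hidden_dim = 8L,
                          num_heads = 2L, word_dim = 6L, m = 2L)
    expect_s3_class(cfg, "encoder_config")
  }
  expect_error(encoder_config(layers = 2, fusion_layer = 3), "fusion_layer")
})

test_that("the bidirectional layer preserves length and splits directions", {
  set.seed(71)
  d <- 8L; n <- 11L
  X <- matrix(rnorm(n * d), n, d)
  p <- lextriple:::init_bilstm(d)
  out <- lextriple:::bilstm_fwd(X, p)$out
  expect_equal(dim(out), c(n, d))

  # reversing the input swaps the two directional halves (with weights
  # swapped accordingly)
  pswap <- list(f_W = p$b_W, f_U = p$b_U, f_b = p$b_b,
                b_W = p$f_W, b_U = p$f_U, b_b = p$f_b)
  out2 <- lextriple:::bilstm_fwd(X[n:1, ], pswap)$out
  h <- d %/% 2L
  expect_equal(out2[n:1, (h + 1):d], out[, 1:h], tolerance = 1e-12)
  expect_equal(out2[n:1, 1:h], out[, (h + 1):d], tolerance = 1e-12)
})

test_that("disabling the bidirectional layer passes M1 through", {
  ts <- tiny_setup(use_bilstm = FALSE)
  enc <- encode_sentence(ts$model, ts$corpus$train[[1]])
  expect_identical(enc$M2, enc$M1)
})

test_that("masking PAD slots changes only padded positions' weights", {
  tab <- toy_table(c("ab",  "abc"), dim = 5, seed = 2)
  cm <- match_candidate_words("abcd", tab, m = 3)
  expect_true(any(cm$is_pad) && any(!cm$is_pad))
  W <- diag(5)
  z <- rnorm(5)
  Cp <- cm$vectors[1:3, ]
  fused_nomask <- word_attention_fuse(z, Cp, W)
  fused_mask <- word_attention_fuse(z, Cp, W, mask = cm$is_pad[1, ])
  expect_equal(sum(fused_mask$weights), 1)
  expect_true(all(fused_mask$weights[cm$is_pad[1, ]] == 0))
  expect_true(any(fused_nomask$weights[cm$is_pad[1, ]] > 0))
})

test_that("analytic gradients match finite differences everywhere", {
  ts <- tiny_setup(n_sentences = 3, seed = 2, hidden_dim = 8, word_dim = 12,
                   num_heads = 2)
  mdl <- ts$model
  ns <- asNamespace("lextriple")
  ex <- ns$prepare_example(mdl, ts$corpus$train[[1]])
  flat <- ns$flatten_params(mdl$params)
  loss_at <- function(fl) {
    p <- ns$assign_flat(mdl$params, fl)
    set.seed(11)
    ns$sentence_grad(p, mdl$config, ex, mdl$relations)$loss
  }
  set.seed(11)
  g <- ns$sentence_grad(mdl$params, mdl$config, ex, mdl$relations)$grads
  eps <- 1e-5
  set.seed(300)
  for (key in names(flat)) {
    x <- flat[[key]]
    for (ii in sample(length(x), min(2, length(x)))) {
      fp <- flat; fp[[key]][ii] <- fp[[key]][ii] + eps
      fm <- flat; fm[[key]][ii] <- fm[[key]][ii] - eps
      num <- (loss_at(fp) - loss_at(fm)) / (2 * eps)
      ana <- if (is.null(g[[key]])) 0 else g[[key]][ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})
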