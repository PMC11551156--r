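test_that("pointer loss has the right limits and closed form", {
  eps <- 1e-6
  p <- c(1 - eps, eps, 1 - eps)
  y <- c(1L, 0L, 1L)
  expect_lte(pointer_loss(p, y), 10 * eps)
  expect_equal(pointer_loss(rep(0.5, 7), rbinom(7, 1, 0.5)), log(2))
  expect_error(pointer_loss(c(0.5, 0.5), c(1L)), "mismatch")
})

test_that("pointer loss equals the elementwise BCE oracle", {
  set.seed(44)
  for (case in 1:25) {
    n <- sample(3:40, 1)
    p <- runif(n, 0.01, 0.99)
    y <- rbinom(n, 1, 0.5)
    oracle <- -mean(ifelse(y == 1, log(p), log(1 - p)))
    expect_equal(pointer_loss(p, y), oracle, tolerance = 1e-12)
  }
})

test_that("exact-match metrics follow their defining ratios", {
  s <- overlap_example_sentence()
  gold <- list(s$triples)
  expect_equal(evaluate_triples(gold, gold),
               list(precision = 1, recall = 1, f1 = 1,
                    counts = list(n_pred = 2L, n_right = 2L, n_gold = 2L)))

  # n_pred = 4, n_right = 3, n_gold = 5
  mk <- function(i) triple(span(0, 1, "x", is_text = TRUE), paste0("r", i),
                           span(1, 2, "y", is_text = TRUE))
  gold5 <- lapply(1:5, mk)
  pred4 <- c(lapply(1:3, mk), list(mk(9)))
  res <- evaluate_triples(list(pred4), list(gold5))
  expect_equal(res$precision, 0.75)
  expect_equal(res$recall, 0.6)
  expect_equal(res$f1, 2 * 0.75 * 0.6 / 1.35)

  empty <- evaluate_triples(list(list()), list(gold5))
  expect_equal(empty$precision, 0)
  expect_equal(empty$f1, 0)
})

test_that("metrics agree with a brute-force counting oracle", {
  set.seed(55)
  rels <- paste0("r", 1:4)
  rand_triples <- function(k) {
    lapply(seq_len(k), function(i) {
      s <- sample(0:5, 1)
      t <- sample(0:5, 1)
      triple(span(s, s + sample(1:3, 1), "t", is_text = TRUE),
             sample(rels, 1),
             span(t, t + sample(1:3, 1), "t", is_text = TRUE))
    })
  }
  key <- function(t) paste(t$head$start, t$head$end, t$relation,
                           t$tail$start, t$tail$end)
  for (case in 1:50) {
    nsent <- sample(1:4, 1)
    pred <- lapply(seq_len(nsent), function(i) rand_triples(sample(0:5, 1)))
    gold <- lapply(seq_len(nsent), function(i) rand_triples(sample(0:5, 1)))
    res <- evaluate_triples(pred, gold)
    np <- nr <- ng <- 0L
    for (i in seq_len(nsent)) {
      pk <- unique(vapply(pred[[i]], key, character(1)))
      gk <- unique(vapply(gold[[i]], key, character(1)))
      np <- np + length(pk); ng <- ng + length(gk)
      nr <- nr + sum(pk %in% gk)
    }
    expect_equal(res$counts, list(n_pred = np, n_right = nr, n_gold = ng))
    if (np > 0 && ng > 0) {
      expect_equal(res$precision, nr / np)
      expect_equal(res$recall, nr / ng)
      # harmonic mean lies between precision and recall
      expect_gte(res$f1 + 1e-12, min(res$precision, res$recall) *
                   (res$precision + res$recall > 0))
      expect_lte(res$f1, max(res$precision, res$recall) + 1e-12)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  corp <- generate_corpus(synth_config(n_sentences = 25, seed = 61,
                                       word_dim = 16))
  train <- c(corp$train, corp$dev, corp$test)[1:20]
  cfg <- encoder_config(layers = 1, hidden_dim = 16, num_heads = 2,
                        word_dim = 16, seed = 61)
  first_last <- vapply(1:3, function(sd) {
    mdl <- new_model(cfg, corp$schema, corp$lexicon, train)
    mdl <- train_model(mdl, train,
                       train_config(epochs = 5, seed = sd,
                                    learning_rate = 2e-3))
    c(mdl$log$loss[1], mdl$log$loss[5])
  }, numeric(2))
  expect_lt(median(first_last[2, ]), median(first_last[1, ]))

  # same seed, same first-epoch loss; epochs = 0 keeps initial weights
  m1 <- new_model(cfg, corp$schema, corp$lexicon, train)
  a <- train_model(m1, train, train_config(epochs = 1, seed = 9))
  b <- train_model(m1, train, train_config(epochs = 1, seed = 9))
  expect_identical(a$log$loss, b$log$loss)
  z <- train_model(m1, train, train_config(epochs = 0, seed = 9))
  expect_identical(z$params, m1$params)

  no_gold <- list(annotated_sentence("plain text"))
  expect_error(train_model(m1, no_gold, train_config(epochs = 1)),
               "no gold triples")
  expect_error(train_model(m1, list(), train_config(epochs = 1)), "empty")
})

test_that("models persist through save and load", {
  ts <- tiny_setup(n_sentences = 6, seed = 13)
  dir <- withr::local_tempdir()
  save_model(ts$model, dir)
  back <- load_model(dir)
  s <- ts$corpus$train[[1]]$text
  expect_equal(predict_triples(back, s), predict_triples(ts$model, s))
  expect_true(file.exists(file.path(dir, "vectors.txt")))
  expect_true(file.exists(file.path(dir, "schema.json")))
})

test_that("configuration files round through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("layers: 2", "fusion_layer: 2", "hidden_dim: 32",
               "heads: 4", "word_dim: 24", "m: 2", "max_len: 128",
               "use_bilstm: false", "mask_pad: true", "seed: 7",
               "learning_rate: 0.002", "batch_size: 8", "epochs: 3"), f)
  cfg <- read_config(f)
  expect_equal(cfg$encoder$layers, 2L)
  expect_equal(cfg$encoder$fusion_layer, 2L)
  expect_equal(cfg$encoder$num_heads, 4L)
  expect_false(cfg$encoder$use_bilstm)
  expect_true(cfg$encoder$mask_pad)
  expect_equal(cfg$train$learning_rate, 0.002)
  expect_equal(cfg$train$batch_size, 8L)
})
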