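test_that("pointer probabilities are sigmoids of affine maps", {
  set.seed(8)
  M2 <- matrix(rnorm(12), 3, 4)
  p0 <- list(head_w_start = numeric(4), head_b_start = 0,
             head_w_end = numeric(4), head_b_end = 0)
  hp <- head_pointer_probs(M2, p0)
  expect_equal(hp$start, rep(0.5, 3))
  expect_equal(hp$end, rep(0.5, 3))

  w <- c(1, -2, 0.5, 0)
  p1 <- list(head_w_start = w, head_b_start = 0.3,
             head_w_end = -w, head_b_end = -0.1)
  hp <- head_pointer_probs(M2, p1)
  for (i in 1:3) {
    expect_equal(hp$start[i], 1 / (1 + exp(-(sum(w * M2[i, ]) + 0.3))))
    expect_equal(hp$end[i], 1 / (1 + exp(-(sum(-w * M2[i, ]) - 0.1))))
  }
  expect_true(all(hp$start > 0 & hp$start < 1))
})

test_that("binarize applies a strict threshold", {
  expect_equal(binarize(0.7, 0.5), 1L)
  expect_equal(binarize(0.5, 0.5), 0L)
  expect_equal(binarize(rep(0.5, 4), 0.4), rep(1L, 4))
  expect_error(binarize(0.5, 0), "threshold")
  expect_error(binarize(0.5, 1), "threshold")
})

test_that("proximity decoding matches the worked start/end example", {
  text <- "Zhongmai 159, rongzhong 827g/L, cudanbai 14.8%."
  ch <- strsplit(text, "")[[1]]
  n <- length(ch)
  starts <- integer(n); ends <- integer(n)
  starts[c(1, 25, 42)] <- 1L   # "Z", "8" of 827, "1" of 14.8
  ends[c(12, 30, 46)] <- 1L    # "9", "L", "%"
  spans <- decode_spans_proximity(starts, ends, text)
  expect_length(spans, 3L)
  expect_equal(vapply(spans, function(s) s$text, character(1)),
               c("Zhongmai 159", "827g/L", "14.8%"))
  # the start at "8" pairs with the nearest following end "L"
  expect_equal(spans[[2]]$start, 24L)
  expect_equal(spans[[2]]$end, 30L)
})

test_that("no starts means no spans", {
  expect_length(decode_spans_proximity(integer(5), c(0L, 1L, 0L, 0L, 1L)), 0L)
})

test_that("proximity decoding equals the exhaustive nearest-end oracle", {
  set.seed(99)
  for (case in 1:150) {
    n <- sample(1:20, 1)
    s <- rbinom(n, 1, 0.3)
    e <- rbinom(n, 1, 0.3)
    got <- decode_spans_proximity(s, e)
    want <- oracle_decode(s, e)
    expect_length(got, length(want))
    for (i in seq_along(want)) {
      expect_equal(got[[i]]$start, unname(want[[i]]["start"]))
      expect_equal(got[[i]]$end, unname(want[[i]]["end"]))
    }
  }
})

test_that("raising the threshold never adds decoded spans", {
  set.seed(5)
  for (case in 1:30) {
    n <- 15
    ps <- runif(n); pe <- runif(n)
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
      length(decode_spans_proximity(binarize(ps, th), binarize(pe, th))),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("subject representation is the span mean of M2", {
  set.seed(2)
  M2 <- matrix(rnorm(20), 5, 4)
  sp1 <- span(2, 3, "abcde")
  expect_equal(subject_rep(M2, sp1), M2[3, ])
  Mc <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  expect_equal(subject_rep(Mc, span(0, 5, "abcde")), c(1, 2, 3, 4))
  sp3 <- span(1, 4, "abcde")
  expect_equal(subject_rep(M2, sp3), colMeans(M2[2:4, ]))
})

test_that("tail scoring is per-relation and subject-conditioned", {
  set.seed(3)
  d <- 6; n <- 4
  rel <- c("Yield", "Plant height", "Maturity")
  M2 <- matrix(rnorm(n * d), n, d)
  p <- lextriple:::init_pointer_params(d, rel)
  v <- rnorm(d)
  tp <- tail_pointer_probs(M2, v, p, rel)
  expect_equal(dim(tp$start), c(n, 3L))
  expect_equal(dim(tp$end), c(n, 3L))
  expect_equal(colnames(tp$start), rel)

  # a zero subject reduces to head-style scoring with tail parameters
  tp0 <- tail_pointer_probs(M2, numeric(d), p, rel)
  for (r in 1:3) {
    hp <- head_pointer_probs(M2, list(
      head_w_start = p$tail_W_start[, r], head_b_start = p$tail_b_start[r],
      head_w_end = p$tail_W_end[, r], head_b_end = p$tail_b_end[r]))
    expect_equal(unname(tp0$start[, r]), hp$start)
    expect_equal(unname(tp0$end[, r]), hp$end)
  }

  # perturbing one relation's parameters leaves the others unchanged
  p2 <- p
  p2$tail_W_start[, 2] <- p2$tail_W_start[, 2] + 1
  p2$tail_b_end[2] <- 5
  tp2 <- tail_pointer_probs(M2, v, p2, rel)
  expect_equal(tp2$start[, c(1, 3)], tp$start[, c(1, 3)])
  expect_equal(tp2$end[, c(1, 3)], tp$end[, c(1, 3)])
  expect_false(isTRUE(all.equal(tp2$start[, 2], tp$start[, 2])))

  expect_error(tail_pointer_probs(M2, v, p, character(0)), "empty")
})

test_that("gold 01 labels decode back to exactly the gold triples", {
  corp <- generate_corpus(synth_config(n_sentences = 100, seed = 23))
  sents <- c(corp$train, corp$dev, corp$test)
  key <- function(t) paste(t$head$start, t$head$end, t$relation,
                           t$tail$start, t$tail$end)
  for (s in sents) {
    lb <- spans_to_labels(s, corp$schema)
    # decode through the cascade: heads from the pooled head labels,
    # then per decoded head the per-relation tail labels
    heads <- decode_spans_proximity(binarize(lb$head_start, 0.4),
                                    binarize(lb$head_end, 0.4), s$text)
    got <- list()
    for (h in heads) {
      ki <- match(paste(h$start, h$end, sep = ":"),
                  vapply(lb$heads, function(x)
                    paste(x$start, x$end, sep = ":"), character(1)))
      expect_false(is.na(ki))
      for (r in seq_along(lb$relations)) {
        for (tl in decode_spans_proximity(lb$tail_start[[ki]][, r],
                                          lb$tail_end[[ki]][, r], s$text)) {
          got[[length(got) + 1L]] <- triple(h, lb$relations[r], tl)
        }
      }
    }
    expect_setequal(vapply(got, key, character(1)),
                    vapply(s$triples, key, character(1)))
  }
})

test_that("decoded spans re-encode and decode to themselves", {
  set.seed(31)
  for (case in 1:40) {
    n <- 18
    s <- rbinom(n, 1, 0.25); e <- rbinom(n, 1, 0.25)
    spans <- decode_spans_proximity(s, e)
    s2 <- integer(n); e2 <- integer(n)
    for (sp in spans) {
      s2[sp$start + 1L] <- 1L
      e2[sp$end] <- 1L
    }
    again <- decode_spans_proximity(s2, e2)
    key <- vapply(spans, function(x) paste(x$start, x$end), character(1))
    key2 <- vapply(again, function(x) paste(x$start, x$end), character(1))
    expect_setequal(unique(key), key2)
  }
})

test_that("one head span can feed several triples through the cascade", {
  s <- overlap_example_sentence()
  lb <- spans_to_labels(s)
  back <- labels_to_spans(lb, s$text)
  heads <- vapply(back$triples, function(t) t$head$text, character(1))
  expect_length(back$triples, 2L)
  expect_equal(unique(heads), "Zhongmai 159")
})
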