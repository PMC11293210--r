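test_that("uniform scores cost ln 4 per cell and masked background costs nothing", {
  sc <- array(0, c(3, 2, 3, 4))
  gold <- tag_tensor(3, 2)
  gold[1, 1, 2] <- 1L
  expect_equal(compute_loss(sc, gold), log(4), tolerance = 1e-12)
  # gold all background, weight 0: every cell masked
  expect_equal(compute_loss(sc, tag_tensor(3, 2), class_weight_background = 0), 0)
  expect_error(compute_loss(sc, tag_tensor(4, 2)), "shape")
})

test_that("the loss equals a per-cell hand computation", {
  set.seed(21)
  for (wb in c(1, 0.3)) {
    sc <- array(rnorm(4 * 2 * 4 * 4), c(4, 2, 4, 4))
    gold <- random_sparse_tensor(4, 2)
    expect_equal(compute_loss(sc, gold, wb), naive_loss(sc, gold, wb),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  sch <- relation_schema(c("a", "b"))
  m <- new_model(sch, vocab = c("x", "y", "z", "w"), d = 5, d_e = 7, seed = 3)
  ids <- c(1L, 3L, 2L, 4L, 2L)
  K <- 2L
  g <- matrix(0L, 25L, K)
  g[cbind(c(3L, 7L, 11L), c(1L, 2L, 1L))] <- c(1L, 2L, 3L)
  fb <- triplink:::.fwd_bwd(m$par, ids, g, K, dropout_rate = 0, wb = 0.7)
  for (nm in names(m$par)) {
    idx <- sample(length(m$par[[nm]]), min(4, length(m$par[[nm]])))
    numeric_grad <- vapply(idx, function(i) {
      eps <- 1e-6
      p <- m$par
      p[[nm]][i] <- p[[nm]][i] + eps
      up <- triplink:::.fwd_bwd(p, ids, g, K, 0, 0.7)$loss
      p[[nm]][i] <- p[[nm]][i] - 2 * eps
      dn <- triplink:::.fwd_bwd(p, ids, g, K, 0, 0.7)$loss
      (up - dn) / (2 * eps)
    }, numeric(1))
    expect_equal(fb$grads[[nm]][idx], numeric_grad, tolerance = 1e-6)
  }
})

test_that("training is reproducible and records one history row per epoch", {
  co <- tiny_corpus(n = 12, seed = 19)
  cfg <- train_config(learning_rate = 5e-3, epochs = 3, batch_size = 64,
                      dropout_rate = 0.2, max_len = 30, seed = 77,
                      class_weight_background = 0.4)
  f1 <- train_model(co$sentences, co$gold, co$schema, cfg, d = 8, d_e = 16)
  f2 <- train_model(co$sentences, co$gold, co$schema, cfg, d = 8, d_e = 16)
  expect_equal(nrow(f1$history), 3L)
  expect_identical(f1$history$loss, f2$history$loss) # bit-identical runs
  expect_identical(f1$model$par, f2$model$par)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$epochs, 3L)
})

test_that("loss decreases over early epochs on a learnable corpus", {
  co <- tiny_corpus(n = 40, seed = 23)
  cfg <- train_config(learning_rate = 5e-3, epochs = 4, batch_size = 16,
                      dropout_rate = 0, max_len = 30, seed = 1,
                      class_weight_background = 0.4)
  fit <- train_model(co$sentences, co$gold, co$schema, cfg, d = 16, d_e = 32)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("an untrained zero model predicts nothing and prediction is stable", {
  sch <- relation_schema(c("r1", "r2"))
  m <- new_model(sch, vocab = c("a", "b", "c"), d = 8, seed = 1, init = "zero")
  s <- tibble::tibble(id = "s1", text = "abcabc")
  expect_equal(nrow(predict_triples(m, s)), 0L)
  expect_identical(predict_triples(m, s), predict_triples(m, s))
})

test_that("training rejects empty corpora and unknown relation labels", {
  co <- tiny_corpus(n = 4, seed = 3)
  expect_error(
    train_model(co$sentences[0, ], co$gold, co$schema, train_config(epochs = 1)),
    "empty corpus"
  )
  bad_gold <- co$gold
  bad_gold$relation <- "no_such_relation"
  expect_error(
    train_model(co$sentences, bad_gold, co$schema, train_config(epochs = 1)),
    "no_such_relation"
  )
})

test_that("over-long sentences are truncated with their clipped triples dropped", {
  sch <- relation_schema("r1")
  sents <- tibble::tibble(id = c("a", "b"), text = c("abcdefgh", "abcd"))
  gold <- triple_tbl(c(0, 0), c(1, 1), c(0, 0), c(6, 3), c(7, 3), id = c("a", "b"))
  cfg <- train_config(epochs = 1, max_len = 4, learning_rate = 1e-3, seed = 1)
  expect_warning(
    expect_warning(
      fit <- train_model(sents, gold, sch, cfg, d = 4, d_e = 4),
      "truncated"
    ),
    "dropped"
  )
  expect_equal(nrow(fit$history), 1L)
})

test_that("checkpoints restore a model that predicts identically", {
  co <- tiny_corpus(n = 10, seed = 9)
  cfg <- train_config(learning_rate = 5e-3, epochs = 2, batch_size = 8,
                      dropout_rate = 0, max_len = 30, seed = 2,
                      class_weight_background = 0.4)
  fit <- train_model(co$sentences, co$gold, co$schema, cfg, d = 8, d_e = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit$model, path)
  m2 <- read_checkpoint(path)
  expect_equal(m2$schema$labels, co$schema$labels)
  expect_identical(predict_triples(fit$model, co$sentences),
                   predict_triples(m2, co$sentences))
})
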