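test_that("strict matching reproduces hand-computed metrics", {
  g <- triple_tbl(c(0, 2, 4, 6), c(1, 3, 5, 7), c(0, 0, 1, 1),
                  c(2, 4, 6, 0), c(2, 4, 6, 0), id = "s1")
  # identity
  m <- strict_match(g, g)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  # empty predictions
  m0 <- strict_match(g, g[0, ])
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 4L))
  # 3 predictions, 2 correct, 4 gold: P = 2/3, R = 1/2, F1 = 4/7
  pred <- dplyr::bind_rows(g[1:2, ], triple_tbl(9, 9, 0, 8, 8, id = "s1"))
  m2 <- strict_match(g, pred)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 1 / 2)
  expect_equal(m2$f1, 4 / 7)
})

test_that("span or relation mismatches are not true positives", {
  g <- triple_tbl(0, 2, 0, 4, 5, id = "s1")
  off_span <- triple_tbl(0, 1, 0, 4, 5, id = "s1")
  off_rel <- triple_tbl(0, 2, 1, 4, 5, id = "s1")
  other_sentence <- triple_tbl(0, 2, 0, 4, 5, id = "s2")
  expect_equal(strict_match(g, off_span)$tp, 0L)
  expect_equal(strict_match(g, off_rel)$tp, 0L)
  expect_equal(strict_match(g, other_sentence, ids = c("s1", "s2"))$tp, 0L)
})

test_that("predictions for unknown sentence ids are rejected by name", {
  g <- triple_tbl(0, 1, 0, 2, 3, id = "s1")
  p <- triple_tbl(0, 1, 0, 2, 3, id = "ghost")
  expect_error(strict_match(g, p), "ghost")
})

test_that("overlap classification separates Normal, SEO and EPO", {
  normal <- triple_tbl(0, 1, 0, 3, 4)
  expect_equal(classify_overlap(normal), "Normal")
  epo <- triple_tbl(c(0, 0), c(1, 1), c(0, 1), c(3, 3), c(4, 4))
  expect_equal(classify_overlap(epo), "EPO")
  seo <- triple_tbl(c(0, 0), c(1, 1), c(0, 0), c(3, 6), c(4, 7))
  expect_equal(classify_overlap(seo), "SEO")
  # a shared entity in different roles still counts as SEO
  chain <- triple_tbl(c(0, 3), c(1, 4), c(0, 1), c(3, 6), c(4, 7))
  expect_equal(classify_overlap(chain), "SEO")
  # SEO and EPO can co-occur in one sentence
  both <- dplyr::bind_rows(epo, triple_tbl(0, 1, 2, 6, 7))
  expect_setequal(classify_overlap(both), c("SEO", "EPO"))
  expect_error(classify_overlap(normal[0, ]), "nonempty")
  # permutation invariance
  set.seed(1)
  for (i in 1:5) {
    shuffled <- both[sample(nrow(both)), ]
    expect_setequal(classify_overlap(shuffled), classify_overlap(both))
  }
})

test_that("triple-count buckets partition the corpus", {
  gold <- dplyr::bind_rows(lapply(seq_along(c(1, 1, 2, 5, 7)), function(i) {
    n <- c(1, 1, 2, 5, 7)[i]
    triple_tbl(seq_len(n) * 2L, seq_len(n) * 2L + 1L, 0L,
               seq_len(n) * 20L, seq_len(n) * 20L, id = paste0("s", i))
  }))
  b <- bucket_by_triple_count(gold)
  sizes <- table(b$bucket)
  expect_equal(as.integer(sizes[c("1", "2", "3", "4", "5+")]), c(2L, 1L, 0L, 0L, 2L))
  expect_equal(sum(sizes), 5L)
  # empty corpus: no rows, all buckets empty
  expect_equal(nrow(bucket_by_triple_count(gold[0, ])), 0L)
})

test_that("per-relation counts conserve the global strict-match counts", {
  set.seed(12)
  sch <- relation_schema(sprintf("r%d", 1:4))
  rand_triples <- function(n, ids) {
    h <- sample(0:8, n, replace = TRUE)
    oh <- sample(0:8, n, replace = TRUE)
    triple_tbl(h, h + sample(0:2, n, TRUE), sample(0:3, n, TRUE),
               oh, oh + sample(0:2, n, TRUE),
               id = sample(ids, n, replace = TRUE))
  }
  for (i in 1:5) {
    gold <- rand_triples(20, c("a", "b", "c"))
    pred <- dplyr::bind_rows(gold[sample(20, 10), ], rand_triples(8, c("a", "b", "c")))
    global <- strict_match(gold, pred)
    per <- per_relation_metrics(gold, pred, sch)
    expect_equal(sum(per$tp), global$tp)
    expect_equal(sum(per$fp), global$fp)
    expect_equal(sum(per$fn), global$fn)
  }
})

test_that("relations with no gold and no predictions are flagged absent", {
  sch <- relation_schema(c("used", "unused"))
  gold <- triple_tbl(0, 1, 0, 3, 4, id = "s1")
  per <- per_relation_metrics(gold, gold, sch)
  expect_equal(per$f1, c(1, 0))
  expect_equal(per$absent, c(FALSE, TRUE))
  expect_equal(per$tp[2] + per$fp[2] + per$fn[2], 0L)
})

test_that("the evaluation report aggregates all breakdowns consistently", {
  co <- tiny_corpus(n = 40, seed = 15)
  m <- new_model(co$schema, vocab = c("a"), d = 4, init = "zero")
  pred <- predict_triples(m, co$sentences) # empty: untrained model
  rep <- evaluation_report(co$gold, pred, co$schema, ids = co$sentences$id)
  expect_s3_class(rep, "tl_report")
  expect_equal(rep$global$recall, 0)
  expect_equal(sum(rep$by_bucket$n_sentences), nrow(co$sentences))
  expect_equal(sum(rep$by_relation$fn), rep$global$fn)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
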