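test_that("collision priority follows the total order 1 > 2 > 3 > 0", {
  expect_equal(resolve_collision(3, 1), 1L) # single-char object: 1 overwrites 3
  expect_equal(resolve_collision(0, 2), 2L)
  expect_equal(resolve_collision(2, 3), 2L)
  # winner independent of write order, for every tag pair
  grid <- expand.grid(a = 0:3, b = 0:3)
  expect_equal(resolve_collision(grid$a, grid$b), resolve_collision(grid$b, grid$a))
  expect_error(resolve_collision(4, 1), "tag values")
})

test_that("encoding a multi-character pair writes exactly the three link cells", {
  tt <- encode_triples(8, triple_tbl(4, 7, 0, 4, 5), K = 1)
  cells <- tensor_cells(tt)
  expect_equal(nrow(cells), 3L)
  expect_equal(tt[5, 1, 5], 1L) # head -> head (0-based (4, 4))
  expect_equal(tt[8, 1, 6], 2L) # tail -> tail (7, 5)
  expect_equal(tt[5, 1, 6], 3L) # head -> tail (4, 5)
  expect_equal(sum(tt != 0L), 3L)
})

test_that("a single-character object collapses tag 3 into tag 1", {
  tt <- encode_triples(6, triple_tbl(2, 3, 0, 2, 2), K = 1)
  expect_equal(tt[3, 1, 3], 1L) # tag 3 at (2, 2) overwritten with tag 1
  expect_equal(tt[4, 1, 3], 2L)
  expect_equal(sum(tt != 0L), 2L)
})

test_that("empty triple sets and all-zero tensors are each other's images", {
  tt <- encode_triples(5, triple_tbl(), K = 3)
  expect_equal(dim(tt), c(5L, 3L, 5L))
  expect_true(all(tt == 0L))
  expect_equal(nrow(decode_tensor(tt)), 0L)
  expect_equal(nrow(oracle_decode(tt)), 0L)
})

test_that("encoding rejects out-of-range spans and relations", {
  expect_error(encode_triples(4, triple_tbl(0, 4, 0, 0, 1), K = 1), "out of range")
  expect_error(encode_triples(4, triple_tbl(0, 1, 2, 0, 1), K = 2), "out of range")
  expect_error(encode_triples(4, triple_tbl(2, 1, 0, 0, 1), K = 1), "head <= tail")
})

test_that("the worked single- and multi-character examples decode exactly", {
  fig_a <- encode_triples(8, triple_tbl(4, 7, 0, 4, 5), K = 1)
  expect_same_triples(decode_tensor(fig_a), triple_tbl(4, 7, 0, 4, 5))
  fig_b <- encode_triples(6, triple_tbl(2, 3, 0, 2, 2), K = 1)
  expect_same_triples(decode_tensor(fig_b), triple_tbl(2, 3, 0, 2, 2))
  # both entities single characters: one surviving tag-1 cell
  both <- encode_triples(5, triple_tbl(1, 1, 0, 3, 3), K = 1)
  expect_equal(tensor_cells(both)$tag, 1L)
  expect_same_triples(decode_tensor(both), triple_tbl(1, 1, 0, 3, 3))
})

test_that("a lone tag 1 decodes as a both-single-character triple", {
  tt <- tag_tensor(5, 1)
  tt[2, 1, 4] <- 1L # 0-based (1, 0, 3)
  expect_same_triples(oracle_decode(tt), triple_tbl(1, 1, 0, 3, 3))
  expect_same_triples(decode_tensor(tt), triple_tbl(1, 1, 0, 3, 3))
})

test_that("a tensor with only tag 3 yields no triples", {
  tt <- tag_tensor(6, 2)
  tt[2, 1, 5] <- 3L
  tt[4, 2, 4] <- 3L
  expect_equal(nrow(decode_tensor(tt)), 0L)
  expect_equal(nrow(oracle_decode(tt)), 0L)
})

test_that("round trip holds on randomized collision-free corpora", {
  co <- tiny_corpus(n = 120, seed = 31, p_single_char = 0.2, p_nested = 0.3)
  K <- co$schema$K
  for (i in seq_len(nrow(co$sentences))) {
    g <- co$gold[co$gold$id == co$sentences$id[i], ]
    rt <- decode_tensor(encode_triples(nchar(co$sentences$text[i]), g, K))
    expect_same_triples(rt, g)
  }
})

test_that("decoder matches the brute-force oracle on random sparse tensors", {
  set.seed(88)
  for (it in 1:150) {
    L <- sample(2:12, 1)
    K <- sample(1:3, 1)
    tt <- random_sparse_tensor(L, K)
    expect_same_triples(decode_tensor(tt), oracle_decode(tt))
  }
})

test_that("removing a nonzero cell never adds general-case triples", {
  set.seed(17)
  for (it in 1:40) {
    tt <- random_sparse_tensor(sample(3:8, 1), sample(1:2, 1))
    full <- decode_tensor(tt, keep_case = TRUE)
    full_a <- triple_key(full[full$case == "general", , drop = FALSE])
    nz <- which(tt != 0L)
    for (pos in nz) {
      tt2 <- tt
      tt2[pos] <- 0L
      sub <- decode_tensor(tt2, keep_case = TRUE)
      sub_a <- triple_key(sub[sub$case == "general", , drop = FALSE])
      expect_true(all(sub_a %in% full_a))
    }
  }
})

test_that("encoding writes at most three nonzero cells per triple", {
  set.seed(5)
  co <- tiny_corpus(n = 40, seed = 6)
  for (i in seq_len(nrow(co$sentences))) {
    g <- co$gold[co$gold$id == co$sentences$id[i], ]
    tt <- encode_triples(nchar(co$sentences$text[i]), g, co$schema$K)
    expect_lte(sum(tt != 0L), 3L * nrow(g))
  }
})

test_that("sparse JSON serialization round-trips losslessly", {
  co <- tiny_corpus(n = 5, seed = 44)
  g <- co$gold[co$gold$id == co$sentences$id[1], ]
  tt <- encode_triples(nchar(co$sentences$text[1]), g, co$schema$K)
  path <- withr::local_tempfile(fileext = ".json")
  write_tag_tensor(tt, path)
  expect_identical(read_tag_tensor(path), tt)
  # empty tensor round trip
  write_tag_tensor(tag_tensor(4, 2), path)
  expect_identical(read_tag_tensor(path), tag_tensor(4, 2))
})

test_that("duplicate triples collapse to one", {
  tr <- tibble::tibble(sub_head = c(1L, 1L), sub_tail = c(2L, 2L),
                       relation = c(0L, 0L), obj_head = c(4L, 4L),
                       obj_tail = c(5L, 5L))
  tt <- encode_triples(7, tr, K = 1)
  expect_equal(nrow(decode_tensor(tt)), 1L)
})
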