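# Independent reference implementations used as oracles, plus small
# fixture helpers.  These deliberately use naive loops, not the package's
# vectorized code paths.

triple_key <- function(tr) {
  do.call(paste, tr[, c("sub_head", "sub_tail", "relation", "obj_head", "obj_tail")])
}

expect_same_triples <- function(a, b) {
  expect_setequal(triple_key(a), triple_key(b))
}

# Eq.-style naive scorer: one independent evaluation per (i, k, j) cell
naive_score_tensor <- function(E, params) {
  L <- nrow(E)
  K <- params$K
  out <- array(NA_real_, c(L, K, L, 4L))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      h <- pmax(drop(params$W %*% c(E[i, ], E[j, ])) + params$b, 0)
      v <- drop(crossprod(params$R_w, h)) # length 4K, relation-major
      for (k in seq_len(K)) {
        out[i, k, j, ] <- v[(k - 1L) * 4L + 1:4]
      }
    }
  }
  out
}

# per-cell cross-entropy computed the slow way
naive_loss <- function(scores, gold, wb = 1) {
  d <- dim(scores)
  total <- 0
  for (i in seq_len(d[1])) {
    for (k in seq_len(d[2])) {
      for (j in seq_len(d[3])) {
        v <- scores[i, k, j, ]
        p <- exp(v - max(v))
        p <- p / sum(p)
        g <- gold[i, k, j]
        w <- if (g == 0L) wb else 1
        total <- total + w * (-log(p[g + 1L]))
      }
    }
  }
  total / prod(d[1:3])
}

random_sparse_tensor <- function(L, K, max_cells = 6L) {
  tt <- tag_tensor(L, K)
  n <- sample.int(min(max_cells, L * K * L), 1L)
  pos <- sample(L * K * L, n)
  tt[pos] <- sample(1:3, n, replace = TRUE)
  tt
}

tiny_corpus <- function(n = 30L, seed = 402L, ...) {
  generate_corpus(gen_config(n_sentences = n, seed = seed, ...))
}
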