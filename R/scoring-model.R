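# Scoring model: sentence -> L x K x L x 4 tag score tensor.
#
# The score of token pair (i, j) for relation k is
#     v(w_i, r_k, w_j) = R^T ReLU(drop(W [e_i; e_j] + b))
# computed once per ordered pair (i, j): the single projection through R
# yields the scores of all K relations and all 4 tags simultaneously, so
# scoring costs L x 1 x L pair evaluations rather than L x K x L.

# pair-representation evaluation counter (efficiency instrumentation)
.pair_counter <- new.env(parent = emptyenv())
.pair_counter$n <- 0L

#' Pair-representation evaluation counter
#'
#' Every evaluation of a pair representation — whether through
#' [pair_representation()] or the batched path inside [score_all_pairs()] —
#' increments this counter by one per ordered position pair.  Used to verify
#' that scoring a sentence costs exactly L^2 pair evaluations, independent
#' of the number of relations.
#'
#' @return `pair_rep_count()`: the current count.
#' @export
pair_rep_count <- function() .pair_counter$n

#' @rdname pair_rep_count
#' @export
reset_pair_rep_count <- function() {
  .pair_counter$n <- 0L
  invisible(0L)
}

#' Scoring-head parameters
#'
#' Trainable weights of the two fully connected layers: `W` (`d_e x 2d`) and
#' bias `b` project the concatenated pair `[e_i; e_j]` to the pair
#' representation, and `R_w` (`d_e x 4K`) projects the pair representation to
#' the scores of all K relations times 4 tags.  The 4K output columns are
#' grouped relation-major: column `(k-1)*4 + t` holds the score of tag
#' `t - 1` under relation `k`.
#'
#' @param d Encoder embedding width.
#' @param K Number of relations.
#' @param d_e Pair-representation width (defaults to `d`).
#' @param init `"glorot"` for scaled random initialization, `"zero"` for
#'   all-zero weights.
#' @param seed Optional seed for reproducible initialization.
#' @return A list of class `tl_scorer` with elements `W`, `b`, `R_w` and the
#'   dimensions `d`, `d_e`, `K`.
#' @export
scorer_params <- function(d, K, d_e = d, init = c("glorot", "zero"),
                          seed = NULL) {
  init <- arg_match(init)
  stopifnot(d >= 1L, d_e >= 1L, K >= 1L)
  if (!is.null(seed)) set.seed(seed)
  gl <- function(nr, nc) {
    if (init == "zero") {
      matrix(0, nr, nc)
    } else {
      matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
    }
  }
  structure(
    list(W = gl(d_e, 2L * d), b = numeric(d_e), R_w = gl(d_e, 4L * K),
         d = as.integer(d), d_e = as.integer(d_e), K = as.integer(K)),
    class = "tl_scorer"
  )
}

#' @rdname scorer_params
#' @param params A `tl_scorer`.
#' @return `n_scorer_params()`: the scoring-head parameter count,
#'   `d_e * 2d + d_e + d_e * 4K` (two fully connected layers).
#' @export
n_scorer_params <- function(params) {
  length(params$W) + length(params$b) + length(params$R_w)
}

# batched pair representations for all ordered pairs of rows of E (L x d):
# returns the P = L^2 x d_e ReLU'd representation matrix, rows ordered
# subject-major (p = (i-1)*L + j)
.pair_rep_matrix <- function(E, params, training = FALSE, dropout_rate = 0) {
  L <- nrow(E)
  idx_i <- rep(seq_len(L), each = L)
  idx_j <- rep(seq_len(L), times = L)
  C <- cbind(E[idx_i, , drop = FALSE], E[idx_j, , drop = FALSE])
  A <- C %*% t(params$W) + rep(params$b, each = nrow(C))
  if (training && dropout_rate > 0) {
    keep <- (runif(length(A)) >= dropout_rate) / (1 - dropout_rate)
    A <- A * keep
  }
  .pair_counter$n <- .pair_counter$n + nrow(C)
  pmax(A, 0)
}

#' Pair representation of two token embeddings
#'
#' The non-linear concatenation projection
#' `ReLU(drop(W [e_i; e_j] + b))`.  Concatenation order matters: swapping
#' `e_i` and `e_j` changes the result in general, which is what lets the
#' model distinguish subject from object.  Dropout (inside the ReLU) is
#' applied only when `training` is set.
#'
#' @param e_i,e_j Numeric vectors of length `d` (subject- and
#'   object-position embeddings).
#' @param params A `tl_scorer`.
#' @param training Apply dropout?
#' @param dropout_rate Dropout probability used when `training` is `TRUE`.
#' @return Numeric vector of length `d_e`.
#' @export
pair_representation <- function(e_i, e_j, params, training = FALSE,
                                dropout_rate = 0) {
  if (length(e_i) != params$d || length(e_j) != params$d) {
    abort(paste0("embedding dimension mismatch: expected d = ", params$d))
  }
  a <- drop(params$W %*% c(e_i, e_j)) + params$b
  if (training && dropout_rate > 0) {
    a <- a * (runif(length(a)) >= dropout_rate) / (1 - dropout_rate)
  }
  .pair_counter$n <- .pair_counter$n + 1L
  pmax(a, 0)
}

#' Score every (subject position, relation, object position) combination
#'
#' Computes one pair representation per ordered position pair and projects
#' it once through `R_w`, yielding the raw (pre-softmax) scores of all
#' `K x 4` relation/tag combinations simultaneously.
#'
#' @param emb An `L x d` embedding matrix (one row per token), e.g. from
#'   [encode_sentence()].
#' @inheritParams pair_representation
#' @param max_cells Capacity guard: an `L * K * L * 4` result exceeding this
#'   many cells raises an error before any allocation.
#' @return An `L x K x L x 4` numeric array of raw scores (first axis
#'   subject position, third axis object position).
#' @export
score_all_pairs <- function(emb, params, training = FALSE, dropout_rate = 0,
                            max_cells = 2^26) {
  stopifnot(is.matrix(emb))
  L <- nrow(emb)
  K <- params$K
  if (ncol(emb) != params$d) {
    abort(paste0("embedding dimension mismatch: expected d = ", params$d))
  }
  if (L * K * L * 4 > max_cells) {
    abort(paste0("score tensor of ", L, "x", K, "x", L, "x4 = ",
                 L * K * L * 4, " cells exceeds the capacity budget (",
                 max_cells, ")"))
  }
  H <- .pair_rep_matrix(emb, params, training, dropout_rate)
  S <- H %*% params$R_w # P x 4K, rows p = (i-1)*L + j
  # S[p, (k-1)*4 + t] -> array[(i, k, j, t)]
  a1 <- array(S, dim = c(L, L, 4L, K)) # (j, i, t, k)
  aperm(a1, c(2L, 4L, 1L, 3L))
}

#' Softmax over the four tag scores of every cell
#'
#' @param scores An `L x K x L x 4` raw score array.
#' @return Array of the same shape; the 4 values at each `(i, k, j)` are
#'   nonnegative and sum to one.
#' @export
softmax_scores <- function(scores) {
  stopifnot(length(dim(scores)) == 4L, dim(scores)[4L] == 4L)
  d <- dim(scores)
  m <- matrix(scores, ncol = 4L)
  mx <- pmax(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
  ex <- exp(m - mx) # mx recycles down columns
  p <- ex / rowSums(ex)
  array(p, dim = d)
}

#' Predicted tag tensor from a score tensor
#'
#' Per cell the predicted tag is the argmax of the 4 tag scores (softmax is
#' monotone, so raw scores give the same argmax).  Ties break toward the
#' lower tag value, i.e. toward background.
#'
#' @param scores An `L x K x L x 4` score array (raw or softmaxed).
#' @return An `L x K x L` integer tag tensor.
#' @export
tags_from_scores <- function(scores) {
  stopifnot(length(dim(scores)) == 4L, dim(scores)[4L] == 4L)
  d <- dim(scores)
  m <- matrix(scores, ncol = 4L)
  tags <- max.col(m, ties.method = "first") - 1L
  array(as.integer(tags), dim = d[1:3])
}
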