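# Full extraction model: character encoder + scoring head.
#
# The desk-scale encoder is a trainable character-embedding table plus a
# one-hop bidirectional context mixer,
#     e_i = x_i + A_l x_{i-1} + A_r x_{i+1},
# which gives every position a view of its immediate neighbours while
# keeping the whole model a few small dense matrices.  Any external encoder
# producing one d-vector per character can be plugged in by passing its
# output directly to score_all_pairs(); the tagging scheme and scoring head
# are agnostic to where the embeddings come from.

#' Create an extraction model
#'
#' Bundles the character encoder (embedding table + bidirectional context
#' mixer) with the scoring head and the relation schema.  Characters outside
#' `vocab` map to a reserved unknown embedding, never to an error.
#'
#' @param schema A [relation_schema()].
#' @param vocab Character vector of known single-character tokens.
#' @param d Embedding width (default 32).
#' @param d_e Pair-representation width (default `2 * d`).
#' @param seed Seed for reproducible initialization.
#' @param init `"glorot"` or `"zero"` (all-zero weights are handy in tests:
#'   they yield uniform tag probabilities and an empty decoded triple set).
#' @return An object of class `tl_model`.
#' @export
new_model <- function(schema, vocab, d = 32L, d_e = 2L * d, seed = NULL,
                      init = c("glorot", "zero")) {
  stopifnot(inherits(schema, "tl_schema"))
  init <- arg_match(init)
  vocab <- as.character(vocab)
  if (any(nchar(vocab) != 1L)) abort("vocab entries must be single characters")
  if (anyDuplicated(vocab)) abort("vocab entries must be unique")
  if (!is.null(seed)) set.seed(seed)
  V <- length(vocab)
  mat <- function(nr, nc, sd) {
    if (init == "zero") matrix(0, nr, nc) else matrix(rnorm(nr * nc, sd = sd), nr, nc)
  }
  scorer <- scorer_params(d = d, K = schema$K, d_e = d_e, init = init)
  par <- list(
    Emb = mat(V + 1L, d, sd = 0.5), # last row = unknown token
    A_l = mat(d, d, sd = 0.05),
    A_r = mat(d, d, sd = 0.05),
    W = scorer$W, b = scorer$b, R_w = scorer$R_w
  )
  structure(
    list(schema = schema, vocab = vocab, d = as.integer(d),
         d_e = as.integer(d_e), par = par),
    class = "tl_model"
  )
}

#' @export
print.tl_model <- function(x, ...) {
  cat("<triplink model: |vocab| = ", length(x$vocab), ", d = ", x$d,
      ", d_e = ", x$d_e, ", K = ", x$schema$K, ">\n", sep = "")
  invisible(x)
}

.scorer_of <- function(model) {
  structure(
    list(W = model$par$W, b = model$par$b, R_w = model$par$R_w,
         d = model$d, d_e = model$d_e, K = model$schema$K),
    class = "tl_scorer"
  )
}

.char_ids <- function(model, text) {
  tokens <- strsplit(text, "", fixed = TRUE)[[1L]]
  ids <- match(tokens, model$vocab)
  ids[is.na(ids)] <- length(model$vocab) + 1L # reserved unknown row
  ids
}

# encoder forward given integer character ids; returns X (raw embeddings)
# and E (mixed embeddings), both L x d
.encode_ids <- function(par, ids) {
  X <- par$Emb[ids, , drop = FALSE]
  L <- length(ids)
  if (L > 1L) {
    Xl <- rbind(0, X[-L, , drop = FALSE])
    Xr <- rbind(X[-1L, , drop = FALSE], 0)
  } else {
    Xl <- matrix(0, 1L, ncol(X))
    Xr <- Xl
  }
  list(X = X, Xl = Xl, Xr = Xr, E = X + Xl %*% par$A_l + Xr %*% par$A_r)
}

#' Encode a sentence into per-character embeddings
#'
#' @param model A `tl_model`.
#' @param text A single string; tokenization is strictly per character.
#' @return An `L x d` matrix, row `i` aligned with character `i`.
#' @export
encode_sentence <- function(model, text) {
  stopifnot(inherits(model, "tl_model"), is.character(text), length(text) == 1L)
  L <- nchar(text)
  if (L < 1L) abort("cannot encode an empty sentence")
  .encode_ids(model$par, .char_ids(model, text))$E
}

#' Predict triples for sentences
#'
#' Runs the full pipeline encoder -> pair scoring (dropout off) -> argmax
#' tags -> tensor decoding, deterministically.
#'
#' @param object A `tl_model` or a fitted `tl_fit` (from [train_model()]).
#' @param sentences Tibble with columns `id` and `text` (or a character
#'   vector, in which case ids `s1, s2, ...` are assigned).
#' @return A triple table with an `id` column (0-based spans).
#' @export
predict_triples <- function(object, sentences) {
  model <- if (inherits(object, "tl_fit")) object$model else object
  stopifnot(inherits(model, "tl_model"))
  if (is.character(sentences)) {
    sentences <- tibble(id = paste0("s", seq_along(sentences)), text = sentences)
  }
  stopifnot(all(c("id", "text") %in% names(sentences)))
  K <- model$schema$K
  out <- map2(sentences$id, sentences$text, function(id, text) {
    tags <- .predict_tags(model, text)
    tr <- decode_tensor(tags)
    if (nrow(tr)) tibble(id = id, !!!tr) else NULL
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(id = character(), sub_head = integer(), sub_tail = integer(),
                  relation = integer(), obj_head = integer(), obj_tail = integer())
  }
  res
}

# fast path: argmax tags without materializing the 4-d score array
.predict_tags <- function(model, text) {
  ids <- .char_ids(model, text)
  L <- length(ids)
  K <- model$schema$K
  enc <- .encode_ids(model$par, ids)
  H <- .pair_rep_matrix(enc$E, .scorer_of(model))
  S <- H %*% model$par$R_w # P x 4K
  P <- L * L
  M2 <- matrix(aperm(array(S, dim = c(P, 4L, K)), c(1L, 3L, 2L)), ncol = 4L)
  tg <- max.col(M2, ties.method = "first") - 1L # ties favor background
  # rows of M2: p fast then k, with p = (i-1)*L + j  ->  (j, i, k) array
  aperm(array(as.integer(tg), dim = c(L, L, K)), c(2L, 3L, 1L))
}

#' @export
predict.tl_model <- function(object, newdata, ...) predict_triples(object, newdata)

#' Checkpoint serialization
#'
#' Writes the complete model — weights, vocabulary and relation schema — to
#' one JSON file, so predictions are reproducible from the file alone.
#'
#' @param model A `tl_model`.
#' @param path Output path.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tl_model"))
  payload <- list(
    format = "triplink-checkpoint-v1",
    schema = model$schema$labels,
    vocab = model$vocab,
    d = model$d, d_e = model$d_e,
    par = lapply(model$par, function(p) {
      if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
      else list(dim = length(p), values = as.numeric(p))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return `read_checkpoint()`: the restored `tl_model`.
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "triplink-checkpoint-v1")) {
    abort("not a triplink checkpoint file")
  }
  par <- lapply(x$par, function(p) {
    if (length(p$dim) == 2L) matrix(p$values, p$dim[1L], p$dim[2L])
    else as.numeric(p$values)
  })
  structure(
    list(schema = relation_schema(x$schema), vocab = x$vocab,
         d = as.integer(x$d), d_e = as.integer(x$d_e), par = par),
    class = "tl_model"
  )
}
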