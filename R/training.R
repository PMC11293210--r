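# Training: per-cell categorical cross-entropy over the 4 tag classes,
# optimized with Adam.  Backpropagation is written out by hand over the
# model's few dense matrices and verified against finite differences in the
# test suite.

#' Training configuration
#'
#' Defaults follow the published training setup of the method: Adam with
#' learning rate 1e-5, 50 epochs, batch size 64, dropout 0.5 and a maximum
#' sentence length of 256.  `class_weight_background` down-weights the
#' (overwhelmingly frequent) background cells in the loss; 1 keeps the plain
#' mean.  For training the small from-scratch encoder on synthetic corpora a
#' much larger learning rate is appropriate (see the package vignette).
#'
#' @param learning_rate Positive Adam step size.
#' @param epochs Number of passes over the corpus.
#' @param batch_size Sentences per optimization step.
#' @param dropout_rate Dropout probability in the scoring head.
#' @param max_len Maximum sentence length; longer sentences are truncated
#'   (with a warning) and triples touching truncated positions dropped.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param class_weight_background Nonnegative weight of gold-background
#'   cells in the loss.
#' @param val_every Evaluate strict F1 on the validation split every this
#'   many epochs (0 = never).
#' @return A list of class `tl_train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 50L, batch_size = 64L,
                         dropout_rate = 0.5, max_len = 256L, seed = 1L,
                         class_weight_background = 1,
                         val_every = 0L) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L,
            dropout_rate >= 0, dropout_rate < 1, max_len >= 1L,
            class_weight_background >= 0)
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), dropout_rate = dropout_rate,
         max_len = as.integer(max_len), seed = as.integer(seed),
         class_weight_background = class_weight_background,
         val_every = as.integer(val_every)),
    class = "tl_train_config"
  )
}

#' Per-cell cross-entropy loss
#'
#' Mean over all `L * K * L` cells of the negative log softmax probability
#' of the gold tag; gold-background cells may be down-weighted.  The
#' denominator is always the full cell count, so an all-background gold
#' tensor with background weight 0 gives loss 0.
#'
#' @param scores An `L x K x L x 4` raw score array.
#' @param gold An `L x K x L` integer gold tag tensor.
#' @param class_weight_background Weight of cells whose gold tag is 0.
#' @return A nonnegative scalar.
#' @export
compute_loss <- function(scores, gold, class_weight_background = 1) {
  dsc <- dim(scores)
  if (length(dsc) != 4L || !identical(dsc[1:3], dim(gold))) {
    abort("scores and gold tensors disagree in shape")
  }
  m <- matrix(scores, ncol = 4L)
  g <- as.integer(gold) # same (i, k, j) cell ordering as rows of m
  mx <- pmax(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
  lz <- mx + log(rowSums(exp(m - mx)))
  nll <- lz - m[cbind(seq_along(g), g + 1L)]
  w <- ifelse(g == 0L, class_weight_background, 1)
  sum(w * nll) / length(g)
}

# ---- internal training engine ---------------------------------------------

# gold cell list of one sentence -> (P x K) tag matrix, p = (i-1)*L + j
.gold_mat <- function(triples, L, K) {
  g <- matrix(0L, L * L, K)
  if (nrow(triples)) {
    cells <- tensor_cells(encode_triples(L, triples, K))
    g[cbind(cells$row * L + cells$col + 1L, cells$relation + 1L)] <- cells$tag
  }
  g
}

# forward + backward for one sentence; returns loss and gradient list
.fwd_bwd <- function(par, ids, gmat, K, dropout_rate, wb, training = TRUE) {
  d <- ncol(par$Emb)
  d_e <- length(par$b)
  L <- length(ids)
  P <- L * L
  enc <- .encode_ids(par, ids)
  idx_i <- rep(seq_len(L), each = L)
  idx_j <- rep(seq_len(L), times = L)
  C <- cbind(enc$E[idx_i, , drop = FALSE], enc$E[idx_j, , drop = FALSE])
  A <- C %*% t(par$W) + rep(par$b, each = P)
  if (training && dropout_rate > 0) {
    keep <- matrix((runif(P * d_e) >= dropout_rate) / (1 - dropout_rate), P, d_e)
    Ad <- A * keep
  } else {
    keep <- NULL
    Ad <- A
  }
  H <- pmax(Ad, 0)
  S <- H %*% par$R_w # P x 4K

  # softmax cross-entropy over tag axis; rows of M2 ordered (p fast, k)
  M2 <- matrix(aperm(array(S, dim = c(P, 4L, K)), c(1L, 3L, 2L)), ncol = 4L)
  gv <- as.integer(gmat)
  mx <- pmax(M2[, 1L], M2[, 2L], M2[, 3L], M2[, 4L])
  ex <- exp(M2 - mx)
  Z <- rowSums(ex)
  pick <- cbind(seq_along(gv), gv + 1L)
  nll <- log(Z) - (M2[pick] - mx)
  w <- ifelse(gv == 0L, wb, 1)
  N <- P * K
  loss <- sum(w * nll) / N

  dM2 <- ex / Z
  dM2[pick] <- dM2[pick] - 1
  dM2 <- dM2 * (w / N)
  dS <- matrix(aperm(array(dM2, dim = c(P, K, 4L)), c(1L, 3L, 2L)), nrow = P)

  dR_w <- crossprod(H, dS)
  dH <- dS %*% t(par$R_w)
  dAd <- dH * (Ad > 0)
  dA <- if (is.null(keep)) dAd else dAd * keep
  db <- colSums(dA)
  dW <- t(crossprod(C, dA)) # d_e x 2d
  dC <- dA %*% par$W # P x 2d
  dE <- rowsum(dC[, seq_len(d), drop = FALSE], idx_i) +
    rowsum(dC[, d + seq_len(d), drop = FALSE], idx_j)

  dA_l <- crossprod(enc$Xl, dE)
  dA_r <- crossprod(enc$Xr, dE)
  dX <- dE
  if (L > 1L) {
    dXl <- dE %*% t(par$A_l)
    dXr <- dE %*% t(par$A_r)
    dX <- dX + rbind(dXl[-1L, , drop = FALSE], matrix(0, 1L, d)) +
      rbind(matrix(0, 1L, d), dXr[-L, , drop = FALSE])
  }
  dEmb <- matrix(0, nrow(par$Emb), d)
  acc <- rowsum(dX, ids)
  dEmb[sort(unique(ids)), ] <- acc

  list(loss = loss,
       grads = list(Emb = dEmb, A_l = dA_l, A_r = dA_r, W = dW, b = db,
                    R_w = dR_w))
}

.adam_new <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# truncate over-long sentences and drop triples touching cut positions
.truncate_corpus <- function(sentences, gold, max_len) {
  too_long <- nchar(sentences$text) > max_len
  if (any(too_long)) {
    warn(paste0(sum(too_long), " sentence(s) longer than max_len = ", max_len,
                " truncated"))
    sentences$text[too_long] <- substr(sentences$text[too_long], 1L, max_len)
    keep <- gold$sub_tail < max_len & gold$obj_tail < max_len |
      !gold$id %in% sentences$id[too_long]
    n_drop <- sum(!keep)
    if (n_drop > 0L) {
      warn(paste0(n_drop, " gold triple(s) touching truncated positions dropped"))
      gold <- gold[keep, , drop = FALSE]
    }
  }
  list(sentences = sentences, gold = gold)
}

#' Fit the encoder and scoring head to a tagged corpus
#'
#' Gold triples are encoded to tag tensors once per sentence; parameters are
#' updated with Adam on the per-cell cross-entropy.  With a fixed seed the
#' run — shuffling, dropout, initialization — is fully reproducible.
#'
#' @param sentences Tibble with columns `id`, `text`.
#' @param gold Triple table with an `id` column; `relation` may be a 0-based
#'   integer index or a label resolvable against `schema`.
#' @param schema A [relation_schema()].
#' @param config A [train_config()].
#' @param model Optional starting `tl_model`; by default a fresh model is
#'   initialized from the corpus vocabulary and `config$seed`.
#' @param d,d_e Encoder and pair-representation widths for the default model.
#' @param val_sentences,val_gold Optional held-out split evaluated with
#'   strict matching every `config$val_every` epochs.
#' @param quiet Suppress the per-epoch progress messages?
#' @return A `tl_fit`: list with the trained `model`, a per-epoch `history`
#'   tibble (epoch, loss, and validation metrics when computed) and the
#'   `config`.
#' @export
train_model <- function(sentences, gold, schema, config = train_config(),
                        model = NULL, d = 32L, d_e = 2L * d,
                        val_sentences = NULL, val_gold = NULL, quiet = TRUE) {
  stopifnot(inherits(schema, "tl_schema"), inherits(config, "tl_train_config"))
  if (nrow(sentences) == 0L) abort("cannot train on an empty corpus")
  if (is.character(gold$relation)) {
    gold$relation <- rel_index(schema, gold$relation) # errors name the label
  }
  validate_triples(gold, K = schema$K)
  tc <- .truncate_corpus(sentences, gold, config$max_len)
  sentences <- tc$sentences
  gold <- tc$gold

  set.seed(config$seed)
  if (is.null(model)) {
    vocab <- sort(unique(unlist(strsplit(sentences$text, "", fixed = TRUE))))
    model <- new_model(schema, vocab, d = d, d_e = d_e)
  }
  par <- model$par
  K <- schema$K

  # precompute character ids and dense gold matrices per sentence
  prep <- map(seq_len(nrow(sentences)), function(i) {
    ids <- .char_ids(model, sentences$text[i])
    tri <- gold[gold$id == sentences$id[i], , drop = FALSE]
    list(ids = ids, gmat = .gold_mat(tri, length(ids), K))
  })

  n <- length(prep)
  state <- .adam_new(par)
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      acc <- NULL
      bl <- 0
      for (si in bt) {
        fb <- .fwd_bwd(par, prep[[si]]$ids, prep[[si]]$gmat, K,
                       config$dropout_rate, config$class_weight_background)
        bl <- bl + fb$loss
        acc <- if (is.null(acc)) fb$grads else {
          Map(`+`, acc, fb$grads)
        }
      }
      nb <- length(bt)
      acc <- lapply(acc, function(g) g / nb)
      upd <- .adam_step(par, acc, state, config$learning_rate)
      par <- upd$par
      state <- upd$state
      ep_loss <- ep_loss + bl
    }
    ep_loss <- ep_loss / n

    row <- tibble(epoch = epoch, loss = ep_loss,
                  val_precision = NA_real_, val_recall = NA_real_,
                  val_f1 = NA_real_)
    if (!is.null(val_sentences) && config$val_every > 0L &&
        (epoch %% config$val_every == 0L || epoch == config$epochs)) {
      model$par <- par
      pred <- predict_triples(model, val_sentences)
      mm <- strict_match(val_gold, pred, ids = val_sentences$id)
      row$val_precision <- mm$precision
      row$val_recall <- mm$recall
      row$val_f1 <- mm$f1
    }
    history[[epoch]] <- row
    if (!quiet) {
      inform(sprintf("epoch %3d  loss %.6f%s", epoch, ep_loss,
                     if (!is.na(row$val_f1)) sprintf("  val F1 %.4f", row$val_f1) else ""))
    }
  }
  model$par <- par
  structure(
    list(model = model, history = bind_rows(history), config = config),
    class = "tl_fit"
  )
}

#' @export
print.tl_fit <- function(x, ...) {
  cat("<triplink fit: ", nrow(x$history), " epochs, final loss ",
      signif(tail(x$history$loss, 1L), 6), ">\n", sep = "")
  invisible(x)
}

#' @describeIn train_model per-epoch training history as a tibble.
#' @param x A `tl_fit`.
#' @param ... Unused.
#' @export
tidy.tl_fit <- function(x, ...) x$history

#' @describeIn train_model one-row fit summary.
#' @export
glance.tl_fit <- function(x, ...) {
  h <- x$history
  last_val <- h$val_f1[!is.na(h$val_f1)]
  tibble(
    epochs = nrow(h),
    final_loss = tail(h$loss, 1L),
    val_f1 = if (length(last_val)) tail(last_val, 1L) else NA_real_,
    learning_rate = x$config$learning_rate,
    batch_size = x$config$batch_size
  )
}

#' Plot a training history
#'
#' Loss per epoch, plus validation strict F1 where recorded.
#'
#' @param object A `tl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_fit <- function(object, ...) {
  h <- object$history |>
    select("epoch", "loss", "val_f1") |>
    tidyr::pivot_longer(c("loss", "val_f1"), names_to = "metric") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
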