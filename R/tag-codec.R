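# Tag codec: triples <-> L x K x L global-pointer tag tensor.
#
# Conventions (used everywhere in the package):
#   * spans are 0-based inclusive [head, tail], head <= tail;
#   * rows of the tensor are subject positions, columns object positions;
#   * relation indices are 0-based;
#   * tags: 0 background, 1 head-head, 2 tail-tail, 3 head-tail.

# Collision priority: 1 > 2 > 3 > 0.  Only 1-over-3 arises from a single
# triple's own cells colliding (single-character object); the rest of the
# order is forced so that a triple whose subject and object are both single
# characters leaves exactly one final tag (tag 1) in its only cell.
.tag_rank <- c(1L, 4L, 3L, 2L) # rank of tags 0,1,2,3; higher rank wins

#' Triple tables
#'
#' Construct / validate a tibble of triples.  A triple table has integer
#' columns `sub_head`, `sub_tail`, `relation`, `obj_head`, `obj_tail`
#' (0-based, spans inclusive).  An optional `id` column keys triples to
#' sentences in multi-sentence tables.
#'
#' @param sub_head,sub_tail,obj_head,obj_tail Integer vectors, 0-based
#'   inclusive span endpoints.
#' @param relation Integer vector of 0-based relation indices.
#' @param id Optional sentence id (recycled).
#' @return A tibble with one row per triple, duplicate rows dropped.
#' @export
triple_tbl <- function(sub_head = integer(), sub_tail = integer(),
                       relation = integer(), obj_head = integer(),
                       obj_tail = integer(), id = NULL) {
  out <- tibble(
    sub_head = as.integer(sub_head), sub_tail = as.integer(sub_tail),
    relation = as.integer(relation),
    obj_head = as.integer(obj_head), obj_tail = as.integer(obj_tail)
  )
  if (!is.null(id)) out <- tibble(id = id, !!!out)
  validate_triples(out)
  distinct(out)
}

validate_triples <- function(triples, L = NULL, K = NULL) {
  needed <- c("sub_head", "sub_tail", "relation", "obj_head", "obj_tail")
  missing_cols <- setdiff(needed, names(triples))
  if (length(missing_cols)) {
    abort(paste0("triple table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(triples) == 0L) return(invisible(triples))
  with(triples, {
    if (any(sub_head > sub_tail) || any(obj_head > obj_tail)) {
      abort("entity spans must satisfy head <= tail")
    }
    if (any(sub_head < 0L) || any(obj_head < 0L) || any(relation < 0L)) {
      abort("spans and relation indices are 0-based and nonnegative")
    }
    if (!is.null(L) && (any(sub_tail >= L) || any(obj_tail >= L))) {
      abort(paste0("entity span out of range for sentence length ", L))
    }
    if (!is.null(K) && any(relation >= K)) {
      abort(paste0("relation index out of range for K = ", K))
    }
  })
  invisible(triples)
}

#' Resolve a tag collision
#'
#' Two link types can map to the same tensor cell when an entity is a single
#' character (head == tail).  The surviving tag is decided by the fixed total
#' order 1 > 2 > 3 > 0, so the outcome does not depend on write order.
#'
#' @param existing,incoming Integer vectors of tag values in `{0, 1, 2, 3}`.
#' @return The winning tag value(s).
#' @examples
#' resolve_collision(3, 1) # tag 1 overwrites tag 3
#' @export
resolve_collision <- function(existing, incoming) {
  existing <- as.integer(existing)
  incoming <- as.integer(incoming)
  if (any(!existing %in% 0:3) || any(!incoming %in% 0:3)) {
    abort("tag values must lie in {0, 1, 2, 3}")
  }
  ifelse(.tag_rank[existing + 1L] >= .tag_rank[incoming + 1L], existing, incoming)
}

#' Empty tag tensor
#'
#' @param L Sentence length (positive integer).
#' @param K Number of relations (positive integer).
#' @return An all-zero integer array of dimension `L x K x L`.
#' @export
tag_tensor <- function(L, K) {
  stopifnot(L >= 1L, K >= 1L)
  array(0L, dim = c(L, K, L))
}

#' Encode gold triples as a tag tensor
#'
#' Writes, for each triple, tag 1 at (sub_head, k, obj_head), tag 2 at
#' (sub_tail, k, obj_tail) and tag 3 at (sub_head, k, obj_tail).  Coincident
#' cells — within a triple (single-character entities) or across triples —
#' are resolved by [resolve_collision()].
#'
#' @param L Sentence length.
#' @param triples A triple table (see [triple_tbl()]); spans must lie in
#'   `[0, L)` and relations in `[0, K)`.
#' @param K Number of relations.
#' @return An `L x K x L` integer array with values in `{0, 1, 2, 3}`.
#' @examples
#' tt <- encode_triples(8, triple_tbl(4, 7, 0, 4, 5), K = 1)
#' which(tt != 0, arr.ind = TRUE) # three cells
#' @export
encode_triples <- function(L, triples, K) {
  L <- as.integer(L); K <- as.integer(K)
  validate_triples(triples, L = L, K = K)
  tags <- tag_tensor(L, K)
  if (nrow(triples) == 0L) return(tags)
  # 1-based array coordinates for the three cells of every triple
  cells <- with(triples, tibble(
    row = c(sub_head, sub_tail, sub_head) + 1L,
    rel = rep.int(relation, 3L) + 1L,
    col = c(obj_head, obj_tail, obj_tail) + 1L,
    tag = rep(c(1L, 2L, 3L), each = nrow(triples))
  ))
  # resolve collisions per cell: keep the highest-priority tag
  cells <- cells |>
    mutate(rank = .tag_rank[.data$tag + 1L]) |>
    group_by(.data$row, .data$rel, .data$col) |>
    summarise(tag = .data$tag[which.max(.data$rank)], .groups = "drop")
  tags[as.matrix(cells[, c("row", "rel", "col")])] <- cells$tag
  tags
}

.no_triples <- function() {
  tibble(
    sub_head = integer(), sub_tail = integer(), relation = integer(),
    obj_head = integer(), obj_tail = integer(), case = character()
  )
}

# decode one L x L relation slice; returns a list of equal-length vectors
# (sh, st, oh, ot, case), 1-based.  Plain vectorized base R: this sits in
# the inner loop of validation and of the oracle-equivalence tests, where
# data-frame-per-slice overhead would dominate.
.decode_slice <- function(m, L) {
  w1 <- which(m == 1L)
  if (length(w1) == 0L) return(NULL) # every decode case needs a tag 1
  sh1 <- (w1 - 1L) %% L + 1L
  oh1 <- (w1 - 1L) %/% L + 1L
  w2 <- which(m == 2L)
  st2 <- (w2 - 1L) %% L + 1L
  ot2 <- (w2 - 1L) %/% L + 1L
  w3 <- which(m == 3L)
  sh3 <- (w3 - 1L) %% L + 1L
  ot3 <- (w3 - 1L) %/% L + 1L

  out <- list()
  add <- function(sh, st, oh, ot, case) {
    if (length(sh)) {
      out[[length(out) + 1L]] <<- list(sh = sh, st = st, oh = oh, ot = ot,
                                       case = rep(case, length(sh)))
    }
  }

  # (A) general: tag3 fixes (sub_head, obj_tail); join heads and tails
  if (length(w3) && length(w2)) {
    p13 <- which(outer(sh3, sh1, "==") & outer(ot3, oh1, ">="), arr.ind = TRUE)
    if (nrow(p13)) {
      i3 <- p13[, 1L]; i1 <- p13[, 2L]
      p2 <- which(outer(ot3[i3], ot2, "==") & outer(sh3[i3], st2, "<="),
                  arr.ind = TRUE)
      if (nrow(p2)) {
        pi <- p2[, 1L]; i2 <- p2[, 2L]
        add(sh3[i3[pi]], st2[i2], oh1[i1[pi]], ot3[i3[pi]], "general")
      }
    }
  }
  # (B) single-char object: tag1 (sh, j) + tag2 (st, j) in one column; the
  # cell (sh, j) holds tag 1, so the no-tag-3-there guard is implicit
  if (length(w2)) {
    pb <- which(outer(oh1, ot2, "==") & outer(sh1, st2, "<="), arr.ind = TRUE)
    if (nrow(pb)) {
      add(sh1[pb[, 1L]], st2[pb[, 2L]], oh1[pb[, 1L]], oh1[pb[, 1L]],
          "single_obj")
    }
    # (C) single-char subject: tag1 (i, oh) + tag2 (i, ot) in one row
    pc <- which(outer(sh1, st2, "==") & outer(oh1, ot2, "<="), arr.ind = TRUE)
    if (nrow(pc)) {
      add(sh1[pc[, 1L]], sh1[pc[, 1L]], oh1[pc[, 1L]], ot2[pc[, 2L]],
          "single_subj")
    }
  }
  # (D) both single: lone tag1 with no tag2 in its row/column and no tag3
  # in its row — otherwise the cell belongs to one of the cases above
  lone <- !(oh1 %in% ot2) & !(sh1 %in% st2) & !(sh1 %in% sh3)
  add(sh1[lone], sh1[lone], oh1[lone], oh1[lone], "both_single")

  if (length(out) == 0L) return(NULL)
  list(sh = unlist(lapply(out, `[[`, "sh")),
       st = unlist(lapply(out, `[[`, "st")),
       oh = unlist(lapply(out, `[[`, "oh")),
       ot = unlist(lapply(out, `[[`, "ot")),
       case = unlist(lapply(out, `[[`, "case")))
}

#' Decode a tag tensor into triples
#'
#' Recovers the duplicate-free triple set from a (predicted or gold) tag
#' tensor.  Per relation slice, four guard-ordered cases are applied, from
#' the general pattern down to fully degenerate single-character ones:
#'
#' * general: a tag-3 cell (sh, ot) joined with tag-1 (sh, oh), oh <= ot,
#'   and tag-2 (st, ot), st >= sh;
#' * single-character object: tag-1 and tag-2 in one column (the tag 3 was
#'   overwritten by tag 1);
#' * single-character subject: tag-1 and tag-2 in one row (tag 3 overwritten
#'   by tag 2);
#' * both single characters: a lone tag-1 with no tag-2 in its row or
#'   column and no tag-3 in its row.
#'
#' Malformed tag patterns yield fewer triples, never an error.
#'
#' @param tags An `L x K x L` integer array with values in `{0, 1, 2, 3}`.
#' @param keep_case Keep a `case` column naming the decode case
#'   (`"general"`, `"single_obj"`, `"single_subj"`, `"both_single"`)?
#' @return A triple table, sorted, with 0-based spans.
#' @export
decode_tensor <- function(tags, keep_case = FALSE) {
  stopifnot(is.array(tags), length(dim(tags)) == 3L)
  L <- dim(tags)[1L]; K <- dim(tags)[2L]
  parts <- vector("list", K)
  for (k in seq_len(K)) {
    m <- tags[, k, , drop = FALSE]
    dim(m) <- c(L, L)
    found <- .decode_slice(m, L)
    if (is.null(found)) next
    parts[[k]] <- tibble(
      sub_head = found$sh - 1L, sub_tail = found$st - 1L,
      relation = k - 1L,
      obj_head = found$oh - 1L, obj_tail = found$ot - 1L,
      case = found$case
    )
  }
  res <- bind_rows(parts)
  if (nrow(res) == 0L) res <- .no_triples()
  keep <- !duplicated(res[, c("sub_head", "sub_tail", "relation",
                              "obj_head", "obj_tail")])
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$relation, res$sub_head, res$sub_tail,
                   res$obj_head, res$obj_tail), , drop = FALSE]
  if (!keep_case) res$case <- NULL
  res
}

#' Brute-force reference decoder
#'
#' Enumerates every candidate triple ((sh, st), k, (oh, ot)) with sh <= st,
#' oh <= ot and accepts it when the tensor carries exactly the cell pattern
#' that encoding the candidate alone would produce (after intra-triple
#' collision resolution), with the degenerate single-character cases subject
#' to the same absence guards as [decode_tensor()].  Independent of the
#' production decoder; used as its oracle in tests.
#'
#' @inheritParams decode_tensor
#' @return A triple table with 0-based spans.
#' @export
oracle_decode <- function(tags) {
  stopifnot(is.array(tags), length(dim(tags)) == 3L)
  L <- dim(tags)[1L]; K <- dim(tags)[2L]
  grid <- .oracle_grid(L, K)
  sh <- grid$sh; st <- grid$st; oh <- grid$oh; ot <- grid$ot; k <- grid$k

  at <- function(i, j) tags[cbind(i, k, j)]
  sub_single <- sh == st
  obj_single <- oh == ot

  # expected observed pattern after intra-candidate collision resolution
  ok <- ifelse(
    !sub_single & !obj_single,
    at(sh, oh) == 1L & at(st, ot) == 2L & at(sh, ot) == 3L,
    ifelse(
      !sub_single & obj_single,
      at(sh, oh) == 1L & at(st, ot) == 2L, # tag 3 overwritten by tag 1
      ifelse(
        sub_single & !obj_single,
        at(sh, oh) == 1L & at(st, ot) == 2L, # tag 3 overwritten by tag 2
        at(sh, oh) == 1L # all three cells collapse to tag 1
      )
    )
  )

  # degenerate both-single candidates additionally require that their lone
  # tag-1 cell is not part of a larger pattern
  bs <- which(ok & sub_single & obj_single)
  if (length(bs)) {
    keep <- vapply(bs, function(i) {
      row_i <- sh[i]; col_j <- oh[i]; kk <- k[i]
      !any(tags[, kk, col_j] == 2L) &&
        !any(tags[row_i, kk, ] == 2L) &&
        !any(tags[row_i, kk, ] == 3L)
    }, logical(1))
    ok[bs] <- keep
  }

  res <- tibble(
    sub_head = sh[ok] - 1L, sub_tail = st[ok] - 1L, relation = k[ok] - 1L,
    obj_head = oh[ok] - 1L, obj_tail = ot[ok] - 1L
  )
  res <- res[!duplicated(res), , drop = FALSE]
  res[order(res$relation, res$sub_head, res$sub_tail,
            res$obj_head, res$obj_tail), , drop = FALSE]
}

# memoized candidate enumeration for oracle_decode (the oracle is hammered
# by the equivalence tests at a handful of small sizes)
.oracle_cache <- new.env(parent = emptyenv())
.oracle_grid <- function(L, K) {
  key <- paste0(L, "_", K)
  hit <- .oracle_cache[[key]]
  if (!is.null(hit)) return(hit)
  spans <- expand.grid(h = seq_len(L), t = seq_len(L))
  spans <- spans[spans$h <= spans$t, , drop = FALSE]
  n_sp <- nrow(spans)
  cand <- expand.grid(s = seq_len(n_sp), o = seq_len(n_sp), k = seq_len(K))
  grid <- list(sh = spans$h[cand$s], st = spans$t[cand$s],
               oh = spans$h[cand$o], ot = spans$t[cand$o], k = cand$k)
  .oracle_cache[[key]] <- grid
  grid
}

#' Sparse tensor serialization
#'
#' A tag tensor serializes to a list of nonzero `(row, relation, col, tag)`
#' records (0-based) plus the dimensions `L` and `K`; the round trip is
#' lossless.
#'
#' @inheritParams decode_tensor
#' @return `tensor_cells()`: a tibble of nonzero cells (0-based coordinates).
#' @export
tensor_cells <- function(tags) {
  stopifnot(is.array(tags), length(dim(tags)) == 3L)
  w <- which(tags != 0L, arr.ind = TRUE)
  tibble(
    row = as.integer(w[, 1L]) - 1L,
    relation = as.integer(w[, 2L]) - 1L,
    col = as.integer(w[, 3L]) - 1L,
    tag = as.integer(tags[w])
  ) |> arrange(.data$relation, .data$row, .data$col)
}

#' @rdname tensor_cells
#' @param cells A tibble as returned by `tensor_cells()`.
#' @param L,K Tensor dimensions.
#' @return `cells_to_tensor()`: the reconstructed `L x K x L` array.
#' @export
cells_to_tensor <- function(cells, L, K) {
  tags <- tag_tensor(L, K)
  if (nrow(cells)) {
    if (any(!cells$tag %in% 1:3)) abort("cell tags must lie in {1, 2, 3}")
    tags[cbind(cells$row + 1L, cells$relation + 1L, cells$col + 1L)] <-
      as.integer(cells$tag)
  }
  tags
}

#' @rdname tensor_cells
#' @param path File path for the JSON form.
#' @export
write_tag_tensor <- function(tags, path) {
  d <- dim(tags)
  jsonlite::write_json(
    list(L = d[1L], K = d[2L], cells = tensor_cells(tags)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname tensor_cells
#' @export
read_tag_tensor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as_tibble(x$cells)
  if (length(cells) == 0L || nrow(cells) == 0L) {
    cells <- tibble(row = integer(), relation = integer(),
                    col = integer(), tag = integer())
  }
  cells_to_tensor(cells, L = x$L, K = x$K)
}
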