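# Strict triple-match evaluation and the analysis breakdowns:
# overlap pattern (Normal / SEO / EPO), triples-per-sentence buckets,
# per-relation metrics.

.metrics_row <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         precision = precision, recall = recall, f1 = f1)
}

.triple_cols <- c("sub_head", "sub_tail", "relation", "obj_head", "obj_tail")

#' Strict triple matching
#'
#' A predicted triple is a true positive only if a gold triple of the same
#' sentence matches it exactly: both entity spans and the relation.  Counts
#' are micro-averaged over sentences; each gold triple can absorb at most
#' one prediction (triples are sets, so duplicates are collapsed first).
#'
#' @param gold,pred Triple tables with an `id` column.
#' @param ids Optional full universe of sentence ids (so predictions for
#'   sentences whose gold set is empty are not flagged as unknown).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @examples
#' g <- triple_tbl(0, 1, 0, 3, 4, id = "a")
#' strict_match(g, g)
#' @export
strict_match <- function(gold, pred, ids = NULL) {
  universe <- unique(c(gold$id, ids))
  bad <- setdiff(unique(pred$id), universe)
  if (length(bad)) {
    abort(paste0("predictions refer to unknown sentence id(s): ",
                 paste(bad, collapse = ", ")))
  }
  gold <- distinct(gold[, c("id", .triple_cols)])
  pred <- distinct(pred[, c("id", .triple_cols)])
  tp <- nrow(inner_join(pred, gold, by = c("id", .triple_cols)))
  .metrics_row(tp, nrow(pred) - tp, nrow(gold) - tp)
}

#' Overlap pattern of one sentence's gold triples
#'
#' * `EPO` (entity-pair overlap): two distinct triples share both the
#'   subject span and the object span (hence differ in relation).
#' * `SEO` (single-entity overlap): two distinct triples share exactly one
#'   entity span (in any role).
#' * `Normal`: neither holds.
#'
#' `SEO` and `EPO` can co-occur; `Normal` excludes both.
#'
#' @param triples Nonempty triple table of a single sentence.
#' @return Character vector of applicable labels.
#' @export
classify_overlap <- function(triples) {
  n <- nrow(triples)
  if (n == 0L) abort("classify_overlap needs a nonempty triple set")
  triples <- distinct(triples[, .triple_cols])
  n <- nrow(triples)
  if (n == 1L) return("Normal")
  sub <- paste(triples$sub_head, triples$sub_tail)
  obj <- paste(triples$obj_head, triples$obj_tail)
  epo <- FALSE
  seo <- FALSE
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      same_pair <- sub[a] == sub[b] && obj[a] == obj[b]
      if (same_pair) {
        epo <- TRUE
        next
      }
      shared <- length(intersect(c(sub[a], obj[a]), c(sub[b], obj[b])))
      if (shared == 1L) seo <- TRUE
    }
  }
  labels <- c(if (seo) "SEO", if (epo) "EPO")
  if (is.null(labels)) "Normal" else labels
}

#' Overlap labels for every sentence of a corpus
#'
#' @param gold Triple table with an `id` column.
#' @param ids Optional sentence universe; ids without gold triples get no row.
#' @return Tibble `id`, `normal`, `seo`, `epo` (logical flags).
#' @export
overlap_labels <- function(gold, ids = NULL) {
  per <- split(gold, gold$id)
  out <- map(names(per), function(i) {
    lab <- classify_overlap(per[[i]])
    tibble(id = i, normal = identical(lab, "Normal"),
           seo = "SEO" %in% lab, epo = "EPO" %in% lab)
  })
  bind_rows(out)
}

#' Bucket sentences by gold triple count
#'
#' Five categories — 1, 2, 3, 4 and 5 or more triples per sentence — as used
#' in the sentence-complexity analysis.  Sentences with an empty gold set
#' (possible after anchoring losses) fall into a `"0"` bucket.
#'
#' @param gold Triple table with an `id` column.
#' @param ids Optional full sentence universe (needed to count empty
#'   sentences).
#' @return Tibble `id`, `n_triples`, `bucket` (factor with levels
#'   `0, 1, 2, 3, 4, 5+`).
#' @export
bucket_by_triple_count <- function(gold, ids = NULL) {
  counts <- gold |>
    distinct(.data$id, .data$sub_head, .data$sub_tail, .data$relation,
             .data$obj_head, .data$obj_tail) |>
    count(.data$id, name = "n_triples")
  if (!is.null(ids)) {
    counts <- tibble(id = ids) |>
      left_join(counts, by = "id") |>
      mutate(n_triples = ifelse(is.na(.data$n_triples), 0L, .data$n_triples))
  }
  counts |>
    mutate(
      bucket = factor(
        ifelse(.data$n_triples >= 5L, "5+", as.character(.data$n_triples)),
        levels = c("0", "1", "2", "3", "4", "5+")
      )
    )
}

#' Strict metrics per relation
#'
#' Strict matching restricted to the triples of each schema relation;
#' per-relation counts add up to the global strict-match counts.
#'
#' @inheritParams strict_match
#' @param schema A [relation_schema()].
#' @return Tibble with one row per relation: `relation`, `label`, counts,
#'   metrics and an `absent` flag (no gold triples and no predictions).
#' @export
per_relation_metrics <- function(gold, pred, schema, ids = NULL) {
  stopifnot(inherits(schema, "tl_schema"))
  rows <- map(seq_len(schema$K) - 1L, function(k) {
    m <- strict_match(gold[gold$relation == k, , drop = FALSE],
                      pred[pred$relation == k, , drop = FALSE],
                      ids = unique(c(gold$id, pred$id, ids)))
    tibble(relation = k, label = rel_label(schema, k), !!!m,
           absent = m$tp + m$fp + m$fn == 0L)
  })
  bind_rows(rows)
}

#' Full evaluation report
#'
#' Global strict metrics plus the three analysis breakdowns: per overlap
#' pattern (a sentence counts under every label that applies to it), per
#' triples-per-sentence bucket, and per relation.
#'
#' @inheritParams per_relation_metrics
#' @param ids Optional full sentence universe.
#' @return A list of class `tl_report` with tibbles `global`, `by_overlap`,
#'   `by_bucket`, `by_relation`.
#' @export
evaluation_report <- function(gold, pred, schema, ids = NULL) {
  universe <- unique(c(gold$id, ids))
  global <- strict_match(gold, pred, ids = universe)

  labs <- overlap_labels(gold)
  by_overlap <- bind_rows(map(c("Normal", "SEO", "EPO"), function(lb) {
    sel <- switch(lb, Normal = labs$id[labs$normal], SEO = labs$id[labs$seo],
                  EPO = labs$id[labs$epo])
    m <- strict_match(gold[gold$id %in% sel, , drop = FALSE],
                      pred[pred$id %in% sel, , drop = FALSE], ids = sel)
    tibble(pattern = lb, n_sentences = length(sel), !!!m)
  }))

  buckets <- bucket_by_triple_count(gold, ids = universe)
  by_bucket <- bind_rows(map(levels(buckets$bucket), function(bk) {
    sel <- buckets$id[buckets$bucket == bk]
    if (length(sel) == 0L && bk == "0") return(NULL)
    m <- strict_match(gold[gold$id %in% sel, , drop = FALSE],
                      pred[pred$id %in% sel, , drop = FALSE], ids = sel)
    tibble(bucket = bk, n_sentences = length(sel), !!!m)
  }))

  structure(
    list(global = global, by_overlap = by_overlap, by_bucket = by_bucket,
         by_relation = per_relation_metrics(gold, pred, schema, ids = universe)),
    class = "tl_report"
  )
}

#' @export
print.tl_report <- function(x, ...) {
  g <- x$global
  cat(sprintf("<evaluation: P %.4f  R %.4f  F1 %.4f  (tp %d, fp %d, fn %d)>\n",
              g$precision, g$recall, g$f1, g$tp, g$fp, g$fn))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A `tl_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "tl_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Plot an evaluation report
#'
#' Bar charts of strict F1 by overlap pattern, triple-count bucket and
#' relation.
#'
#' @param object A `tl_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_report <- function(object, ...) {
  d <- bind_rows(
    object$by_overlap |> mutate(facet = "overlap pattern") |> rename(group = "pattern"),
    object$by_bucket |> mutate(facet = "triples per sentence") |> rename(group = "bucket"),
    object$by_relation |> mutate(facet = "relation") |> rename(group = "label") |>
      select(-"relation")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$f1)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$facet), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "strict F1") +
    ggplot2::ylim(0, 1)
}
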