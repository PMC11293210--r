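# CMeIE-style JSON-lines I/O.
#
# One JSON object per line: {"text": ..., "spo_list": [{"predicate": ...,
# "subject": ..., "object": {"@value": ...}}, ...]}.  The public release
# carries surface forms only (no character offsets), so spans are recovered
# by exact substring search over code points.  Entity-type fields
# (subject_type / object_type) are preserved verbatim but never used.

.spo_value <- function(obj) {
  # the object field nests its value under "@value" in the public dialect;
  # plain strings are accepted too
  if (is.list(obj)) {
    v <- obj[["@value"]]
    if (is.null(v)) NULL else as.character(v)
  } else {
    as.character(obj)
  }
}

#' Read a CMeIE-style JSON-lines corpus
#'
#' Malformed lines are skipped with a message naming the line numbers;
#' predicates missing from `schema` are collected and reported once with
#' counts (their triples are kept in the raw records and dropped later by
#' [anchor_spans()]).
#'
#' @param path Path to a JSON-lines file.
#' @param schema Optional [relation_schema()] used to report unknown
#'   predicates.
#' @return A tibble of raw records: `id` (`r<line>` or the record's own id
#'   field), `text`, and `spo` (list column of per-record tibbles with
#'   `predicate`, `subject`, `object`).
#' @export
read_jsonl <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  records <- vector("list", length(lines))
  bad <- integer()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$text) || !nzchar(rec$text)) {
      bad <- c(bad, i)
      next
    }
    spo <- map(rec$spo_list, function(s) {
      obj <- .spo_value(s$object)
      if (is.null(s$predicate) || is.null(s$subject) || is.null(obj)) return(NULL)
      tibble(predicate = as.character(s$predicate),
             subject = as.character(s$subject), object = obj)
    })
    spo <- bind_rows(spo)
    if (nrow(spo) == 0L) {
      spo <- tibble(predicate = character(), subject = character(),
                    object = character())
    }
    id <- if (!is.null(rec$id)) as.character(rec$id) else sprintf("r%05d", i)
    records[[i]] <- tibble(id = id, text = as.character(rec$text), spo = list(spo))
  }
  if (length(bad)) {
    inform(paste0("skipped ", length(bad), " malformed line(s): ",
                  paste(head(bad, 20L), collapse = ", ")))
  }
  out <- bind_rows(records)
  if (nrow(out) == 0L) abort(paste0("no parseable records in ", path))
  if (!is.null(schema)) {
    preds <- unlist(map(out$spo, ~ .x$predicate))
    unknown <- preds[!preds %in% schema$labels]
    if (length(unknown)) {
      tb <- table(unknown)
      inform(paste0("unknown predicate(s): ",
                    paste0(names(tb), " (", as.integer(tb), ")", collapse = ", ")))
    }
  }
  out
}

# all 0-based start offsets (code points) of `needle` in `haystack`
.occurrences <- function(haystack, needle) {
  if (!nzchar(needle)) return(integer())
  m <- gregexpr(needle, haystack, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

#' Anchor surface-form triples to character spans
#'
#' Locates each subject/object string in its sentence by exact substring
#' search (counting code points, not bytes).  Under policy `"first"` the
#' first occurrence is used; under `"all"` one triple is emitted per
#' (subject occurrence, object occurrence) pair.  Triples whose entity
#' cannot be found, or whose predicate is not in the schema, are dropped
#' with a reason; a record losing all its triples stays in the corpus with
#' an empty gold set.
#'
#' @param records Raw records from [read_jsonl()].
#' @param schema A [relation_schema()].
#' @param policy Occurrence policy, `"first"` (default) or `"all"`.
#' @return A triple table with `id` and surface-form columns; the attribute
#'   `"dropped"` holds a tibble of dropped triples with reasons.
#' @export
anchor_spans <- function(records, schema, policy = c("first", "all")) {
  policy <- arg_match(policy)
  stopifnot(inherits(schema, "tl_schema"))
  out <- vector("list", nrow(records))
  dropped <- list()
  for (i in seq_len(nrow(records))) {
    text <- records$text[i]
    spo <- records$spo[[i]]
    rows <- list()
    for (r in seq_len(nrow(spo))) {
      pred <- spo$predicate[r]
      if (!pred %in% schema$labels) {
        dropped[[length(dropped) + 1L]] <- tibble(
          id = records$id[i], predicate = pred, subject = spo$subject[r],
          object = spo$object[r], reason = "unknown predicate")
        next
      }
      s_occ <- .occurrences(text, spo$subject[r])
      o_occ <- .occurrences(text, spo$object[r])
      if (length(s_occ) == 0L || length(o_occ) == 0L) {
        dropped[[length(dropped) + 1L]] <- tibble(
          id = records$id[i], predicate = pred, subject = spo$subject[r],
          object = spo$object[r], reason = "entity string not found in text")
        next
      }
      if (policy == "first") {
        s_occ <- s_occ[1L]
        o_occ <- o_occ[1L]
      }
      pairs <- expand.grid(s = s_occ, o = o_occ)
      rows[[length(rows) + 1L]] <- tibble(
        id = records$id[i],
        sub_head = as.integer(pairs$s),
        sub_tail = as.integer(pairs$s) + nchar(spo$subject[r]) - 1L,
        relation = rel_index(schema, pred),
        obj_head = as.integer(pairs$o),
        obj_tail = as.integer(pairs$o) + nchar(spo$object[r]) - 1L,
        subject = spo$subject[r], object = spo$object[r]
      )
    }
    out[[i]] <- bind_rows(rows)
  }
  gold <- bind_rows(out)
  if (nrow(gold) == 0L) {
    gold <- tibble(id = character(), sub_head = integer(), sub_tail = integer(),
                   relation = integer(), obj_head = integer(),
                   obj_tail = integer(), subject = character(),
                   object = character())
  }
  gold <- distinct(gold)
  dropped <- if (length(dropped)) bind_rows(dropped) else
    tibble(id = character(), predicate = character(), subject = character(),
           object = character(), reason = character())
  if (nrow(dropped)) {
    inform(paste0(nrow(dropped), " triple(s) dropped during anchoring"))
  }
  attr(gold, "dropped") <- dropped
  gold
}

.spo_json_line <- function(text, triples, schema) {
  spo <- map(seq_len(nrow(triples)), function(r) {
    list(
      predicate = rel_label(schema, triples$relation[r]),
      subject = substr(text, triples$sub_head[r] + 1L, triples$sub_tail[r] + 1L),
      object = list(`@value` = substr(text, triples$obj_head[r] + 1L,
                                      triples$obj_tail[r] + 1L))
    )
  })
  jsonlite::toJSON(list(text = text, spo_list = spo), auto_unbox = TRUE)
}

#' Write triples in the CMeIE-style dialect
#'
#' Emits one JSON line per sentence, with entity surface forms sliced from
#' the sentence text; reading the file back and re-anchoring recovers the
#' spans whenever surface forms are unambiguous.  Sentences without triples
#' get an empty `spo_list`.
#'
#' @param sentences Tibble with `id` and `text`.
#' @param triples Triple table with an `id` column (predicted or gold spans).
#' @param schema A [relation_schema()].
#' @param path Output path.
#' @export
write_predictions <- function(sentences, triples, schema, path) {
  stopifnot(all(c("id", "text") %in% names(sentences)))
  validate_triples(triples, K = schema$K)
  if (!"id" %in% names(triples)) triples$id <- character(nrow(triples))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    tr <- triples[triples$id == sentences$id[i], , drop = FALSE]
    L <- nchar(sentences$text[i])
    if (nrow(tr) && (any(tr$sub_tail >= L) || any(tr$obj_tail >= L))) {
      abort(paste0("span out of range for sentence ", sentences$id[i]))
    }
    writeLines(.spo_json_line(sentences$text[i], tr, schema), con)
  }
  invisible(path)
}

#' Write a synthetic corpus to disk
#'
#' The corpus goes out in the same JSON-lines dialect [read_jsonl()] reads,
#' plus a TSV sidecar with the exact gold spans so downstream tools can
#' bypass string anchoring.
#'
#' @param corpus A `tl_corpus` from [generate_corpus()].
#' @param path Output path for the JSON-lines file.
#' @param spans_path Output path for the span sidecar (default: `path` with
#'   a `.spans.tsv` suffix).
#' @export
write_corpus <- function(corpus, path, spans_path = paste0(path, ".spans.tsv")) {
  stopifnot(inherits(corpus, "tl_corpus"))
  write_predictions(corpus$sentences, corpus$gold, corpus$schema, path)
  utils::write.table(
    corpus$gold[, c("id", .triple_cols)], spans_path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
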