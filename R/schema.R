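#' Relation schema
#'
#' An ordered set of K relation labels.  The position of a label fixes its
#' 0-based relation index for the lifetime of a run; the schema is embedded
#' in checkpoints so indices stay stable across sessions.
#'
#' @param labels Character vector of unique relation labels.
#' @return An object of class `tl_schema` with elements `labels` and `K`.
#' @examples
#' sch <- relation_schema(c("diseased_part", "synonym"))
#' rel_index(sch, "synonym")
#' @export
relation_schema <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    abort("a relation schema needs at least one label")
  }
  if (anyDuplicated(labels)) {
    abort("relation labels must be unique")
  }
  structure(list(labels = labels, K = length(labels)), class = "tl_schema")
}

#' @export
print.tl_schema <- function(x, ...) {
  cat("<relation schema: ", x$K, " relations>\n", sep = "")
  cat(paste0("  [", seq_along(x$labels) - 1L, "] ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

#' @describeIn relation_schema 0-based index of `label`; errors on unknown labels,
#'   naming them.
#' @param schema A `tl_schema`.
#' @param label Character vector of labels to resolve.
#' @export
rel_index <- function(schema, label) {
  stopifnot(inherits(schema, "tl_schema"))
  idx <- match(label, schema$labels)
  if (anyNA(idx)) {
    abort(paste0(
      "unknown relation label(s): ",
      paste(unique(label[is.na(idx)]), collapse = ", ")
    ))
  }
  idx - 1L
}

#' @describeIn relation_schema label for a 0-based relation index.
#' @param k Integer vector of 0-based relation indices.
#' @export
rel_label <- function(schema, k) {
  stopifnot(inherits(schema, "tl_schema"))
  if (any(k < 0L | k >= schema$K)) {
    abort("relation index out of range [0, K)")
  }
  schema$labels[k + 1L]
}
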