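# Synthetic corpus generator.
#
# Sentences are character sequences over an abstract glyph vocabulary; no
# attempt is made at fluent text — the tagging scheme operates on spans.
# Learnability is built in deliberately: every entity type owns three marker
# glyphs (head, tail, singleton) that occur nowhere else, interiors and
# filler come from a shared neutral pool, and a sparse "link table" over
# entity-type pairs decides which relations hold between which types.  Gold
# tags are then a deterministic function of the character pair at a cell,
# so the pair-scoring head can in principle reach perfect strict F1 — which
# is exactly what a parameter-recovery experiment needs.
#
# Overlap patterns are realized structurally:
#   * EPO: one type pair linked under two distinct relations;
#   * SEO: two link entries sharing one entity type (the shared entity is
#     planted once and reused by both triples);
#   * Normal: link entries with disjoint types.
# Entries grouped in one sentence are chosen so that no unintended link
# exists between the planted types, keeping the gold set exactly the
# planted set.

.default_glyphs <- function(n) {
  pool <- c(letters, LETTERS, as.character(0:9),
            strsplit("+-*/=@#%&!?.:;<>~^", "")[[1L]])
  if (n <= length(pool)) {
    pool[seq_len(n)]
  } else {
    vapply(seq_len(n) - 1L, function(i) intToUtf8(0x4E00 + i), character(1))
  }
}

#' Generator configuration
#'
#' Defaults describe the desk-scale study corpus: 2000 sentences over a
#' 60-glyph vocabulary, 4 relations, sentences of at most 30 characters.
#' The triples-per-sentence distribution and the overlap-pattern mix follow
#' the published corpus statistics of the CMeIE training split (about 37.5%
#' single-triple sentences; Normal 39%, SEO 52%, EPO 9% of sentences).
#'
#' @param n_sentences Number of sentences to generate.
#' @param K Number of relation types (>= 2 whenever EPO has mass).
#' @param vocab_size Total glyph count; must cover `3 * n_entity_types`
#'   marker glyphs plus at least 4 neutral filler glyphs.
#' @param max_len Maximum sentence length in characters (<= 256).
#' @param entity_len_distribution Named probabilities over multi-character
#'   entity lengths (names are the lengths, >= 2).
#' @param p_single_char Probability that an entity is a single character.
#' @param triples_per_sentence_distribution Probabilities for 1..4 and 5+
#'   triples per sentence (length 5; 5+ realizes as 5 or 6).
#' @param pattern_mix Sentence-level marginal probabilities of the Normal,
#'   SEO and EPO patterns (named, summing to 1).
#' @param p_nested Per-eligible-triple probability of planting the object
#'   strictly inside the subject span.
#' @param reject_cross_triple_collisions Re-draw any sentence whose gold set
#'   does not survive the encode/decode round trip.
#' @param allow_repeated_surfaces Stress-test flag: let filler reuse marker
#'   glyphs, so entity surface strings are no longer guaranteed unique
#'   within a sentence (anchoring by substring search becomes ambiguous).
#' @param n_entity_types Number of abstract entity types (>= 10).
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return A list of class `tl_gen_config`.
#' @export
gen_config <- function(n_sentences = 2000L, K = 4L, vocab_size = 60L,
                       max_len = 30L,
                       entity_len_distribution = c(`2` = 0.45, `3` = 0.30,
                                                   `4` = 0.15, `5` = 0.10),
                       p_single_char = 0.1,
                       triples_per_sentence_distribution =
                         c(0.375, 0.207, 0.129, 0.091, 0.198),
                       pattern_mix = c(Normal = 0.387, SEO = 0.525, EPO = 0.088),
                       p_nested = 0.15,
                       reject_cross_triple_collisions = TRUE,
                       allow_repeated_surfaces = FALSE,
                       n_entity_types = 16L,
                       seed = 1L) {
  stopifnot(n_sentences >= 0L, K >= 1L, max_len >= 4L, max_len <= 256L,
            n_entity_types >= 10L, p_single_char >= 0, p_single_char < 1,
            p_nested >= 0, p_nested <= 1)
  if (vocab_size < 3L * n_entity_types + 4L) {
    abort("vocab_size must cover 3 * n_entity_types marker glyphs plus >= 4 filler glyphs")
  }
  norm <- function(p) {
    if (any(p < 0) || sum(p) <= 0) abort("probabilities must be nonnegative and sum > 0")
    p / sum(p)
  }
  entity_len_distribution <- norm(entity_len_distribution)
  if (any(as.integer(names(entity_len_distribution)) < 2L)) {
    abort("entity_len_distribution covers multi-character lengths (>= 2)")
  }
  if (length(triples_per_sentence_distribution) != 5L) {
    abort("triples_per_sentence_distribution needs 5 entries (1..4, 5+)")
  }
  triples_per_sentence_distribution <- norm(triples_per_sentence_distribution)
  if (!setequal(names(pattern_mix), c("Normal", "SEO", "EPO"))) {
    abort("pattern_mix must name Normal, SEO and EPO")
  }
  pattern_mix <- norm(pattern_mix)[c("Normal", "SEO", "EPO")]
  if (pattern_mix[["EPO"]] > 0 && K < 2L) {
    abort("EPO sentences need K >= 2 (two relations over one entity pair)")
  }
  if ((pattern_mix[["SEO"]] > 0 || pattern_mix[["EPO"]] > 0) && K < 2L) {
    abort("overlap patterns need K >= 2")
  }
  structure(
    list(n_sentences = as.integer(n_sentences), K = as.integer(K),
         vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
         entity_len_distribution = entity_len_distribution,
         p_single_char = p_single_char,
         triples_per_sentence_distribution = triples_per_sentence_distribution,
         pattern_mix = pattern_mix, p_nested = p_nested,
         reject_cross_triple_collisions = reject_cross_triple_collisions,
         allow_repeated_surfaces = allow_repeated_surfaces,
         n_entity_types = as.integer(n_entity_types),
         seed = as.integer(seed)),
    class = "tl_gen_config"
  )
}

# vocabulary layout: glyph roles per entity type plus neutral filler
.build_vocab <- function(config) {
  glyphs <- .default_glyphs(config$vocab_size)
  E <- config$n_entity_types
  roles <- tibble(
    glyph = glyphs,
    role = c(rep(c("head", "tail", "single"), E),
             rep("filler", config$vocab_size - 3L * E)),
    type = c(rep(seq_len(E), each = 3L),
             rep(NA_integer_, config$vocab_size - 3L * E))
  )
  roles
}

# sparse link table over entity-type pairs; relations 0-based
.build_link_table <- function(K, E) {
  pick2 <- function() sample.int(K, 2L) - 1L # two distinct relations
  epo <- pick2()
  seo_s <- pick2()
  seo_o <- pick2()
  normal_types <- seq.int(9L, E)
  n_norm <- length(normal_types) %/% 2L
  rows <- list(
    tibble(sub_type = 1L, obj_type = 2L, relation = epo,
           block = 1L, kind = "epo"),
    tibble(sub_type = 3L, obj_type = c(4L, 5L), relation = seo_s,
           block = 2L, kind = "seo"),
    tibble(sub_type = c(6L, 7L), obj_type = 8L, relation = seo_o,
           block = 3L, kind = "seo")
  )
  for (i in seq_len(n_norm)) {
    rows[[length(rows) + 1L]] <- tibble(
      sub_type = normal_types[2L * i - 1L], obj_type = normal_types[2L * i],
      relation = sample.int(K, 1L) - 1L, block = 3L + i, kind = "normal"
    )
  }
  out <- bind_rows(rows)
  out$entry <- seq_len(nrow(out))
  out
}

# choose link-table entries realizing `pattern` with `n` triples
.choose_entries <- function(link_table, pattern, n) {
  normals <- link_table[link_table$kind == "normal", ]
  seo_blocks <- unique(link_table$block[link_table$kind == "seo"])
  draw_fill <- function(pool_blocks, m) {
    # one entry per block; seo blocks contribute a single random entry
    if (m == 0L) return(integer())
    picked_blocks <- pool_blocks[sample.int(length(pool_blocks), m)]
    vapply(picked_blocks, function(b) {
      cand <- link_table$entry[link_table$block == b]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
  }
  if (pattern == "Normal") {
    pool <- c(normals$block, seo_blocks)
    if (n > length(pool)) return(NULL)
    draw_fill(pool, n)
  } else if (pattern == "SEO") {
    if (n < 2L) return(NULL)
    blk <- seo_blocks[sample.int(length(seo_blocks), 1L)]
    base <- link_table$entry[link_table$block == blk]
    pool <- c(normals$block, setdiff(seo_blocks, blk))
    if (n - 2L > length(pool)) return(NULL)
    c(base, draw_fill(pool, n - 2L))
  } else { # EPO
    if (n < 2L) return(NULL)
    base <- link_table$entry[link_table$kind == "epo"]
    pool <- c(normals$block, seo_blocks)
    if (n - 2L > length(pool)) return(NULL)
    c(base, draw_fill(pool, n - 2L))
  }
}

# sanity: the only link-table entries among the planted types are the chosen
# ones — otherwise the gold set would be incomplete
.assert_no_stray_links <- function(link_table, entries) {
  chosen <- link_table[link_table$entry %in% entries, ]
  types <- unique(c(chosen$sub_type, chosen$obj_type))
  present <- link_table[link_table$sub_type %in% types &
                          link_table$obj_type %in% types, ]
  if (!setequal(present$entry, chosen$entry)) {
    abort("internal error: stray link among planted entity types")
  }
  invisible(TRUE)
}

# realize one entity instance of a type
.make_entity <- function(type, roles, filler_pool, config, force = NULL) {
  markers <- roles[!is.na(roles$type) & roles$type == type, ]
  single <- if (is.null(force)) runif(1) < config$p_single_char else force == "single"
  if (single) {
    return(list(type = type, single = TRUE, len = 1L,
                chars = markers$glyph[markers$role == "single"]))
  }
  lens <- as.integer(names(config$entity_len_distribution))
  len <- lens[sample.int(length(lens), 1L,
                         prob = config$entity_len_distribution)]
  interior <- if (len > 2L) {
    filler_pool[sample.int(length(filler_pool), len - 2L, replace = TRUE)]
  } else {
    character()
  }
  list(type = type, single = FALSE, len = len,
       chars = c(markers$glyph[markers$role == "head"], interior,
                 markers$glyph[markers$role == "tail"]))
}

# build one sentence for the chosen entries; returns NULL on budget failure
.build_sentence <- function(link_table, entries, roles, config,
                            force_entity = NULL, force_nested = FALSE) {
  chosen <- link_table[link_table$entry %in% entries, ]
  types <- unique(c(chosen$sub_type, chosen$obj_type))
  filler_pool <- if (config$allow_repeated_surfaces) {
    roles$glyph
  } else {
    roles$glyph[roles$role == "filler"]
  }

  ents <- setNames(vector("list", length(types)), as.character(types))
  for (ty in types) {
    force <- NULL
    if (!is.null(force_entity) && as.character(ty) %in% names(force_entity)) {
      force <- force_entity[[as.character(ty)]]
    }
    ents[[as.character(ty)]] <- .make_entity(ty, roles, filler_pool, config, force)
  }

  # shrink entity lengths until the footprint fits max_len
  total <- sum(vapply(ents, `[[`, integer(1), "len"))
  while (total > config$max_len) {
    lens <- vapply(ents, `[[`, integer(1), "len")
    i <- which.max(lens)
    if (lens[i] <= 2L) return(NULL) # cannot fit; caller re-draws
    e <- ents[[i]]
    e$len <- e$len - 1L
    e$chars <- c(e$chars[1L], head(e$chars[-c(1L, length(e$chars))], -1L),
                 e$chars[length(e$chars)])
    ents[[i]] <- e
    total <- total - 1L
  }

  # nesting: object planted strictly inside the subject, for entries whose
  # entities are used by no other chosen entry
  type_use <- table(c(chosen$sub_type, chosen$obj_type))
  nested_of <- integer() # nested object type, named by subject type
  for (r in seq_len(nrow(chosen))) {
    st <- chosen$sub_type[r]; ot <- chosen$obj_type[r]
    if (type_use[as.character(st)] > 1L || type_use[as.character(ot)] > 1L) next
    if (st %in% names(nested_of) || ot %in% nested_of) next
    want <- force_nested || runif(1) < config$p_nested
    if (!want) next
    sub <- ents[[as.character(st)]]
    obj <- ents[[as.character(ot)]]
    if (sub$single) next
    new_len <- obj$len + 4L # head + pad + object + pad + tail
    if (total - sub$len - obj$len + new_len > config$max_len) next
    total <- total - sub$len - obj$len + new_len
    pad <- function() filler_pool[sample.int(length(filler_pool), 1L)]
    sub$chars <- c(sub$chars[1L], pad(), obj$chars, pad(),
                   sub$chars[length(sub$chars)])
    sub$len <- new_len
    sub$nested_obj <- ot
    ents[[as.character(st)]] <- sub
    nested_of[as.character(st)] <- ot
  }

  # placement units: every entity except nested objects
  unit_types <- types[!types %in% nested_of]
  unit_types <- unit_types[sample.int(length(unit_types))]
  gaps <- length(unit_types) + 1L
  budget <- config$max_len - total
  gap_len <- integer(gaps)
  for (g in seq_len(gaps)) {
    gap_len[g] <- sample.int(min(3L, budget) + 1L, 1L) - 1L
    budget <- budget - gap_len[g]
  }

  chars <- character(0)
  span <- matrix(NA_integer_, nrow = max(types), ncol = 2L) # 0-based [head, tail]
  pos <- 0L
  for (u in seq_along(unit_types)) {
    fill <- filler_pool[sample.int(length(filler_pool), gap_len[u], replace = TRUE)]
    chars <- c(chars, fill)
    pos <- pos + gap_len[u]
    ty <- unit_types[u]
    e <- ents[[as.character(ty)]]
    span[ty, ] <- c(pos, pos + e$len - 1L)
    if (!is.null(e$nested_obj)) {
      ot <- e$nested_obj
      olen <- ents[[as.character(ot)]]$len
      span[ot, ] <- c(pos + 2L, pos + 2L + olen - 1L)
    }
    chars <- c(chars, e$chars)
    pos <- pos + e$len
  }
  chars <- c(chars, filler_pool[sample.int(length(filler_pool), gap_len[gaps],
                                           replace = TRUE)])

  text <- paste(chars, collapse = "")
  gold <- tibble(
    sub_head = span[chosen$sub_type, 1L], sub_tail = span[chosen$sub_type, 2L],
    relation = chosen$relation,
    obj_head = span[chosen$obj_type, 1L], obj_tail = span[chosen$obj_type, 2L]
  )
  gold$subject <- substr(rep(text, nrow(gold)), gold$sub_head + 1L, gold$sub_tail + 1L)
  gold$object <- substr(rep(text, nrow(gold)), gold$obj_head + 1L, gold$obj_tail + 1L)
  list(text = text, gold = gold)
}

.sentence_ok <- function(sent, pattern, config, K) {
  lab <- classify_overlap(sent$gold)
  pattern_ok <- switch(pattern,
    Normal = identical(lab, "Normal"),
    SEO = "SEO" %in% lab,
    EPO = "EPO" %in% lab,
    TRUE
  )
  if (!pattern_ok) return(FALSE)
  if (config$reject_cross_triple_collisions) {
    rt <- decode_tensor(encode_triples(nchar(sent$text), sent$gold, K))
    gold_key <- do.call(paste, sent$gold[, .triple_cols])
    rt_key <- do.call(paste, rt[, .triple_cols])
    if (!setequal(gold_key, rt_key)) return(FALSE)
  }
  TRUE
}

#' Plant one sentence realizing a pattern
#'
#' Produces a single sentence whose gold triples verifiably realize the
#' requested overlap pattern or special case.
#'
#' @param pattern One of `"Normal"`, `"SEO"`, `"EPO"` or the special tags
#'   `"nested"` (object strictly inside the subject span),
#'   `"single_char_subject"`, `"single_char_object"`, `"both_single"`.
#' @param config A [gen_config()]; its seed is *not* applied here, so calls
#'   compose under one outer `set.seed()`.
#' @param roles,link_table Optional precomputed vocabulary/link table (used
#'   internally by [generate_corpus()]).
#' @return A list with `text` (string) and `gold` (triple table with
#'   surface-form columns `subject`, `object`).
#' @export
plant_pattern <- function(pattern, config = gen_config(),
                          roles = NULL, link_table = NULL) {
  pattern <- arg_match(pattern, c("Normal", "SEO", "EPO", "nested",
                                  "single_char_subject", "single_char_object",
                                  "both_single"))
  if (is.null(roles)) roles <- .build_vocab(config)
  if (is.null(link_table)) link_table <- .build_link_table(config$K, config$n_entity_types)
  special <- !pattern %in% c("Normal", "SEO", "EPO")
  base_pattern <- if (special) "Normal" else pattern
  n <- if (special) 1L else max(1L, 2L * (pattern != "Normal"))

  for (try in 1:200) {
    entries <- .choose_entries(link_table, base_pattern, n)
    if (is.null(entries)) abort("pattern unrealizable under this configuration")
    force_entity <- NULL
    force_nested <- FALSE
    if (special) {
      ch <- link_table[link_table$entry %in% entries, ]
      st <- as.character(ch$sub_type[1L]); ot <- as.character(ch$obj_type[1L])
      force_entity <- switch(pattern,
        nested = setNames(list("multi", "multi"), c(st, ot)),
        single_char_subject = setNames(list("single", "multi"), c(st, ot)),
        single_char_object = setNames(list("multi", "single"), c(st, ot)),
        both_single = setNames(list("single", "single"), c(st, ot))
      )
      force_nested <- pattern == "nested"
    }
    sent <- .build_sentence(link_table, entries, roles, config,
                            force_entity = force_entity,
                            force_nested = force_nested)
    if (is.null(sent)) next
    if (pattern == "nested") {
      inside <- sent$gold$obj_head > sent$gold$sub_head &
        sent$gold$obj_tail < sent$gold$sub_tail
      if (!any(inside)) next
    }
    if (pattern == "single_char_subject" &&
        !any(sent$gold$sub_head == sent$gold$sub_tail)) next
    if (pattern == "single_char_object" &&
        !any(sent$gold$obj_head == sent$gold$obj_tail)) next
    if (pattern == "both_single" &&
        !any(sent$gold$sub_head == sent$gold$sub_tail &
             sent$gold$obj_head == sent$gold$obj_tail)) next
    if (!.sentence_ok(sent, base_pattern, config, config$K)) next
    return(sent)
  }
  abort("failed to realize the requested pattern within 200 attempts")
}

#' Generate a synthetic corpus
#'
#' Draws `n_sentences` sentences whose gold triples realize the configured
#' triples-per-sentence distribution and overlap-pattern mix, with nested
#' and single-character entities sprinkled in.  Every sentence's requested
#' pattern is verified with [classify_overlap()]; with
#' `reject_cross_triple_collisions` every gold set also survives the tag
#' encode/decode round trip.
#'
#' @param config A [gen_config()].
#' @return A list of class `tl_corpus`: `sentences` (tibble `id`, `text`,
#'   `pattern`, `n_triples`), `gold` (triple table with `id` and surface
#'   forms), `schema` (a [relation_schema()] with labels `rel01..relK`) and
#'   `manifest` (config, link table, vocabulary roles, seed).
#' @export
generate_corpus <- function(config = gen_config()) {
  stopifnot(inherits(config, "tl_gen_config"))
  set.seed(config$seed)
  roles <- .build_vocab(config)
  link_table <- .build_link_table(config$K, config$n_entity_types)
  schema <- relation_schema(sprintf("rel%02d", seq_len(config$K)))

  dist <- config$triples_per_sentence_distribution
  p1 <- dist[1L]
  pge2 <- 1 - p1
  mix <- config$pattern_mix
  cond <- c(Normal = max(0, mix[["Normal"]] - p1),
            SEO = mix[["SEO"]], EPO = mix[["EPO"]])
  if (sum(cond) > 0) cond <- cond / sum(cond)

  n_norm_entries <- sum(link_table$kind == "normal")
  max_normal_n <- n_norm_entries + 2L # plus one entry from each SEO block
  sentence_rows <- vector("list", config$n_sentences)
  gold_rows <- vector("list", config$n_sentences)
  retries <- 0L

  for (i in seq_len(config$n_sentences)) {
    nt_bucket <- sample.int(5L, 1L, prob = dist)
    n <- if (nt_bucket < 5L) nt_bucket else sample(c(5L, 6L), 1L, prob = c(0.7, 0.3))
    pattern <- if (n == 1L) {
      "Normal"
    } else {
      c("Normal", "SEO", "EPO")[sample.int(3L, 1L, prob = cond)]
    }
    if (pattern == "Normal" && n > max_normal_n) {
      abort(paste0("configuration cannot realize a Normal sentence with ", n,
                   " triples; increase n_entity_types"))
    }
    sent <- NULL
    for (try in 1:200) {
      entries <- .choose_entries(link_table, pattern, n)
      if (is.null(entries)) {
        abort(paste0("configuration cannot realize pattern ", pattern,
                     " with ", n, " triples"))
      }
      .assert_no_stray_links(link_table, entries)
      cand <- .build_sentence(link_table, entries, roles, config)
      if (!is.null(cand) && .sentence_ok(cand, pattern, config, config$K)) {
        sent <- cand
        break
      }
      retries <- retries + 1L
    }
    if (is.null(sent)) {
      abort("failed to realize a sentence within 200 attempts; relax the configuration")
    }
    id <- sprintf("s%05d", i)
    sentence_rows[[i]] <- tibble(id = id, text = sent$text, pattern = pattern,
                                 n_triples = nrow(sent$gold))
    gold_rows[[i]] <- tibble(id = id, !!!sent$gold)
  }

  sentences <- bind_rows(sentence_rows)
  gold <- bind_rows(gold_rows)
  if (config$n_sentences == 0L) {
    sentences <- tibble(id = character(), text = character(),
                        pattern = character(), n_triples = integer())
    gold <- tibble(id = character(), sub_head = integer(), sub_tail = integer(),
                   relation = integer(), obj_head = integer(),
                   obj_tail = integer(), subject = character(),
                   object = character())
  }
  structure(
    list(sentences = sentences, gold = gold, schema = schema,
         manifest = list(config = unclass(config), seed = config$seed,
                         link_table = link_table, vocabulary = roles,
                         retries = retries)),
    class = "tl_corpus"
  )
}

#' @export
print.tl_corpus <- function(x, ...) {
  cat("<synthetic corpus: ", nrow(x$sentences), " sentences, ",
      nrow(x$gold), " gold triples, K = ", x$schema$K, ">\n", sep = "")
  invisible(x)
}
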