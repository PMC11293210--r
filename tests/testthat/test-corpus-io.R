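write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}

test_that("well-formed JSON lines are read in order", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_lines_utf8(c(
    '{"text": "XYABCD", "spo_list": [{"predicate": "p1", "subject": "ABC", "object": {"@value": "D"}}]}',
    '{"text": "QQQQ", "spo_list": []}',
    '{"text": "AB", "spo_list": [{"predicate": "p2", "subject": "A", "object": {"@value": "B"}}]}'
  ), path)
  recs <- read_jsonl(path)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$text[2], "QQQQ")
  expect_equal(recs$spo[[1]]$object, "D")
  # plain-string object values are accepted too
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_lines_utf8('{"text": "AB", "spo_list": [{"predicate": "p", "subject": "A", "object": "B"}]}',
                   path2)
  expect_equal(read_jsonl(path2)$spo[[1]]$object, "B")
})

test_that("empty or unreadable inputs error; malformed lines are skipped", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  expect_error(read_jsonl(path), "no parseable records")
  expect_error(read_jsonl(file.path(tempdir(), "does_not_exist.jsonl")), "no such file")
  write_lines_utf8(c(
    '{"text": "AB", "spo_list": []}',
    "not json at all {{{",
    '{"text": "CD", "spo_list": []}'
  ), path)
  expect_message(recs <- read_jsonl(path), "skipped 1 malformed")
  expect_equal(recs$text, c("AB", "CD"))
})

test_that("unknown predicates are reported once with counts", {
  sch <- relation_schema("known")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_lines_utf8(c(
    '{"text": "ABCD", "spo_list": [{"predicate": "mystery", "subject": "A", "object": {"@value": "B"}}, {"predicate": "mystery", "subject": "C", "object": {"@value": "D"}}]}'
  ), path)
  expect_message(recs <- read_jsonl(path, schema = sch), "mystery \\(2\\)")
  gold <- suppressMessages(anchor_spans(recs, sch))
  expect_equal(nrow(gold), 0L)
  expect_equal(attr(gold, "dropped")$reason,
               rep("unknown predicate", 2))
})

test_that("anchoring finds spans by exact substring arithmetic", {
  sch <- relation_schema("p1")
  recs <- tibble::tibble(
    id = "r1", text = "XYABCD",
    spo = list(tibble::tibble(predicate = "p1", subject = "ABC", object = "D"))
  )
  gold <- anchor_spans(recs, sch)
  expect_equal(gold$sub_head, 2L)
  expect_equal(gold$sub_tail, 4L)
  expect_equal(gold$obj_head, 5L)
  expect_equal(gold$obj_tail, 5L)
})

test_that("absent entities drop their triple but keep the record", {
  sch <- relation_schema("p1")
  recs <- tibble::tibble(
    id = "r1", text = "ABCD",
    spo = list(tibble::tibble(predicate = "p1", subject = "ZZ", object = "A"))
  )
  gold <- suppressMessages(anchor_spans(recs, sch))
  expect_equal(nrow(gold), 0L)
  expect_equal(attr(gold, "dropped")$reason, "entity string not found in text")
})

test_that("occurrence policy controls how repeated strings anchor", {
  sch <- relation_schema("p1")
  recs <- tibble::tibble(
    id = "r1", text = "ABxABy",
    spo = list(tibble::tibble(predicate = "p1", subject = "AB", object = "y"))
  )
  first <- anchor_spans(recs, sch, policy = "first")
  expect_equal(nrow(first), 1L)
  expect_equal(first$sub_head, 0L)
  all_occ <- anchor_spans(recs, sch, policy = "all")
  expect_equal(nrow(all_occ), 2L) # one triple per subject occurrence
  expect_setequal(all_occ$sub_head, c(0L, 3L))
})

test_that("write -> read -> anchor is the identity on synthetic corpora", {
  co <- tiny_corpus(n = 25, seed = 61, p_single_char = 0.2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(co, path)
  expect_true(file.exists(paste0(path, ".spans.tsv")))
  recs <- read_jsonl(path, schema = co$schema)
  expect_equal(nrow(recs), nrow(co$sentences))
  expect_equal(recs$text, co$sentences$text)
  gold2 <- anchor_spans(recs, co$schema)
  # identify records with sentences by position (writer preserves order)
  gold2$id <- co$sentences$id[match(gold2$id, recs$id)]
  expect_same_triples(gold2, co$gold)
  expect_equal(nrow(attr(gold2, "dropped")), 0L)
})

test_that("sentences without predictions serialize with an empty spo_list", {
  sch <- relation_schema("p1")
  sents <- tibble::tibble(id = "s1", text = "ABCD")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions(sents, triple_tbl(), sch, path)
  rec <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8"))
  expect_equal(length(rec$spo_list), 0L)
  # and a real triple slices its surface forms from the text
  write_predictions(sents, triple_tbl(0, 1, 0, 3, 3, id = "s1"), sch, path)
  rec <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8"),
                            simplifyVector = FALSE)
  expect_equal(rec$spo_list[[1]]$subject, "AB")
  expect_equal(rec$spo_list[[1]]$object$`@value`, "D")
})
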