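test_that("parse_brat reads T lines, normalizes types, ignores other lines", {
  pair <- fig_pair()
  expect_s3_class(pair$doc, "Document")
  expect_identical(pair$ann$role, "gold")
  expect_length(pair$ann$mentions, 2)
  m1 <- pair$ann$mentions[[1]]
  expect_identical(m1$entity_type, "rare_disease")
  expect_equal(unname(m1$fragments), matrix(c(0L, 13L), ncol = 2))
  expect_identical(m1$surface, "Keratomalacia")
  m2 <- pair$ann$mentions[[2]]
  expect_identical(m2$surface, "corneal scarring")
  expect_equal(unname(m2$fragments), matrix(c(28L, 44L), ncol = 2))

  # empty annotation content and non-T lines
  expect_length(parse_brat(FIG_TEXT, "", "d")$ann$mentions, 0)
  with_notes <- paste0(FIG_ANN, "\n#1\tAnnotatorNotes T1\tnote\nR1\tRel Arg1:T1 Arg2:T2")
  expect_length(parse_brat(FIG_TEXT, with_notes, "d")$ann$mentions, 2)
})

test_that("parse_brat error and policy handling", {
  expect_error(parse_brat(FIG_TEXT, "T1\tRAREDISEASE zero 13\tx", "d"),
               "line 1")
  expect_error(parse_brat(FIG_TEXT, "T1\tSIGN 0 999\tx", "d"), "outside")
  bad_surface <- "T1\tRAREDISEASE 0 13\tWrongSurface"
  expect_error(parse_brat(FIG_TEXT, bad_surface, "d", policy = "strict"),
               "differs")
  expect_warning(
    lenient <- parse_brat(FIG_TEXT, bad_surface, "d", policy = "lenient"),
    "differs")
  # lenient keeps the offsets and adopts the text slice
  expect_identical(lenient$ann$mentions[[1]]$surface, "Keratomalacia")
})

test_that("discontinuous fragments parse, preserve order, and round-trip", {
  txt <- "severe scarring of the cornea observed"
  ann <- "T1\tSIGN 0 6;23 29\tsevere cornea"
  pair <- parse_brat(txt, ann, "disc")
  m <- pair$ann$mentions[[1]]
  expect_equal(nrow(m$fragments), 2)
  expect_identical(m$surface, "severe cornea")
  rt <- parse_brat(txt, write_brat(pair$doc, pair$ann), "disc")
  expect_same_ann(pair$ann, rt$ann)
})

test_that("write_brat orders by start, rejects ungrounded, and round-trips", {
  pair <- fig_pair()
  out <- write_brat(pair$doc, pair$ann)
  lines <- strsplit(out, "\n")[[1]]
  expect_match(lines[1], "^T1\tRAREDISEASE 0 13")
  expect_match(lines[2], "^T2\tSIGN 28 44")
  expect_identical(write_brat(pair$doc, annotation_set("fig1")), "")
  ungrounded <- annotation_set("fig1", list(
    entity_mention("sign", surface = "phantom")))
  expect_error(write_brat(pair$doc, ungrounded), "ungrounded")
  rt <- parse_brat(pair$doc$text, out, "fig1")
  expect_same_ann(pair$ann, rt$ann)
})

test_that("tokenize follows the maximal-run/single-punctuation rule", {
  toks <- tokenize("corneal scarring.")
  expect_equal(toks$surface, c("corneal", "scarring", "."))
  expect_equal(toks$start, c(0L, 8L, 16L))
  expect_equal(toks$end, c(7L, 16L, 17L))
  expect_equal(nrow(tokenize("")), 0)
})

test_that("token spans are sorted, disjoint, and cover non-space text", {
  samples <- c(FIG_TEXT, "a-b c(d) 4.5mg/kg!", "  spaced   out  ",
               "Prader-Willi syndrome, q.v.; [rare]")
  for (text in samples) {
    toks <- tokenize(text)
    expect_true(all(toks$start >= 0 & toks$end <= nchar(text)))
    if (nrow(toks) > 1) {
      expect_true(all(diff(toks$start) > 0))
      expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
    }
    # concatenating surfaces with the original gaps reconstructs the text
    rebuilt <- character(0)
    pos <- 0L
    for (r in seq_len(nrow(toks))) {
      rebuilt <- c(rebuilt, substring(text, pos + 1, toks$start[r]),
                   toks$surface[r])
      pos <- toks$end[r]
    }
    rebuilt <- paste0(paste(rebuilt, collapse = ""),
                      substring(text, pos + 1, nchar(text)))
    expect_identical(rebuilt, text)
  }
})

test_that("to_bio assigns B/I by span intersection and O elsewhere", {
  pair <- fig_pair()
  bio <- to_bio(pair$doc, pair$ann)
  expect_identical(bio$tags,
                   c("B-rare_disease", "O", "O", "O", "O",
                     "B-sign", "I-sign", "O"))
  empty <- to_bio(pair$doc, annotation_set("fig1"))
  expect_true(all(empty$tags == "O"))
  # partial-token overlap still tags the token
  part <- annotation_set("fig1", list(
    entity_mention("sign", surface = "corneal sc", start = 28, end = 38)))
  expect_identical(to_bio(pair$doc, part)$tags[6:7], c("B-sign", "I-sign"))
})

test_that("to_bio rejects overlapping and discontinuous mentions in strict mode", {
  pair <- fig_pair()
  overlapping <- annotation_set("fig1", list(
    entity_mention("sign", surface = "corneal scarring", start = 28, end = 44),
    entity_mention("sign", surface = "scarring", start = 36, end = 44)))
  expect_error(to_bio(pair$doc, overlapping), "overlapping")
  expect_warning(dropped <- to_bio(pair$doc, overlapping, on_invalid = "drop"),
                 "dropping")
  expect_identical(dropped$tags[6:7], c("B-sign", "I-sign"))
  disc <- annotation_set("fig1", list(
    entity_mention("sign", surface = "Keratomalacia cause",
                   fragments = rbind(c(0, 13), c(19, 24)))))
  expect_error(to_bio(pair$doc, disc), "discontinuous")
})

test_that("from_bio decodes runs and handles orphan I tags", {
  pair <- fig_pair()
  bio <- to_bio(pair$doc, pair$ann)
  expect_same_ann(from_bio(bio, "fig1", doc = pair$doc), pair$ann)
  expect_length(from_bio(list(tokens = bio$tokens,
                              tags = rep("O", 8)), "fig1")$mentions, 0)
  # adjacent B tags force a run boundary
  two <- from_bio(list(tokens = tokenize("rash fever"),
                       tags = c("B-sign", "B-sign")), "d")
  expect_length(two$mentions, 2)
  expect_identical(two$mentions[[1]]$surface, "rash")
  orphan <- list(tokens = tokenize("rash fever"), tags = c("O", "I-sign"))
  expect_error(from_bio(orphan, "d"), "orphan")
  repaired <- from_bio(orphan, "d", lenient = TRUE)
  expect_identical(repaired$mentions[[1]]$surface, "fever")
})

test_that("BIO round-trip is exact on generated fixtures", {
  for (entry in small_corpus(8, seed = 3)) {
    rt <- from_bio(to_bio(entry$doc, entry$ann), entry$doc$doc_id,
                   doc = entry$doc, role = "gold")
    expect_same_ann(entry$ann, rt)
  }
})

test_that("corpus_stats totals, means, SD flavors, and reorder invariance", {
  one <- list(list(doc = document("d1", "A rash appeared."),
                   ann = annotation_set("d1", list(
                     entity_mention("sign", surface = "rash",
                                    start = 2, end = 6)))))
  s <- corpus_stats(one)
  expect_equal(s$total[s$entity == "sign"], 1)
  expect_equal(s$mean_per_doc[s$entity == "sign"], 1)
  expect_equal(s$sd_per_doc[s$entity == "sign"], 0)
  expect_error(corpus_stats(list()), "empty")

  corp <- small_corpus(10, seed = 5)
  a <- corpus_stats(corp)
  b <- corpus_stats(rev(corp))
  expect_equal(a$total, b$total)
  expect_equal(a$mean_per_doc, b$mean_per_doc)
  expect_equal(sum(a$total[a$entity != "overall"]),
               a$total[a$entity == "overall"])
  # mean * n_docs recovers the total
  expect_equal(a$mean_per_doc * attr(a, "n_docs"), a$total)
  pop <- corpus_stats(corp, sd_type = "population")
  n <- attr(a, "n_docs")
  expect_equal(pop$sd_per_doc^2 * n, a$sd_per_doc^2 * (n - 1), tolerance = 1e-9)
})

test_that("split_corpus uses floor sizes with remainder to train", {
  ids <- sprintf("d%02d", 1:10)
  s <- split_corpus(ids, c(0.8, 0.1, 0.1), seed = 42)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  expect_setequal(unlist(s), ids)
  expect_identical(s, split_corpus(ids, c(0.8, 0.1, 0.1), seed = 42))
  expect_false(identical(s, split_corpus(ids, c(0.8, 0.1, 0.1), seed = 43)))

  big <- split_corpus(as.character(1:832), c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(big), c(train = 666L, val = 83L, test = 83L))

  expect_error(split_corpus(c("a", "b"), c(0.8, 0.1, 0.1), 1), "fewer")
  expect_error(split_corpus(ids, c(0.5, 0.2, 0.2), 1), "sum to 1")
})
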