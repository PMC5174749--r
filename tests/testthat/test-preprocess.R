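test_that("tokenization splits on whitespace and punctuation and collapses entities", {
  text <- "the interaction of omeprazole and ketoconazole has been established"
  s <- annotated_sentence("pp.s0", text,
    rbind(mention_at("e0", text, "omeprazole"),
          mention_at("e1", text, "ketoconazole")))
  toks <- tokenize_sentence(s)
  expect_equal(toks$token,
               c("the", "interaction", "of", "omeprazole", "and",
                 "ketoconazole", "has", "been", "established"))
  expect_equal(toks$entity_id[toks$token == "omeprazole"], "e0")

  # multiword entity becomes a single token covering its whole span
  text2 <- "combining beta blockers with digoxin, however, is risky"
  s2 <- annotated_sentence("pp.s1", text2,
    rbind(mention_at("e0", text2, "beta blockers"),
          mention_at("e1", text2, "digoxin")))
  toks2 <- tokenize_sentence(s2)
  expect_true("beta blockers" %in% toks2$token)
  expect_equal(sum(toks2$token == ","), 2)
})

test_that("token spans reconstruct the non-whitespace text in order", {
  corpus <- generate_corpus(synth_config(n_sentences = 30, seed = 7))
  for (s in corpus$sentences) {
    toks <- tokenize_sentence(s)
    rebuilt <- paste(
      vapply(seq_len(nrow(toks)),
             function(i) substr(s$text, toks$start[i] + 1, toks$end[i] + 1),
             character(1)), collapse = "")
    expect_equal(rebuilt, gsub("[[:space:]]", "", s$text))
    expect_equal(toks$token, vapply(seq_len(nrow(toks)), function(i) {
      substr(s$text, toks$start[i] + 1, toks$end[i] + 1)
    }, character(1)))
  }
})

test_that("overlapping entity spans are a validation error", {
  text <- "alpha beta gamma"
  ents <- rbind(entity_mention("e0", "alpha beta", 0, 9),
                entity_mention("e1", "beta", 6, 9))
  s <- structure(list(id = "pp.ov", text = text, entities = ents,
                      pairs = data.frame(e1 = character(), e2 = character(),
                                         label = character())),
                 class = "annotated_sentence")
  expect_error(tokenize_sentence(s), "overlaps")
})

test_that("pair enumeration yields choose(n, 2) pairs in document order", {
  expect_equal(nrow(enumerate_pairs(caution_sentence())), 3)
  expect_equal(nrow(enumerate_pairs(annotated_sentence("pp.s2", "nothing"))), 0)
  text <- "only lonedrug here"
  one <- annotated_sentence("pp.s3", text, mention_at("e0", text, "lonedrug"))
  expect_equal(nrow(enumerate_pairs(one)), 0)
  five <- coordinate_sentence()
  pr <- enumerate_pairs(five)
  expect_equal(nrow(pr), 10)
  # double-loop oracle: every unordered pair appears exactly once
  ids <- five$entities$id[order(five$entities$char_start)]
  for (i in seq_len(nrow(pr))) {
    expect_lt(match(pr$e1[i], ids), match(pr$e2[i], ids))
  }
  expect_equal(nrow(unique(pr)), 10)
})

test_that("blinding substitutes targets and bystanders correctly", {
  s <- caution_sentence()
  toks <- tokenize_sentence(s)
  b1 <- blind_pair(toks, "fix.s1.e0", "fix.s1.e1")
  expect_equal(paste(b1, collapse = " "),
               paste("Caution should be exercised when administering Entity1",
                     "with Entity2 since interactions have been seen with other EntityOther"))
  b3 <- blind_pair(toks, "fix.s1.e1", "fix.s1.e2")
  expect_equal(paste(b3, collapse = " "),
               paste("Caution should be exercised when administering EntityOther",
                     "with Entity1 since interactions have been seen with other Entity2"))
  # blinding preserves token count and is label-independent
  expect_length(b1, nrow(toks))
  # two entities only: no EntityOther in output
  text <- "giving aspirin with ibuprofen"
  s2 <- annotated_sentence("pp.s4", text,
    rbind(mention_at("e0", text, "aspirin"),
          mention_at("e1", text, "ibuprofen")))
  b <- blind_pair(tokenize_sentence(s2), "e0", "e1")
  expect_false("EntityOther" %in% b)
  expect_equal(sum(b == "Entity1"), 1)
  expect_equal(sum(b == "Entity2"), 1)
  # Entity1 precedes Entity2 regardless of argument order
  brev <- blind_pair(tokenize_sentence(s2), "e1", "e0")
  expect_equal(b, brev)
})

test_that("rule 1 flags same names, parenthesized short forms and acronyms", {
  sn <- same_name_sentence()
  expect_true(rule1_same_name(sn, "fix.s2.e0", "fix.s2.e1"))

  # retained pair from the three-drug sentence is not same-name
  expect_false(rule1_same_name(caution_sentence(), "fix.s1.e1", "fix.s1.e2"))

  # identical strings
  text <- "mixing aspirin with aspirin"
  s <- annotated_sentence("pp.r1", text,
    rbind(mention_at("e0", text, "aspirin", 1),
          mention_at("e1", text, "aspirin", 2)))
  expect_true(rule1_same_name(s, "e0", "e1"))

  # long form (SHORT) pattern
  text2 <- "treated with selective serotonin reuptake inhibitors (SSRI) daily"
  s2 <- annotated_sentence("pp.r1b", text2,
    rbind(mention_at("e0", text2, "selective serotonin reuptake inhibitors"),
          mention_at("e1", text2, "SSRI")))
  expect_true(rule1_same_name(s2, "e0", "e1"))

  # acronym far from its long form, no parentheses
  text3 <- "SSRI exposure mirrors selective serotonin reuptake inhibitors effects"
  s3 <- annotated_sentence("pp.r1c", text3,
    rbind(mention_at("e0", text3, "SSRI"),
          mention_at("e1", text3, "selective serotonin reuptake inhibitors")))
  expect_true(rule1_same_name(s3, "e0", "e1"))
})

test_that("rule 2 detects coordinate lists and spares normal pairs", {
  co <- coordinate_sentence()
  toks <- tokenize_sentence(co)
  ids <- co$entities$id
  expect_true(rule2_coordinate(blind_pair(toks, ids[1], ids[2])))
  expect_true(rule2_coordinate(blind_pair(toks, ids[1], ids[5])))

  # intervening content word blocks the rule
  ca <- caution_sentence()
  expect_false(rule2_coordinate(blind_pair(tokenize_sentence(ca),
                                           "fix.s1.e0", "fix.s1.e1")))

  # adjacent entities: no separator, not coordinate
  text <- "mix aspirin ibuprofen now"
  s <- annotated_sentence("pp.r2", text,
    rbind(mention_at("e0", text, "aspirin"),
          mention_at("e1", text, "ibuprofen")))
  expect_false(rule2_coordinate(blind_pair(tokenize_sentence(s), "e0", "e1")))
})

test_that("build_dataset partitions candidates and reports reasons", {
  ds <- build_dataset(list(caution_sentence()))
  expect_length(ds$kept, 3)
  expect_length(ds$removed, 0)

  co <- build_dataset(list(coordinate_sentence()))
  expect_length(co$kept, 0)
  expect_length(co$removed, 10)
  expect_true(all(vapply(co$removed, function(i) i$filtered, character(1)) == "rule2"))

  # filters off keeps everything
  off <- build_dataset(list(coordinate_sentence(), same_name_sentence()),
                       apply_filters = FALSE)
  expect_length(off$removed, 0)
  expect_length(off$kept, 11)

  # kept/removed re-satisfy their predicates on a mixed synthetic corpus
  corpus <- generate_corpus(synth_config(n_sentences = 60, seed = 13))
  ds2 <- build_dataset(corpus$sentences)
  smap <- setNames(corpus$sentences,
                   vapply(corpus$sentences, function(s) s$id, character(1)))
  for (inst in ds2$removed) {
    s <- smap[[inst$sentence_id]]
    if (inst$filtered == "rule1") {
      expect_true(rule1_same_name(s, inst$e1, inst$e2))
    } else {
      expect_true(rule2_coordinate(inst$tokens))
    }
  }
  for (inst in ds2$kept) {
    s <- smap[[inst$sentence_id]]
    expect_false(rule1_same_name(s, inst$e1, inst$e2) ||
                   rule2_coordinate(inst$tokens))
  }
  # partition: kept + removed = all enumerated pairs
  n_pairs <- sum(vapply(corpus$sentences,
                        function(s) nrow(enumerate_pairs(s)), numeric(1)))
  expect_equal(length(ds2$kept) + length(ds2$removed), n_pairs)
  expect_equal(sum(ds2$report$kept + ds2$report$removed_rule1 +
                     ds2$report$removed_rule2), n_pairs)
})
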