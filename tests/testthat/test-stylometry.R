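test_that("script-type ratios count non-whitespace characters", {
  doc <- make_doc("ねこがすき。", list(make_ann(c("ねこ", "が", "すき"))))
  r <- char_type_ratios(doc)
  expect_equal(unname(r), c(5 / 6, 0, 0)) # 。 is neither script
  doc <- make_doc("ネコ", list(make_ann("ネコ")))
  expect_equal(unname(char_type_ratios(doc)["katakana"]), 1)
  # ratios plus the implicit other class partition the characters
  doc <- fixture_doc()
  r <- char_type_ratios(doc)
  expect_true(all(r >= 0 & r <= 1))
  expect_lte(sum(r), 1)
})

test_that("lexical ratios follow the printed definitions", {
  doc <- make_doc("猫が好きだ。", list(make_ann(c("猫", "が", "好き", "だ"),
    pos = c("NOUN", "OTHER", "ADJ", "OTHER")
  )))
  r <- lexical_ratios(doc)
  expect_equal(unname(r["ttr"]), 1)
  expect_equal(unname(r["content_words"]), 0.5)
  expect_equal(unname(r["proper_nouns"]), 0)
  expect_equal(unname(r["mvr"]), 0) # 0 verbs over 1 adjective

  doc <- make_doc("走る速く。", list(make_ann(c("走る", "速く"),
    pos = c("VERB", "ADV")
  )))
  expect_equal(unname(lexical_ratios(doc)["mvr"]), 1)

  # no modifiers at all: mvr is missing, not infinite
  doc <- make_doc("走る。", list(make_ann("走る", pos = "VERB")))
  expect_true(is.na(lexical_ratios(doc)["mvr"]))

  # one token repeated ten times: ttr = 0.1
  doc <- make_doc(
    paste0(strrep("猫", 10), "。"),
    list(make_ann(rep("猫", 10)))
  )
  expect_equal(unname(lexical_ratios(doc)["ttr"]), 0.1)
})

test_that("abstraction statistics use top-5 hits and report misses as NA", {
  lex <- abstraction_lexicon(paste0("w", 1:6), c(1, 2, 3, 4, 5, 6))
  doc3 <- make_doc("あ。", list(make_ann(c("w1", "w2", "w3"))))
  s <- abstraction_stats(doc3, lex)
  expect_equal(unname(s), c(3, 2)) # fewer than 5 hits: mean of all
  doc6 <- make_doc("あ。", list(make_ann(paste0("w", 1:6))))
  s <- abstraction_stats(doc6, lex)
  expect_equal(unname(s), c(6, 4)) # top 5 of 1..6
  none <- make_doc("あ。", list(make_ann("nohit")))
  expect_true(all(is.na(abstraction_stats(none, lex))))
})

test_that("sentence statistics average lengths and flag dialogue", {
  doc <- make_doc(
    c(paste0(strrep("あ", 9), "。"), paste0(strrep("い", 19), "。")),
    list(make_ann("あ"), make_ann("い"))
  )
  s <- sentence_stats(doc)
  expect_equal(unname(s), c(2, 15, 0))
  conv <- make_doc("「はい」。", list(make_ann("はい")))
  expect_equal(unname(sentence_stats(conv)["conversational"]), 1)
})

test_that("dependency statistics match hand-worked topologies", {
  # chain A -> B -> ROOT(C): depth 3
  chain <- make_doc("あ。", list(make_ann(
    c("a", "b", "c"),
    chunk_index = 0:2, chunk_heads = c(1L, 2L, -1L)
  )))
  s <- syntax_stats(chain)
  expect_equal(unname(s), c(3, 3, 1))
  # single chunk: depth 1
  single <- make_doc("あ。", list(make_ann(c("a", "b"), chunk_index = c(0L, 0L))))
  expect_equal(unname(syntax_stats(single)), c(1, 1, 2))
  # star: 3 chunks all pointing at the root, depth 2
  star <- make_doc("あ。", list(make_ann(
    letters[1:4],
    chunk_index = 0:3, chunk_heads = c(3L, 3L, 3L, -1L)
  )))
  expect_equal(unname(syntax_stats(star)["tree_depth"]), 2)
  # cyclic heads are rejected at construction
  expect_error(
    make_doc("あ。", list(make_ann(c("a", "b", "c"),
      chunk_index = 0:2, chunk_heads = c(1L, 0L, -1L)
    ))),
    "cyclic"
  )
})

test_that("tree depth agrees with brute-force path enumeration", {
  set.seed(97)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    heads <- random_heads(n)
    doc <- make_doc("あ。", list(make_ann(
      paste0("t", seq_len(n)),
      chunk_index = seq_len(n) - 1L, chunk_heads = heads
    )))
    expect_equal(
      unname(syntax_stats(doc)["tree_depth"]),
      oracle_tree_depth(heads)
    )
  }
})

test_that("extract_features composes the sub-operations deterministically", {
  doc <- fixture_doc()
  emo <- fixture_emotion_lexicon()
  alex <- fixture_abstraction_lexicon()
  fv <- extract_features(doc, emo, alex)
  expect_identical(names(fv), c("doc_id", METRIC_ORDER))
  expect_identical(fv, extract_features(doc, emo, alex))

  # full hand reconciliation of the fixture:
  # text 猫が好きだ。「走る犬」と猫。 = 14 chars:
  # kanji 猫好走犬猫 (5), hiragana がきだると (5), other 。「」。 (4)
  expect_equal(fv$hiragana, 5 / 14)
  expect_equal(fv$kanji, 5 / 14)
  expect_equal(fv$katakana, 0)
  expect_equal(fv$ttr, 7 / 8) # 猫 repeats
  expect_equal(fv$content_words, 5 / 8) # 猫 好き 走る 犬 猫
  expect_equal(fv$mvr, 1) # 1 verb / 1 adjective
  expect_equal(fv$proper_nouns, 0)
  expect_equal(fv$abstraction_max, 2.4) # hits: 猫 好き 走る 犬 猫
  expect_equal(fv$abstraction_top5, mean(c(2.4, 1.9, 1.3, 1.3, 1.1)))
  # emotion: hits 猫(hap 1), 好き(.5 trust .5 hap), 走る miss? 走る not in
  # lexicon; 犬(surprise 1), 猫(hap 1) -> 4 matches
  expect_equal(fv$happiness, (1 + 0.5 + 0 + 1) / 4)
  expect_equal(fv$surprise, 1 / 4)
  expect_equal(fv$trust, 0.5 / 4)
  expect_equal(fv$n_sentences, 2)
  expect_equal(fv$mean_sentence_length, (6 + 8) / 2)
  expect_equal(fv$conversational, 0.5)
  expect_equal(fv$tree_depth, (2 + 2) / 2)
  expect_equal(fv$chunks_per_sentence, (2 + 3) / 2)
  expect_equal(fv$words_per_chunk, mean(c(2, 2, 1, 2, 1)))
})
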