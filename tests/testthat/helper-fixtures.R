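# Fixture builders used across the suite. Everything is constructed in code;
# no binary fixtures.

# One annotation block: defaults give a single-chunk sentence of NOUN tokens.
make_ann <- function(surface,
                     pos = rep("NOUN", length(surface)),
                     chunk_index = rep(0L, length(surface)),
                     chunk_heads = -1L) {
  list(
    surface = surface, pos = pos,
    chunk_index = as.integer(chunk_index),
    chunk_heads = as.integer(chunk_heads)
  )
}

# Document from sentence texts + annotation blocks (no truncation applied).
make_doc <- function(texts, anns, doc_id = "d1") {
  annotated_document(
    doc_id = doc_id,
    text = paste0(texts, collapse = ""),
    sentences = segment_sentences(paste0(texts, collapse = "")),
    annotations = anns
  )
}

# A small hand-worked document used for full feature reconciliation:
# sentence 1: 猫が好きだ。 tokens 猫/NOUN が/OTHER 好き/ADJ だ/OTHER,
#   chunks [猫 が][好き だ], chunk 0 -> chunk 1 (root)
# sentence 2: 「走る犬」と猫。 tokens 走る/VERB 犬/NOUN と/OTHER 猫/NOUN,
#   chunks [走る][犬 と][猫], 0 -> 2, 1 -> 2 (root), conversational
fixture_doc <- function() {
  make_doc(
    c("猫が好きだ。", "「走る犬」と猫。"),
    list(
      make_ann(c("猫", "が", "好き", "だ"),
        pos = c("NOUN", "OTHER", "ADJ", "OTHER"),
        chunk_index = c(0L, 0L, 1L, 1L), chunk_heads = c(1L, -1L)
      ),
      make_ann(c("走る", "犬", "と", "猫"),
        pos = c("VERB", "NOUN", "OTHER", "NOUN"),
        chunk_index = c(0L, 1L, 1L, 2L), chunk_heads = c(2L, 2L, -1L)
      )
    )
  )
}

# Tiny in-code lexicons matching fixture_doc surfaces.
fixture_emotion_lexicon <- function() {
  emotion_lexicon(
    c("猫", "犬", "好き"),
    rbind(
      c(0, 0, 0, 0, 0, 0, 1),
      c(0, 0, 0, 0, 0, 1, 0),
      c(0, 0, 0, 0, 0.5, 0, 0.5)
    )
  )
}

fixture_abstraction_lexicon <- function() {
  abstraction_lexicon(c("猫", "犬", "好き", "走る"), c(1.3, 1.1, 2.4, 1.9))
}

# Sentence table with given whitespace-free character counts (texts are
# synthesised hiragana runs; only the counts matter to truncation).
sentences_of_lengths <- function(lens) {
  data.frame(
    index = seq_along(lens) - 1L,
    text = vapply(lens, function(k) strrep("あ", k), ""),
    char_count = as.integer(lens),
    is_conversational = FALSE,
    stringsAsFactors = FALSE
  )
}
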