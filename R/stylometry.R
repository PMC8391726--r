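# Annotated documents and the stylometric measures computed on them.
#
# A document carries its (possibly truncated) text, the sentence table from
# segment_sentences(), and one annotation block per sentence:
#   surface      character vector, one token surface per token
#   pos          POS tag per token, one of POS_TAGS
#   chunk_index  0-based bunsetsu (chunk) index per token
#   chunk_heads  0-based head chunk per chunk, -1 for the root
# Dependency links connect chunks (bunsetsu), not words.

#' Part-of-speech tag set
#'
#' Coarse tags the pipeline consumes: `NOUN`, `PROPN`, `VERB`, `ADJ`, `ADV`,
#' `CONJ`, `OTHER` (particles, auxiliaries, punctuation, ...).
#'
#' @export
POS_TAGS <- c("NOUN", "PROPN", "VERB", "ADJ", "ADV", "CONJ", "OTHER")

#' Assemble an annotated document
#'
#' Validates the sentence/annotation structure: at least one sentence and one
#' token; per sentence, `chunk_index` values form a contiguous 0-based block
#' per chunk, exactly one chunk has head -1 (root), and head links are
#' acyclic.
#'
#' @param doc_id Document identifier.
#' @param text The document text (concatenation of the sentence texts).
#' @param sentences Sentence data frame as from [segment_sentences()].
#' @param annotations List, one element per sentence, each a list with
#'   `surface`, `pos`, `chunk_index`, `chunk_heads` as described above.
#' @param meta Optional list of writer metadata (e.g. `k10_items`,
#'   `age_group`, `gender`).
#' @param validate Run the structural checks (default). Callers that have
#'   already validated the structure (e.g. tight simulation loops over
#'   generated corpora) may skip them.
#' @return An object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, text, sentences, annotations,
                               meta = list(), validate = TRUE) {
  if (!is.data.frame(sentences) || nrow(sentences) < 1L) {
    stop("document must have at least one sentence", call. = FALSE)
  }
  if (!is.list(annotations) || length(annotations) != nrow(sentences)) {
    stop("need one annotation block per sentence", call. = FALSE)
  }
  if (!validate) {
    return(structure(
      list(
        doc_id = as.character(doc_id), text = text,
        sentences = sentences, annotations = annotations, meta = meta
      ),
      class = "annotated_document"
    ))
  }
  n_tok <- 0L
  for (s in seq_along(annotations)) {
    a <- annotations[[s]]
    if (!all(c("surface", "pos", "chunk_index", "chunk_heads") %in% names(a))) {
      stop("annotation block ", s, " lacks required fields", call. = FALSE)
    }
    nt <- length(a$surface)
    if (nt < 1L || length(a$pos) != nt || length(a$chunk_index) != nt) {
      stop("annotation block ", s, ": surface/pos/chunk_index lengths differ",
        call. = FALSE
      )
    }
    if (!all(a$pos %in% POS_TAGS)) {
      stop("annotation block ", s, ": unknown POS tag", call. = FALSE)
    }
    nc <- length(a$chunk_heads)
    ci <- as.integer(a$chunk_index)
    if (nc < 1L || !setequal(unique(ci), 0:(nc - 1L))) {
      stop("annotation block ", s, ": chunk spans must partition the tokens",
        call. = FALSE
      )
    }
    heads <- as.integer(a$chunk_heads)
    if (sum(heads == -1L) != 1L) {
      stop("annotation block ", s, ": exactly one chunk must be the root",
        call. = FALSE
      )
    }
    if (any(heads < -1L | heads >= nc) || any(heads == seq_len(nc) - 1L)) {
      stop("annotation block ", s, ": invalid chunk head link", call. = FALSE)
    }
    .chunk_depths(heads) # errors on cycles
    n_tok <- n_tok + nt
  }
  if (n_tok < 1L) stop("document must have at least one token", call. = FALSE)
  structure(
    list(
      doc_id = as.character(doc_id), text = text,
      sentences = sentences, annotations = annotations, meta = meta
    ),
    class = "annotated_document"
  )
}

# Depth of every chunk, root = 1, counted in chunks along the head path.
.chunk_depths <- function(heads) {
  nc <- length(heads)
  depth <- integer(nc)
  for (i in seq_len(nc)) {
    d <- 1L
    j <- i
    while (heads[j] != -1L) {
      j <- heads[j] + 1L
      d <- d + 1L
      if (d > nc) stop("cyclic chunk head links", call. = FALSE)
    }
    depth[i] <- d
  }
  depth
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(
    "<annotated_document> ", x$doc_id, ": ", nrow(x$sentences),
    " sentence(s), ", sum(vapply(x$annotations, function(a) length(a$surface), 0L)),
    " token(s)\n",
    sep = ""
  )
  invisible(x)
}

.doc_surfaces <- function(doc) {
  unlist(lapply(doc$annotations, `[[`, "surface"), use.names = FALSE)
}

.doc_pos <- function(doc) {
  unlist(lapply(doc$annotations, `[[`, "pos"), use.names = FALSE)
}

#' Script-type character ratios
#'
#' Proportion of hiragana, katakana and kanji among all non-whitespace
#' characters of the document text. The remainder (punctuation, Latin,
#' digits) is the implicit `other` class, so the three ratios sum to at most
#' one.
#'
#' @param doc An `annotated_document`.
#' @return Named numeric vector `hiragana`, `katakana`, `kanji`.
#' @export
char_type_ratios <- function(doc) {
  cp <- utf8ToInt(doc$text)
  cp <- cp[!(cp %in% .WHITESPACE)]
  if (!length(cp)) stop("document has no non-whitespace characters", call. = FALSE)
  cls <- .char_class(cp)
  c(
    hiragana = mean(cls == "hiragana"),
    katakana = mean(cls == "katakana"),
    kanji = mean(cls == "kanji")
  )
}

#' Lexical composition ratios
#'
#' Type-token ratio (distinct surfaces over tokens), content-word ratio
#' (nouns incl. proper nouns, verbs, adjectives, adverbs over tokens), the
#' verb-to-modifier ratio (verbs over adjectives + adverbs + conjunctions,
#' `NA` when that denominator is zero) and the proper-noun ratio.
#'
#' @param doc An `annotated_document`.
#' @return Named numeric vector `ttr`, `content_words`, `mvr`, `proper_nouns`.
#' @export
lexical_ratios <- function(doc) {
  surf <- .doc_surfaces(doc)
  pos <- .doc_pos(doc)
  n <- length(surf)
  modifiers <- sum(pos %in% c("ADJ", "ADV", "CONJ"))
  c(
    ttr = length(unique(surf)) / n,
    content_words = sum(pos %in% c("NOUN", "PROPN", "VERB", "ADJ", "ADV")) / n,
    mvr = if (modifiers == 0L) NA_real_ else sum(pos == "VERB") / modifiers,
    proper_nouns = sum(pos == "PROPN") / n
  )
}

#' Word-abstraction statistics
#'
#' Over tokens found in the abstraction lexicon: the maximum degree and the
#' mean of the five largest degrees (mean of all hits when fewer than five).
#' Both are `NA` when no token hits the lexicon; a miss contributes nothing.
#'
#' @param doc An `annotated_document`.
#' @param lex An `abstraction_lexicon`.
#' @return Named numeric vector `abstraction_max`, `abstraction_top5`.
#' @export
abstraction_stats <- function(doc, lex) {
  deg <- abstraction_degrees(lex, .doc_surfaces(doc))
  deg <- deg[!is.na(deg)]
  if (!length(deg)) {
    return(c(abstraction_max = NA_real_, abstraction_top5 = NA_real_))
  }
  top <- sort(deg, decreasing = TRUE)
  c(
    abstraction_max = top[1L],
    abstraction_top5 = mean(top[seq_len(min(5L, length(top)))])
  )
}

#' Sentence-level statistics
#'
#' Sentence count, mean sentence length in non-whitespace characters, and
#' the proportion of conversational (quoted-speech) sentences.
#'
#' @param doc An `annotated_document`.
#' @return Named numeric vector `n_sentences`, `mean_sentence_length`,
#'   `conversational`.
#' @export
sentence_stats <- function(doc) {
  s <- doc$sentences
  c(
    n_sentences = nrow(s),
    mean_sentence_length = mean(s$char_count),
    conversational = mean(s$is_conversational)
  )
}

#' Dependency-structure statistics
#'
#' Per sentence: tree depth is the longest chunk-to-root path counted in
#' chunks (a single-chunk sentence has depth 1). Document values are the
#' mean depth over sentences, the mean chunk count per sentence, and the
#' mean token count per chunk over all chunks of the document.
#'
#' @param doc An `annotated_document`.
#' @return Named numeric vector `tree_depth`, `chunks_per_sentence`,
#'   `words_per_chunk`.
#' @export
syntax_stats <- function(doc) {
  depths <- numeric(length(doc$annotations))
  n_chunks <- integer(length(doc$annotations))
  chunk_sizes <- vector("list", length(doc$annotations))
  for (s in seq_along(doc$annotations)) {
    a <- doc$annotations[[s]]
    heads <- as.integer(a$chunk_heads)
    depths[s] <- max(.chunk_depths(heads))
    n_chunks[s] <- length(heads)
    chunk_sizes[[s]] <- tabulate(as.integer(a$chunk_index) + 1L, length(heads))
  }
  c(
    tree_depth = mean(depths),
    chunks_per_sentence = mean(n_chunks),
    words_per_chunk = mean(unlist(chunk_sizes))
  )
}

#' Canonical metric order of the comparison report
#'
#' Script ratios, lexical ratios, abstraction, the seven emotion categories,
#' sentence statistics, then dependency statistics (tree depth is computed
#' and reported even though it has no counterpart row in typical cohort
#' summaries).
#'
#' @export
METRIC_ORDER <- c(
  "hiragana", "katakana", "kanji",
  "ttr", "content_words", "mvr", "proper_nouns",
  "abstraction_max", "abstraction_top5",
  EMOTION_CATEGORIES,
  "n_sentences", "mean_sentence_length", "conversational",
  "tree_depth", "chunks_per_sentence", "words_per_chunk"
)

#' Extract the full feature vector of a document
#'
#' Assembles the stylometric measures and the seven-category emotion profile
#' into one row: script-type ratios, lexical ratios, abstraction statistics,
#' emotion profile, sentence statistics and dependency statistics, in
#' [METRIC_ORDER]. Deterministic for fixed inputs.
#'
#' @param doc An `annotated_document`.
#' @param emotion_lex An `emotion_lexicon`.
#' @param abstraction_lex An `abstraction_lexicon`.
#' @param emotion_mode Profile normalisation, see [emotion_profile()].
#' @return A one-row data frame with column `doc_id` plus the 22 metrics.
#' @export
extract_features <- function(doc, emotion_lex, abstraction_lex,
                             emotion_mode = c("normalized", "per_all_words")) {
  emotion_mode <- match.arg(emotion_mode)
  vals <- c(
    char_type_ratios(doc),
    lexical_ratios(doc),
    abstraction_stats(doc, abstraction_lex),
    emotion_profile(doc, emotion_lex, mode = emotion_mode),
    sentence_stats(doc),
    syntax_stats(doc)
  )
  out <- data.frame(doc_id = doc$doc_id, stringsAsFactors = FALSE)
  for (m in METRIC_ORDER) out[[m]] <- unname(vals[[m]])
  out
}

#' Extract features for a list of documents
#'
#' @param docs List of `annotated_document` objects.
#' @inheritParams extract_features
#' @return A data frame, one row per document.
#' @export
extract_features_corpus <- function(docs, emotion_lex, abstraction_lex,
                                    emotion_mode = c("normalized", "per_all_words")) {
  emotion_mode <- match.arg(emotion_mode)
  do.call(rbind, lapply(docs, extract_features,
    emotion_lex = emotion_lex,
    abstraction_lex = abstraction_lex, emotion_mode = emotion_mode
  ))
}
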