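# Sentence segmentation, character classification and the sentence-preserving
# truncation rule for short Japanese narratives.

# Terminal punctuation that closes a sentence when outside any bracket span.
.TERMINALS <- c(0x3002L, 0xFF01L, 0xFF1FL, 0x21L, 0x3FL) # 。！？!?
# Bracket pairs whose interior is protected from sentence splitting.
.OPENERS <- c(0x300CL, 0x300EL, 0xFF08L, 0x28L) # 「『（(
.CLOSERS <- c(0x300DL, 0x300FL, 0xFF09L, 0x29L) # 」』）)
# Corner-bracket quotes mark conversational (quoted-speech) spans.
.CORNER_OPEN <- c(0x300CL, 0x300EL)
.CORNER_CLOSE <- c(0x300DL, 0x300FL)
.WHITESPACE <- c(0x20L, 0x09L, 0x0AL, 0x0DL, 0x3000L) # incl. ideographic space

#' Classify a single character by Japanese script type
#'
#' Maps one character to `"hiragana"`, `"katakana"`, `"kanji"` or `"other"`
#' using fixed Unicode blocks: hiragana U+3040--U+309F, katakana
#' U+30A0--U+30FF (so the prolonged sound mark ー counts as katakana), kanji
#' U+4E00--U+9FFF plus the iteration mark 々 (U+3005). Everything else,
#' including punctuation and Latin script, is `"other"`. Whitespace is never
#' passed in by the package's own callers; they strip it first.
#'
#' @param ch A single character (one code point).
#' @return One of `"hiragana"`, `"katakana"`, `"kanji"`, `"other"`.
#' @examples
#' classify_char("あ") # hiragana
#' classify_char("物") # kanji
#' @export
classify_char <- function(ch) {
  if (!is.character(ch) || length(ch) != 1L || is.na(ch) || nchar(ch) != 1L) {
    stop("`ch` must be exactly one character", call. = FALSE)
  }
  .char_class(utf8ToInt(ch))
}

# Vectorised class lookup on integer code points.
.char_class <- function(cp) {
  out <- rep.int("other", length(cp))
  out[cp >= 0x3040L & cp <= 0x309FL] <- "hiragana"
  out[cp >= 0x30A0L & cp <= 0x30FFL] <- "katakana"
  out[(cp >= 0x4E00L & cp <= 0x9FFFL) | cp == 0x3005L] <- "kanji"
  out
}

#' Split a narrative into sentences at terminal punctuation
#'
#' A sentence boundary falls after each 。！？! or ? that is not inside an
#' open bracket span (pairs 「」, 『』, （）, `()`; an unbalanced opener
#' protects to the end of the text). Trailing text without terminal
#' punctuation forms a final sentence. Every character of the input is
#' assigned to exactly one sentence, so concatenating the `text` column
#' reconstructs the input. A sentence is conversational when any of its
#' characters lies inside a corner-bracket quote (「…」 or 『…』).
#'
#' @param text A single non-empty string.
#' @return A data frame with one row per sentence and columns `index`
#'   (0-based), `text`, `char_count` (characters excluding whitespace) and
#'   `is_conversational`.
#' @examples
#' segment_sentences("昨日は雨。今日は晴れ。")
#' @export
segment_sentences <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single string", call. = FALSE)
  }
  if (!nzchar(trimws(text))) {
    stop("`text` is empty or whitespace-only", call. = FALSE)
  }
  cp <- utf8ToInt(text)
  n <- length(cp)

  special <- which(cp %in% c(.OPENERS, .CLOSERS, .TERMINALS))
  boundaries <- integer(0)
  if (length(special)) {
    stack <- integer(0)
    for (i in special) {
      ci <- cp[i]
      k <- match(ci, .OPENERS)
      if (!is.na(k)) {
        stack <- c(stack, ci)
      } else {
        k <- match(ci, .CLOSERS)
        if (!is.na(k)) {
          # pop only a matching opener; stray/mismatched closers are inert
          if (length(stack) && stack[length(stack)] == .OPENERS[k]) {
            stack <- stack[-length(stack)]
          }
        } else if (!length(stack)) {
          boundaries <- c(boundaries, i)
        }
      }
    }
  }

  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  keep <- starts <= ends
  starts <- starts[keep]
  ends <- ends[keep]

  ws <- cp %in% .WHITESPACE
  # a trailing whitespace-only fragment belongs to the last real sentence
  m <- length(starts)
  if (m > 1L && all(ws[starts[m]:ends[m]])) {
    ends[m - 1L] <- ends[m]
    starts <- starts[-m]
    ends <- ends[-m]
    m <- m - 1L
  }

  # conversational spans: inside corner quotes, brackets themselves included
  corner_delta <- (cp %in% .CORNER_OPEN) - (cp %in% .CORNER_CLOSE)
  depth_after <- cumsum(corner_delta)
  inside <- depth_after > 0L | (cp %in% .CORNER_CLOSE & depth_after >= 0L)

  texts <- character(m)
  counts <- integer(m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    span <- starts[j]:ends[j]
    texts[j] <- intToUtf8(cp[span])
    counts[j] <- sum(!ws[span])
    conv[j] <- any(inside[span])
  }
  data.frame(
    index = seq_len(m) - 1L,
    text = texts,
    char_count = counts,
    is_conversational = conv,
    stringsAsFactors = FALSE
  )
}

#' Truncate a narrative to a character budget, preserving whole sentences
#'
#' Keeps the longest sentence prefix whose last sentence either (a) ends at
#' or under `limit` characters, or (b) overshoots the limit by strictly fewer
#' characters than the previous sentence left unused below it. Character
#' counts exclude whitespace, matching [segment_sentences()]. If even the
#' first sentence exceeds the limit it is kept anyway, so the result is never
#' empty. The operation is idempotent.
#'
#' @param sentences A data frame as returned by [segment_sentences()].
#' @param limit Character budget (default 200).
#' @return The kept prefix of `sentences`, same columns, order preserved.
#' @export
truncate_narrative <- function(sentences, limit = 200L) {
  if (!is.data.frame(sentences) || nrow(sentences) == 0L) {
    stop("`sentences` must be a non-empty sentence data frame", call. = FALSE)
  }
  if (!is.numeric(limit) || length(limit) != 1L || limit < 1) {
    stop("`limit` must be a single integer >= 1", call. = FALSE)
  }
  cc <- cumsum(sentences$char_count)
  under <- which(cc <= limit)
  m <- if (length(under)) under[length(under)] else 0L
  keep <- if (m == 0L) {
    1L # floor rule: never drop the only candidate sentence
  } else if (m < nrow(sentences) && (cc[m + 1L] - limit) < (limit - cc[m])) {
    m + 1L # clause (b): overshoot strictly smaller than the remaining gap
  } else {
    m
  }
  sentences[seq_len(keep), , drop = FALSE]
}
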