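# Emotion-weight and word-abstraction lexicons: constructors, TSV readers and
# writers, and lookup with an explicit miss (NA), never a default weight.

#' The seven emotion categories, in canonical order
#'
#' Category order is fixed throughout the package: sadness, anxiety, anger,
#' disgust, trust, surprise, happiness.
#'
#' @export
EMOTION_CATEGORIES <- c(
  "sadness", "anxiety", "anger", "disgust", "trust", "surprise", "happiness"
)

#' Construct an emotion lexicon
#'
#' An emotion lexicon maps each word surface to a weight vector over the
#' seven categories in [EMOTION_CATEGORIES]. Weights lie in \[0, 1\] and sum
#' to 1 per word (JIWC-style normalisation).
#'
#' @param words Character vector of unique word surfaces.
#' @param weights Numeric matrix, one row per word, seven columns.
#' @param tol Tolerance on the per-row sum-to-1 check.
#' @return An object of class `emotion_lexicon`.
#' @export
emotion_lexicon <- function(words, weights, tol = 1e-6) {
  words <- as.character(words)
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (nrow(weights) != length(words) || ncol(weights) != 7L) {
    stop("`weights` must have one row per word and 7 columns", call. = FALSE)
  }
  dup <- words[duplicated(words)]
  if (length(dup)) {
    stop("duplicate surface(s) in emotion lexicon: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(words)) {
    if (anyNA(weights) || any(!is.finite(weights))) {
      stop("emotion weights must be finite", call. = FALSE)
    }
    if (any(weights < 0) || any(weights > 1)) {
      bad <- words[which(rowSums(weights < 0 | weights > 1) > 0)[1L]]
      stop("emotion weights outside [0, 1] for word '", bad, "'", call. = FALSE)
    }
    s <- rowSums(weights)
    off <- which(abs(s - 1) > tol)
    if (length(off)) {
      stop("emotion weights for word '", words[off[1L]], "' sum to ",
        format(s[off[1L]]), ", not 1",
        call. = FALSE
      )
    }
  }
  colnames(weights) <- EMOTION_CATEGORIES
  rownames(weights) <- NULL
  structure(list(words = words, weights = weights), class = "emotion_lexicon")
}

#' Read an emotion lexicon from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row and columns `word`,
#' then the seven categories of [EMOTION_CATEGORIES]. Every row is validated
#' (weights in \[0, 1\], summing to 1 within `tol`); duplicate surfaces and
#' malformed rows are rejected, never repaired.
#'
#' @param path Path to the TSV file.
#' @param tol Tolerance on the sum-to-1 check (default 1e-6).
#' @return An `emotion_lexicon`.
#' @export
load_emotion_lexicon <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = "character", fileEncoding = "UTF-8", check.names = FALSE
  )
  need <- c("word", EMOTION_CATEGORIES)
  if (!all(need %in% names(df))) {
    stop("emotion lexicon header must declare columns: ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  w <- suppressWarnings(
    vapply(EMOTION_CATEGORIES, function(k) as.numeric(df[[k]]), numeric(nrow(df)))
  )
  w <- matrix(w, nrow = nrow(df), ncol = 7L)
  if (nrow(df) && anyNA(w)) {
    bad <- which(rowSums(is.na(w)) > 0)[1L]
    stop("non-numeric weight in emotion lexicon row for word '",
      df$word[bad], "'",
      call. = FALSE
    )
  }
  emotion_lexicon(df$word, w, tol = tol)
}

#' Write an emotion lexicon to TSV
#'
#' Weights are printed with full double precision (`%.17g`) so that
#' write--read round trips reproduce the lexicon exactly.
#'
#' @param lex An `emotion_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emotion_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "emotion_lexicon"))
  cols <- apply(lex$weights, 2L, function(x) sprintf("%.17g", x))
  cols <- matrix(cols, nrow = length(lex$words), ncol = 7L)
  lines <- c(
    paste(c("word", EMOTION_CATEGORIES), collapse = "\t"),
    if (length(lex$words)) {
      paste(lex$words, apply(cols, 1L, paste, collapse = "\t"), sep = "\t")
    }
  )
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Look up emotion weights for token surfaces
#'
#' @param lex An `emotion_lexicon`.
#' @param surfaces Character vector of token surfaces.
#' @return A numeric matrix, one row per surface; rows for surfaces absent
#'   from the lexicon are all `NA` (a miss, not a zero-weight match).
#' @export
emotion_weights <- function(lex, surfaces) {
  stopifnot(inherits(lex, "emotion_lexicon"))
  idx <- match(surfaces, lex$words)
  out <- matrix(NA_real_,
    nrow = length(surfaces), ncol = 7L,
    dimnames = list(NULL, EMOTION_CATEGORIES)
  )
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- lex$weights[idx[hit], , drop = FALSE]
  out
}

#' Construct a word-abstraction lexicon
#'
#' Maps word surfaces to real-valued abstraction degrees (AWD-J-style).
#'
#' @param words Character vector of unique surfaces.
#' @param degrees Numeric vector of finite abstraction degrees.
#' @return An object of class `abstraction_lexicon`.
#' @export
abstraction_lexicon <- function(words, degrees) {
  words <- as.character(words)
  degrees <- as.numeric(degrees)
  if (length(words) != length(degrees)) {
    stop("`words` and `degrees` must have equal length", call. = FALSE)
  }
  dup <- words[duplicated(words)]
  if (length(dup)) {
    stop("duplicate surface(s) in abstraction lexicon: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(degrees) && (anyNA(degrees) || any(!is.finite(degrees)))) {
    stop("abstraction degrees must be finite numbers", call. = FALSE)
  }
  structure(list(words = words, degrees = degrees), class = "abstraction_lexicon")
}

#' Read a word-abstraction lexicon from TSV
#'
#' Expects UTF-8 TSV with header columns `word` and `degree`. Non-numeric
#' degrees and duplicate surfaces are rejected.
#'
#' @param path Path to the TSV file.
#' @return An `abstraction_lexicon`.
#' @export
load_abstraction_lexicon <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = "character", fileEncoding = "UTF-8", check.names = FALSE
  )
  if (!all(c("word", "degree") %in% names(df))) {
    stop("abstraction lexicon header must declare columns: word, degree",
      call. = FALSE
    )
  }
  deg <- suppressWarnings(as.numeric(df$degree))
  if (nrow(df) && anyNA(deg)) {
    bad <- which(is.na(deg))[1L]
    stop("non-numeric degree '", df$degree[bad], "' for word '",
      df$word[bad], "'",
      call. = FALSE
    )
  }
  abstraction_lexicon(df$word, deg)
}

#' Write a word-abstraction lexicon to TSV
#'
#' @param lex An `abstraction_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstraction_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "abstraction_lexicon"))
  lines <- c(
    "word\tdegree",
    if (length(lex$words)) {
      paste(lex$words, sprintf("%.17g", lex$degrees), sep = "\t")
    }
  )
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Look up abstraction degrees for token surfaces
#'
#' @param lex An `abstraction_lexicon`.
#' @param surfaces Character vector of token surfaces.
#' @return Numeric vector; `NA` for surfaces absent from the lexicon.
#' @export
abstraction_degrees <- function(lex, surfaces) {
  stopifnot(inherits(lex, "abstraction_lexicon"))
  lex$degrees[match(surfaces, lex$words)]
}
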