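# Weighted emotion profile of a document from a JIWC-style lexicon.

#' Seven-category emotion profile of a document
#'
#' Each token occurrence that hits the emotion lexicon contributes its weight
#' vector; tokens absent from the lexicon contribute nothing (they are not
#' zero-weight matches). With `M` matched tokens:
#'
#' * `mode = "normalized"` (default): the profile is the mean weight vector
#'   over matched tokens, so its seven components sum to 1 whenever `M >= 1`.
#'   This is the normalisation under which the seven group means of a cohort
#'   report each sum to ~1.
#' * `mode = "per_all_words"`: the summed weights are divided by the total
#'   token count instead, so the components sum to `M / n_tokens` (the
#'   literal "ratio relative to all words" reading).
#'
#' When no token matches (`M = 0`) all seven components are `NA` and the
#' document should be excluded from emotion comparisons.
#'
#' @param doc An `annotated_document`.
#' @param lex An `emotion_lexicon`.
#' @param mode Normalisation mode, see above.
#' @return Named numeric vector over [EMOTION_CATEGORIES].
#' @export
emotion_profile <- function(doc, lex, mode = c("normalized", "per_all_words")) {
  mode <- match.arg(mode)
  surf <- .doc_surfaces(doc)
  w <- emotion_weights(lex, surf)
  hit <- !is.na(w[, 1L])
  m <- sum(hit)
  if (m == 0L) {
    return(stats::setNames(rep(NA_real_, 7L), EMOTION_CATEGORIES))
  }
  total <- colSums(w[hit, , drop = FALSE])
  denom <- if (mode == "normalized") m else length(surf)
  total / denom
}
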