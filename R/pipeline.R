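# End-to-end drivers: raw record -> truncated annotated document -> feature
# table -> group comparison; plus seeded Monte-Carlo rejection-rate runs used
# for calibration and power checks.

#' Prepare a raw document: segment, truncate, attach annotations
#'
#' Re-segments the raw text, checks that the sentence count matches the
#' annotation blocks, applies the sentence-preserving truncation and keeps
#' the annotations of the retained sentences.
#'
#' @param doc A raw document record (fields `doc_id`, `text`, `annotations`,
#'   optionally `k10_items`, `age_group`, `gender`), e.g. one element of
#'   `generate_corpus()$documents` or of [read_corpus()].
#' @param limit Character budget for truncation (default 200).
#' @param validate Forwarded to [annotated_document()].
#' @return An `annotated_document` containing only the retained sentences.
#' @export
prepare_document <- function(doc, limit = 200L, validate = TRUE) {
  if (is.null(doc$annotations) || !length(doc$annotations)) {
    stop("document '", doc$doc_id, "' has no annotations", call. = FALSE)
  }
  sents <- segment_sentences(doc$text)
  if (nrow(sents) != length(doc$annotations)) {
    stop(
      "document '", doc$doc_id, "': ", nrow(sents),
      " segmented sentences but ", length(doc$annotations),
      " annotation blocks",
      call. = FALSE
    )
  }
  kept <- truncate_narrative(sents, limit)
  n <- nrow(kept)
  annotated_document(
    doc_id = doc$doc_id,
    text = paste0(kept$text, collapse = ""),
    sentences = kept,
    annotations = doc$annotations[seq_len(n)],
    meta = list(
      k10_items = doc$k10_items, age_group = doc$age_group,
      gender = doc$gender
    ),
    validate = validate
  )
}

#' Run the full comparison pipeline on a corpus
#'
#' Prepares every document (segmentation + truncation), extracts the feature
#' table, scores each document's K-10 response, and compares the two
#' distress groups.
#'
#' @param corpus A `narrative_corpus` (or a list with `documents`,
#'   `emotion_lexicon`, `abstraction_lexicon`).
#' @param limit Truncation character budget (default the corpus config's
#'   `truncation_limit`, else 200).
#' @param variant Test variant, `"welch"` (default) or `"pooled"`.
#' @param emotion_mode See [emotion_profile()].
#' @param cutoff K-10 cutoff (default 30).
#' @param adjust `"none"` or `"BH"`, see [compare_groups()].
#' @return A list with `features` (data frame), `groups` (character vector),
#'   `k10_totals` and `table` (a `comparison_table`).
#' @export
analyze_corpus <- function(corpus, limit = NULL,
                           variant = c("welch", "pooled"),
                           emotion_mode = c("normalized", "per_all_words"),
                           cutoff = 30L, adjust = c("none", "BH")) {
  variant <- match.arg(variant)
  emotion_mode <- match.arg(emotion_mode)
  adjust <- match.arg(adjust)
  if (is.null(limit)) {
    limit <- if (!is.null(corpus$config$truncation_limit)) {
      corpus$config$truncation_limit
    } else {
      200L
    }
  }
  docs <- lapply(corpus$documents, prepare_document, limit = limit)
  features <- extract_features_corpus(
    docs, corpus$emotion_lexicon, corpus$abstraction_lexicon,
    emotion_mode = emotion_mode
  )
  scored <- lapply(corpus$documents, function(d) score_k10(d$k10_items, cutoff = cutoff))
  groups <- vapply(scored, `[[`, "", "group")
  totals <- vapply(scored, `[[`, 0L, "total")
  tab <- compare_groups(features, groups,
    variant = variant, adjust = adjust,
    metadata = list(
      cutoff = cutoff, emotion_mode = emotion_mode,
      limit = limit, seed = corpus$config$seed
    )
  )
  list(features = features, groups = groups, k10_totals = totals, table = tab)
}

#' Monte-Carlo rejection rate of a metric's group comparison
#'
#' Repeatedly generates a corpus from `config`, runs the pipeline
#' (segmentation, truncation, feature extraction for the requested metric,
#' K-10 grouping, two-sample test) and records whether the metric's p value
#' falls below `alpha`. With identical Dirichlet parameters for both groups
#' this measures type-I error of the happiness comparison; with the default
#' (shifted) config it measures power.
#'
#' For emotion metrics only the emotion profile is computed per document,
#' which keeps a 1000-replicate run inside a few minutes.
#'
#' @param config A `generator_config`; its `seed` field is ignored here.
#' @param n_reps Number of replicate corpora.
#' @param alpha Significance level (default 0.05).
#' @param metric Metric to test (default `"happiness"`).
#' @param variant Test variant (default `"welch"`).
#' @param seed Seed for the whole run, or `NULL` to use the current stream.
#' @return A list with `rate`, `rejections`, `n_reps` and the vector of
#'   `p_values`.
#' @export
simulate_rejection_rate <- function(config = generator_config(), n_reps = 1000L,
                                    alpha = 0.05, metric = "happiness",
                                    variant = c("welch", "pooled"),
                                    seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$seed <- NULL
  emotion_only <- metric %in% EMOTION_CATEGORIES
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    corpus <- generate_corpus(cfg)
    groups <- corpus$k10$group
    vals <- if (emotion_only) {
      vapply(corpus$documents, function(d) {
        doc <- prepare_document(d, limit = cfg$truncation_limit, validate = FALSE)
        emotion_profile(doc, corpus$emotion_lexicon)[[metric]]
      }, 0)
    } else {
      docs <- lapply(corpus$documents, prepare_document,
        limit = cfg$truncation_limit, validate = FALSE
      )
      extract_features_corpus(
        docs, corpus$emotion_lexicon,
        corpus$abstraction_lexicon
      )[[metric]]
    }
    ok <- !is.na(vals)
    pvals[r] <- two_sample_test(
      vals[ok & groups == "higher"],
      vals[ok & groups == "lower"],
      variant = variant
    )$p
  }
  rej <- sum(pvals < alpha)
  list(rate = rej / n_reps, rejections = rej, n_reps = n_reps, p_values = pvals)
}
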