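# K-10 scoring, two-sample tests (Welch and pooled, from data or from summary
# statistics), rounding-interval reconciliation, and the comparison table.

#' Score a K-10 questionnaire response
#'
#' The Kessler Psychological Distress Scale has 10 ordinal items scored 1-5;
#' the total ranges 10-50 and a total at or above the cutoff (default 30)
#' assigns the respondent to the higher-distress group.
#'
#' @param items Numeric vector of exactly 10 item scores, each in 1..5.
#' @param cutoff Distress cutoff on the total (default 30, boundary
#'   inclusive: a total of exactly 30 is `"higher"`).
#' @return A list with `total` (integer) and `group` (`"higher"` or
#'   `"lower"`).
#' @examples
#' score_k10(rep(3, 10)) # total 30 -> higher
#' @export
score_k10 <- function(items, cutoff = 30L) {
  if (length(items) != 10L) {
    stop("K-10 has exactly 10 items, got ", length(items), call. = FALSE)
  }
  if (anyNA(items) || !is.numeric(items) || any(items != round(items)) ||
    any(items < 1 | items > 5)) {
    stop("K-10 items must be integers in 1..5", call. = FALSE)
  }
  total <- as.integer(sum(items))
  list(total = total, group = if (total >= cutoff) "higher" else "lower")
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided t-test from group sizes, means and standard
#' deviations. `variant = "welch"` uses the unpooled standard error with
#' Satterthwaite degrees of freedom; `variant = "pooled"` uses the pooled
#' variance with `n1 + n2 - 2` degrees of freedom. The sign convention is
#' `mean1 - mean2`. When both SDs are zero and the means are equal the test
#' is degenerate and returns `t = 0`, `p = 1`.
#'
#' @param n1,m1,s1 Size, mean, SD of the first group.
#' @param n2,m2,s2 Size, mean, SD of the second group.
#' @param variant `"welch"` or `"pooled"`.
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
two_sample_test_from_summaries <- function(n1, m1, s1, n2, m2, s2,
                                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative", call. = FALSE)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (variant == "welch") {
    se2 <- v1 + v2
    df <- if (se2 > 0) {
      se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    } else {
      n1 + n2 - 2
    }
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample t-test from raw data
#'
#' Same formulas as [two_sample_test_from_summaries()], computed from the
#' observations. Sign convention: `mean(x) - mean(y)`.
#'
#' @param x,y Numeric vectors of at least 2 finite observations each.
#' @param variant `"welch"` or `"pooled"`.
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
two_sample_test <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("observations must be finite and non-missing", call. = FALSE)
  }
  two_sample_test_from_summaries(
    length(x), mean(x), stats::sd(x),
    length(y), mean(y), stats::sd(y),
    variant = variant
  )
}

#' Attainable t-statistic interval under rounding of printed summaries
#'
#' Printed group means and SDs are rounded; the true t statistic computed
#' from unrounded data can therefore lie anywhere in an interval. This
#' evaluates the test statistic at every corner of the rounding box (means
#' and SDs each within half an ulp of the printed precision) and returns its
#' range. Used to reconcile a reported t value with printed summaries: the
#' reported value should fall inside the interval of the variant that was
#' actually run.
#'
#' @inheritParams two_sample_test_from_summaries
#' @param digits Printed decimal places of the summaries (default 3).
#' @return Numeric vector `c(lower, upper)` of attainable t values.
#' @export
t_rounding_interval <- function(n1, m1, s1, n2, m2, s2,
                                variant = c("welch", "pooled"), digits = 3L) {
  variant <- match.arg(variant)
  h <- 0.5 * 10^(-digits)
  corners <- expand.grid(
    m1 = m1 + c(-h, h), s1 = pmax(0, s1 + c(-h, h)),
    m2 = m2 + c(-h, h), s2 = pmax(0, s2 + c(-h, h))
  )
  tt <- apply(corners, 1L, function(r) {
    two_sample_test_from_summaries(n1, r[["m1"]], r[["s1"]],
      n2, r[["m2"]], r[["s2"]],
      variant = variant
    )$t
  })
  range(tt)
}

#' Compare feature distributions between distress groups
#'
#' Builds a cohort comparison table: one row per metric with group sizes,
#' means, SDs, the t statistic, degrees of freedom and two-sided p value.
#' Documents with a missing value for a metric are dropped from that metric's
#' row only. The sign convention is higher-distress minus lower-distress.
#' No multiple-testing correction is applied by default; `adjust = "BH"`
#' appends a Benjamini-Hochberg column.
#'
#' @param features Data frame from [extract_features_corpus()] (column
#'   `doc_id` plus metric columns).
#' @param groups Character vector aligned with `features` rows, values
#'   `"higher"` / `"lower"`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param adjust `"none"` or `"BH"`.
#' @param metrics Metrics to report; defaults to the intersection of
#'   [METRIC_ORDER] with the feature columns, in canonical order.
#' @param metadata Optional named list recorded as the table's `metadata`
#'   attribute (e.g. cutoff, emotion mode, seed).
#' @return A data frame of class `comparison_table` with columns `metric`,
#'   `n_high`, `mean_high`, `sd_high`, `n_low`, `mean_low`, `sd_low`, `t`,
#'   `df`, `p` (and `p_adj` when requested).
#' @export
compare_groups <- function(features, groups, variant = c("welch", "pooled"),
                           adjust = c("none", "BH"), metrics = NULL,
                           metadata = list()) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  if (nrow(features) != length(groups)) {
    stop("`groups` must align with the rows of `features`", call. = FALSE)
  }
  if (!all(groups %in% c("higher", "lower"))) {
    stop("group labels must be 'higher' or 'lower'", call. = FALSE)
  }
  if (sum(groups == "higher") < 2L || sum(groups == "lower") < 2L) {
    stop("need at least 2 documents in each distress group", call. = FALSE)
  }
  if (is.null(metrics)) {
    metrics <- intersect(METRIC_ORDER, names(features))
  }
  rows <- lapply(metrics, function(m) {
    x <- features[[m]][groups == "higher"]
    y <- features[[m]][groups == "lower"]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(
        metric = m, n_high = length(x), mean_high = NA_real_, sd_high = NA_real_,
        n_low = length(y), mean_low = NA_real_, sd_low = NA_real_,
        t = NA_real_, df = NA_real_, p = NA_real_, stringsAsFactors = FALSE
      ))
    }
    tt <- two_sample_test(x, y, variant = variant)
    data.frame(
      metric = m,
      n_high = length(x), mean_high = mean(x), sd_high = stats::sd(x),
      n_low = length(y), mean_low = mean(y), sd_low = stats::sd(y),
      t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  metadata$test_variant <- variant
  attr(out, "metadata") <- metadata
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  md <- attr(x, "metadata")
  cat("Group comparison (", md$test_variant, " t-test, higher - lower)\n", sep = "")
  extra <- setdiff(names(md), "test_variant")
  if (length(extra)) {
    cat("  ", paste(extra, vapply(md[extra], function(v) paste(format(v), collapse = ","), ""),
      sep = "=", collapse = "  "
    ), "\n", sep = "")
  }
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}
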