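# Independent oracles. These deliberately avoid the package's code paths:
# tree depth by exhaustive path enumeration, t statistics by directly typed
# closed forms, and the happiness power oracle by simulating the generative
# model with base RNG draws and stats::t.test.

# Longest root-to-leaf path (in chunks) by enumerating every path of the
# tree; heads are 0-based with -1 at the root.
oracle_tree_depth <- function(heads) {
  nc <- length(heads)
  children <- lapply(seq_len(nc) - 1L, function(j) which(heads == j) - 1L)
  root <- which(heads == -1L) - 1L
  walk <- function(node, depth) {
    kids <- children[[node + 1L]]
    if (!length(kids)) {
      return(depth)
    }
    max(vapply(kids, function(k) walk(k, depth + 1L), 0L))
  }
  walk(root, 1L)
}

# Random rooted tree over n chunks: node j (0-based) attaches to a uniformly
# chosen later node, last node is the root.
random_heads <- function(n) {
  if (n == 1L) {
    return(-1L)
  }
  heads <- integer(n)
  for (i in seq_len(n - 1L)) {
    # 1-based head position uniform in (i+1)..n; stored 0-based
    heads[i] <- (if (i + 1L == n) n else sample((i + 1L):n, 1L)) - 1L
  }
  heads[n] <- -1L
  heads
}

oracle_t_pooled <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_t_welch <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- var(x) / n1
  v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_t_summary <- function(n1, m1, s1, n2, m2, s2, variant) {
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
  }
}

# Range of t over the 3-decimal rounding box of the printed summaries.
oracle_t_interval <- function(n1, m1, s1, n2, m2, s2, variant, digits = 3) {
  h <- 0.5 * 10^(-digits)
  grid <- expand.grid(
    a = m1 + c(-h, h), b = max(0, s1 - h) + c(0, 2 * h),
    c = m2 + c(-h, h), d = max(0, s2 - h) + c(0, 2 * h)
  )
  range(apply(grid, 1, function(r) {
    oracle_t_summary(n1, r[["a"]], r[["b"]], n2, r[["c"]], r[["d"]], variant)
  }))
}

# Brute-force Monte-Carlo of the happiness comparison under the generative
# model: per document, sentence and token counts are Poisson (floored),
# token lengths uniform 1..3 (emotion words length 4), a sentence costs its
# token characters + 1 terminal (+2 if quoted), truncation keeps the longest
# prefix under the 200-character rule with the strict clause-(b) overshoot
# test, matched tokens are Bernoulli(rate) with happiness weights from the
# group's Beta marginal, and groups are compared with stats::t.test (Welch).
oracle_happiness_rejection <- function(cfg, n_reps, alpha = 0.05) {
  a_hi <- cfg$emotion_dirichlet_high
  a_lo <- cfg$emotion_dirichlet_low
  limit <- cfg$truncation_limit
  doc_value <- function(alpha7) {
    S <- max(1L, rpois(1L, cfg$sentences_per_doc))
    Tv <- pmax(2L, rpois(S, cfg$tokens_per_sentence))
    emo <- lapply(Tv, function(n) runif(n) < cfg$emotion_match_rate)
    lens <- lapply(seq_len(S), function(s) {
      ifelse(emo[[s]], 4L, sample(3L, Tv[s], replace = TRUE))
    })
    conv <- runif(S) < cfg$conversational_rate
    chars <- vapply(lens, sum, 0L) + 1L + 2L * conv
    cc <- cumsum(chars)
    under <- which(cc <= limit)
    m <- if (length(under)) under[length(under)] else 0L
    keep <- if (m == 0L) {
      1L
    } else if (m < S && (cc[m + 1L] - limit) < (limit - cc[m])) {
      m + 1L
    } else {
      m
    }
    k <- sum(unlist(emo[seq_len(keep)]))
    if (k == 0L) {
      return(NA_real_)
    }
    mean(rbeta(k, alpha7[7L], sum(alpha7) - alpha7[7L]))
  }
  rej <- 0L
  for (r in seq_len(n_reps)) {
    x <- vapply(seq_len(cfg$n_high), function(i) doc_value(a_hi), 0)
    y <- vapply(seq_len(cfg$n_low), function(i) doc_value(a_lo), 0)
    p <- stats::t.test(x[!is.na(x)], y[!is.na(y)])$p.value
    if (p < alpha) rej <- rej + 1L
  }
  rej / n_reps
}
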