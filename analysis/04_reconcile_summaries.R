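#!/usr/bin/env Rscript
# Step 4: reconcile reported cohort summary statistics with the test
# formulas. Published group comparisons print means and SDs to 3 decimals;
# the t computable from unrounded data therefore lies in an interval. For
# the youth happiness row (n 21, mean 0.134, SD 0.049 vs n 31, mean 0.109,
# SD 0.018, printed |t| 2.657 at df 50) we ask which variant — pooled or
# Welch — can have produced the printed value.

suppressPackageStartupMessages(library(narrastyle))

n1 <- 21
m1 <- 0.134
s1 <- 0.049
n2 <- 31
m2 <- 0.109
s2 <- 0.018
printed_t <- 2.657

rows <- list()
for (variant in c("pooled", "welch")) {
  fit <- two_sample_test_from_summaries(n1, m1, s1, n2, m2, s2, variant)
  int <- t_rounding_interval(n1, m1, s1, n2, m2, s2, variant)
  inside <- printed_t >= int[1] && printed_t <= int[2]
  rows[[variant]] <- data.frame(
    variant = variant, t = fit$t, df = fit$df, p = fit$p,
    t_low = int[1], t_high = int[2], printed_t_attainable = inside
  )
  cat(sprintf(
    "%s: t = %0.3f (df %0.1f, p %0.4f), rounding interval [%0.3f, %0.3f] -> printed 2.657 %s\n",
    variant, fit$t, fit$df, fit$p, int[1], int[2],
    if (inside) "ATTAINABLE" else "not attainable"
  ))
}

tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/reconciliation.csv", row.names = FALSE)

cat("\npooled df from the cohort sizes:\n")
cat("  youth 21 + 31 - 2 =", two_sample_test_from_summaries(21, 0, 1, 31, 0, 1, "pooled")$df, "\n")
cat("  adult 94 + 483 - 2 =", two_sample_test_from_summaries(94, 0, 1, 483, 0, 1, "pooled")$df, "\n")
cat("\nConclusion: the printed happiness t and the df column match the\n")
cat("pooled formula; the Welch interval excludes the printed value even\n")
cat("though the cohort table's footnote names Welch. Both variants are\n")
cat("therefore computed throughout this package and named in every output.\n")
cat("wrote results/reconciliation.csv\n")
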