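#!/usr/bin/env Rscript
# Step 3: score the K-10 responses (cutoff 30, boundary inclusive), split
# writers into higher/lower distress, and compare every metric between
# groups. The Welch test is the default (variances are not assumed equal);
# the pooled-variance table is written alongside because reported cohort
# tables of this kind are sometimes consistent with the pooled formula
# (df = n1 + n2 - 2) rather than Welch.

suppressPackageStartupMessages(library(narrastyle))

docs_raw <- read_corpus("results/corpus.jsonl")
emo <- load_emotion_lexicon("results/emotion_lexicon.tsv")
abs_lex <- load_abstraction_lexicon("results/abstraction_lexicon.tsv")
corpus <- list(
  documents = docs_raw, emotion_lexicon = emo,
  abstraction_lexicon = abs_lex, config = list(seed = 20L, truncation_limit = 200L)
)

for (variant in c("welch", "pooled")) {
  res <- analyze_corpus(corpus, variant = variant)
  out <- sprintf("results/comparison_%s.csv", variant)
  write_results(res$table, out)
  cat("\n==", variant, "t-test (higher - lower) ==\n")
  show <- res$table[res$table$metric %in%
    c("ttr", "content_words", "happiness", "sadness", "n_sentences"), ]
  print(as.data.frame(show), digits = 3, row.names = FALSE)
  cat("wrote", out, "and its _full companion\n")
}

res <- analyze_corpus(corpus)
hap <- res$table[res$table$metric == "happiness", ]
cat(sprintf(
  "\nhappiness row (welch): mean %0.3f (SD %0.3f) vs %0.3f (SD %0.3f), t = %0.2f, p = %0.3f\n",
  hap$mean_high, hap$sd_high, hap$mean_low, hap$sd_low, hap$t, hap$p
))
cat("The injected happiness shift is the only built-in group effect;\n")
cat("emotion rows are correlated because normalized profiles sum to 1.\n")
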