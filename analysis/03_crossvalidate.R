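#!/usr/bin/env Rscript
# Fivefold cross-validation of every pooled pair dataset of the corpus.
suppressPackageStartupMessages(library(mnscaling))

corpus <- load_corpus("results/synthetic_corpus.csv")
globals <- corpus_to_globals(corpus)
seed <- 0
tab <- do.call(rbind, lapply(names(globals), function(key) {
  cv <- crossvalidate(globals[[key]], folds = 5, seed = seed)
  data.frame(pair = key, n = length(globals[[key]]$x),
             nME = cv$nME, nRMSE = cv$nRMSE,
             r2pred = cv$r2pred, r2exp = cv$r2exp)
}))
write.csv(tab, "results/crossvalidation.csv", row.names = FALSE)
cat(sprintf("Fivefold CV over %d pooled datasets (seed %d):\n", nrow(tab), seed))
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("nME range %.0f-%.0f%%, nRMSE range %.0f-%.0f%%; r2pred tracks r2exp (max gap %.2f).\n",
            min(tab$nME), max(tab$nME), min(tab$nRMSE), max(tab$nRMSE),
            max(abs(tab$r2pred - tab$r2exp))))
cat("Table -> results/crossvalidation.csv\n")
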