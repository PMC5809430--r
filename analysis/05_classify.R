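#!/usr/bin/env Rscript
# Rank amino-acid features for predicting cleavage: forward-stepwise
# logistic regression with AUROC, cleaved peptides against a size-matched
# random draw from the neutral pool, globally and per position.

library(nnkscreen)

records <- read.delim("results/enrichment.tsv", stringsAsFactors = FALSE)
cleaved <- records$peptide[records$label == "cleaved"]
neg <- sample_negatives(records, seed = 20260919)
peps <- c(cleaved, neg)
y <- rep(c(1, 0), c(length(cleaved), length(neg)))

for (mode in c("global", "positional")) {
  X <- build_features(peps, mode)
  sw <- forward_stepwise(X, y, tol = 0.001)
  write.table(sw$path, sprintf("results/stepwise_%s.tsv", mode), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%s features: %s; final AUROC %.3f", mode,
                  paste0(sw$path$sign, sw$path$feature, collapse = " "),
                  sw$auroc))
}
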