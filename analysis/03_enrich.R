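#!/usr/bin/env Rscript
# Test every peptide (>= 4 reads combined) for enrichment or depletion with
# the negative-binomial Wald model and BH FDR at 0.05.

library(nnkscreen)

counts <- as.matrix(read.delim("results/counts.tsv", row.names = 1,
                               check.names = FALSE))
manifest <- read.delim("scratch/screen/manifest.tsv", stringsAsFactors = FALSE)
pc <- list(counts = counts,
           sample_info = manifest[, c("name", "role", "replicate")])

records <- run_enrichment(pc, min_total = 4L, alpha = 0.05)
write.table(records, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tab <- table(records$label)
message(sprintf("tested %d peptides: %d cleaved, %d depleted, %d neutral",
                nrow(records), tab["cleaved"], tab["depleted"], tab["neutral"]))
top <- rank_order_report(records)
message("top cleaved peptides by p_fdr:")
print(head(top, 5))
write.table(top, "results/rank_order.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
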