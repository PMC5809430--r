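#!/usr/bin/env Rscript
# Convert the paired-end reads into a peptide count table through the three
# quality filters (seed orientation, mate perfect match, Phred >= 5), with
# stop-codon accounting.

library(nnkscreen)

manifest <- read.delim("scratch/screen/manifest.tsv", stringsAsFactors = FALSE)
pc <- tally_peptides(manifest, default_template())

dir.create("results", showWarnings = FALSE)
write.table(data.frame(peptide = rownames(pc$counts), pc$counts,
                       check.names = FALSE),
            "results/counts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pc$qc, "results/qc.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d unique stop-free peptides across %d samples",
                nrow(pc$counts), ncol(pc$counts)))
message(sprintf("passed-filter fraction: %.1f%% (min %.1f%%)",
                100 * mean(pc$qc$passed_fraction), 100 * min(pc$qc$passed_fraction)))
message(sprintf("stop-read fraction among passed: %.4f%%",
                100 * sum(pc$qc$stop_reads) / sum(pc$qc$passed)))
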