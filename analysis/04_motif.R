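#!/usr/bin/env Rscript
# Build the substrate-recognition motif from the classified peptides:
# residue proportions, Arg-anchored differential logo, and p-value-binned
# frequency profiles.

library(nnkscreen)

records <- read.delim("results/enrichment.tsv", stringsAsFactors = FALSE)

prop <- aa_proportion_comparison(records)
write.table(prop, "results/aa_proportions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("residues ordered by cleaved-minus-depleted proportion difference:")
message(paste(head(prop$aa, 5), collapse = " "), " ... ",
        paste(tail(prop$aa, 3), collapse = " "))

cleaved <- records$peptide[records$label == "cleaved"]
depleted <- records$peptide[records$label == "depleted"]
al_c <- align_on_anchor(cleaved, "R", "center_most")
al_d <- align_on_anchor(depleted, "R", "center_most")
message(sprintf("anchored %d/%d cleaved and %d/%d depleted peptides on Arg",
                nrow(al_c), length(cleaved), nrow(al_d), length(depleted)))
logo <- differential_logo(position_frequencies(al_c), position_frequencies(al_d))
write.table(logo, "results/differential_logo.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
calls <- table(logo$call)
message(sprintf("logo cells: %d enriched, %d depleted, %d unpopulated",
                calls["enriched"], calls["depleted"], calls["unpopulated"]))

binned <- pvalue_binned_profiles(records, min_bin = 10L)
write.table(binned, "results/pvalue_binned_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("p-value bins: %d enriched-arm, %d depleted-arm",
                sum(binned$arm == "enriched"), sum(binned$arm == "depleted")))
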