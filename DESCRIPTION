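Package: nnkscreen
Title: Substrate Phage Display Screening Analysis with NNK Hexapeptide Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of substrate phage display screens read out
    by high-throughput sequencing. Generates NNK-randomized hexapeptide phage
    libraries with a planted protease cleavage motif and paired-end FASTQ reads;
    converts paired-end reads into quality-filtered peptide count tables
    (seed-based orientation, mate perfect-match and Phred quality filters, NNK
    translation with stop-codon accounting); tests peptides for enrichment or
    depletion with a negative-binomial Wald model and Benjamini-Hochberg FDR;
    builds substrate-recognition motifs (anchored alignment, position frequency
    matrices, differential logos, p-value-binned profiles); and ranks
    amino-acid features by forward-stepwise logistic regression with AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
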