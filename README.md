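# nnkscreen

Analysis of substrate phage display screens read out by high-throughput
sequencing, together with a simulator that generates fully specified
screens so every stage can be tested against known ground truth.

## The problem

Substrate phage display fuses a randomized peptide (here, six residues
encoded by NNK degenerate codons) to the phage coat protein between a
capture tag and the phage body. Incubation with a protease releases phage
displaying cleavable peptides into the supernatant; sequencing the variable
region before and after selection turns substrate specificity profiling
into a counting problem. The analysis has four stages:

1. **Read processing** — paired-end reads are oriented by any of three 8-bp
   seed sequences in the forward flank, required to agree perfectly between
   mates across the 18-nt variable region, required to have Phred ≥ 5 at
   every variable-region base, then translated; stop-codon reads are
   tallied and removed. The mate-concordance filter suppresses a per-read
   error rate *p* to roughly *p*² among accepted reads (1% → 0.01%).
2. **Enrichment testing** — peptides with ≥ 4 reads combined are tested for
   differential abundance between selected and unselected samples with a
   negative-binomial generalized linear model: median-of-ratios size
   factors *s\_j*, per-peptide dispersions α (method-of-moments shrunk
   toward an α(μ) = a/μ + b trend), counts *K\_ij* ~ NB(μ\_ij, α\_i) with
   log μ\_ij = log s\_j + β₀ + β₁·selected\_j, and a Wald test on β₁.
   Benjamini–Hochberg adjusted p\_FDR < 0.05 with log₂FC > 0 calls a
   peptide **cleaved**, with log₂FC < 0 **depleted**.
3. **Motif construction** — residue proportions in cleaved vs depleted
   pools; Schechter–Berger alignment anchored on a chosen P1 residue
   (center-most occurrence, ties to the lower position); differential
   logos using the two-proportion z statistic
   z = (f₁ − f₂) / √(f̄(1 − f̄)(1/n₁ + 1/n₂)); residue-frequency profiles
   across p-value bins.
4. **Feature ranking** — forward-stepwise logistic regression over
   amino-acid presence indicators (global `R` or positional `R@3`),
   greedily maximizing in-sample AUROC, cleaved peptides against a
   size-matched draw from the neutral pool.

The simulator plants a position-weight cleavage motif
(p = logistic(b + Σ w\[pos, aa\])) in an NNK library with log-normal clone
abundance skew, applies one saturating selection round, and writes
paired-end FASTQ with substitution errors and Phred+33 qualities — so the
pipeline's statistical behavior (error suppression, FDR control, motif
recovery) is verifiable end to end.

## Worked example

The numbered drivers under `analysis/` run a complete simulated screen
(10,000 clones, planted P1-Arg motif, 2 × 2 samples × 250,000 read pairs);
tables land in `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract.R
Rscript analysis/03_enrich.R
Rscript analysis/04_motif.R
Rscript analysis/05_classify.R
```

which prints, stage by stage:

```
library: 10000 clones, 17.2% stop-containing (NNK expectation 17.3%)
8270 unique stop-free peptides across 4 samples
passed-filter fraction: 96.3% (min 96.2%)
tested 8175 peptides: 789 cleaved, 375 depleted, 7011 neutral
residues ordered by cleaved-minus-depleted proportion difference:
R K Y W Q ... L P T
anchored 788/789 cleaved and 147/375 depleted peptides on Arg
global features: +R -P +K -E -M -C -V -Q -H; final AUROC 0.843
positional features: +R@3; final AUROC 0.999
```

Reading this: stop-containing clones are synthesized at the NNK-expected
17% but never displayed; virtually all significantly enriched peptides
carry the planted Arg, which tops the proportion ranking and is the first
feature selected in both stepwise modes; the positional model pins the
effect to position 3 almost perfectly, while the position-free model
settles near AUROC 0.84 because Arg presence alone cannot say where.

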