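---
title: "Models and methods behind nnkscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nnkscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnkscreen)
```

This vignette explains the models implemented in `nnkscreen`, the
parameters a user might want to change, what the simulator does and does
not emulate, and the numerical choices made where the design was open.

## The screen being modeled

A phage display library presents a randomized hexapeptide, encoded by six
NNK degenerate codons (N = A/C/G/T at codon positions 1–2, K = G/T at
position 3), between a bead-capture tag and the phage body. Protease
treatment releases phage whose displayed peptide is cleavable; deep
sequencing of the 18-nt variable region before and after selection gives
per-peptide read counts in unselected and selected samples. The NNK scheme
matters in three ways:

- 31 of the 32 NNK codons are sense codons covering all 20 amino acids, so
  residue frequencies are codon-count weighted (Leu 3/32, Met 1/32, ...);
  `nnk_expected_frequencies()` enumerates this.
- TAG is the only stop reachable without an A in the codon's third
  position, so error-free libraries contain TAG stops exclusively. The
  expected fraction of hexamer inserts carrying at least one stop is
  1 − (31/32)⁶ ≈ 17.3%.
- Because the displayed peptide is fused N-terminally to the essential
  coat protein, a stop prevents phage assembly: the simulator gives
  stop-containing clones zero display abundance while keeping them in the
  ground-truth record.

## The synthetic-data generator

`simulate_screen()` draws a library, applies selection, and writes
paired-end FASTQ. Its defaults are the study conditions the analyses and
tests run under:

- **Library**: `n_clones` independent clones; abundances log-normal with
  `abundance_log_sd = 1`. The skew default reflects that real screens see
  per-peptide counts spanning two to three orders of magnitude; 1.0 on the
  log scale reproduces that span at typical depths.
- **Selection**: one saturating round. Overnight digestion is modeled as
  proceeding to completion, so the selected abundance of clone *i* is
  proportional to (input abundance) × (cleavage probability); there are no
  partial-round kinetics. The cleavage probability comes from a
  position-weight model `cleavage_motif()`: logistic(intercept +
  Σ weights[pos, residue]). A constant-probability motif cancels under
  renormalization, which is the simulator's built-in null.
- **Sequencing**: paired-end 50-bp reads covering the full variable region
  from both strands; substitution errors only, at `per_base_error`
  defaulting to 0.01/18 so that a variable region accumulates an error
  with probability 1% per read — the per-sequence error convention used
  when quoting the 1% → 0.01% concordance-filter suppression. Indels are
  not simulated: the amplicon is fixed-length and Illumina's error profile
  is substitution-dominated. Phred scores (0–40, +33 encoding) are drawn
  from a fixed distribution concentrated near Q40 with per-base
  P(Q < 5) = 5 × 10⁻⁴; by default quality is independent of error status,
  and `quality_model = "error_low_q"` instead marks error sites with Q < 5
  to exercise the quality filter.
- **Amplicon layout**: the forward flank carries three 8-bp orientation
  seeds at offsets 0, 8, 16. Seed identities are configuration, not
  constants — they are whatever the flank text contains at those offsets
  (`extraction_template()` derives them), since real seed sequences are
  primer-design choices.

What the simulator does **not** emulate: stop-codon read-through (real
libraries show a small stop-read fraction with TAG dominating; simulated
stop clones are simply never displayed, so simulated stop fractions are
~0), PCR chimeras, amplification bias beyond the abundance skew, optical
duplicates, and indels. Passing tests therefore demonstrate the
statistical machinery on an idealized substitution-error channel, not
robustness to every artifact of real runs.

## Read processing

Three filters, applied in a fixed order but jointly equivalent to
requiring all of them:

1. **Orientation**: a pair is accepted if either mate carries any of the
   three seeds exactly at its stated offset; matching is exact because
   error tolerance comes from having three chances, not fuzzy matching.
2. **Mate concordance**: the sense read's variable region must match the
   reverse-complemented antisense read's base for base. A per-read error
   rate *p* survives this filter only when both mates err identically, so
   the accepted-read error rate falls to the *p*² scale (the coincident
   same-position, same-base substitution rate is lower still, ≈ 18 ·
   (p/18)²/3).
3. **Quality**: Phred ≥ 5 at every variable-region position of *both*
   mates — the stringent reading of a per-position threshold that does not
   name a mate.

Reads whose variable region is incomplete (template misconfiguration,
short reads) are rejected and tallied separately as `incomplete`;
coordinates are 0-based half-open internally and 1-based in reports.
Translation uses the standard genetic code; the first in-frame stop sets
the stop flag and its codon identity feeds the TAG/TAA/TGA QC breakdown.

## Enrichment model

Counts are modeled per peptide as negative binomial with mean
μ_ij = s_j · exp(β₀ + β₁ x_j), x the selected-condition indicator:

- **Size factors** are median-of-ratios: the median over all-positive
  peptides of count/geometric-mean, with a total-count fallback (and
  warning) when no peptide is positive everywhere. The median is taken on
  the log scale, so even-count medians interpolate geometrically.
- **Dispersions**: method-of-moments α̂ = max(0, (s² − μ)/μ²) from
  within-condition pooled moments of normalized counts, a trend
  α(μ) = a/μ + b fit by least squares over peptides with α̂ > 0, and the
  final value 0.5·α̂ + 0.5·trend (weight configurable), floored at 10⁻⁸.
  With a single replicate per condition, per-peptide moments are
  unidentifiable and a blind (condition-ignoring) estimate is used with a
  warning — conservative, since it absorbs the condition effect into the
  dispersion.
- **Wald test**: the two-parameter IRLS is vectorized across peptides
  (closed-form 2×2 weighted solves), with log size factors as offsets and
  expected-information standard errors. Fitted means are floored at
  `minmu = 0.5` inside the iteration — the convention of count-based
  differential testing — which keeps coefficients and standard errors
  finite when one condition has all-zero counts, without pseudocounts.
  Convergence is a relative deviance change below 10⁻¹⁰; non-converged
  peptides get `p = NA` and are excluded from the FDR adjustment. No fold
  change shrinkage is applied, and no independent filtering beyond the
  minimum-4-reads rule.
- **Classification**: BH-adjusted p_FDR < 0.05 and the sign of log₂FC give
  cleaved / depleted / neutral.

Against DESeq2 on shared dispersions, the Wald statistics agree to ~10⁻⁵
(see the test suite); dispersion estimation is deliberately simpler than
DESeq2's empirical-Bayes machinery, so exact numerical equality with a
DESeq2 analysis is not promised and not needed for the calibration
properties the tests check (null uniformity, FDR control, planted-effect
recovery).

## Motif construction

- **Anchored alignment**: with multiple anchor residues, the center-most
  occurrence wins, formalized as minimizing |position − 3.5| with ties to
  the lower position — which makes an anchor at 3 beat one at 4 and
  extends the rule deterministically to every pattern. `single_only` mode
  restricts to single-anchor peptides instead. Frame labels follow
  Schechter–Berger (anchor = P1, N-terminal P2, P3, ... and C-terminal
  P1', P2', ...), and frequencies for aligned pools use per-frame
  denominators because different anchors populate different frames.
- **Differential logo**: per cell, the frequency difference and a pooled
  two-proportion z statistic; calls use the two-sided normal quantile at
  α = 0.05. Cells observed fewer than `min_support = 5` times in both
  pools are "unpopulated" — a concrete threshold standing in for the
  qualitative notion of a residue that does not appreciably populate
  either pool.
- **P-value-binned profiles**: significant peptides are split into
  enriched and depleted arms (the two significance regimes of a
  rank-ordered screen), binned on the log₁₀ p_FDR scale in one-decade
  bins, and adjacent bins merged from the significant end until each holds
  more than `min_bin = 10` peptides; each bin reports mean per-peptide
  residue frequencies.

## Feature ranking

Presence indicators (20 global, 120 positional; constant columns dropped)
feed a forward-stepwise logistic regression that greedily maximizes
in-sample AUROC (rank-based, ties at half credit). In-sample evaluation
matches how a single screen-level AUROC is usually quoted; a
cross-validated variant was considered and left out to keep the reported
number's meaning unambiguous. The stopping rule — improvement below 0.001
AUROC or 20 features — is a pragmatic default; presence features on small
pools often separate perfectly, so fits falling into separation are
refit with a ridge penalty (λ = 10⁻⁴) and flagged. Negatives are drawn
uniformly from the neutral pool, size-matched to the positives.

## Problem sizes and determinism

The bundled analyses and tests run at desk scale: 10⁴-clone libraries,
2 replicates × 2 conditions × 2.5 × 10⁵ read pairs, 10⁴-peptide null
calibrations, and a 10⁶-pair error-suppression simulation — sizes at which
every statistical property under test (error rates, FDR, recovery) has
comfortable Monte-Carlo resolution. All randomness flows through explicit
integer seeds; rerunning any driver or the acceptance script with the same
seed reproduces byte-identical tables. Library depth in coverage
arithmetic is taken as 2.3 × 10⁸ (the value the 3.5× coverage claim
derives from); the simulator takes depth as a parameter and does not
arbitrate between the two depths quoted for the real library. The
VWF73 P3–P3' reference interval is taken as LVYMVT.

## Known limitations

- The pipeline does not locate the scissile bond within a peptide; the P1
  assignment is an alignment convention, supported for Arg-anchored serine
  protease data but a hypothesis elsewhere.
- Dispersion shrinkage is moment-based with a fixed weight, adequate for
  2 + 2 designs at the simulated depths but less efficient than full
  empirical-Bayes estimation for very shallow counts.
- The stepwise AUROC is in-sample and will be optimistic for small pools;
  the trajectory output lets users apply any share-of-predictive-capacity
  definition they prefer, and none is enforced.
- Hierarchical clustering of cleaved peptides is not implemented; the
  feature-ranking stage covers the predictive analysis.
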