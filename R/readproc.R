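#' Amplicon extraction template
#'
#' Describes the amplicon layout used both by the simulator and by read
#' extraction: a forward flank carrying three 8-bp orientation seeds at fixed
#' offsets, the variable region, and a reverse flank. Seeds are taken as
#' substrings of the forward flank at the stated offsets, so they are always
#' consistent with it. The variable region sits at 0-based
#' `[var_start, var_start + var_len)` within the oriented sense read.
#'
#' @param forward_flank Nucleotide text 5' of the variable region.
#' @param reverse_flank Nucleotide text 3' of the variable region.
#' @param seed_offsets Three 0-based offsets of the 8-bp seeds within the
#'   forward flank.
#' @param seed_length Seed length in bases (8).
#' @param var_len Variable region length; must be divisible by 3.
#' @return An `extraction_template` list with derived fields `seeds` and
#'   `var_start`.
#' @export
extraction_template <- function(forward_flank, reverse_flank,
                                seed_offsets = c(0L, 8L, 16L),
                                seed_length = 8L, var_len = 18L) {
  stopifnot(var_len %% 3L == 0L, length(seed_offsets) == 3L)
  if (grepl("[^ACGT]", paste0(forward_flank, reverse_flank))) {
    stop("flanks must contain only A/C/G/T")
  }
  if (max(seed_offsets) + seed_length > nchar(forward_flank)) {
    stop("seeds must lie within the forward flank")
  }
  seeds <- substr(rep(forward_flank, 3L), seed_offsets + 1L,
                  seed_offsets + seed_length)
  structure(list(forward_flank = forward_flank, reverse_flank = reverse_flank,
                 seeds = seeds, seed_offsets = as.integer(seed_offsets),
                 seed_length = as.integer(seed_length),
                 var_start = nchar(forward_flank), var_len = as.integer(var_len)),
            class = "extraction_template")
}

#' Default amplicon layout used by the simulator
#' @export
default_template <- function() {
  extraction_template(
    forward_flank = "GCTAGTTGCCAGTCAAGGCTTGACACCGTC",
    reverse_flank = "GGTGGAGGATCCGGAG")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## TRUE where any seed matches mate sequences exactly at its offset
.has_seed <- function(seqs, tmpl) {
  hit <- rep(FALSE, length(seqs))
  for (s in seq_len(3L)) {
    off <- tmpl$seed_offsets[s]
    hit <- hit | substr(seqs, off + 1L, off + tmpl$seed_length) == tmpl$seeds[s]
  }
  hit
}

## quality chars below Phred 5 (Phred+33: ASCII 33..37)
.has_low_q <- function(qual_sub) grepl("[\x21-\x25]", qual_sub)

#' Orient read pairs by the three forward-flank seeds
#'
#' A pair is oriented by an exact match of any of the template's three 8-bp
#' seeds at its stated offset: first on mate 1 (mate 1 is the sense read),
#' then on mate 2 (mates are swapped). Having three seeds tolerates
#' sequencing errors knocking out any one or two of them. No match on
#' either mate rejects the pair.
#'
#' @param seq1,seq2 Character vectors of mate sequences.
#' @param tmpl An [extraction_template()].
#' @return Character vector per pair: `"mate1"`, `"mate2"`, or `NA`
#'   (rejection, reason `no_seed`).
#' @export
orient_read_pairs <- function(seq1, seq2, tmpl) {
  sense1 <- .has_seed(seq1, tmpl)
  sense2 <- !sense1 & .has_seed(seq2, tmpl)
  ifelse(sense1, "mate1", ifelse(sense2, "mate2", NA_character_))
}

#' Process paired-end reads through the three quality filters
#'
#' Implements, in order: (1) orientation — either mate must carry one of the
#' three 8-bp seeds exactly at its offset (multiple seeds tolerate sequencing
#' errors hitting any one of them); (2) a perfect nucleotide match between
#' the sense and reverse-complemented antisense reads across the variable
#' region; (3) Phred >= 5 at every variable-region position of both mates.
#' Passing reads are translated; stop-containing reads are flagged.
#'
#' @param seq1,qual1,seq2,qual2 Character vectors: mate sequences and Phred+33
#'   quality strings.
#' @param tmpl An [extraction_template()].
#' @return Data frame with one row per pair: `status` (one of `pass`,
#'   `no_seed`, `incomplete`, `mate_mismatch`, `low_quality`), `region`,
#'   `peptide`, `has_stop`, `stop_codon` (NA unless passed).
#' @export
process_read_pairs <- function(seq1, qual1, seq2, qual2, tmpl) {
  n <- length(seq1)
  stopifnot(length(seq2) == n, length(qual1) == n, length(qual2) == n)
  status <- rep("pass", n)
  region <- rep(NA_character_, n)

  orient <- orient_read_pairs(seq1, seq2, tmpl)
  sense_is_1 <- !is.na(orient) & orient == "mate1"
  status[is.na(orient)] <- "no_seed"

  sense_seq <- ifelse(sense_is_1, seq1, seq2)
  sense_qual <- ifelse(sense_is_1, qual1, qual2)
  anti_seq <- ifelse(sense_is_1, seq2, seq1)
  anti_qual <- ifelse(sense_is_1, qual2, qual1)

  vs <- tmpl$var_start; vl <- tmpl$var_len
  L_amp <- vs + vl + nchar(tmpl$reverse_flank)
  La <- nchar(anti_seq)
  ## revcomp(antisense read) covers amplicon [L_amp - La + 1, L_amp];
  ## the variable region sits at offset vs - (L_amp - La) within it
  rc_start <- vs - (L_amp - La) + 1L
  ok <- status == "pass"
  incomplete <- ok & (nchar(sense_seq) < vs + vl | rc_start < 1L | La < vl)
  status[incomplete] <- "incomplete"
  ok <- status == "pass"

  sense_var <- substr(sense_seq, vs + 1L, vs + vl)
  anti_rc <- character(n)
  anti_rc[ok] <- .revcomp(anti_seq[ok])
  anti_var <- substr(anti_rc, rc_start, rc_start + vl - 1L)
  status[ok & sense_var != anti_var] <- "mate_mismatch"
  ok <- status == "pass"

  ## antisense-read coordinates of the variable region (read is the
  ## reverse complement, so indices flip end-for-end)
  a_from <- La - (rc_start + vl - 1L) + 1L
  a_to <- La - rc_start + 1L
  lowq <- ok & (.has_low_q(substr(sense_qual, vs + 1L, vs + vl)) |
                  .has_low_q(substr(anti_qual, a_from, a_to)))
  status[lowq] <- "low_quality"
  ok <- status == "pass"

  region[ok] <- sense_var[ok]
  out <- data.frame(status = status, region = region,
                    peptide = NA_character_, has_stop = NA,
                    stop_codon = NA_character_, stringsAsFactors = FALSE)
  if (any(ok)) {
    tr <- translate_nnk(region[ok])
    out$peptide[ok] <- tr$peptide
    out$has_stop[ok] <- tr$has_stop
    out$stop_codon[ok] <- tr$stop_codon
  }
  out
}

#' Tally peptides across samples into a count table with QC report
#'
#' Runs [process_read_pairs()] on each sample's FASTQ pair and counts
#' stop-free peptides per sample. Stop-containing reads are tallied in the QC
#' report (with their stop codon identity) but excluded from the count table.
#'
#' @param manifest Data frame with columns `name`, `role`
#'   (`"unselected"`/`"selected"`), `replicate`, `r1`, `r2`.
#' @param tmpl An [extraction_template()].
#' @return A `peptide_counts` list: `counts` (peptide x sample integer
#'   matrix), `sample_info`, and `qc` (per-sample totals, pass fraction,
#'   rejection tallies, stop counts and TAG/TAA/TGA breakdown).
#' @export
tally_peptides <- function(manifest, tmpl) {
  stopifnot(all(c("name", "role", "replicate", "r1", "r2") %in% names(manifest)))
  per_sample <- vector("list", nrow(manifest))
  qc <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f1 <- read_fastq(manifest$r1[i]); f2 <- read_fastq(manifest$r2[i])
    res <- process_read_pairs(f1$seq, f1$qual, f2$seq, f2$qual, tmpl)
    qc[[i]] <- qc_report(res, manifest$name[i])
    keep <- res$status == "pass" & !res$has_stop
    tab <- table(res$peptide[keep])
    if (length(tab) == 0L) warning("sample ", manifest$name[i], ": zero passed reads")
    per_sample[[i]] <- tab
  }
  peptides <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0L, nrow = length(peptides), ncol = nrow(manifest),
                   dimnames = list(peptides, manifest$name))
  for (i in seq_len(nrow(manifest))) {
    tab <- per_sample[[i]]
    counts[names(tab), i] <- as.integer(tab)
  }
  structure(list(counts = counts,
                 sample_info = manifest[, c("name", "role", "replicate")],
                 qc = do.call(rbind, qc)),
            class = "peptide_counts")
}

#' Summarize filter outcomes for one sample
#' @param res Result of [process_read_pairs()].
#' @param name Sample name.
#' @return One-row data frame of QC tallies.
#' @export
qc_report <- function(res, name = "sample") {
  n <- nrow(res)
  passed <- sum(res$status == "pass")
  stops <- sum(res$has_stop, na.rm = TRUE)
  brk <- table(factor(res$stop_codon, levels = c("TAG", "TAA", "TGA")))
  data.frame(name = name, total_pairs = n,
             passed = passed,
             passed_fraction = if (n > 0) passed / n else NA_real_,
             no_seed = sum(res$status == "no_seed"),
             incomplete = sum(res$status == "incomplete"),
             mate_mismatch = sum(res$status == "mate_mismatch"),
             low_quality = sum(res$status == "low_quality"),
             stop_reads = stops,
             stop_fraction = if (passed > 0) stops / passed else NA_real_,
             stop_TAG = as.integer(brk["TAG"]), stop_TAA = as.integer(brk["TAA"]),
             stop_TGA = as.integer(brk["TGA"]),
             stringsAsFactors = FALSE)
}
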