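# hand-built pairs around the default template for targeted filter checks
tmpl <- default_template()
fwd <- tmpl$forward_flank
rev_fl <- tmpl$reverse_flank
mk_pair <- function(insert, q1 = NULL, q2 = NULL, mutate_sense = NULL,
                    mutate_seed = 0L) {
  amp <- paste0(fwd, insert, rev_fl)
  L <- 50L
  s1 <- substr(amp, 1, L)
  s2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(amp, nchar(amp) - L + 1, nchar(amp)))))
  if (!is.null(mutate_sense)) {
    at <- tmpl$var_start + mutate_sense
    substr(s1, at, at) <- setdiff(c("A", "C", "G", "T"), substr(s1, at, at))[1]
  }
  if (mutate_seed > 0L) {
    for (k in seq_len(mutate_seed)) {
      at <- tmpl$seed_offsets[k] + 1L
      substr(s1, at, at) <- setdiff(c("A", "C", "G", "T"), substr(s1, at, at))[1]
    }
  }
  list(s1 = s1, s2 = s2,
       q1 = if (is.null(q1)) strrep("I", L) else q1,
       q2 = if (is.null(q2)) strrep("I", L) else q2)
}
insert <- "TTGGTGTATATGGTTACG"  # LVYMVT

test_that("orientation accepts any one intact seed and swaps mates", {
  p <- mk_pair(insert)
  expect_identical(orient_read_pairs(p$s1, p$s2, tmpl), "mate1")
  # seeds knocked out one then two at a time: still oriented via the rest
  p1 <- mk_pair(insert, mutate_seed = 1L)
  p2 <- mk_pair(insert, mutate_seed = 2L)
  expect_identical(orient_read_pairs(p1$s1, p1$s2, tmpl), "mate1")
  expect_identical(orient_read_pairs(p2$s1, p2$s2, tmpl), "mate1")
  # swapped mates orient on mate2
  expect_identical(orient_read_pairs(p$s2, p$s1, tmpl), "mate2")
  res <- process_read_pairs(p$s2, p$q2, p$s1, p$q1, tmpl)
  expect_identical(res$status, "pass")
  expect_identical(res$region, insert)
  # all three seeds gone on both mates: no_seed
  p3 <- mk_pair(insert, mutate_seed = 3L)
  res3 <- process_read_pairs(p3$s1, p3$q1, p3$s2, p3$q2, tmpl)
  expect_identical(res3$status, "no_seed")
})

test_that("a single variable-region substitution in either mate rejects the pair", {
  p <- mk_pair(insert, mutate_sense = 7L)
  res <- process_read_pairs(p$s1, p$q1, p$s2, p$q2, tmpl)
  expect_identical(res$status, "mate_mismatch")
  # perfect agreement passes and translates
  good <- mk_pair(insert)
  res2 <- process_read_pairs(good$s1, good$q1, good$s2, good$q2, tmpl)
  expect_identical(res2$status, "pass")
  expect_identical(res2$peptide, "LVYMVT")
})

test_that("Phred < 5 anywhere in either mate's variable region rejects the pair", {
  L <- 50L
  # Q4 ('%') at the first variable base of the sense read
  q_bad <- paste0(strrep("I", tmpl$var_start), "%", strrep("I", L - tmpl$var_start - 1))
  p <- mk_pair(insert, q1 = q_bad)
  expect_identical(process_read_pairs(p$s1, p$q1, p$s2, p$q2, tmpl)$status,
                   "low_quality")
  # Q5 ('&') passes: boundary is inclusive
  q_edge <- paste0(strrep("I", tmpl$var_start), "&", strrep("I", L - tmpl$var_start - 1))
  p2 <- mk_pair(insert, q1 = q_edge)
  expect_identical(process_read_pairs(p2$s1, p2$q1, p2$s2, p2$q2, tmpl)$status, "pass")
  # low quality within the antisense mate's variable region also rejects;
  # the variable region sits at positions 3..20 of the 50-nt reverse read
  amp_len <- tmpl$var_start + tmpl$var_len + nchar(rev_fl)
  rc_start <- tmpl$var_start - (amp_len - L) + 1L
  a_pos <- L - (rc_start + tmpl$var_len - 1L) + 1L
  q2_bad <- paste0(strrep("I", a_pos - 1), "!", strrep("I", L - a_pos))
  p3 <- mk_pair(insert, q2 = q2_bad)
  expect_identical(process_read_pairs(p3$s1, p3$q1, p3$s2, p3$q2, tmpl)$status,
                   "low_quality")
  # but low quality in the antisense flank region is ignored
  q2_ok <- paste0("!", strrep("I", L - 1))
  p4 <- mk_pair(insert, q2 = q2_ok)
  expect_identical(process_read_pairs(p4$s1, p4$q1, p4$s2, p4$q2, tmpl)$status, "pass")
})

test_that("filters agree with an independent per-pair re-scan on a noisy run", {
  scr <- small_screen()
  f1 <- read_fastq(scr$manifest$r1[1]); f2 <- read_fastq(scr$manifest$r2[1])
  idx <- seq_len(2000)
  res <- process_read_pairs(f1$seq[idx], f1$qual[idx], f2$seq[idx], f2$qual[idx], tmpl)
  oracle <- oracle_rescan(f1$seq[idx], f1$qual[idx], f2$seq[idx], f2$qual[idx], tmpl)
  expect_identical(res$status, unname(oracle))
})

test_that("tally conserves reads and excludes stop peptides from the table", {
  scr <- small_screen()
  pc <- tally_peptides(scr$manifest, tmpl)
  qc <- pc$qc
  # rejection reasons + passed = total pairs
  expect_equal(qc$no_seed + qc$incomplete + qc$mate_mismatch + qc$low_quality +
                 qc$passed, qc$total_pairs)
  # column sums equal passed, stop-free reads
  expect_equal(unname(colSums(pc$counts)), qc$passed - qc$stop_reads)
  # every counted peptide is stop-free
  expect_false(any(grepl("\\*", rownames(pc$counts))))
  # ten identical perfect pairs of one clone -> one peptide, count 10
  p <- mk_pair(insert)
  tendir <- tempfile()
  dir.create(tendir)
  nnkscreen:::.write_fastq(paste0("r", 1:10), rep(p$s1, 10), rep(p$q1, 10),
                           file.path(tendir, "t_R1.fastq"))
  nnkscreen:::.write_fastq(paste0("r", 1:10), rep(p$s2, 10), rep(p$q2, 10),
                           file.path(tendir, "t_R2.fastq"))
  man <- data.frame(name = "t", role = "unselected", replicate = 1,
                    r1 = file.path(tendir, "t_R1.fastq"),
                    r2 = file.path(tendir, "t_R2.fastq"))
  pc1 <- tally_peptides(man, tmpl)
  expect_identical(rownames(pc1$counts), "LVYMVT")
  expect_identical(unname(pc1$counts[1, 1]), 10L)
})

test_that("stop reads are tallied in QC with their codon but kept out of the table", {
  stop_insert <- "TAGGTGTATATGGTTACG"
  ps <- mk_pair(stop_insert)
  pg <- mk_pair(insert)
  d <- tempfile(); dir.create(d)
  s1 <- c(rep(ps$s1, 3), rep(pg$s1, 7)); s2 <- c(rep(ps$s2, 3), rep(pg$s2, 7))
  nnkscreen:::.write_fastq(paste0("r", 1:10), s1, rep(ps$q1, 10),
                           file.path(d, "m_R1.fastq"))
  nnkscreen:::.write_fastq(paste0("r", 1:10), s2, rep(ps$q2, 10),
                           file.path(d, "m_R2.fastq"))
  man <- data.frame(name = "m", role = "selected", replicate = 1,
                    r1 = file.path(d, "m_R1.fastq"), r2 = file.path(d, "m_R2.fastq"))
  pc <- tally_peptides(man, tmpl)
  expect_identical(rownames(pc$counts), "LVYMVT")
  expect_identical(unname(pc$counts[1, 1]), 7L)
  expect_identical(pc$qc$stop_reads, 3L)
  expect_identical(pc$qc$stop_TAG, 3L)
  expect_equal(pc$qc$stop_fraction, 0.3)
})

test_that("stop-free error-free run has zero stop fraction", {
  lib <- build_library(nnk_library_config(100, seed = 55))
  lib <- lib[!lib$has_stop, ]
  lib$abundance <- lib$abundance / sum(lib$abundance)
  attr(lib, "config") <- nnk_library_config(100, seed = 55)
  class(lib) <- c("nnk_library", "data.frame")
  cfg <- sequencing_config(3000, per_base_error = 0, seed = 56)
  out <- simulate_read_pairs(lib$abundance, lib, cfg)
  f1 <- read_fastq(out$r1); f2 <- read_fastq(out$r2)
  res <- process_read_pairs(f1$seq, f1$qual, f2$seq, f2$qual, tmpl)
  expect_equal(sum(res$has_stop[res$status == "pass"]), 0L)
})
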