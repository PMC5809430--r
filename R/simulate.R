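#' Configuration for a simulated NNK phage display library
#'
#' @param n_clones Number of independent clones to draw.
#' @param abundance_log_sd Standard deviation of the log-normal clone abundance
#'   skew (0 gives a uniform library).
#' @param context_mode `"random_hexamer"` for a free hexapeptide library or
#'   `"fixed_context"` for a library embedded in a constant substrate context
#'   (VWF73-style); the mode is carried through to the ground-truth record.
#' @param template Amplicon layout ([extraction_template()]); supplies the
#'   nucleotide flanks placed around the 18-nt variable region.
#' @param seed Integer RNG seed.
#' @return An `nnk_library_config` list.
#' @export
nnk_library_config <- function(n_clones, abundance_log_sd = 1,
                               context_mode = c("random_hexamer", "fixed_context"),
                               template = default_template(), seed = 1L) {
  context_mode <- match.arg(context_mode)
  stopifnot(n_clones >= 0, abundance_log_sd >= 0)
  if (grepl("[^ACGT]", paste0(template$forward_flank, template$reverse_flank))) {
    stop("flanks must contain only A/C/G/T")
  }
  structure(list(n_clones = as.integer(n_clones),
                 abundance_log_sd = abundance_log_sd,
                 context_mode = context_mode,
                 template = template, seed = as.integer(seed)),
            class = "nnk_library_config")
}

#' Build a simulated NNK library
#'
#' Draws `n_clones` NNK 18-nt inserts, translates them, assigns log-normal
#' clone abundances, and zeroes the display abundance of stop-containing
#' clones (premature stops abolish phage assembly in pIII display, so such
#' clones are synthesized but never displayed). Stop clones are retained in
#' the record with their stop codon identity for QC tests.
#'
#' @param config An [nnk_library_config()].
#' @return An `nnk_library`: data frame with columns `insert`, `peptide`,
#'   `has_stop`, `stop_codon`, `abundance` (summing to 1 over stop-free
#'   clones), plus the config as an attribute.
#' @export
build_library <- function(config) {
  stopifnot(inherits(config, "nnk_library_config"))
  lib <- withr::with_seed(config$seed, {
    inserts <- generate_nnk_inserts(config$n_clones, n_codons = 6L)
    tr <- translate_nnk(inserts)
    w <- if (config$n_clones > 0)
      exp(stats::rnorm(config$n_clones, 0, config$abundance_log_sd)) else numeric(0)
    w[tr$has_stop] <- 0
    if (sum(w) > 0) w <- w / sum(w)
    data.frame(insert = inserts, peptide = tr$peptide, has_stop = tr$has_stop,
               stop_codon = tr$stop_codon, abundance = w,
               stringsAsFactors = FALSE)
  })
  attr(lib, "config") <- config
  class(lib) <- c("nnk_library", "data.frame")
  lib
}

#' Position-weight cleavage motif model
#'
#' Maps a hexapeptide to a cleavage probability through a logistic link:
#' `p = plogis(intercept + sum_k weights[k, aa_k])`. This is the planted
#' ground truth the pipeline is asked to recover; zero weights give the same
#' probability `plogis(intercept)` to every peptide.
#'
#' @param weights 6 x 20 numeric matrix, rows = peptide positions 1-6,
#'   columns named by [amino_acids()]. Missing columns are taken as 0.
#' @param intercept Baseline log-odds of cleavage.
#' @return A `cleavage_motif` object.
#' @export
cleavage_motif <- function(weights = matrix(0, 6, 20, dimnames = list(NULL, amino_acids())),
                           intercept = 0) {
  full <- matrix(0, 6, 20, dimnames = list(NULL, amino_acids()))
  if (!is.null(weights)) {
    if (is.null(colnames(weights))) stop("weights columns must be named by amino acid")
    full[, colnames(weights)] <- weights
  }
  structure(list(weights = full, intercept = intercept), class = "cleavage_motif")
}

#' A simple planted motif: Arg strongly favored at one peptide position
#'
#' Emulates a P1-Arg protease (thrombin-like) read out through center-most
#' Arg alignment: peptides carrying Arg at `position` are cleaved with high
#' probability, everything else at the low baseline.
#'
#' @param position Peptide position carrying the Arg requirement (default 3,
#'   the position the center-most alignment maps to P1).
#' @param strength Log-odds added when Arg occupies `position`.
#' @param intercept Baseline log-odds.
#' @export
p1_arg_motif <- function(position = 3L, strength = 6, intercept = -4) {
  w <- matrix(0, 6, 1, dimnames = list(NULL, "R"))
  w[position, "R"] <- strength
  cleavage_motif(w, intercept = intercept)
}

#' Cleavage probability of hexapeptides under a motif model
#'
#' @param motif A [cleavage_motif()].
#' @param peptides Character vector of 6-residue peptides (no stops).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
cleavage_probability <- function(motif, peptides) {
  stopifnot(inherits(motif, "cleavage_motif"))
  if (length(peptides) == 0L) return(numeric(0))
  score <- rep(motif$intercept, length(peptides))
  for (k in 1:6) {
    aa <- substr(peptides, k, k)
    score <- score + motif$weights[k, ][aa]
  }
  unname(stats::plogis(score))
}

#' Apply one saturating round of protease selection
#'
#' Models overnight digestion proceeding to completion: cleaved phage are
#' released into the supernatant, so the selected abundance of clone i is
#' proportional to its input abundance times its cleavage probability. A
#' constant-probability motif therefore leaves normalized abundances
#' unchanged. Stop-containing (undisplayed) clones stay at 0.
#'
#' @param library An [build_library()] result.
#' @param motif A [cleavage_motif()].
#' @return Numeric vector of selected abundances summing to 1, aligned to the
#'   library rows.
#' @export
apply_selection <- function(library, motif) {
  stopifnot(inherits(library, "nnk_library"), nrow(library) > 0)
  p <- numeric(nrow(library))
  disp <- !library$has_stop
  p[disp] <- cleavage_probability(motif, library$peptide[disp])
  sel <- library$abundance * p
  if (sum(sel) <= 0) stop("empty selection: all cleavage probabilities are zero")
  sel / sum(sel)
}

#' Sequencing run configuration
#'
#' @param n_read_pairs Number of read pairs to emit.
#' @param read_length Bases per mate (paired-end 50 bp by default).
#' @param per_base_error Substitution probability per base. The default,
#'   0.01/18, corresponds to a 1% error rate per sequence over the 18-nt
#'   variable region.
#' @param quality_model `"independent"` draws Phred scores independently of
#'   error status; `"error_low_q"` additionally emits Phred < 5 at error
#'   sites, to exercise the quality filter.
#' @param seed Integer RNG seed.
#' @export
sequencing_config <- function(n_read_pairs, read_length = 50L,
                              per_base_error = 0.01 / 18,
                              quality_model = c("independent", "error_low_q"),
                              seed = 1L) {
  quality_model <- match.arg(quality_model)
  stopifnot(n_read_pairs >= 0, per_base_error >= 0, per_base_error <= 1)
  structure(list(n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 per_base_error = per_base_error,
                 quality_model = quality_model, seed = as.integer(seed)),
            class = "sequencing_config")
}

## Phred score distribution of a well-behaved short-read run: concentrated
## near Q40 with a thin low-quality tail (per-base P(Q < 5) = 5e-4).
.phred_levels <- c(40L, 38L, 35L, 30L, 25L, 15L, 8L, 3L)
.phred_probs  <- c(0.55, 0.25, 0.10, 0.06, 0.02, 0.015, 0.0045, 0.0005)

## inject k substitutions at sampled flat positions into length-L reads
.inject_subs <- function(reads, L, pos_flat, rng_bases) {
  read_i <- ((pos_flat - 1L) %/% L) + 1L
  base_i <- ((pos_flat - 1L) %% L) + 1L
  for (e in seq_along(pos_flat)) {
    i <- read_i[e]; j <- base_i[e]
    orig <- substr(reads[i], j, j)
    alt <- setdiff(c("A", "C", "G", "T"), orig)
    substr(reads[i], j, j) <- alt[rng_bases[e]]
  }
  reads
}

## one long quality string chopped into per-read strings
.chop <- function(big, n, L) substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)

#' Simulate paired-end reads over an NNK amplicon and write FASTQ
#'
#' Draws clones multinomially from `abundances`, lays each insert into the
#' amplicon `forward_flank + insert + reverse_flank`, and emits a forward
#' (sense-strand) read from the 5' end and a reverse (antisense,
#' reverse-complemented) read from the 3' end, both spanning the full
#' variable region. Substitution errors are injected independently per mate
#' at `per_base_error`; qualities are Phred+33.
#'
#' @param abundances Normalized abundance vector aligned to `library` rows.
#' @param library An `nnk_library`.
#' @param cfg A [sequencing_config()].
#' @param r1,r2 Output FASTQ paths (`.gz` suffix compresses).
#' @return Invisibly, a list with the per-clone true read counts and paths.
#' @export
simulate_read_pairs <- function(abundances, library, cfg,
                                r1 = tempfile(fileext = "_R1.fastq"),
                                r2 = tempfile(fileext = "_R2.fastq")) {
  stopifnot(inherits(library, "nnk_library"), inherits(cfg, "sequencing_config"))
  stopifnot(length(abundances) == nrow(library),
            abs(sum(abundances) - 1) < 1e-6)
  tmpl <- attr(library, "config")$template
  fwd <- tmpl$forward_flank; rev <- tmpl$reverse_flank
  amplicon <- paste0(fwd, library$insert, rev)
  L_amp <- nchar(fwd) + 18L + nchar(rev)
  L <- cfg$read_length
  if (L < nchar(fwd) + 18L || L < nchar(rev) + 18L || L > L_amp) {
    stop("read_length does not span flank + variable region")
  }
  withr::with_seed(cfg$seed, {
    n <- cfg$n_read_pairs
    idx <- sample.int(nrow(library), n, replace = TRUE, prob = abundances)
    f_tpl <- substr(amplicon, 1L, L)
    r_tpl <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substr(amplicon, L_amp - L + 1L, L_amp))))
    reads1 <- f_tpl[idx]
    reads2 <- r_tpl[idx]
    for (mate in 1:2) {
      k <- stats::rbinom(1L, n * L, cfg$per_base_error)
      pos <- if (k > 0) sample.int(n * L, k) else integer(0)
      which_alt <- if (k > 0) sample.int(3L, k, replace = TRUE) else integer(0)
      if (mate == 1L) reads1 <- .inject_subs(reads1, L, pos, which_alt)
      else            reads2 <- .inject_subs(reads2, L, pos, which_alt)
      q <- sample(.phred_levels, n * L, replace = TRUE, prob = .phred_probs)
      if (cfg$quality_model == "error_low_q" && k > 0) q[pos] <- sample(0:4, k, replace = TRUE)
      qual <- .chop(rawToChar(as.raw(33L + q)), n, L)
      if (mate == 1L) qual1 <- qual else qual2 <- qual
    }
    ids <- sprintf("pair%07d", seq_len(n))
    .write_fastq(ids, reads1, qual1, r1)
    .write_fastq(ids, reads2, qual2, r2)
    counts <- tabulate(idx, nbins = nrow(library))
    invisible(list(r1 = r1, r2 = r2, clone_counts = counts))
  })
}

.write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into sequences and quality strings
#' @param path FASTQ path (optionally gzipped).
#' @return List with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ## QualityScaledDNAStringSet accessors warn about dropped metadata cols
  suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
    list(id = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
  })
}

#' Write simulation ground truth as TSV
#'
#' Clone table (insert, peptide, stop flag, abundances, cleavage
#' probability) and motif weights, for use as test oracles.
#'
#' @param library An `nnk_library`.
#' @param motif A [cleavage_motif()].
#' @param selected Selected abundance vector from [apply_selection()].
#' @param dir Output directory.
#' @export
write_ground_truth <- function(library, motif, selected, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- numeric(nrow(library))
  p[!library$has_stop] <- cleavage_probability(motif, library$peptide[!library$has_stop])
  clone <- cbind(as.data.frame(library), cleavage_prob = p, selected_abundance = selected)
  utils::write.table(clone, file.path(dir, "clones.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  w <- data.frame(position = rep(1:6, times = 20),
                  aa = rep(amino_acids(), each = 6),
                  weight = as.vector(motif$weights))
  w <- rbind(w, data.frame(position = NA, aa = "(intercept)", weight = motif$intercept))
  utils::write.table(w, file.path(dir, "motif.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
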