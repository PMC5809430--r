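#' Simulate a complete selection screen (library, selection, FASTQ)
#'
#' Builds an NNK library, applies one saturating round of selection under
#' `motif`, and writes paired-end FASTQ for `n_replicates` unselected and
#' `n_replicates` selected samples (independent sequencing draws from the
#' same pools, emulating replicate runs). Per-sample seeds are derived from
#' `seed` by small offsets, so the whole screen is reproducible.
#'
#' @param n_clones Clones in the library.
#' @param motif A [cleavage_motif()].
#' @param n_read_pairs Read pairs per sample.
#' @param n_replicates Replicates per condition (default 2, as in a
#'   two-run-per-condition screen).
#' @param seed Integer master seed.
#' @param dir Output directory for FASTQ and ground truth.
#' @param abundance_log_sd Clone abundance skew.
#' @param per_base_error Substitution rate per base (see
#'   [sequencing_config()]).
#' @param quality_model Passed to [sequencing_config()].
#' @param template Amplicon layout.
#' @return List: `manifest` (for [tally_peptides()]), `library`, `selected`
#'   abundances, `motif`, `template`.
#' @export
simulate_screen <- function(n_clones, motif, n_read_pairs,
                            n_replicates = 2L, seed = 1L,
                            dir = tempfile("screen"),
                            abundance_log_sd = 1,
                            per_base_error = 0.01 / 18,
                            quality_model = "independent",
                            template = default_template()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- nnk_library_config(n_clones, abundance_log_sd = abundance_log_sd,
                            template = template, seed = seed)
  lib <- build_library(cfg)
  sel <- apply_selection(lib, motif)
  roles <- rep(c("unselected", "selected"), each = n_replicates)
  reps <- rep(seq_len(n_replicates), times = 2L)
  manifest <- data.frame(name = paste0(roles, reps), role = roles,
                         replicate = reps, r1 = NA_character_,
                         r2 = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    ab <- if (roles[i] == "unselected") lib$abundance else sel
    sc <- sequencing_config(n_read_pairs, per_base_error = per_base_error,
                            quality_model = quality_model, seed = seed + 100L + i)
    out <- simulate_read_pairs(ab, lib, sc,
                               r1 = file.path(dir, paste0(manifest$name[i], "_R1.fastq")),
                               r2 = file.path(dir, paste0(manifest$name[i], "_R2.fastq")))
    manifest$r1[i] <- out$r1; manifest$r2[i] <- out$r2
  }
  write_ground_truth(lib, motif, sel, file.path(dir, "truth"))
  list(manifest = manifest, library = lib, selected = sel, motif = motif,
       template = template, dir = dir)
}

#' Rank-order listing of cleaved peptides
#'
#' Cleaved peptides sorted by ascending p_fdr, ties broken by descending
#' |log2fc|, then lexicographically. Optionally reports the rank of a query
#' peptide (`NA` if the query is not cleaved).
#'
#' @param records Classified enrichment records.
#' @param query Optional peptide to look up.
#' @return Data frame `rank`, `peptide`, `log2fc`, `p_fdr`; if `query` is
#'   given, its rank is attached as attribute `query_rank`.
#' @export
rank_order_report <- function(records, query = NULL) {
  cl <- records[records$label == "cleaved", , drop = FALSE]
  ord <- order(cl$p_fdr, -abs(cl$log2fc), cl$peptide)
  out <- data.frame(rank = seq_len(nrow(cl)), peptide = cl$peptide[ord],
                    log2fc = cl$log2fc[ord], p_fdr = cl$p_fdr[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(query)) {
    hit <- match(query, out$peptide)
    attr(out, "query_rank") <- if (is.na(hit)) NA_integer_ else out$rank[hit]
  }
  out
}

#' Run the full analysis: extract, enrich, motif, classify
#'
#' Executes the downstream pipeline on a sample manifest: peptide tallying
#' with QC, negative-binomial enrichment testing with BH FDR, motif
#' construction (residue proportions, anchored differential logo, p-value-
#' binned profiles), and forward-stepwise AUROC classification of cleaved
#' vs sampled neutral peptides. All stage outputs are written as TSV under
#' `outdir` and returned as a bundle. Deterministic given `seed`.
#'
#' @param manifest Data frame with `name`, `role`, `replicate`, `r1`, `r2`.
#' @param template An [extraction_template()].
#' @param outdir Output directory for TSVs (default: no files written).
#' @param min_total,alpha,min_bin,tol The stage thresholds (defaults 4,
#'   0.05, 10, 0.001).
#' @param anchor Anchor residue for motif alignment (default "R").
#' @param anchor_mode Alignment mode (default "center_most").
#' @param classify_mode Feature mode for the stepwise stage.
#' @param seed Seed for the neutral-negative draw.
#' @return List: `counts` (peptide_counts), `records`, `qc`,
#'   `aa_proportions`, `logo`, `binned`, `stepwise`, `rank_report`.
#' @export
run_all <- function(manifest, template = default_template(), outdir = NULL,
                    min_total = 4L, alpha = 0.05, min_bin = 10L, tol = 0.001,
                    anchor = "R", anchor_mode = "center_most",
                    classify_mode = "global", seed = 1L) {
  pc <- tally_peptides(manifest, template)
  records <- run_enrichment(pc, min_total = min_total, alpha = alpha)

  aa_prop <- aa_proportion_comparison(records)
  cleaved <- records$peptide[records$label == "cleaved"]
  depleted <- records$peptide[records$label == "depleted"]
  logo <- NULL
  if (length(cleaved) > 0L && length(depleted) > 0L) {
    al_c <- align_on_anchor(cleaved, anchor, anchor_mode)
    al_d <- align_on_anchor(depleted, anchor, anchor_mode)
    if (nrow(al_c) > 0L && nrow(al_d) > 0L) {
      logo <- differential_logo(position_frequencies(al_c),
                                position_frequencies(al_d))
    }
  }
  binned <- pvalue_binned_profiles(records, min_bin = min_bin, alpha = alpha)

  stepwise <- NULL
  n_neut <- sum(records$label == "neutral")
  if (length(cleaved) >= 2L && n_neut >= length(cleaved)) {
    neg <- sample_negatives(records, seed = seed)
    peps <- c(cleaved, neg)
    y <- rep(c(1, 0), c(length(cleaved), length(neg)))
    X <- build_features(peps, classify_mode)
    stepwise <- forward_stepwise(X, y, tol = tol)
  }
  rank_rep <- rank_order_report(records)

  bundle <- list(counts = pc, records = records, qc = pc$qc,
                 aa_proportions = aa_prop, logo = logo, binned = binned,
                 stepwise = stepwise, rank_report = rank_rep)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write a [run_all()] bundle as TSV files
#' @param bundle List returned by [run_all()].
#' @param outdir Directory to create and write into.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    if (!is.null(x)) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  }
  cnt <- data.frame(peptide = rownames(bundle$counts$counts),
                    bundle$counts$counts, check.names = FALSE)
  wt(cnt, "counts.tsv")
  wt(bundle$qc, "qc.tsv")
  wt(bundle$records, "enrichment.tsv")
  wt(bundle$aa_proportions, "aa_proportions.tsv")
  wt(bundle$logo, "differential_logo.tsv")
  wt(bundle$binned, "pvalue_binned_profiles.tsv")
  if (!is.null(bundle$stepwise)) wt(bundle$stepwise$path, "stepwise_path.tsv")
  wt(bundle$rank_report, "rank_order.tsv")
  invisible(outdir)
}
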