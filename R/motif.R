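#' Anchor-align hexapeptides on a residue (P1 assignment)
#'
#' Aligns peptides by declaring an occurrence of `anchor_residue` to be P1
#' (Schechter-Berger): residue i of a peptide anchored at k maps to
#' P(k - i + 1) for i <= k and P(i - k)' for i > k. `single_only` keeps only
#' peptides with exactly one anchor occurrence; `center_most` picks, among
#' multiple occurrences, the one minimizing |position - 3.5| with ties
#' broken toward the lower position (so an Arg at 3 beats an Arg at 4).
#' Peptides without the anchor are skipped and tallied.
#'
#' @param peptides Character vector of 6-residue peptides.
#' @param anchor_residue Single residue to anchor on (default "R").
#' @param mode `"center_most"` or `"single_only"`.
#' @return An `aligned_peptides` data frame (`peptide`, `anchor`) with the
#'   number of skipped peptides as attribute `n_skipped`.
#' @export
align_on_anchor <- function(peptides, anchor_residue = "R",
                            mode = c("center_most", "single_only")) {
  mode <- match.arg(mode)
  stopifnot(all(nchar(peptides) == 6L), nchar(anchor_residue) == 1L)
  pos_mat <- vapply(1:6, function(k) substr(peptides, k, k) == anchor_residue,
                    logical(length(peptides)))
  pos_mat <- matrix(pos_mat, ncol = 6L)
  n_anchor <- rowSums(pos_mat)
  keep <- if (mode == "single_only") n_anchor == 1L else n_anchor >= 1L
  if (!any(keep)) warning("no peptide contains the anchor residue")
  anchor <- apply(pos_mat[keep, , drop = FALSE], 1L, function(hit) {
    pos <- which(hit)
    pos[order(abs(pos - 3.5), pos)][1L]
  })
  out <- data.frame(peptide = peptides[keep], anchor = as.integer(anchor),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  class(out) <- c("aligned_peptides", "data.frame")
  out
}

#' Schechter-Berger frame labels for an anchored hexapeptide
#' @param anchor Anchor (P1) position, 1-6.
#' @return Character vector of 6 labels, e.g. `P3 P2 P1 P1' P2' P3'` for
#'   anchor 3.
#' @export
frame_labels <- function(anchor) {
  i <- 1:6
  ifelse(i <= anchor, paste0("P", anchor - i + 1L), paste0("P", i - anchor, "'"))
}

## all frame labels in N-to-C order for hexapeptides (anchor 1..6)
.all_frames <- function() c(paste0("P", 6:1), paste0("P", 1:5, "'"))

#' Position-by-residue frequency matrix
#'
#' For a plain peptide pool, per-position amino-acid frequencies over
#' positions 1-6. For an [align_on_anchor()] result, frequencies are
#' computed per Schechter-Berger frame label with per-label denominators
#' (positions outside a peptide's frame contribute nothing).
#'
#' @param x Character vector of peptides, or an `aligned_peptides` object.
#' @return A `pfm` object: `freq` and `counts` (positions x 20 matrices),
#'   `n` (per-position denominators), `pool_size`.
#' @export
position_frequencies <- function(x) {
  if (inherits(x, "aligned_peptides")) {
    frames <- .all_frames()
    counts <- matrix(0L, length(frames), 20L,
                     dimnames = list(frames, amino_acids()))
    for (k in sort(unique(x$anchor))) {
      sub <- x$peptide[x$anchor == k]
      labs <- frame_labels(k)
      for (i in 1:6) {
        tab <- table(factor(substr(sub, i, i), levels = amino_acids()))
        counts[labs[i], ] <- counts[labs[i], ] + as.integer(tab)
      }
    }
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    pool <- nrow(x)
  } else {
    peptides <- as.character(x)
    if (length(peptides) == 0L) stop("empty peptide pool")
    stopifnot(all(nchar(peptides) == 6L))
    counts <- t(vapply(1:6, function(i) {
      as.integer(table(factor(substr(peptides, i, i), levels = amino_acids())))
    }, integer(20L)))
    dimnames(counts) <- list(as.character(1:6), amino_acids())
    pool <- length(peptides)
  }
  n <- rowSums(counts)
  structure(list(freq = counts / n, counts = counts, n = n, pool_size = pool),
            class = "pfm")
}

#' Differential logo between cleaved and uncleaved pools
#'
#' Per position/residue, the frequency difference d = f_cleaved -
#' f_uncleaved and the two-proportion z statistic
#' `z = d / sqrt(fbar (1 - fbar) (1/n1 + 1/n2))` with pooled `fbar`. Cells
#' are called `enriched`/`depleted` when |z| exceeds the two-sided normal
#' quantile at `z_alpha`, and `unpopulated` when the residue is observed
#' fewer than `min_support` times in both pools.
#'
#' @param cleaved_pfm,uncleaved_pfm [position_frequencies()] results on
#'   matching position sets.
#' @param min_support Minimum absolute count per pool (default 5).
#' @param z_alpha Two-sided significance level for calls (default 0.05).
#' @return Data frame with one row per shared position/residue: frequencies,
#'   difference, ratio, z, and `call` in
#'   {enriched, depleted, none, unpopulated}.
#' @export
differential_logo <- function(cleaved_pfm, uncleaved_pfm, min_support = 5L,
                              z_alpha = 0.05) {
  stopifnot(inherits(cleaved_pfm, "pfm"), inherits(uncleaved_pfm, "pfm"))
  if (cleaved_pfm$pool_size == 0L || uncleaved_pfm$pool_size == 0L) {
    stop("zero-size pool")
  }
  pos <- intersect(rownames(cleaved_pfm$freq), rownames(uncleaved_pfm$freq))
  zcrit <- stats::qnorm(1 - z_alpha / 2)
  out <- do.call(rbind, lapply(pos, function(pp) {
    n1 <- cleaved_pfm$n[pp]; n2 <- uncleaved_pfm$n[pp]
    c1 <- cleaved_pfm$counts[pp, ]; c2 <- uncleaved_pfm$counts[pp, ]
    f1 <- cleaved_pfm$freq[pp, ]; f2 <- uncleaved_pfm$freq[pp, ]
    d <- f1 - f2
    fbar <- (c1 + c2) / (n1 + n2)
    se <- sqrt(fbar * (1 - fbar) * (1 / n1 + 1 / n2))
    z <- ifelse(se > 0, d / se, 0)
    call <- rep("none", 20L)
    call[z > zcrit] <- "enriched"
    call[z < -zcrit] <- "depleted"
    call[c1 < min_support & c2 < min_support] <- "unpopulated"
    data.frame(position = pp, aa = amino_acids(), f_cleaved = unname(f1),
               f_uncleaved = unname(f2), diff = unname(d),
               ratio = unname(ifelse(f2 > 0, f1 / f2, NA_real_)),
               z = unname(z), call = call, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Residue frequency profiles across p-value bins
#'
#' Orders significant peptides from most enriched to most depleted on the
#' signed -log10 p_fdr scale, partitions each arm (enriched: log2fc > 0;
#' depleted: log2fc < 0) into bins one log10-decade wide, and merges
#' adjacent bins (from the significant end) until every bin holds more than
#' `min_bin` peptides. Per bin, the mean per-peptide residue frequency
#' (occurrences / 6) is reported.
#'
#' @param records Enrichment records with `p_fdr`, `log2fc`, `label`.
#' @param min_bin Minimum peptides per bin (default 10).
#' @param alpha Significance cut for inclusion (default 0.05).
#' @return Data frame: `arm`, `bin`, `n`, `p_min`, `p_max`, then one column
#'   per amino acid; rows ordered enriched (most significant first) then
#'   depleted (toward most significant last).
#' @export
pvalue_binned_profiles <- function(records, min_bin = 10L, alpha = 0.05) {
  sig <- records[!is.na(records$p_fdr) & records$p_fdr < alpha &
                   records$log2fc != 0, , drop = FALSE]
  one_arm <- function(sub) {
    if (nrow(sub) == 0L) return(NULL)
    lp <- log10(pmax(sub$p_fdr, .Machine$double.xmin))
    if (nrow(sub) <= min_bin || diff(range(lp)) == 0) {
      grp <- rep(1L, nrow(sub))
    } else {
      breaks <- seq(floor(min(lp)), ceiling(max(lp)))
      if (length(breaks) < 2L) breaks <- c(floor(min(lp)), ceiling(max(lp)) + 1L)
      grp <- findInterval(lp, breaks, rightmost.closed = TRUE)
      ## merge from the most significant (lowest p) end until all bins > min_bin
      grp <- match(grp, sort(unique(grp)))
      repeat {
        sizes <- tabulate(grp)
        small <- which(sizes <= min_bin)
        if (length(small) == 0L || max(grp) == 1L) break
        s <- small[1L]
        into <- if (s < max(grp)) s + 1L else s - 1L
        grp[grp == s] <- into
        grp <- match(grp, sort(unique(grp)))
      }
    }
    res <- lapply(sort(unique(grp)), function(g) {
      pep <- sub$peptide[grp == g]
      freq <- colMeans(t(vapply(pep, function(p) {
        tab <- table(factor(strsplit(p, "")[[1]], levels = amino_acids()))
        as.numeric(tab) / 6
      }, numeric(20L))))
      c(n = length(pep), p_min = min(sub$p_fdr[grp == g]),
        p_max = max(sub$p_fdr[grp == g]), freq)
    })
    df <- as.data.frame(do.call(rbind, res))
    names(df) <- c("n", "p_min", "p_max", amino_acids())
    df$bin <- sort(unique(grp))
    df
  }
  enr <- sig[sig$log2fc > 0, , drop = FALSE]
  dep <- sig[sig$log2fc < 0, , drop = FALSE]
  enr <- enr[order(enr$p_fdr), , drop = FALSE]
  dep <- dep[order(dep$p_fdr), , drop = FALSE]
  e <- one_arm(enr); d <- one_arm(dep)
  if (!is.null(e)) e <- cbind(arm = "enriched", e)
  if (!is.null(d)) { d <- cbind(arm = "depleted", d); d <- d[rev(seq_len(nrow(d))), ] }
  out <- rbind(e, d)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out[, c("arm", "bin", "n", "p_min", "p_max", amino_acids())]
}

#' Residue proportions in cleaved, depleted, and all peptides
#'
#' Relative proportion of each amino acid (occurrences over total residue
#' occurrences) within the cleaved pool, the depleted pool, and all
#' peptides, sorted by the cleaved-minus-depleted difference.
#'
#' @param records Enrichment records with `peptide` and `label`.
#' @return Data frame: `aa`, `cleaved`, `depleted`, `all`, `diff`, sorted by
#'   decreasing `diff`.
#' @export
aa_proportion_comparison <- function(records) {
  prop <- function(peptides) {
    if (length(peptides) == 0L) {
      warning("empty peptide pool; proportions undefined")
      return(rep(NA_real_, 20L))
    }
    res <- unlist(strsplit(peptides, ""))
    as.numeric(table(factor(res, levels = amino_acids()))) / length(res)
  }
  out <- data.frame(aa = amino_acids(),
                    cleaved = prop(records$peptide[records$label == "cleaved"]),
                    depleted = prop(records$peptide[records$label == "depleted"]),
                    all = prop(records$peptide), stringsAsFactors = FALSE)
  out$diff <- out$cleaved - out$depleted
  out[order(-out$diff), ]
}
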