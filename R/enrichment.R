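#' Minimum-total count filter
#'
#' Retains peptides with at least `min_total` reads summed across all
#' selected and unselected samples; the boundary is inclusive.
#'
#' @param counts Peptide x sample integer matrix.
#' @param min_total Minimum combined read count (default 4).
#' @export
filter_min_total <- function(counts, min_total = 4L) {
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per sample, the median across all-positive peptides of the ratio of its
#' count to the peptide's geometric mean across samples. Falls back to
#' total-count ratios (scaled to geometric mean 1) when no peptide is
#' positive in every sample.
#'
#' @param counts Peptide x sample matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    warning("no peptide with positive counts in every sample; ",
            "using total-count normalization")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts[use, , drop = FALSE], 2L,
        function(cnt) exp(stats::median(log(cnt) - log_geo[use])))
}

#' Method-of-moments dispersions with trend shrinkage
#'
#' Per peptide, alpha-hat = max(0, (s2 - mu) / mu^2) from within-condition
#' pooled moments of size-factor-normalized counts; a mean-dispersion trend
#' alpha(mu) = a/mu + b is fit across peptides and the final dispersion is
#' the weighted combination `weight * alpha_hat + (1 - weight) * trend`.
#' With a single replicate per condition the per-peptide moments are
#' unidentifiable and a blind estimate across all samples is used instead,
#' with a warning.
#'
#' @param counts Peptide x sample matrix.
#' @param size_factors From [estimate_size_factors()].
#' @param condition Factor/vector of length ncol(counts) with two levels.
#' @param weight Weight on the per-peptide estimate (default 0.5).
#' @return List with `dispersion` (final), `raw`, `trend` vectors.
#' @export
estimate_dispersions <- function(counts, size_factors, condition, weight = 0.5) {
  cond <- as.factor(condition)
  norm <- sweep(counts, 2L, size_factors, "/")
  reps <- table(cond)
  if (any(reps < 2L)) {
    warning("single replicate in a condition; using blind dispersion estimates")
    mu <- rowMeans(norm)
    s2 <- apply(norm, 1L, stats::var)
  } else {
    ## pooled within-condition variance and overall mean
    mu <- rowMeans(norm)
    ss <- 0; df <- 0
    for (lv in levels(cond)) {
      sub <- norm[, cond == lv, drop = FALSE]
      ss <- ss + rowSums((sub - rowMeans(sub))^2)
      df <- df + ncol(sub) - 1L
    }
    s2 <- ss / df
  }
  raw <- pmax(0, (s2 - mu) / mu^2)
  raw[!is.finite(raw)] <- 0
  use <- raw > 0 & mu > 0
  if (sum(use) >= 10L) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a <- max(0, stats::coef(fit)[2L]); b <- max(0, stats::coef(fit)[1L])
    trend <- a / mu + b
  } else {
    trend <- rep(mean(raw), length(raw))
  }
  disp <- pmax(1e-8, weight * raw + (1 - weight) * trend)
  list(dispersion = disp, raw = raw, trend = trend)
}

#' Negative-binomial Wald test, selected vs unselected
#'
#' Per-peptide NB GLM with log link, design intercept + condition indicator,
#' log size factors as offsets and fixed per-peptide dispersion. The IRLS
#' updates are vectorized across peptides (the 2 x 2 weighted least-squares
#' solve has a closed form). The condition coefficient divided by ln 2 is the
#' log2 fold change; the Wald p-value is the two-sided normal tail of
#' coefficient / SE, with SE from the expected information. Peptides with
#' zero counts in one condition are handled by the same iteration without
#' pseudocounts: fitted means are floored at `minmu` inside the iteration,
#' which bounds the working weights so the coefficient and its (enlarged)
#' SE stay finite.
#'
#' @param counts Peptide x sample matrix.
#' @param size_factors Per-sample size factors.
#' @param dispersions Per-peptide NB dispersion alpha (Var = mu + alpha mu^2).
#' @param condition Two-level factor; the second level is "selected" (its
#'   coefficient is reported). A character vector is cast with levels
#'   `c("unselected", "selected")` when both appear.
#' @param maxit,tol IRLS iteration cap and deviance-change tolerance.
#' @param minmu Lower bound on fitted means inside the iteration (0.5, the
#'   convention of count-based differential testing).
#' @return Data frame with `base_mean`, `log2fc`, `se_log2fc`, `stat`, `p`,
#'   `converged`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, condition,
                         maxit = 50L, tol = 1e-10, minmu = 0.5) {
  cond <- .as_condition(condition)
  x <- as.numeric(cond == levels(cond)[2L])
  m <- nrow(counts); ns <- ncol(counts)
  stopifnot(length(x) == ns, length(dispersions) %in% c(1L, m))
  alpha <- rep_len(dispersions, m)
  y <- as.matrix(counts)
  off <- matrix(log(size_factors), m, ns, byrow = TRUE)
  norm_mean <- rowMeans(sweep(y, 2L, size_factors, "/"))
  b0 <- log(pmax(norm_mean, 1e-8))
  b1 <- rep(0, m)
  xm <- matrix(x, m, ns, byrow = TRUE)
  dev_old <- rep(Inf, m)
  converged <- rep(FALSE, m)
  for (it in seq_len(maxit)) {
    eta <- off + b0 + b1 * xm
    mu <- pmax(pmin(exp(eta), 1e12), minmu)
    w <- mu / (1 + alpha * mu)
    z <- (b0 + b1 * xm) + (y - mu) / mu
    S00 <- rowSums(w); S01 <- rowSums(w * xm); S11 <- rowSums(w * xm * xm)
    T0 <- rowSums(w * z); T1 <- rowSums(w * xm * z)
    det <- S00 * S11 - S01^2
    det[det < 1e-12] <- NA_real_
    b0n <- (S11 * T0 - S01 * T1) / det
    b1n <- (S00 * T1 - S01 * T0) / det
    upd <- !converged & is.finite(b0n) & is.finite(b1n)
    b0[upd] <- pmax(pmin(b0n[upd], 50), -50)
    b1[upd] <- pmax(pmin(b1n[upd], 50), -50)
    mu2 <- pmax(pmin(exp(off + b0 + b1 * xm), 1e12), minmu)
    dev <- rowSums(.nb_dev_resid(y, mu2, alpha))
    newly <- upd & abs(dev - dev_old) < tol * (abs(dev) + 0.1)
    converged <- converged | newly
    dev_old <- dev
    if (all(converged)) break
  }
  eta <- off + b0 + b1 * xm
  mu <- pmax(pmin(exp(eta), 1e12), minmu)
  w <- mu / (1 + alpha * mu)
  S00 <- rowSums(w); S01 <- rowSums(w * xm); S11 <- rowSums(w * xm * xm)
  det <- S00 * S11 - S01^2
  se_b1 <- sqrt(S00 / det)
  stat <- b1 / se_b1
  p <- 2 * stats::pnorm(-abs(stat))
  p[!converged] <- NA_real_
  if (any(!converged)) {
    message(sum(!converged), " peptide(s) did not converge; p set to NA")
  }
  data.frame(base_mean = norm_mean, log2fc = b1 / log(2),
             se_log2fc = se_b1 / log(2), stat = stat, p = p,
             converged = converged, row.names = rownames(counts))
}

.nb_dev_resid <- function(y, mu, alpha) {
  ## 2 * (loglik(saturated) - loglik(mu)) for NB with fixed alpha
  a <- matrix(alpha, nrow(y), ncol(y))
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / a) * log((1 + a * mu) / (1 + a * y))
  2 * (t1 + t2)
}

.as_condition <- function(condition) {
  if (is.factor(condition)) {
    stopifnot(nlevels(condition) == 2L)
    condition
  } else if (all(condition %in% c("unselected", "selected"))) {
    factor(condition, levels = c("unselected", "selected"))
  } else {
    factor(condition)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; NA/NaN p-values are excluded
#' from the adjustment and propagated.
#'
#' @param p Numeric vector of p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Classify peptides as cleaved / depleted / neutral
#'
#' @param records Data frame with `p_fdr` and `log2fc`.
#' @param alpha Significance level on the BH-adjusted p (default 0.05).
#' @return `records` with a `label` column: `cleaved` when `p_fdr < alpha`
#'   and `log2fc > 0`, `depleted` when `p_fdr < alpha` and `log2fc < 0`,
#'   else `neutral`.
#' @export
classify_peptides <- function(records, alpha = 0.05) {
  lab <- rep("neutral", nrow(records))
  sig <- !is.na(records$p_fdr) & records$p_fdr < alpha
  lab[sig & records$log2fc > 0] <- "cleaved"
  lab[sig & records$log2fc < 0] <- "depleted"
  records$label <- lab
  records
}

#' Full enrichment stage: filter, normalize, test, adjust, classify
#'
#' @param pc A `peptide_counts` object from [tally_peptides()], or a list
#'   with `counts` and `sample_info` (`role` column).
#' @param min_total Minimum combined read count (default 4).
#' @param alpha FDR level (default 0.05).
#' @param dispersion_weight Weight on per-peptide dispersion estimates.
#' @return Data frame of enrichment records (peptide, base_mean, log2fc, p,
#'   p_fdr, label), one row per retained peptide.
#' @export
run_enrichment <- function(pc, min_total = 4L, alpha = 0.05,
                           dispersion_weight = 0.5) {
  counts <- filter_min_total(pc$counts, min_total)
  cond <- .as_condition(pc$sample_info$role)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, cond, weight = dispersion_weight)
  wt <- nb_wald_test(counts, sf, disp$dispersion, cond)
  rec <- data.frame(peptide = rownames(counts), base_mean = wt$base_mean,
                    log2fc = wt$log2fc, p = wt$p,
                    p_fdr = adjust_bh(wt$p), stringsAsFactors = FALSE)
  classify_peptides(rec, alpha = alpha)
}
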