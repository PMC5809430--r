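cond22 <- factor(rep(c("unselected", "selected"), each = 2),
                 levels = c("unselected", "selected"))

test_that("minimum-total filter keeps the inclusive boundary", {
  m <- rbind(a = c(2, 1, 0, 0), b = c(2, 2, 0, 0), c = c(0, 0, 2, 1))
  expect_identical(rownames(filter_min_total(m, 4)), "b")
  expect_identical(nrow(filter_min_total(m[0, , drop = FALSE], 4)), 0L)
})

test_that("size factors equal the median-of-ratios oracle and scale exactly", {
  withr::with_seed(7, {
    m <- matrix(rnbinom(200, mu = 50, size = 5) + 1, ncol = 4)
  })
  rownames(m) <- paste0("p", 1:50)
  # mine medians log-ratios (geometric middle under even counts), the naive
  # oracle medians raw ratios: identical up to the even-median convention
  expect_equal(unname(estimate_size_factors(m)), oracle_size_factors(m),
               tolerance = 1e-3)
  # identical columns -> equal factors; doubled column -> doubled factor
  m2 <- cbind(m[, 1], m[, 1])
  expect_equal(unname(estimate_size_factors(m2)), c(1, 1))
  m3 <- cbind(m[, 1], 2 * m[, 1])
  sf <- estimate_size_factors(m3)
  expect_equal(sf[2] / sf[1], 2)
  # all-zero-containing table falls back with a warning
  m4 <- rbind(c(5, 0, 3, 2), c(0, 4, 1, 1))
  expect_warning(estimate_size_factors(m4), "total-count")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  withr::with_seed(13, {
    pois <- matrix(rpois(4e4, 100), ncol = 4)
    nb <- matrix(rnbinom(4e4, mu = 100, size = 2), ncol = 4)  # alpha = 0.5
  })
  rownames(pois) <- rownames(nb) <- paste0("p", 1:1e4)
  dp <- estimate_dispersions(pois, rep(1, 4), cond22)
  expect_lt(mean(dp$dispersion), 0.05)
  dn <- estimate_dispersions(nb, rep(1, 4), cond22)
  expect_gt(median(dn$dispersion), 0.3)
  expect_lt(median(dn$dispersion), 0.7)
  # constant counts: raw estimate 0 before shrinkage
  cst <- matrix(7, nrow = 2, ncol = 4, dimnames = list(c("a", "b"), NULL))
  expect_equal(estimate_dispersions(cst, rep(1, 4), cond22)$raw, c(0, 0))
  # single replicate per condition warns
  expect_warning(
    estimate_dispersions(pois[1:50, 1:2], rep(1, 2), factor(c("u", "s"))),
    "single replicate")
})

test_that("Wald test: exact fold changes, null p near 1, matches DESeq2 given dispersions", {
  m <- matrix(c(10, 10, 40, 40), nrow = 1, dimnames = list("x", NULL))
  r <- nb_wald_test(m, rep(1, 4), 0.01, cond22)
  expect_equal(r$log2fc, 2, tolerance = 1e-6)
  m2 <- matrix(rep(20, 4), nrow = 1, dimnames = list("x", NULL))
  r2 <- nb_wald_test(m2, rep(1, 4), 0.01, cond22)
  expect_equal(r2$log2fc, 0, tolerance = 1e-9)
  expect_equal(r2$p, 1, tolerance = 1e-6)

  skip_if_not_installed("DESeq2")
  withr::with_seed(29, {
    cnt <- matrix(rnbinom(400 * 4, mu = exp(rnorm(400, 4, 1)), size = 5), ncol = 4)
  })
  cnt <- cnt[rowSums(cnt) >= 4, ]
  rownames(cnt) <- paste0("p", seq_len(nrow(cnt)))
  colnames(cnt) <- c("u1", "u2", "s1", "s2")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, data.frame(cond = cond22), stats::formula("~cond"))
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  mine <- nb_wald_test(cnt, DESeq2::sizeFactors(dds), DESeq2::dispersions(dds), cond22)
  res <- DESeq2::results(dds)
  expect_equal(mine$log2fc, res$log2FoldChange, tolerance = 1e-4)
  expect_equal(mine$stat, res$stat, tolerance = 1e-4)
  expect_equal(unname(estimate_size_factors(cnt)),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-10)
})

test_that("Wald p-values are uniform under the complete null with known dispersion", {
  withr::with_seed(37, {
    cnt <- matrix(rnbinom(1e4 * 4, mu = 100, size = 10), ncol = 4)
  })
  rownames(cnt) <- paste0("p", 1:1e4)
  w <- nb_wald_test(cnt, rep(1, 4), 0.1, cond22)
  ks <- suppressWarnings(stats::ks.test(w$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  withr::with_seed(3, {
    p <- runif(200)
  })
  expect_equal(adjust_bh(p), oracle_bh(p))
  # NA propagates without affecting the rest
  p2 <- c(0.01, NA, 0.04)
  expect_true(is.na(adjust_bh(p2)[2]))
  expect_equal(adjust_bh(p2)[c(1, 3)], oracle_bh(c(0.01, 0.04)))
})

test_that("classification thresholds and labels follow p_fdr and sign", {
  rec <- data.frame(peptide = c("A", "B", "C", "D"),
                    log2fc = c(0.84, -1.20, 3, -3),
                    p_fdr = c(0.01, 0.01, 0.2, NA))
  out <- classify_peptides(rec)
  expect_identical(out$label, c("cleaved", "depleted", "neutral", "neutral"))
})

test_that("swapping conditions negates fold changes and swaps labels", {
  withr::with_seed(41, {
    cnt <- matrix(rnbinom(500 * 4, mu = 80, size = 8), ncol = 4)
    cnt[1:20, 3:4] <- cnt[1:20, 3:4] * 4L
  })
  rownames(cnt) <- paste0("p", 1:500)
  sf <- estimate_size_factors(cnt)
  disp <- estimate_dispersions(cnt, sf, cond22)$dispersion
  fwd <- nb_wald_test(cnt, sf, disp, cond22)
  swapped <- factor(as.character(cond22), levels = c("selected", "unselected"))
  bwd <- nb_wald_test(cnt, sf, disp, swapped)
  expect_equal(fwd$log2fc, -bwd$log2fc, tolerance = 1e-6)
  expect_equal(fwd$p, bwd$p, tolerance = 1e-6)
  lf <- classify_peptides(data.frame(peptide = rownames(cnt), log2fc = fwd$log2fc,
                                     p_fdr = adjust_bh(fwd$p)))
  lb <- classify_peptides(data.frame(peptide = rownames(cnt), log2fc = bwd$log2fc,
                                     p_fdr = adjust_bh(bwd$p)))
  expect_identical(lf$label == "cleaved", lb$label == "depleted")
  expect_identical(lf$label == "depleted", lb$label == "cleaved")
})

test_that("complete-null screens stay within the FDR budget", {
  withr::with_seed(43, {
    cnt <- matrix(rnbinom(1e4 * 4, mu = 100, size = 10), ncol = 4)
  })
  rownames(cnt) <- paste0("p", 1:1e4)
  colnames(cnt) <- c("u1", "u2", "s1", "s2")
  pc <- list(counts = cnt,
             sample_info = data.frame(name = colnames(cnt),
                                      role = rep(c("unselected", "selected"), each = 2),
                                      replicate = c(1, 2, 1, 2)))
  rec <- run_enrichment(pc)
  frac <- mean(rec$label != "neutral")
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(rec)))
})

test_that("planted strong effects are recovered as cleaved", {
  # 2000 peptides; 200 planted with a 10-fold selection advantage
  withr::with_seed(47, {
    ab <- exp(rnorm(2000, 0, 1)); ab <- ab / sum(ab)
    eff <- rep(1, 2000); eff[1:200] <- 10
    sel <- ab * eff; sel <- sel / sum(sel)
    depth <- 2.5e5
    cnt <- cbind(rmultinom(2, depth, ab), rmultinom(2, depth, sel))
  })
  rownames(cnt) <- paste0("p", 1:2000)
  colnames(cnt) <- c("u1", "u2", "s1", "s2")
  pc <- list(counts = cnt,
             sample_info = data.frame(name = colnames(cnt),
                                      role = rep(c("unselected", "selected"), each = 2),
                                      replicate = c(1, 2, 1, 2)))
  rec <- run_enrichment(pc)
  # the 100 most abundant planted peptides are the best powered
  top <- paste0("p", order(-ab[1:200])[1:100])
  expect_gte(mean(rec$label[match(top, rec$peptide)] == "cleaved"), 0.9)
})
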