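# Independent, deliberately naive reference implementations used as oracles.
# These share no code with the package internals.

# median-of-ratios, peptide-by-peptide loop
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(r) prod(r)^(1 / length(r)))
  keep <- apply(counts, 1, function(r) all(r > 0))
  sapply(seq_len(ncol(counts)), function(j) {
    median(counts[keep, j] / geo[keep])
  })
}

# BH step-up by its textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUROC by explicit pair counting with half-credit ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# per-pair reimplementation of the three read filters
oracle_rescan <- function(seq1, qual1, seq2, qual2, tmpl) {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  vs <- tmpl$var_start; vl <- tmpl$var_len
  L_amp <- vs + vl + nchar(tmpl$reverse_flank)
  sapply(seq_along(seq1), function(i) {
    seed_on <- function(s) {
      any(sapply(seq_len(3), function(k) {
        off <- tmpl$seed_offsets[k]
        substring(s, off + 1, off + tmpl$seed_length) == tmpl$seeds[k]
      }))
    }
    if (seed_on(seq1[i])) {
      sseq <- seq1[i]; squal <- qual1[i]; aseq <- seq2[i]; aqual <- qual2[i]
    } else if (seed_on(seq2[i])) {
      sseq <- seq2[i]; squal <- qual2[i]; aseq <- seq1[i]; aqual <- qual1[i]
    } else return("no_seed")
    La <- nchar(aseq)
    rc_start <- vs - (L_amp - La) + 1
    if (nchar(sseq) < vs + vl || rc_start < 1) return("incomplete")
    v1 <- substring(sseq, vs + 1, vs + vl)
    v2 <- substring(rc1(aseq), rc_start, rc_start + vl - 1)
    if (v1 != v2) return("mate_mismatch")
    q1 <- utf8ToInt(substring(squal, vs + 1, vs + vl)) - 33
    a_from <- La - (rc_start + vl - 1) + 1
    q2 <- utf8ToInt(substring(aqual, a_from, La - rc_start + 1)) - 33
    if (any(q1 < 5) || any(q2 < 5)) return("low_quality")
    "pass"
  })
}

# a small planted-motif screen shared across test files, built once
.fixture_env <- new.env()
small_screen <- function() {
  if (is.null(.fixture_env$scr)) {
    .fixture_env$scr <- simulate_screen(
      n_clones = 500, motif = p1_arg_motif(), n_read_pairs = 20000,
      seed = 101, dir = file.path(tempdir(), "small_screen"))
  }
  .fixture_env$scr
}
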