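#' The 32 NNK codons
#'
#' NNK degenerate codons have N = A/C/G/T at codon positions 1-2 and
#' K = G/T at position 3. The 32 codons cover all 20 amino acids with
#' 31 sense codons; the single stop codon reachable in NNK space is TAG
#' (TAA and TGA need an A in the third position).
#'
#' @return Character vector of the 32 NNK codons.
#' @export
nnk_codons <- function() {
  nuc <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(nuc, nuc, function(a, b) paste0(a, b))),
                  c("G", "T"), paste0))
}

#' Amino acids in the order used throughout the package
#' @return Character vector of the 20 standard one-letter amino acid codes.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Expected NNK amino-acid frequencies
#'
#' Frequency of each amino acid under uniform draws from the 32 NNK codons:
#' (number of NNK codons encoding the residue) / 32. The stop mass (1/32,
#' all of it TAG) is returned as an attribute rather than a 21st entry.
#'
#' @return Named numeric vector over the 20 amino acids, summing with the
#'   `stop` attribute to 1.
#' @export
nnk_expected_frequencies <- function() {
  codons <- nnk_codons()
  aa <- translate_codons(codons)
  tab <- table(factor(aa[aa != "*"], levels = amino_acids()))
  out <- as.numeric(tab) / length(codons)
  names(out) <- amino_acids()
  attr(out, "stop") <- sum(aa == "*") / length(codons)
  out
}

#' Draw random NNK inserts
#'
#' Each insert is `n_codons` NNK codons: positions 1 and 2 uniform over
#' A/C/G/T, position 3 uniform over G/T. Uses the current R random number
#' generator state.
#'
#' @param n Number of inserts to draw.
#' @param n_codons Codons per insert (6 for a hexapeptide library).
#' @return Character vector of `n` nucleotide strings of length `3 * n_codons`.
#' @export
generate_nnk_inserts <- function(n, n_codons = 6L) {
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (n == 0L) return(character(0))
  nuc <- c("A", "C", "G", "T")
  cols <- lapply(seq_len(3L * n_codons), function(j) {
    if (j %% 3L == 0L) sample(c("G", "T"), n, replace = TRUE)
    else sample(nuc, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

#' @rdname generate_nnk_inserts
#' @export
generate_nnk_insert <- function(n_codons = 6L) generate_nnk_inserts(1L, n_codons)

## standard genetic code lookup, stops as "*"
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("non-ACGT character in codon")
  aa
}

#' Translate an NNK variable region
#'
#' Standard genetic-code translation of in-frame nucleotide regions.
#' Translation runs over the whole region; the first in-frame stop codon,
#' if any, sets the stop flag and its identity (TAG/TAA/TGA) is recorded.
#' Vectorized over `regions`.
#'
#' @param regions Character vector of nucleotide strings, lengths divisible by 3.
#' @return Data frame with columns `peptide` (full translation, stops as `*`),
#'   `has_stop` and `stop_codon` (NA when stop-free).
#' @export
translate_nnk <- function(regions) {
  if (length(regions) == 0L) {
    return(data.frame(peptide = character(0), has_stop = logical(0),
                      stop_codon = character(0), stringsAsFactors = FALSE))
  }
  len <- unique(nchar(regions))
  if (length(len) != 1L || len %% 3L != 0L) {
    stop("regions must share a common length divisible by 3")
  }
  if (any(grepl("[^ACGT]", regions))) stop("non-ACGT character in region")
  n_cod <- len %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  cod_cols <- lapply(starts, function(s) substr(regions, s, s + 2L))
  aa_cols <- lapply(cod_cols, translate_codons)
  peptide <- do.call(paste0, aa_cols)
  stop_codon <- rep(NA_character_, length(regions))
  for (j in rev(seq_len(n_cod))) {
    is_stop <- aa_cols[[j]] == "*"
    stop_codon[is_stop] <- cod_cols[[j]][is_stop]  # reverse scan keeps first
  }
  has_stop <- !is.na(stop_codon)
  data.frame(peptide = peptide, has_stop = has_stop, stop_codon = stop_codon,
             stringsAsFactors = FALSE)
}
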