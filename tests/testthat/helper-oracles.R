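# Independent oracles used by the tests; these deliberately share no code
# with the package implementation paths they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Exhaustive pair-counting AUC: fraction of (positive, negative) pairs the
# positive wins, ties count one half.
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Affine-gap local alignment (Smith-Waterman) by dynamic programming:
# a gap of length L costs open + L * ext, matching the package convention.
brute_local_align <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- Ix <- Iy <- matrix(-Inf, n + 1L, m + 1L)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Count of length-L windows of a length-n protein that contain position
# pos (closed form used against the enumeration).
window_count <- function(n, pos, L) {
  if (L > n) return(0L)
  as.integer(max(0, min(pos, n - L + 1) - max(1, pos - L + 1) + 1))
}

# Column-wise residue proportions of a peptide set (direct counting).
count_profile <- function(peptides) {
  chars <- do.call(rbind, strsplit(peptides, ""))
  apply(chars, 2L, function(col)
    table(factor(col, levels = AA20)) / length(col))
}

random_peptide <- function(n, len, prob = NULL) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = ""),
    character(1))
}

# A PSSM whose every matrix entry is the constant that maps to the given
# IC50, so any peptide of that length predicts exactly that IC50.
constant_ic50_pssm <- function(allele, length, ic50,
                               transform = ic50_transform()) {
  p <- build_pssm(rep(strrep("A", length), 10), allele = allele)
  p$matrix[] <- ic50_to_score(ic50, transform)
  p
}
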