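# Core scoring: PSSM construction, peptide scoring, IC50 transform.
#
# The model for one (allele, peptide length) pair is a 20 x N log-odds
# matrix P_ai = log((F_ai + omega) / BG_a), where F_ai is the observed
# proportion of residue a at position i over the training binders, BG_a the
# background frequency, and omega a pseudocount that keeps unobserved
# residues finite. A peptide's binding score is the length-normalized sum
# of its matrix lookups, mapped to IC50 nM by
# base^((Max - score)/(Max - Min)).

#' Pseudocount policy for PSSM construction
#'
#' The pseudocount omega added to every observed frequency before the
#' log-odds. `"fixed"` mode (the reproducible default) uses a single
#' constant. `"dirichlet"` mode draws, for each matrix column, one
#' symmetric Dirichlet(`concentration`) vector across the 20 residues and
#' uses each component (which lies in (0, 1)) as that cell's omega; draws
#' are fully determined by `seed`.
#'
#' @param mode `"fixed"` or `"dirichlet"`.
#' @param fixed_value Constant omega for fixed mode; must be > 0 (omega = 0
#'   would produce `log(0)` for unobserved residues).
#' @param concentration Positive Dirichlet concentration for dirichlet mode.
#' @param seed Integer seed for dirichlet mode.
#' @return An object of class `omega_policy`.
#' @export
omega_policy <- function(mode = c("fixed", "dirichlet"), fixed_value = 0.02,
                         concentration = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(fixed_value), length(fixed_value) == 1L,
            is.numeric(concentration), length(concentration) == 1L,
            concentration > 0)
  if (fixed_value <= 0 || fixed_value > 1)
    stop("fixed_value must lie in (0, 1]")
  structure(list(mode = mode, fixed_value = fixed_value,
                 concentration = concentration, seed = as.integer(seed)),
            class = "omega_policy")
}

# 20 x N matrix of per-cell pseudocounts under a policy.
omega_matrix <- function(policy, n_cols) {
  if (policy$mode == "fixed")
    return(matrix(policy$fixed_value, nrow = 20L, ncol = n_cols,
                  dimnames = list(AMINO_ACIDS, NULL)))
  with_seed_if(policy$seed, {
    m <- matrix(0, nrow = 20L, ncol = n_cols,
                dimnames = list(AMINO_ACIDS, NULL))
    for (j in seq_len(n_cols)) {
      g <- rgamma(20L, shape = policy$concentration)
      m[, j] <- g / sum(g)
    }
    m
  })
}

#' Build a position-specific scoring matrix from binder peptides
#'
#' Computes `P_ai = log((F_ai + omega) / BG_a)` (logarithm in `log_base`),
#' where `F_ai` is the proportion of residue `a` at position `i` over the
#' binder set. Duplicate peptides count with multiplicity; deduplication is
#' the responsibility of the training-data cleaning step. Construction is
#' bit-reproducible: fixed omega is deterministic and dirichlet omega is
#' seeded.
#'
#' @param binders Character vector of binder peptides, all the same length
#'   N in 8..25, canonical residues only.
#' @param background Named background frequency vector (see
#'   [uniprot_background()]).
#' @param omega An [omega_policy()].
#' @param log_base Base of the logarithm; stored in the model (the
#'   score-to-IC50 constants were tuned against an unstated base, so it is
#'   kept explicit).
#' @param allele Optional allele name recorded in the model (normalized if
#'   given).
#' @return An object of class `pssm`: list with `allele`, `length`,
#'   `matrix` (20 x N, rows in fixed alphabetical residue order),
#'   `log_base`, `n_training_binders`, `omega`.
#' @examples
#' p <- build_pssm(rep("AAAAAAAAA", 10),
#'                 background = uniprot_background(),
#'                 omega = omega_policy(fixed_value = 0.05))
#' score_peptides(p, "AAAAAAAAA")
#' @export
build_pssm <- function(binders, background = uniprot_background(),
                       omega = omega_policy(), log_base = exp(1),
                       allele = NA_character_) {
  if (length(binders) == 0L) stop("empty binder list")
  binders <- validate_peptides(binders)
  n <- nchar(binders)
  if (length(unique(n)) != 1L)
    stop("mixed peptide lengths in binder set: ",
         paste(sort(unique(n)), collapse = ", "))
  N <- n[1L]
  background <- validate_background(background)
  if (!inherits(omega, "omega_policy")) stop("omega must be an omega_policy")
  stopifnot(is.numeric(log_base), length(log_base) == 1L, log_base > 1)

  chars <- matrix(unlist(strsplit(binders, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(binders), byrow = TRUE)
  counts <- apply(chars, 2L, function(col)
    tabulate(factor(col, levels = AMINO_ACIDS), nbins = 20L))
  F_ai <- counts / length(binders)            # 20 x N, each column sums to 1
  stopifnot(all(abs(colSums(F_ai) - 1) < 1e-9))
  mat <- log((F_ai + omega_matrix(omega, N)) / background) / log(log_base)
  dimnames(mat) <- list(AMINO_ACIDS, NULL)
  if (!all(is.finite(mat))) stop("non-finite PSSM entries")

  structure(list(
    allele = if (is.na(allele)) NA_character_ else normalize_allele(allele),
    length = N,
    matrix = mat,
    log_base = log_base,
    n_training_binders = length(binders),
    omega = omega), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM %s length %d (log base %.4g, %d training binders, omega %s)\n",
              if (is.na(x$allele)) "<unnamed>" else x$allele,
              x$length, x$log_base,
              x$n_training_binders, x$omega$mode))
  invisible(x)
}

#' Score peptides against a PSSM
#'
#' The binding score of a peptide is the sum over positions of the matrix
#' entry for its residue at that position, divided by the peptide length.
#' Higher score means higher predicted affinity; score > 0 is the
#' qualitative score-sign binder flag (the IC50 < 500 nM rule is the
#' authoritative classification, see [classify_affinity()]).
#'
#' @param pssm A `pssm` object.
#' @param peptides Character vector; every peptide must have length
#'   `pssm$length`.
#' @return Numeric vector of binding scores.
#' @export
score_peptides <- function(pssm, peptides) {
  stopifnot(inherits(pssm, "pssm"))
  peptides <- validate_peptides(peptides, length_range = NULL)
  n <- nchar(peptides)
  if (any(n != pssm$length))
    stop("peptide length mismatch: PSSM expects ", pssm$length,
         ", observed ", paste(sort(unique(n[n != pssm$length])), collapse = ", "))
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), byrow = TRUE)
  idx <- match(chars, AMINO_ACIDS)            # same shape as chars
  looked <- matrix(pssm$matrix[cbind(as.vector(idx),
                                     as.vector(col(chars)))],
                   nrow = length(peptides))
  rowSums(looked) / pssm$length
}

#' Score-to-IC50 transform
#'
#' Parameters of the analytic map from binding score to IC50 nM:
#' `IC50 = base^((Max - s)/(Max - Min))` with the score clamped into
#' `[Min, Max]` before exponentiation (keeping IC50 in `[1, base]` nM).
#' Defaults are base 50000 nM, Max 0.8, Min -0.8, with the 500 nM binder
#' and 50 nM strong-binder cutoffs.
#'
#' @param base Positive scale, > 1 (nM).
#' @param score_max,score_min The Max/Min score constants, `score_max >
#'   score_min`.
#' @param binder_cutoff,strong_cutoff IC50 class cutoffs in nM,
#'   `0 < strong_cutoff < binder_cutoff`.
#' @return An object of class `ic50_transform`.
#' @export
ic50_transform <- function(base = 50000, score_max = 0.8, score_min = -0.8,
                           binder_cutoff = 500, strong_cutoff = 50) {
  stopifnot(base > 1, score_max > score_min,
            strong_cutoff > 0, binder_cutoff > strong_cutoff)
  structure(list(base = base, score_max = score_max, score_min = score_min,
                 binder_cutoff = binder_cutoff,
                 strong_cutoff = strong_cutoff),
            class = "ic50_transform")
}

#' Convert binding scores to IC50 (nM) and back
#'
#' `score_to_ic50()` maps scores through
#' `base^((Max - s')/(Max - Min))` where `s'` is the score clamped into
#' `[Min, Max]`; it is strictly decreasing on the interior. `ic50_to_score()`
#' is its analytic inverse on `[1, base]`.
#'
#' @param binding_score,ic50 Numeric vectors.
#' @param transform An [ic50_transform()].
#' @return Numeric vector (nM or score units respectively).
#' @examples
#' tr <- ic50_transform()
#' score_to_ic50(c(-0.8, 0, 0.8), tr)  # 50000, ~223.6, 1
#' @export
score_to_ic50 <- function(binding_score, transform = ic50_transform()) {
  stopifnot(inherits(transform, "ic50_transform"), is.numeric(binding_score))
  s <- pmin(pmax(binding_score, transform$score_min), transform$score_max)
  transform$base ^ ((transform$score_max - s) /
                    (transform$score_max - transform$score_min))
}

#' @rdname score_to_ic50
#' @export
ic50_to_score <- function(ic50, transform = ic50_transform()) {
  stopifnot(inherits(transform, "ic50_transform"), is.numeric(ic50))
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  transform$score_max - log(ic50, base = transform$base) *
    (transform$score_max - transform$score_min)
}

#' Classify predicted affinity by IC50
#'
#' Strong binder iff IC50 < 50 nM; binder iff 50 <= IC50 < 500 nM;
#' nonbinder otherwise. Cutoffs are strict less-than; exactly 500 nM is a
#' nonbinder.
#'
#' @param ic50 Positive numeric vector, nM.
#' @param transform An [ic50_transform()] carrying the cutoffs.
#' @return Character vector over `{"strong_binder", "binder", "nonbinder"}`.
#' @export
classify_affinity <- function(ic50, transform = ic50_transform()) {
  stopifnot(inherits(transform, "ic50_transform"), is.numeric(ic50))
  if (anyNA(ic50) || any(ic50 <= 0)) stop("IC50 must be positive")
  ifelse(ic50 < transform$strong_cutoff, "strong_binder",
         ifelse(ic50 < transform$binder_cutoff, "binder", "nonbinder"))
}
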