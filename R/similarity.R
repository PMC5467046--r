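# Pan-specific prediction: HLA similarity-weight library and the weighted
# mean IC50 over characterized neighbor alleles.
#
# The rationale: HLA class I protein sequences are highly similar across
# alleles, and peptides bound by similar alleles have similar affinities.
# An allele with no training data ("uncharacterized") is therefore
# predicted as the similarity-weighted mean of the allele-specific IC50s
# of its sequence neighbors.

#' BLOSUM62 local-alignment weight between two protein sequences
#'
#' Optimal local (Smith-Waterman, BLAST-like) alignment raw score under
#' BLOSUM62 with affine gaps, protein-BLAST defaults (gap open 11, extend
#' 1 per gapped residue). Symmetric in its arguments.
#'
#' @param seq_a,seq_b Protein sequences (character scalars, canonical
#'   amino-acid alphabet).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return The raw alignment score (numeric scalar, >= 0 for local
#'   alignment).
#' @examples
#' alignment_weight("ARND", "ARND")  # 21, the BLOSUM62 diagonal sum
#' @export
alignment_weight <- function(seq_a, seq_b, gap_opening = 11,
                             gap_extension = 1) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  validate_peptides(c(seq_a, seq_b), length_range = NULL)
  Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b),
    substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "local", scoreOnly = TRUE)
}

# BLOSUM62 lazily loaded from Biostrings' bundled data.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Build the HLA similarity-weight library
#'
#' For every uncharacterized allele with a protein sequence, emits one pair
#' per characterized allele, weighted by the BLOSUM62 local-alignment raw
#' score of the two protein sequences (source `"alignment"`). Optional
#' nearest-distance pairs (e.g. extracted from another pan-allele tool) are
#' added with a constant weight (source `"nearest_distance"`); when a pair
#' occurs in both sources the alignment row wins. Uncharacterized alleles
#' that end up with no pair are reported in the `"uncoverable"` attribute,
#' not an error.
#'
#' @param hla_sequences Named character vector of HLA protein sequences
#'   (names are allele names, normalized on input) or a path to a
#'   multi-FASTA file.
#' @param characterized Character vector of characterized allele names
#'   (those with trained PSSMs).
#' @param nearest_pairs Optional data frame (or TSV path) with columns
#'   `uncharacterized`, `characterized`.
#' @param constant_weight Weight for nearest-distance pairs; `NULL` (the
#'   default) uses the median alignment weight in the library so the two
#'   sources live on comparable scales.
#' @param region Optional integer pair restricting the alignment to a
#'   subsequence interval (1-based, inclusive), e.g. an alpha1/alpha2
#'   groove-domain window; `NULL` aligns full sequences.
#' @return Data frame of class `similarity_library` with columns
#'   `uncharacterized`, `characterized`, `weight`, `source`; attribute
#'   `"uncoverable"` lists alleles with no usable pair.
#' @export
build_similarity_library <- function(hla_sequences, characterized,
                                     nearest_pairs = NULL,
                                     constant_weight = NULL,
                                     region = NULL) {
  seqs <- read_hla_sequences(hla_sequences)
  if (length(characterized) == 0L) stop("characterized allele set is empty")
  characterized <- unique(normalize_allele(characterized))
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 1, region[2] >= region[1])
    seqs <- vapply(seqs, function(s)
      substr(s, region[1], min(region[2], nchar(s))), character(1))
  }
  unchar <- setdiff(names(seqs), characterized)
  char_with_seq <- intersect(characterized, names(seqs))

  rows <- list()
  for (u in unchar) {
    for (ch in char_with_seq) {
      rows[[length(rows) + 1L]] <- data.frame(
        uncharacterized = u, characterized = ch,
        weight = alignment_weight(seqs[[u]], seqs[[ch]]),
        source = "alignment")
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(uncharacterized = character(0), characterized = character(0),
               weight = numeric(0), source = character(0))

  if (!is.null(nearest_pairs)) {
    if (is.character(nearest_pairs))
      nearest_pairs <- read.delim(nearest_pairs, colClasses = "character")
    stopifnot(all(c("uncharacterized", "characterized") %in%
                    names(nearest_pairs)))
    if (nrow(nearest_pairs) > 0L) {
      cw <- constant_weight %||%
        (if (nrow(pairs) > 0L) median(pairs$weight) else 1)
      if (cw <= 0) stop("constant_weight must be positive")
      nd <- data.frame(
        uncharacterized = normalize_allele(nearest_pairs$uncharacterized),
        characterized = normalize_allele(nearest_pairs$characterized),
        weight = cw, source = "nearest_distance")
      pairs <- rbind(pairs, nd)
    }
  }
  # dedup: one row per (uncharacterized, characterized); alignment wins
  pairs <- pairs[order(pairs$uncharacterized, pairs$characterized,
                       pairs$source != "alignment"), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[c("uncharacterized", "characterized")]), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  stopifnot(all(pairs$weight > 0))
  covered <- unique(pairs$uncharacterized)
  uncoverable <- setdiff(unchar, covered)
  if (length(uncoverable))
    message(length(uncoverable),
            " uncharacterized allele(s) have no usable pair: ",
            paste(uncoverable, collapse = ", "))
  structure(pairs, uncoverable = uncoverable,
            class = c("similarity_library", "data.frame"))
}

read_hla_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
    x <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  if (!is.character(x) || is.null(names(x)) || !all(nzchar(names(x))))
    stop("hla_sequences must be a named character vector or a FASTA path")
  setNames(toupper(x), normalize_allele(names(x)))
}

#' Read / write a similarity library TSV
#'
#' Columns `uncharacterized_allele`, `characterized_allele`, `weight`,
#' `source`, written and read verbatim.
#'
#' @param sim A `similarity_library` data frame.
#' @param path TSV path.
#' @export
write_similarity_library <- function(sim, path) {
  stopifnot(is.data.frame(sim))
  out <- data.frame(uncharacterized_allele = sim$uncharacterized,
                    characterized_allele = sim$characterized,
                    weight = sim$weight, source = sim$source)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_library
#' @export
read_similarity_library <- function(path) {
  tab <- read.delim(path)
  need <- c("uncharacterized_allele", "characterized_allele", "weight",
            "source")
  if (!all(need %in% names(tab)))
    stop("similarity library ", path, " must have columns ",
         paste(need, collapse = ", "))
  structure(data.frame(uncharacterized = normalize_allele(tab$uncharacterized_allele),
                       characterized = normalize_allele(tab$characterized_allele),
                       weight = as.numeric(tab$weight),
                       source = tab$source),
            class = c("similarity_library", "data.frame"))
}

#' Pan-specific prediction for an uncharacterized allele
#'
#' Predicts IC50 for peptides against an allele with no trained PSSM as
#' the weighted mean over its similarity neighbors:
#' `IC50_un = sum(w_i * IC50_i) / sum(w_i)` across the S characterized
#' alleles paired with the query allele whose PSSM covers the peptide
#' length (optionally restricted to the `top_k` heaviest). IC50_i is the
#' allele-specific prediction through neighbor i's PSSM. Classification
#' uses the same 500/50 nM cutoffs as the allele-specific path.
#'
#' @param peptides Character vector of peptides (one shared length per
#'   call is not required; neighbors are selected per length).
#' @param allele The uncharacterized allele name.
#' @param lib A [pssm_library()] of characterized models.
#' @param sim A similarity library ([build_similarity_library()]).
#' @param top_k Keep only the `top_k` neighbors by weight (ties broken by
#'   allele name for determinism); `Inf` uses all.
#' @param transform An [ic50_transform()].
#' @return Data frame: `peptide`, `allele`, `mode` (`"pan-specific"`),
#'   `binding_score` (NA: scores from different neighbor PSSMs are not
#'   commensurable), `ic50_nM`, `class`, `n_neighbors`.
#' @export
predict_pan <- function(peptides, allele, lib, sim, top_k = Inf,
                        transform = ic50_transform()) {
  stopifnot(inherits(lib, "pssm_library"), is.data.frame(sim),
            top_k >= 1)
  allele <- normalize_allele(allele)
  if (allele %in% characterized_alleles(lib))
    stop("allele ", allele,
         " is characterized; use the allele-specific path")
  peptides <- validate_peptides(peptides)
  pairs <- sim[sim$uncharacterized == allele, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("uncoverable allele: ", allele, " has no similarity pair")

  out <- data.frame(peptide = peptides, allele = allele,
                    mode = "pan-specific", binding_score = NA_real_,
                    ic50_nM = NA_real_, class = NA_character_,
                    n_neighbors = 0L)
  for (L in unique(nchar(peptides))) {
    rows <- which(nchar(peptides) == L)
    usable <- pairs[vapply(pairs$characterized, function(a)
      !is.null(get_pssm(lib, a, L)), logical(1)), , drop = FALSE]
    if (nrow(usable) == 0L) next  # degraded rows stay NA
    usable <- usable[order(-usable$weight, usable$characterized), ,
                     drop = FALSE]
    if (is.finite(top_k) && nrow(usable) > top_k)
      usable <- usable[seq_len(top_k), , drop = FALSE]
    ic50_mat <- vapply(usable$characterized, function(a) {
      p <- get_pssm(lib, a, L)
      score_to_ic50(score_peptides(p, peptides[rows]), transform)
    }, numeric(length(rows)))
    ic50_mat <- matrix(ic50_mat, nrow = length(rows))
    w <- usable$weight
    # single neighbor: the weighted mean is that neighbor's IC50 exactly
    ic50_un <- if (nrow(usable) == 1L) ic50_mat[, 1L] else
      as.vector(ic50_mat %*% w) / sum(w)
    out$ic50_nM[rows] <- ic50_un
    out$class[rows] <- classify_affinity(ic50_un, transform)
    out$n_neighbors[rows] <- nrow(usable)
  }
  if (all(out$n_neighbors == 0L))
    stop("uncoverable allele: no neighbor of ", allele,
         " has a PSSM for the queried peptide length(s)")
  out
}
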