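# Neoantigen candidate enumeration and filtering.
#
# Input is protein-level: a protein sequence plus a somatic mutation
# (substitution, insertion or deletion) in 1-based protein coordinates.
# Mutant peptide windows of lengths 8..13 covering the altered site are
# enumerated, paired with the positionally corresponding wild-type window
# for substitutions, and filtered by the two candidate rules:
# (i) the mutant peptide is a predicted binder (IC50 < 500 nM);
# (ii) for substitution-derived candidates, the mutant IC50 is smaller
#     than the wild-type IC50.

#' Read a protein mutation table
#'
#' TSV with header columns `protein_id`, `position`, `kind`
#' (substitution/insertion/deletion), `ref_aa`, `alt_aa`. For insertions
#' `alt_aa` is the inserted run (placed after `position`); for deletions
#' `ref_aa` is the deleted run starting at `position`.
#'
#' @param path TSV path.
#' @return Data frame with those columns (`position` integer).
#' @export
read_mutation_table <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("protein_id", "position", "kind", "ref_aa", "alt_aa")
  if (!all(need %in% names(tab)))
    stop("mutation table ", path, " must have columns ",
         paste(need, collapse = ", "))
  tab$position <- as.integer(tab$position)
  tab$kind <- tolower(tab$kind)
  bad <- !tab$kind %in% c("substitution", "insertion", "deletion")
  if (any(bad)) stop("unknown mutation kind: ", tab$kind[bad][1L])
  tab
}

apply_mutation <- function(protein, mutation) {
  pos <- mutation$position
  ref <- toupper(mutation$ref_aa %||% "")
  alt <- toupper(mutation$alt_aa %||% "")
  if (is.na(ref)) ref <- ""
  if (is.na(alt)) alt <- ""
  n <- nchar(protein)
  check_ref <- function(run, at) {
    if (nzchar(run) && substr(protein, at, at + nchar(run) - 1L) != run)
      stop("ref_aa mismatch at position ", at, ": expected ", run,
           ", observed ", substr(protein, at, at + nchar(run) - 1L))
  }
  switch(mutation$kind,
    substitution = {
      if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
        stop("substitution requires single, differing ref_aa and alt_aa")
      if (pos < 1L || pos > n) stop("position ", pos, " outside protein")
      check_ref(ref, pos)
      list(mutant = paste0(substr(protein, 1L, pos - 1L), alt,
                           substr(protein, pos + 1L, n)),
           altered = pos, kind = "substitution")
    },
    insertion = {
      if (!nzchar(alt)) stop("insertion requires non-empty alt_aa")
      if (pos < 0L || pos > n) stop("position ", pos, " outside protein")
      if (nzchar(ref)) check_ref(ref, pos)
      # inserted residues occupy mutant positions pos+1 .. pos+nchar(alt)
      list(mutant = paste0(substr(protein, 1L, pos), alt,
                           substr(protein, pos + 1L, n)),
           altered = seq(pos + 1L, pos + nchar(alt)), kind = "insertion")
    },
    deletion = {
      if (!nzchar(ref)) stop("deletion requires non-empty ref_aa")
      if (pos < 1L || pos + nchar(ref) - 1L > n)
        stop("deleted run outside protein bounds")
      check_ref(ref, pos)
      # junction: the two mutant residues flanking the excision
      mut <- paste0(substr(protein, 1L, pos - 1L),
                    substr(protein, pos + nchar(ref), n))
      junction <- intersect(c(pos - 1L, pos), seq_len(nchar(mut)))
      if (length(junction) == 0L) junction <- 1L
      list(mutant = mut, altered = junction, kind = "deletion")
    },
    stop("unknown mutation kind: ", mutation$kind))
}

#' Enumerate mutant/wild-type peptide windows around a mutation
#'
#' For a substitution, returns every window of each requested length that
#' contains the mutated residue and lies within bounds, paired with the
#' positionally identical wild-type window (the two differ at exactly one
#' position). For insertions and deletions, returns every window of the
#' mutated sequence overlapping an altered or junction position; the
#' wild-type pairing is absent (`NA`) because no positionally
#' corresponding wild-type peptide exists. Windows are unique.
#'
#' @param protein Wild-type protein sequence (character scalar).
#' @param mutation One-row data frame or list with fields `position`,
#'   `kind`, `ref_aa`, `alt_aa` (see [read_mutation_table()]).
#' @param lengths Integer vector of peptide lengths, default `8:13`.
#' @return Data frame: `mutant_peptide`, `wild_type_peptide` (NA for
#'   indels), `length`, `start` (1-based start in the mutant sequence).
#' @examples
#' enumerate_windows(strrep("A", 20),
#'                   list(position = 10, kind = "substitution",
#'                        ref_aa = "A", alt_aa = "V"))
#' @export
enumerate_windows <- function(protein, mutation, lengths = 8:13) {
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  validate_peptides(protein, length_range = NULL)
  lengths <- sort(unique(as.integer(lengths)))
  stopifnot(all(lengths >= 1L))
  mut <- apply_mutation(protein, as.list(mutation))
  m <- nchar(mut$mutant)
  rows <- list()
  for (L in lengths) {
    if (L > m) next
    # starts of length-L windows overlapping any altered position
    starts <- sort(unique(unlist(lapply(mut$altered, function(p)
      seq.int(max(1L, p - L + 1L), min(p, m - L + 1L))))))
    starts <- starts[starts >= 1L & starts + L - 1L <= m]
    for (s in starts) {
      wt <- if (mut$kind == "substitution")
        substr(protein, s, s + L - 1L) else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        mutant_peptide = substr(mut$mutant, s, s + L - 1L),
        wild_type_peptide = wt, length = L, start = s)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mutant_peptide = character(0),
               wild_type_peptide = character(0), length = integer(0),
               start = integer(0))
  out[!duplicated(out$mutant_peptide), , drop = FALSE]
}

#' Score and filter neoantigen candidates
#'
#' Scores each mutant window (and its wild-type partner when present)
#' against each allele, and applies the candidate rules: pass iff
#' (i) `ic50_mut < binder_cutoff` (500 nM) and (ii) the wild-type window
#' is absent or `ic50_mut < ic50_wt`. Failures carry reason codes
#' `fail_binder` (rule i) or `fail_wt_comparison` (rule ii). The
#' per-sample neoantigen load is the number of passing (peptide, allele)
#' rows.
#'
#' @param windows Data frame from [enumerate_windows()] (columns
#'   `mutant_peptide`, `wild_type_peptide`; extra columns are carried
#'   through).
#' @param alleles Character vector of HLA alleles to test.
#' @param lib A [pssm_library()].
#' @param sim Optional similarity library enabling pan-specific coverage.
#' @param top_k Pan-specific neighbor cap.
#' @param transform An [ic50_transform()].
#' @return Data frame: the window columns plus `allele`, `ic50_mut`,
#'   `ic50_wt` (NA when absent), `pass`, `reason` (`"pass"`,
#'   `"fail_binder"`, `"fail_wt_comparison"`, or `"no_model"`).
#' @export
call_neoantigens <- function(windows, alleles, lib, sim = NULL,
                             top_k = Inf, transform = ic50_transform()) {
  stopifnot(is.data.frame(windows),
            all(c("mutant_peptide", "wild_type_peptide") %in% names(windows)),
            length(alleles) >= 1L)
  alleles <- normalize_allele(alleles)
  uncovered <- setdiff(alleles, characterized_alleles(lib))
  if (length(uncovered) && is.null(sim))
    stop("no coverage for allele(s) ", paste(uncovered, collapse = ", "),
         "; characterized: ",
         paste(characterized_alleles(lib), collapse = ", "))
  if (!is.null(sim)) {
    covered_pan <- unique(sim$uncharacterized)
    still <- setdiff(uncovered, covered_pan)
    if (length(still))
      stop("no coverage for allele(s) ", paste(still, collapse = ", "))
  }
  out <- list()
  for (al in alleles) {
    mu <- predict_binding(windows$mutant_peptide, al, lib, sim = sim,
                          top_k = top_k, transform = transform)
    has_wt <- !is.na(windows$wild_type_peptide)
    ic50_wt <- rep(NA_real_, nrow(windows))
    if (any(has_wt)) {
      wt <- predict_binding(windows$wild_type_peptide[has_wt], al, lib,
                            sim = sim, top_k = top_k, transform = transform)
      ic50_wt[has_wt] <- wt$ic50_nM
    }
    res <- cbind(windows,
                 data.frame(allele = al, ic50_mut = mu$ic50_nM,
                            ic50_wt = ic50_wt))
    res$reason <- ifelse(is.na(res$ic50_mut), "no_model",
                  ifelse(res$ic50_mut >= transform$binder_cutoff, "fail_binder",
                  ifelse(!is.na(res$ic50_wt) & res$ic50_mut >= res$ic50_wt,
                         "fail_wt_comparison", "pass")))
    res$pass <- res$reason == "pass"
    out[[al]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Consensus IC50 across multiple predictors
#'
#' When IC50 predictions from several tools are available for the same
#' candidates, a candidate counts as a consensus binder when at least
#' `min_support` predictors call it a binder (IC50 < `cutoff`); the
#' reported value is the median IC50 across the predictors. With a single
#' predictor this reduces to that predictor's call.
#'
#' @param ic50_matrix Numeric matrix, one row per candidate, one column
#'   per predictor.
#' @param cutoff Binder cutoff (nM), default 500.
#' @param min_support Minimum number of predictors calling binder
#'   (default 2, clipped to the number of predictors supplied).
#' @return Data frame: `ic50` (row median), `n_support`, `binder`.
#' @export
consensus_ic50 <- function(ic50_matrix, cutoff = 500, min_support = 2L) {
  ic50_matrix <- as.matrix(ic50_matrix)
  stopifnot(is.numeric(ic50_matrix), ncol(ic50_matrix) >= 1L)
  min_support <- min(min_support, ncol(ic50_matrix))
  n_support <- rowSums(ic50_matrix < cutoff)
  data.frame(ic50 = apply(ic50_matrix, 1L, median),
             n_support = n_support,
             binder = n_support >= min_support)
}
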