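#' Predict peptide binding to an HLA allele
#'
#' Dispatches between the allele-specific path (the allele has trained
#' PSSMs in `lib`) and the pan-specific path (otherwise, through `sim`).
#' Peptides whose length has no PSSM (allele-specific) or no usable
#' neighbor (pan-specific) get a row-level `status`, not an error.
#'
#' @param peptides Character vector of peptides, lengths 8..25.
#' @param allele Allele name (normalized internally).
#' @param lib A [pssm_library()].
#' @param sim Optional similarity library for uncharacterized alleles.
#' @param top_k Pan-specific neighbor cap (see [predict_pan()]).
#' @param transform An [ic50_transform()].
#' @return Data frame: `peptide`, `allele`, `mode` (`"allele-specific"` or
#'   `"pan-specific"`), `binding_score` (allele-specific only),
#'   `binder_by_score` (the score-sign flag, allele-specific only),
#'   `ic50_nM`, `class`, `n_neighbors`, `status` (`"ok"` or
#'   `"no_model_for_length"`).
#' @examples
#' bg <- uniprot_background()
#' lib <- pssm_library(list(build_pssm(rep("SIINFEKLM", 10), bg,
#'                                     allele = "A*0201")))
#' predict_binding("SIINFEKLM", "A*0201", lib)
#' @export
predict_binding <- function(peptides, allele, lib, sim = NULL, top_k = Inf,
                            transform = ic50_transform()) {
  stopifnot(inherits(lib, "pssm_library"))
  allele <- normalize_allele(allele)
  peptides <- validate_peptides(peptides)

  if (allele %in% characterized_alleles(lib)) {
    out <- data.frame(peptide = peptides, allele = allele,
                      mode = "allele-specific",
                      binding_score = NA_real_, binder_by_score = NA,
                      ic50_nM = NA_real_, class = NA_character_,
                      n_neighbors = NA_integer_, status = "no_model_for_length")
    for (L in unique(nchar(peptides))) {
      p <- get_pssm(lib, allele, L)
      if (is.null(p)) next
      rows <- which(nchar(peptides) == L)
      s <- score_peptides(p, peptides[rows])
      out$binding_score[rows] <- s
      out$binder_by_score[rows] <- s > 0
      out$ic50_nM[rows] <- score_to_ic50(s, transform)
      out$class[rows] <- classify_affinity(out$ic50_nM[rows], transform)
      out$status[rows] <- "ok"
    }
    return(out)
  }

  if (is.null(sim))
    stop("allele ", allele, " has no trained PSSM and no similarity ",
         "library was supplied")
  res <- predict_pan(peptides, allele, lib, sim, top_k = top_k,
                     transform = transform)
  data.frame(peptide = res$peptide, allele = res$allele, mode = res$mode,
             binding_score = NA_real_, binder_by_score = NA,
             ic50_nM = res$ic50_nM, class = res$class,
             n_neighbors = res$n_neighbors,
             status = ifelse(res$n_neighbors > 0L, "ok",
                             "no_model_for_length"))
}
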