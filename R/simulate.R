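# Seeded synthetic fixtures: planted binding motifs, binder samples, and
# synthetic HLA protein sequence sets. These emulate the statistical
# structure the method assumes — fixed-length peptides with 2 anchor
# positions of strong residue preference over a near-background remainder,
# and HLA class I heavy chains that are highly similar across alleles —
# so every module is testable without external downloads.

#' Make a planted binding-motif profile
#'
#' A per-position residue probability profile of the given length. Anchor
#' columns place `dominance` probability on one seeded-random residue and
#' distribute the remainder proportionally to background; non-anchor
#' columns equal the background. Defaults (2 anchors, dominance 0.7)
#' emulate published class I binding motifs.
#'
#' @param length Peptide length.
#' @param anchors Integer vector of anchor column indices within
#'   `1..length` (default positions 2 and `length`, the canonical class I
#'   anchors).
#' @param dominance Anchor residue probability in (max background, 1].
#' @param background Named background frequency vector.
#' @param seed Optional integer seed (`NULL` = ambient RNG).
#' @return Object of class `motif_profile`: list with `length`, `columns`
#'   (20 x length probability matrix, columns sum to 1), `anchors`,
#'   `dominance`, `anchor_residues`.
#' @export
make_motif_profile <- function(length, anchors = c(2L, length),
                               dominance = 0.7,
                               background = uniprot_background(),
                               seed = NULL) {
  stopifnot(length >= 1L)
  anchors <- unique(as.integer(anchors))
  background <- validate_background(background)
  if (length(anchors) && (any(anchors < 1L) || any(anchors > length)))
    stop("anchor positions must lie in 1..", length)
  if (dominance <= max(background))
    stop("ineffective anchor: dominance (", dominance,
         ") must exceed the maximum background frequency (",
         signif(max(background), 3L), ")")
  if (dominance > 1) stop("dominance must be <= 1")
  with_seed_if(seed, {
    cols <- matrix(background, nrow = 20L, ncol = length,
                   dimnames = list(AMINO_ACIDS, NULL))
    anchor_res <- character(0)
    for (a in anchors) {
      res <- sample(AMINO_ACIDS, 1L)
      anchor_res <- c(anchor_res, res)
      rest <- background
      rest[res] <- 0
      col <- (1 - dominance) * rest / sum(rest)
      col[res] <- dominance
      cols[, a] <- col
    }
    stopifnot(all(abs(colSums(cols) - 1) < 1e-9))
    structure(list(length = length, columns = cols, anchors = anchors,
                   dominance = dominance,
                   anchor_residues = setNames(anchor_res,
                                              as.character(anchors))),
              class = "motif_profile")
  })
}

#' Sample binder peptides from a motif profile
#'
#' Independent per-column sampling from the profile probabilities.
#'
#' @param profile A [make_motif_profile()] object.
#' @param n Number of peptides.
#' @param seed Optional integer seed.
#' @return Character vector of `n` peptides of the profile length.
#' @export
sample_binders <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "motif_profile"), n >= 1L)
  with_seed_if(seed, {
    chars <- vapply(seq_len(profile$length), function(j)
      sample(AMINO_ACIDS, n, replace = TRUE, prob = profile$columns[, j]),
      character(n))
    chars <- matrix(chars, nrow = n)
    apply(chars, 1L, paste, collapse = "")
  })
}

#' Simulate a set of HLA class I protein sequences
#'
#' Draws one seeded ancestor sequence (default length 365, a typical
#' class I heavy chain) from background frequencies; each allele is the
#' ancestor with i.i.d. residue substitutions at `mutation_rate`, so
#' pairwise identity is about `(1 - mutation_rate)^2`. Names follow the
#' normalized allele grammar (`HLA-A*90:01`, `HLA-A*90:02`, ...).
#' Uncharacterized alleles generated with `copy_of` set are exact copies
#' of that characterized allele — the fixture for the pan-specific
#' consistency checks.
#'
#' @param n_characterized,n_uncharacterized Counts of alleles of each
#'   kind.
#' @param mutation_rate Per-site substitution probability in `[0, 0.5]`.
#' @param seed Optional integer seed.
#' @param length Ancestor length.
#' @param background Named background frequency vector.
#' @param copy_of Optional: name (or index into the characterized set) of
#'   the characterized allele that the FIRST uncharacterized allele copies
#'   exactly.
#' @return List with `sequences` (named character vector),
#'   `characterized`, `uncharacterized` (allele name vectors).
#' @export
make_synthetic_hla_set <- function(n_characterized, n_uncharacterized = 0L,
                                   mutation_rate = 0.02, seed = NULL,
                                   length = 365L,
                                   background = uniprot_background(),
                                   copy_of = NULL) {
  stopifnot(n_characterized >= 1L, n_uncharacterized >= 0L,
            mutation_rate >= 0, mutation_rate <= 0.5)
  background <- validate_background(background)
  with_seed_if(seed, {
    ancestor <- sample(AMINO_ACIDS, length, replace = TRUE,
                       prob = background)
    mutate <- function(chars) {
      hit <- runif(length) < mutation_rate
      if (any(hit))
        chars[hit] <- sample(AMINO_ACIDS, sum(hit), replace = TRUE,
                             prob = background)
      chars
    }
    char_names <- sprintf("HLA-A*90:%02d", seq_len(n_characterized))
    unchar_names <- if (n_uncharacterized > 0L)
      sprintf("HLA-B*90:%02d", seq_len(n_uncharacterized)) else character(0)
    seqs <- c(
      vapply(char_names, function(nm) paste(mutate(ancestor), collapse = ""),
             character(1)),
      vapply(unchar_names, function(nm) paste(mutate(ancestor), collapse = ""),
             character(1)))
    if (!is.null(copy_of) && n_uncharacterized > 0L) {
      target <- if (is.numeric(copy_of)) char_names[copy_of] else
        normalize_allele(copy_of)
      stopifnot(target %in% char_names)
      seqs[unchar_names[1L]] <- seqs[[target]]
    }
    list(sequences = seqs, characterized = char_names,
         uncharacterized = unchar_names)
  })
}

#' Fixture writers
#'
#' Emit the plain-text dialects consumed by the other modules: the
#' training TSV (`allele`, `peptide`, `label`), a multi-FASTA of HLA
#' protein sequences, and the mutation TSV.
#'
#' @param records Data frame with `allele`, `peptide` and optionally
#'   `label`.
#' @param path Output path.
#' @export
write_training_table <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("allele", "peptide") %in% names(records)))
  if (is.null(records$label)) records$label <- "binder"
  write.table(records[c("allele", "peptide", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_table
#' @param sequences Named character vector of protein sequences.
#' @export
write_hla_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_training_table
#' @param mutations Data frame with the [read_mutation_table()] columns.
#' @export
write_mutation_table <- function(mutations, path) {
  need <- c("protein_id", "position", "kind", "ref_aa", "alt_aa")
  stopifnot(is.data.frame(mutations), all(need %in% names(mutations)))
  write.table(mutations[need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
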