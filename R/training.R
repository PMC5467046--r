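# Training data I/O: parse, clean, and group (allele, peptide) binder
# tables into per-(allele, length) binder sets.

#' Load a training table
#'
#' Tab-separated file with a header naming at least `allele` and `peptide`;
#' an optional `label` column ("binder"/"nonbinder") defaults to "binder".
#' Rows are parsed with line-number provenance and are NOT filtered here;
#' see [clean_training()].
#'
#' @param path TSV path.
#' @return Data frame with columns `line`, `allele`, `peptide`, `label`,
#'   `source_tag` (empty string when absent from the file).
#' @export
load_training_table <- function(path) {
  if (!file.exists(path)) stop("cannot read training table: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty training table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  for (need in c("allele", "peptide"))
    if (!need %in% header)
      stop("training table ", path, " is missing required column '", need, "'")
  ncol_expect <- length(header)
  body <- fields[-1L]
  body <- body[!vapply(body, function(f) all(!nzchar(f)), logical(1))]
  if (length(body) == 0L)
    return(data.frame(line = integer(0), allele = character(0),
                      peptide = character(0), label = character(0),
                      source_tag = character(0)))
  nf <- lengths(body)
  if (any(nf != ncol_expect)) {
    bad <- which(nf != ncol_expect)[1L]
    stop("training table ", path, " line ", bad + 1L, ": expected ",
         ncol_expect, " fields, found ", nf[bad])
  }
  get_col <- function(name, default = NULL) {
    i <- match(name, header)
    if (is.na(i)) return(rep(default, length(body)))
    vapply(body, `[`, character(1), i)
  }
  out <- data.frame(
    line = seq_along(body) + 1L,
    allele = get_col("allele"),
    peptide = get_col("peptide"),
    label = tolower(get_col("label", default = "binder")),
    source_tag = get_col("source", default = ""))
  bad_label <- !out$label %in% c("binder", "nonbinder")
  if (any(bad_label))
    stop("training table ", path, " line ", out$line[bad_label][1L],
         ": label must be 'binder' or 'nonbinder'")
  out
}

#' Clean training records
#'
#' Applies the data-cleaning rules, in order, recording one reason per
#' dropped row:
#' 1. `abnormal_residue` — the peptide contains B, J, O, U, X, Z or any
#'    other non-canonical character (sequences are uppercased first);
#' 2. `bad_allele` — the allele name does not normalize;
#' 3. `length` — peptide length outside 8..25;
#' 4. `duplicate` — an exact (allele, peptide, label) triple already kept
#'    (the same peptide under two alleles is NOT a duplicate).
#'
#' Kept plus dropped counts always equal the input count, and cleaning is
#' idempotent.
#'
#' @param records Data frame from [load_training_table()] (columns `allele`,
#'   `peptide`, `label`; `line` optional).
#' @return List with `kept` (records with normalized alleles and uppercased
#'   peptides) and `dropped` (columns `line`, `allele`, `peptide`,
#'   `reason`).
#' @export
clean_training <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("allele", "peptide") %in% names(records)))
  n <- nrow(records)
  if (is.null(records$label)) records$label <- "binder"
  if (is.null(records$line)) records$line <- seq_len(n)
  peptide <- toupper(records$peptide)
  reason <- rep(NA_character_, n)

  ok_residues <- !grepl(sprintf("[^%s]", paste(AMINO_ACIDS, collapse = "")),
                        peptide) & nzchar(peptide)
  reason[!ok_residues] <- "abnormal_residue"

  norm <- rep(NA_character_, n)
  todo <- which(is.na(reason))
  norm[todo] <- vapply(records$allele[todo], function(a) {
    tryCatch(suppressMessages(normalize_allele(a)),
             error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  reason[is.na(reason) & is.na(norm)] <- "bad_allele"

  len <- nchar(peptide)
  bad_len <- len < PEPTIDE_LENGTH_RANGE[1L] | len > PEPTIDE_LENGTH_RANGE[2L]
  reason[is.na(reason) & bad_len] <- "length"

  key <- paste(norm, peptide, records$label, sep = "\r")
  dup <- duplicated(key)
  reason[is.na(reason) & dup] <- "duplicate"

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  kept$allele <- norm[keep]
  kept$peptide <- peptide[keep]
  rownames(kept) <- NULL
  dropped <- data.frame(line = records$line[!keep],
                        allele = records$allele[!keep],
                        peptide = records$peptide[!keep],
                        reason = reason[!keep])
  list(kept = kept, dropped = dropped)
}

#' Group cleaned records into per-(allele, length) binder sets
#'
#' Keeps binder-labeled records only, groups them by (allele, peptide
#' length), and excludes groups with fewer than `min_binders` members
#' (default 10, the minimum training-set size for one PSSM). Every kept
#' binder lands in exactly one group or one excluded-report row.
#'
#' @param records Cleaned records (the `kept` element of [clean_training()]).
#' @param min_binders Minimum group size to train on.
#' @return Named list of peptide character vectors, names `"<allele>|<N>"`;
#'   attribute `"excluded"` is a data frame (`allele`, `length`, `n`) of
#'   under-threshold groups.
#' @export
group_for_training <- function(records, min_binders = 10L) {
  stopifnot(is.data.frame(records), min_binders >= 1L)
  empty <- structure(list(),
                     excluded = data.frame(allele = character(0),
                                           length = integer(0),
                                           n = integer(0)))
  if (nrow(records) == 0L) return(empty)
  if (is.null(records$label)) records$label <- "binder"
  b <- records[records$label == "binder", , drop = FALSE]
  if (nrow(b) == 0L) return(empty)
  key <- lib_key(b$allele, nchar(b$peptide))
  groups <- split(b$peptide, key)
  sizes <- lengths(groups)
  small <- groups[sizes < min_binders]
  excluded <- data.frame(
    allele = sub("\\|.*$", "", names(small)),
    length = as.integer(sub("^.*\\|", "", names(small))),
    n = unname(lengths(small)))
  structure(groups[sizes >= min_binders], excluded = excluded)
}

#' Train a PSSM library from grouped binder sets
#'
#' Builds one PSSM per (allele, length) group; a convenience composing
#' [group_for_training()] output with [build_pssm()].
#'
#' @param groups Named list from [group_for_training()].
#' @inheritParams build_pssm
#' @return A [pssm_library()].
#' @export
train_library <- function(groups, background = uniprot_background(),
                          omega = omega_policy(), log_base = exp(1)) {
  if (length(groups) == 0L) stop("no trainable groups")
  pssm_library(lapply(names(groups), function(key) {
    allele <- sub("\\|.*$", "", key)
    build_pssm(groups[[key]], background = background, omega = omega,
               log_base = log_base, allele = allele)
  }))
}
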