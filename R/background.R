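# Background amino-acid frequencies.
#
# The log-odds denominator BG_a is the proportion of each residue expected
# by chance. The bundled table is the UniProtKB/Swiss-Prot proteome-wide
# amino-acid composition (percent values as released circa 2017), pinned
# here so that models are reproducible without a network fetch; it is
# renormalized to sum exactly to 1.

.UNIPROT_COMPOSITION <- c(
  A = 8.26, C = 1.37, D = 5.46, E = 6.74, F = 3.86,
  G = 7.08, H = 2.27, I = 5.94, K = 5.82, L = 9.67,
  M = 2.41, N = 4.06, P = 4.71, Q = 3.93, R = 5.53,
  S = 6.60, T = 5.34, V = 6.87, W = 1.09, Y = 2.92)

#' Background amino-acid frequencies
#'
#' Returns the bundled UniProt-derived background proportions `BG_a` used as
#' the denominator of the PSSM log-odds, a named numeric vector over the 20
#' canonical residues in fixed alphabetical order, summing to 1.
#'
#' @return Named numeric vector of length 20.
#' @examples
#' bg <- uniprot_background()
#' sum(bg)  # 1
#' @export
uniprot_background <- function() {
  validate_background(.UNIPROT_COMPOSITION / sum(.UNIPROT_COMPOSITION))
}

validate_background <- function(freq) {
  if (!is.numeric(freq) || length(freq) != 20L)
    stop("background must be a numeric vector of 20 frequencies")
  if (is.null(names(freq)) || !setequal(names(freq), AMINO_ACIDS))
    stop("background must be named by the 20 canonical amino acids")
  freq <- freq[AMINO_ACIDS]
  if (any(freq <= 0)) stop("background frequencies must all be > 0")
  if (abs(sum(freq) - 1) > 1e-9)
    stop("background frequencies must sum to 1 (got ", sum(freq), ")")
  freq
}

#' Read / write a background-frequency table
#'
#' Two-column headerless TSV, one row per residue: `<AA>\t<freq>`, 20 rows.
#' Frequencies must be positive and sum to 1 within 1e-9.
#'
#' @param path File path.
#' @param freq Named numeric vector over the 20 canonical residues.
#' @return `read_background()` returns the named frequency vector in
#'   alphabetical residue order; `write_background()` returns `path`
#'   invisibly.
#' @export
read_background <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("aa", "freq"),
                    colClasses = c("character", "numeric"))
  if (nrow(tab) != 20L)
    stop("background file ", path, " must have 20 rows, found ", nrow(tab))
  validate_background(setNames(tab$freq, toupper(tab$aa)))
}

#' @rdname read_background
#' @export
write_background <- function(freq, path) {
  freq <- validate_background(freq)
  write.table(data.frame(aa = names(freq), freq = freq), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
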