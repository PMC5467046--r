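#' Normalize an HLA class I allele name
#'
#' Canonicalizes the allele spellings found in the wild to the two-field
#' form `HLA-<locus>*<group>:<protein>`, e.g. `"A*0201"`, `"HLA-A*0201"`,
#' `"HLA-A02:01"` and `"HLA-A*02:01"` all normalize to `"HLA-A*02:01"`.
#' Fields beyond the second (synonymous substitutions etc.) are truncated
#' with a message; unrecognizable strings are an error, never a guess.
#' Normalization is idempotent and vectorized.
#'
#' @param raw Character vector of allele names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_allele(c("A*0201", "HLA-B*5701", "HLA-A*02:01"))
#' @export
normalize_allele <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw) || anyNA(raw))
    stop("allele names must be a character vector without NA")
  vapply(raw, normalize_allele_one, character(1), USE.NAMES = FALSE)
}

normalize_allele_one <- function(raw) {
  x <- toupper(trimws(raw))
  x <- sub("^HLA-", "", x)
  m <- regmatches(x, regexec("^([A-CEFG])\\*?([0-9:]+)$", x))[[1]]
  if (length(m) == 0L)
    stop("unrecognized HLA class I allele name: '", raw, "'")
  locus <- m[2]
  digits <- m[3]
  if (grepl(":", digits)) {
    fields <- strsplit(digits, ":", fixed = TRUE)[[1]]
    if (length(fields) < 2L || !all(nzchar(fields)) ||
        !all(grepl("^[0-9]{2,3}$", fields[1:2])))
      stop("unrecognized HLA class I allele name: '", raw, "'")
    if (length(fields) > 2L)
      message("allele '", raw, "' truncated to two-field resolution")
    fields <- fields[1:2]
  } else if (nchar(digits) == 4L) {
    # compact four-digit legacy form, split two/two
    fields <- c(substr(digits, 1, 2), substr(digits, 3, 4))
  } else if (nchar(digits) == 5L) {
    # five digits: three-digit allele group + two-digit protein
    fields <- c(substr(digits, 1, 3), substr(digits, 4, 5))
  } else {
    stop("unrecognized HLA class I allele name: '", raw, "'")
  }
  sprintf("HLA-%s*%s:%s", locus, fields[1], fields[2])
}
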