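# Model store: a library of PSSMs keyed by (allele, length), with
# plain-text serialization.
#
# File format, one file per (allele, length):
#   #allele=HLA-A*02:01
#   #length=9
#   #log_base=2.71828
#   #omega=fixed:0.02:NA
#   #n_binders=120
#   A<TAB>v1<TAB>...<TAB>vN      (20 rows, fixed alphabetical residue order,
#   ...                           values rendered with 6 significant digits)

lib_key <- function(allele, length) paste0(allele, "|", length)

#' Create a PSSM library
#'
#' A container mapping (normalized allele, peptide length) to a [build_pssm()]
#' model. Lookups normalize the query name, so `"A*0201"` finds the entry
#' stored under `"HLA-A*02:01"`.
#'
#' @param pssms Optional list of `pssm` objects (each must carry an allele).
#' @return An object of class `pssm_library`.
#' @export
pssm_library <- function(pssms = list()) {
  lib <- structure(list(entries = list()), class = "pssm_library")
  for (p in pssms) lib <- add_pssm(lib, p)
  lib
}

#' @rdname pssm_library
#' @param lib A `pssm_library`.
#' @param pssm A `pssm` with a non-missing allele.
#' @export
add_pssm <- function(lib, pssm) {
  stopifnot(inherits(lib, "pssm_library"), inherits(pssm, "pssm"))
  if (is.na(pssm$allele)) stop("PSSM must carry an allele to enter a library")
  key <- lib_key(pssm$allele, pssm$length)
  if (!is.null(lib$entries[[key]]))
    stop("duplicate library entry for ", pssm$allele, " length ", pssm$length)
  lib$entries[[key]] <- pssm
  lib
}

#' @rdname pssm_library
#' @param allele Allele name, normalized on lookup.
#' @param length Peptide length.
#' @export
get_pssm <- function(lib, allele, length) {
  stopifnot(inherits(lib, "pssm_library"))
  lib$entries[[lib_key(normalize_allele(allele), length)]]
}

#' @rdname pssm_library
#' @export
characterized_alleles <- function(lib) {
  stopifnot(inherits(lib, "pssm_library"))
  unique(vapply(lib$entries, function(p) p$allele, character(1),
                USE.NAMES = FALSE))
}

#' @export
print.pssm_library <- function(x, ...) {
  cat(sprintf("PSSM library: %d models, %d alleles\n",
              length(x$entries), length(characterized_alleles(x))))
  invisible(x)
}

#' Write / read a single PSSM file
#'
#' Plain-text format with `#key=value` headers followed by 20 tab-separated
#' data rows in fixed alphabetical residue order; matrix values are
#' rendered with 6 significant digits (the round-trip contract).
#'
#' @param pssm A `pssm` object.
#' @param path File path.
#' @return `read_pssm()` returns a `pssm`; `write_pssm()` returns `path`
#'   invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  om <- pssm$omega
  om_val <- if (om$mode == "fixed") om$fixed_value else om$concentration
  om_seed <- if (om$mode == "fixed") "NA" else om$seed
  header <- c(
    sprintf("#allele=%s", pssm$allele),
    sprintf("#length=%d", pssm$length),
    sprintf("#log_base=%s", formatC(pssm$log_base, digits = 6, format = "g")),
    sprintf("#omega=%s:%s:%s", om$mode,
            formatC(om_val, digits = 6, format = "g"), om_seed),
    sprintf("#n_binders=%d", pssm$n_training_binders))
  rows <- vapply(seq_len(20L), function(i)
    paste(c(AMINO_ACIDS[i],
            formatC(pssm$matrix[i, ], digits = 6, format = "g")),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  for (need in c("allele", "length", "log_base", "omega", "n_binders"))
    if (!need %in% names(meta))
      stop("malformed PSSM file ", path, ": missing header #", need)
  data <- lines[!is_hdr & nzchar(lines)]
  if (length(data) != 20L)
    stop("malformed PSSM file ", path, ": expected 20 amino-acid rows, found ",
         length(data), " (line ", sum(is_hdr) + length(data) + 1L, ")")
  parts <- strsplit(data, "\t", fixed = TRUE)
  aa <- vapply(parts, `[`, character(1), 1L)
  if (!identical(aa, AMINO_ACIDS))
    stop("malformed PSSM file ", path,
         ": amino-acid rows out of order or mislabeled")
  N <- as.integer(meta["length"])
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  if (any(lengths(vals) != N) || anyNA(unlist(vals)))
    stop("malformed PSSM file ", path, ": expected ", N,
         " numeric values per row")
  om_parts <- strsplit(meta["omega"], ":", fixed = TRUE)[[1]]
  om <- if (om_parts[1] == "fixed")
    omega_policy("fixed", fixed_value = as.numeric(om_parts[2]))
  else
    omega_policy("dirichlet", concentration = as.numeric(om_parts[2]),
                 seed = as.integer(om_parts[3]))
  structure(list(
    allele = normalize_allele(meta[["allele"]]),
    length = N,
    matrix = matrix(unlist(vals), nrow = 20L, byrow = TRUE,
                    dimnames = list(AMINO_ACIDS, NULL)),
    log_base = as.numeric(meta["log_base"]),
    n_training_binders = as.integer(meta["n_binders"]),
    omega = om), class = "pssm")
}

pssm_filename <- function(allele, length) {
  sprintf("%s.%d.pssm", gsub("*", "_", allele, fixed = TRUE), length)
}

#' Save / load a PSSM library directory
#'
#' One `.pssm` file per (allele, length) entry plus a `manifest.tsv` with
#' columns `allele`, `length`, `n_binders`, `file`. `load_library()` of a
#' saved directory reproduces every matrix entry to 6 significant digits
#' and all metadata exactly; a directory with no `.pssm` files yields an
#' empty library with a warning.
#'
#' @param lib A `pssm_library`.
#' @param dir Directory path (created if needed).
#' @return `save_library()` returns the manifest data frame invisibly;
#'   `load_library()` returns a `pssm_library`.
#' @export
save_library <- function(lib, dir) {
  stopifnot(inherits(lib, "pssm_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(unname(lib$entries), function(p) {
    f <- pssm_filename(p$allele, p$length)
    write_pssm(p, file.path(dir, f))
    data.frame(allele = p$allele, length = p$length,
               n_binders = p$n_training_binders, file = f)
  }))
  if (is.null(manifest))
    manifest <- data.frame(allele = character(0), length = integer(0),
                           n_binders = integer(0), file = character(0))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
  if (length(files) == 0L) {
    warning("no .pssm files in ", dir, "; returning an empty library")
    return(pssm_library())
  }
  pssm_library(lapply(sort(files), read_pssm))
}
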