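#' Read and write MAF-like mutation tables
#'
#' Tab-separated, one row per variant, 1-based fully-closed coordinates,
#' with the read-level evidence columns the filter cascade consumes.
#'
#' @param path File path.
#' @return `read_maf()` returns a tibble.
#' @export
read_maf <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

#' @rdname read_maf
#' @param maf Mutation tibble.
#' @export
write_maf <- function(maf, path) {
  readr::write_tsv(maf, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of gene identifier character vectors.
#' @export
read_gene_sets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, "", 1))
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of gene vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
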