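#' Trinucleotide substitution channel labels
#'
#' The 96 single-base-substitution channels in the standard pyrimidine-centred
#' order: substitution class major (C>A, C>G, C>T, T>A, T>C, T>G), then the 5'
#' base and the 3' base each in alphabetical order, formatted as `A[C>A]A`.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }))
}

# peak helper: channels for a substitution class with given 5'/3' bases
.chan <- function(sub, p5 = c("A", "C", "G", "T"), p3 = c("A", "C", "G", "T")) {
  as.vector(outer(p5, p3, function(a, b) paste0(a, "[", sub, "]", b)))
}

#' Synthetic 13-signature breast cancer catalogue
#'
#' A stand-in for the COSMIC v2 breast cancer signature matrix (signatures
#' 1, 2, 13, 3, 8, 6, 15, 20, 26, 5, 17, 18 and 30). The true catalogue is a
#' licensed download; this synthetic version reproduces the qualitative peak
#' structure of each signature (e.g. C>T at NpCpG for the ageing-like
#' Signature 1, `T[C>T]N`/`T[C>G]N` peaks for the APOBEC-like Signatures 2
#' and 13, a near-flat profile for the HR-deficiency-like Signature 3) so
#' that refitting, recovery and carrier statistics behave realistically.
#' Columns sum to 1. For real analyses load the actual COSMIC matrix with
#' [read_signature_catalog()].
#'
#' @return A 96 x 13 numeric matrix; rows are [sbs_channels()], columns are
#'   `"Signature.1"`, `"Signature.2"`, ... in the catalogue order above.
#' @export
synthetic_signature_catalog <- function() {
  ch <- sbs_channels()
  base <- setNames(rep(1, 96), ch)

  mk <- function(peaks, weight = 30, flat = 1) {
    pr <- setNames(rep(flat, 96), ch)
    pr[peaks] <- pr[peaks] + weight
    pr / sum(pr)
  }

  sigs <- list(
    # ageing-like: C>T at NpCpG
    Signature.1 = mk(.chan("C>T", p3 = "G"), weight = 60),
    # APOBEC-like C>T at TpCpN
    Signature.2 = mk(.chan("C>T", p5 = "T", p3 = c("A", "T")), weight = 90),
    # APOBEC-like C>G at TpCpN
    Signature.13 = mk(.chan("C>G", p5 = "T", p3 = c("A", "T")), weight = 90),
    # HR-deficiency-like: flat
    Signature.3 = base / sum(base),
    # broad C>A
    Signature.8 = mk(.chan("C>A"), weight = 12),
    # MMR-like C>T
    Signature.6 = mk(.chan("C>T", p5 = "G", p3 = c("A", "C")), weight = 70),
    Signature.15 = mk(.chan("C>T", p5 = "A", p3 = c("C", "T")), weight = 70),
    Signature.20 = mk(c(.chan("C>T", p5 = "C", p3 = "A"),
                        .chan("T>C", p5 = "A", p3 = "A")), weight = 55),
    Signature.26 = mk(.chan("T>C", p5 = c("C", "G")), weight = 35),
    # clock-like, mild T>C lean
    Signature.5 = mk(c(.chan("T>C"), .chan("C>T")), weight = 4),
    # T>G at NpTpT with CpTpT peak
    Signature.17 = mk(.chan("T>G", p5 = c("C", "G"), p3 = "T"), weight = 110),
    # C>A peaks
    Signature.18 = mk(.chan("C>A", p5 = c("G", "T"), p3 = c("A", "T")),
                      weight = 60),
    Signature.30 = mk(.chan("C>T", p5 = c("A", "C"), p3 = "A"), weight = 50)
  )
  m <- do.call(cbind, sigs)
  rownames(m) <- ch
  # catalogue order as used for breast tumours
  m[, paste0("Signature.", c(1, 2, 13, 3, 8, 6, 15, 20, 26, 5, 17, 18, 30))]
}

#' Read and write a signature catalogue TSV
#'
#' The file has channels in the first column (labels as in [sbs_channels()],
#' any order) and one column per signature with channel probabilities.
#'
#' @param path File path.
#' @return `read_signature_catalog()` returns a 96 x K matrix with channel
#'   rownames ordered as [sbs_channels()].
#' @export
read_signature_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ch <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ch
  bad <- setdiff(sbs_channels(), ch)
  if (length(bad)) {
    cc_abort(sprintf("catalogue is missing %d channels (e.g. %s)",
                     length(bad), bad[1]))
  }
  m <- m[sbs_channels(), , drop = FALSE]
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6) || any(m < 0)) {
    cc_abort("catalogue columns must be non-negative and sum to 1")
  }
  m
}

#' @rdname read_signature_catalog
#' @param catalog A 96 x K matrix as returned by [synthetic_signature_catalog()].
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- tibble::as_tibble(catalog)
  df <- dplyr::bind_cols(tibble::tibble(channel = rownames(catalog)), df)
  readr::write_tsv(df, path)
  invisible(path)
}
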