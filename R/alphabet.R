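#' RNA alphabet utilities
#'
#' All sequences inside the package are RNA (`A`, `C`, `G`, `U`).  DNA input
#' (`T`, lower case, either alphabet) is accepted everywhere and silently
#' normalized: EST and transcript databases are typically DNA while small-RNA
#' tables are RNA, and nothing downstream cares about the difference.
#'
#' @param x character vector of nucleotide sequences.
#' @return `normalize_rna()`: the sequences upper-cased with `T` replaced by
#'   `U`.  `revcomp_rna()`: the reverse complements (RNA alphabet).
#' @examples
#' normalize_rna("acgt")      # "ACGU"
#' revcomp_rna("AAGC")        # "GCUU"
#' @export
normalize_rna <- function(x) {
  x <- toupper(as.character(x))
  chartr("T", "U", x)
}

#' @rdname normalize_rna
#' @export
revcomp_rna <- function(x) {
  x <- normalize_rna(x)
  out <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# error unless every sequence is non-empty {A,C,G,U} after normalization
check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x) | !nzchar(x)
  if (any(bad)) {
    abort(sprintf("%s %s is not a valid non-empty A/C/G/U sequence",
                  what, which(bad)[1]))
  }
  invisible(x)
}

# RNA -> DNA view for Biostrings matching
rna_to_dna <- function(x) chartr("U", "T", normalize_rna(x))

# optional-column accessor (tibbles warn on `$` for missing columns)
tbl_col <- function(tbl, name) {
  if (name %in% names(tbl)) tbl[[name]] else NULL
}
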