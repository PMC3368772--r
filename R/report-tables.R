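#' Published rubber-tree mature miRNA set
#'
#' Mature miRNA sequences reported for *Hevea brasiliensis* (conserved
#' families and putatively novel miRNAs with their precursor lengths and
#' star-strand support), bundled as a worked example and validation input
#' for the report builders.
#'
#' @return tibble: `name`, `accession`, `mature_sequence`, `star_support`,
#'   `precursor_length`, `source`, `set`.
#' @export
hevea_mature_mirnas <- function() {
  path <- system.file("extdata", "hevea_mature_mirnas.tsv",
                      package = "mirforge", mustWork = TRUE)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Precursor report table
#'
#' Builds the standard precursor report (miRNA name, accession, mature
#' sequence and its computed length, star support, precursor length, source
#' transcript) from a table of mature sequences, normalizing the alphabet
#' and computing `mature_length` from the sequence itself.
#'
#' @param tbl tibble with at least `name` and `mature_sequence`; optional
#'   `accession`, `star_support`, `precursor_length`, `source`.
#' @return tibble with the report columns, `mature_length` included.
#' @export
precursor_report <- function(tbl) {
  if (is.null(tbl_col(tbl, "mature_sequence"))) abort("`mature_sequence` column required")
  seqs <- normalize_rna(tbl$mature_sequence)
  check_rna_alphabet(seqs, "mature sequence")
  tibble(
    name = if (!is.null(tbl_col(tbl, "name"))) tbl$name else NA_character_,
    accession = if (!is.null(tbl_col(tbl, "accession"))) tbl$accession else NA_character_,
    mature_sequence = seqs,
    mature_length = nchar(seqs),
    star_support = if (!is.null(tbl_col(tbl, "star_support"))) tbl$star_support else NA_character_,
    precursor_length = if (!is.null(tbl_col(tbl, "precursor_length"))) tbl$precursor_length else NA_integer_,
    source = if (!is.null(tbl_col(tbl, "source"))) tbl$source else NA_character_
  )
}
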