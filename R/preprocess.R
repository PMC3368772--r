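#' Trim the 3' adapter off raw small-RNA reads
#'
#' A read produced from a short insert runs into the 3' sequencing adapter, so
#' the adapter appears as a suffix of the read that matches a prefix of the
#' adapter sequence.  Trimming removes the leftmost such suffix/prefix overlap
#' of at least `min_clip` nucleotides (the leftmost qualifying match removes
#' the longest adapter stretch and so leaves the shortest insert consistent
#' with the evidence).  Reads showing no adapter evidence are dropped by
#' default; librarians who size-select tightly may prefer `keep_untrimmed =
#' TRUE`.
#'
#' @param seqs character vector of read sequences (RNA or DNA alphabet).
#' @param adapter3 the 3' adapter sequence; must be at least `min_clip` long.
#' @param min_clip minimum adapter overlap required to trim (default 6 nt).
#' @param max_mismatch substitutions tolerated inside the overlap (0, the
#'   default, or 1).
#' @param keep_untrimmed keep reads without adapter evidence untouched instead
#'   of rejecting them.
#' @return character vector of inserts, `NA` for rejected reads.
#' @examples
#' trim_adapter("UUGACAGAAGAUAGAGAGCUCGUAU", "UCGUAUGCCGUCUUCUGCUUG")
#' @export
trim_adapter <- function(seqs, adapter3, min_clip = 6L, max_mismatch = 0L,
                         keep_untrimmed = FALSE) {
  adapter3 <- normalize_rna(adapter3)
  if (nchar(adapter3) < min_clip) {
    abort("adapter is shorter than `min_clip`")
  }
  seqs <- normalize_rna(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    # leftmost i such that s[i..n] matches adapter prefix of length n-i+1
    for (i in seq_len(n)) {
      ov <- n - i + 1L
      if (ov < min_clip) break
      if (ov > nchar(adapter3)) next
      mm <- sum(utf8ToInt(substr(s, i, n)) != utf8ToInt(substr(adapter3, 1L, ov)))
      if (mm <= max_mismatch) {
        return(if (i == 1L) NA_character_ else substr(s, 1L, i - 1L))
      }
    }
    if (keep_untrimmed) s else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Length-filter small RNA inserts
#'
#' Keeps sequences whose length falls in `[min_len, max_len]`.  Defaults are
#' the 17-32 nt window typical of plant small RNA libraries.
#'
#' @param seqs character vector of sequences.
#' @param min_len,max_len inclusive length bounds.
#' @return logical vector, `TRUE` where the sequence is kept.
#' @export
filter_length <- function(seqs, min_len = 17L, max_len = 32L) {
  if (min_len > max_len) abort("`min_len` must be <= `max_len`")
  n <- nchar(seqs)
  n >= min_len & n <= max_len
}

new_srna_library <- function(tbl, total_raw = sum(tbl$count)) {
  tbl <- as_tibble(tbl)
  structure(tbl,
            class = c("srna_library", class(tbl)),
            total_raw = as.integer(total_raw),
            total_clean = as.integer(sum(tbl$count)))
}

#' Collapse reads into a counted unique-sequence library
#'
#' @param seqs character vector of clean (trimmed, length-filtered) read
#'   sequences.
#' @param total_raw number of raw reads before cleanup, for the summary
#'   statistics; defaults to `length(seqs)`.
#' @return A collapsed library: a tibble of class `srna_library` with columns
#'   `seq` and `count`, ordered by decreasing count then sequence, carrying
#'   `total_raw` and `total_clean` attributes.  The sum of `count` always
#'   equals the number of clean reads supplied.
#' @export
collapse_reads <- function(seqs, total_raw = length(seqs)) {
  seqs <- normalize_rna(seqs)
  if (length(seqs) == 0L) {
    return(new_srna_library(tibble(seq = character(), count = integer()),
                            total_raw = total_raw))
  }
  tab <- table(seqs)
  tbl <- tibble(seq = names(tab), count = as.integer(tab)) |>
    arrange(desc(.data$count), .data$seq)
  new_srna_library(tbl, total_raw = total_raw)
}

#' Length histogram of a collapsed library
#'
#' @param library an `srna_library`.
#' @return tibble with `length`, `unique_count` (distinct sequences) and
#'   `read_count` (reads, i.e. count-weighted) per length.
#' @export
length_histogram <- function(library) {
  library |>
    as_tibble() |>
    mutate(length = nchar(.data$seq)) |>
    group_by(.data$length) |>
    summarise(unique_count = n(), read_count = sum(.data$count), .groups = "drop") |>
    arrange(.data$length)
}

#' One-call cleanup of a raw read table
#'
#' Runs adapter trimming, optional mean-quality filtering, length filtering
#' and collapsing, and keeps per-stage drop counts for the run log.
#'
#' @param reads tibble with a `seq` column (e.g. from [read_fastq()] or
#'   [read_fasta()]); a `qual` column is used when `min_mean_qual` is set.
#' @param adapter3 3' adapter sequence; `NULL` skips trimming (pre-trimmed
#'   input).
#' @param min_clip,max_mismatch,keep_untrimmed see [trim_adapter()].
#' @param min_len,max_len see [filter_length()].
#' @param min_mean_qual optional mean Phred threshold; reads below it are
#'   dropped before trimming.  Default `NULL` (off).
#' @return An `srna_library` whose `dropped` attribute is a tibble of
#'   per-stage drop counts (`stage`, `reads`).
#' @export
preprocess_reads <- function(reads, adapter3 = NULL, min_clip = 6L,
                             max_mismatch = 0L, keep_untrimmed = FALSE,
                             min_len = 17L, max_len = 32L,
                             min_mean_qual = NULL) {
  total_raw <- nrow(reads)
  seqs <- normalize_rna(reads$seq)
  n_lowq <- 0L
  if (!is.null(min_mean_qual) && !is.null(tbl_col(reads, "qual"))) {
    mq <- vapply(reads$qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                 USE.NAMES = FALSE)
    keep <- is.na(mq) | mq >= min_mean_qual
    n_lowq <- sum(!keep)
    seqs <- seqs[keep]
  }
  n_noadapter <- 0L
  if (!is.null(adapter3)) {
    trimmed <- trim_adapter(seqs, adapter3, min_clip = min_clip,
                            max_mismatch = max_mismatch,
                            keep_untrimmed = keep_untrimmed)
    n_noadapter <- sum(is.na(trimmed))
    seqs <- trimmed[!is.na(trimmed)]
  }
  keep <- filter_length(seqs, min_len = min_len, max_len = max_len)
  n_len <- sum(!keep)
  lib <- collapse_reads(seqs[keep], total_raw = total_raw)
  attr(lib, "dropped") <- tibble(
    stage = c("low_quality", "no_adapter", "length_filter"),
    reads = c(n_lowq, n_noadapter, n_len)
  )
  lib
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library> %d unique sequences, %d clean reads (of %d raw)\n",
              nrow(x), attr(x, "total_clean"), attr(x, "total_raw")))
  NextMethod()
}

#' Summary statistics of a collapsed library
#'
#' @param x an `srna_library`.
#' @param ... unused.
#' @return one-row tibble: `total_raw`, `total_clean`, `unique_clean`,
#'   `singleton_fraction`, `doubleton_fraction` (fractions of unique
#'   sequences seen once / twice).
#' @importFrom generics glance
#' @export
glance.srna_library <- function(x, ...) {
  tibble(
    total_raw = attr(x, "total_raw"),
    total_clean = attr(x, "total_clean"),
    unique_clean = nrow(x),
    singleton_fraction = if (nrow(x)) mean(x$count == 1L) else NA_real_,
    doubleton_fraction = if (nrow(x)) mean(x$count == 2L) else NA_real_
  )
}

#' @importFrom generics glance tidy
#' @export
generics::glance

#' @export
generics::tidy
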