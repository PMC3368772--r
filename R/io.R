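#' Read a FASTA file into a tibble
#'
#' Sequences are normalized to the RNA alphabet (T accepted on input and
#' rewritten to U; case folded).  `key=value` tokens in the description line
#' (for example `category=miRNA` or `family=miR156`) are parsed into columns,
#' one per key seen anywhere in the file, so annotated reference sets and
#' mature miRNA databases come back ready to use.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `desc` plus one column per
#'   `key=value` tag found in the descriptions.  Record order is preserved.
#' @details Malformed input (text before the first header, a header with no
#'   sequence line, duplicated ids, non-nucleotide characters) raises an error
#'   naming the offending line.
#' @seealso [write_fasta()], [read_fastq()], [write_collapsed_fasta()]
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(id = character(), seq = character(), desc = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    abort(sprintf("FASTA parse error at line %d: sequence before first '>' header",
                  line_no[1]))
  }
  grp <- cumsum(is_hdr)
  hdr_idx <- which(is_hdr)
  header <- sub("^>", "", lines[hdr_idx])
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  seq <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[grp == i & !is_hdr], collapse = "")
  }, character(1))
  empty <- !nzchar(seq)
  if (any(empty)) {
    abort(sprintf("FASTA parse error at line %d: record '%s' has no sequence",
                  line_no[hdr_idx[which(empty)[1]]], id[which(empty)[1]]))
  }
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    abort(sprintf("FASTA parse error at line %d: duplicated id '%s'",
                  line_no[hdr_idx[which(id == dup)[2]]], dup))
  }
  seq <- normalize_rna(gsub("\\s", "", seq))
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    abort(sprintf("FASTA parse error at line %d: record '%s' contains non-nucleotide characters",
                  line_no[hdr_idx[which(bad)[1]]], id[which(bad)[1]]))
  }
  out <- tibble(id = id, seq = seq, desc = desc)
  add_desc_tags(out)
}

# parse key=value tokens of `desc` into columns
add_desc_tags <- function(tbl) {
  tok <- strsplit(tbl$desc, "\\s+")
  tagged <- lapply(tok, function(t) t[grepl("=", t, fixed = TRUE)])
  keys <- unique(unlist(lapply(tagged, function(t) sub("=.*$", "", t))))
  for (k in keys) {
    tbl[[k]] <- vapply(tagged, function(t) {
      hit <- t[startsWith(t, paste0(k, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, character(1))
  }
  tbl
}

#' Write sequences to FASTA
#'
#' @param tbl tibble with columns `id` and `seq`; an optional `desc` column is
#'   appended to the header after a space.
#' @param path output path.
#' @param width line-wrap width for sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path, width = 70L) {
  hdr <- paste0(">", tbl$id,
                if (!is.null(tbl_col(tbl, "desc"))) ifelse(nzchar(tbl$desc), paste0(" ", tbl$desc), "") else "")
  chunks <- lapply(seq_len(nrow(tbl)), function(i) {
    s <- tbl$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    c(hdr[i], substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(chunks, use.names = FALSE), path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Qualities are carried along as strings; the pipeline only uses them for the
#' optional mean-quality filter in [preprocess_reads()].
#'
#' @param path path to a FASTQ file.
#' @return tibble with columns `id`, `seq` (RNA alphabet), `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- S4Vectors::mcols(x)$qualities
  tibble(
    id = names(x),
    seq = normalize_rna(as.character(x)),
    qual = if (is.null(qual)) NA_character_ else as.character(qual)
  )
}

#' Write reads to FASTQ
#'
#' @param tbl tibble with `id` and `seq`; optional `qual` (defaults to "I",
#'   Phred 40, for every base).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(tbl, path) {
  qual <- if (!is.null(tbl_col(tbl, "qual")) && !anyNA(tbl$qual)) tbl$qual else
    vapply(nchar(tbl$seq), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", tbl$id), tbl$seq, "+", qual)), path)
  invisible(path)
}

#' Write a collapsed library as FASTA
#'
#' One record per unique sequence with header `acc_<i>_x<count>`, the
#' accession-plus-count dialect used throughout the reports.  The counterpart
#' [read_collapsed_fasta()] recovers the library bit-exactly.
#'
#' @param library a collapsed library from [collapse_reads()] (tibble with
#'   `seq`, `count`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(library, path) {
  if (nrow(library) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  tbl <- tibble(
    id = sprintf("acc_%d_x%d", seq_len(nrow(library)), library$count),
    seq = library$seq
  )
  write_fasta(tbl, path)
}

#' @rdname write_collapsed_fasta
#' @return `read_collapsed_fasta()`: a collapsed-library tibble (`seq`,
#'   `count`) with `total_clean`/`total_raw` attributes rebuilt from counts.
#' @export
read_collapsed_fasta <- function(path) {
  fa <- read_fasta(path)
  count <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", fa$id)))
  if (nrow(fa) > 0 && anyNA(count)) {
    abort("collapsed FASTA headers must end in '_x<count>'")
  }
  new_srna_library(tibble(seq = fa$seq, count = as.integer(count)),
                   total_raw = sum(count))
}
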