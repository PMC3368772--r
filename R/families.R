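#' Assign a read to a known mature miRNA family
#'
#' Reads are placed ungapped against each reference mature (same strand), at
#' every offset, 5'/3' extensions beyond the reference allowed; a placement
#' is admissible when the read/reference overlap reaches `min_overlap`
#' nucleotides with at most `max_mismatch` substitutions inside the overlap.
#' The best assignment maximizes overlap, then minimizes mismatches; ties
#' between families are broken lexicographically by family name.  Allowing
#' extensions past the reference ends lets 23-27 nt long isoforms of a 21-nt
#' mature still be pooled with their family.
#'
#' @param read a single read sequence.
#' @param mature_db tibble of reference matures: `id`, `seq`, `family`.
#' @param min_overlap minimum read/reference overlap (default 19 nt).
#' @param max_mismatch maximum substitutions in the overlap (default 1).
#' @return one-row tibble `family`, `ref_id`, `overlap`, `mismatches`,
#'   `offset` (read 5' end minus reference 5' end, 0-based shift), or a
#'   zero-row tibble when no admissible placement exists.
#' @export
assign_family <- function(read, mature_db, min_overlap = 19L, max_mismatch = 1L) {
  read <- normalize_rna(read)
  empty <- tibble(family = character(), ref_id = character(),
                  overlap = integer(), mismatches = integer(), offset = integer())
  if (nrow(mature_db) == 0L) return(empty)
  hits <- lapply(seq_len(nrow(mature_db)), function(i) {
    h <- overlap_scan_cpp(read, normalize_rna(mature_db$seq[i]),
                          as.integer(min_overlap), as.integer(max_mismatch))
    if (h$overlap < 0) return(NULL)
    tibble(family = mature_db$family[i], ref_id = mature_db$id[i],
           overlap = h$overlap, mismatches = h$mismatches, offset = h$offset)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) return(empty)
  hits |>
    arrange(desc(.data$overlap), .data$mismatches, .data$family, .data$ref_id) |>
    slice(1)
}

#' Assign every unique read of a library to a family
#'
#' @param library `srna_library` (or tibble with `seq`, `count`).
#' @param mature_db reference matures (`id`, `seq`, `family`).
#' @param min_overlap,max_mismatch see [assign_family()].
#' @param synonyms optional named list of family synonym groups to merge, e.g.
#'   `list("miR159/319" = c("miR159", "miR319"))`; members are renamed to the
#'   group name before profiling.
#' @return tibble of assigned reads only: `seq`, `count`, `family`, `ref_id`,
#'   `overlap`, `mismatches`, `offset`.  Each unique read appears at most
#'   once.
#' @export
assign_families <- function(library, mature_db, min_overlap = 19L,
                            max_mismatch = 1L, synonyms = NULL) {
  if (is.null(tbl_col(mature_db, "family"))) abort("`mature_db` must carry a `family` column")
  rows <- lapply(seq_len(nrow(library)), function(i) {
    a <- assign_family(library$seq[i], mature_db,
                       min_overlap = min_overlap, max_mismatch = max_mismatch)
    if (nrow(a) == 0L) return(NULL)
    cbind(tibble(seq = library$seq[i], count = library$count[i]), a)
  })
  out <- as_tibble(bind_rows(rows))
  if (nrow(out) == 0L) {
    return(tibble(seq = character(), count = integer(), family = character(),
                  ref_id = character(), overlap = integer(),
                  mismatches = integer(), offset = integer()))
  }
  if (!is.null(synonyms)) {
    for (grp in names(synonyms)) {
      out$family[out$family %in% synonyms[[grp]]] <- grp
    }
  }
  out
}

#' Per-family abundance and length profiles
#'
#' Aggregates family assignments into read-count profiles, count-weighted by
#' the collapsed library.  Families are flagged `short` when the dominant
#' read length is 20-22 nt (canonical miRNA output) and `long` when 23-27 nt
#' (long miRNA-like species); anything else is `other`.  Dominant-length ties
#' go to the shorter length.
#'
#' @param assignments output of [assign_families()].
#' @return tibble `family`, `total_reads`, `unique_seqs`, `dominant_length`,
#'   `length_class`, plus one `len_<k>` column per observed read length;
#'   sorted by decreasing total reads.  Families with zero assigned reads do
#'   not appear.
#' @export
family_profiles <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(tibble(family = character(), total_reads = integer(),
                  unique_seqs = integer(), dominant_length = integer(),
                  length_class = character()))
  }
  long <- assignments |>
    mutate(length = nchar(.data$seq)) |>
    group_by(.data$family, .data$length) |>
    summarise(reads = sum(.data$count), uniq = n(), .groups = "drop")
  prof <- long |>
    group_by(.data$family) |>
    summarise(
      total_reads = sum(.data$reads),
      unique_seqs = sum(.data$uniq),
      dominant_length = .data$length[order(-.data$reads, .data$length)][1],
      .groups = "drop"
    ) |>
    mutate(length_class = dplyr::case_when(
      .data$dominant_length >= 20 & .data$dominant_length <= 22 ~ "short",
      .data$dominant_length >= 23 & .data$dominant_length <= 27 ~ "long",
      TRUE ~ "other"
    ))
  wide <- long |>
    mutate(length = sprintf("len_%02d", .data$length)) |>
    select("family", "length", "reads") |>
    tidyr::pivot_wider(names_from = "length", values_from = "reads",
                       values_fill = 0L, names_sort = TRUE)
  prof |>
    left_join(wide, by = "family") |>
    arrange(desc(.data$total_reads), .data$family)
}
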