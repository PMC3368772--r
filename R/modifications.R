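#' Detect single-nucleotide editing within a family's reads
#'
#' Reads assigned to a family that differ from the reference mature by
#' exactly one substitution (at their best ungapped placement) are collected
#' into modification events.  Each distinct (position, reference base,
#' observed base) combination becomes one event whose frequency is the
#' percentage of all reads assigned to the family carrying it.  Substitutions
#' falling in a 5'/3' extension beyond the reference are not editing and are
#' ignored.  Sequencing error is not distinguished from editing; use
#' `min_support` to require more supporting reads per event.
#'
#' @param family_reads tibble of the family's assigned reads: `seq`, `count`.
#' @param reference_mature the family's reference mature sequence.
#' @param min_support minimum supporting reads per reported event (default 1).
#' @param min_overlap,max_mismatch placement parameters, as in
#'   [assign_family()].
#' @return tibble of events sorted by descending frequency: `position`
#'   (1-based on the reference), `ref_base`, `obs_base`, `reads`, `frequency`
#'   (percent of all family reads, 3 decimals), `label` (e.g. `"G-A: 7.692%"`).
#' @examples
#' fam <- tibble::tibble(
#'   seq = c("UUGACAGAAGAUAGAGAGC", "UUGACAGAAGAUAGAGAGA"),
#'   count = c(12L, 1L))
#' detect_editing(fam, "UUGACAGAAGAUAGAGAGC")
#' @export
detect_editing <- function(family_reads, reference_mature, min_support = 1L,
                           min_overlap = 19L, max_mismatch = 1L) {
  total <- sum(family_reads$count)
  if (is.na(total) || total == 0L) abort("family has zero assigned reads")
  ref <- normalize_rna(reference_mature)
  events <- list()
  for (i in seq_len(nrow(family_reads))) {
    read <- normalize_rna(family_reads$seq[i])
    h <- overlap_scan_cpp(read, ref, as.integer(min_overlap),
                          as.integer(max_mismatch))
    if (h$overlap < 0 || h$mismatches != 1L) next
    lo <- max(0L, h$offset); hi <- min(nchar(ref), h$offset + nchar(read)) # 0-based ref window
    refpos <- (lo + 1L):hi
    rb <- substring(ref, refpos, refpos)
    ob <- substring(read, refpos - h$offset, refpos - h$offset)
    d <- which(rb != ob)
    if (length(d) != 1L) next   # mismatch outside the reference body
    events[[length(events) + 1L]] <- tibble(
      position = refpos[d], ref_base = rb[d], obs_base = ob[d],
      reads = family_reads$count[i]
    )
  }
  ev <- bind_rows(events)
  if (nrow(ev) == 0L) {
    return(tibble(position = integer(), ref_base = character(),
                  obs_base = character(), reads = integer(),
                  frequency = numeric(), label = character()))
  }
  ev |>
    group_by(.data$position, .data$ref_base, .data$obs_base) |>
    summarise(reads = sum(.data$reads), .groups = "drop") |>
    filter(.data$reads >= min_support) |>
    mutate(
      frequency = round(100 * .data$reads / total, 3),
      label = sprintf("%s-%s: %.3f%%", .data$ref_base, .data$obs_base,
                      .data$frequency)
    ) |>
    arrange(desc(.data$frequency), .data$position)
}

#' Is a read the -1+UU isoform of a reference mature?
#'
#' The -1+UU modification combines a one-nucleotide 5' deletion with 3'
#' uridylation: the isoform is the reference minus its first nucleotide with
#' `UU` appended, and is therefore exactly one nucleotide longer than the
#' reference.
#'
#' @param read read sequence(s).
#' @param reference_mature reference mature sequence.
#' @return logical vector.
#' @examples
#' detect_minus1_uu("UGACAGAAGAUAGAGAGCUU", "UUGACAGAAGAUAGAGAGC")  # TRUE
#' @export
detect_minus1_uu <- function(read, reference_mature) {
  ref <- normalize_rna(reference_mature)
  normalize_rna(read) == paste0(substr(ref, 2L, nchar(ref)), "UU")
}

#' Family-level modification table
#'
#' Runs [detect_editing()] and [detect_minus1_uu()] over every family in an
#' assignment table and formats the per-family summary (one row per family,
#' substitution events joined into a single annotation string, -1+UU presence
#' flagged with its supporting read count).
#'
#' @param assignments output of [assign_families()].
#' @param mature_db the mature reference tibble (`id`, `seq`, `family`).
#' @param min_support see [detect_editing()].
#' @return tibble: `family`, `modifications` (collapsed `"G-A: 7.692%"`
#'   labels, `""` when none), `minus1_uu` (`"yes"`/`"no"`), `minus1_uu_reads`,
#'   plus a nested `events` list-column of the per-event tibbles.
#' @export
detect_modifications <- function(assignments, mature_db, min_support = 1L) {
  fams <- unique(assignments$family)
  rows <- lapply(fams, function(fam) {
    fr <- assignments[assignments$family == fam, c("seq", "count")]
    ref <- mature_db$seq[match(assignments$ref_id[assignments$family == fam][1],
                               mature_db$id)]
    ev <- detect_editing(fr, ref, min_support = min_support)
    uu <- detect_minus1_uu(fr$seq, ref)
    tibble(
      family = fam,
      modifications = paste(ev$label, collapse = " "),
      minus1_uu = if (any(uu)) "yes" else "no",
      minus1_uu_reads = sum(fr$count[uu]),
      events = list(ev)
    )
  })
  bind_rows(rows) |> arrange(.data$family)
}
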