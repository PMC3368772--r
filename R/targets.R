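#' Target-scoring parameter presets
#'
#' Penalty-scored complementarity scoring for plant miRNA target search:
#' each alignment column contributes 0 (Watson-Crick), `gu_value` (G:U
#' wobble), `mm_value` (other mismatch) or `gap_value` (gap column); a site
#' is reported when the minimal total penalty is at most `score_threshold`,
#' the alignment spans at least `min_length_alignment` columns, and the
#' miRNA positions in `no_mismatch_positions` (1-based from the 5' end,
#' flanking the cleavage site) are perfectly Watson-Crick paired with no
#' insertion between consecutive constrained positions.  Two presets are
#' provided: `"conserved"` (minimum alignment length 20) and `"novel"`
#' (minimum 18).
#'
#' @param mode `"conserved"` or `"novel"`.
#' @param gap_value,mm_value,gu_value column penalties.
#' @param score_threshold maximum admissible penalty.
#' @param min_length_alignment minimum alignment columns; default by `mode`.
#' @param no_mismatch_positions integer vector of constrained miRNA
#'   positions.
#' @return object of class `target_params`.
#' @export
target_params <- function(mode = c("conserved", "novel"), gap_value = 2,
                          mm_value = 1, gu_value = 0.5, score_threshold = 3,
                          min_length_alignment = NULL,
                          no_mismatch_positions = c(10L, 11L)) {
  mode <- match.arg(mode)
  if (is.null(min_length_alignment)) {
    min_length_alignment <- if (mode == "conserved") 20L else 18L
  }
  if (any(c(gap_value, mm_value, gu_value) < 0) || score_threshold < 0)
    abort("penalties and threshold must be >= 0")
  structure(list(mode = mode, gap_value = gap_value, mm_value = mm_value,
                 gu_value = gu_value, score_threshold = score_threshold,
                 min_length_alignment = as.integer(min_length_alignment),
                 no_mismatch_positions = as.integer(no_mismatch_positions)),
            class = "target_params")
}

is_wc_pair <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC")
is_gu_pair <- function(a, b) paste0(a, b) %in% c("GU", "UG")

# Table-8-style duplex block: miRNA 3'->5' over match line over site 5'->3'
render_duplex <- function(mir_aln, site_aln) {
  m <- strsplit(mir_aln, "")[[1]]; s <- strsplit(site_aln, "")[[1]]
  match_ch <- vapply(seq_along(m), function(k) {
    if (m[k] == "-" || s[k] == "-") " "
    else if (is_wc_pair(m[k], s[k])) ":"
    else if (is_gu_pair(m[k], s[k])) "."
    else " "
  }, character(1))
  paste(
    paste(rev(m), collapse = ""),
    paste(rev(match_ch), collapse = ""),
    paste(rev(s), collapse = ""),
    sep = "\n"
  )
}

duplex_energy_cols <- function(mir_aln, site_aln, params_fold = fold_params()) {
  m <- strsplit(mir_aln, "")[[1]]; s <- strsplit(site_aln, "")[[1]]
  ptypes <- vapply(seq_along(m), function(k) {
    p <- paste0(m[k], s[k])
    if (p %in% PAIR_LEVELS) p else NA_character_
  }, character(1))
  e <- 0
  for (k in seq_len(length(ptypes) - 1L)) {
    if (!is.na(ptypes[k]) && !is.na(ptypes[k + 1L])) {
      e <- e + params_fold$stack[ptypes[k], ptypes[k + 1L]]
    }
  }
  round(e, 10)
}

#' Nearest-neighbour energy of an aligned miRNA:target duplex
#'
#' Sums stacking energies over consecutive paired columns of the duplex
#' alignment under the shipped stacking table (see [fold_params()]); unpaired
#' or gapped columns contribute nothing, so a fully unpaired alignment scores
#' 0 and adding a stacked pair can only lower the energy.  These estimates
#' carry the energy-model version and are not comparable across models.
#'
#' @param mir_aln,site_aln aligned strands (miRNA 5'->3', site 3'->5'), `-`
#'   for gaps, equal lengths.
#' @param params_fold a [fold_params()] object supplying the stacking table.
#' @return energy estimate in kcal/mol (<= 0).
#' @export
duplex_energy <- function(mir_aln, site_aln, params_fold = fold_params()) {
  if (nchar(mir_aln) != nchar(site_aln)) abort("aligned strands differ in length")
  duplex_energy_cols(normalize_rna(mir_aln), normalize_rna(site_aln),
                     params_fold)
}

#' Scan transcripts for miRNA target sites
#'
#' Every transcript window whose optimal gapped complementarity alignment to
#' the miRNA passes the [target_params()] criteria is reported; overlapping
#' windows are reduced to the minimum-penalty site (ties broken by lower
#' duplex energy, then leftmost).  The search over window widths is
#' exhaustive for reportable sites: an alignment with more than
#' `floor(score_threshold / gap_value)` gap columns already exceeds the
#' threshold.
#'
#' @param mirnas tibble (`id`, `seq`) of mature miRNAs, 17-27 nt.
#' @param transcripts tibble (`id`, `seq`).
#' @param params a [target_params()] object.
#' @param params_fold [fold_params()] for the duplex-energy estimate.
#' @return tibble with one row per site: `mirna_id`, `mirna_seq`,
#'   `transcript_id`, `start`, `end` (site coordinates, 1-based inclusive),
#'   `penalty`, `energy`, `aligned_length`, `mir_aln`, `site_aln` (miRNA
#'   5'->3' vs site 3'->5'), `duplex` (printable three-line block, miRNA
#'   3'->5' on top), `cleavage_site` (transcript coordinate paired with the
#'   canonical 10th miRNA nucleotide), `cleavage_mir_pos` (that column's
#'   position counted from the miRNA 5' end).
#' @export
align_targets <- function(mirnas, transcripts, params = target_params(),
                          params_fold = fold_params()) {
  bad <- nchar(mirnas$seq) < 17 | nchar(mirnas$seq) > 27
  if (any(bad)) {
    abort(sprintf("miRNA '%s' is outside the 17-27 nt length bounds",
                  mirnas$id[bad][1]))
  }
  max_gap <- max(0L, as.integer(floor(params$score_threshold / max(params$gap_value, 1e-9))))
  res <- list()
  for (i in seq_len(nrow(mirnas))) {
    mir <- normalize_rna(mirnas$seq[i])
    for (j in seq_len(nrow(transcripts))) {
      tr <- normalize_rna(transcripts$seq[j])
      cand <- target_scan_cpp(mir, tr,
                              centi(params$mm_value), centi(params$gu_value),
                              centi(params$gap_value),
                              centi(params$score_threshold),
                              params$min_length_alignment,
                              params$no_mismatch_positions, max_gap)
      if (length(cand) == 0L) next
      rows <- lapply(cand, function(cc) {
        cleav_col <- which(cc$col_mir == 10L)
        cleav_tr <- if (length(cleav_col)) cc$col_tr[cleav_col[1]] else NA_integer_
        tibble(
          mirna_id = mirnas$id[i], mirna_seq = mir,
          transcript_id = transcripts$id[j],
          start = cc$start, end = cc$end,
          penalty = cc$penalty_centi / 100,
          energy = duplex_energy_cols(cc$mir_aln, cc$site_aln, params_fold),
          aligned_length = cc$ncols,
          mir_aln = cc$mir_aln, site_aln = cc$site_aln,
          duplex = render_duplex(cc$mir_aln, cc$site_aln),
          cleavage_site = cleav_tr,
          cleavage_mir_pos = if (length(cleav_col)) cc$col_mir[cleav_col[1]] else NA_integer_
        )
      })
      res[[length(res) + 1L]] <- bind_rows(rows)
    }
  }
  sites <- bind_rows(res)
  if (nrow(sites) == 0L) {
    return(tibble(mirna_id = character(), mirna_seq = character(),
                  transcript_id = character(), start = integer(),
                  end = integer(), penalty = numeric(), energy = numeric(),
                  aligned_length = integer(), mir_aln = character(),
                  site_aln = character(), duplex = character(),
                  cleavage_site = integer(), cleavage_mir_pos = integer()))
  }
  # overlapping windows for the same miRNA/transcript -> best site
  sites <- sites |>
    arrange(.data$mirna_id, .data$transcript_id, .data$penalty, .data$energy,
            .data$start)
  keep <- rep(TRUE, nrow(sites))
  for (a in seq_len(nrow(sites))) {
    if (!keep[a]) next
    overl <- keep & sites$mirna_id == sites$mirna_id[a] &
      sites$transcript_id == sites$transcript_id[a] &
      sites$start <= sites$end[a] & sites$end >= sites$start[a]
    overl[a] <- FALSE
    keep[overl] <- FALSE
  }
  sites[keep, ] |> arrange(.data$mirna_id, .data$transcript_id, .data$start)
}

#' Predicted cleavage coordinate of a target site
#'
#' Plant ARGONAUTE cleaves its target opposite the canonical 10th nucleotide
#' of the miRNA (between the bases paired to positions 10 and 11); this
#' returns the transcript coordinate paired with miRNA position 10 together
#' with the miRNA-relative position of that column.
#'
#' @param site one row of [align_targets()] output.
#' @return one-row tibble: `transcript_id`, `cleavage_site` (1-based
#'   transcript coordinate), `cleavage_mir_pos`.
#' @export
predict_cleavage <- function(site) {
  if (is.na(site$cleavage_site)) {
    abort("no alignment column pairs miRNA position 10")
  }
  tibble(transcript_id = site$transcript_id,
         cleavage_site = site$cleavage_site,
         cleavage_mir_pos = site$cleavage_mir_pos)
}
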