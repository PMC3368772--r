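#' Structural rules for miRNA precursor acceptance
#'
#' The rule set a candidate hairpin must satisfy: mature length window,
#' free-energy ceiling, a bound on unpaired nucleotides inside the miR:miR*
#' duplex, and a bound on the loop distance separating miR from miR*.
#' Defaults are the classical plant criteria (20-22 nt mature, -25 kcal/mol,
#' at most 6 unpaired duplex nucleotides, 5-240 nt miR-miR* distance, 2-nt 3'
#' overhangs).  `mature_len` may be widened (e.g. to `c(20, 27)`) to admit
#' long miRNA-like species.
#'
#' @param mature_len length-2 integer vector, admissible mature lengths.
#' @param max_energy free-energy ceiling, kcal/mol (must be negative).
#' @param max_unpaired maximum unpaired nucleotides within the duplex.
#' @param loop_range length-2 vector, admissible miR-miR* distance in nt.
#' @param overhang duplex 3' overhang length in nt.
#' @param duplex_margin margin (nt, per side) defining the "around the
#'   duplex" region used by the read-stack classifier.
#' @return object of class `precursor_rules`.
#' @export
precursor_rules <- function(mature_len = c(20L, 22L), max_energy = -25,
                            max_unpaired = 6L, loop_range = c(5L, 240L),
                            overhang = 2L, duplex_margin = 12L) {
  if (max_energy >= 0) abort("`max_energy` must be negative")
  if (mature_len[1] > mature_len[2] || loop_range[1] > loop_range[2])
    abort("rule ranges must be increasing")
  structure(list(mature_len = as.integer(mature_len), max_energy = max_energy,
                 max_unpaired = as.integer(max_unpaired),
                 loop_range = as.integer(loop_range),
                 overhang = as.integer(overhang),
                 duplex_margin = as.integer(duplex_margin)),
            class = "precursor_rules")
}

# estimated pairing partner of position p, interpolating across bulged
# (unpaired) positions from the nearest paired neighbour in `range`
partner_est <- function(partner, p, range) {
  if (!is.na(partner[p])) return(partner[p])
  cand <- range[!is.na(partner[range])]
  if (length(cand) == 0L) return(NA_integer_)
  q <- cand[order(abs(cand - p), -cand)][1]
  partner[q] + (q - p)
}

#' Predict the miRNA* coordinates from a precursor structure
#'
#' The star strand occupies the positions pairing the mature in the hairpin
#' duplex, shifted so both duplex ends carry the 2-nt 3' overhang left by
#' Dicer-like processing.  Bulged mature positions are interpolated from the
#' nearest paired neighbour.
#'
#' @param structure dot-bracket structure of the precursor.
#' @param mature_start,mature_end 1-based mature coordinates on the
#'   precursor.
#' @param overhang overhang size (default 2 nt).
#' @return integer vector `c(start, end)` of the star on the precursor.
#'   Errors if the mature is entirely unpaired.
#' @export
predict_star <- function(structure, mature_start, mature_end, overhang = 2L) {
  partner <- db_partners(structure)
  mrange <- mature_start:mature_end
  if (all(is.na(partner[mrange]))) abort("mature region is entirely unpaired")
  s1 <- partner_est(partner, mature_end - overhang, mrange)
  s2 <- partner_est(partner, mature_start, mrange) + overhang
  star <- sort(c(s1, s2))
  star[1] <- max(1L, star[1]); star[2] <- min(length(partner), star[2])
  as.integer(star)
}

# count unpaired nucleotides inside the miR:miR* duplex (3' overhangs on
# both strands excluded)
duplex_unpaired_count <- function(partner, mature, star, overhang = 2L) {
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  # the 3' overhang of each strand sits at its high-coordinate end and is
  # not expected to pair
  mcore <- mature[1]:(mature[2] - overhang)
  score <- star[1]:(star[2] - overhang)
  sum(!in_range(partner[mcore], star)) + sum(!in_range(partner[score], mature))
}

check_candidate <- function(seq, structure, energy, mature, rules) {
  partner <- db_partners(structure)
  mlen <- mature[2] - mature[1] + 1L
  checks <- list()
  checks$mature_length <- mlen >= rules$mature_len[1] && mlen <= rules$mature_len[2]
  pp <- partner[mature[1]:mature[2]]
  paired <- pp[!is.na(pp)]
  checks$mature_in_arm <- length(paired) > 0 &&
    (all(paired > mature[2]) || all(paired < mature[1]))
  if (!checks$mature_in_arm) {
    star <- c(NA_integer_, NA_integer_)
    checks$loop_distance <- FALSE
    checks$duplex_unpaired <- FALSE
  } else {
    star <- predict_star(structure, mature[1], mature[2], rules$overhang)
    dist <- if (mature[1] < star[1]) star[1] - mature[2] - 1L
            else mature[1] - star[2] - 1L
    checks$loop_distance <- dist >= rules$loop_range[1] && dist <= rules$loop_range[2]
    star_usable <- !anyNA(star) && star[1] >= 1 && star[2] <= nchar(seq) &&
      dist >= 1L
    checks$duplex_unpaired <- star_usable &&
      duplex_unpaired_count(partner, mature, star, rules$overhang) <= rules$max_unpaired
  }
  checks$energy <- energy <= rules$max_energy
  list(checks = checks, star = star)
}

#' Validate a precursor candidate against the structural rules
#'
#' Independent re-check of every rule on a candidate's own sequence and
#' structure; used on pipeline output and on planted/decoy loci in synthetic
#' data.
#'
#' @param seq precursor sequence.
#' @param mature_start,mature_end mature coordinates on the precursor.
#' @param rules a [precursor_rules()] object.
#' @param params a [fold_params()] object; the precursor is folded with
#'   [rna_fold()] unless `structure`/`energy` are supplied.
#' @param structure,energy optional pre-computed structure annotation.
#' @return tibble with columns `rule` and `pass`, one row per rule
#'   (`mature_length`, `mature_in_arm`, `loop_distance`, `duplex_unpaired`,
#'   `energy`).
#' @export
validate_precursor <- function(seq, mature_start, mature_end,
                               rules = precursor_rules(),
                               params = fold_params(),
                               structure = NULL, energy = NULL) {
  seq <- normalize_rna(seq)
  if (is.null(structure) || is.null(energy)) {
    f <- rna_fold(seq, params)
    structure <- f$structure; energy <- f$energy
  }
  res <- check_candidate(seq, structure, energy,
                         c(mature_start, mature_end), rules)
  tibble(rule = names(res$checks), pass = unlist(res$checks, use.names = FALSE))
}

#' Discover hairpin precursors around a read locus
#'
#' For every exact (0-mismatch, plus-strand) occurrence of `read` in the
#' transcript set, windows around the locus (the full `window` extent plus
#' shrinking sub-windows) are folded; a window survives when the read sits
#' wholly in one stem arm and the predicted miR:miR* duplex satisfies all
#' [precursor_rules()].  Surviving windows are trimmed to the duplex-bearing
#' stem, refolded, re-checked, and overlapping candidates are reduced to the
#' lowest-energy one.
#'
#' @param transcripts tibble (`id`, `seq`).
#' @param read the candidate mature sequence; must occur in at least one
#'   transcript.
#' @param rules [precursor_rules()].
#' @param params [fold_params()].
#' @param window length-2 integer vector: nucleotides examined on each side
#'   of the read locus (default 250 both sides).
#' @param pad nucleotides kept on each side when trimming to the stem.
#' @return tibble of candidates: `transcript_id`, `start`, `end` (precursor
#'   coordinates on the transcript, 1-based inclusive), `precursor`,
#'   `structure`, `energy`, `mature_start`, `mature_end`, `star_start`,
#'   `star_end` (precursor-relative), `arm` (`5p`/`3p`).
#' @export
find_precursors <- function(transcripts, read, rules = precursor_rules(),
                            params = fold_params(), window = c(250L, 250L),
                            pad = 5L) {
  read <- normalize_rna(read)
  loci <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    st <- gregexpr(read, transcripts$seq[i], fixed = TRUE)[[1]]
    if (st[1] == -1L) return(NULL)
    tibble(idx = i, pos = as.integer(st))
  })
  if (nrow(loci) == 0L) abort("read not found in any transcript")
  shrink <- c(1, 0.5, 0.25, 0.1)
  out <- list()
  for (r in seq_len(nrow(loci))) {
    tseq <- transcripts$seq[loci$idx[r]]
    tid <- transcripts$id[loci$idx[r]]
    L <- nchar(tseq); pos <- loci$pos[r]; rend <- pos + nchar(read) - 1L
    wins <- unique(purrr::map_dfr(shrink, function(f1) {
      purrr::map_dfr(shrink, function(f2) {
        tibble(ws = max(1L, pos - as.integer(round(window[1] * f1))),
               we = min(L, rend + as.integer(round(window[2] * f2))))
      })
    }))
    for (w in seq_len(nrow(wins))) {
      ws <- wins$ws[w]; we <- wins$we[w]
      if (we - ws + 1L < 40L) next
      wseq <- substr(tseq, ws, we)
      f <- rna_fold(wseq, params)
      mat <- c(pos - ws + 1L, rend - ws + 1L)
      chk <- check_candidate(wseq, f$structure, f$energy, mat, rules)
      if (!all(unlist(chk$checks))) next
      # trim to the duplex-bearing stem and confirm on the refold
      lo <- max(1L, min(mat[1], chk$star[1]) - pad)
      hi <- min(nchar(wseq), max(mat[2], chk$star[2]) + pad)
      pseq <- substr(wseq, lo, hi)
      pf <- rna_fold(pseq, params)
      pmat <- mat - lo + 1L
      pchk <- check_candidate(pseq, pf$structure, pf$energy, pmat, rules)
      if (!all(unlist(pchk$checks))) next
      arm <- if (pmat[1] < pchk$star[1]) "5p" else "3p"
      out[[length(out) + 1L]] <- tibble(
        transcript_id = tid,
        start = ws + lo - 1L, end = ws + hi - 1L,
        precursor = pseq, structure = pf$structure, energy = pf$energy,
        mature_start = pmat[1], mature_end = pmat[2],
        star_start = pchk$star[1], star_end = pchk$star[2], arm = arm
      )
    }
  }
  cands <- bind_rows(out)
  if (nrow(cands) == 0L) return(cands)
  # reduce overlapping candidates to the lowest-energy survivor
  cands <- cands |> arrange(.data$transcript_id, .data$energy, .data$start)
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cands))) {
      if (i == j || !keep[j]) next
      if (cands$transcript_id[i] == cands$transcript_id[j] &&
          cands$start[j] <= cands$end[i] && cands$end[j] >= cands$start[i]) {
        keep[j] <- FALSE
      }
    }
  }
  cands[keep, ] |> arrange(.data$transcript_id, .data$start)
}

#' Classify a precursor by its supporting read stack
#'
#' The five-class taxonomy of hairpins by how sequenced reads distribute over
#' the predicted miR/miR* regions versus elsewhere on the precursor:
#' \describe{
#'   \item{1}{all reads fall inside the regions around the predicted miR and
#'     miR* (`duplex_margin` tolerance) and both strands are read-supported;}
#'   \item{2}{miR and miR* both supported, plus lower-abundance reads
#'     outside;}
#'   \item{3a}{reads on the defining miR region only, at least two reads;}
#'   \item{3b}{a single read on the defining miR region;}
#'   \item{4}{defining miR plus lower-abundance reads outside the duplex, no
#'     star support;}
#'   \item{5}{some read outside the duplex region is more abundant than the
#'     defining read.}
#' }
#'
#' @param candidate one row of [find_precursors()] output (needs
#'   `mature_start`, `mature_end`, `star_start`, `star_end`).
#' @param read_stack tibble of reads mapped on the precursor: `start`, `end`
#'   (precursor-relative), `count`.  Must be non-empty.
#' @param rules [precursor_rules()]; supplies the margin and overhang
#'   tolerances.
#' @return a class label: `"1"`, `"2"`, `"3a"`, `"3b"`, `"4"` or `"5"`.
#' @export
classify_precursor <- function(candidate, read_stack, rules = precursor_rules()) {
  if (nrow(read_stack) == 0L) abort("read stack is empty")
  m <- c(candidate$mature_start, candidate$mature_end)
  s <- c(candidate$star_start, candidate$star_end)
  marg <- rules$duplex_margin
  within <- function(st, en, r) st >= r[1] - marg & en <= r[2] + marg
  supports <- function(st, en, r) abs(st - r[1]) <= rules$overhang &
    abs(en - r[2]) <= rules$overhang
  inside <- within(read_stack$start, read_stack$end, m) |
    within(read_stack$start, read_stack$end, s)
  mir_support <- supports(read_stack$start, read_stack$end, m)
  star_support <- supports(read_stack$start, read_stack$end, s)
  defining <- max(read_stack$count[mir_support], 0)
  outside <- read_stack[!inside, , drop = FALSE]
  if (nrow(outside) > 0 && any(outside$count > defining)) return("5")
  has_star <- any(star_support)
  if (nrow(outside) == 0L) {
    if (has_star && any(mir_support)) return("1")
    total <- sum(read_stack$count)
    return(if (total >= 2L) "3a" else "3b")
  }
  if (has_star) "2" else "4"
}
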