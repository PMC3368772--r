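#' Reference categories and their precedence
#'
#' The closed category set for annotated references, ordered by the precedence
#' used to resolve multi-category hits: structural RNA classes outrank mRNA so
#' that degradation products of structural RNAs are not mislabelled as mRNA
#' fragments.
#'
#' @export
REFERENCE_CATEGORIES <- c("miRNA", "tRNA", "rRNA", "sn/snoRNA", "ncRNA",
                          "transposon", "pseudo mRNA", "coding mRNA")

normalize_category <- function(x) {
  x <- gsub("_", " ", x)
  bad <- !is.na(x) & !(x %in% REFERENCE_CATEGORIES)
  if (any(bad)) {
    abort(sprintf("unknown reference category '%s'", x[bad][1]))
  }
  x
}

#' Find ungapped full-length matches of a short query in a reference set
#'
#' Every placement of the whole query on either strand of a reference record
#' with at most `max_mismatch` substitutions is reported.  For 17-32 nt small
#' RNAs this exhaustive scan is the exact, reproducible replacement for a
#' heuristic sequence search.
#'
#' @param query a single sequence (character scalar), at least 17 nt.
#' @param reference tibble with `id` and `seq` (e.g. from [read_fasta()]).
#' @param max_mismatch maximum substitutions (default 1).
#' @return tibble with one row per hit: `ref_id`, `start` (1-based on the plus
#'   strand of the record), `strand` (`+`/`-`), `mismatches`.
#' @export
match_reference <- function(query, reference, max_mismatch = 1L) {
  if (nrow(reference) == 0L) abort("reference set is empty")
  query <- normalize_rna(query)
  check_rna_alphabet(query, "query")
  h <- ref_scan_cpp(query, normalize_rna(reference$seq),
                    as.integer(max_mismatch))
  tibble(ref_id = reference$id[h$ref], start = as.integer(h$start),
         strand = h$strand, mismatches = as.integer(h$mismatches)) |>
    arrange(.data$ref_id, .data$start)
}

#' Categorize one query from its reference hits
#'
#' @param hits hit table from [match_reference()].
#' @param reference the reference tibble, with a `category` column (`NA` for
#'   uncategorized records).
#' @return one-row tibble: `category` (a reference category, `"no hit"`, or
#'   `"hit, unknown"`), `best_hit` (reference id or `NA`), `mismatches`.
#' @details With no hits the call is `"no hit"`.  If every hit lands on an
#'   uncategorized record the call is `"hit, unknown"`.  Otherwise the best
#'   categorized hit wins: fewest mismatches, ties broken by the fixed
#'   precedence in [REFERENCE_CATEGORIES].
#' @export
categorize <- function(hits, reference) {
  cat_of <- setNames(normalize_category(
    if (is.null(tbl_col(reference, "category"))) rep(NA_character_, nrow(reference)) else reference$category
  ), reference$id)
  if (nrow(hits) == 0L) {
    return(tibble(category = "no hit", best_hit = NA_character_,
                  mismatches = NA_integer_))
  }
  hits$category <- unname(cat_of[hits$ref_id])
  labelled <- hits[!is.na(hits$category), , drop = FALSE]
  if (nrow(labelled) == 0L) {
    best <- hits[which.min(hits$mismatches), ]
    return(tibble(category = "hit, unknown", best_hit = best$ref_id,
                  mismatches = best$mismatches))
  }
  best_mm <- min(labelled$mismatches)
  top <- labelled[labelled$mismatches == best_mm, , drop = FALSE]
  top <- top[order(match(top$category, REFERENCE_CATEGORIES), top$ref_id), ]
  tibble(category = top$category[1], best_hit = top$ref_id[1],
         mismatches = best_mm)
}

#' Categorize every unique read of a collapsed library
#'
#' @param library an `srna_library` (or any tibble with `seq` and `count`).
#' @param reference annotated reference tibble (`id`, `seq`, `category`).
#' @param max_mismatch maximum substitutions per match (default 1).
#' @return tibble: `seq`, `count`, `category`, `best_hit`, `mismatches`; one
#'   row per unique read, so the categories partition the library.
#' @export
classify_reads <- function(library, reference, max_mismatch = 1L) {
  if (nrow(reference) == 0L) abort("reference set is empty")
  reference$category <- normalize_category(
    if (is.null(tbl_col(reference, "category"))) rep(NA_character_, nrow(reference)) else reference$category)
  all_hits <- ref_scan_cpp(normalize_rna(library$seq),
                           normalize_rna(reference$seq),
                           as.integer(max_mismatch))
  by_query <- split(seq_len(nrow(all_hits)), all_hits$query)
  calls <- lapply(seq_len(nrow(library)), function(i) {
    idx <- by_query[[as.character(i)]]
    hits <- if (is.null(idx)) {
      tibble(ref_id = character(), start = integer(), strand = character(),
             mismatches = integer())
    } else {
      tibble(ref_id = reference$id[all_hits$ref[idx]],
             start = as.integer(all_hits$start[idx]),
             strand = all_hits$strand[idx],
             mismatches = as.integer(all_hits$mismatches[idx]))
    }
    categorize(hits, reference)
  })
  bind_rows(
    lapply(seq_len(nrow(library)), function(i) {
      cbind(tibble(seq = library$seq[i], count = library$count[i]), calls[[i]])
    })
  ) |> as_tibble()
}

#' Category summary table
#'
#' @param calls output of [classify_reads()].
#' @return tibble `category`, `unique_reads`, `total_reads`, one row per
#'   category present (including `"no hit"` / `"hit, unknown"`), ordered by
#'   precedence then the two fallback classes.
#' @export
summarize_categories <- function(calls) {
  lv <- c(REFERENCE_CATEGORIES, "hit, unknown", "no hit")
  calls |>
    group_by(category = factor(.data$category, levels = lv)) |>
    summarise(unique_reads = n(), total_reads = sum(.data$count), .groups = "drop") |>
    arrange(.data$category) |>
    mutate(category = as.character(.data$category))
}
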