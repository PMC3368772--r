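#' Run the full small-RNA analysis pipeline
#'
#' Orchestrates the stages end to end on in-memory tables: cleanup and
#' collapsing, categorization against the annotated reference, conserved
#' family assignment and profiling, modification detection, hairpin
#' precursor discovery with read-stack classification, and target
#' prediction.  Every filtering decision is tallied in the run log, and all
#' cross-table counts are mutually consistent (categories partition the
#' unique reads; family totals equal their per-length sums).
#'
#' @param reads raw read tibble (`id`, `seq`, optionally `qual`).
#' @param references annotated reference tibble (`id`, `seq`, `category`).
#' @param mature_db mature miRNA database (`id`, `seq`, `family`).
#' @param transcripts transcript/EST tibble (`id`, `seq`) searched for
#'   precursors and targets.
#' @param adapter3 3' adapter; `NULL` for pre-trimmed input.
#' @param rules [precursor_rules()].
#' @param params_fold [fold_params()].
#' @param params_target [target_params()]; target search runs with the
#'   pipeline's miRNA set against `transcripts`.
#' @param min_clip,min_len,max_len,keep_untrimmed preprocess settings.
#' @param classify_max_mismatch substitutions allowed in categorization.
#' @param min_overlap,family_max_mismatch,synonyms family-assignment
#'   settings.
#' @param hairpin_min_count minimum collapsed count before a read is tried
#'   as a precursor-defining mature.
#' @param run_targets,run_hairpins stage switches.
#' @return a `mirforge_report`: list of tibbles `stats`, `categories`,
#'   `length_histogram`, `assignments`, `profiles`, `modifications`,
#'   `precursors`, `targets`, `log`, plus the collapsed `library`.
#' @export
run_pipeline <- function(reads, references, mature_db, transcripts,
                         adapter3 = NULL,
                         rules = precursor_rules(),
                         params_fold = fold_params(),
                         params_target = target_params("conserved"),
                         min_clip = 6L, min_len = 17L, max_len = 32L,
                         keep_untrimmed = FALSE,
                         classify_max_mismatch = 1L,
                         min_overlap = 19L, family_max_mismatch = 1L,
                         synonyms = NULL,
                         hairpin_min_count = 10L,
                         run_targets = TRUE, run_hairpins = TRUE) {
  lib <- preprocess_reads(reads, adapter3 = adapter3, min_clip = min_clip,
                          min_len = min_len, max_len = max_len,
                          keep_untrimmed = keep_untrimmed)
  calls <- classify_reads(lib, references, max_mismatch = classify_max_mismatch)
  categories <- summarize_categories(calls)
  assignments <- assign_families(lib, mature_db, min_overlap = min_overlap,
                                 max_mismatch = family_max_mismatch,
                                 synonyms = synonyms)
  profiles <- family_profiles(assignments)
  modifications <- if (nrow(assignments)) {
    detect_modifications(assignments, mature_db)
  } else {
    tibble(family = character(), modifications = character(),
           minus1_uu = character(), minus1_uu_reads = integer())
  }
  precursors <- tibble()
  if (run_hairpins) {
    cand_reads <- lib |>
      as_tibble() |>
      filter(.data$count >= hairpin_min_count,
             nchar(.data$seq) >= rules$mature_len[1],
             nchar(.data$seq) <= rules$mature_len[2])
    found <- list()
    for (i in seq_len(nrow(cand_reads))) {
      rd <- cand_reads$seq[i]
      hit <- any(vapply(transcripts$seq,
                        function(ts) grepl(rd, ts, fixed = TRUE), logical(1)))
      if (!hit) next
      pc <- find_precursors(transcripts, rd, rules = rules,
                            params = params_fold)
      if (nrow(pc) == 0L) next
      pc$mature <- rd
      pc$mature_count <- cand_reads$count[i]
      found[[length(found) + 1L]] <- pc
    }
    precursors <- bind_rows(found)
    if (nrow(precursors)) {
      # the mature and its star both define the same hairpin locus; keep the
      # more abundant defining read per locus
      precursors <- precursors |>
        arrange(desc(.data$mature_count)) |>
        distinct(.data$transcript_id, .data$start, .data$end, .keep_all = TRUE) |>
        arrange(.data$transcript_id, .data$start)
    }
    if (nrow(precursors)) {
      # read stacks: collapsed reads occurring inside each precursor
      precursors$class <- vapply(seq_len(nrow(precursors)), function(k) {
        pseq <- precursors$precursor[k]
        pos <- lapply(lib$seq, function(s) {
          m <- gregexpr(s, pseq, fixed = TRUE)[[1]]
          if (m[1] == -1L) NULL else as.integer(m[1])
        })
        keep <- !vapply(pos, is.null, logical(1))
        stack <- tibble(
          start = unlist(pos[keep]),
          end = unlist(pos[keep]) + nchar(lib$seq[keep]) - 1L,
          count = lib$count[keep]
        )
        classify_precursor(precursors[k, ], stack, rules)
      }, character(1))
      precursors$star_reads <- vapply(seq_len(nrow(precursors)), function(k) {
        star <- substr(precursors$precursor[k], precursors$star_start[k],
                       precursors$star_end[k])
        idx <- match(star, lib$seq)
        if (is.na(idx)) 0L else lib$count[idx]
      }, integer(1))
    }
  }
  targets <- tibble()
  if (run_targets && nrow(mature_db)) {
    ok_len <- nchar(mature_db$seq) >= 17 & nchar(mature_db$seq) <= 27
    targets <- align_targets(mature_db[ok_len, ], transcripts,
                             params = params_target,
                             params_fold = params_fold)
  }
  g <- glance(lib)
  stats <- tibble(
    metric = c("raw_reads", "clean_reads", "unique_clean",
               "families_detected", "precursor_candidates", "target_sites"),
    value = c(g$total_raw, g$total_clean, g$unique_clean,
              nrow(profiles), nrow(precursors), nrow(targets))
  )
  log <- bind_rows(
    attr(lib, "dropped"),
    tibble(stage = "classified_unique", reads = nrow(calls)),
    tibble(stage = "family_assigned_unique", reads = nrow(assignments))
  )
  structure(list(library = lib, stats = stats, categories = categories,
                 length_histogram = length_histogram(lib),
                 assignments = assignments, profiles = profiles,
                 modifications = modifications, precursors = precursors,
                 targets = targets, log = log),
            class = "mirforge_report")
}

#' @export
print.mirforge_report <- function(x, ...) {
  cat("<mirforge_report>\n")
  print(x$stats)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits each report table as a TSV (tab-separated, header line, UTF-8,
#' 1-based inclusive coordinates) plus a single machine-readable JSON mirror
#' of everything; re-running with the same inputs reproduces the files
#' byte-identically.
#'
#' @param report a `mirforge_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_report_bundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("stats", "categories", "length_histogram", "assignments",
              "profiles", "modifications", "precursors", "targets", "log")
  files <- character(0)
  for (tb in tables) {
    x <- report[[tb]]
    if (is.null(x) || nrow(as_tibble(x)) == 0L && tb %in% c("precursors", "targets")) {
      x <- as_tibble(x)
    }
    x <- as_tibble(x)
    x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
    f <- file.path(dir, paste0(tb, ".tsv"))
    write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  jf <- file.path(dir, "report.json")
  json_obj <- lapply(report[tables], function(x) {
    x <- as_tibble(x); x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  })
  jsonlite::write_json(json_obj, jf, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}
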