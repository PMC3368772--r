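#' Length-distribution plot of a collapsed library
#'
#' Bar plot of unique sequences and total reads per insert length, the
#' standard first look at a small-RNA library (21/24 nt miRNA/siRNA peaks,
#' degradation shoulders).
#'
#' @param object an `srna_library`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.srna_library <- function(object, ...) {
  h <- length_histogram(object) |>
    tidyr::pivot_longer(c("unique_count", "read_count"),
                        names_to = "measure", values_to = "n")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "insert length (nt)", y = NULL,
                  title = "Small RNA length distribution")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Family abundance plot
#'
#' @param profiles output of [family_profiles()].
#' @param top number of families shown (by total reads).
#' @return a ggplot object.
#' @export
plot_family_profiles <- function(profiles, top = 20L) {
  d <- head(profiles, top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$family, .data$total_reads),
    y = .data$total_reads, fill = .data$length_class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reads", fill = "dominant length class",
                  title = "miRNA family abundance")
}

#' Precursor structure plot
#'
#' Displays the per-position pairing state of a precursor with the mature
#' and star intervals highlighted.
#'
#' @param candidate one row of [find_precursors()] output.
#' @return a ggplot object.
#' @export
plot_precursor <- function(candidate) {
  n <- nchar(candidate$precursor)
  paired <- !is.na(db_partners(candidate$structure))
  d <- tibble(pos = seq_len(n), paired = paired,
              region = dplyr::case_when(
                seq_len(n) >= candidate$mature_start &
                  seq_len(n) <= candidate$mature_end ~ "mature",
                seq_len(n) >= candidate$star_start &
                  seq_len(n) <= candidate$star_end ~ "star",
                TRUE ~ "other"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = as.integer(.data$paired),
                                  fill = .data$region)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "precursor position", y = "paired",
                  title = sprintf("%s  (%.1f kcal/mol)",
                                  candidate$transcript_id, candidate$energy))
}
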