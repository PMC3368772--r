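# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rna <- function(n, bases = c("A", "C", "G", "U"),
                       prob = rep(0.25, length(bases))) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

#' Configuration of the synthetic small-RNA study
#'
#' The generator emulates the statistical structure of a deeply sequenced
#' plant small-RNA library: a handful of predominant conserved families
#' (read counts spanning roughly a hundred to tens of thousands), a heavy
#' singleton/doubleton skew among unique background sequences (32% seen
#' once, 53% twice), read lengths concentrated at the 21/24 nt miRNA/siRNA
#' modes with a long-species shoulder at 27 nt, star strands at a few
#' percent of their mature, planted editing and -1+UU isoforms, and
#' degradation fragments sampled from the transcripts themselves.  All draws
#' are fixed by `seed`.
#'
#' @param seed integer seed fixing every draw.
#' @param n_families conserved families in the mature database.
#' @param n_predominant families planted above 1,000 reads.
#' @param predominant_range,minor_range log-uniform abundance ranges for
#'   predominant and minor families.
#' @param singleton_fraction,doubleton_fraction fractions of unique
#'   background sequences seen once / twice.
#' @param length_weights named numeric vector of sampling weights over
#'   insert lengths 17-32 for background fragments.
#' @param n_planted_hairpins,n_decoy_hairpins rule-satisfying precursor loci
#'   and single-rule-violating decoy loci planted in the transcriptome.
#' @param editing tibble (`family_index`, `position`, `rate`) of planted
#'   single-nucleotide editing events.
#' @param minus1_uu tibble (`family_index`, `rate`) of planted -1+UU
#'   isoforms.
#' @param star_ratio star/mature abundance ratio.
#' @param adapter 3' adapter appended to every raw read.
#' @param n_background_unique unique degradation fragments.
#' @param n_transcripts background transcripts (hairpin loci get their own).
#' @param transcript_len length range of background transcripts.
#' @param deterministic_counts plant isoform counts as rounded expectations
#'   instead of binomial draws (keeps event frequencies exact).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_families = 30L, n_predominant = 12L,
                             predominant_range = c(1500, 20000),
                             minor_range = c(20, 800),
                             singleton_fraction = 0.32,
                             doubleton_fraction = 0.53,
                             length_weights = NULL,
                             n_planted_hairpins = 20L,
                             n_decoy_hairpins = 20L,
                             editing = NULL, minus1_uu = NULL,
                             star_ratio = 0.05,
                             adapter = "UCGUAUGCCGUCUUCUGCUUGU",
                             n_background_unique = 2000L,
                             n_transcripts = 30L,
                             transcript_len = c(300L, 700L),
                             deterministic_counts = TRUE) {
  if (singleton_fraction + doubleton_fraction > 1) {
    abort("singleton + doubleton fractions exceed 1")
  }
  if (is.null(length_weights)) {
    length_weights <- setNames(
      c(2, 1, 2, 3, 6, 2, 2, 10, 2, 2, 8, 1, 1, 1, 1, 1), as.character(17:32))
  }
  if (is.null(editing)) {
    editing <- tibble(family_index = c(1L, 2L, 3L, 4L),
                      position = c(10L, 16L, 5L, 12L),
                      rate = c(1 / 13, 0.04, 0.062, 0.02))
  }
  if (is.null(minus1_uu)) {
    minus1_uu <- tibble(family_index = c(1L, 5L), rate = c(0.03, 0.01))
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 n_predominant = as.integer(n_predominant),
                 predominant_range = predominant_range,
                 minor_range = minor_range,
                 singleton_fraction = singleton_fraction,
                 doubleton_fraction = doubleton_fraction,
                 length_weights = length_weights,
                 n_planted_hairpins = as.integer(n_planted_hairpins),
                 n_decoy_hairpins = as.integer(n_decoy_hairpins),
                 editing = editing, minus1_uu = minus1_uu,
                 star_ratio = star_ratio, adapter = normalize_rna(adapter),
                 n_background_unique = as.integer(n_background_unique),
                 n_transcripts = as.integer(n_transcripts),
                 transcript_len = as.integer(transcript_len),
                 deterministic_counts = isTRUE(deterministic_counts)),
            class = "synthetic_config")
}

# one rule-satisfying precursor: GC-rich 25-nt arm + weak loop + reverse
# complement; the mature is arm positions 3..23 so both duplex ends carry
# the 2-nt overhang geometry
build_planted_precursor <- function() {
  arm <- random_rna(25, prob = c(0.15, 0.35, 0.35, 0.15))
  loop <- random_rna(15, bases = c("A", "C"), prob = c(0.7, 0.3))
  precursor <- paste0(arm, loop, revcomp_rna(arm))
  list(precursor = precursor, mature = substr(precursor, 3, 23),
       mature_at = c(3L, 23L))
}

mutate_base <- function(seq, pos, avoid_pair_with) {
  partners <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")
  ok <- setdiff(c("A", "C", "G", "U"), partners[[avoid_pair_with]])
  b <- sample(ok, 1)
  paste0(substr(seq, 1, pos - 1), b, substr(seq, pos + 1, nchar(seq)))
}

build_decoy_precursor <- function(rule) {
  arm <- random_rna(25, prob = c(0.15, 0.35, 0.35, 0.15))
  loop <- random_rna(15, bases = c("A", "C"), prob = c(0.7, 0.3))
  if (rule == "duplex_unpaired") {
    # long stem with a 7-nt bulge opposite mature positions 10-16: seven
    # unpaired duplex nucleotides while the flanking helices stay strong.
    # The bulged bases are S-only and the loop A-only so the bulge cannot
    # re-pair locally.
    arm <- paste0(substr(random_rna(30, prob = c(0.15, 0.35, 0.35, 0.15)), 1, 9),
                  random_rna(7, bases = c("C", "G"), prob = c(0.5, 0.5)),
                  substr(random_rna(30, prob = c(0.15, 0.35, 0.35, 0.15)), 17, 30))
    loop <- strrep("A", 15)
    rc <- revcomp_rna(arm)
    # delete the star bases opposite mature 10..16 (arm indices 10..16 map
    # to rc indices 30-16+1 .. 30-10+1 = 15..21)
    star_arm <- paste0(substr(rc, 1, 14), substr(rc, 22, 30))
    precursor <- paste0(arm, loop, star_arm)
    mature_at <- c(3L, 23L)
  } else if (rule == "energy") {
    # A/U-only stem: even the best-case stack sum of a 23-bp A:U helix stays
    # above the -25 kcal/mol bound.  C-only buffers keep chance flank
    # complementarity from extending the stem.
    arm <- random_rna(23, bases = c("A", "U"), prob = c(0.5, 0.5))
    buf <- strrep("C", 8L)
    precursor <- paste0(buf, arm, loop, revcomp_rna(arm), buf)
    mature_at <- c(11L, 31L)
  } else if (rule == "loop_long") {
    spacer <- random_rna(300, bases = c("A", "C"), prob = c(0.6, 0.4))
    precursor <- paste0(arm, spacer, revcomp_rna(arm))
    mature_at <- c(3L, 23L)
  } else if (rule == "mature_length") {
    arm <- random_rna(28, prob = c(0.15, 0.35, 0.35, 0.15))
    precursor <- paste0(arm, loop, revcomp_rna(arm))
    mature_at <- c(3L, 26L)   # 24-nt defining read, outside 20-22
  } else if (rule == "mature_in_loop") {
    stem <- random_rna(22, prob = c(0.15, 0.35, 0.35, 0.15))
    core <- random_rna(21, bases = c("A", "C"), prob = c(0.6, 0.4))
    precursor <- paste0(stem, core, revcomp_rna(stem))
    mature_at <- c(23L, 43L)
  } else {
    abort(sprintf("unknown decoy rule '%s'", rule))
  }
  list(precursor = precursor,
       mature = substr(precursor, mature_at[1], mature_at[2]),
       mature_at = mature_at, rule = rule)
}

#' Generate the synthetic transcriptome with planted ground truth
#'
#' Builds background transcripts, a mature miRNA family database, hairpin
#' precursor loci engineered to satisfy every [precursor_rules()] criterion,
#' decoy loci violating exactly one named rule each, planted target sites
#' (perfect, one-wobble, and a shuffled decoy per miRNA used), and the
#' annotated reference set used for read categorization.
#'
#' @param config a [synthetic_config()].
#' @return list with tibbles `transcripts`, `mature_db`, `references`, and a
#'   `truth` list (`precursors`, `decoys`, `targets`).  Fully deterministic
#'   given `config$seed`.
#' @export
generate_transcriptome <- function(config) {
  with_local_seed(config$seed, {
    # mature family database
    fam <- sprintf("sfam%02d", seq_len(config$n_families))
    mat_len <- sample(c(20L, 21L, 22L), config$n_families, replace = TRUE,
                      prob = c(0.2, 0.6, 0.2))
    mature_db <- tibble(
      id = paste0(fam, "-mat"),
      seq = vapply(mat_len, random_rna, character(1)),
      family = fam
    )
    # background transcripts
    tr_len <- sample(seq(config$transcript_len[1], config$transcript_len[2]),
                     config$n_transcripts, replace = TRUE)
    transcripts <- tibble(
      id = sprintf("syn_tr_%03d", seq_len(config$n_transcripts)),
      seq = vapply(tr_len, random_rna, character(1))
    )
    # planted hairpin loci, one transcript each
    prec_rows <- list()
    for (k in seq_len(config$n_planted_hairpins)) {
      p <- build_planted_precursor()
      fl <- random_rna(sample(40:80, 1)); fr <- random_rna(sample(40:80, 1))
      tid <- sprintf("syn_hp_%03d", k)
      tseq <- paste0(fl, p$precursor, fr)
      off <- nchar(fl)
      transcripts <- bind_rows(transcripts, tibble(id = tid, seq = tseq))
      prec_rows[[k]] <- tibble(
        transcript_id = tid, mature = p$mature,
        mature_start = off + p$mature_at[1], mature_end = off + p$mature_at[2],
        precursor_start = off + 1L, precursor_end = off + nchar(p$precursor)
      )
    }
    # decoys, one rule broken each
    decoy_rules <- rep(c("duplex_unpaired", "energy", "loop_long",
                         "mature_length", "mature_in_loop"),
                       length.out = config$n_decoy_hairpins)
    decoy_rows <- list()
    for (k in seq_len(config$n_decoy_hairpins)) {
      d <- build_decoy_precursor(decoy_rules[k])
      fl <- random_rna(sample(40:80, 1)); fr <- random_rna(sample(40:80, 1))
      tid <- sprintf("syn_decoy_%03d", k)
      transcripts <- bind_rows(transcripts,
                               tibble(id = tid, seq = paste0(fl, d$precursor, fr)))
      off <- nchar(fl)
      decoy_rows[[k]] <- tibble(
        transcript_id = tid, mature = d$mature,
        mature_start = off + d$mature_at[1], mature_end = off + d$mature_at[2],
        precursor_start = off + 1L, precursor_end = off + nchar(d$precursor),
        violated_rule = d$rule
      )
    }
    # planted target sites for the first miRNAs long enough for the
    # conserved-mode alignment-length bound
    target_rows <- list()
    long_mirs <- head(which(nchar(mature_db$seq) >= 21), 4)
    for (k in seq_along(long_mirs)) {
      mir <- mature_db$seq[long_mirs[k]]
      site_perfect <- revcomp_rna(mir)
      # one G:U wobble at a miRNA position where the base allows it
      wob_pos <- setdiff(which(strsplit(mir, "")[[1]] %in% c("G", "U")),
                         c(10L, 11L))
      site_wobble <- NULL
      if (length(wob_pos)) {
        p <- wob_pos[1]
        b <- substr(mir, p, p)
        sw <- strsplit(site_perfect, "")[[1]]
        sw[nchar(mir) - p + 1L] <- if (b == "G") "U" else "G"
        site_wobble <- paste(sw, collapse = "")
      }
      site_decoy <- paste(sample(strsplit(site_perfect, "")[[1]]), collapse = "")
      tri <- sample(seq_len(config$n_transcripts), 3)
      plant <- function(tr_idx, site, kind, pen) {
        tseq <- transcripts$seq[tr_idx]
        pos <- sample(seq(30L, nchar(tseq) - nchar(site) - 30L), 1)
        transcripts$seq[tr_idx] <<- paste0(
          substr(tseq, 1, pos - 1L), site,
          substr(tseq, pos + nchar(site), nchar(tseq)))
        tibble(mirna_id = mature_db$id[long_mirs[k]],
               transcript_id = transcripts$id[tr_idx],
               start = pos, end = pos + nchar(site) - 1L,
               kind = kind, expected_penalty = pen)
      }
      target_rows[[length(target_rows) + 1L]] <-
        plant(tri[1], site_perfect, "perfect", 0)
      if (!is.null(site_wobble)) {
        target_rows[[length(target_rows) + 1L]] <-
          plant(tri[2], site_wobble, "wobble", 0.5)
      }
      target_rows[[length(target_rows) + 1L]] <-
        plant(tri[3], site_decoy, "decoy", NA_real_)
    }
    references <- bind_rows(
      transcripts |> mutate(category = "coding mRNA"),
      tibble(id = sprintf("syn_rrna_%d", 1:3),
             seq = vapply(c(120L, 160L, 200L), random_rna, character(1)),
             category = "rRNA"),
      tibble(id = sprintf("syn_trna_%d", 1:3),
             seq = vapply(c(76L, 76L, 76L), random_rna, character(1)),
             category = "tRNA"),
      tibble(id = sprintf("syn_te_%d", 1:2),
             seq = vapply(c(250L, 300L), random_rna, character(1)),
             category = "transposon"),
      mature_db |> select("id", "seq") |> mutate(category = "miRNA")
    )
    list(transcripts = transcripts, mature_db = mature_db,
         references = references,
         truth = list(precursors = bind_rows(prec_rows),
                      decoys = bind_rows(decoy_rows),
                      targets = bind_rows(target_rows)))
  })
}

round_count <- function(n, rate, deterministic) {
  if (deterministic) as.integer(round(n * rate)) else rbinom(1, n, rate)
}

#' Generate the raw read library over a synthetic transcriptome
#'
#' Plants family reads at log-uniform abundances (with editing, -1+UU and
#' star isoforms at their configured rates), mature/star read stacks on
#' every planted hairpin and decoy locus, and background degradation
#' fragments sampled from the transcripts with the configured
#' singleton/doubleton skew.  The 3' adapter is appended to every read.
#'
#' @param config a [synthetic_config()].
#' @param sim output of [generate_transcriptome()] under the same config.
#' @return list: `reads` (tibble `id`, `seq`, `qual`, adapter-bearing raw
#'   reads in randomized order) and `truth` extended with `families`
#'   (planted per-family totals and expected modification frequencies) and
#'   `hairpin_reads`.
#' @export
generate_library <- function(config, sim) {
  with_local_seed(config$seed + 1L, {
    det <- config$deterministic_counts
    n_pre <- min(config$n_predominant, config$n_families)
    loguni <- function(n, range) {
      as.integer(round(exp(runif(n, log(range[1]), log(range[2])))))
    }
    abundance <- c(loguni(n_pre, config$predominant_range),
                   loguni(config$n_families - n_pre, config$minor_range))
    inserts <- list(); truth_fams <- list()
    for (i in seq_len(config$n_families)) {
      fam <- sim$mature_db$family[i]
      ref <- sim$mature_db$seq[i]
      A <- abundance[i]
      ed <- config$editing[config$editing$family_index == i, , drop = FALSE]
      uu <- config$minus1_uu[config$minus1_uu$family_index == i, , drop = FALSE]
      n_ed <- if (nrow(ed)) vapply(ed$rate, function(r)
        round_count(A, r, det), integer(1)) else integer(0)
      n_uu <- if (nrow(uu)) round_count(A, uu$rate, det) else 0L
      n_mat <- A - sum(n_ed) - n_uu
      stopifnot(n_mat > 0)
      fam_seqs <- c(rep(ref, n_mat))
      ed_seqs <- character(0)
      if (nrow(ed)) {
        for (e in seq_len(nrow(ed))) {
          b <- substr(ref, ed$position[e], ed$position[e])
          alt <- sample(setdiff(c("A", "C", "G", "U"), b), 1)
          ed_seqs <- c(ed_seqs, rep(paste0(substr(ref, 1, ed$position[e] - 1L),
                                           alt,
                                           substr(ref, ed$position[e] + 1L, nchar(ref))),
                                    n_ed[e]))
        }
      }
      uu_seq <- paste0(substr(ref, 2, nchar(ref)), "UU")
      star <- revcomp_rna(substr(ref, 3, nchar(ref)))  # offset star isoform
      n_star <- max(0L, round_count(A, config$star_ratio, det))
      inserts[[length(inserts) + 1L]] <-
        c(fam_seqs, ed_seqs, rep(uu_seq, n_uu), rep(star, n_star))
      truth_fams[[length(truth_fams) + 1L]] <- tibble(
        family = fam, planted_reads = A,
        editing_freq = if (length(n_ed)) list(round(100 * n_ed / A, 3)) else list(numeric(0)),
        editing_position = if (nrow(ed)) list(ed$position) else list(integer(0)),
        minus1_uu_reads = n_uu,
        minus1_uu_freq = round(100 * n_uu / A, 3)
      )
    }
    # hairpin locus read stacks
    hp_reads <- list()
    for (k in seq_len(nrow(sim$truth$precursors))) {
      row <- sim$truth$precursors[k, ]
      cnt <- sample(50:400, 1)
      tseq <- sim$transcripts$seq[sim$transcripts$id == row$transcript_id]
      # star read: the strand pairing the mature with 2-nt 3' overhangs on
      # both duplex ends, read off the planted precursor geometry
      prec <- substr(tseq, row$precursor_start, row$precursor_end)
      pl <- nchar(prec)
      m1 <- row$mature_start - row$precursor_start + 1L
      m2 <- row$mature_end - row$precursor_start + 1L
      s1 <- pl - (m2 - 2L) + 1L; s2 <- pl - m1 + 1L + 2L
      s2 <- min(s2, pl)
      star_seq <- substr(prec, s1, s2)
      n_star <- max(1L, round(cnt * config$star_ratio))
      hp_reads[[length(hp_reads) + 1L]] <- tibble(
        transcript_id = row$transcript_id,
        seq = c(row$mature, star_seq),
        count = c(cnt, n_star), role = c("mature", "star")
      )
    }
    for (k in seq_len(nrow(sim$truth$decoys))) {
      row <- sim$truth$decoys[k, ]
      hp_reads[[length(hp_reads) + 1L]] <- tibble(
        transcript_id = row$transcript_id, seq = row$mature,
        count = sample(40:120, 1), role = "decoy_mature"
      )
    }
    hp_reads <- bind_rows(hp_reads)
    if (nrow(hp_reads) == 0L) {
      hp_reads <- tibble(transcript_id = character(), seq = character(),
                         count = integer(), role = character())
    }
    # background degradation fragments
    lens <- as.integer(names(config$length_weights))
    planted_set <- unique(c(sim$mature_db$seq, hp_reads$seq))
    bg <- character(0)
    guard <- 0L
    while (length(bg) < config$n_background_unique && guard < 50L) {
      need <- config$n_background_unique - length(bg)
      li <- sample(lens, need * 1.2, replace = TRUE,
                   prob = config$length_weights)
      ti <- sample(nrow(sim$transcripts), need * 1.2, replace = TRUE)
      frag <- vapply(seq_along(li), function(q) {
        ts <- sim$transcripts$seq[ti[q]]
        if (nchar(ts) <= li[q]) return(NA_character_)
        st <- sample(nchar(ts) - li[q], 1)
        substr(ts, st, st + li[q] - 1L)
      }, character(1))
      frag <- frag[!is.na(frag)]
      bg <- unique(c(bg, setdiff(frag, planted_set)))
      guard <- guard + 1L
    }
    bg <- head(bg, config$n_background_unique)
    cat3 <- 1 - config$singleton_fraction - config$doubleton_fraction
    bg_count <- sample(c(1L, 2L, 0L), length(bg), replace = TRUE,
                       prob = c(config$singleton_fraction,
                                config$doubleton_fraction, cat3))
    bg_count[bg_count == 0L] <- sample(3:8, sum(bg_count == 0L), replace = TRUE)
    all_inserts <- c(unlist(inserts, use.names = FALSE),
                     rep(hp_reads$seq, hp_reads$count),
                     rep(bg, bg_count))
    all_inserts <- sample(all_inserts)
    reads <- tibble(
      id = sprintf("read_%07d", seq_along(all_inserts)),
      seq = paste0(all_inserts, config$adapter),
      qual = strrep("I", nchar(all_inserts) + nchar(config$adapter))
    )
    truth <- sim$truth
    truth$families <- bind_rows(truth_fams)
    truth$hairpin_reads <- hp_reads
    truth$n_background_unique <- length(bg)
    list(reads = reads, truth = truth)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `reads.fastq`, `transcripts.fa`, `references.fa`, `mature_db.fa`
#' and `truth.json` into `dir`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the in-memory dataset (as from
#'   [generate_transcriptome()] plus `reads`).
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- generate_transcriptome(config)
  lib <- generate_library(config, sim)
  write_fastq(lib$reads, file.path(dir, "reads.fastq"))
  write_fasta(sim$transcripts, file.path(dir, "transcripts.fa"))
  refs <- sim$references |>
    mutate(desc = paste0("category=", gsub(" ", "_", .data$category)))
  write_fasta(refs, file.path(dir, "references.fa"))
  mats <- sim$mature_db |> mutate(desc = paste0("family=", .data$family))
  write_fasta(mats, file.path(dir, "mature_db.fa"))
  truth <- lib$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(reads = lib$reads, truth = lib$truth)))
}
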