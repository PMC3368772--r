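small_cfg <- function(seed = 42L) {
  synthetic_config(seed = seed, n_families = 8L, n_predominant = 3L,
                   n_planted_hairpins = 5L, n_decoy_hairpins = 5L,
                   n_background_unique = 300L, n_transcripts = 12L)
}

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- small_cfg()
  s1 <- generate_transcriptome(cfg); s2 <- generate_transcriptome(cfg)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$mature_db, s2$mature_db)
  expect_identical(s1$truth, s2$truth)
  l1 <- generate_library(cfg, s1); l2 <- generate_library(cfg, s2)
  expect_identical(l1$reads, l2$reads)
})

test_that("planted precursor loci pass the independent rule validator", {
  cfg <- small_cfg()
  sim <- generate_transcriptome(cfg)
  expect_equal(nrow(sim$truth$precursors), 5L)
  for (k in seq_len(5L)) {
    row <- sim$truth$precursors[k, ]
    ts <- sim$transcripts$seq[sim$transcripts$id == row$transcript_id]
    pre <- substr(ts, row$precursor_start, row$precursor_end)
    v <- validate_precursor(pre, row$mature_start - row$precursor_start + 1L,
                            row$mature_end - row$precursor_start + 1L)
    expect_true(all(v$pass), info = row$transcript_id)
  }
})

test_that("each decoy violates its registered rule; the bulged decoy violates only it", {
  cfg <- small_cfg()
  sim <- generate_transcriptome(cfg)
  named <- c(duplex_unpaired = "duplex_unpaired", energy = "energy",
             loop_long = "loop_distance", mature_length = "mature_length",
             mature_in_loop = "mature_in_arm")
  for (k in seq_len(nrow(sim$truth$decoys))) {
    d <- sim$truth$decoys[k, ]
    ts <- sim$transcripts$seq[sim$transcripts$id == d$transcript_id]
    pre <- substr(ts, d$precursor_start, d$precursor_end)
    v <- validate_precursor(pre, d$mature_start - d$precursor_start + 1L,
                            d$mature_end - d$precursor_start + 1L)
    failed <- v$rule[!v$pass]
    expect_true(named[[d$violated_rule]] %in% failed, info = d$violated_rule)
    if (d$violated_rule == "duplex_unpaired") {
      expect_identical(failed, "duplex_unpaired")
    }
  }
})

test_that("planted hairpin star reads follow the configured star/mature ratio", {
  cfg <- small_cfg()
  sim <- generate_transcriptome(cfg)
  lib <- generate_library(cfg, sim)
  hp <- lib$truth$hairpin_reads
  for (tid in unique(hp$transcript_id[hp$role == "star"])) {
    cnt <- hp$count[hp$transcript_id == tid & hp$role == "mature"]
    star <- hp$count[hp$transcript_id == tid & hp$role == "star"]
    expect_equal(star, max(1L, round(cnt * cfg$star_ratio)))
  }
})

test_that("planted editing and -1+UU isoforms are recovered at their deterministic frequencies", {
  cfg <- small_cfg(seed = 9L)
  sim <- generate_transcriptome(cfg)
  lib <- generate_library(cfg, sim)
  raw <- tibble::tibble(seq = lib$reads$seq)
  pre <- preprocess_reads(raw, adapter3 = cfg$adapter)
  asg <- assign_families(pre, sim$mature_db)
  for (k in seq_len(nrow(cfg$editing))) {
    fam <- sim$mature_db$family[cfg$editing$family_index[k]]
    truth <- lib$truth$families[lib$truth$families$family == fam, ]
    ev <- detect_editing(asg[asg$family == fam, c("seq", "count")],
                         sim$mature_db$seq[cfg$editing$family_index[k]])
    expect_equal(ev$frequency[1], truth$editing_freq[[1]][1], info = fam)
    expect_equal(ev$position[1], cfg$editing$position[k])
  }
  for (k in seq_len(nrow(cfg$minus1_uu))) {
    idx <- cfg$minus1_uu$family_index[k]
    fam <- sim$mature_db$family[idx]
    truth <- lib$truth$families[lib$truth$families$family == fam, ]
    fr <- asg[asg$family == fam, ]
    uu <- detect_minus1_uu(fr$seq, sim$mature_db$seq[idx])
    expect_equal(sum(fr$count[uu]), truth$minus1_uu_reads)
  }
})

test_that("the unique-sequence singleton fraction lands within 3% of its 32% target", {
  cfg <- synthetic_config(seed = 31L, n_families = 5L, n_predominant = 2L,
                          n_planted_hairpins = 0L, n_decoy_hairpins = 0L,
                          n_background_unique = 50000L, n_transcripts = 60L,
                          transcript_len = c(900L, 1500L))
  sim <- generate_transcriptome(cfg)
  lib <- generate_library(cfg, sim)
  pre <- preprocess_reads(tibble::tibble(seq = lib$reads$seq),
                          adapter3 = cfg$adapter)
  g <- glance(pre)
  # family reads perturb the fractions only marginally at this scale
  expect_lt(abs(g$singleton_fraction - 0.32), 0.03)
  expect_lt(abs(g$doubleton_fraction - 0.53), 0.03)
})

test_that("simulate_dataset writes a readable, consistent bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 3L)
  out <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("reads.fastq", "transcripts.fa", "references.fa",
           "mature_db.fa", "truth.json")))))
  reads <- read_fastq(file.path(dir, "reads.fastq"))
  expect_equal(nrow(reads), nrow(out$reads))
  refs <- read_fasta(file.path(dir, "references.fa"))
  expect_true("category" %in% names(refs))
  mats <- read_fasta(file.path(dir, "mature_db.fa"))
  expect_equal(sort(mats$family), sort(out$mature_db$family))
})
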