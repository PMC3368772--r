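test_that("a single substituted read among 13 gives the 7.692% frequency", {
  ref <- "UUGACAGAAGAUAGAGAGC"          # position 10 is G
  edited <- paste0(substr(ref, 1, 9), "A", substr(ref, 11, 19))
  fam <- tibble::tibble(seq = c(ref, edited), count = c(12L, 1L))
  ev <- detect_editing(fam, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$frequency, 7.692)
  expect_equal(ev$label, "G-A: 7.692%")
  expect_equal(ev$position, 10L)
})

test_that("identical reads yield no events; distinct substitutions are additive", {
  ref <- "UUGACAGAAGAUAGAGAGC"
  expect_equal(nrow(detect_editing(tibble::tibble(seq = ref, count = 10L), ref)),
               0L)
  e1 <- paste0("A", substr(ref, 2, 19))       # U1A
  e2 <- paste0(substr(ref, 1, 4), "G", substr(ref, 6, 19))  # C5G
  fam <- tibble::tibble(seq = c(ref, e1, e2), count = c(8L, 1L, 1L))
  ev <- detect_editing(fam, ref)
  expect_equal(nrow(ev), 2L)
  expect_equal(sum(ev$frequency), round(100 * 2 / 10, 3))
})

test_that("substitutions in 5'/3' extensions beyond the reference are ignored", {
  ref <- "UUGACAGAAGAUAGAGAGC"
  ext <- paste0(ref, "AGG")   # extension only, zero mismatches in the body
  fam <- tibble::tibble(seq = c(ref, ext), count = c(5L, 2L))
  expect_equal(nrow(detect_editing(fam, ref)), 0L)
  expect_error(detect_editing(tibble::tibble(seq = character(0),
                                             count = integer(0)), ref),
               "zero")
})

test_that("supporting reads never exceed the family total", {
  set.seed(424)
  for (k in 1:20) {
    ref <- random_rna_str(21)
    n <- sample(2:6, 1)
    seqs <- vapply(seq_len(n), function(i) {
      if (i == 1) return(ref)
      p <- sample(21, 1)
      b <- sample(setdiff(c("A", "C", "G", "U"), substr(ref, p, p)), 1)
      paste0(substr(ref, 1, p - 1), b, substr(ref, p + 1, 21))
    }, character(1))
    fam <- tibble::tibble(seq = seqs, count = sample(1:20, n, replace = TRUE))
    ev <- detect_editing(fam, ref)
    expect_lte(sum(ev$reads), sum(fam$count))
    expect_true(all(ev$frequency > 0 & ev$frequency <= 100))
  }
})

test_that("the -1+UU isoform is exactly the 5'-deleted, 3'-uridylated sequence", {
  ref <- "UUGACAGAAGAUAGAGAGC"
  expect_true(detect_minus1_uu("UGACAGAAGAUAGAGAGCUU", ref))
  expect_false(detect_minus1_uu(ref, ref))
  expect_false(detect_minus1_uu("UGACAGAAGAUAGAGAGCU", ref))   # single U
  expect_false(detect_minus1_uu("GACAGAAGAUAGAGAGCUU", ref))   # -2 deletion
  set.seed(425)
  for (k in 1:30) {
    r <- random_rna_str(sample(19:24, 1))
    iso <- paste0(substr(r, 2, nchar(r)), "UU")
    expect_true(detect_minus1_uu(iso, r))
    expect_equal(nchar(iso), nchar(r) + 1L)
  }
})

test_that("editing planted at a binomial rate is recovered within three standard errors", {
  set.seed(426)
  ref <- random_rna_str(21)
  p <- 0.05; n <- 2000L
  k <- rbinom(1, n, p)
  edited <- paste0(substr(ref, 1, 9),
                   sample(setdiff(c("A", "C", "G", "U"), substr(ref, 10, 10)), 1),
                   substr(ref, 11, 21))
  fam <- tibble::tibble(seq = c(ref, edited), count = c(n - k, k))
  ev <- detect_editing(fam, ref)
  se <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(ev$frequency - 100 * p), 3 * se)
})

test_that("the family-level table joins substitution labels and -1+UU flags", {
  ref <- "UUGACAGAAGAUAGAGAGC"
  db <- tibble::tibble(id = "f-mat", seq = ref, family = "famF")
  asg <- tibble::tibble(
    seq = c(ref, paste0(substr(ref, 1, 9), "A", substr(ref, 11, 19)),
            paste0(substr(ref, 2, 19), "UU")),
    count = c(11L, 1L, 1L),
    family = "famF", ref_id = "f-mat", overlap = c(19L, 19L, 18L),
    mismatches = 0L, offset = 0L
  )
  tbl <- detect_modifications(asg, db)
  expect_equal(tbl$minus1_uu, "yes")
  expect_equal(tbl$minus1_uu_reads, 1L)
  expect_match(tbl$modifications, "^G-A: 7\\.692%$")
})
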