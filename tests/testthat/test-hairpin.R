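# a rule-satisfying hairpin embedded mid-transcript: 25-bp arm, weak loop,
# mature at arm positions 3..23
make_hairpin_transcript <- function(loop = strrep("A", 15)) {
  arm <- random_rna_str(25)
  while (sum(strsplit(arm, "")[[1]] %in% c("G", "C")) < 14) {
    arm <- random_rna_str(25)
  }
  pre <- paste0(arm, loop, revcomp_rna(arm))
  fl <- random_rna_str(60); fr <- random_rna_str(60)
  list(transcript = tibble::tibble(id = "t1", seq = paste0(fl, pre, fr)),
       mature = substr(pre, 3, 23),
       mature_tr = c(nchar(fl) + 3L, nchar(fl) + 23L))
}

test_that("an engineered precursor is recovered exactly once with correct coordinates", {
  set.seed(417)
  hp <- make_hairpin_transcript()
  pc <- find_precursors(hp$transcript, hp$mature)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$start + pc$mature_start - 1L, hp$mature_tr[1])
  expect_equal(pc$start + pc$mature_end - 1L, hp$mature_tr[2])
  expect_lte(pc$energy, -25)
  v <- validate_precursor(pc$precursor, pc$mature_start, pc$mature_end,
                          structure = pc$structure, energy = pc$energy)
  expect_true(all(v$pass))
})

test_that("a duplex with more than six unpaired nucleotides is rejected", {
  set.seed(418)
  arm <- paste0(substr(random_rna_str(30), 1, 9),
                paste(sample(c("C", "G"), 7, TRUE), collapse = ""),
                substr(random_rna_str(30), 17, 30))
  rc <- revcomp_rna(arm)
  star_arm <- paste0(substr(rc, 1, 14), substr(rc, 22, 30))  # 7-nt bulge
  pre <- paste0(arm, strrep("A", 15), star_arm)
  tr <- tibble::tibble(id = "t1",
                       seq = paste0(random_rna_str(50), pre, random_rna_str(50)))
  mature <- substr(pre, 3, 23)
  pc <- find_precursors(tr, mature)
  expect_equal(nrow(pc), 0L)
  v <- validate_precursor(pre, 3, 23)
  expect_false(v$pass[v$rule == "duplex_unpaired"])
})

test_that("a mature sitting in the terminal loop is rejected", {
  set.seed(419)
  stem <- random_rna_str(22)
  core <- paste(sample(c("A", "C"), 21, TRUE, prob = c(0.6, 0.4)), collapse = "")
  pre <- paste0(stem, core, revcomp_rna(stem))
  tr <- tibble::tibble(id = "t1",
                       seq = paste0(random_rna_str(50), pre, random_rna_str(50)))
  pc <- find_precursors(tr, core)
  expect_equal(nrow(pc), 0L)
  v <- validate_precursor(pre, 23, 43)
  expect_false(v$pass[v$rule == "mature_in_arm"])
})

test_that("a read absent from every transcript is an error", {
  set.seed(420)
  tr <- tibble::tibble(id = "t1", seq = random_rna_str(200))
  expect_error(find_precursors(tr, strrep("ACGU", 5) |> substr(1, 21)),
               "not found")
})

test_that("star prediction honours the 2-nt 3' overhang geometry", {
  # perfect 25-bp palindrome: partner(p) = L + 1 - p
  set.seed(421)
  arm <- random_rna_str(25)
  pre <- paste0(arm, strrep("A", 15), revcomp_rna(arm))
  f <- rna_fold(pre)
  st <- predict_star(f$structure, 3, 23)
  L <- nchar(pre)
  expect_equal(st, c(L - 21L + 1L, L))       # rc block shifted by the overhang
  expect_equal(st[2] - st[1] + 1L, 21L)
  # star and mature never overlap
  expect_gt(st[1], 23)
})

test_that("a 1-nt bulge on the star arm lengthens the star to 22 nt", {
  set.seed(422)
  arm <- random_rna_str(25)
  while (sum(strsplit(arm, "")[[1]] %in% c("G", "C")) < 14) arm <- random_rna_str(25)
  rc <- revcomp_rna(arm)
  # insert one extra base mid-star so the pairing trace must interpolate
  star_arm <- paste0(substr(rc, 1, 12), "A", substr(rc, 13, 25))
  pre <- paste0(arm, strrep("A", 15), star_arm)
  f <- rna_fold(pre)
  st <- predict_star(f$structure, 3, 23)
  expect_equal(st[2] - st[1] + 1L, 22L)
})

test_that("star prediction fails on an entirely unpaired mature", {
  expect_error(predict_star(strrep(".", 60), 10, 30), "unpaired")
})

test_that("read stacks classify into the five precursor classes", {
  cand <- tibble::tibble(mature_start = 10L, mature_end = 30L,
                         star_start = 60L, star_end = 80L)
  stack <- function(...) tibble::tibble(...)
  # reads only at miR (count 10) and star (count 2): class 1
  expect_equal(classify_precursor(cand, stack(
    start = c(10L, 60L), end = c(30L, 80L), count = c(10L, 2L))), "1")
  # both strands supported plus weaker reads outside: class 2
  expect_equal(classify_precursor(cand, stack(
    start = c(10L, 60L, 100L), end = c(30L, 80L, 120L),
    count = c(10L, 2L, 1L))), "2")
  # miR region only, two or more reads: 3a; a single read: 3b
  expect_equal(classify_precursor(cand, stack(
    start = 10L, end = 30L, count = 2L)), "3a")
  expect_equal(classify_precursor(cand, stack(
    start = 10L, end = 30L, count = 1L)), "3b")
  # defining read plus weaker outside reads, no star: class 4
  expect_equal(classify_precursor(cand, stack(
    start = c(10L, 100L), end = c(30L, 120L), count = c(5L, 2L))), "4")
  # an outside read more abundant than the defining read: class 5
  expect_equal(classify_precursor(cand, stack(
    start = c(10L, 100L), end = c(30L, 120L), count = c(5L, 9L))), "5")
  expect_error(classify_precursor(cand, stack(
    start = integer(0), end = integer(0), count = integer(0))), "empty")
})

test_that("every non-empty read stack receives exactly one class label", {
  set.seed(423)
  cand <- tibble::tibble(mature_start = 20L, mature_end = 40L,
                         star_start = 70L, star_end = 90L)
  for (k in 1:60) {
    n <- sample(1:6, 1)
    st <- sample(1:100, n, replace = TRUE)
    rs <- tibble::tibble(start = st, end = st + 20L,
                         count = sample(1:50, n, replace = TRUE))
    cl <- classify_precursor(cand, rs)
    expect_true(cl %in% c("1", "2", "3a", "3b", "4", "5"))
    expect_length(cl, 1L)
  }
})
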