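make_reference <- function() {
  set.seed(405)
  tibble::tibble(
    id = c("mrna1", "mir1", "trna1", "anon1"),
    seq = c(random_rna_str(120), random_rna_str(60), random_rna_str(76),
            random_rna_str(90)),
    category = c("coding mRNA", "miRNA", "tRNA", NA)
  )
}

test_that("ungapped full-length matching finds plus and minus strand hits", {
  ref <- make_reference()
  q <- substr(ref$seq[1], 31, 51)
  h <- match_reference(q, ref)
  expect_true(any(h$ref_id == "mrna1" & h$start == 31 & h$strand == "+" &
                    h$mismatches == 0))

  qrc <- revcomp_rna(substr(ref$seq[1], 61, 80))
  h <- match_reference(qrc, ref)
  expect_true(any(h$ref_id == "mrna1" & h$strand == "-" & h$mismatches == 0))
})

test_that("matching agrees with a brute-force window scan", {
  set.seed(406)
  ref <- tibble::tibble(id = "r", seq = random_rna_str(80))
  for (k in 1:20) {
    q <- random_rna_str(sample(17:24, 1))
    h <- match_reference(q, ref, max_mismatch = 1)
    brute <- 0L
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else revcomp_rna(q)
      for (s in 1:(80 - nchar(qq) + 1)) {
        w <- substr(ref$seq, s, s + nchar(qq) - 1)
        mm <- sum(strsplit(w, "")[[1]] != strsplit(qq, "")[[1]])
        if (mm <= 1) brute <- brute + 1L
      }
    }
    expect_equal(nrow(h), brute)
  }
  # a query 2 mismatches from every window yields no hit
  q2 <- substr(ref$seq, 11, 31)
  qc <- strsplit(q2, "")[[1]]
  flip <- function(b) c(A = "C", C = "A", G = "U", U = "G")[[b]]
  qc[3] <- flip(qc[3]); qc[10] <- flip(qc[10])
  h <- match_reference(paste(qc, collapse = ""), ref, max_mismatch = 1)
  expect_true(!any(h$ref_id == "r" & h$start == 11))
})

test_that("categorization applies precedence, no-hit and hit-unknown rules", {
  ref <- make_reference()
  # equal-mismatch hits on an mRNA and a miRNA record -> miRNA by precedence
  hits <- tibble::tibble(ref_id = c("mrna1", "mir1"), start = c(1L, 1L),
                         strand = "+", mismatches = c(0L, 0L))
  expect_equal(categorize(hits, ref)$category, "miRNA")

  none <- hits[0, ]
  expect_equal(categorize(none, ref)$category, "no hit")

  anon <- tibble::tibble(ref_id = "anon1", start = 5L, strand = "+",
                         mismatches = 0L)
  expect_equal(categorize(anon, ref)$category, "hit, unknown")
})

test_that("category calls partition the library and are monotone in max_mismatch", {
  set.seed(407)
  ref <- make_reference()
  reads <- c(
    substr(ref$seq[1], 1, 20), substr(ref$seq[2], 10, 30),
    substr(ref$seq[3], 20, 40), substr(ref$seq[4], 5, 25),
    replicate(12, random_rna_str(sample(17:28, 1)))
  )
  lib <- collapse_reads(rep(reads, sample(1:4, length(reads), replace = TRUE)))
  calls <- classify_reads(lib, ref)
  expect_equal(nrow(calls), nrow(lib))
  sumtab <- summarize_categories(calls)
  expect_equal(sum(sumtab$unique_reads), nrow(lib))
  expect_equal(sum(sumtab$total_reads), attr(lib, "total_clean"))

  for (k in 1:10) {
    q <- lib$seq[k]
    h0 <- match_reference(q, ref, max_mismatch = 0)
    h1 <- match_reference(q, ref, max_mismatch = 1)
    expect_lte(nrow(h0), nrow(h1))
  }
})

test_that("planted categories are recovered exactly on disjoint references", {
  set.seed(408)
  ref <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = vapply(c(100L, 100L, 100L), random_rna_str, character(1)),
    category = c("rRNA", "tRNA", "transposon")
  )
  truth <- c(rep("rRNA", 3), rep("tRNA", 2), rep("transposon", 4))
  reads <- c(
    vapply(1:3, function(i) substr(ref$seq[1], i * 10, i * 10 + 20), character(1)),
    vapply(1:2, function(i) substr(ref$seq[2], i * 15, i * 15 + 21), character(1)),
    vapply(1:4, function(i) substr(ref$seq[3], i * 8, i * 8 + 19), character(1))
  )
  lib <- collapse_reads(reads)
  calls <- classify_reads(lib, ref)
  got <- calls$category[match(reads, calls$seq)]
  expect_equal(got, truth)
})
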