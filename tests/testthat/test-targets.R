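embed_site <- function(site, left = 30, right = 30) {
  tibble::tibble(id = "t1",
                 seq = paste0(random_rna_str(left), site, random_rna_str(right)))
}

test_that("a perfect reverse-complement site scores penalty 0; one wobble scores 0.5", {
  set.seed(427)
  mir <- random_rna_str(21)
  tr <- embed_site(revcomp_rna(mir))
  s <- align_targets(tibble::tibble(id = "m", seq = mir), tr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$penalty, 0)
  expect_equal(s$start, 31L)
  expect_equal(s$end, 51L)

  # flip one non-constrained site base to make a single G:U wobble
  wpos <- setdiff(which(strsplit(mir, "")[[1]] %in% c("G", "U")), c(10, 11))[1]
  expect_false(is.na(wpos))   # deterministic under the fixed seed
  site <- strsplit(revcomp_rna(mir), "")[[1]]
  site[21 - wpos + 1] <- if (substr(mir, wpos, wpos) == "G") "U" else "G"
  s <- align_targets(tibble::tibble(id = "m", seq = mir),
                     embed_site(paste(site, collapse = "")))
  expect_equal(s$penalty, 0.5)
})

test_that("the published miR156/Squamosa duplex is reported with its printed geometry", {
  mir <- "UGACAGAAGAGAGAGAGCACAUC"
  site <- "GUUGUGCUCUCUCUCUUCUGUCA"
  set.seed(428)
  tr <- embed_site(site, 60, 60)
  s <- align_targets(tibble::tibble(id = "hbmir156", seq = mir), tr,
                     target_params("conserved"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$penalty, 1)          # single mismatch, far from the cleavage site
  expect_equal(s$aligned_length, 23L)
  cl <- predict_cleavage(s[1, ])
  expect_equal(cl$cleavage_mir_pos, 10L)
  # position 10 pairs the 14th site base: transcript coordinate start + 13
  expect_equal(cl$cleavage_site, s$start + 13L)
  # the printable block carries the miRNA 3'->5' over the site 5'->3'
  lines <- strsplit(s$duplex, "\n")[[1]]
  expect_equal(lines[1], "CUACACGAGAGAGAGAAGACAGU")
  expect_equal(lines[3], site)
})

test_that("translating the site translates the cleavage coordinate equivariantly", {
  set.seed(429)
  mir <- random_rna_str(21)
  site <- revcomp_rna(mir)
  base <- paste0(random_rna_str(25), site, random_rna_str(40))
  shifted <- paste0(random_rna_str(30), site, random_rna_str(35))
  s1 <- align_targets(tibble::tibble(id = "m", seq = mir),
                      tibble::tibble(id = "t", seq = base))
  s2 <- align_targets(tibble::tibble(id = "m", seq = mir),
                      tibble::tibble(id = "t", seq = shifted))
  expect_equal(s2$cleavage_site - s1$cleavage_site, 5L)
})

test_that("duplex energies are zero when unpaired and ordered by stacking strength", {
  expect_equal(duplex_energy("AAAA", "CCCC"), 0)
  gc <- duplex_energy(strrep("G", 21), strrep("C", 21))
  au <- duplex_energy(strrep("A", 21), strrep("U", 21))
  expect_lt(gc, au)
  # one extra stacked pair can only lower the energy
  set.seed(430)
  for (k in 1:10) {
    m <- random_rna_str(15)
    s <- revcomp_rna(m) |> (\(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""))()
    e0 <- duplex_energy(m, s)
    m1 <- paste0(m, "G"); s1 <- paste0(s, "C")
    expect_lte(duplex_energy(m1, s1), e0 + 1e-9)
  }
})

test_that("miRNA length bounds are enforced", {
  expect_error(align_targets(tibble::tibble(id = "m", seq = strrep("A", 16)),
                             tibble::tibble(id = "t", seq = strrep("U", 50))),
               "17-27")
})

test_that("raising the score threshold never removes a reported site", {
  set.seed(431)
  for (k in 1:10) {
    mir <- random_rna_str(21)
    sc <- strsplit(revcomp_rna(mir), "")[[1]]
    for (p in sample(setdiff(1:21, c(11, 12)), sample(0:3, 1))) {
      sc[p] <- sample(c("A", "C", "G", "U"), 1)
    }
    tr <- embed_site(paste(sc, collapse = ""))
    p3 <- align_targets(tibble::tibble(id = "m", seq = mir), tr,
                        target_params("conserved", score_threshold = 3))
    p5 <- align_targets(tibble::tibble(id = "m", seq = mir), tr,
                        target_params("conserved", score_threshold = 5))
    if (nrow(p3)) {
      key3 <- paste(p3$transcript_id, p3$start)
      key5 <- paste(p5$transcript_id, p5$start)
      expect_true(all(key3 %in% key5))
    }
  }
})

test_that("reported sites satisfy every scoring rule on independent re-checking", {
  set.seed(432)
  params <- target_params("conserved")
  for (k in 1:12) {
    mir <- random_rna_str(sample(20:23, 1))
    sc <- strsplit(revcomp_rna(mir), "")[[1]]
    for (p in sample(length(sc), sample(0:4, 1))) sc[p] <- sample(c("A","C","G","U"), 1)
    s <- align_targets(tibble::tibble(id = "m", seq = mir),
                       embed_site(paste(sc, collapse = "")), params)
    for (r in seq_len(nrow(s))) {
      ma <- strsplit(s$mir_aln[r], "")[[1]]
      sa <- strsplit(s$site_aln[r], "")[[1]]
      pen <- 0; mirpos <- 0
      for (c2 in seq_along(ma)) {
        if (ma[c2] != "-") mirpos <- mirpos + 1
        if (ma[c2] == "-" || sa[c2] == "-") { pen <- pen + params$gap_value; next }
        pr <- paste0(ma[c2], sa[c2])
        wc <- pr %in% c("AU", "UA", "CG", "GC")
        gu <- pr %in% c("GU", "UG")
        if (mirpos %in% params$no_mismatch_positions) expect_true(wc)
        pen <- pen + if (wc) 0 else if (gu) params$gu_value else params$mm_value
      }
      expect_equal(pen, s$penalty[r])
      expect_lte(s$penalty[r], params$score_threshold)
      expect_gte(s$aligned_length[r], params$min_length_alignment)
    }
  }
})

test_that("the optimal penalty matches gap-placement enumeration on random pairs", {
  set.seed(433)
  params <- target_params("novel")
  for (k in 1:50) {
    m <- sample(18:22, 1)
    mir <- random_rna_str(m)
    stretch <- if (k %% 2 == 0) {
      sc <- strsplit(revcomp_rna(mir), "")[[1]]
      for (q in sample(m, sample(0:3, 1))) sc[q] <- sample(c("A","C","G","U"), 1)
      paste0(random_rna_str(4), paste(sc, collapse = ""), random_rna_str(4))
    } else random_rna_str(30)
    s <- align_targets(tibble::tibble(id = "m", seq = mir),
                       tibble::tibble(id = "t", seq = stretch), params)
    got <- if (nrow(s)) min(s$penalty) else Inf
    exp <- oracle_best_site(mir, stretch, params)
    expect_equal(got, exp, info = paste(mir, stretch))
  }
})
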