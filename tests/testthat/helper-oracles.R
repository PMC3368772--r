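# Independent oracles used by the unit and acceptance tests.  They share the
# package's energy *tables* (the model definition) but reimplement all logic
# -- structure enumeration, loop decomposition, alignment enumeration --
# without touching the dynamic programs they check.

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# energy of an explicit pair set by direct loop decomposition
oracle_energy_pairs <- function(chars, pairs, params = fold_params()) {
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- list(); unpaired <- 0L; k <- i + 1L
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k]); k <- partner[k] + 1L
      } else { unpaired <- unpaired + 1L; k <- k + 1L }
    }
    pt <- function(a, b) paste0(chars[a], chars[b])
    if (length(kids) == 0L) {
      total <- total + mirforge:::hairpin_penalty(j - i - 1L)
    } else if (length(kids) == 1L) {
      k1 <- kids[[1]][1]; l1 <- kids[[1]][2]
      n1 <- k1 - i - 1L; n2 <- j - l1 - 1L
      if (n1 + n2 > params$max_interior) return(Inf)
      total <- total +
        if (n1 == 0L && n2 == 0L) params$stack[pt(i, j), pt(k1, l1)]
        else if (n1 == 0L || n2 == 0L) mirforge:::bulge_penalty(n1 + n2)
        else mirforge:::internal_penalty(n1 + n2)
    } else {
      total <- total + params$ml_a + params$ml_b * (length(kids) + 1L) +
        params$ml_c * unpaired
    }
  }
  total
}

# exhaustive enumeration of every nested structure (allowed pairs, hairpin
# loop >= 3); returns the minimum energy over all of them
oracle_mfe <- function(seq, params = fold_params()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cache <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (j - i + 1L < 5L) {
      return(list(matrix(integer(0), ncol = 2)))
    }
    key <- paste(i, j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- enum(i + 1L, j)                     # i unpaired
    for (k in (i + 4L):j) {
      if (!oracle_pairable(chars[i], chars[k])) next
      left <- enum(i + 1L, k - 1L)
      right <- if (k + 1L <= j) enum(k + 1L, j) else list(matrix(integer(0), ncol = 2))
      for (a in left) for (b in right) {
        res[[length(res) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
      }
    }
    cache[[key]] <- res
    res
  }
  structs <- enum(1L, n)
  min(vapply(structs, function(p) {
    if (nrow(p) == 0L) 0 else oracle_energy_pairs(chars, p, params)
  }, numeric(1)))
}

# --- target-alignment oracle ------------------------------------------------
# Optimal penalty of a miRNA against one transcript window under the
# reporting rules, by closed-form enumeration over gap placements.  With the
# default penalties any alignment with >= 2 gap columns already costs > 3,
# so enumerating 0- and 1-gap alignments is exhaustive for reportable sites.
oracle_column_cost <- function(a, b, p, params) {
  wc <- paste0(a, b) %in% c("AU", "UA", "CG", "GC")
  gu <- paste0(a, b) %in% c("GU", "UG")
  if (p %in% params$no_mismatch_positions && !wc) return(Inf)
  if (wc) 0 else if (gu) params$gu_value else params$mm_value
}

oracle_window_penalty <- function(mir, window, params) {
  m <- nchar(mir); w <- nchar(window)
  mirc <- strsplit(mir, "")[[1]]
  sitec <- rev(strsplit(window, "")[[1]])   # site read 3'->5'
  nm <- params$no_mismatch_positions
  best <- Inf
  if (w == m) {
    cost <- sum(vapply(seq_len(m), function(p)
      oracle_column_cost(mirc[p], sitec[p], p, params), numeric(1)))
    if (m >= params$min_length_alignment) best <- min(best, cost)
  } else if (w == m - 1L) {
    # one deletion: mir position i aligned to a gap
    A <- vapply(seq_len(w), function(p)
      oracle_column_cost(mirc[p], sitec[p], p, params), numeric(1))
    B <- vapply(seq_len(w), function(p)
      oracle_column_cost(mirc[p + 1L], sitec[p], p + 1L, params), numeric(1))
    for (i in seq_len(m)) {
      if (i %in% nm) next
      cost <- params$gap_value +
        (if (i > 1L) sum(A[seq_len(i - 1L)]) else 0) +
        (if (i < m) sum(B[i:(m - 1L)]) else 0)
      if (m >= params$min_length_alignment) best <- min(best, cost)
    }
  } else if (w == m + 1L) {
    # one insertion: site_rev position j aligned to a gap
    A <- vapply(seq_len(m), function(p)
      oracle_column_cost(mirc[p], sitec[p], p, params), numeric(1))
    B <- vapply(seq_len(m), function(p)
      oracle_column_cost(mirc[p], sitec[p + 1L], p, params), numeric(1))
    for (j in seq_len(m + 1L)) {
      # the inserted base falls between mir positions j-1 and j; forbidden
      # when both are constrained
      if ((j - 1L) %in% nm && j %in% nm) next
      cost <- params$gap_value +
        (if (j > 1L) sum(A[seq_len(j - 1L)]) else 0) +
        (if (j <= m) sum(B[j:m]) else 0)
      if (m + 1L >= params$min_length_alignment) best <- min(best, cost)
    }
  }
  best
}

# minimum reportable penalty over all sub-windows of a transcript stretch
oracle_best_site <- function(mir, stretch, params) {
  m <- nchar(mir); L <- nchar(stretch)
  best <- Inf
  for (wl in c(m - 1L, m, m + 1L)) {
    if (wl < 1L || wl > L) next
    for (s in seq_len(L - wl + 1L)) {
      p <- oracle_window_penalty(mir, substr(stretch, s, s + wl - 1L), params)
      best <- min(best, p)
    }
  }
  if (best > params$score_threshold) Inf else best
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
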