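ENERGY_MODEL_VERSION <- "mirforge-nn-1.0"

PAIR_LEVELS <- c("AU", "UA", "CG", "GC", "GU", "UG")

# 6x6 stacking table, kcal/mol: rows = outer (closing) pair 5'side.3'side,
# columns = inner pair.  Watson-Crick entries follow the standard
# nearest-neighbour measurements; wobble-containing stacks use class
# averages.  The table satisfies the strand-reversal symmetry
# E(p, q) == E(rev(q), rev(p)).
build_stack_table <- function() {
  E <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  E["AU", "AU"] <- -0.93; E["AU", "UA"] <- -1.10
  E["UA", "AU"] <- -1.33; E["UA", "UA"] <- -0.93
  E["CG", "AU"] <- -2.11; E["CG", "UA"] <- -2.08
  E["GC", "AU"] <- -2.35; E["GC", "UA"] <- -2.24
  E["CG", "GC"] <- -2.36; E["CG", "CG"] <- -3.26
  E["GC", "GC"] <- -3.26; E["GC", "CG"] <- -3.42
  E["AU", "CG"] <- -2.24; E["AU", "GC"] <- -2.08
  E["UA", "CG"] <- -2.35; E["UA", "GC"] <- -2.11
  wob <- c("GU", "UG")
  strong <- c("CG", "GC")
  weak <- c("AU", "UA")
  for (p in PAIR_LEVELS) {
    for (q in PAIR_LEVELS) {
      if (!is.na(E[p, q])) next
      nw <- (p %in% wob) + (q %in% wob)
      if (nw == 2L) E[p, q] <- -0.5
      else if (p %in% strong || q %in% strong) E[p, q] <- -1.5
      else E[p, q] <- -1.0
    }
  }
  E
}

loop_extrapolate <- function(base_size, base_val, n) {
  round(base_val + 1.08 * log(n / base_size), 2)
}

hairpin_penalty <- function(n) {
  tab <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)  # sizes 3..9
  ifelse(n < 3, Inf,
         ifelse(n <= 9, tab[pmax(n, 3) - 2], loop_extrapolate(9, 6.4, pmax(n, 10))))
}

bulge_penalty <- function(n) {
  tab <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)  # sizes 1..6
  ifelse(n < 1, Inf,
         ifelse(n <= 6, tab[pmax(n, 1)], loop_extrapolate(6, 4.4, pmax(n, 7))))
}

internal_penalty <- function(n) {
  tab <- c(1.5, 1.6, 1.7, 2.0, 2.0)  # sizes 2..6
  ifelse(n < 2, Inf,
         ifelse(n <= 6, tab[pmax(n, 2) - 1], loop_extrapolate(6, 2.0, pmax(n, 7))))
}

#' Folding model parameters
#'
#' The shipped nearest-neighbour model behind [rna_fold()]: a 6x6 stacking
#' table over the allowed pairs (AU, UA, CG, GC, GU, UG), size-dependent
#' hairpin / bulge / interior-loop penalties with logarithmic extrapolation,
#' and an affine multiloop term `ml_a + ml_b * branches + ml_c * unpaired`.
#' Terminal mismatches, dangles and loop-asymmetry terms are deliberately
#' omitted; interior and bulge loops above `max_interior` unpaired
#' nucleotides are disallowed.  All energies are kcal/mol at 37 degrees.
#'
#' @param stack 6x6 stacking matrix (kcal/mol, all entries <= 0).
#' @param ml_a,ml_b,ml_c multiloop closing / branch / unpaired penalties.
#' @param min_hairpin minimum hairpin loop size in nucleotides.
#' @param max_interior largest interior or bulge loop considered.
#' @return an object of class `fold_params`.
#' @export
fold_params <- function(stack = build_stack_table(), ml_a = 3.4, ml_b = 0.4,
                        ml_c = 0.0, min_hairpin = 3L, max_interior = 30L) {
  stopifnot(is.matrix(stack), dim(stack) == c(6, 6))
  if (any(stack > 0)) abort("stacking energies must all be <= 0")
  if (ml_a < 0 || ml_b < 0 || ml_c < 0) abort("multiloop penalties must be >= 0")
  structure(list(stack = stack, ml_a = ml_a, ml_b = ml_b, ml_c = ml_c,
                 min_hairpin = as.integer(min_hairpin),
                 max_interior = as.integer(max_interior),
                 version = ENERGY_MODEL_VERSION),
            class = "fold_params")
}

centi <- function(x) as.integer(round(100 * x))

# loop-penalty lookup vectors for the C++ kernel; element k+1 holds the
# centi-kcal penalty of a loop of k unpaired nucleotides
penalty_vectors <- function(params, n) {
  ks <- 0:max(n, params$max_interior)
  safe_centi <- function(v) { v[!is.finite(v)] <- 9999; centi(v) }
  list(
    hp = as.integer(safe_centi(hairpin_penalty(ks))),
    bu = as.integer(safe_centi(bulge_penalty(ks))),
    int = as.integer(safe_centi(internal_penalty(ks)))
  )
}

#' Fold RNA sequences to their minimum-free-energy structure
#'
#' An exact dynamic program over all nested (pseudoknot-free) secondary
#' structures under the shipped nearest-neighbour model (see
#' [fold_params()]).  Deterministic: ties are resolved in favour of the
#' structure whose leftmost differing base is paired.
#'
#' @param seqs character vector of RNA/DNA sequences.
#' @param params a [fold_params()] object.
#' @param min_len,max_len admissible sequence lengths; sequences outside the
#'   bounds raise an error.
#' @return tibble with columns `seq`, `structure` (dot-bracket) and `energy`
#'   (kcal/mol, `<= 0`).
#' @examples
#' rna_fold("GGGGGAAAACCCCC")
#' @export
rna_fold <- function(seqs, params = fold_params(), min_len = 1L, max_len = 1000L) {
  seqs <- normalize_rna(seqs)
  check_rna_alphabet(seqs)
  n <- nchar(seqs)
  if (any(n < min_len) || any(n > max_len)) {
    abort(sprintf("sequence length outside [%d, %d]", min_len, max_len))
  }
  stack_centi <- matrix(centi(params$stack), 6, 6)
  res <- lapply(seqs, function(s) {
    pv <- penalty_vectors(params, nchar(s) + 1L)
    fold_cpp(s, stack_centi, pv$hp, pv$bu, pv$int,
             centi(params$ml_a), centi(params$ml_b), centi(params$ml_c),
             params$min_hairpin, params$max_interior)
  })
  tibble(
    seq = seqs,
    structure = vapply(res, function(x) x$structure, character(1)),
    energy = vapply(res, function(x) x$energy_centi / 100, numeric(1))
  )
}

#' Pair partners of a dot-bracket structure
#'
#' @param structure a dot-bracket string.
#' @return integer vector: `partner[i]` is the position paired with `i`, or
#'   `NA` when `i` is unpaired.  Unbalanced parentheses raise an error.
#' @export
db_partners <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) abort("structure must be over '(', ')', '.'")
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) abort("unbalanced ')' in structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced '(' in structure")
  partner
}

#' Evaluate a structure's free energy under the shipped model
#'
#' Computes the energy of an explicit dot-bracket structure by loop
#' decomposition -- the same model [rna_fold()] optimizes, evaluated directly
#' from the structure.  Useful for validating candidate precursors or scoring
#' externally produced structures.
#'
#' @param seq the sequence the structure annotates.
#' @param structure dot-bracket string of the same length.
#' @param params a [fold_params()] object.
#' @return energy in kcal/mol; `Inf` if the structure is invalid under the
#'   model (disallowed pair, loop too short or too large).
#' @export
structure_energy <- function(seq, structure, params = fold_params()) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != nchar(structure)) abort("sequence and structure lengths differ")
  partner <- db_partners(structure)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  ptype <- function(i, j) {
    p <- paste0(s[i], s[j])
    if (p %in% PAIR_LEVELS) p else NA_character_
  }
  total <- 0
  closing <- which(!is.na(partner) & partner > seq_along(partner))
  for (i in closing) {
    j <- partner[i]
    if (is.na(ptype(i, j))) return(Inf)
    # children: maximal pairs directly inside (i, j)
    kids <- list(); unpaired <- 0L; k <- i + 1L
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(kids) == 0L) {
      sz <- j - i - 1L
      if (sz < params$min_hairpin) return(Inf)
      total <- total + hairpin_penalty(sz)
    } else if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 + n2 > params$max_interior) return(Inf)
      if (n1 == 0L && n2 == 0L) {
        total <- total + params$stack[ptype(i, j), ptype(k, l)]
      } else if (n1 == 0L || n2 == 0L) {
        total <- total + bulge_penalty(n1 + n2)
      } else {
        total <- total + internal_penalty(n1 + n2)
      }
    } else {
      total <- total + params$ml_a + params$ml_b * (length(kids) + 1L) +
        params$ml_c * unpaired
    }
  }
  round(total, 10)
}
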