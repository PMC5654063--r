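# Independent oracles and fixture samplers used across the suite.

# --- exhaustive folding oracle -----------------------------------------------
# Enumerates every pseudoknot-free structure (as a list of pair matrices) of
# a short sequence by direct recursion, then scores each one. Independent of
# the dynamic-programming folder: no tables, explicit structure lists.

oracle_canonical <- function(a, b, allow_gu) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "GC", "CG", if (allow_gu) c("GU", "UG"))
}

oracle_enumerate <- function(chars, i, j, min_hairpin, allow_gu) {
  if (i >= j) return(list(matrix(integer(0), ncol = 2)))
  out <- oracle_enumerate(chars, i + 1L, j, min_hairpin, allow_gu)
  ks <- if (i + min_hairpin + 1L <= j) (i + min_hairpin + 1L):j else integer(0)
  for (k in ks) {
    if (!oracle_canonical(chars[i], chars[k], allow_gu)) next
    inner <- oracle_enumerate(chars, i + 1L, k - 1L, min_hairpin, allow_gu)
    outer <- oracle_enumerate(chars, k + 1L, j, min_hairpin, allow_gu)
    for (s1 in inner) for (s2 in outer)
      out[[length(out) + 1L]] <- rbind(s1, s2, c(i, k))
  }
  out
}

oracle_score <- function(pairs_mat, stacking_bonus) {
  if (!nrow(pairs_mat)) return(0)
  key <- paste(pairs_mat[, 1], pairs_mat[, 2])
  stacked <- sum(paste(pairs_mat[, 1] + 1L, pairs_mat[, 2] - 1L) %in% key)
  nrow(pairs_mat) + stacking_bonus * stacked
}

oracle_best_score <- function(seq, min_hairpin = 3L, allow_gu = TRUE,
                              stacking_bonus = 0) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < min_hairpin + 2L) return(0)
  structs <- oracle_enumerate(chars, 1L, length(chars), min_hairpin, allow_gu)
  max(vapply(structs, oracle_score, numeric(1),
             stacking_bonus = stacking_bonus))
}

# --- brute-force global alignment score --------------------------------------
# Plain recursion over the three alignment moves; no DP tables.

oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av)) return(gap * (length(bv) - j + 1L))
    if (j > length(bv)) return(gap * (length(av) - i + 1L))
    max(rec(i + 1L, j + 1L) + (if (av[i] == bv[j]) match else mismatch),
        rec(i + 1L, j) + gap,
        rec(i, j + 1L) + gap)
  }
  rec(1L, 1L)
}

# --- random inputs -----------------------------------------------------------

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# A feasible random barbell spec: interruptions sit at the outer end of the
# edited stem, the edit pair index k0 lies beyond them, and the distance is
# derived so placement always succeeds.
random_barbell_spec <- function(seed) {
  set.seed(seed)
  bp1 <- sample(20:34, 1)
  n_int1 <- sample(0:2, 1)
  ints1 <- if (n_int1 > 0)
    replicate(n_int1,
              if (runif(1) < 0.5) c(1L, 1L) else c(sample(1:6, 1), 0L),
              simplify = FALSE)
  else list()
  loop <- c(sample(8:25, 1), sample(5:20, 1))
  bp2 <- sample(21:50, 1)
  n_int2 <- sample(0:3, 1)
  ints2 <- if (n_int2 > 0)
    replicate(n_int2,
              if (runif(1) < 0.5) c(1L, 1L) else c(sample(1:8, 1), 0L),
              simplify = FALSE)
  else list()
  side <- sample(c("3p", "5p"), 1)
  k0 <- sample((2L * n_int1 + 1L):bp1, 1)
  dist <- if (side == "3p") loop[1] + bp1 - k0 else loop[2] + bp1 - k0
  barbell_spec(edited_stem_bp = bp1, edited_stem_interruptions = ints1,
               internal_loop = loop, eie_stem_bp = bp2,
               eie_interruptions = ints2, distance_nt = dist, side = side,
               hairpin = sample(3:8, 1), linker = c(sample(4:15, 1),
                                                    sample(4:15, 1)),
               seed = seed)
}

# Insert k unpaired adenosines immediately before 1-based position `at`,
# shifting the pair table — used for the distance-additivity property.
insert_unpaired <- function(struct, at, k) {
  n <- length(struct)
  shift <- function(p) ifelse(p >= at, p + k, p)
  new_pairs <- integer(n + k)
  for (i in seq_len(n)) {
    j <- struct$pairs[i]
    if (j > 0L) new_pairs[shift(i)] <- shift(j)
  }
  chars <- strsplit(struct$seq, "")[[1]]
  new_seq <- paste(c(head(chars, at - 1L), rep("A", k),
                     tail(chars, n - at + 1L)), collapse = "")
  rna_structure(new_seq, new_pairs, id = struct$id)
}
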