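#' Global pairwise alignment (Needleman–Wunsch, linear gaps)
#'
#' Optimal global alignment under match/mismatch/linear-gap scoring. The
#' scoring contract and the tie-break are fixed so alignments are
#' deterministic: on ties the diagonal (substitution) move is preferred,
#' then the up move (gap in `b`), then the left move (gap in `a`).
#'
#' @param a,b Nucleotide sequences (character scalars; `T` normalised to
#'   `U`).
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap Per-position gap penalty (default -2, linear).
#' @return A list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length strings with `-` gaps) and `score`.
#' @examples
#' global_align("ACGU", "ACU")
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- normalize_rna(a); b <- normalize_rna(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(av[i] == bv, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],       # diagonal
                               S[i, j + 1L] + gap,     # up: gap in b
                               S[i + 1L, j] + gap)     # left: gap in a
    }
  }
  # traceback, preferring diagonal, then up, then left
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  structure(list(aligned_a = paste(ra, collapse = ""),
                 aligned_b = paste(rb, collapse = ""),
                 score = S[n + 1L, m + 1L],
                 params = list(match = match, mismatch = mismatch, gap = gap)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment (score ", x$score, ")\n", x$aligned_a, "\n",
      x$aligned_b, "\n", sep = "")
  invisible(x)
}

canonical_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Position-by-position alignment of equal-length sequences
#'
#' Builds a gap-free `pairwise_alignment` aligning position i to position i.
#' This is the correct alignment for orthologs generated by
#' [mutate_ortholog()] (which never introduces indels), where the optimal
#' scored alignment could otherwise slide within repetitive regions.
#'
#' @param a,b Equal-length sequences.
#' @return A `pairwise_alignment`.
#' @export
ungapped_alignment <- function(a, b) {
  a <- normalize_rna(a); b <- normalize_rna(b)
  if (nchar(a) != nchar(b))
    stop("ungapped alignment requires equal-length sequences")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  structure(list(aligned_a = a, aligned_b = b,
                 score = sum(ifelse(av == bv, 1, -1)),
                 params = list(match = 1, mismatch = -1, gap = NA)),
            class = "pairwise_alignment")
}

#' Classify ortholog substitutions against a structure
#'
#' Maps every aligned difference between two orthologous sequences onto the
#' secondary structure of the first and classifies it by its structural
#' consequence, the logic used to judge whether compensatory evolution has
#' preserved an editing-inducer-element duplex:
#'
#' * `compensatory` — both pairing partners changed, canonical pairing
#'   retained (e.g. G-C to A-U);
#' * `wobble_preserving` — a single change that retains a canonical pair
#'   (e.g. A-U to G-U);
#' * `loop_located` — change at an unpaired position;
#' * `disruptive` — change at a paired position that breaks the pair;
#' * gap columns are recorded as `indel` (disruptive only when they delete
#'   a paired position of the structure-bearing sequence).
#'
#' The class of a substitution depends only on the two residues, the partner
#' residues and paired/unpaired status, so swapping the species (with the
#' structure mapped through the alignment) never flips a
#' compensatory/disruptive call.
#'
#' @param alignment A `pairwise_alignment` from [global_align()], with the
#'   structure-bearing sequence as `a`.
#' @param structure_a An `rna_structure` on the coordinates of sequence `a`.
#' @return Data frame with one row per non-identical column: `column`,
#'   `position_a`, `position_b` (NA within a gap), `residue_a`, `residue_b`,
#'   `paired`, `class`.
#' @export
classify_substitutions <- function(alignment, structure_a) {
  stopifnot(inherits(alignment, "pairwise_alignment"),
            inherits(structure_a, "rna_structure"))
  av <- strsplit(alignment$aligned_a, "")[[1]]
  bv <- strsplit(alignment$aligned_b, "")[[1]]
  n_a <- sum(av != "-")
  if (n_a != length(structure_a))
    stop("structure length (", length(structure_a),
         ") does not match degapped sequence a (", n_a, ")")
  if (gsub("-", "", alignment$aligned_a) != structure_a$seq)
    stop("structure sequence differs from aligned sequence a")
  pos_a <- cumsum(av != "-"); pos_a[av == "-"] <- NA
  pos_b <- cumsum(bv != "-"); pos_b[bv == "-"] <- NA
  # b residue aligned to each a position (NA where b is gapped)
  b_at_a <- rep(NA_character_, n_a)
  ok <- !is.na(pos_a)
  b_at_a[pos_a[ok]] <- ifelse(bv[ok] == "-", NA, bv[ok])

  rows <- lapply(which(av != bv), function(col) {
    ra <- av[col]; rb <- bv[col]
    if (ra == "-" || rb == "-") {
      paired <- if (ra != "-") structure_a$pairs[pos_a[col]] > 0L else NA
      cls <- if (isTRUE(paired)) "disruptive" else "indel"
      if (ra != "-" && !isTRUE(paired)) cls <- "indel"
      return(data.frame(column = col, position_a = pos_a[col],
                        position_b = pos_b[col], residue_a = ra,
                        residue_b = rb, paired = isTRUE(paired),
                        class = cls, indel = TRUE,
                        stringsAsFactors = FALSE))
    }
    p <- structure_a$pairs[pos_a[col]]
    if (p == 0L) {
      cls <- "loop_located"
      paired <- FALSE
    } else {
      paired <- TRUE
      partner_a <- substr(structure_a$seq, p, p)
      partner_b <- b_at_a[p]
      if (is.na(partner_b)) {
        cls <- "disruptive"  # partner deleted in b
      } else {
        # the pair must be canonical in both species to count as retained;
        # a pair broken in either direction is the same disrupted column
        ok_a <- paste0(ra, partner_a) %in% canonical_pairs
        ok_b <- paste0(rb, partner_b) %in% canonical_pairs
        if (!ok_a || !ok_b) cls <- "disruptive"
        else if (partner_b != partner_a) cls <- "compensatory"
        else cls <- "wobble_preserving"
      }
    }
    data.frame(column = col, position_a = pos_a[col], position_b = pos_b[col],
               residue_a = ra, residue_b = rb, paired = paired, class = cls,
               indel = FALSE, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(column = integer(0), position_a = integer(0),
                      position_b = integer(0), residue_a = character(0),
                      residue_b = character(0), paired = logical(0),
                      class = character(0), indel = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conservation verdict for an ortholog pair
#'
#' Aggregates substitution records into a yes/no conservation call. A
#' region is called conserved when the aligned identity is at least
#' `min_identity` and the fraction of disruptive changes among paired
#' columns is at most `max_disruptive_fraction`. Compensatory,
#' wobble-preserving and loop-located changes do not count against
#' structure conservation — they are exactly the changes expected when a
#' duplex is maintained by compensatory evolution.
#'
#' @param alignment The `pairwise_alignment` the records came from.
#' @param records Substitution records from [classify_substitutions()].
#' @param structure_a The `rna_structure` used for classification.
#' @param min_identity Minimum aligned identity fraction (default 0.85).
#' @param max_disruptive_fraction Maximum disruptive changes per paired
#'   column (default 0.05).
#' @return An object of class `conservation_verdict`: `identity_fraction`,
#'   `n_columns`, `paired_columns`, `class_counts` (named integer vector),
#'   `disruptive_fraction`, `conserved` (logical), and the thresholds used.
#' @export
conservation_verdict <- function(alignment, records, structure_a,
                                 min_identity = 0.85,
                                 max_disruptive_fraction = 0.05) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  av <- strsplit(alignment$aligned_a, "")[[1]]
  bv <- strsplit(alignment$aligned_b, "")[[1]]
  n_col <- length(av)
  identical_cols <- sum(av == bv & av != "-")
  paired_cols <- sum(structure_a$pairs > 0L)
  classes <- c("compensatory", "wobble_preserving", "loop_located",
               "disruptive", "indel")
  counts <- vapply(classes, function(cl) sum(records$class == cl), integer(1))
  disruptive_fraction <- if (paired_cols > 0) counts[["disruptive"]] / paired_cols
                         else 0
  identity_fraction <- identical_cols / n_col
  structure(list(identity_fraction = identity_fraction,
                 n_columns = n_col,
                 paired_columns = paired_cols,
                 class_counts = counts,
                 disruptive_fraction = disruptive_fraction,
                 conserved = identity_fraction >= min_identity &&
                   disruptive_fraction <= max_disruptive_fraction,
                 min_identity = min_identity,
                 max_disruptive_fraction = max_disruptive_fraction),
            class = "conservation_verdict")
}

#' @export
print.conservation_verdict <- function(x, ...) {
  cat("conservation_verdict: ", if (x$conserved) "conserved" else "not conserved",
      " (identity ", round(x$identity_fraction, 3), ", disruptive ",
      round(x$disruptive_fraction, 3), " per paired column)\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

#' Align an ortholog pair and judge conservation in one step
#'
#' Convenience wrapper: [global_align()], [classify_substitutions()],
#' [conservation_verdict()].
#'
#' @param seq_a Structure-bearing sequence (character scalar).
#' @param seq_b Ortholog sequence.
#' @param structure_a `rna_structure` on `seq_a` coordinates.
#' @inheritParams conservation_verdict
#' @return A `conservation_verdict`, with the alignment and records
#'   attached as attributes `alignment` and `records`.
#' @export
assess_conservation <- function(seq_a, seq_b, structure_a,
                                min_identity = 0.85,
                                max_disruptive_fraction = 0.05) {
  aln <- global_align(seq_a, seq_b)
  rec <- classify_substitutions(aln, structure_a)
  v <- conservation_verdict(aln, rec, structure_a,
                            min_identity = min_identity,
                            max_disruptive_fraction = max_disruptive_fraction)
  attr(v, "alignment") <- aln
  attr(v, "records") <- rec
  v
}
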