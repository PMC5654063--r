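#' RNA sequence and secondary-structure containers
#'
#' `rna_structure()` couples a nucleotide sequence with a pair table: an
#' integer vector of the same length whose entry at position `i` is the
#' 1-based partner of `i`, or 0 when `i` is unpaired. Structures are
#' validated on construction: the pair table must be an involution without
#' self-pairs, pseudoknot-free (no crossing pairs), and every pair `(i, j)`
#' must enclose at least `min_hairpin` unpaired-capable positions
#' (`j - i - 1 >= min_hairpin`, default 3, the steric minimum for a hairpin
#' loop).
#'
#' Sequences are stored as uppercase RNA; `T` is accepted on input and
#' normalised to `U`. Coordinates are 1-based and inclusive throughout the
#' package, always on the given (sense) strand.
#'
#' @param seq Character scalar, the nucleotide sequence (A/C/G/U, `T`
#'   accepted and converted, case-insensitive).
#' @param pairs Integer vector of partners (0 = unpaired). Defaults to an
#'   all-unpaired table.
#' @param id Optional sequence identifier.
#' @param min_hairpin Minimum number of nucleotides enclosed by any pair.
#' @return An object of class `rna_structure` with elements `id`, `seq`
#'   (character scalar), and `pairs` (integer vector).
#' @examples
#' hp <- rna_structure("GGGAAACCC", c(9, 8, 7, 0, 0, 0, 3, 2, 1))
#' hp
#' @export
rna_structure <- function(seq, pairs = NULL, id = NULL, min_hairpin = 3L) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (is.null(pairs)) pairs <- integer(n)
  pairs <- as.integer(pairs)
  if (length(pairs) != n)
    stop("pair table length (", length(pairs), ") != sequence length (", n, ")")
  validate_pairs(pairs, min_hairpin = min_hairpin)
  structure(list(id = id, seq = seq, pairs = pairs),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure", if (!is.null(x$id)) paste0("'", x$id, "'") else "",
      "(", nchar(x$seq), " nt, ", sum(x$pairs > 0) %/% 2, " pairs )\n",
      sep = "")
  if (nchar(x$seq) <= 120) {
    cat(x$seq, "\n", sep = "")
    cat(dotbracket(x), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.rna_structure <- function(x) nchar(x$seq)

# Normalise a nucleotide string: uppercase, T -> U, validate alphabet.
normalize_rna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("sequence must be a single character string")
  seq <- chartr("tT", "uU", toupper(seq))
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("sequence must have length >= 1")
  bad <- regmatches(seq, regexpr("[^ACGU]", seq))
  if (length(bad) && nchar(bad))
    stop("invalid residue '", bad, "' (alphabet is A, C, G, U/T)")
  seq
}

# Validate a pair table: involution, no self pairs, no crossings, hairpin
# constraint. Stops with a positional message on violation.
validate_pairs <- function(pairs, min_hairpin = 3L) {
  n <- length(pairs)
  paired <- which(pairs > 0L)
  if (any(pairs < 0L) || any(pairs > n))
    stop("pair table entries must lie in 0..", n)
  for (i in paired) {
    j <- pairs[i]
    if (j == i) stop("position ", i, " pairs with itself")
    if (pairs[j] != i)
      stop("pair table is not an involution at position ", i,
           " (partner ", j, " claims ", pairs[j], ")")
  }
  open <- paired[pairs[paired] > paired]
  if (length(open)) {
    # stack parse: matched nesting iff no crossings
    stack <- integer(0)
    for (pos in sort(c(open, pairs[open]))) {
      j <- pairs[pos]
      if (j > pos) {
        stack <- c(stack, pos)
      } else {
        if (!length(stack) || stack[length(stack)] != j)
          stop("crossing pairs (pseudoknot) involving pair (", j, ",", pos, ")")
        stack <- stack[-length(stack)]
      }
    }
    hp <- open[pairs[open] - open - 1L < min_hairpin]
    if (length(hp))
      stop("pair (", hp[1], ",", pairs[hp[1]], ") violates the minimum ",
           "hairpin size of ", min_hairpin)
  }
  invisible(TRUE)
}

#' Convert a structure to dot-bracket notation
#'
#' @param x An `rna_structure`.
#' @return Character scalar over `.`, `(`, `)`.
#' @export
dotbracket <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  out <- rep(".", length(x$pairs))
  out[x$pairs > 0 & x$pairs > seq_along(x$pairs)] <- "("
  out[x$pairs > 0 & x$pairs < seq_along(x$pairs)] <- ")"
  paste(out, collapse = "")
}

#' Parse dot-bracket notation into a structure
#'
#' Matched parentheses become base pairs; dots are unpaired. The sequence
#' and structure lines must have equal length, brackets must balance, and
#' every implied pair must satisfy the minimum hairpin constraint.
#'
#' @param seq Sequence line.
#' @param db Structure line over `.`, `(`, `)`.
#' @inheritParams rna_structure
#' @return An `rna_structure`.
#' @examples
#' parse_dotbracket("GGGAAACCC", "(((...)))")
#' @export
parse_dotbracket <- function(seq, db, id = NULL, min_hairpin = 3L) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != nchar(db))
    stop("sequence length (", nchar(seq), ") != structure length (",
         nchar(db), ")")
  chars <- strsplit(db, "")[[1]]
  if (any(!chars %in% c(".", "(", ")")))
    stop("structure line may only contain '.', '(' and ')'")
  pairs <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack))
        stop("unbalanced brackets: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced brackets: unmatched '(' at position ", stack[1])
  rna_structure(seq, pairs, id = id, min_hairpin = min_hairpin)
}

#' Read and write Vienna dot-bracket files
#'
#' A record is a FASTA-style header line (optional), a sequence line and a
#' structure line. `read_dotbracket()` returns a list of `rna_structure`
#' objects; `write_dotbracket()` writes them back.
#'
#' @param path File path.
#' @return `read_dotbracket()`: list of `rna_structure`.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    id <- NULL
    if (startsWith(lines[i], ">")) {
      id <- sub("^>\\s*", "", lines[i])
      i <- i + 1L
    }
    if (i + 1L > length(lines))
      stop("truncated dot-bracket record", if (!is.null(id)) paste0(" '", id, "'"))
    out[[length(out) + 1L]] <-
      parse_dotbracket(lines[i], lines[i + 1L], id = id)
    i <- i + 2L
  }
  out
}

#' @param structures List of `rna_structure` (or a single one).
#' @rdname read_dotbracket
#' @export
write_dotbracket <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  lines <- unlist(lapply(seq_along(structures), function(k) {
    s <- structures[[k]]
    id <- if (is.null(s$id)) paste0("structure_", k) else s$id
    c(paste0(">", id), s$seq, dotbracket(s))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning plain named
#' character strings normalised to the RNA alphabet (uppercase, `T -> U`).
#' Record order is preserved; empty record bodies and duplicate identifiers
#' are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: '", ids[duplicated(ids)][1], "'")
  empty <- Biostrings::width(set) == 0L
  if (any(empty))
    stop("empty record body for FASTA id: '", ids[empty][1], "'")
  seqs <- vapply(as.character(set), normalize_rna, character(1))
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read and write CT (connectivity table) structure files
#'
#' The CT dialect used is the classic Zuker layout: a header line beginning
#' with the residue count, then one line per residue with columns index,
#' base, index-1, index+1, partner (0 = unpaired), index. `write_ct()` and
#' `read_ct()` round-trip exactly.
#'
#' @param path File path.
#' @return `read_ct()`: an `rna_structure`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) stop("CT header does not start with a residue count")
  id <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else NULL
  if (length(lines) < n + 1L) stop("CT file truncated: expected ", n, " rows")
  bases <- character(n)
  pairs <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    if (length(f) < 6L) stop("malformed CT line ", k + 1L)
    idx <- as.integer(f[1])
    if (idx != k) stop("CT line ", k + 1L, ": index ", idx, ", expected ", k)
    bases[k] <- f[2]
    pairs[k] <- as.integer(f[5])
  }
  for (k in seq_len(n)) {
    j <- pairs[k]
    if (j > 0L && pairs[j] != k)
      stop("CT partner asymmetry at line ", k + 1L, ": position ", k,
           " claims partner ", j, " but ", j, " claims ", pairs[j])
  }
  rna_structure(paste(bases, collapse = ""), pairs, id = id)
}

#' @param x An `rna_structure` to serialise.
#' @rdname read_ct
#' @export
write_ct <- function(x, path) {
  stopifnot(inherits(x, "rna_structure"))
  n <- length(x)
  bases <- strsplit(x$seq, "")[[1]]
  hdr <- paste(n, if (is.null(x$id)) "structure" else x$id)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases, seq_len(n) - 1L,
                  ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L), x$pairs,
                  seq_len(n))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Fold an RNA sequence by base-pair maximisation
#'
#' A deterministic dynamic-programming folder that maximises
#' `pairs + stacking_bonus * stacked_pairs` over pseudoknot-free structures
#' with canonical pairs (AU, GC, and GU wobble when `allow_gu = TRUE`) and a
#' minimum hairpin of `min_hairpin` nucleotides. It serves as the package's
#' built-in structure oracle for designed substrates; thermodynamic
#' predictions from external tools can be supplied instead as dot-bracket or
#' CT files wherever a structure is accepted.
#'
#' Traceback ties are resolved deterministically: each position is paired
#' with the smallest admissible partner achieving the optimum, and inside a
#' closed pair the stacked continuation is preferred, so a given input
#' always yields the same structure.
#'
#' @param seq Sequence (character scalar) or an `rna_structure` (its
#'   sequence is used).
#' @param min_hairpin Minimum unpaired span enclosed by a pair (default 3).
#' @param allow_gu Allow GU wobble pairs (default `TRUE`).
#' @param stacking_bonus Score bonus per stacked pair (default 0.5); 0 gives
#'   plain pair-count maximisation.
#' @param id Identifier for the returned structure.
#' @return An `rna_structure` with attribute `score` (the optimal score).
#' @examples
#' fold_rna("GGGAAAACCC", stacking_bonus = 0)
#' @export
fold_rna <- function(seq, min_hairpin = 3L, allow_gu = TRUE,
                     stacking_bonus = 0.5, id = NULL) {
  if (inherits(seq, "rna_structure")) {
    if (is.null(id)) id <- seq$id
    seq <- seq$seq
  }
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n < min_hairpin + 2L)
    stop("sequence of length ", n, " is shorter than min_hairpin + 2 = ",
         min_hairpin + 2L)
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  res <- .fold_cpp(code, as.integer(min_hairpin), isTRUE(allow_gu),
                   as.numeric(stacking_bonus))
  out <- rna_structure(seq, res$pairs, id = id, min_hairpin = min_hairpin)
  attr(out, "score") <- res$score
  out
}
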