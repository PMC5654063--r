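#' Percent editing from Sanger peak heights
#'
#' A-to-I editing appears as an A/G double peak in Sanger traces of RT-PCR
#' products; the editing level is quantified as the G peak height over the
#' summed A and G peak heights, in percent: `100 * G / (A + G)`.
#'
#' @param height_A,height_G Non-negative peak heights (vectorised).
#' @return Percent editing in `[0, 100]`.
#' @examples
#' percent_editing(340, 660)  # 66
#' @export
percent_editing <- function(height_A, height_G) {
  if (any(height_A < 0) || any(height_G < 0))
    stop("peak heights must be non-negative")
  tot <- height_A + height_G
  if (any(tot == 0))
    stop("unquantifiable site: A + G peak height is zero")
  100 * height_G / tot
}

#' Summarise replicate editing measurements
#'
#' Computes per-site replicate percents and their mean and sample standard
#' deviation (n - 1 denominator, the convention for error bars on
#' triplicate transfection experiments). A single replicate is reported
#' with `sd = 0` and flagged via `n = 1`.
#'
#' @param peaks Data frame of peak records with columns `site` (relative
#'   offset, edit site = 0), `replicate`, `height_A`, `height_G`; an
#'   optional `substrate_id` column is carried through.
#' @return Data frame with one row per site: `site`, `n`, `mean_percent`,
#'   `sd_percent`.
#' @examples
#' peaks <- data.frame(site = 0, replicate = 1:3,
#'                     height_A = c(36, 34, 32), height_G = c(64, 66, 68))
#' summarize_editing(peaks)
#' @export
summarize_editing <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("site", "replicate", "height_A", "height_G") %in%
                  names(peaks)))
  if (!nrow(peaks)) stop("no peak records to summarise")
  pct <- percent_editing(peaks$height_A, peaks$height_G)
  out <- do.call(rbind, lapply(split(seq_len(nrow(peaks)), peaks$site),
                               function(idx) {
    p <- pct[idx]
    data.frame(site = peaks$site[idx[1]], n = length(p),
               mean_percent = mean(p),
               sd_percent = if (length(p) > 1L) sd(p) else 0,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Validate a list of inclusive relative ranges; each element c(from, to).
check_ranges <- function(ranges) {
  if (!length(ranges)) return(invisible(ranges))
  mat <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2L || !is.numeric(r)) stop("each range must be c(from, to)")
    if (r[1] > r[2]) stop("range has from > to: [", r[1], ", ", r[2], "]")
    as.integer(r)
  }))
  mat <- mat[order(mat[, 1]), , drop = FALSE]
  if (nrow(mat) > 1L && any(mat[-1, 1] <= mat[-nrow(mat), 2]))
    stop("overlapping deletion ranges")
  invisible(ranges)
}

#' Total length of a deletion specification
#'
#' Deletion ranges are relative coordinates (edit site = 0, downstream
#' positive) and inclusive at both ends, so `[+24, +44]` removes 21 nt.
#'
#' @param ranges List of inclusive relative ranges, each `c(from, to)`.
#' @return Total nucleotides removed.
#' @examples
#' deletion_length(list(c(24, 44), c(276, 291)))  # 37
#' @export
deletion_length <- function(ranges) {
  check_ranges(ranges)
  if (!length(ranges)) return(0L)
  sum(vapply(ranges, function(r) as.integer(r[2] - r[1] + 1L), integer(1)))
}

#' Delete regions from a reporter substrate
#'
#' Applies a deletion specification (relative, inclusive ranges) to a
#' sequence, mimicking reporter constructs in which loops or inducer
#' elements are removed. The edit site itself (offset 0) must not be
#' deleted. A coordinate map from old to new positions is returned so
#' downstream coordinates (structures, edit annotations) can be carried
#' across the construct.
#'
#' @param seq Sequence (character scalar) or `rna_structure` (pairs are
#'   remapped; pairs losing a partner are opened).
#' @param site Edit site: an `edit_site` or 1-based absolute position.
#' @param ranges List of inclusive relative ranges `c(from, to)` to delete.
#' @return A list: `seq` (new sequence, or remapped `rna_structure`),
#'   `edit_position` (new absolute position), `map` (integer vector: new
#'   position for each old position, NA where deleted).
#' @export
apply_deletion <- function(seq, site, ranges) {
  pos <- if (inherits(site, "edit_site")) site$position else as.integer(site)
  struct <- NULL
  if (inherits(seq, "rna_structure")) { struct <- seq; seq <- struct$seq }
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  check_ranges(ranges)
  keep <- rep(TRUE, n)
  for (r in ranges) {
    if (r[1] <= 0 && r[2] >= 0) stop("edit site deleted: range [", r[1], ", ",
                                     r[2], "] covers offset 0")
    abs_from <- pos + r[1]; abs_to <- pos + r[2]
    if (abs_from < 1 || abs_to > n)
      stop("range [", r[1], ", ", r[2], "] falls outside the sequence")
    keep[abs_from:abs_to] <- FALSE
  }
  map <- rep(NA_integer_, n)
  map[keep] <- seq_len(sum(keep))
  new_seq <- paste(strsplit(seq, "")[[1]][keep], collapse = "")
  out <- list(seq = new_seq, edit_position = map[pos], map = map)
  if (!is.null(struct)) out$seq <- remap_structure(struct, map, new_seq)
  out
}

# Carry a pair table through a coordinate map; pairs with a deleted partner
# are opened, and pairs whose hairpin shrinks below the minimum are opened
# too (deletion can fuse strands).
remap_structure <- function(struct, map, new_seq, min_hairpin = 3L) {
  n_new <- nchar(new_seq)
  pr <- integer(n_new)
  for (i in seq_along(struct$pairs)) {
    j <- struct$pairs[i]
    if (j > i && !is.na(map[i]) && !is.na(map[j])) {
      ni <- map[i]; nj <- map[j]
      if (nj - ni - 1L >= min_hairpin) {
        pr[ni] <- nj; pr[nj] <- ni
      }
    }
  }
  rna_structure(new_seq, pr, id = struct$id, min_hairpin = min_hairpin)
}

#' Relocate a segment within a reporter substrate
#'
#' Excises the contiguous segment at relative range `[from, to]` and
#' re-inserts it so that its 3'-most nucleotide lands at relative offset
#' `anchor` (counted in the reconstructed transcript, edit site = 0).
#' This mirrors reporter constructs that move an inducer element upstream
#' of the edited stem: an element whose 3' end sits at `anchor = -(k + 1)`
#' is separated from the edit site by exactly `k` nucleotides. Total length
#' and residue content are unchanged; a coordinate map is returned.
#'
#' Relocating a segment onto its current position is the identity.
#'
#' @param seq Sequence (character scalar) or `rna_structure` (pairs are
#'   carried through the map; the moved segment keeps its internal pairs
#'   only if both partners move with it).
#' @param site Edit site: an `edit_site` or 1-based absolute position.
#' @param from,to Inclusive relative range of the segment; must exclude 0.
#' @param anchor Relative offset at which the segment's 3' end is placed;
#'   must itself exclude 0 and may not fall inside the segment's own span
#'   unless it reproduces the current position.
#' @return A list: `seq`, `edit_position`, `map` (new position per old
#'   position; all positions survive).
#' @export
apply_relocation <- function(seq, site, from, to, anchor) {
  pos <- if (inherits(site, "edit_site")) site$position else as.integer(site)
  struct <- NULL
  if (inherits(seq, "rna_structure")) { struct <- seq; seq <- struct$seq }
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (from > to) stop("segment range has from > to")
  if (from <= 0 && to >= 0) stop("segment range covers the edit site")
  abs_from <- pos + from; abs_to <- pos + to
  if (abs_from < 1 || abs_to > n) stop("segment range outside the sequence")
  if (anchor == to) {  # identity relocation
    return(list(seq = if (is.null(struct)) seq else struct,
                edit_position = pos, map = seq_len(n)))
  }
  if (anchor >= from && anchor <= to)
    stop("relocation target lies inside the segment")
  seg_idx <- abs_from:abs_to
  rest_idx <- setdiff(seq_len(n), seg_idx)
  seg_len <- length(seg_idx)
  # position of the edit site among the remaining nucleotides
  pos_rest <- match(pos, rest_idx)
  # the segment's 3' end must land 'anchor' offsets from the edit site in
  # the new transcript: insert after slot `ins` of rest (0 = at 5' end)
  ins <- if (anchor < 0) pos_rest + anchor  # upstream: anchor = -(gap + 1)
         else pos_rest + anchor - seg_len   # downstream: 3' end at +anchor
  if (ins < 0 || ins > length(rest_idx))
    stop("relocation target falls outside the sequence")
  if (anchor > 0 && ins < pos_rest)
    stop("relocation target overlaps the edit-site region")
  new_order <- append(rest_idx, seg_idx, after = ins)
  new_edit <- match(pos, new_order)
  map <- match(seq_len(n), new_order)
  chars <- strsplit(seq, "")[[1]]
  new_seq <- paste(chars[new_order], collapse = "")
  out <- list(seq = new_seq, edit_position = new_edit, map = map)
  if (!is.null(struct)) out$seq <- remap_structure(struct, map, new_seq)
  out
}

#' Read a peak-height table
#'
#' Reads a TSV of Sanger peak heights with columns `substrate_id`, `site`
#' (relative offset), `replicate`, `height_A`, `height_G`.
#'
#' @param path TSV path.
#' @return Data frame of peak records.
#' @export
read_peaks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "replicate", "height_A", "height_G")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}
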