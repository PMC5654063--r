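#' Find maximal helices in a pair table
#'
#' A helix is a maximal run of stacked pairs `(i, j), (i+1, j-1), ...` with
#' no intervening unpaired nucleotides on either strand. Helices are the raw
#' material the segmenter merges into stems.
#'
#' @param x An `rna_structure`.
#' @return A data frame with one row per helix, ordered by 5' start:
#'   `outer_i`, `outer_j` (outermost pair), `inner_i`, `inner_j` (innermost
#'   pair), `bp` (number of pairs).
#' @examples
#' find_helices(parse_dotbracket("GGGAAACCC", "(((...)))"))
#' @export
find_helices <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  pairs <- x$pairs
  open <- which(pairs > seq_along(pairs))
  rows <- list()
  k <- 1L
  while (k <= length(open)) {
    i <- open[k]
    j <- pairs[i]
    ii <- i; jj <- j
    # extend inward while the next pair stacks directly
    while (ii + 1L <= length(pairs) && pairs[ii + 1L] == jj - 1L &&
           jj - 1L > ii + 1L) {
      ii <- ii + 1L; jj <- jj - 1L
    }
    rows[[length(rows) + 1L]] <-
      data.frame(outer_i = i, outer_j = j, inner_i = ii, inner_j = jj,
                 bp = ii - i + 1L)
    k <- k + (ii - i + 1L)
  }
  if (!length(rows))
    return(data.frame(outer_i = integer(0), outer_j = integer(0),
                      inner_i = integer(0), inner_j = integer(0),
                      bp = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$outer_i), , drop = FALSE]
}

# Direct child helices of helix h: helices whose outer pair lies strictly
# inside h's inner pair and is not enclosed by another helix in between.
helix_children <- function(hx, h) {
  inside <- which(hx$outer_i > hx$inner_i[h] & hx$outer_j < hx$inner_j[h])
  if (!length(inside)) return(integer(0))
  direct <- inside
  for (cand in inside) {
    enclosed_by_other <- any(hx$outer_i[inside] < hx$outer_i[cand] &
                               hx$outer_j[inside] > hx$outer_j[cand])
    if (enclosed_by_other) direct <- setdiff(direct, cand)
  }
  sort(direct)
}

#' Segment a structure into stems, loops and bulges
#'
#' Decomposes a pair table into the segment classes of the barbell model:
#' stems (helices merged across small interruptions), internal loops,
#' hairpin loops, multibranch junctions and exterior (unpaired, unenclosed)
#' runs. The merge rule encodes how ADAR enzymes read interruptions in a
#' duplex: small internal loops act as part of the helix while large ones
#' terminate it, and one-sided bulges leave one strand continuous and never
#' terminate a stem.
#'
#' Two consecutive nested helices are merged into one stem when the
#' intervening unpaired nucleotides form a bulge (one strand only, any
#' size) or a two-sided interruption whose total (both strands summed) is
#' at most `merge_tolerance`. Two-sided interruptions with totals above
#' `helix_end_threshold` always end the stem; totals strictly between the
#' two thresholds follow `boundary_policy`: `"helix_end"` (default,
#' conservative stem termination) ends the stem, `"merge"` extends it.
#'
#' @param x An `rna_structure`.
#' @param merge_tolerance Maximum total unpaired nucleotides (both strands)
#'   of a two-sided interruption that still extends a stem. Default 4.
#' @param helix_end_threshold Internal-loop total above which a stem always
#'   ends. Default 6. Must be `>= merge_tolerance`.
#' @param boundary_policy Treatment of two-sided interruption totals in
#'   `(merge_tolerance, helix_end_threshold]`: `"helix_end"` or `"merge"`.
#' @return An object of class `segmented_rna`: a list with `structure` (the
#'   input), `segments` (data frame: `segment_id`, `kind`, `start_5p`,
#'   `end_5p`, `start_3p`, `end_3p`, `bp_count`, `left_unpaired`,
#'   `right_unpaired`), `stems` (per-stem detail: helix table and
#'   interruption table), and `position_segment` (segment id per position;
#'   the segments partition `1..length`).
#' @examples
#' s <- parse_dotbracket("GGGGGAAAAAAAACCCCC", "(((((........)))))")
#' segment_structure(s)$segments
#' @export
segment_structure <- function(x, merge_tolerance = 4L,
                              helix_end_threshold = 6L,
                              boundary_policy = c("helix_end", "merge")) {
  stopifnot(inherits(x, "rna_structure"))
  boundary_policy <- match.arg(boundary_policy)
  if (merge_tolerance > helix_end_threshold)
    stop("merge_tolerance must be <= helix_end_threshold")
  eff_tol <- if (boundary_policy == "merge") helix_end_threshold
             else merge_tolerance
  n <- length(x)
  hx <- find_helices(x)
  nh <- nrow(hx)
  children <- lapply(seq_len(nh), function(h) helix_children(hx, h))

  # decide merge for each helix with exactly one direct child
  merged_with_child <- rep(FALSE, nh)
  inter_kind <- character(nh); inter_l <- integer(nh); inter_r <- integer(nh)
  for (h in seq_len(nh)) {
    ch <- children[[h]]
    if (length(ch) != 1L) next
    c1 <- ch[1]
    gl <- hx$outer_i[c1] - hx$inner_i[h] - 1L
    gr <- hx$inner_j[h] - hx$outer_j[c1] - 1L
    inter_l[h] <- gl; inter_r[h] <- gr
    if (gl == 0L || gr == 0L) {
      merged_with_child[h] <- TRUE
      inter_kind[h] <- "bulge"
    } else if (gl + gr <= eff_tol) {
      merged_with_child[h] <- TRUE
      inter_kind[h] <- if (gl == 1L && gr == 1L) "mismatch"
                       else "small_internal_loop"
    }
  }

  # chain helices into stems
  stem_of <- integer(nh)
  stem_id <- 0L
  for (h in seq_len(nh)) {
    if (stem_of[h] != 0L) next
    stem_id <- stem_id + 1L
    cur <- h
    repeat {
      stem_of[cur] <- stem_id
      if (!merged_with_child[cur]) break
      cur <- children[[cur]][1]
    }
  }

  seg_rows <- list()
  pos_seg <- integer(n)
  next_id <- 0L
  add_seg <- function(kind, s5, e5, s3, e3, bp, lu, ru) {
    next_id <<- next_id + 1L
    seg_rows[[next_id]] <<- data.frame(
      segment_id = next_id, kind = kind,
      start_5p = s5, end_5p = e5, start_3p = s3, end_3p = e3,
      bp_count = bp, left_unpaired = lu, right_unpaired = ru,
      stringsAsFactors = FALSE)
    if (!is.na(s5) && e5 >= s5) pos_seg[s5:e5] <<- next_id
    if (!is.na(s3) && e3 >= s3) pos_seg[s3:e3] <<- next_id
    next_id
  }

  stems_detail <- list()
  stem_seg_id <- integer(max(stem_of, 0L))
  if (stem_id > 0L) {
    for (s in seq_len(stem_id)) {
      hs <- which(stem_of == s)
      hs <- hs[order(hx$outer_i[hs])]
      first <- hs[1]; last <- hs[length(hs)]
      bp <- sum(hx$bp[hs])
      interruptions <- if (length(hs) > 1L) {
        data.frame(kind = inter_kind[hs[-length(hs)]],
                   left_unpaired = inter_l[hs[-length(hs)]],
                   right_unpaired = inter_r[hs[-length(hs)]],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(kind = character(0), left_unpaired = integer(0),
                   right_unpaired = integer(0), stringsAsFactors = FALSE)
      }
      id <- add_seg("stem",
                    hx$outer_i[first], hx$inner_i[last],
                    hx$inner_j[last], hx$outer_j[first],
                    bp,
                    sum(inter_l[hs[-length(hs)]]),
                    sum(inter_r[hs[-length(hs)]]))
      stem_seg_id[s] <- id
      stems_detail[[id]] <- list(helices = hx[hs, , drop = FALSE],
                                 interruptions = interruptions)
    }
  }

  # loop segments hang off the terminal helix of each stem chain
  if (nh > 0L) {
    for (h in seq_len(nh)) {
      if (merged_with_child[h]) next
      ch <- children[[h]]
      ii <- hx$inner_i[h]; jj <- hx$inner_j[h]
      if (!length(ch)) {
        if (jj - ii > 1L)
          add_seg("hairpin_loop", ii + 1L, jj - 1L, NA_integer_, NA_integer_,
                  0L, jj - ii - 1L, 0L)
      } else if (length(ch) == 1L) {
        c1 <- ch[1]
        gl <- hx$outer_i[c1] - ii - 1L
        gr <- jj - hx$outer_j[c1] - 1L
        add_seg("internal_loop",
                if (gl > 0L) ii + 1L else NA_integer_,
                if (gl > 0L) hx$outer_i[c1] - 1L else NA_integer_,
                if (gr > 0L) hx$outer_j[c1] + 1L else NA_integer_,
                if (gr > 0L) jj - 1L else NA_integer_,
                0L, gl, gr)
      } else {
        # multibranch junction: one row per unpaired run inside the loop
        bounds <- c(ii, as.vector(rbind(hx$outer_i[ch], hx$outer_j[ch])), jj)
        for (k in seq_len(length(ch) + 1L)) {
          a <- bounds[2L * k - 1L] + 1L
          b <- bounds[2L * k] - 1L
          if (b >= a)
            add_seg("junction", a, b, NA_integer_, NA_integer_, 0L,
                    b - a + 1L, 0L)
        }
      }
    }
  }

  # exterior runs: unpaired positions not enclosed by any helix
  uncovered <- which(pos_seg == 0L)
  if (length(uncovered)) {
    runs <- split(uncovered, cumsum(c(1L, diff(uncovered) != 1L)))
    for (r in runs)
      add_seg("exterior", r[1], r[length(r)], NA_integer_, NA_integer_,
              0L, length(r), 0L)
  }

  segs <- do.call(rbind, seg_rows)
  ord <- order(ifelse(is.na(segs$start_5p), segs$start_3p, segs$start_5p))
  segs <- segs[ord, , drop = FALSE]
  old2new <- setNames(seq_len(nrow(segs)), segs$segment_id)
  segs$segment_id <- seq_len(nrow(segs))
  rownames(segs) <- NULL
  pos_seg <- as.integer(old2new[as.character(pos_seg)])
  new_stems <- list()
  for (old_id in seq_along(stems_detail)) {
    if (!is.null(stems_detail[[old_id]])) {
      new_id <- old2new[[as.character(old_id)]]
      new_stems[[as.character(new_id)]] <- stems_detail[[old_id]]
    }
  }
  stems_detail <- new_stems

  structure(list(structure = x, segments = segs,
                 stems = stems_detail, position_segment = pos_seg,
                 params = list(merge_tolerance = merge_tolerance,
                               helix_end_threshold = helix_end_threshold,
                               boundary_policy = boundary_policy)),
            class = "segmented_rna")
}

#' @export
print.segmented_rna <- function(x, ...) {
  tab <- table(x$segments$kind)
  cat("segmented_rna (", length(x$structure), " nt): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Locate the stem containing a position
#'
#' Returns the stem segment whose 5' or 3' span (including merged
#' interruptions) contains `position`, or `NULL` when the position lies in a
#' loop, junction or exterior region.
#'
#' @param segmented A `segmented_rna` from [segment_structure()].
#' @param position 1-based position.
#' @return One row of the segment table (kind `"stem"`), or `NULL`.
#' @export
stem_at <- function(segmented, position) {
  stopifnot(inherits(segmented, "segmented_rna"))
  n <- length(segmented$structure)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1L || position > n)
    stop("position must lie in 1..", n)
  sid <- segmented$position_segment[as.integer(position)]
  row <- segmented$segments[segmented$segments$segment_id == sid, , drop = FALSE]
  if (nrow(row) == 1L && row$kind == "stem") row else NULL
}

# Mirror a structure: reverse the sequence, complement residues, reflect the
# pair table. Used by symmetry property tests.
mirror_structure <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  n <- length(x)
  seq_rev <- chartr("ACGU", "UGCA",
                    paste(rev(strsplit(x$seq, "")[[1]]), collapse = ""))
  pr <- integer(n)
  for (i in seq_len(n)) {
    j <- x$pairs[i]
    if (j > 0L) pr[n - i + 1L] <- n - j + 1L
  }
  rna_structure(seq_rev, pr, id = x$id)
}
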