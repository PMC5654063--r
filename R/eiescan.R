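#' Define an edit site
#'
#' An edit site is a 1-based absolute position on a substrate; other
#' positions are conventionally expressed relative to it (site = 0,
#' downstream positive, upstream negative).
#'
#' @param position 1-based absolute position of the edited adenosine.
#' @param substrate_id Optional substrate label.
#' @param amino_acid_change Optional recoding label, e.g. `"Q/R"`, `"I/M"`.
#' @return An object of class `edit_site`.
#' @export
edit_site <- function(position, substrate_id = NULL,
                      amino_acid_change = NULL) {
  stopifnot(is.numeric(position), length(position) == 1L, position >= 1)
  structure(list(substrate_id = substrate_id,
                 position = as.integer(position),
                 amino_acid_change = amino_acid_change),
            class = "edit_site")
}

#' @export
print.edit_site <- function(x, ...) {
  cat("edit_site at position ", x$position,
      if (!is.null(x$substrate_id)) paste0(" on '", x$substrate_id, "'"),
      if (!is.null(x$amino_acid_change)) paste0(" (", x$amino_acid_change, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Identify the stem containing an edit site
#'
#' Selective A-to-I editing requires the edited adenosine to sit in a
#' duplex. This returns the stem segment containing the site (a position
#' within a merged interruption of the stem counts as inside it) and raises
#' an error when the site falls in a loop, junction or exterior region —
#' the structure then cannot support the barbell model.
#'
#' @param segmented A `segmented_rna`.
#' @param site An `edit_site` or a bare position.
#' @return One stem row of the segment table.
#' @export
identify_edited_stem <- function(segmented, site) {
  pos <- if (inherits(site, "edit_site")) site$position else as.integer(site)
  row <- stem_at(segmented, pos)
  if (is.null(row))
    stop("unpaired edit site: position ", pos,
         " lies outside any stem segment")
  row
}

#' Find editing-inducer-element candidate stems
#'
#' Scans a segmented structure for stems, other than the one containing the
#' edit site, that could act as editing inducer elements (EIEs): ADAR
#' recruitment duplexes that are structurally separate from the edited stem.
#' Separation is guaranteed by the segmentation itself — distinct stems are
#' always delimited by an internal loop, junction or unpaired exterior run,
#' never by a mere bulge (bulges extend a stem).
#'
#' For each candidate the report gives, in the conventions of the
#' substrate-screen tables of the field: `length_nt`, the nucleotides inside
#' the stem's two spans including merged interruptions; `bp_count`;
#' `distance_nt`, the nucleotides strictly between the edit site and the
#' nearest stem nucleotide along the transcript; `side`, `"5p"` or `"3p"`;
#' and `stable`, the [stability_check()] verdict.
#'
#' @param segmented A `segmented_rna`.
#' @param site An `edit_site` or bare position.
#' @param min_bp Minimum pairs for a candidate (default 20, the duplex
#'   length sufficient for the ADAR2 deaminase domain to engage).
#' @param min_paired_fraction Passed to [stability_check()].
#' @return Data frame of candidates sorted by `distance_nt` (possibly zero
#'   rows, e.g. for EIE-deletion constructs): `segment_id`, `side`,
#'   `length_nt`, `bp_count`, `distance_nt`, `stable`.
#' @export
find_eie_candidates <- function(segmented, site, min_bp = 20L,
                                min_paired_fraction = 0.6) {
  stopifnot(inherits(segmented, "segmented_rna"))
  pos <- if (inherits(site, "edit_site")) site$position else as.integer(site)
  edited <- identify_edited_stem(segmented, pos)
  segs <- segmented$segments
  cand <- segs[segs$kind == "stem" & segs$segment_id != edited$segment_id &
                 segs$bp_count >= min_bp, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(segment_id = integer(0), side = character(0),
                      length_nt = integer(0), bp_count = integer(0),
                      distance_nt = integer(0), stable = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, ]
    stem_pos <- c(r$start_5p:r$end_5p, r$start_3p:r$end_3p)
    nearest <- stem_pos[which.min(abs(stem_pos - pos))]
    len_nt <- (r$end_5p - r$start_5p + 1L) + (r$end_3p - r$start_3p + 1L)
    data.frame(segment_id = r$segment_id,
               side = if (nearest < pos) "5p" else "3p",
               length_nt = len_nt,
               bp_count = r$bp_count,
               distance_nt = abs(nearest - pos) - 1L,
               stringsAsFactors = FALSE)
  }))
  out$stable <- vapply(seq_len(nrow(out)), function(k)
    stability_check(out[k, ], min_bp = min_bp,
                    min_paired_fraction = min_paired_fraction), logical(1))
  out <- out[order(out$distance_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stability criterion for an EIE candidate
#'
#' Operationalises the "stable adjacent stem" judgement of substrate-screen
#' tables: the candidate must have at least `min_bp` base pairs and at least
#' `min_paired_fraction` of the nucleotides inside its spans must be paired
#' (`2 * bp_count / length_nt`).
#'
#' @param candidate One row from [find_eie_candidates()] (or any list with
#'   `bp_count` and `length_nt`).
#' @param min_bp Minimum base pairs (default 20).
#' @param min_paired_fraction Minimum paired fraction of the stem span
#'   (default 0.6).
#' @return Logical.
#' @examples
#' stability_check(list(bp_count = 43, length_nt = 102))
#' @export
stability_check <- function(candidate, min_bp = 20L,
                            min_paired_fraction = 0.6) {
  bp <- candidate$bp_count
  len <- candidate$length_nt
  stopifnot(is.numeric(bp), is.numeric(len), len > 0)
  bp >= min_bp && (2 * bp / len) >= min_paired_fraction
}

#' Classify editing efficiency
#'
#' Substrates are grouped by measured editing level: `"high"` for 50–100%
#' (highly efficient editing in adult tissue), `"low"` for 1–45% (consistent
#' low efficiency), and `"unclassified"` for the gap between 45 and 50%.
#'
#' @param editing_percent Editing level in percent, in `[0, 100]`.
#' @return `"high"`, `"low"` or `"unclassified"` (vectorised).
#' @examples
#' classify_efficiency(c(100, 25, 47))
#' @export
classify_efficiency <- function(editing_percent) {
  if (any(!is.finite(editing_percent)) ||
      any(editing_percent < 0 | editing_percent > 100))
    stop("editing_percent must lie in [0, 100]")
  ifelse(editing_percent >= 50, "high",
         ifelse(editing_percent <= 45, "low", "unclassified"))
}

#' Assemble an EIE report for one substrate
#'
#' Combines the structural scan, the measured editing level and an optional
#' ortholog-conservation verdict into one report row per substrate — the
#' shape of a substrate-screen table: efficiency class, presence of a
#' conserved and of a stable adjacent stem, and the candidate metrics.
#'
#' @param substrate_id Substrate label.
#' @param segmented A `segmented_rna` of the substrate.
#' @param site An `edit_site` or bare position.
#' @param editing_percent Measured editing level (input, never predicted).
#' @param conservation Optional `conservation_verdict` object (or `NULL`
#'   when no ortholog was analysed).
#' @param min_bp,min_paired_fraction Candidate thresholds, see
#'   [find_eie_candidates()].
#' @return An object of class `eie_report`: list with `substrate_id`,
#'   `edit_position`, `editing_percent`, `efficiency_class`,
#'   `conserved_adjacent_stem`, `stable_adjacent_stem` (each `"yes"`,
#'   `"no"` or `"not_determined"`), and `candidates` (data frame).
#' @export
build_report <- function(substrate_id, segmented, site, editing_percent,
                         conservation = NULL, min_bp = 20L,
                         min_paired_fraction = 0.6) {
  pos <- if (inherits(site, "edit_site")) site$position else as.integer(site)
  cands <- find_eie_candidates(segmented, pos, min_bp = min_bp,
                               min_paired_fraction = min_paired_fraction)
  stable <- if (!nrow(cands)) "not_determined"
            else if (any(cands$stable)) "yes" else "no"
  conserved <- if (is.null(conservation)) "not_determined"
               else if (isTRUE(conservation$conserved)) "yes" else "no"
  structure(list(substrate_id = substrate_id,
                 edit_position = pos,
                 editing_percent = editing_percent,
                 efficiency_class = classify_efficiency(editing_percent),
                 conserved_adjacent_stem = conserved,
                 stable_adjacent_stem = stable,
                 candidates = cands),
            class = "eie_report")
}

#' @export
print.eie_report <- function(x, ...) {
  cat("eie_report '", x$substrate_id, "': ", x$editing_percent,
      "% editing (", x$efficiency_class, "), conserved stem: ",
      x$conserved_adjacent_stem, ", stable stem: ", x$stable_adjacent_stem,
      ", ", nrow(x$candidates), " candidate(s)\n", sep = "")
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}
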