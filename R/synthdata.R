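#' Specify a synthetic barbell substrate
#'
#' A barbell substrate is the canonical architecture of an efficiently
#' edited site: an edited stem and a longer inducer-element (EIE) stem,
#' separated by a large internal loop that acts as a helix end. The
#' specification object records every structural parameter;
#' [make_barbell()] realises it exactly.
#'
#' Defaults describe a GluA2-like substrate: a 28-bp edited stem with two
#' mismatches, a 20+15 internal loop, a 43-bp EIE interrupted by four
#' mismatches and an 8-nt bulge (102 nt of stem span), and 45 nt between
#' the edit site and the EIE on its 3' side.
#'
#' @param edited_stem_bp Base pairs in the edited stem.
#' @param edited_stem_interruptions List of `c(left, right)` unpaired sizes;
#'   `c(1, 1)` is a mismatch, one-sided entries are bulges. Each must be
#'   one-sided or total at most 4 so the stem survives segmentation.
#' @param internal_loop `c(left, right)` unpaired counts of the separating
#'   loop; the total must exceed 6 (the helix-end threshold) so the two
#'   stems stay separate.
#' @param eie_stem_bp Base pairs in the EIE stem; 0 builds an EIE-deletion
#'   substrate with no flanking stem.
#' @param eie_interruptions As above, for the EIE stem.
#' @param distance_nt Nucleotides strictly between the edit site and the
#'   nearest EIE nucleotide.
#' @param side `"3p"` (EIE downstream of the edit site) or `"5p"`.
#' @param hairpin Loop size closing the EIE stem (>= 3).
#' @param linker `c(l5, l3)` unpaired exterior linker lengths.
#' @param gc_bias Probability that a stem pair is G-C/C-G (default 0.8;
#'   GC-rich stems let base-pair maximisation recover the design).
#' @param seed Seed for the sequence draw.
#' @return A list of class `barbell_spec`.
#' @export
barbell_spec <- function(edited_stem_bp = 28L,
                         edited_stem_interruptions = list(c(1L, 1L), c(1L, 1L)),
                         internal_loop = c(20L, 15L),
                         eie_stem_bp = 43L,
                         eie_interruptions = list(c(1L, 1L), c(1L, 1L),
                                                  c(1L, 1L), c(1L, 1L),
                                                  c(8L, 0L)),
                         distance_nt = 45L,
                         side = c("3p", "5p"),
                         hairpin = 4L,
                         linker = c(10L, 10L),
                         gc_bias = 0.8,
                         seed = NULL) {
  side <- match.arg(side)
  spec <- list(edited_stem_bp = as.integer(edited_stem_bp),
               edited_stem_interruptions = edited_stem_interruptions,
               internal_loop = as.integer(internal_loop),
               eie_stem_bp = as.integer(eie_stem_bp),
               eie_interruptions = eie_interruptions,
               distance_nt = as.integer(distance_nt),
               side = side, hairpin = as.integer(hairpin),
               linker = as.integer(linker), gc_bias = gc_bias, seed = seed)
  class(spec) <- "barbell_spec"
  spec
}

# Lay out one stem element. Returns left/right strand character vectors and
# per-pair indices into each (pair 1 = outermost). `at` gives the pair index
# after which each interruption sits.
design_stem <- function(bp, interruptions, at, gc_bias, unpaired_base = "A") {
  stopifnot(bp >= 1L, length(interruptions) == length(at))
  if (length(at)) {
    if (any(at < 1L | at >= bp)) stop("interruption placement outside stem")
    if (any(duplicated(at))) stop("two interruptions at the same pair index")
    ord <- order(at)
    at <- at[ord]; interruptions <- interruptions[ord]
    for (intr in interruptions) {
      l <- intr[1]; r <- if (length(intr) > 1L) intr[2] else 0L
      if (l > 0L && r > 0L && l + r > 4L)
        stop("two-sided interruption of total ", l + r,
             " would terminate the stem (max 4)")
      if (l == 0L && r == 0L) stop("empty interruption")
    }
  }
  pair_types <- sample(c("GC", "CG", "AU", "UA"), bp, replace = TRUE,
                       prob = c(gc_bias / 2, gc_bias / 2,
                                (1 - gc_bias) / 2, (1 - gc_bias) / 2))
  left <- character(0); right <- character(0)
  li <- integer(bp); ri <- integer(bp)
  for (k in seq_len(bp)) {
    left <- c(left, substr(pair_types[k], 1, 1))
    li[k] <- length(left)
    hit <- which(at == k)
    if (length(hit)) {
      l <- interruptions[[hit]][1]
      if (l > 0L) left <- c(left, rep(unpaired_base, l))
    }
  }
  for (k in rev(seq_len(bp))) {
    right <- c(right, substr(pair_types[k], 2, 2))
    ri[k] <- length(right)
    hit <- which(at == k - 1L)
    if (length(hit)) {
      r <- if (length(interruptions[[hit]]) > 1L) interruptions[[hit]][2] else 0L
      if (r > 0L) right <- c(right, rep(unpaired_base, r))
    }
  }
  list(left = left, right = right, li = li, ri = ri)
}

#' Build a synthetic barbell substrate
#'
#' Realises a [barbell_spec()] exactly: the returned structure has the
#' specified stem base-pair counts, interruption sizes, internal-loop total
#' and edit-site-to-EIE distance, so the segmenter and EIE scan recover
#' every spec parameter. Stem sequences are GC-biased and loops are
#' adenosine runs, so base-pair maximisation folding of the bare sequence
#' recovers at least the designed number of pairs. The edited position is
#' an adenosine in an A-U pair. Output is deterministic for a fixed seed.
#'
#' @param spec A `barbell_spec` (or arguments forwarded to [barbell_spec()]).
#' @param ... Forwarded to [barbell_spec()] when `spec` is missing.
#' @return A list of class `barbell_substrate`: `seq` (character scalar),
#'   `structure` (`rna_structure` of the design), `site` (`edit_site`),
#'   and `design` (realised metrics: `edited_stem_bp`, `eie_stem_bp`,
#'   `eie_length_nt`, `loop_total`, `distance_nt`, `side`).
#' @examples
#' sub <- make_barbell(barbell_spec(seed = 1))
#' sub$design
#' @export
make_barbell <- function(spec = barbell_spec(...), ...) {
  stopifnot(inherits(spec, "barbell_spec"))
  if (spec$hairpin < 3L) stop("infeasible spec: hairpin loop below 3 nt")
  has_eie <- spec$eie_stem_bp > 0L
  loopL <- spec$internal_loop[1]; loopR <- spec$internal_loop[2]
  if (has_eie) {
    if (loopL < 1L || loopR < 1L)
      stop("infeasible spec: the separating internal loop needs unpaired ",
           "nucleotides on both strands")
    if (loopL + loopR <= 6L)
      stop("infeasible spec: internal loop total must exceed 6 nt to ",
           "separate the stems")
  }
  with_seed(spec$seed, {
    n_int1 <- length(spec$edited_stem_interruptions)
    at1 <- if (n_int1) 2L * seq_len(n_int1) else integer(0)
    if (n_int1 && 2L * n_int1 >= spec$edited_stem_bp)
      stop("infeasible spec: too many interruptions for the edited stem")
    stem1 <- design_stem(spec$edited_stem_bp, spec$edited_stem_interruptions,
                         at1, spec$gc_bias)
    eie <- NULL
    if (has_eie) {
      n_int2 <- length(spec$eie_interruptions)
      at2 <- if (n_int2) as.integer(floor(spec$eie_stem_bp *
                                            seq_len(n_int2) / (n_int2 + 1L)))
             else integer(0)
      if (n_int2 && (any(at2 < 1L) || any(duplicated(at2))))
        stop("infeasible spec: too many interruptions for the EIE stem")
      eie <- design_stem(spec$eie_stem_bp, spec$eie_interruptions, at2,
                         spec$gc_bias)
    }

    # edit-site placement within the edited stem
    if (spec$side == "3p") {
      idx <- length(stem1$left) - (spec$distance_nt - loopL)
      k0 <- match(idx, stem1$li)
      if (spec$distance_nt < loopL || is.na(k0))
        stop("infeasible spec: no paired edit position gives distance ",
             spec$distance_nt, " with a ", loopL, "-nt loop strand")
      stem1$left[stem1$li[k0]] <- "A"
      stem1$right[stem1$ri[k0]] <- "U"
    } else {
      idx <- spec$distance_nt - loopR + 1L
      k0 <- match(idx, stem1$ri)
      if (spec$distance_nt < loopR || is.na(k0))
        stop("infeasible spec: no paired edit position gives distance ",
             spec$distance_nt, " with a ", loopR, "-nt loop strand")
      stem1$right[stem1$ri[k0]] <- "A"
      stem1$left[stem1$li[k0]] <- "U"
    }

    # assemble blocks 5' -> 3'
    blocks <- list(linker5 = rep("A", spec$linker[1]),
                   stem1_left = stem1$left)
    if (has_eie) {
      blocks <- c(blocks, list(loopL = rep("A", loopL),
                               eie_left = eie$left,
                               hairpin = rep("A", spec$hairpin),
                               eie_right = eie$right,
                               loopR = rep("A", loopR)))
    } else {
      blocks <- c(blocks, list(hairpin = rep("A", max(spec$hairpin,
                                                      loopL + loopR))))
    }
    blocks <- c(blocks, list(stem1_right = stem1$right,
                             linker3 = rep("A", spec$linker[2])))
    lens <- vapply(blocks, length, integer(1))
    offset <- c(0L, cumsum(lens))[seq_along(lens)]
    names(offset) <- names(blocks)
    n <- sum(lens)
    pairs <- integer(n)
    link <- function(block_a, ia, block_b, ib) {
      pa <- offset[[block_a]] + ia
      pb <- offset[[block_b]] + ib
      pairs[pa] <<- pb
      pairs[pb] <<- pa
    }
    for (k in seq_len(spec$edited_stem_bp))
      link("stem1_left", stem1$li[k], "stem1_right", stem1$ri[k])
    if (has_eie)
      for (k in seq_len(spec$eie_stem_bp))
        link("eie_left", eie$li[k], "eie_right", eie$ri[k])

    seq <- paste(unlist(blocks), collapse = "")
    struct <- rna_structure(seq, pairs, id = "barbell")
    edit_pos <- if (spec$side == "3p") offset[["stem1_left"]] + stem1$li[k0]
                else offset[["stem1_right"]] + stem1$ri[k0]
    site <- edit_site(edit_pos, substrate_id = "barbell")
    eie_len <- if (has_eie) length(eie$left) + length(eie$right) else 0L
    structure(list(seq = seq, structure = struct, site = site,
                   design = list(edited_stem_bp = spec$edited_stem_bp,
                                 eie_stem_bp = spec$eie_stem_bp,
                                 eie_length_nt = eie_len,
                                 loop_total = if (has_eie) loopL + loopR else 0L,
                                 distance_nt = if (has_eie) spec$distance_nt
                                               else NA_integer_,
                                 side = if (has_eie) spec$side
                                        else NA_character_),
                   spec = spec),
              class = "barbell_substrate")
  })
}

#' @export
print.barbell_substrate <- function(x, ...) {
  d <- x$design
  cat("barbell_substrate (", nchar(x$seq), " nt): edited stem ",
      d$edited_stem_bp, " bp", sep = "")
  if (d$eie_stem_bp > 0)
    cat(", EIE ", d$eie_stem_bp, " bp / ", d$eie_length_nt, " nt, loop ",
        d$loop_total, " nt, distance ", d$distance_nt, " nt (", d$side, ")",
        sep = "")
  else cat(", no EIE")
  cat(", edit site at ", x$site$position, "\n", sep = "")
  invisible(x)
}

#' Simulate an ortholog with planted substitution classes
#'
#' Mutates a sequence under its structure so that every introduced change
#' belongs to a requested structural class: compensatory (both partners of
#' a pair replaced, pairing retained), wobble-preserving (single change
#' retaining a canonical pair), loop-located (change at an unpaired
#' position), or disruptive (single change breaking a pair). Each pair or
#' unpaired position receives at most one event; draws are deterministic
#' per seed.
#'
#' @param struct An `rna_structure` (sequence plus pairs) to diverge from.
#' @param rate_compensatory,rate_wobble,rate_disruptive Per-pair event
#'   probabilities (summing to at most 1).
#' @param rate_loop Per-unpaired-position substitution probability.
#' @param seed RNG seed.
#' @return Character scalar: the ortholog sequence (same length, no indels).
#' @export
mutate_ortholog <- function(struct, rate_compensatory = 0,
                            rate_wobble = 0, rate_loop = 0,
                            rate_disruptive = 0, seed = NULL) {
  stopifnot(inherits(struct, "rna_structure"))
  rates <- c(rate_compensatory, rate_wobble, rate_disruptive)
  if (any(rates < 0) || rate_loop < 0 || sum(rates) > 1 || rate_loop > 1)
    stop("rates must be non-negative and feasible")
  with_seed(seed, {
    chars <- strsplit(struct$seq, "")[[1]]
    comp_map <- c(GC = "AU", CG = "UA", AU = "GC", UA = "CG",
                  GU = "UA", UG = "AU")
    wobble_map <- c(AU = "GU", UA = "UG", GC = "GU", CG = "UG",
                    GU = "AU", UG = "UA")
    break_map <- c(U = "C", G = "A", C = "A", A = "C")  # by partner residue
    loop_map <- c(A = "C", C = "A", G = "A", U = "C")
    open <- which(struct$pairs > seq_along(struct$pairs))
    for (i in open) {
      j <- struct$pairs[i]
      u <- runif(1)
      pair <- paste0(chars[i], chars[j])
      if (u < rates[1]) {
        new <- comp_map[[pair]]
        chars[i] <- substr(new, 1, 1); chars[j] <- substr(new, 2, 2)
      } else if (u < rates[1] + rates[2]) {
        new <- wobble_map[[pair]]
        chars[i] <- substr(new, 1, 1); chars[j] <- substr(new, 2, 2)
      } else if (u < rates[1] + rates[2] + rates[3]) {
        chars[i] <- break_map[[chars[j]]]
      }
    }
    for (i in which(struct$pairs == 0L)) {
      if (runif(1) < rate_loop) chars[i] <- loop_map[[chars[i]]]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate Sanger A/G peak heights at an edited site
#'
#' Peak heights are modelled as intensities proportional to the unedited
#' (A) and edited (G) transcript fractions with multiplicative Gaussian
#' noise truncated at -0.9 (heights stay positive):
#' `A = H (1 - f)(1 + eps_A)`, `G = H f (1 + eps_G)`,
#' `eps ~ N(0, sd^2)`. With `noise_sd = 0` the ratio is exact:
#' `percent_editing(A, G) = 100 f`.
#'
#' @param true_fraction True edited fraction `f` in `[0, 1]`.
#' @param base_height Peak-height scale `H` (default 1000).
#' @param noise_sd Relative noise standard deviation.
#' @param n_replicates Number of replicates.
#' @param seed RNG seed.
#' @param site Relative site offset recorded in the records (default 0).
#' @return Data frame of peak records: `site`, `replicate`, `height_A`,
#'   `height_G`.
#' @examples
#' simulate_peaks(0.66, noise_sd = 0, n_replicates = 3)
#' @export
simulate_peaks <- function(true_fraction, base_height = 1000,
                           noise_sd = 0.05, n_replicates = 3L, seed = NULL,
                           site = 0L) {
  stopifnot(true_fraction >= 0, true_fraction <= 1, noise_sd >= 0,
            n_replicates >= 1)
  with_seed(seed, {
    eps_A <- pmax(rnorm(n_replicates, 0, noise_sd), -0.9)
    eps_G <- pmax(rnorm(n_replicates, 0, noise_sd), -0.9)
    data.frame(site = site, replicate = seq_len(n_replicates),
               height_A = base_height * (1 - true_fraction) * (1 + eps_A),
               height_G = base_height * true_fraction * (1 + eps_G))
  })
}

#' Generate a screening cohort with planted ground truth
#'
#' Builds a set of synthetic substrates for the efficiency-vs-EIE screen:
#' `n_high` substrates with editing drawn from `high_range` (of which
#' `n_high_with_eie` carry an EIE stem) and `n_low` from `low_range` (of
#' which `n_low_with_eie` carry one). Substrates without an EIE are bare
#' edited hairpins. Every substrate gets an ortholog diverged only by
#' structure-preserving changes, so conservation calls reflect EIE
#' presence. The truth table records the planted design.
#'
#' @param n_high,n_high_with_eie,n_low,n_low_with_eie Cohort counts;
#'   `*_with_eie` may not exceed the class count.
#' @param high_range,low_range Editing-percent ranges per class (defaults
#'   50–100 and 1–45).
#' @param seed RNG seed.
#' @return A list of class `screen_cohort`: `substrates` (list; each has
#'   `id`, `seq`, `structure`, `site`, `editing_percent`, `ortholog`) and
#'   `truth` (data frame: `id`, `class`, `has_eie`, `editing_percent`).
#' @export
make_screen_cohort <- function(n_high, n_high_with_eie, n_low,
                               n_low_with_eie, high_range = c(50, 100),
                               low_range = c(1, 45), seed = NULL) {
  stopifnot(n_high >= 0, n_low >= 0,
            n_high_with_eie <= n_high, n_low_with_eie <= n_low,
            n_high_with_eie >= 0, n_low_with_eie >= 0)
  with_seed(seed, {
    n_tot <- n_high + n_low
    if (n_tot == 0L)
      return(structure(list(substrates = list(),
                            truth = data.frame(id = character(0),
                                               class = character(0),
                                               has_eie = logical(0),
                                               editing_percent = numeric(0))),
                       class = "screen_cohort"))
    classes <- c(rep("high", n_high), rep("low", n_low))
    has_eie <- c(rep(c(TRUE, FALSE), c(n_high_with_eie, n_high - n_high_with_eie)),
                 rep(c(TRUE, FALSE), c(n_low_with_eie, n_low - n_low_with_eie)))
    percents <- numeric(n_tot)
    percents[classes == "high"] <- runif(n_high, high_range[1], high_range[2])
    percents[classes == "low"] <- runif(n_low, low_range[1], low_range[2])
    subs <- vector("list", n_tot)
    for (k in seq_len(n_tot)) {
      sub_seed <- sample.int(2^31 - 1L, 1L)
      spec <- barbell_spec(
        edited_stem_bp = sample(24:32, 1),
        edited_stem_interruptions = list(),
        eie_stem_bp = if (has_eie[k]) sample(25:45, 1) else 0L,
        eie_interruptions = if (has_eie[k]) list(c(1L, 1L), c(1L, 1L))
                            else list(),
        distance_nt = sample(22:42, 1),
        seed = sub_seed)
      bb <- make_barbell(spec)
      id <- sprintf("synthetic_%s_%02d", classes[k], k)
      bb$site$substrate_id <- id
      orth <- mutate_ortholog(bb$structure, rate_compensatory = 0.05,
                              rate_wobble = 0.03, rate_loop = 0.05,
                              seed = sub_seed + 1L)
      subs[[k]] <- list(id = id, seq = bb$seq, structure = bb$structure,
                        site = bb$site, editing_percent = percents[k],
                        ortholog = orth, design = bb$design)
    }
    structure(list(substrates = subs,
                   truth = data.frame(id = vapply(subs, `[[`, "", "id"),
                                      class = classes, has_eie = has_eie,
                                      editing_percent = percents,
                                      stringsAsFactors = FALSE)),
              class = "screen_cohort")
  })
}
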