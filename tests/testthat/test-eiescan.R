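glua2_like <- make_barbell(barbell_spec(seed = 1))
glua2_seg <- segment_structure(glua2_like$structure)

test_that("the edited stem is identified and unpaired sites are rejected", {
  stem <- identify_edited_stem(glua2_seg, glua2_like$site)
  expect_equal(stem$bp_count, 28L)

  # single hairpin substrate: the site in its helix maps to that stem
  hp <- parse_dotbracket("GGGGGGGGAAAACCCCCCCC", "((((((((....))))))))")
  seg <- segment_structure(hp)
  expect_equal(identify_edited_stem(seg, 4)$bp_count, 8L)

  loop <- glua2_seg$segments[glua2_seg$segments$kind == "internal_loop", ]
  expect_error(identify_edited_stem(glua2_seg, loop$start_5p),
               "unpaired edit site")
})

test_that("the GluA2-like barbell yields one stable 3' EIE with the published metrics", {
  cands <- find_eie_candidates(glua2_seg, glua2_like$site)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$side, "3p")
  expect_equal(cands$bp_count, 43L)
  expect_equal(cands$length_nt, 102L)
  expect_equal(cands$distance_nt, 45L)
  expect_true(cands$stable)
})

test_that("deleting the EIE leaves no candidates (delta-EIE construct)", {
  no_eie <- make_barbell(barbell_spec(eie_stem_bp = 0L,
                                      eie_interruptions = list(), seed = 1))
  seg <- segment_structure(no_eie$structure)
  expect_equal(nrow(find_eie_candidates(seg, no_eie$site)), 0L)

  # equivalently, excising the element from the full substrate
  row <- glua2_seg$segments[glua2_seg$segments$segment_id ==
                              find_eie_candidates(glua2_seg,
                                                  glua2_like$site)$segment_id, ]
  rng <- c(row$start_5p, row$end_3p) - glua2_like$site$position
  del <- apply_deletion(glua2_like$structure, glua2_like$site, list(rng))
  seg2 <- segment_structure(del$seq)
  expect_equal(nrow(find_eie_candidates(seg2, del$edit_position)), 0L)
})

test_that("mirroring the substrate flips candidate sides and keeps metrics", {
  for (seed in c(3, 8, 15)) {
    bb <- make_barbell(random_barbell_spec(seed))
    seg <- segment_structure(bb$structure)
    cand <- find_eie_candidates(seg, bb$site)
    mir <- mirror_structure(bb$structure)
    mir_pos <- length(bb$structure) - bb$site$position + 1L
    cand_m <- find_eie_candidates(segment_structure(mir), mir_pos)
    expect_equal(nrow(cand_m), nrow(cand))
    expect_equal(cand_m$bp_count, cand$bp_count)
    expect_equal(cand_m$length_nt, cand$length_nt)
    expect_equal(cand_m$distance_nt, cand$distance_nt)
    expect_true(all(cand_m$side != cand$side))
  }
})

test_that("inserting unpaired spacers adds exactly their length to the distance", {
  bb <- make_barbell(barbell_spec(seed = 2))
  seg <- segment_structure(bb$structure)
  base <- find_eie_candidates(seg, bb$site)
  row <- seg$segments[seg$segments$segment_id == base$segment_id, ]
  for (k in c(1L, 5L, 12L)) {
    # splice k adenosines just before the EIE's 5' span
    widened <- insert_unpaired(bb$structure, row$start_5p, k)
    cand <- find_eie_candidates(segment_structure(widened), bb$site)
    expect_equal(cand$distance_nt, base$distance_nt + k)
    expect_equal(cand$bp_count, base$bp_count)
    expect_equal(cand$length_nt, base$length_nt)
    expect_equal(cand$side, base$side)
  }
})

test_that("stability requires both enough pairs and a paired-enough span", {
  expect_true(stability_check(list(bp_count = 43, length_nt = 102)))
  expect_false(stability_check(list(bp_count = 8, length_nt = 16)))
  expect_false(stability_check(list(bp_count = 25, length_nt = 90)))
})

test_that("efficiency classes follow the 50/45 thresholds with a gap", {
  expect_equal(classify_efficiency(100), "high")
  expect_equal(classify_efficiency(50), "high")
  expect_equal(classify_efficiency(25), "low")
  expect_equal(classify_efficiency(45), "low")
  expect_equal(classify_efficiency(47), "unclassified")
  expect_error(classify_efficiency(101), "\\[0, 100\\]")
  expect_error(classify_efficiency(-1), "\\[0, 100\\]")
})

test_that("reports assemble efficiency, conservation and candidates consistently", {
  orth <- mutate_ortholog(glua2_like$structure, rate_compensatory = 0.05,
                          seed = 12)
  cons <- assess_conservation(glua2_like$seq, orth, glua2_like$structure)
  rep1 <- build_report("GluA2-like", glua2_seg, glua2_like$site, 100, cons)
  expect_equal(rep1$efficiency_class, "high")
  expect_equal(rep1$conserved_adjacent_stem, "yes")
  expect_equal(rep1$stable_adjacent_stem, "yes")
  expect_equal(nrow(rep1$candidates), 1L)

  no_eie <- make_barbell(barbell_spec(eie_stem_bp = 0L,
                                      eie_interruptions = list(), seed = 3))
  rep2 <- build_report("bare-hairpin", segment_structure(no_eie$structure),
                       no_eie$site, 10, NULL)
  expect_equal(rep2$efficiency_class, "low")
  expect_equal(nrow(rep2$candidates), 0L)
  expect_equal(rep2$stable_adjacent_stem, "not_determined")
  expect_equal(rep2$conserved_adjacent_stem, "not_determined")
})

test_that("a substrate with stems on both sides reports two candidates", {
  # two EIE-sized hairpin elements flanking a central edited hairpin
  arm <- function(n, ch) paste(rep(ch, n), collapse = "")
  elem <- function(bp) paste0(arm(bp, "G"), arm(4, "A"), arm(bp, "C"))
  elem_db <- function(bp) paste0(arm(bp, "("), arm(4, "."), arm(bp, ")"))
  sq <- paste0(elem(25), arm(9, "A"), elem(12), arm(7, "A"), elem(22))
  db <- paste0(elem_db(25), arm(9, "."), elem_db(12), arm(7, "."),
               elem_db(22))
  seg <- segment_structure(parse_dotbracket(sq, db))
  edit_pos <- 2 * 25 + 4 + 9 + 5   # inside the middle 12-bp stem
  cands <- find_eie_candidates(seg, edit_pos)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$side, c("5p", "3p"))
  expect_setequal(cands$bp_count, c(25L, 22L))
})

test_that("planted screens separate real EIEs from sub-threshold decoys", {
  # decoy stems below min_bp must never be reported at default thresholds
  arm <- function(n, ch) paste(rep(ch, n), collapse = "")
  elem <- function(bp) paste0(arm(bp, "G"), arm(4, "A"), arm(bp, "C"))
  elem_db <- function(bp) paste0(arm(bp, "("), arm(4, "."), arm(bp, ")"))
  sq <- paste0(elem(10), arm(9, "A"), elem(12), arm(7, "A"), elem(30))
  db <- paste0(elem_db(10), arm(9, "."), elem_db(12), arm(7, "."),
               elem_db(30))
  seg <- segment_structure(parse_dotbracket(sq, db))
  edit_pos <- 2 * 10 + 4 + 9 + 5
  cands <- find_eie_candidates(seg, edit_pos)
  expect_equal(nrow(cands), 1L)   # the 30-bp element only
  expect_equal(cands$bp_count, 30L)
})
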