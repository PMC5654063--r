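test_that("barbell generation is deterministic and realises its spec", {
  a <- make_barbell(barbell_spec(seed = 9))
  b <- make_barbell(barbell_spec(seed = 9))
  expect_identical(a$seq, b$seq)
  expect_identical(a$structure$pairs, b$structure$pairs)

  # the designed structure is valid and the edit site is a paired adenosine
  expect_s3_class(a$structure, "rna_structure")
  p <- a$site$position
  expect_equal(substr(a$seq, p, p), "A")
  expect_gt(a$structure$pairs[p], 0)
})

test_that("generator and analysers agree on every design parameter", {
  for (seed in 1:25) {
    bb <- make_barbell(random_barbell_spec(seed + 900))
    seg <- segment_structure(bb$structure)
    d <- bb$design
    expect_equal(identify_edited_stem(seg, bb$site)$bp_count,
                 d$edited_stem_bp)
    cand <- find_eie_candidates(seg, bb$site, min_bp = 21L)
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$bp_count, d$eie_stem_bp)
    expect_equal(cand$length_nt, d$eie_length_nt)
    expect_equal(cand$distance_nt, d$distance_nt)
    expect_equal(cand$side, d$side)
    loops <- seg$segments[seg$segments$kind == "internal_loop", ]
    expect_equal(loops$left_unpaired + loops$right_unpaired, d$loop_total)
  }
})

test_that("folding a GC-rich design recovers at least the designed pairs", {
  for (seed in c(2, 13, 77)) {
    bb <- make_barbell(random_barbell_spec(seed + 2000))
    designed <- sum(bb$structure$pairs > 0) / 2
    folded <- fold_rna(bb$seq, stacking_bonus = 0)
    expect_gte(sum(folded$pairs > 0) / 2, designed)
  }
})

test_that("infeasible barbell specs are rejected up front", {
  expect_error(make_barbell(barbell_spec(hairpin = 2)), "hairpin")
  expect_error(make_barbell(barbell_spec(internal_loop = c(3, 3))),
               "internal loop")
  expect_error(make_barbell(barbell_spec(internal_loop = c(0, 9))),
               "both strands")
  expect_error(make_barbell(barbell_spec(distance_nt = 500)), "infeasible")
})

test_that("ortholog mutagenesis plants exactly the requested classes", {
  bb <- make_barbell(barbell_spec(seed = 30))
  expect_identical(mutate_ortholog(bb$structure, seed = 1), bb$seq)

  comp <- mutate_ortholog(bb$structure, rate_compensatory = 0.3, seed = 2)
  rec <- classify_substitutions(ungapped_alignment(bb$seq, comp),
                                bb$structure)
  expect_true(nrow(rec) > 0)
  expect_setequal(unique(rec$class), "compensatory")

  wob <- mutate_ortholog(bb$structure, rate_wobble = 0.3, seed = 3)
  rec <- classify_substitutions(ungapped_alignment(bb$seq, wob),
                                bb$structure)
  expect_setequal(unique(rec$class), "wobble_preserving")

  disr <- mutate_ortholog(bb$structure, rate_disruptive = 0.3, seed = 4)
  rec <- classify_substitutions(ungapped_alignment(bb$seq, disr),
                                bb$structure)
  expect_setequal(unique(rec$class), "disruptive")

  lp <- mutate_ortholog(bb$structure, rate_loop = 0.3, seed = 5)
  rec <- classify_substitutions(ungapped_alignment(bb$seq, lp),
                                bb$structure)
  expect_setequal(unique(rec$class), "loop_located")

  expect_identical(mutate_ortholog(bb$structure, rate_compensatory = 0.2,
                                   seed = 7),
                   mutate_ortholog(bb$structure, rate_compensatory = 0.2,
                                   seed = 7))
})

test_that("noise-free peak simulation reproduces the true fraction exactly", {
  peaks <- simulate_peaks(0.66, base_height = 1000, noise_sd = 0,
                          n_replicates = 3, seed = 1)
  expect_equal(peaks$height_A, rep(340, 3))
  expect_equal(peaks$height_G, rep(660, 3))
  expect_equal(summarize_editing(peaks)$mean_percent, 66)

  zero <- simulate_peaks(0, noise_sd = 0.1, n_replicates = 5, seed = 2)
  expect_equal(zero$height_G, rep(0, 5))
  expect_equal(summarize_editing(zero)$mean_percent, 0)
})

test_that("the peak-ratio estimator converges to the true fraction", {
  peaks <- simulate_peaks(0.66, noise_sd = 0.05, n_replicates = 200,
                          seed = 33)
  m <- summarize_editing(peaks)
  expect_lt(abs(m$mean_percent - 66), 3 * 0.05 * 100 / sqrt(200))
  expect_identical(peaks,
                   simulate_peaks(0.66, noise_sd = 0.05, n_replicates = 200,
                                  seed = 33))
})

test_that("screen cohorts carry their planted truth", {
  coh <- make_screen_cohort(5, 4, 6, 1, seed = 44)
  expect_equal(nrow(coh$truth), 11L)
  expect_equal(sum(coh$truth$class == "high"), 5L)
  expect_equal(sum(coh$truth$has_eie[coh$truth$class == "high"]), 4L)
  expect_equal(sum(coh$truth$has_eie[coh$truth$class == "low"]), 1L)
  expect_true(all(coh$truth$editing_percent[coh$truth$class == "high"] >= 50))
  expect_true(all(coh$truth$editing_percent[coh$truth$class == "low"] <= 45))

  empty <- make_screen_cohort(0, 0, 0, 0, seed = 1)
  expect_equal(length(empty$substrates), 0L)
  expect_equal(nrow(empty$truth), 0L)

  again <- make_screen_cohort(5, 4, 6, 1, seed = 44)
  expect_identical(coh$truth, again$truth)
  expect_identical(coh$substrates[[3]]$seq, again$substrates[[3]]$seq)
})
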