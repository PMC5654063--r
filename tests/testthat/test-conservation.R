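test_that("global alignment reproduces known scores and tie-breaks", {
  ident <- global_align("ACGU", "ACGU")
  expect_equal(ident$score, 4)
  expect_equal(ident$aligned_a, "ACGU")
  expect_equal(ident$aligned_b, "ACGU")

  gapped <- global_align("ACGU", "ACU")
  expect_equal(gapped$score, 1)           # 3 matches + 1 gap
  expect_equal(nchar(gapped$aligned_a), 4L)

  mis <- global_align("A", "G")
  expect_equal(mis$score, -1)
  expect_equal(mis$aligned_a, "A")
  expect_equal(mis$aligned_b, "G")
})

test_that("alignment scores equal the brute-force optimum on short pairs", {
  set.seed(31)
  for (r in 1:80) {
    a <- random_rna(sample(1:8, 1))
    b <- random_rna(sample(1:8, 1))
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent aligner on longer pairs", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(37)
  for (r in 1:25) {
    a <- random_rna(sample(5:60, 1))
    b <- random_rna(sample(5:60, 1))
    ref <- Biostrings::pairwiseAlignment(chartr("U", "T", a),
                                         chartr("U", "T", b),
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2,
                                         type = "global")
    expect_equal(global_align(a, b)$score, BiocGenerics::score(ref),
                 info = paste(a, b))
  }
})

test_that("substitutions classify by their structural consequence", {
  # (1,9) G-C, (2,8) G-C, (3,7) A-U pairs
  s <- parse_dotbracket("GGAAAAUCC", "(((...)))")
  # compensatory: G-C -> A-U at (1,9)
  rec <- classify_substitutions(global_align("GGAAAAUCC", "AGAAAAUCU"), s)
  expect_setequal(rec$class, "compensatory")
  expect_equal(nrow(rec), 2L)

  # wobble-preserving: A-U -> G-U at position 3
  rec <- classify_substitutions(global_align("GGAAAAUCC", "GGGAAAUCC"), s)
  expect_equal(rec$class, "wobble_preserving")

  # disruptive: G-C -> A-C at position 1
  rec <- classify_substitutions(global_align("GGAAAAUCC", "AGAAAAUCC"), s)
  expect_equal(rec$class, "disruptive")

  # loop-located: change in the hairpin loop
  rec <- classify_substitutions(global_align("GGAAAAUCC", "GGACAAUCC"), s)
  expect_equal(rec$class, "loop_located")
})

test_that("verdicts combine identity and disruptive-fraction thresholds", {
  s <- parse_dotbracket("GGAAAAUCC", "(((...)))")
  v <- assess_conservation("GGAAAAUCC", "GGAAAAUCC", s)
  expect_true(v$conserved)
  expect_equal(v$identity_fraction, 1)

  bb <- make_barbell(barbell_spec(seed = 21))
  comp <- mutate_ortholog(bb$structure, rate_compensatory = 0.08,
                          rate_loop = 0.05, seed = 22)
  v1 <- assess_conservation(bb$seq, comp, bb$structure)
  expect_true(v1$conserved)
  expect_equal(unname(v1$class_counts["disruptive"]), 0L)

  disr <- mutate_ortholog(bb$structure, rate_disruptive = 0.2, seed = 23)
  v2 <- assess_conservation(bb$seq, disr, bb$structure)
  expect_false(v2$conserved)
  expect_gt(v2$disruptive_fraction, 0.05)
})

test_that("class calls are symmetric in the two species", {
  bb <- make_barbell(barbell_spec(seed = 41))
  orth <- mutate_ortholog(bb$structure, rate_compensatory = 0.06,
                          rate_wobble = 0.04, rate_disruptive = 0.03,
                          rate_loop = 0.05, seed = 42)
  fwd <- classify_substitutions(ungapped_alignment(bb$seq, orth),
                                bb$structure)
  # no indels here, so the structure maps position-for-position onto b
  orth_struct <- rna_structure(orth, bb$structure$pairs)
  rev <- classify_substitutions(ungapped_alignment(orth, bb$seq),
                                orth_struct)
  count <- function(rec, cls) sum(rec$class == cls)
  expect_equal(count(fwd, "compensatory"), count(rev, "compensatory"))
  expect_equal(count(fwd, "disruptive"), count(rev, "disruptive"))
  expect_equal(count(fwd, "loop_located"), count(rev, "loop_located"))
})

test_that("class counts cover every non-identical aligned column", {
  bb <- make_barbell(barbell_spec(seed = 51))
  orth <- mutate_ortholog(bb$structure, rate_compensatory = 0.05,
                          rate_disruptive = 0.05, rate_loop = 0.08,
                          seed = 52)
  aln <- global_align(bb$seq, orth)
  rec <- classify_substitutions(aln, bb$structure)
  av <- strsplit(aln$aligned_a, "")[[1]]
  bv <- strsplit(aln$aligned_b, "")[[1]]
  expect_equal(nrow(rec), sum(av != bv))
})

test_that("indels count against identity and only paired deletions disrupt", {
  #      123456789
  s <- parse_dotbracket("GGGACACCC", "(((...)))")
  # delete the unpaired loop C at position 5: indel, not disruptive
  rec <- classify_substitutions(global_align("GGGACACCC", "GGGAACCC"), s)
  expect_true(all(rec$indel))
  expect_false(any(rec$class == "disruptive"))
  # delete paired position 1 (G): disruptive indel
  rec2 <- classify_substitutions(global_align("GGGACACCC", "GGACACCC"), s)
  expect_true(any(rec2$class == "disruptive" & rec2$indel))
})
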