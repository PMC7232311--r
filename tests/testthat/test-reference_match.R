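test_that("align_pair reproduces the canonical worked examples", {
  x <- strrep("ACGT", 100)
  al <- align_pair(x, x)
  expect_equal(al$identity, 1.0)
  expect_equal(al$query_coverage, 1.0)

  al2 <- align_pair("AAAA", "AAAT")
  expect_identical(al2$aligned_columns, 4L)
  expect_identical(al2$matches, 3L)
  expect_equal(al2$identity, 0.75)

  al3 <- align_pair("ACGTACGT", "ACGACGT")
  expect_identical(al3$aligned_columns, 8L)
  expect_equal(al3$identity, 7 / 8)
  expect_identical(nchar(al3$gapped_subject), 8L)
  expect_identical(lengths(regmatches(al3$gapped_subject,
                                      gregexpr("-", al3$gapped_subject)))[[1]], 1L)
  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("aligner optimum matches an exhaustive affine DP oracle", {
  set.seed(2)
  for (i in 1:10) {
    a <- random_sequence(12)
    b <- random_sequence(sample(9:12, 1))
    al <- align_pair(a, b, scoring = list(match = 2, mismatch = -3,
                                          gap_open = 5, gap_extend = 2))
    got <- bf_score_gapped(al$gapped_query, al$gapped_subject)
    expect_identical(got, bf_affine_score(a, b), info = paste("case", i))
  }
  # the worked deletion example is the true optimum too
  al <- align_pair("ACGTACGT", "ACGACGT")
  expect_identical(bf_score_gapped(al$gapped_query, al$gapped_subject),
                   bf_affine_score("ACGTACGT", "ACGACGT"))
})

test_that("percent_identity conventions: arithmetic and N handling", {
  expect_equal(percent_identity(alignment_stats("AAAA", "AAAA")), 1.0)
  expect_equal(percent_identity(alignment_stats("AAAA", "TTTT")), 0.0)
  # 392 matches over 400 columns
  q <- strrep("A", 400)
  s <- paste0(strrep("A", 392), strrep("C", 8))
  expect_equal(percent_identity(alignment_stats(q, s)), 0.98)
  # N never counts as a match, in either sequence
  expect_equal(alignment_stats("ANAN", "ANAA")$matches, 2L)
})

test_that("identity is symmetric and equals planted p-distance on gap-free pairs", {
  set.seed(8)
  anc <- random_sequence(300)
  for (k in c(0, 3, 15, 60)) {
    other <- evolve_sequence(anc, k)
    ab <- align_pair(anc, other)
    ba <- align_pair(other, anc)
    expect_equal(ab$identity, ba$identity)
    expect_equal(1 - ab$identity, k / 300)
  }
  # symmetry with indels too
  a <- random_sequence(60)
  b <- paste0(substr(a, 1, 30), substr(a, 36, 60))
  expect_equal(align_pair(a, b)$identity, align_pair(b, a)$identity)
})

test_that("best_reference_hit filters, tie-breaks and matches brute force", {
  set.seed(14)
  refs <- stats::setNames(replicate(8, random_sequence(380)),
                          sprintf("R%02d", 1:8))
  # identical query
  hit <- best_reference_hit(stats::setNames(refs[["R03"]], "q"), refs)
  expect_identical(hit$reference_id, "R03")
  expect_equal(hit$identity, 1.0)
  # short query: span below 200 bp fails the length filter
  short <- stats::setNames(substr(refs[["R01"]], 1, 150), "q")
  expect_null(best_reference_hit(short, refs))
  expect_error(best_reference_hit(stats::setNames("ACGT", "q"), character(0)),
               "empty reference set")
  # brute-force equivalence over queries at assorted distances
  for (i in 1:6) {
    q <- stats::setNames(evolve_sequence(refs[[sample(8, 1)]],
                                         sample(c(2, 10, 45), 1)), "q")
    hit <- best_reference_hit(q, refs)
    oracle <- bf_best_hit(q, refs)
    expect_identical(hit$reference_id, oracle$reference_id)
    expect_equal(hit$identity, oracle$identity)
  }
})

test_that("classify_otus agrees with best_reference_hit per query", {
  set.seed(31)
  refs <- stats::setNames(replicate(5, random_sequence(380)),
                          sprintf("R%d", 1:5))
  focal <- stats::setNames(
    c(evolve_sequence(refs[[1]], 4), evolve_sequence(refs[[2]], 50),
      random_sequence(380)),
    c("near", "mid", "far"))
  tab <- classify_otus(focal, refs)
  for (id in names(focal)) {
    hit <- best_reference_hit(stats::setNames(focal[id], id), refs)
    row <- tab[tab$otu_id == id, ]
    expect_identical(row$reference_id, hit$reference_id)
    expect_equal(row$identity, hit$identity)
  }
})

test_that("distribution status bands and boundaries", {
  expect_identical(classify_distribution_status(0.005), "similar")
  expect_identical(classify_distribution_status(0.062), "unclear")
  expect_identical(classify_distribution_status(0.118), "potential_endemic")
  expect_identical(classify_distribution_status(0.01), "similar")    # inclusive
  expect_identical(classify_distribution_status(0.10), "unclear")    # inclusive
  expect_identical(classify_distribution_status(NA), "potential_endemic")
  # total function over a grid; every value maps to exactly one status
  grid <- seq(0, 1, by = 0.001)
  st <- classify_distribution_status(grid)
  expect_true(all(st %in% c("similar", "unclear", "potential_endemic")))
  expect_identical(length(st), length(grid))
})

test_that("80-90 band is half-open and nested in the Type 2 ceiling", {
  expect_true(in_band_80_90(0.85))
  expect_false(in_band_80_90(0.90))
  expect_false(in_band_80_90(0.79))
  expect_true(in_band_80_90(0.80))
  # band members always sit below the Type 2 ceiling
  ids <- stats::runif(200, 0, 1)
  p <- classify_params()
  expect_true(all(ids[in_band_80_90(ids, p)] < p$type2_identity_ceiling))
})

test_that("abundance classes with inclusive intermediate boundaries", {
  total <- 2284061
  expect_identical(classify_abundance(214236, total), "abundant")
  expect_identical(classify_abundance(1, total), "rare")
  expect_identical(classify_abundance(round(0.001 * total), total), "intermediate")
  expect_identical(classify_abundance(0.01 * total, total), "intermediate")
  expect_identical(classify_abundance(0.0001 * total, total), "intermediate")
})
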