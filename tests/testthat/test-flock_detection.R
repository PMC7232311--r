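test_that("mean_pairwise_divergence averages over unordered focal pairs", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(mean_pairwise_divergence(c("a", "b", "c"), d), 0)
  d[upper.tri(d)] <- d[lower.tri(d)] <- 0.02
  expect_equal(mean_pairwise_divergence(c("a", "b", "c"), d), 0.02)
  expect_error(mean_pairwise_divergence("a", d), "at least 2")
  expect_error(mean_pairwise_divergence(c("a", "zz"), d), "no distances")
})

test_that("a 53-tip planted radiation averages near its 2.2% target", {
  set.seed(53)
  pf <- plant_flock(random_sequence(380), 53, 0.022)
  dmat <- pairwise_divergences(pf$sequences)
  m <- mean_pairwise_divergence(names(pf$sequences), dmat)
  expect_equal(m, bf_mean_pairwise(pf$sequences))  # brute-force pair scan
  expect_gte(m, 0.018)
  expect_lte(m, 0.026)
})

test_that("abundance rule: worked examples", {
  # dominant with sub-100-read satellites: no valid 3-set containing it
  gyro <- c(d = 214236, s1 = 99, s2 = 98, s3 = 97, s4 = 50)
  res <- abundance_compatible(gyro)
  expect_false(res$passes)
  expect_identical(res$compatible_set, "d")
  # katablepharid-style cloud
  kata <- c(a = 30958, b = 86, c = 50, d = 2, e = 10, f = 4, g = 7)
  expect_false(abundance_compatible(kata)$passes)
  # comparable abundances: the 2-read OTU still within 100x of the max
  res3 <- abundance_compatible(c(w = 100, x = 50, y = 30, z = 2))
  expect_true(res3$passes)
  expect_setequal(res3$compatible_set, c("w", "x", "y", "z"))
  expect_error(abundance_compatible(numeric(0)), "empty")
  expect_error(abundance_compatible(c(a = 0, b = 5)), ">= 1")
})

test_that("abundance rule equals exhaustive subset search", {
  set.seed(26)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    reads <- stats::setNames(
      pmax(1, round(stats::rlnorm(n, 3, 2.5))), paste0("o", seq_len(n)))
    for (req_dom in c(TRUE, FALSE)) {
      p <- flock_params(require_dominant_in_set = req_dom)
      got <- abundance_compatible(reads, p)
      oracle <- bf_abundance_sets(unname(reads), require_dominant = req_dom)
      expect_identical(length(got$compatible_set), length(oracle),
                       info = paste("seed case", i, "dom", req_dom))
      expect_identical(got$passes, length(oracle) >= 3)
    }
  }
})

test_that("classify_clade decision order", {
  ok <- list(passes = TRUE, compatible_set = c("a", "b", "c"))
  bad <- list(passes = FALSE, compatible_set = "a")
  expect_identical(classify_clade(0.024, ok), "flock")
  expect_identical(classify_clade(0.05, ok), "divergent_clade")
  expect_identical(classify_clade(0.004, bad), "intragenomic_candidate")
  expect_identical(classify_clade(0.03, ok), "divergent_clade")  # strict <
})

test_that("detect_flocks recovers planted truth on a synthetic dataset", {
  fx <- make_small_dataset(seed = 7)
  ds <- fx$ds
  calls <- detect_flocks(fx$tree, names(ds$focal), ds$focal, ds$counts)
  flocks <- calls[calls$label == "flock", ]
  truth_sets <- lapply(ds$truth$flocks, function(f) sort(f$member_ids))
  expect_identical(nrow(flocks), length(truth_sets))
  for (ts in truth_sets)
    expect_true(any(vapply(flocks$member_ids, identical, TRUE, y = ts)))
  # the planted cloud is flagged intragenomic
  cl <- ds$truth$clouds$cloud1
  cloud_ids <- sort(c(cl$dominant_id, cl$satellite_ids))
  intra <- calls[calls$label == "intragenomic_candidate", ]
  expect_true(any(vapply(intra$member_ids,
                         function(m) all(cloud_ids %in% m), TRUE)))
})

test_that("no supported clades means no calls", {
  tr <- read_newick_text("((F1,F2)55,(F3,F4)60);")
  seqs <- stats::setNames(replicate(4, random_sequence(100)), paste0("F", 1:4))
  calls <- detect_flocks(tr, names(seqs), seqs,
                         stats::setNames(rep(10, 4), names(seqs)))
  expect_identical(nrow(calls), 0L)
})

test_that("nested same-label clades collapse to the maximal one", {
  set.seed(41)
  anc <- random_sequence(300)
  inner <- plant_flock(anc, 3, 0.01, prefix = "IN")$sequences
  outer <- vapply(1:2, function(i) evolve_sequence(anc, 4), "")
  names(outer) <- paste0("OUT", 1:2)
  seqs <- c(inner, outer)
  tr <- read_newick_text(
    "(((IN_01,IN_02,IN_03)99,OUT1,OUT2)95,(R1,R2)90);")
  totals <- stats::setNames(rep(50, 5), names(seqs))
  # the outer clade also passes every flock criterion here, so only the
  # maximal flock is reported
  calls <- detect_flocks(tr, names(seqs), seqs, totals)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$label, "flock")
  expect_setequal(calls$member_ids[[1]], names(seqs))
  # without collapsing, both nodes are scored
  calls2 <- detect_flocks(tr, names(seqs), seqs, totals,
                          collapse_nested = FALSE)
  expect_identical(nrow(calls2), 2L)
})

test_that("a flock nested inside a larger divergent clade is kept", {
  set.seed(43)
  anc <- random_sequence(300)
  inner <- plant_flock(anc, 3, 0.01, prefix = "IN")$sequences
  far <- vapply(1:2, function(i) evolve_sequence(anc, 60), "")  # 20% away
  names(far) <- paste0("FAR", 1:2)
  seqs <- c(inner, far)
  tr <- read_newick_text(
    "(((IN_01,IN_02,IN_03)99,FAR1,FAR2)95,(R1,R2)90);")
  totals <- stats::setNames(rep(50, 5), names(seqs))
  calls <- detect_flocks(tr, names(seqs), seqs, totals)
  expect_setequal(calls$label, c("flock", "divergent_clade"))
  expect_setequal(calls$member_ids[[which(calls$label == "flock")]],
                  names(inner))
})

test_that("every candidate gets exactly one label (partition invariant)", {
  for (seed in c(3, 19)) {
    sc <- make_random_scenario(seed)
    for (collapse in c(TRUE, FALSE)) {
      calls <- detect_flocks(sc$tree, sc$focal, sc$seqs, sc$totals,
                             collapse_nested = collapse)
      cands <- focal_clades(sc$tree, sc$focal)
      if (!collapse) expect_identical(nrow(calls), nrow(cands))
      expect_true(all(calls$label %in% c("flock", "divergent_clade",
                                         "intragenomic_candidate", "rejected")))
    }
  }
})

test_that("threshold monotonicity", {
  sc <- make_random_scenario(101)
  n_cand <- vapply(c(40, 60, 75, 90), function(ms)
    nrow(focal_clades(sc$tree, sc$focal, min_support = ms)), integer(1))
  expect_true(all(diff(n_cand) <= 0))
  # on the raw per-node view labels shift monotonically with the threshold
  n_flock <- vapply(c(0.01, 0.03, 0.10, 0.50), function(md) {
    p <- flock_params(max_mean_divergence = md)
    sum(detect_flocks(sc$tree, sc$focal, sc$seqs, sc$totals, params = p,
                      collapse_nested = FALSE)$label == "flock")
  }, integer(1))
  expect_true(all(diff(n_flock) >= 0))
})

test_that("endemism typing follows the Type 1 > 2 > 3 precedence", {
  flock_calls <- data.frame(call_id = "clade01", label = "flock",
                            stringsAsFactors = FALSE)
  flock_calls$member_ids <- list(c("F1", "F2", "F3"))
  tr <- read_newick_text("(((F1,F2,F3)100,Q85)70,((Q95,F4)40,R1)30,R2);")
  hit85 <- data.frame(query_id = "Q85", reference_id = "R1", identity = 0.85,
                      aligned_length = 380, coverage = 1)
  hit95 <- data.frame(query_id = "Q95", reference_id = "R1", identity = 0.95,
                      aligned_length = 380, coverage = 1)
  refs <- c("R1", "R2")
  # flock membership wins even when the member is < 90% to references
  t1 <- type_endemism("F1", flock_calls, hit85, tr, refs)
  expect_identical(t1$type, "type1_flock")
  # < 90% identity, not in a flock
  t2 <- type_endemism("Q85", flock_calls, hit85, tr, refs)
  expect_identical(t2$type, "type2_divergent")
  # no passing hit at all is Type 2 as well
  t2b <- type_endemism("Q85", flock_calls, NULL, tr, refs)
  expect_identical(t2b$type, "type2_divergent")
  # >= 90% identity but no supported reference-containing ancestor
  t3 <- type_endemism("Q95", flock_calls, hit95, tr, refs)
  expect_identical(t3$type, "type3_unplaced")
  # placed and similar: none
  tr2 <- read_newick_text("((Q95,R1)99,(F1,F2)50);")
  t0 <- type_endemism("Q95", flock_calls[0, ], hit95, tr2, refs)
  expect_identical(t0$type, "none")
})

test_that("detect_flocks equals the brute-force all-nodes scan (small batch)", {
  for (seed in c(2, 5, 8, 13, 21)) {
    sc <- make_random_scenario(seed, n_tips = 16)
    calls <- detect_flocks(sc$tree, sc$focal, sc$seqs, sc$totals)
    oracle <- bf_flock_scan(sc$tree, sc$focal, sc$seqs, sc$totals)
    expect_identical(nrow(calls), length(oracle), info = paste("seed", seed))
    got <- lapply(seq_len(nrow(calls)), function(i)
      list(members = calls$member_ids[[i]], label = calls$label[i]))
    key <- function(x) paste(x$label, paste(x$members, collapse = ","))
    expect_setequal(vapply(got, key, ""), vapply(oracle, key, ""))
  }
})
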