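make_cm <- function(counts, basins = NULL) {
  meta <- data.frame(sample_id = rownames(counts),
                     basin = if (is.null(basins)) "S" else basins,
                     site_class = "deep", depth_m = 15)
  suppressWarnings(community_matrix(counts, meta))
}

test_that("rarefaction conserves depth exactly and is deterministic", {
  counts <- matrix(c(300L, 150L, 50L, 0L,
                     500L, 0L, 0L, 0L,
                     40L, 30L, 20L, 10L), 3, 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"), paste0("o", 1:4)))
  cm <- make_cm(counts)
  r <- rarefy_counts(cm, depth = "min", seed = 5)
  expect_true(all(rowSums(r$counts) == 100L))
  # forced case: a sample with a single nonzero OTU keeps it all
  expect_identical(unname(r$counts["s2", ]), c(100L, 0L, 0L, 0L))
  # determinism
  r2 <- rarefy_counts(cm, depth = "min", seed = 5)
  expect_identical(r$counts, r2$counts)
  # samples below the target depth are dropped with a warning
  expect_warning(r3 <- rarefy_counts(cm, depth = 200, seed = 1),
                 "dropping sample")
  expect_false("s3" %in% rownames(r3$counts))
  expect_error(rarefy_counts(cm, depth = 0), "positive")
})

test_that("expected rarefied counts track depth * N_i / N", {
  counts <- matrix(c(600L, 300L, 100L), 1, 3,
                   dimnames = list("s1", paste0("o", 1:3)))
  cm <- make_cm(counts)
  set.seed(99)
  acc <- numeric(3)
  n_draws <- 400
  for (k in seq_len(n_draws)) {
    acc <- acc + rarefy_counts(cm, depth = 100)$counts[1, ]
  }
  avg <- acc / n_draws
  expected <- 100 * c(600, 300, 100) / 1000
  expect_true(all(abs(avg - expected) < 3 * sqrt(expected)))  # MC slack
})

test_that("Bray-Curtis formula, hand example and vegan oracle", {
  m <- matrix(c(6, 2, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("u", "v"), c("o1", "o2")))
  bc <- bray_curtis(m)
  expect_equal(bc["u", "v"], 1 / 3)  # 1 - 2*(2+2)/(8+4)
  # identical and disjoint rows
  m2 <- matrix(c(5, 0, 5, 0, 0, 7), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("o1", "o2")))
  bc2 <- bray_curtis(m2)
  expect_equal(bc2["a", "b"], 0)
  expect_equal(bc2["a", "c"], 1)
  # axioms + agreement with vegan on random fixtures
  set.seed(7)
  r <- matrix(rpois(60, 8), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  got <- bray_curtis(r)
  expect_equal(got, as.matrix(vegan::vegdist(r, method = "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(diag(got) == 0))
  expect_true(all(got >= 0 & got <= 1))
  expect_identical(got, t(got))
})

test_that("richness counts nonzero OTUs per sample", {
  counts <- matrix(c(0L, 0L, 0L, 4L, 0L, 1L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:3)))
  cm <- make_cm(counts)
  expect_identical(unname(richness(cm)), c(0L, 2L))
  set.seed(3)
  r <- matrix(rbinom(50, 3, 0.3), 5, 10,
              dimnames = list(paste0("s", 1:5), paste0("o", 1:10)))
  expect_identical(unname(richness(r)),
                   unname(apply(r, 1, function(x) sum(x > 0))))
})

test_that("rarefaction curve: closed form vs exhaustive enumeration", {
  # [5,5], n = 2: enumerate all unordered pairs of the 10 reads
  reads <- rep(c(1L, 2L), each = 5)  # OTU identity of each read
  pairs <- utils::combn(10, 2)
  mean_rich <- mean(apply(pairs, 2, function(ix) length(unique(reads[ix]))))
  got <- rarefaction_curve(c(5L, 5L), 2L)
  expect_equal(got, mean_rich)
  expect_equal(got, 2 - 2 * choose(5, 2) / choose(10, 2))
  # boundary depths
  expect_equal(rarefaction_curve(c(5L, 5L), 10L), 2)  # full depth: observed
  expect_equal(rarefaction_curve(c(5L, 5L), 1L), 1)
  expect_error(rarefaction_curve(c(5L, 5L), 11L), "outside")
  # vegan oracle on a bigger fixture
  counts <- c(40L, 25L, 10L, 3L, 1L)
  depths <- c(5L, 20L, 50L)
  expect_equal(rarefaction_curve(counts, depths),
               unname(vegan::rarefy(counts, depths)[1, ]),
               tolerance = 1e-10)
})

test_that("shared OTU partition covers every observed OTU exactly once", {
  counts <- matrix(c(1L, 1L, 0L, 0L,
                     0L, 1L, 1L, 0L,
                     0L, 1L, 0L, 0L), 3, 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"), paste0("o", 1:4)))
  cm <- make_cm(counts, basins = c("S", "N", "N"))
  part <- shared_otus(cm, stats::setNames(c("S", "N", "N"),
                                          c("s1", "s2", "s3")))
  get <- function(r) { x <- part$n_otus[part$region == r]
                       if (length(x) == 0) 0L else x }
  expect_identical(get("S"), 1L)        # o1 only in S
  expect_identical(get("N"), 1L)        # o3 only in N
  expect_identical(get("N&S"), 1L)      # o2 shared
  expect_identical(sum(part$n_otus), 3L)  # o4 unobserved
  # single group: everything unique to it
  one <- shared_otus(cm, stats::setNames(rep("S", 3), rownames(counts)))
  expect_identical(one$region, "S")
  expect_identical(one$n_otus, 3L)
  # partition-sum property on a random fixture vs brute-force set algebra
  set.seed(12)
  r <- matrix(rbinom(80, 2, 0.3), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("o", 1:10)))
  gr <- stats::setNames(rep(c("S", "C", "N"), length.out = 8), rownames(r))
  part2 <- shared_otus(make_cm(r, basins = unname(gr)), gr)
  expect_identical(sum(part2$n_otus), sum(colSums(r) > 0))
})
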