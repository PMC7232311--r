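# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive and separate from the package's own code paths.

# naive per-position distance: proportion of differing positions
bf_pdist <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  diff <- 0
  for (i in seq_along(av)) if (av[i] != bv[i]) diff <- diff + 1
  diff / length(av)
}

# mean pairwise distance by explicit double loop
bf_mean_pairwise <- function(seqs) {
  n <- length(seqs)
  tot <- 0; k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + bf_pdist(seqs[[i]], seqs[[j]]); k <- k + 1
  }
  tot / k
}

# exhaustive global affine-gap optimum by 3-state DP (tiny strings only):
# independent check that the aligner's optimum is the true optimum.
# A gap run of length L costs open + ext * L (the aligner's convention).
bf_affine_score <- function(a, b, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  n <- nchar(a); m <- nchar(b)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# score a gapped alignment pair under the same affine convention
bf_score_gapped <- function(gq, gs, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  q <- strsplit(gq, "")[[1]]; s <- strsplit(gs, "")[[1]]
  score <- 0; in_gap <- FALSE
  for (k in seq_along(q)) {
    if (q[k] == "-" || s[k] == "-") {
      score <- score - ext - (if (!in_gap) open else 0)
      in_gap <- TRUE
    } else {
      score <- score + (if (q[k] == s[k]) match else mismatch)
      in_gap <- FALSE
    }
  }
  score
}

# brute-force nearest-reference scan: align query to every reference with
# the package aligner, apply the filter by hand, pick the best by the
# documented tie-breaks
bf_best_hit <- function(query, refs, min_cov = 0.70, min_len = 200) {
  best <- NULL
  for (rid in sort(names(refs))) {
    al <- align_pair(query, refs[[rid]])
    if (al$query_coverage > min_cov && al$aligned_columns >= min_len) {
      cand <- list(reference_id = rid, identity = al$identity,
                   aligned_length = al$aligned_columns)
      if (is.null(best) ||
          cand$identity > best$identity ||
          (cand$identity == best$identity &&
           cand$aligned_length > best$aligned_length)) best <- cand
    }
  }
  best
}

# exhaustive abundance-compatibility search over all subsets (n <= 15)
bf_abundance_sets <- function(reads, ratio = 100, require_dominant = TRUE) {
  n <- length(reads)
  stopifnot(n <= 15)
  dom <- which.max(reads)
  best <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (require_dominant && !(dom %in% idx)) next
    r <- reads[idx]
    if (max(r) / min(r) < ratio && length(idx) > length(best)) best <- idx
  }
  best
}

# naive all-nodes flock scan: every internal non-root node, all criteria
# applied directly via ape; every candidate classified first, then calls
# nested inside a same-label call or inside an intragenomic call dropped.
# Returns a list of calls (sorted member ids + label).
bf_flock_scan <- function(tree, focal_ids, seqs, totals,
                          min_support = 60, min_focal = 3,
                          max_div = 0.03, ratio = 100) {
  ntip <- length(tree$tip.label)
  root <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])[1]
  sup <- if (is.null(tree$node.label)) rep(NA, tree$Nnode) else
    suppressWarnings(as.numeric(tree$node.label))
  cand <- list()
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    if (node == root) next
    s <- sup[node - ntip]
    if (is.na(s) || s <= min_support) next
    tips <- ape::extract.clade(tree, node)$tip.label
    foc <- intersect(tips, focal_ids)
    if (length(foc) < min_focal) next
    cand[[length(cand) + 1]] <- list(tips = sort(tips), focal = sort(foc),
                                     support = s)
  }
  if (length(cand) == 0) return(list())
  calls <- list()
  for (i in seq_along(cand)) {
    foc <- cand[[i]]$focal
    withseq <- foc[foc %in% names(seqs)]
    reads <- totals[foc]
    reads <- reads[!is.na(reads) & reads >= 1]
    if (length(withseq) < 2 || length(reads) == 0) {
      label <- "rejected"
    } else {
      div <- bf_mean_pairwise(seqs[withseq])
      # abundance: largest valid set must contain the most abundant OTU;
      # that set is exactly the OTUs within ratio of the dominant
      dom <- max(reads)
      set <- reads[dom / reads < ratio]
      ab_ok <- length(set) >= 3
      label <- if (!ab_ok) "intragenomic_candidate"
        else if (div < max_div) "flock" else "divergent_clade"
    }
    calls[[length(calls) + 1]] <- list(members = foc, label = label,
                                       tips = cand[[i]]$tips)
  }
  keep <- rep(TRUE, length(calls))
  for (i in seq_along(calls)) for (j in seq_along(calls)) {
    if (i != j &&
        length(calls[[i]]$tips) < length(calls[[j]]$tips) &&
        all(calls[[i]]$tips %in% calls[[j]]$tips) &&
        (calls[[j]]$label == calls[[i]]$label ||
         calls[[j]]$label == "intragenomic_candidate")) keep[i] <- FALSE
  }
  lapply(calls[keep], function(x) x[c("members", "label")])
}

# random scenario for the oracle-equivalence suite: a handful of sequence
# clusters (some tight, some loose) placed on a random topology with random
# supports and read totals
make_random_scenario <- function(seed, n_tips = NULL) {
  set.seed(seed)
  if (is.null(n_tips)) n_tips <- sample(8:32, 1)
  len <- 200
  n_clust <- max(2, n_tips %/% 4)
  anc <- replicate(n_clust, random_sequence(len))
  seqs <- character(n_tips)
  for (i in seq_len(n_tips)) {
    cl <- sample(n_clust, 1)
    d <- sample(c(0.01, 0.02, 0.05, 0.2), 1)
    seqs[i] <- evolve_sequence(anc[cl], round(d * len))
  }
  names(seqs) <- sprintf("T%02d", seq_len(n_tips))
  tree <- ape::rtree(n_tips, tip.label = names(seqs))
  lab <- sample(c(NA, 30, 55, 60, 61, 75, 90, 100), tree$Nnode, replace = TRUE)
  tree$node.label <- ifelse(is.na(lab), "", as.character(lab))
  n_focal <- max(3, round(0.8 * n_tips))
  focal <- sample(names(seqs), n_focal)
  totals <- stats::setNames(
    pmax(1, round(stats::rlnorm(n_tips, 4, 2))), names(seqs))
  if (runif(1) < 0.3) totals[sample(n_tips, 1)] <- 250000  # dominant OTU
  list(tree = tree, focal = focal, seqs = seqs, totals = totals)
}

# small bootstrap-supported dataset shared by several tests
make_small_dataset <- function(seed = 7) {
  cfg <- generator_config(
    n_references = 5, n_background_otus = 8,
    flocks = list(list(n_tips = 4, target_divergence = 0.02),
                  list(n_tips = 3, target_divergence = 0.02)),
    clouds = list(list(n_satellites = 4, identity_range = c(0.95, 0.99),
                       dominant_reads = 30958)),
    endemic_otus = list(n = 2, distance_range = c(0.12, 0.18)),
    n_samples = 6, depth_range = c(5000, 8000), seed = seed)
  ds <- generate_dataset(cfg)
  tree <- bootstrap_supports(ds$alignment, n_reps = 100, seed = seed + 101,
                             outgroup = "REF_OUT")
  list(ds = ds, tree = tree)
}
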