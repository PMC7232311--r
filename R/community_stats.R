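# Community-level statistics: rarefaction (single random subsample per
# sample), Bray-Curtis beta-diversity, richness, exact rarefaction curves
# and shared-OTU (Venn) partitions.

#' Rarefy a community matrix to a common depth
#'
#' One random subsample without replacement per sample (rrarefy-style);
#' every retained row sums exactly to `depth`. Samples whose total is below
#' the target depth are dropped with a warning — sampling without
#' replacement cannot exceed the available reads.
#'
#' @param x A `community_matrix`.
#' @param depth Integer target depth, or `"min"` for the minimum positive
#'   sample total.
#' @param seed Optional RNG seed (determinism contract).
#' @param mean_of Optional integer: average this many independent draws
#'   instead of a single one (rounded counts; row sums then only
#'   approximately equal `depth`). Not the default behavior.
#' @return A rarefied `community_matrix`.
#' @export
rarefy_counts <- function(x, depth = "min", seed = NULL, mean_of = NULL) {
  stopifnot(inherits(x, "community_matrix"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  totals <- sample_depths(x)
  if (identical(depth, "min")) {
    pos <- totals[totals > 0L]
    if (length(pos) == 0L) stop("no sample with positive total reads")
    depth <- min(pos)
  }
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0L) stop("depth must be a positive integer")
  keep <- totals >= depth
  if (any(!keep))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(names(totals)[!keep], collapse = ", "))
  if (!any(keep)) stop("no sample reaches depth ", depth)
  m <- x$counts[keep, , drop = FALSE]
  draw_one <- function(row) {
    pool <- rep.int(seq_along(row), row)
    picked <- pool[sample.int(length(pool), depth)]
    tabulate(picked, nbins = length(row))
  }
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    if (is.null(mean_of)) {
      out[i, ] <- draw_one(m[i, ])
    } else {
      acc <- rowSums(vapply(seq_len(mean_of), function(k) draw_one(m[i, ]),
                            numeric(ncol(m))))
      out[i, ] <- as.integer(round(acc / mean_of))
    }
  }
  meta <- x$sample_meta[keep, , drop = FALSE]
  suppressWarnings(community_matrix(out, meta))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u_i) + sum(v_i))` for every
#' sample pair: 0 for identical rows, 1 for rows with disjoint support.
#'
#' @param x A `community_matrix` (or plain samples-by-OTUs matrix).
#' @return Symmetric numeric matrix in \[0,1\] with zero diagonal, sample
#'   ids as dimnames.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "community_matrix")) x$counts else as.matrix(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- sum(m[i, ]) + sum(m[j, ])
    d[i, j] <- d[j, i] <- if (tot == 0) 0 else
      1 - 2 * sum(pmin(m[i, ], m[j, ])) / tot
  }
  d
}

#' Per-sample OTU richness
#' @param x A `community_matrix`.
#' @return Named integer vector: number of OTUs with count > 0 per sample.
#' @export
richness <- function(x) {
  m <- if (inherits(x, "community_matrix")) x$counts else as.matrix(x)
  v <- rowSums(m > 0L)
  stats::setNames(as.integer(v), names(v))
}

#' Exact expected rarefaction curve for one sample
#'
#' Closed-form expectation of richness at subsample size n:
#' `E[S(n)] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated in
#' log space for numerical stability.
#'
#' @param sample_counts Non-negative integer vector of per-OTU reads.
#' @param depths Integer vector of subsample sizes, each in `[0, N]`.
#' @return Numeric vector of expected richness, one per depth.
#' @export
rarefaction_curve <- function(sample_counts, depths) {
  counts <- sample_counts[sample_counts > 0L]
  N <- sum(counts)
  vapply(depths, function(n) {
    if (n < 0 || n > N) stop("depth ", n, " outside [0, ", N, "]")
    if (n == 0L) return(0)
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1L))
}

#' Shared-OTU (Venn) partition across sample groups
#'
#' An OTU belongs to a group when any sample of that group has a positive
#' count; the partition counts OTUs for every non-empty combination of
#' group memberships and sums to the total number of observed OTUs.
#'
#' @param x A `community_matrix`.
#' @param groups Named character vector mapping sample id -> group label
#'   (e.g. basin).
#' @return `data.frame` with columns `region` (ampersand-joined sorted
#'   group labels) and `n_otus`.
#' @export
shared_otus <- function(x, groups) {
  m <- if (inherits(x, "community_matrix")) x$counts else as.matrix(x)
  miss <- setdiff(rownames(m), names(groups))
  if (length(miss) > 0L)
    stop("no group for sample(s): ", paste(miss, collapse = ", "))
  glev <- sort(unique(unname(groups[rownames(m)])))
  present <- vapply(glev, function(g) {
    rows <- rownames(m)[groups[rownames(m)] == g]
    colSums(m[rows, , drop = FALSE] > 0L) > 0L
  }, logical(ncol(m)))
  if (ncol(m) == 1L) present <- matrix(present, nrow = 1L,
                                       dimnames = list(colnames(m), glev))
  observed <- rowSums(present) > 0L
  region <- apply(present[observed, , drop = FALSE], 1L, function(p)
    paste(glev[p], collapse = "&"))
  tab <- table(region)
  data.frame(region = names(tab), n_otus = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
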