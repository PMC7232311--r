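# Clade enumeration over support-labeled trees, placement queries, and a
# lightweight NJ + bootstrap builder used to create test trees.

# Actual root node number (the node that is never a child).
.root_node <- function(tree) {
  unique(tree$edge[!(tree$edge[, 1L] %in% tree$edge[, 2L]), 1L])[1L]
}

# Tip-index sets for every internal node of a phylo, in node-number order
# (Ntip+1 .. Ntip+Nnode), by postorder accumulation over the edge matrix.
.clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  lapply(sets[(ntip + 1L):(ntip + nnode)], sort)
}

#' Enumerate candidate clades of a support-labeled tree
#'
#' One entry per internal node that carries a bootstrap support value; the
#' root is never a candidate (its support is undefined under arbitrary
#' rooting) and nodes with absent supports are ineligible rather than
#' treated as support 0.
#'
#' @param tree A `phylo` with numeric internal node labels (see
#'   [read_newick()]).
#' @return `data.frame` with columns `node` (ape node number), `support`,
#'   `n_tips`, and list-column `tips` (tip labels).
#' @export
enumerate_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  supports <- node_supports(tree)
  sets <- .clade_tip_sets(tree)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  root <- .root_node(tree)
  keep <- which(!is.na(supports) & nodes != root)
  out <- data.frame(node = nodes[keep],
                    support = supports[keep],
                    n_tips = vapply(sets[keep], length, integer(1L)))
  out$tips <- lapply(sets[keep], function(ix) tree$tip.label[ix])
  out
}

#' Candidate clades containing enough focal tips at sufficient support
#'
#' Clades with bootstrap support strictly greater than `min_support` and at
#' least `min_focal` focal tips. Non-focal tips (references, environmental
#' sequences) inside the clade are permitted.
#'
#' @param tree A support-labeled `phylo`.
#' @param focal_ids Character vector of focal tip labels.
#' @param min_support Support threshold, strict (`> min_support`).
#' @param min_focal Minimum number of focal tips in the clade.
#' @return As [enumerate_clades()] plus `n_focal` and list-column
#'   `focal_tips`.
#' @export
focal_clades <- function(tree, focal_ids, min_support = 60, min_focal = 3L) {
  cl <- enumerate_clades(tree)
  cl$focal_tips <- lapply(cl$tips, function(t) intersect(t, focal_ids))
  cl$n_focal <- vapply(cl$focal_tips, length, integer(1L))
  cl[cl$support > min_support & cl$n_focal >= min_focal, , drop = FALSE]
}

#' Smallest supported ancestor clade containing a reference tip
#'
#' Walks from the tip toward the root and returns the first ancestor with
#' support strictly above `min_support` whose clade contains at least one
#' reference tip. `NULL` means the OTU has no supported placement with any
#' reference — the evidence for Type 3 endemism.
#'
#' @param tree A support-labeled `phylo`.
#' @param otu_id Focal tip label.
#' @param reference_ids Character vector of reference tip labels.
#' @param min_support Support threshold, strict.
#' @return One-row `data.frame` (`node`, `support`, `n_tips`, `tips`
#'   list-column) or `NULL`.
#' @export
smallest_supported_clade_with_reference <- function(tree, otu_id,
                                                    reference_ids,
                                                    min_support = 60) {
  tip <- match(otu_id, tree$tip.label)
  if (is.na(tip)) stop("tip not in tree: ", otu_id)
  ntip <- length(tree$tip.label)
  supports <- node_supports(tree)
  sets <- .clade_tip_sets(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- .root_node(tree)
  node <- parent[tip]
  while (node != 0L) {
    if (node != root) {
      sup <- supports[node - ntip]
      tips <- tree$tip.label[sets[[node - ntip]]]
      if (!is.na(sup) && sup > min_support &&
          length(intersect(tips, reference_ids)) > 0L) {
        out <- data.frame(node = node, support = sup, n_tips = length(tips))
        out$tips <- list(tips)
        return(out)
      }
    }
    node <- if (node == root) 0L else parent[node]
  }
  NULL
}

#' Neighbor-joining tree from a distance matrix (fixture builder)
#'
#' Thin validated wrapper over [ape::nj()]; on additive distances it recovers
#' the generating topology exactly.
#'
#' @param distances Square symmetric numeric matrix with zero diagonal and
#'   at least 3 taxa; dimnames become tip labels.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  ape::nj(stats::as.dist(d))
}

# p-distance matrix of a character-matrix alignment (rows = taxa);
# match counts via per-base indicator crossproducts (no pairwise R loop)
.aln_pdist <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (mat == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- 1 - matches / L
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

# named character vector of equal-length sequences -> character matrix
.aln_matrix <- function(seqs) {
  seqs <- as_sequences(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment sequences must all have equal length")
  do.call(rbind, lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]]))
}

#' Bootstrap-supported NJ tree from a gap-free alignment
#'
#' Resamples alignment columns with replacement, rebuilds a
#' neighbor-joining tree per replicate, and assigns each internal clade of
#' the original tree the percentage of replicates containing the same
#' unrooted tip bipartition (so supports are invariant to the arbitrary
#' rooting). Optionally roots the returned tree on an outgroup tip.
#'
#' @param alignment Named equal-length gap-free sequences.
#' @param n_reps Number of bootstrap replicates (> 0).
#' @param seed Optional RNG seed (determinism contract).
#' @param outgroup Optional tip label to root the returned tree on.
#' @return A `phylo` whose `node.label` carries integer support percentages
#'   (root label empty).
#' @export
bootstrap_supports <- function(alignment, n_reps = 100L, seed = NULL,
                               outgroup = NULL) {
  n_reps <- as.integer(n_reps)
  if (n_reps <= 0L) stop("n_reps must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mat <- .aln_matrix(alignment)
  if (nrow(mat) < 4L) stop("need at least 4 sequences for bootstrapping")
  build <- function(m) ape::nj(stats::as.dist(.aln_pdist(m)))
  main <- build(mat)
  counts <- ape::boot.phylo(main, mat, build, B = n_reps,
                            rooted = FALSE, quiet = TRUE)
  pct <- round(100 * counts / n_reps)
  lab <- as.character(pct)
  lab[is.na(pct)] <- ""
  main$node.label <- lab
  if (!is.null(outgroup)) {
    if (!outgroup %in% main$tip.label)
      stop("outgroup not in alignment: ", outgroup)
    main <- ape::root(main, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  lab <- main$node.label
  lab[.root_node(main) - nrow(mat)] <- ""  # root support is undefined
  main$node.label <- lab
  main
}
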