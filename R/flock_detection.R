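# Core inference: classify bootstrap-supported candidate clades into
# species flocks, divergent clades or intragenomic-variation candidates,
# and type each OTU's endemism (Type 1 radiation / Type 2 divergent /
# Type 3 unplaced).

#' Species-flock decision thresholds
#'
#' The operational flock definition: three or more co-clustered OTUs with
#' bootstrap support strictly above 60, mean pairwise identity above 97%
#' (divergence < 3%), and comparable abundances — at least three members
#' whose read counts differ by less than 100-fold. A clade whose members
#' fail the abundance rule is flagged as putative intragenomic rRNA
#' variation instead.
#'
#' @param min_support Bootstrap threshold, strict (`> min_support`).
#' @param min_focal Minimum focal OTUs per candidate clade.
#' @param max_mean_divergence Strict upper bound on mean pairwise
#'   divergence for a flock (default 0.03).
#' @param max_abundance_ratio Strict upper bound on the max/min read ratio
#'   within the compatible set (default 100).
#' @param min_abundance_set Minimum size of the compatible set (default 3).
#' @param require_dominant_in_set When `TRUE` (default) the compatible set
#'   must contain the clade's most abundant OTU — the reading under which a
#'   dominant-plus-satellites clade is intragenomic even when the satellites
#'   are mutually comparable. Set `FALSE` for the literal reading.
#' @return A list of class `flock_params`.
#' @export
flock_params <- function(min_support = 60, min_focal = 3L,
                         max_mean_divergence = 0.03,
                         max_abundance_ratio = 100,
                         min_abundance_set = 3L,
                         require_dominant_in_set = TRUE) {
  stopifnot(max_mean_divergence > 0, max_mean_divergence < 1,
            max_abundance_ratio > 1, min_abundance_set >= 2L)
  structure(list(min_support = min_support, min_focal = as.integer(min_focal),
                 max_mean_divergence = max_mean_divergence,
                 max_abundance_ratio = max_abundance_ratio,
                 min_abundance_set = as.integer(min_abundance_set),
                 require_dominant_in_set = isTRUE(require_dominant_in_set)),
            class = "flock_params")
}

#' Pairwise divergence matrix of a sequence set
#'
#' Divergence = 1 - identity from the package aligner ([align_pair()]).
#' Equal-length sequence pairs take the exact ungapped fast path
#' ([p_distance()]), identical by construction to the aligner on gap-free
#' pairs.
#'
#' @param sequences Named sequences.
#' @param method `"auto"` (fast path when lengths equal), `"align"`
#'   (always align), or `"pdist"` (require equal lengths).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_divergences <- function(sequences, method = c("auto", "align", "pdist")) {
  method <- match.arg(method)
  seqs <- as_sequences(sequences)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  equal_len <- length(unique(nchar(seqs))) == 1L
  use_pdist <- switch(method, auto = equal_len, align = FALSE, pdist = TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- if (use_pdist) p_distance(seqs[[i]], seqs[[j]])
      else 1 - align_pair(seqs[[i]], seqs[[j]])$identity
  }
  d
}

#' Mean pairwise divergence over a set of focal OTUs
#'
#' Arithmetic mean of divergence over all unordered pairs of the given
#' focal ids; non-focal clade members (references, environmental tips) are
#' excluded by construction of the id set.
#'
#' @param focal_ids At least 2 OTU ids.
#' @param distances Square divergence matrix with matching dimnames (see
#'   [pairwise_divergences()]).
#' @return Mean pairwise divergence (fraction).
#' @export
mean_pairwise_divergence <- function(focal_ids, distances) {
  focal_ids <- unique(focal_ids)
  if (length(focal_ids) < 2L) stop("need at least 2 focal ids")
  miss <- setdiff(focal_ids, rownames(distances))
  if (length(miss) > 0L)
    stop("no distances for: ", paste(miss, collapse = ", "))
  sub <- distances[focal_ids, focal_ids, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Abundance-compatibility rule of the flock definition
#'
#' Finds the largest set of OTUs whose maximum/minimum read ratio is
#' strictly below `max_abundance_ratio`; with
#' `require_dominant_in_set = TRUE` the set must contain the most abundant
#' OTU of the clade (so a 214,236-read dominant with sub-100-read
#' satellites can never pass, whatever the satellites do among themselves).
#' The rule passes when the set has at least `min_abundance_set` members.
#'
#' @param total_reads Named integer vector of per-OTU read totals, all >= 1
#'   (zero-read OTUs are excluded upstream).
#' @param params A [flock_params()].
#' @return List with `passes` (logical) and `compatible_set` (OTU ids).
#' @export
abundance_compatible <- function(total_reads, params = flock_params()) {
  if (length(total_reads) == 0L) stop("empty abundance input")
  if (is.null(names(total_reads)))
    names(total_reads) <- paste0("otu", seq_along(total_reads))
  if (any(total_reads < 1)) stop("all read totals must be >= 1")
  r <- sort(total_reads, decreasing = TRUE)
  ratio <- params$max_abundance_ratio
  if (params$require_dominant_in_set) {
    keep <- r[r[1L] / r < ratio]  # strict: max/min must stay < ratio
    set <- names(keep)
  } else {
    # largest window of the sorted vector with max/min < ratio
    best <- integer(0L)
    j <- 1L
    for (i in seq_along(r)) {
      if (j < i) j <- i
      while (j < length(r) && r[i] / r[j + 1L] < ratio) j <- j + 1L
      if (j - i + 1L > length(best)) best <- i:j
    }
    set <- names(r)[best]
  }
  list(passes = length(set) >= params$min_abundance_set,
       compatible_set = set)
}

#' Classify one candidate clade
#'
#' Decision order: a failed abundance rule marks the clade as putative
#' intragenomic variation regardless of divergence; otherwise mean pairwise
#' divergence strictly below the 3% bound makes it a flock, at or above the
#' bound a divergent clade (flock-like support and abundances, deeper
#' splits).
#'
#' @param divergence Mean pairwise divergence among the clade's focal OTUs.
#' @param abundance Result of [abundance_compatible()].
#' @param params A [flock_params()].
#' @return One of `"flock"`, `"divergent_clade"`, `"intragenomic_candidate"`.
#' @export
classify_clade <- function(divergence, abundance, params = flock_params()) {
  if (!abundance$passes) return("intragenomic_candidate")
  if (is.na(divergence)) return("rejected")
  if (divergence < params$max_mean_divergence) "flock" else "divergent_clade"
}

#' Detect species flocks on a support-labeled tree
#'
#' Runs the full candidate-clade pipeline: enumerate clades with support
#' strictly above the threshold containing at least `min_focal` focal tips;
#' score each candidate's mean pairwise divergence (focal OTUs only,
#' sequence-based) and abundance compatibility; classify; then collapse
#' nested calls so a radiation is counted once, not once per internal node.
#'
#' The collapse is label-aware: a call is dropped when its clade is nested
#' inside a same-label call (the maximal clade represents the radiation /
#' divergent group) or inside an `intragenomic_candidate` call (subsets of
#' a variant cloud's satellites belong to the cloud, not to a new flock).
#' A flock nested inside a larger *divergent* clade is kept — that is the
#' normal situation of a radiation inside its parent taxon's clade.
#' Calls are ordered by clade size (descending) then first member id.
#'
#' @param tree A support-labeled `phylo` whose tips include the focal ids.
#' @param focal_ids Focal OTU ids.
#' @param sequences Named sequences for (at least) the focal OTUs.
#' @param counts A `community_matrix` or named per-OTU read totals.
#' @param params A [flock_params()].
#' @param collapse_nested Apply the label-aware nested-call collapse
#'   (default `TRUE`; `FALSE` keeps one call per candidate node — the raw
#'   per-node view, on which threshold monotonicity holds exactly).
#' @param divergence_method Passed to [pairwise_divergences()].
#' @return `data.frame` of flock calls: `call_id`, `label`, `support`,
#'   `n_tips`, `n_focal`, `mean_divergence`, `members` and `abundance_set`
#'   (semicolon-joined), plus list-columns `member_ids`, `abundance_ids`.
#' @export
detect_flocks <- function(tree, focal_ids, sequences, counts,
                          params = flock_params(), collapse_nested = TRUE,
                          divergence_method = "auto") {
  seqs <- as_sequences(sequences)
  totals <- if (inherits(counts, "community_matrix")) otu_totals(counts)
            else counts
  cands <- focal_clades(tree, focal_ids, params$min_support, params$min_focal)
  if (nrow(cands) == 0L) return(.empty_flock_calls())
  # distance cache over all focal OTUs appearing in any candidate
  used <- unique(unlist(cands$focal_tips))
  have_seq <- intersect(used, names(seqs))
  dmat <- pairwise_divergences(seqs[have_seq], method = divergence_method)

  rows <- lapply(seq_len(nrow(cands)), function(i) {
    members <- cands$focal_tips[[i]]
    reads <- totals[members]
    reads <- reads[!is.na(reads) & reads >= 1]
    div_ids <- intersect(members, have_seq)
    divergence <- if (length(div_ids) >= 2L)
      mean_pairwise_divergence(div_ids, dmat) else NA_real_
    if (length(reads) == 0L || length(div_ids) < 2L) {
      label <- "rejected"
      ab <- list(passes = FALSE, compatible_set = character(0L))
    } else {
      ab <- abundance_compatible(reads, params)
      label <- classify_clade(divergence, ab, params)
    }
    out <- data.frame(label = label, support = cands$support[i],
                      n_tips = cands$n_tips[i], n_focal = cands$n_focal[i],
                      mean_divergence = divergence,
                      members = paste(sort(members), collapse = ";"),
                      abundance_set = paste(sort(ab$compatible_set),
                                            collapse = ";"),
                      stringsAsFactors = FALSE)
    out$member_ids <- list(sort(members))
    out$abundance_ids <- list(sort(ab$compatible_set))
    out
  })
  calls <- do.call(rbind, rows)
  if (collapse_nested && nrow(calls) > 1L) {
    tipsets <- cands$tips
    keep <- rep(TRUE, nrow(calls))
    for (i in seq_len(nrow(calls))) {
      for (j in seq_len(nrow(calls))) {
        if (i == j) next
        nested <- length(tipsets[[i]]) < length(tipsets[[j]]) &&
          all(tipsets[[i]] %in% tipsets[[j]])
        if (nested && (calls$label[j] == calls$label[i] ||
                       calls$label[j] == "intragenomic_candidate")) {
          keep[i] <- FALSE
          break
        }
      }
    }
    calls <- calls[keep, , drop = FALSE]
  }
  ord <- order(-calls$n_tips,
               vapply(calls$member_ids, function(m) m[1L], character(1L)))
  calls <- calls[ord, , drop = FALSE]
  calls$call_id <- sprintf("clade%02d", seq_len(nrow(calls)))
  rownames(calls) <- NULL
  calls[, c("call_id", "label", "support", "n_tips", "n_focal",
            "mean_divergence", "members", "abundance_set",
            "member_ids", "abundance_ids")]
}

.empty_flock_calls <- function() {
  out <- data.frame(call_id = character(0L), label = character(0L),
                    support = numeric(0L), n_tips = integer(0L),
                    n_focal = integer(0L), mean_divergence = numeric(0L),
                    members = character(0L), abundance_set = character(0L),
                    stringsAsFactors = FALSE)
  out$member_ids <- list()
  out$abundance_ids <- list()
  out
}

#' Type one OTU's endemism
#'
#' Precedence Type 1 > Type 2 > Type 3: membership in a called flock wins
#' (radiation products are flock members first, however divergent they are
#' from references); otherwise identity below 90% to every known sequence
#' (or no passing hit at all) gives Type 2; otherwise an OTU whose best hit
#' is decent but which has no supported placement with any reference tip is
#' Type 3; everything else is `"none"`.
#'
#' @param otu_id Focal OTU id.
#' @param flock_calls Output of [detect_flocks()].
#' @param best_hit One-row hit `data.frame` from [best_reference_hit()] or
#'   `NULL` when no hit passed the filters.
#' @param tree Support-labeled `phylo` (for the Type 3 placement query).
#' @param reference_ids Reference tip labels in the tree.
#' @param params A [flock_params()] (support threshold reused for placement).
#' @param identity_ceiling Type 2 identity ceiling (default 0.90).
#' @return List with `otu_id`, `type` (`"type1_flock"`, `"type2_divergent"`,
#'   `"type3_unplaced"`, `"none"`), `evidence`.
#' @export
type_endemism <- function(otu_id, flock_calls, best_hit, tree, reference_ids,
                          params = flock_params(), identity_ceiling = 0.90) {
  flocks <- flock_calls[flock_calls$label == "flock", , drop = FALSE]
  in_flock <- vapply(flocks$member_ids, function(m) otu_id %in% m, logical(1L))
  if (any(in_flock))
    return(list(otu_id = otu_id, type = "type1_flock",
                evidence = paste0("member of ",
                                  flocks$call_id[which(in_flock)[1L]])))
  identity <- if (is.null(best_hit) || nrow(best_hit) == 0L) NA_real_
              else best_hit$identity[1L]
  if (is.na(identity) || identity < identity_ceiling)
    return(list(otu_id = otu_id, type = "type2_divergent",
                evidence = if (is.na(identity)) "no passing reference hit"
                           else sprintf("best hit identity %.4f", identity)))
  placement <- if (otu_id %in% tree$tip.label)
    smallest_supported_clade_with_reference(tree, otu_id, reference_ids,
                                            params$min_support) else NULL
  if (is.null(placement))
    return(list(otu_id = otu_id, type = "type3_unplaced",
                evidence = sprintf(
                  "identity %.4f but no supported clade with a reference",
                  identity)))
  list(otu_id = otu_id, type = "none",
       evidence = sprintf("identity %.4f; placed at support %g",
                          identity, placement$support))
}

#' Endemism typing for a set of OTUs
#'
#' Vectorized wrapper around [type_endemism()] driven by the hit report of
#' [classify_otus()].
#'
#' @param otu_ids Focal OTU ids to type.
#' @param flock_calls Output of [detect_flocks()].
#' @param hits Hit report from [classify_otus()].
#' @param tree Support-labeled `phylo`.
#' @param reference_ids Reference tip labels.
#' @param params A [flock_params()].
#' @param identity_ceiling Type 2 identity ceiling.
#' @return `data.frame` with columns `otu_id`, `type`, `evidence`.
#' @export
endemism_table <- function(otu_ids, flock_calls, hits, tree, reference_ids,
                           params = flock_params(), identity_ceiling = 0.90) {
  rows <- lapply(otu_ids, function(id) {
    h <- hits[hits$otu_id == id & hits$passed, , drop = FALSE]
    bh <- if (nrow(h) == 0L) NULL else
      data.frame(query_id = id, reference_id = h$reference_id[1L],
                 identity = h$identity[1L],
                 aligned_length = h$aligned_length[1L],
                 coverage = h$coverage[1L], stringsAsFactors = FALSE)
    as.data.frame(type_endemism(id, flock_calls, bh, tree, reference_ids,
                                params, identity_ceiling),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
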