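# Pairwise alignment and identity, nearest-reference search with hit
# filters, and the divergence-band / abundance-class classifiers.

#' Hit filter thresholds for nearest-reference search
#'
#' Defaults follow the standard practice for V4 amplicon best-hit filtering:
#' query coverage > 70%, aligned span of at least 200 bp. The e-value filter
#' is off by default — Karlin–Altschul statistics are meaningless against the
#' small curated reference sets this pipeline searches; supply `max_evalue`
#' (and an `evalue` column on externally computed hits) to enable it.
#'
#' @param min_coverage Minimum query coverage (fraction), exclusive bound.
#' @param min_aligned_length Minimum number of aligned residue pairs
#'   (columns with a residue in both sequences), inclusive.
#' @param max_evalue Optional e-value ceiling, used only when hits carry an
#'   e-value; `NULL` disables the filter.
#' @return A list of class `hit_filter`.
#' @export
hit_filter <- function(min_coverage = 0.70, min_aligned_length = 200L,
                       max_evalue = NULL) {
  stopifnot(min_coverage > 0, min_coverage <= 1, min_aligned_length > 0)
  structure(list(min_coverage = min_coverage,
                 min_aligned_length = as.integer(min_aligned_length),
                 max_evalue = max_evalue),
            class = "hit_filter")
}

#' Divergence-band and abundance-class thresholds
#'
#' @param similar_max_divergence OTUs within this divergence of a known
#'   sequence are "similar" (default 1%).
#' @param unclear_max_divergence Upper bound of the "unclear distribution"
#'   band (default 10%); beyond it an OTU is a potential endemic.
#' @param type2_identity_ceiling Identity below which an OTU qualifies as a
#'   Type 2 endemic (default 90%).
#' @param band_lo Lower edge of the reported 80–90% identity band.
#' @param abundant_min_fraction Read fraction above which an OTU is
#'   "abundant" (default 1%).
#' @param rare_max_fraction Read fraction below which an OTU is "rare"
#'   (default 0.01%).
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(similar_max_divergence = 0.01,
                            unclear_max_divergence = 0.10,
                            type2_identity_ceiling = 0.90,
                            band_lo = 0.80,
                            abundant_min_fraction = 0.01,
                            rare_max_fraction = 0.0001) {
  stopifnot(similar_max_divergence > 0,
            similar_max_divergence < unclear_max_divergence,
            unclear_max_divergence < 1,
            band_lo < type2_identity_ceiling)
  structure(list(similar_max_divergence = similar_max_divergence,
                 unclear_max_divergence = unclear_max_divergence,
                 type2_identity_ceiling = type2_identity_ceiling,
                 band_lo = band_lo,
                 abundant_min_fraction = abundant_min_fraction,
                 rare_max_fraction = rare_max_fraction),
            class = "classify_params")
}

#' Align two sequences and report identity statistics
#'
#' Needleman–Wunsch global alignment (via
#' [Biostrings::pairwiseAlignment()]); identity, aligned length and
#' coverage are computed on the end-gap-trimmed span — the columns between
#' the first and last position where both sequences carry a residue —
#' mirroring how BLAST reports a hit. `type = "overlap"` switches to free
#' end-gap scoring for genuinely partial queries.
#'
#' Conventions fixed for reproducibility: the identity denominator is every
#' span column (internal gaps count against identity), and `N` never counts
#' as a match.
#'
#' @param query,subject Sequences: single strings, length-1 named vectors or
#'   `DNAString`-like objects.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (positive penalties for the gap terms).
#' @param type `"global"` (default) or `"overlap"`.
#' @return Object of class `pairwise_alignment`: list with `gapped_query`,
#'   `gapped_subject` (full-length, including end gaps), `matches`,
#'   `aligned_columns` (span columns), `aligned_pairs` (columns with a
#'   residue in both sequences), `identity`, `query_coverage`,
#'   `subject_coverage`.
#' @examples
#' align_pair("AAAA", "AAAT")$identity  # 0.75
#' @export
align_pair <- function(query, subject,
                       scoring = list(match = 2, mismatch = -3,
                                      gap_open = 5, gap_extend = 2),
                       type = c("global", "overlap")) {
  type <- match.arg(type)
  q <- unname(as.character(query)[1L]); s <- unname(as.character(subject)[1L])
  .align_batch(q, s, scoring, type)[[1L]]
}

# Vectorized core: align many queries against one subject in a single
# pairwiseAlignment call; returns a list of pairwise_alignment objects.
.align_batch <- function(queries, subject,
                         scoring = list(match = 2, mismatch = -3,
                                        gap_open = 5, gap_extend = 2),
                         type = "global") {
  queries <- as.character(queries)
  s <- as.character(subject)[1L]
  if (any(is.na(queries) | nchar(queries) == 0L)) stop("empty query sequence")
  if (is.na(s) || nchar(s) == 0L) stop("empty subject sequence")
  submat <- .align_submat(scoring$match, scoring$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), s, type = type,
    substitutionMatrix = submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  lapply(seq_along(queries), function(i) {
    if (type == "global") {
      # global alignments already cover both sequences end to end
      return(alignment_stats(ap[i], as_[i]))
    }
    q <- queries[i]
    # overlap type clips overhangs: restore them as end gaps so the gapped
    # strings are total over both sequences
    pre_q <- substr(q, 1L, qs[i] - 1L); post_q <- substr(q, qe[i] + 1L, nchar(q))
    pre_s <- substr(s, 1L, ss[i] - 1L); post_s <- substr(s, se[i] + 1L, nchar(s))
    gq <- paste0(pre_q, strrep("-", nchar(pre_s)), ap[i],
                 post_q, strrep("-", nchar(post_s)))
    gs <- paste0(strrep("-", nchar(pre_q)), pre_s, as_[i],
                 strrep("-", nchar(post_q)), post_s)
    alignment_stats(gq, gs)
  })
}

.align_submat <- function(match, mismatch) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch  # N is never a match
  m
}

#' Statistics of a pre-computed gapped sequence pair
#'
#' Builds a `pairwise_alignment` from two equal-length gapped strings — the
#' route used when alignments come from an external tool.
#'
#' @param gapped_query,gapped_subject Equal-length strings over
#'   `{A,C,G,T,N,-}`.
#' @return A `pairwise_alignment` (see [align_pair()]).
#' @export
alignment_stats <- function(gapped_query, gapped_subject) {
  if (nchar(gapped_query) != nchar(gapped_subject))
    stop("gapped strings must have equal length")
  qc <- strsplit(gapped_query, "", fixed = TRUE)[[1L]]
  sc <- strsplit(gapped_subject, "", fixed = TRUE)[[1L]]
  both <- qc != "-" & sc != "-"
  if (!any(both)) stop("alignment has no column with both residues")
  span <- min(which(both)):max(which(both))
  qs <- qc[span]; ssp <- sc[span]
  matches <- sum(qs == ssp & qs != "-" & qs != "N")
  cols <- length(span)
  structure(list(
    gapped_query = gapped_query,
    gapped_subject = gapped_subject,
    matches = matches,
    aligned_columns = cols,
    aligned_pairs = sum(both),
    identity = matches / cols,
    query_coverage = sum(qs != "-") / sum(qc != "-"),
    subject_coverage = sum(ssp != "-") / sum(sc != "-")),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment: ", x$matches, "/", x$aligned_columns,
      " matches (identity ", format(round(x$identity, 4)), ")\n", sep = "")
  invisible(x)
}

#' Fraction of identical columns in an alignment
#'
#' `matches / aligned_columns` over the end-gap-trimmed span; divergence is
#' `1 - identity`.
#' @param alignment A `pairwise_alignment`.
#' @return Identity fraction in \[0,1\].
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  alignment$matches / alignment$aligned_columns
}

#' Ungapped p-distance between two equal-length sequences
#'
#' Fast path for gap-free pairs (the synthetic world has no indels):
#' proportion of differing positions; a position with `N` in either sequence
#' counts as a difference.
#' @param a,b Equal-length residue strings.
#' @return p-distance in \[0,1\].
#' @export
p_distance <- function(a, b) {
  a <- as.character(a)[1L]; b <- as.character(b)[1L]
  if (nchar(a) != nchar(b)) stop("p_distance requires equal-length sequences")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(av != bv | av == "N" | bv == "N")
}

#' Best reference hit for a query under the hit filters
#'
#' Aligns the query to every reference, applies the filter (query coverage,
#' aligned span length, optional e-value) and returns the best passing hit:
#' highest identity, ties broken by longer aligned span then lexicographic
#' reference id.
#'
#' @param query Single named sequence (name used as `query_id`).
#' @param references Named sequence collection (`DNAStringSet` or named
#'   character vector); must be non-empty.
#' @param filter A [hit_filter()].
#' @param scoring Alignment scoring, see [align_pair()].
#' @return One-row `data.frame` (`query_id`, `reference_id`, `identity`,
#'   `aligned_length`, `coverage`, `passed_filters`) or `NULL` when no hit
#'   passes.
#' @export
best_reference_hit <- function(query, references, filter = hit_filter(),
                               scoring = list(match = 2, mismatch = -3,
                                              gap_open = 5, gap_extend = 2)) {
  if (length(references) == 0L) stop("empty reference set")
  refs <- as_sequences(references)
  qid <- names(as_sequences(if (is.null(names(query))) stats::setNames(as.character(query)[1L], "query") else query))[1L]
  qseq <- as.character(query)[1L]
  hits <- lapply(seq_along(refs), function(i) {
    al <- align_pair(qseq, refs[[i]], scoring = scoring)
    data.frame(query_id = qid, reference_id = names(refs)[i],
               identity = al$identity,
               aligned_length = al$aligned_pairs,
               coverage = al$query_coverage,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits$passed_filters <- hits$coverage > filter$min_coverage &
    hits$aligned_length >= filter$min_aligned_length
  ok <- hits[hits$passed_filters, , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  ord <- order(-ok$identity, -ok$aligned_length, ok$reference_id)
  ok[ord[1L], , drop = FALSE]
}

#' Classify an OTU's distribution status from its divergence to references
#'
#' Divergence to the nearest known sequence maps to one of three bands:
#' `similar` (<= 1%), `unclear` (<= 10%; widespread or endemic, cannot be
#' told apart), `potential_endemic` (> 10% from every known sequence).
#' Both upper bounds are inclusive.
#'
#' @param divergence Numeric vector of divergences (1 - identity) in \[0,1\];
#'   `NA` (no passing hit) maps to `potential_endemic`.
#' @param params [classify_params()].
#' @return Character vector over
#'   `{"similar","unclear","potential_endemic"}`.
#' @export
classify_distribution_status <- function(divergence, params = classify_params()) {
  if (any(!is.na(divergence) & (divergence < 0 | divergence > 1)))
    stop("divergence must be in [0,1]")
  out <- ifelse(is.na(divergence), "potential_endemic",
         ifelse(divergence <= params$similar_max_divergence, "similar",
         ifelse(divergence <= params$unclear_max_divergence, "unclear",
                "potential_endemic")))
  out
}

#' Membership in the 80-90% identity band
#'
#' Half-open band: `0.80 <= identity < 0.90`; the upper edge is exclusive so
#' band membership is consistent with the strict `< 90%` Type 2 endemism
#' ceiling.
#' @param identity Numeric vector of identities.
#' @param params [classify_params()].
#' @return Logical vector.
#' @export
in_band_80_90 <- function(identity, params = classify_params()) {
  !is.na(identity) &
    identity >= params$band_lo & identity < params$type2_identity_ceiling
}

#' Abundance class of an OTU
#'
#' `abundant` when the OTU carries more than 1% of all reads, `rare` below
#' 0.01%, `intermediate` otherwise; both boundaries are inclusive to
#' `intermediate`.
#' @param otu_reads Integer vector of per-OTU read totals.
#' @param total_reads Total reads in the dataset.
#' @param params [classify_params()].
#' @return Character vector over `{"abundant","intermediate","rare"}`.
#' @export
classify_abundance <- function(otu_reads, total_reads,
                               params = classify_params()) {
  if (total_reads <= 0) stop("total_reads must be positive")
  f <- otu_reads / total_reads
  ifelse(f > params$abundant_min_fraction, "abundant",
  ifelse(f < params$rare_max_fraction, "rare", "intermediate"))
}

#' Classify every focal OTU against a reference set
#'
#' Convenience wrapper producing the per-OTU hit report: best passing hit,
#' distribution status, 80-90% band membership and abundance class.
#'
#' @param focal Named focal sequences.
#' @param references Named reference sequences.
#' @param counts Optional `community_matrix` or named per-OTU read totals
#'   (enables the abundance class column).
#' @param filter [hit_filter()].
#' @param params [classify_params()].
#' @return `data.frame` with one row per focal OTU: `otu_id`,
#'   `reference_id`, `identity`, `divergence`, `aligned_length`, `coverage`,
#'   `passed`, `status`, `band_80_90`, and `abundance_class` when counts are
#'   given.
#' @export
classify_otus <- function(focal, references, counts = NULL,
                          filter = hit_filter(), params = classify_params()) {
  fseq <- as_sequences(focal)
  refs <- as_sequences(references)
  if (length(refs) == 0L) stop("empty reference set")
  # one vectorized alignment call per reference (same stats and tie-breaks
  # as best_reference_hit; equivalence is under test)
  per_ref <- lapply(names(refs), function(rid) {
    als <- .align_batch(unname(fseq), refs[[rid]])
    data.frame(otu_id = names(fseq), reference_id = rid,
               identity = vapply(als, `[[`, numeric(1L), "identity"),
               aligned_length = vapply(als, `[[`, numeric(1L),
                                       "aligned_pairs"),
               coverage = vapply(als, `[[`, numeric(1L), "query_coverage"),
               stringsAsFactors = FALSE)
  })
  all_hits <- do.call(rbind, per_ref)
  all_hits$passed <- all_hits$coverage > filter$min_coverage &
    all_hits$aligned_length >= filter$min_aligned_length
  rows <- lapply(names(fseq), function(id) {
    ok <- all_hits[all_hits$otu_id == id & all_hits$passed, , drop = FALSE]
    if (nrow(ok) == 0L) {
      data.frame(otu_id = id, reference_id = NA_character_,
                 identity = NA_real_, aligned_length = NA_integer_,
                 coverage = NA_real_, passed = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      best <- ok[order(-ok$identity, -ok$aligned_length, ok$reference_id)[1L], ]
      data.frame(otu_id = id, reference_id = best$reference_id,
                 identity = best$identity,
                 aligned_length = best$aligned_length,
                 coverage = best$coverage, passed = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  rep_tab <- do.call(rbind, rows)
  rep_tab$divergence <- 1 - rep_tab$identity
  rep_tab$status <- classify_distribution_status(rep_tab$divergence, params)
  rep_tab$band_80_90 <- in_band_80_90(rep_tab$identity, params)
  if (!is.null(counts)) {
    totals <- if (inherits(counts, "community_matrix")) otu_totals(counts) else counts
    reads <- totals[rep_tab$otu_id]
    reads[is.na(reads)] <- 0L
    rep_tab$total_reads <- as.integer(reads)
    rep_tab$abundance_class <- classify_abundance(reads, sum(totals), params)
  }
  rep_tab
}
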