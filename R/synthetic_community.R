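# Synthetic post-clustering communities with planted ground truth:
# star-radiation flocks at controlled divergence, endemics placed > 10%
# from every reference, dominant-plus-satellite intragenomic clouds, and a
# lognormal/Dirichlet/multinomial count model at realistic read depths.

#' Draw a random DNA sequence
#' @param length Sequence length (default 380, the typical V4 amplicon).
#' @return A residue string.
#' @export
random_sequence <- function(length = 380L) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Mutate a sequence by an exact number of substitutions
#'
#' Positions are drawn without replacement and each substituted base differs
#' from the original, so the p-distance between ancestor and result is
#' exactly `substitutions / length` — divergences are exact by construction,
#' not in expectation.
#'
#' @param ancestor Residue string.
#' @param substitutions Number of substitutions, `<= nchar(ancestor)`.
#' @param seed Optional RNG seed; when `NULL` the current RNG stream is used.
#' @return The mutated residue string.
#' @export
evolve_sequence <- function(ancestor, substitutions, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ancestor <- as.character(ancestor)[1L]
  n <- nchar(ancestor)
  substitutions <- as.integer(substitutions)
  if (substitutions < 0L) stop("substitutions must be >= 0")
  if (substitutions > n)
    stop("substitutions (", substitutions, ") exceeds sequence length (", n, ")")
  if (substitutions == 0L) return(ancestor)
  chars <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  pos <- sample.int(n, substitutions)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Plant a species flock as a star radiation
#'
#' Each tip receives roughly `target_divergence / 2` of its length in
#' substitutions from the common ancestor, so the mean pairwise p-distance
#' across tips lands near `target_divergence` (within about 20% relative,
#' the slack coming from substitutions hitting shared positions). Tips are
#' guaranteed mutually distinct.
#'
#' @param ancestor Residue string (the flock's common ancestor).
#' @param n_tips Number of flock members, at least 3 by definition.
#' @param target_divergence Intended mean pairwise p-distance, in (0, 0.5).
#' @param seed Optional RNG seed.
#' @param prefix Tip id prefix.
#' @return List with `sequences` (named character), `ancestor`,
#'   `target_divergence`.
#' @export
plant_flock <- function(ancestor, n_tips, target_divergence, seed = NULL,
                        prefix = "FLK") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_tips <- as.integer(n_tips)
  if (n_tips < 3L) stop("a flock needs at least 3 members (n_tips >= 3)")
  if (target_divergence <= 0 || target_divergence >= 0.5)
    stop("target_divergence must be in (0, 0.5)")
  len <- nchar(ancestor)
  k <- round(target_divergence / 2 * len)
  if (k < 1L)
    stop("target_divergence too small for sequence length: tips would be identical")
  for (attempt in 1:25) {
    seqs <- vapply(seq_len(n_tips),
                   function(i) evolve_sequence(ancestor, k), character(1L))
    if (!anyDuplicated(seqs)) {
      names(seqs) <- sprintf("%s_%02d", prefix, seq_len(n_tips))
      return(list(sequences = seqs, ancestor = ancestor,
                  target_divergence = target_divergence))
    }
  }
  stop("could not generate mutually distinct flock tips")
}

#' Plant an intragenomic-variant cloud
#'
#' One dominant sequence plus `n_satellites` satellites whose identity to
#' the dominant falls inside `identity_range`, with the dominant carrying
#' exactly `dominant_reads` reads and every satellite strictly fewer than
#' `satellite_read_cap` — the abundance signature of divergent rRNA gene
#' copies of a single abundant organism.
#'
#' @param dominant Residue string of the dominant variant.
#' @param n_satellites Number of satellite variants (0 allowed).
#' @param identity_range Length-2 fractions `c(lo, hi)` within (0,1),
#'   `lo <= hi`.
#' @param dominant_reads Total reads assigned to the dominant.
#' @param satellite_read_cap Exclusive upper bound on satellite reads.
#' @param seed Optional RNG seed.
#' @param prefix Id prefix.
#' @return List with `sequences` (dominant first), `reads` (named integer),
#'   `dominant_id`, `satellite_ids`, `identity_range`.
#' @export
plant_cloud <- function(dominant, n_satellites, identity_range = c(0.95, 0.99),
                        dominant_reads, satellite_read_cap = 100L,
                        seed = NULL, prefix = "CLD") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length(identity_range) != 2L || any(identity_range <= 0) ||
      any(identity_range >= 1) || identity_range[1L] > identity_range[2L])
    stop("identity_range must be c(lo, hi) with 0 < lo <= hi < 1")
  n_satellites <- as.integer(n_satellites)
  len <- nchar(dominant)
  dom_id <- paste0(prefix, "_DOM")
  sat_ids <- if (n_satellites > 0L)
    sprintf("%s_S%03d", prefix, seq_len(n_satellites)) else character(0L)
  sats <- character(n_satellites)
  for (i in seq_len(n_satellites)) {
    ident <- stats::runif(1L, identity_range[1L], identity_range[2L])
    k <- max(1L, round((1 - ident) * len))
    # keep realized identity inside the declared range
    k <- min(k, max(1L, floor((1 - identity_range[1L]) * len)))
    sats[i] <- evolve_sequence(dominant, k)
  }
  reads <- c(as.integer(dominant_reads),
             if (n_satellites > 0L)
               sample.int(max(1L, satellite_read_cap - 1L), n_satellites,
                          replace = TRUE) else integer(0L))
  seqs <- c(stats::setNames(dominant, dom_id), stats::setNames(sats, sat_ids))
  names(reads) <- names(seqs)
  list(sequences = seqs, reads = reads, dominant_id = dom_id,
       satellite_ids = sat_ids, identity_range = identity_range)
}

#' Configuration of the synthetic-community generator
#'
#' Defaults state the world the pipeline is built for: ~380 bp V4-like
#' amplicons, per-sample depths uniform on 47,195–142,260 reads, 23 samples
#' across three basins, lognormal relative abundances with a per-sample
#' Dirichlet perturbation whose concentration is higher for deep samples
#' (so 25–50 m communities cluster), star-radiation flocks at 2% divergence,
#' one dominant-plus-satellite cloud, and endemics planted 12–18% away from
#' their nearest reference.
#'
#' @param n_references Number of reference sequences.
#' @param n_background_otus Background focal OTUs, each within 10% of a
#'   reference.
#' @param flocks List of `list(n_tips=, target_divergence=)`.
#' @param clouds List of `list(n_satellites=, identity_range=,
#'   dominant_reads=)`.
#' @param endemic_otus `list(n=, distance_range=)`; `distance_range[1]` must
#'   exceed 0.10 or the config is infeasible.
#' @param n_samples Number of samples.
#' @param depth_range Per-sample read depth range (uniform draw).
#' @param abundance_model `list(meanlog=, sdlog=)` of the lognormal
#'   relative-abundance law.
#' @param seq_length Amplicon length in bp.
#' @param seed Master RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_references = 8L,
                             n_background_otus = 20L,
                             flocks = list(list(n_tips = 5L, target_divergence = 0.02),
                                           list(n_tips = 4L, target_divergence = 0.02)),
                             clouds = list(list(n_satellites = 5L,
                                                identity_range = c(0.95, 0.99),
                                                dominant_reads = 30958L)),
                             endemic_otus = list(n = 3L,
                                                 distance_range = c(0.12, 0.18)),
                             n_samples = 23L,
                             depth_range = c(47195L, 142260L),
                             abundance_model = list(meanlog = 0, sdlog = 1.5),
                             seq_length = 380L,
                             seed = 1L) {
  flocks <- lapply(flocks, function(f) {
    if (f$n_tips < 3L) stop("every flock needs n_tips >= 3")
    if (f$target_divergence <= 0 || f$target_divergence >= 0.5)
      stop("flock target_divergence must be in (0, 0.5)")
    f
  })
  if (depth_range[1L] < 1L) stop("depth_range minimum must be >= 1")
  if (length(endemic_otus$distance_range) != 2L)
    stop("endemic distance_range must be c(lo, hi)")
  structure(list(n_references = as.integer(n_references),
                 n_background_otus = as.integer(n_background_otus),
                 flocks = flocks, clouds = clouds,
                 endemic_otus = endemic_otus,
                 n_samples = as.integer(n_samples),
                 depth_range = as.integer(depth_range),
                 abundance_model = abundance_model,
                 seq_length = as.integer(seq_length),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Emits focal and reference sequences, a sample-by-OTU count matrix, the
#' gap-free alignment used to build tree fixtures, and per-OTU truth labels.
#' Contracts enforced before return: every planted endemic is > 10% p-distance
#' from every reference; every background OTU has a nearest reference within
#' 10%; per-sample totals equal the drawn depths exactly.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_dataset` with elements `focal`,
#'   `references` (named character vectors), `counts` (`community_matrix`),
#'   `truth` (list: per-OTU `table`, `flocks`, `clouds`, `endemic_ids`),
#'   `alignment` (named character; focal then references) and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$endemic_otus$n > 0L &&
      config$endemic_otus$distance_range[1L] <= 0.10)
    stop("infeasible config: endemic distance_range overlaps the ",
         "10% reference radius")
  set.seed(config$seed)
  len <- config$seq_length

  refs <- vapply(seq_len(config$n_references),
                 function(i) random_sequence(len), character(1L))
  names(refs) <- sprintf("REF_%02d", seq_len(config$n_references))
  # dedicated distant outgroup for rooting: isolated, so its attachment is
  # unstable across bootstrap replicates and near-root clades stay
  # unsupported (mirrors standard outgroup-rooting practice)
  refs <- c(refs, REF_OUT = random_sequence(len))

  truth_rows <- list()
  focal <- character(0L)
  weights <- numeric(0L)
  lgn <- function(n) stats::rlnorm(n, config$abundance_model$meanlog,
                                   config$abundance_model$sdlog)

  # background OTUs: each evolved from a reference, within the 10% radius
  if (config$n_background_otus > 0L) {
    ids <- sprintf("OTU_B%02d", seq_len(config$n_background_otus))
    for (i in seq_len(config$n_background_otus)) {
      src <- sample.int(config$n_references, 1L)
      # floor of 3%: background OTUs are known taxa of unremarkable
      # divergence and must not mimic the flock criterion by construction
      d <- stats::runif(1L, 0.03, 0.09)
      s <- evolve_sequence(refs[[src]], round(d * len))
      focal[ids[i]] <- s
      truth_rows[[ids[i]]] <- data.frame(otu_id = ids[i], flock_id = NA_character_,
                                         endemic = FALSE, cloud_id = NA_character_,
                                         dominant = FALSE, stringsAsFactors = FALSE)
    }
    weights <- c(weights, stats::setNames(lgn(length(ids)), ids))
  }

  # flocks: star radiations from ancestors far from everything else
  flock_truth <- list()
  for (fi in seq_along(config$flocks)) {
    f <- config$flocks[[fi]]
    fid <- sprintf("flock%d", fi)
    pf <- plant_flock(random_sequence(len), f$n_tips, f$target_divergence,
                      prefix = sprintf("OTU_F%d", fi))
    focal[names(pf$sequences)] <- pf$sequences
    for (id in names(pf$sequences))
      truth_rows[[id]] <- data.frame(otu_id = id, flock_id = fid,
                                     endemic = TRUE, cloud_id = NA_character_,
                                     dominant = FALSE, stringsAsFactors = FALSE)
    # members of one radiation share a base abundance with modest spread:
    # comparable abundances are part of what "planting a flock" means
    base <- lgn(1L)
    weights <- c(weights, stats::setNames(
      base * stats::rlnorm(f$n_tips, 0, 0.4), names(pf$sequences)))
    flock_truth[[fid]] <- list(member_ids = names(pf$sequences),
                               target_divergence = f$target_divergence)
  }

  # intragenomic clouds: dominant identical to a fresh reference-like
  # organism that IS in the reference set (known abundant species)
  cloud_truth <- list()
  expected_total <- config$n_samples * mean(config$depth_range)
  for (ci in seq_along(config$clouds)) {
    cl <- config$clouds[[ci]]
    cid <- sprintf("cloud%d", ci)
    ref_id <- sprintf("REF_C%d", ci)
    dom_seq <- random_sequence(len)
    refs[ref_id] <- dom_seq
    pc <- plant_cloud(dom_seq, cl$n_satellites, cl$identity_range,
                      dominant_reads = cl$dominant_reads,
                      prefix = sprintf("OTU_C%d", ci))
    focal[names(pc$sequences)] <- pc$sequences
    for (id in names(pc$sequences))
      truth_rows[[id]] <- data.frame(otu_id = id, flock_id = NA_character_,
                                     endemic = FALSE, cloud_id = cid,
                                     dominant = id == pc$dominant_id,
                                     stringsAsFactors = FALSE)
    # weights chosen so expected totals realize the dominant/satellite gap
    base_total <- if (sum(weights) > 0) sum(weights) else 1
    p_dom <- min(cl$dominant_reads / expected_total, 0.9)
    w_dom <- p_dom / (1 - p_dom) * base_total
    w_sat <- rep(20 / expected_total * base_total, cl$n_satellites)
    weights <- c(weights,
                 stats::setNames(c(w_dom, w_sat), names(pc$sequences)))
    cloud_truth[[cid]] <- list(dominant_id = pc$dominant_id,
                               satellite_ids = pc$satellite_ids,
                               identity_range = cl$identity_range)
  }

  # endemics: evolved from a reference at > 10% distance
  endemic_ids <- character(0L)
  if (config$endemic_otus$n > 0L) {
    endemic_ids <- sprintf("OTU_E%02d", seq_len(config$endemic_otus$n))
    dr <- config$endemic_otus$distance_range
    for (i in seq_along(endemic_ids)) {
      src <- sample.int(config$n_references, 1L)
      d <- stats::runif(1L, dr[1L], dr[2L])
      focal[endemic_ids[i]] <- evolve_sequence(refs[[src]], round(d * len))
      truth_rows[[endemic_ids[i]]] <-
        data.frame(otu_id = endemic_ids[i], flock_id = NA_character_,
                   endemic = TRUE, cloud_id = NA_character_,
                   dominant = FALSE, stringsAsFactors = FALSE)
    }
    weights <- c(weights, stats::setNames(lgn(length(endemic_ids)), endemic_ids))
  }

  # contract checks (brute-force p-distance scans)
  for (id in endemic_ids) {
    dmin <- min(vapply(refs, function(r) p_distance(focal[[id]], r), numeric(1L)))
    if (dmin <= 0.10)
      stop("planted endemic ", id, " is within 10% of a reference (", dmin, ")")
  }
  if (config$n_background_otus > 0L) {
    for (id in grep("^OTU_B", names(focal), value = TRUE)) {
      dmin <- min(vapply(refs, function(r) p_distance(focal[[id]], r), numeric(1L)))
      if (dmin > 0.10)
        stop("background OTU ", id, " has no reference within 10% (", dmin, ")")
    }
  }

  weights <- weights[names(focal)]

  # sample design: three basins, a few coastal sites, depths 1/15/25/50 m
  depth_cycle <- c(1, 15, 50, 25, 5)
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(config$n_samples)),
    basin = rep(c("S", "C", "N"), length.out = config$n_samples),
    depth_m = rep(depth_cycle, length.out = config$n_samples),
    stringsAsFactors = FALSE)
  meta$site_class <- ifelse(meta$depth_m == 5, "coastal", "deep")

  depths <- sample(seq(config$depth_range[1L], config$depth_range[2L]),
                   config$n_samples, replace = TRUE)
  counts <- matrix(0L, config$n_samples, length(focal),
                   dimnames = list(meta$sample_id, names(focal)))
  for (s in seq_len(config$n_samples)) {
    conc <- if (meta$depth_m[s] >= 25) 400 else 60  # deep samples cluster
    alpha <- weights / sum(weights) * conc
    rel <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(rel) == 0) rel <- weights
    counts[s, ] <- as.integer(stats::rmultinom(1L, depths[s], rel / sum(rel)))
  }
  cm <- suppressWarnings(community_matrix(counts, meta))

  truth_table <- do.call(rbind, truth_rows[names(focal)])
  rownames(truth_table) <- NULL
  structure(list(
    focal = focal,
    references = refs,
    counts = cm,
    truth = list(table = truth_table, flocks = flock_truth,
                 clouds = cloud_truth, endemic_ids = endemic_ids),
    alignment = c(focal, refs),
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", length(x$focal), " focal OTUs, ",
      length(x$references), " references, ",
      nrow(x$counts$counts), " samples\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `focal.fasta`, `references.fasta`, `counts.tsv`, `truth.json` and
#' `alignment.fasta`. Byte-identical for identical config + seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(dataset$focal, file.path(dir, "focal.fasta"))
  write_fasta(dataset$references, file.path(dir, "references.fasta"))
  write_fasta(dataset$alignment, file.path(dir, "alignment.fasta"))
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  jsonlite::write_json(
    list(table = dataset$truth$table,
         flocks = dataset$truth$flocks,
         clouds = dataset$truth$clouds,
         endemic_ids = dataset$truth$endemic_ids,
         seed = dataset$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
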