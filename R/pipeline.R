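# Orchestration: run the full analysis from a config to a bundle of TSV
# reports plus a JSON manifest, and summarize report bundles into the
# headline counts.

#' Integer percentage, rounded half-up
#'
#' Summary percentages are rounded half-up to integers (`7.5% -> 8%`),
#' matching the usual reporting style ("about 7%", "16%"), not banker's
#' rounding.
#' @param count Numerator.
#' @param total Denominator (> 0).
#' @return Integer percent.
#' @export
percent_int <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  as.integer(floor(100 * count / total + 0.5))
}

#' Run the full pipeline
#'
#' Stage order: `simulate` (only when the config carries a generator) →
#' `classify` → `clades`/`flocks` → `endemism` → `stats`. Every stage
#' writes a TSV report under `config$out_dir`, and a `manifest.json`
#' records the config, seed, input digests, per-stage record counts and
#' package version. Identical config + seed give identical reports.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages to run (default: all that the
#'   config's inputs support).
#' @return Invisible list with the in-memory reports (`classify`, `flocks`,
#'   `endemism`, `stats`, `summary`) and the manifest.
#' @export
run_all <- function(config,
                    stages = c("classify", "flocks", "endemism", "stats")) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("otuflock")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = list(), inputs = list())
  ran <- character(0L)

  fail <- function(stage, msg) stop("stage ", stage, ": ", msg, call. = FALSE)

  if (!is.null(config$generator)) {
    sim_dir <- file.path(out_dir, "simulated")
    ds <- generate_dataset(config$generator)
    write_dataset(ds, sim_dir)
    config$focal_fasta <- file.path(sim_dir, "focal.fasta")
    config$reference_fasta <- file.path(sim_dir, "references.fasta")
    config$count_table <- file.path(sim_dir, "counts.tsv")
    manifest$stages$simulate <- list(n_focal = length(ds$focal),
                                     n_references = length(ds$references))
    ran <- c(ran, "simulate")
    if (is.na(config$tree) && any(c("flocks", "endemism") %in% stages)) {
      og <- if ("REF_OUT" %in% names(ds$references)) "REF_OUT"
            else names(ds$references)[1L]
      tr <- bootstrap_supports(ds$alignment, n_reps = 100L,
                               seed = config$seed + 101L, outgroup = og)
      config$tree <- file.path(sim_dir, "tree.nwk")
      write_newick(tr, config$tree)
    }
  }

  need_input <- function(stage, path, what) {
    if (is.na(path) || !file.exists(path))
      fail(stage, paste0("missing input '", what, "'",
                         if (!is.na(path)) paste0(" (", path, ")")))
  }

  need_input("classify", config$focal_fasta, "focal_fasta")
  need_input("classify", config$reference_fasta, "reference_fasta")
  focal <- read_fasta(config$focal_fasta, role = "focal")
  refs <- read_fasta(config$reference_fasta, role = "reference")
  counts <- NULL
  if (!is.na(config$count_table)) {
    need_input("classify", config$count_table, "count_table")
    counts <- suppressWarnings(read_count_table(config$count_table))
  }
  for (nm in c("focal_fasta", "reference_fasta", "count_table", "tree")) {
    p <- config[[nm]]
    if (!is.na(p) && file.exists(p))
      manifest$inputs[[nm]] <- list(path = p,
                                    md5 = unname(tools::md5sum(p)))
  }

  reports <- list()
  if ("classify" %in% stages) {
    reports$classify <- classify_otus(focal, refs, counts,
                                      filter = config$filter,
                                      params = config$classify)
    .write_report(reports$classify, file.path(out_dir, "classify.tsv"))
    manifest$stages$classify <- list(n_records = nrow(reports$classify))
    ran <- c(ran, "classify")
  }

  tree <- NULL
  if (any(c("flocks", "endemism") %in% stages)) {
    need_input("flocks", config$tree, "tree")
    tree <- read_newick(config$tree)
  }

  if ("flocks" %in% stages) {
    if (is.null(counts)) fail("flocks", "missing input 'count_table'")
    reports$flocks <- detect_flocks(tree, names(focal),
                                    sequences = focal, counts = counts,
                                    params = config$flock)
    .write_report(reports$flocks[, setdiff(names(reports$flocks),
                                           c("member_ids", "abundance_ids"))],
                  file.path(out_dir, "flocks.tsv"))
    manifest$stages$flocks <- list(n_records = nrow(reports$flocks))
    ran <- c(ran, "flocks")
  }

  if ("endemism" %in% stages) {
    if (is.null(reports$flocks)) fail("endemism", "flocks stage did not run")
    if (is.null(reports$classify)) fail("endemism", "classify stage did not run")
    reports$endemism <- endemism_table(names(focal), reports$flocks,
                                       reports$classify, tree, names(refs),
                                       params = config$flock,
                                       identity_ceiling =
                                         config$classify$type2_identity_ceiling)
    .write_report(reports$endemism, file.path(out_dir, "endemism.tsv"))
    manifest$stages$endemism <- list(n_records = nrow(reports$endemism))
    ran <- c(ran, "endemism")
  }

  if ("stats" %in% stages) {
    if (is.null(counts)) fail("stats", "missing input 'count_table'")
    rare <- suppressWarnings(rarefy_counts(counts, depth = "min",
                                           seed = config$seed + 202L))
    bc <- bray_curtis(rare)
    rich <- data.frame(sample_id = rownames(counts$counts),
                       richness = unname(richness(counts)),
                       richness_rarefied =
                         unname(richness(rare))[match(rownames(counts$counts),
                                                      rownames(rare$counts))])
    groups <- stats::setNames(counts$sample_meta$basin,
                              counts$sample_meta$sample_id)
    venn <- if (all(!is.na(groups))) shared_otus(counts, groups) else NULL
    .write_report(as.data.frame(bc) , file.path(out_dir, "bray_curtis.tsv"),
                  rownames = TRUE)
    .write_report(rich, file.path(out_dir, "richness.tsv"))
    if (!is.null(venn)) .write_report(venn, file.path(out_dir, "venn.tsv"))
    reports$stats <- list(bray_curtis = bc, richness = rich, venn = venn,
                          rarefied = rare)
    manifest$stages$stats <- list(n_samples = nrow(rare$counts),
                                  rarefaction_depth =
                                    unname(sample_depths(rare)[1L]))
    ran <- c(ran, "stats")
  }

  reports$summary <- summarize_reports(reports, n_focal = length(focal))
  jsonlite::write_json(reports$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$config <- .config_echo(config)
  manifest$stages_run <- ran
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(reports, list(manifest = manifest)))
}

.write_report <- function(df, path, rownames = FALSE) {
  if (rownames) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$classify <- unclass(cfg$classify)
  cfg$flock <- unclass(cfg$flock)
  cfg$filter <- unclass(cfg$filter)
  if (!is.null(cfg$generator)) cfg$generator <- unclass(cfg$generator)
  cfg
}

#' Headline summary of a report bundle
#'
#' Counts of OTUs by distribution status, 80-90% band, abundance class and
#' endemism type, the flock tally by label, and integer percentages
#' (half-up) against the total number of focal OTUs. Every count equals the
#' corresponding report's row-level tally.
#'
#' @param reports List with any of `classify`, `flocks`, `endemism` as
#'   produced by [run_all()].
#' @param n_focal Total number of focal OTUs (percent denominator).
#' @return Nested list of counts and percentages.
#' @export
summarize_reports <- function(reports, n_focal) {
  out <- list(n_focal_otus = n_focal)
  if (!is.null(reports$classify)) {
    cl <- reports$classify
    status <- table(factor(cl$status, levels = c("similar", "unclear",
                                                 "potential_endemic")))
    out$status_counts <- as.list(as.integer(status))
    names(out$status_counts) <- names(status)
    out$status_percent <- lapply(out$status_counts, percent_int,
                                 total = n_focal)
    out$band_80_90_count <- sum(cl$band_80_90, na.rm = TRUE)
    out$band_80_90_percent <- percent_int(out$band_80_90_count, n_focal)
    if (!is.null(cl$abundance_class)) {
      ab <- table(factor(cl$abundance_class,
                         levels = c("abundant", "intermediate", "rare")))
      out$abundance_counts <- as.list(as.integer(ab))
      names(out$abundance_counts) <- names(ab)
    }
  }
  if (!is.null(reports$flocks)) {
    fl <- reports$flocks
    lab <- table(factor(fl$label, levels = c("flock", "divergent_clade",
                                             "intragenomic_candidate",
                                             "rejected")))
    out$clade_counts <- as.list(as.integer(lab))
    names(out$clade_counts) <- names(lab)
    flock_members <- unique(unlist(fl$member_ids[fl$label == "flock"]))
    out$n_flock_otus <- length(flock_members)
    out$flock_otus_percent <- percent_int(out$n_flock_otus, n_focal)
  }
  if (!is.null(reports$endemism)) {
    en <- reports$endemism
    ty <- table(factor(en$type, levels = c("type1_flock", "type2_divergent",
                                           "type3_unplaced", "none")))
    out$endemism_counts <- as.list(as.integer(ty))
    names(out$endemism_counts) <- names(ty)
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `classify`, `clades`, `flocks`, `stats`,
#' `run-all`; common options `--config <path>`, `--out <dir>`,
#' `--seed <int>`, `--log-level <level>`. Invoked by the
#' `inst/cli/otuflock.R` wrapper script.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process's trailing arguments).
#' @return Integer exit status, invisibly (0 on success).
#' @export
otuflock_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: otuflock <simulate|classify|clades|flocks|stats|run-all> ",
           "--config cfg.json [--out dir] [--seed int]")
    cmd <- args[1L]
    opts <- .parse_cli_opts(args[-1L])
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
           else run_config()
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    switch(cmd,
      "simulate" = {
        if (is.null(cfg$generator)) cfg$generator <- generator_config()
        cfg$generator$seed <- cfg$seed
        ds <- generate_dataset(cfg$generator)
        write_dataset(ds, cfg$out_dir)
        message("simulate: wrote ", length(ds$focal), " focal OTUs to ",
                cfg$out_dir)
      },
      "classify" = run_all(cfg, stages = "classify"),
      "clades" = {
        tree <- read_newick(cfg$tree)
        focal <- read_fasta(cfg$focal_fasta, role = "focal")
        cl <- focal_clades(tree, names(focal), cfg$flock$min_support,
                           cfg$flock$min_focal)
        .write_report(cl[, c("node", "support", "n_tips", "n_focal")],
                      file.path(cfg$out_dir, "clades.tsv"))
      },
      "flocks" = run_all(cfg, stages = c("classify", "flocks", "endemism")),
      "stats" = run_all(cfg, stages = "stats"),
      "run-all" = run_all(cfg),
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    if (i + 1L > length(args)) stop("missing value for ", key)
    opts[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
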