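# Readers/writers for the external formats the pipeline touches:
# FASTA sequence sets, TSV count tables with sample metadata, Newick trees
# with numeric bootstrap labels, TSV taxonomy maps and the JSON run config.

#' Read a DNA FASTA file into a validated sequence set
#'
#' Parses a (wrapped or single-line) FASTA file and returns a
#' \link[Biostrings]{DNAStringSet}. Residues are upper-cased and U is mapped
#' to T so rRNA-style inputs compare directly against DNA references. Ids are
#' the first whitespace-delimited token of each header; the remainder is kept
#' as the record description in `mcols()`.
#'
#' @param path Path to a FASTA file.
#' @param role Role to attach to every record, `"focal"` (query OTUs) or
#'   `"reference"`; stored in `mcols()$role`.
#' @return A `DNAStringSet` named by record id, with `mcols()` columns
#'   `role` and `description`.
#' @details Hard errors: empty file, duplicate ids (the offending id is
#'   named), and residues outside `{A,C,G,T,N}` (reported with the file line
#'   number).
#' @export
read_fasta <- function(path, role = c("focal", "reference")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id in ", path, ": ", dup[1L])
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop("non-IUPAC residue in record '", ids[idx], "' (", path,
         ", line ", .fasta_bad_line(path, idx), "); only A/C/G/T/N allowed")
  }
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence for id '", ids[which(nchar(seqs) == 0L)[1L]], "'")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(role = role, description = desc)
  out
}

# Locate the first offending sequence line of record `rec_idx` (error path only).
.fasta_bad_line <- function(path, rec_idx) {
  lines <- readLines(path, warn = FALSE)
  rec <- 0L
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) rec <- rec + 1L
    else if (rec == rec_idx) {
      norm <- chartr("uU", "tT", toupper(lines[i]))
      if (grepl("[^ACGTN]", norm)) return(i)
    }
  }
  NA_integer_
}

#' Write a sequence set to FASTA
#'
#' @param x A named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- as_sequences(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Coerce to a named character vector of sequences
#'
#' Internal normalizer accepting `DNAStringSet`, named character vectors or
#' lists of single strings.
#' @param x Sequences.
#' @return Named character vector.
#' @keywords internal
#' @export
as_sequences <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.list(x)) {
    out <- vapply(x, as.character, character(1L))
  } else {
    out <- as.character(x)
    names(out) <- names(x)
  }
  if (is.null(names(out)) || any(names(out) == ""))
    stop("sequences must be named")
  out
}

## ---------------------------------------------------------------------------
## Community matrix

#' Construct a community matrix (samples x OTUs)
#'
#' The canonical container for read counts: a non-negative integer matrix
#' with samples as rows and OTUs as columns, plus per-sample metadata
#' (basin, site class, sampling depth).
#'
#' @param counts Integer matrix, samples in rows, OTUs in columns, both
#'   dimensions named.
#' @param sample_meta `data.frame` with columns `sample_id`, `basin`
#'   (one of `"S"`, `"C"`, `"N"`), `site_class` (`"coastal"` or `"deep"`),
#'   `depth_m` (numeric). Optional; a placeholder is built when `NULL`.
#' @return An object of class `community_matrix`: a list with elements
#'   `counts` and `sample_meta`.
#' @export
community_matrix <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ", colnames(counts)[duplicated(colnames(counts))][1L])
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  if (any(counts < 0)) {
    ij <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at sample '", rownames(counts)[ij[1L]],
         "', OTU '", colnames(counts)[ij[2L]], "'")
  }
  if (any(counts != round(counts))) {
    ij <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop("non-integer count at sample '", rownames(counts)[ij[1L]],
         "', OTU '", colnames(counts)[ij[2L]], "'")
  }
  storage.mode(counts) <- "integer"
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = rownames(counts), basin = NA_character_,
                              site_class = NA_character_, depth_m = NA_real_,
                              stringsAsFactors = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta)
  need <- c("sample_id", "basin", "site_class", "depth_m")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss) > 0L) stop("sample_meta missing column(s): ",
                              paste(miss, collapse = ", "))
  if (!setequal(sample_meta$sample_id, rownames(counts)))
    stop("sample_meta sample ids do not match count matrix rows")
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  ok_basin <- is.na(sample_meta$basin) | sample_meta$basin %in% c("S", "C", "N")
  if (!all(ok_basin))
    stop("unknown basin code: ", sample_meta$basin[!ok_basin][1L],
         " (expected S, C or N)")
  zero <- rowSums(counts) == 0L
  if (any(zero))
    warning("sample(s) with zero total reads retained: ",
            paste(rownames(counts)[zero], collapse = ", "))
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix: ", nrow(x$counts), " samples x ",
      ncol(x$counts), " OTUs; total reads ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

#' Total reads per OTU across samples
#' @param x A `community_matrix`.
#' @return Named integer vector over OTU ids.
#' @export
otu_totals <- function(x) {
  v <- colSums(x$counts)
  stats::setNames(as.integer(v), names(v))
}

#' Total reads per sample
#' @param x A `community_matrix`.
#' @return Named integer vector over sample ids.
#' @export
sample_depths <- function(x) {
  v <- rowSums(x$counts)
  stats::setNames(as.integer(v), names(v))
}

#' Read a TSV count table with sample metadata
#'
#' Expected layout (`orientation = "samples_rows"`, the default): one row per
#' sample with columns `sample_id`, `basin`, `site_class`, `depth_m` followed
#' by one integer column per OTU. With `orientation = "otus_rows"` the table
#' is transposed (OTU rows; sample metadata supplied separately is not
#' supported in that layout and placeholders are used).
#'
#' @param path TSV path.
#' @param orientation `"samples_rows"` (default) or `"otus_rows"`.
#' @return A [community_matrix()].
#' @export
read_count_table <- function(path, orientation = c("samples_rows", "otus_rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "otus_rows") {
    otu_ids <- tab[[1L]]
    m <- t(as.matrix(tab[, -1L, drop = FALSE]))
    colnames(m) <- otu_ids
    .check_numeric_cells(m)
    return(community_matrix(m))
  }
  meta_cols <- c("sample_id", "basin", "site_class", "depth_m")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss) > 0L)
    stop("count table missing metadata column(s): ", paste(miss, collapse = ", "))
  otu_cols <- setdiff(names(tab), meta_cols)
  if (length(otu_cols) == 0L) stop("count table has no OTU columns")
  m <- as.matrix(tab[, otu_cols, drop = FALSE])
  rownames(m) <- tab$sample_id
  .check_numeric_cells(m)
  community_matrix(m, tab[, meta_cols])
}

.check_numeric_cells <- function(m) {
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) {
    ij <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric count at row ", ij[1L], ", column ", ij[2L])
  }
  invisible(NULL)
}

#' Write a community matrix to TSV (samples as rows)
#' @param x A `community_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "community_matrix"))
  tab <- cbind(x$sample_meta, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Newick trees with bootstrap supports

#' Read a Newick tree carrying bootstrap supports as internal node labels
#'
#' Supports are read ONLY from internal node labels (the RAxML convention);
#' a non-numeric internal label is a hard error, an absent label is an
#' absent support (distinct from 0).
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] `phylo` object whose `node.label` holds the
#'   support strings; use [node_supports()] for the numeric view.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_text(txt)
}

#' @rdname read_newick
#' @param text A Newick string.
#' @export
read_newick_text <- function(text) {
  if (.paren_unbalanced(text))
    stop("unbalanced parentheses in Newick input")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree read")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    nonempty <- !is.na(lab) & lab != ""
    suppressWarnings(num <- as.numeric(lab[nonempty]))
    if (anyNA(num))
      stop("non-numeric internal node label: '",
           lab[nonempty][is.na(num)][1L],
           "' (supports must be numeric, in [0,100])")
    if (any(num < 0 | num > 100))
      stop("bootstrap support outside [0,100]: ", num[num < 0 | num > 100][1L])
  }
  tree
}

.paren_unbalanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  any(depth < 0) || depth[length(depth)] != 0L
}

#' Numeric bootstrap supports of a tree's internal nodes
#'
#' @param tree A `phylo`.
#' @return Numeric vector of length `tree$Nnode`, `NA` where no support was
#'   recorded (absent label), in node order (root first, per ape numbering).
#' @export
node_supports <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  lab <- tree$node.label
  lab[is.na(lab) | lab == ""] <- NA_character_
  suppressWarnings(as.numeric(lab))
}

#' Write a support-labeled tree to Newick
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Taxonomy map and run configuration

#' Read a TSV taxonomy map (id -> semicolon-joined ranks)
#' @param path TSV with columns `id` and `taxonomy`.
#' @return `data.frame` with columns `id`, `taxonomy` and a list-column
#'   `ranks` (split on `;`).
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "taxonomy") %in% names(tab)))
    stop("taxonomy map must have columns 'id' and 'taxonomy'")
  if (anyDuplicated(tab$id))
    stop("duplicate id in taxonomy map: ", tab$id[duplicated(tab$id)][1L])
  tab$ranks <- strsplit(tab$taxonomy, ";", fixed = TRUE)
  tab
}

#' Build / validate a run configuration
#'
#' Bundles every tunable threshold of the pipeline plus input paths, output
#' directory and the master RNG seed. All thresholds default to the values
#' used throughout the package (see [classify_params()], [flock_params()],
#' [hit_filter()]).
#'
#' @param focal_fasta,reference_fasta,count_table,tree Input file paths
#'   (may be `NA` when a stage is not run).
#' @param out_dir Report output directory.
#' @param seed Master RNG seed (integer); recorded in every report manifest.
#' @param classify [classify_params()] list.
#' @param flock [flock_params()] list.
#' @param filter [hit_filter()] list.
#' @param generator Optional [generator_config()] for the `simulate` stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(focal_fasta = NA_character_,
                       reference_fasta = NA_character_,
                       count_table = NA_character_,
                       tree = NA_character_,
                       out_dir = ".",
                       seed = 1L,
                       classify = classify_params(),
                       flock = flock_params(),
                       filter = hit_filter(),
                       generator = NULL) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  cfg <- list(focal_fasta = focal_fasta, reference_fasta = reference_fasta,
              count_table = count_table, tree = tree, out_dir = out_dir,
              seed = seed, classify = classify, flock = flock,
              filter = filter, generator = generator)
  class(cfg) <- "run_config"
  cfg
}

#' Read a JSON run configuration
#' @param path JSON file with any subset of [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("focal_fasta", "reference_fasta", "count_table", "tree",
               "out_dir", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$classify)) args$classify <- do.call(classify_params, raw$classify)
  if (!is.null(raw$flock))    args$flock    <- do.call(flock_params, raw$flock)
  if (!is.null(raw$filter))   args$filter   <- do.call(hit_filter, raw$filter)
  if (!is.null(raw$generator)) args$generator <- do.call(generator_config, raw$generator)
  do.call(run_config, args)
}
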