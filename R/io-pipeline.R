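# Readers and writers for the interchange formats (FASTA, 12-column
# tabular hit format, TSV, JSON, Newick), pipeline configuration, and the
# end-to-end simulate -> screen pipeline runner.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (nucleotide or peptide).
#' @return `data.frame` with columns `id` (first header token),
#'   `description` (remainder of the header) and `sequence` (uppercased).
#'   Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", ids[which(!nzchar(seqs))[1L]],
         call. = FALSE)
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector, or a `data.frame` with `id`,
#'   `sequence` and optionally `description` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  if (is.data.frame(sequences)) {
    ids <- sequences$id
    desc <- if ("description" %in% names(sequences)) {
      sequences$description
    } else {
      rep("", nrow(sequences))
    }
    seqs <- sequences$sequence
  } else {
    ids <- names(sequences)
    desc <- rep("", length(sequences))
    seqs <- unname(sequences)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    header <- if (nzchar(desc[i])) paste(ids[i], desc[i]) else ids[i]
    writeLines(paste0(">", header), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular search hit file
#'
#' Parses the standard 12-column tab-separated hit format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore). Query coordinates arrive 1-based inclusive; they are
#' additionally exposed as 0-based half-open forward-strand coordinates
#' (`contig_start`, `contig_end`) with a `frame` column whose sign is the
#' strand (reverse-strand rows are those with `qstart > qend`). The frame
#' magnitude on the reverse strand depends on the query length; supply
#' `query_lengths` to compute it, otherwise reverse frames are reported
#' as -1 (downstream excision anchors on coordinates, not on the
#' magnitude).
#'
#' @param path Path to the tab-separated file (no header).
#' @param query_lengths Optional named integer vector of query sequence
#'   lengths.
#' @return `data.frame` with the 12 standard columns plus `contig_start`,
#'   `contig_end`, `frame`.
#' @export
read_hit_table <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(raw),
         " in ", path, call. = FALSE)
  }
  names(raw) <- HIT_COLUMNS
  for (col in c("pident", "evalue", "bitscore")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(raw[[col]])) {
      stop("non-numeric ", col, " in ", path, call. = FALSE)
    }
  }
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")) {
    raw[[col]] <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(raw[[col]])) {
      stop("non-integer ", col, " in ", path, call. = FALSE)
    }
  }
  forward <- raw$qstart <= raw$qend
  raw$contig_start <- ifelse(forward, raw$qstart - 1L, raw$qend - 1L)
  raw$contig_end <- ifelse(forward, raw$qend, raw$qstart)
  if (!is.null(query_lengths)) {
    L <- query_lengths[raw$qseqid]
    raw$frame <- as.integer(ifelse(
      forward, (raw$contig_start %% 3L) + 1L,
      -(((L - raw$contig_end) %% 3L) + 1L)))
  } else {
    raw$frame <- as.integer(ifelse(
      forward, (raw$contig_start %% 3L) + 1L, -1L))
  }
  raw
}

#' Write hit records in the 12-column tabular format
#'
#' Emits only the 12 standard columns (derived coordinate columns are
#' dropped), preserving the original 1-based inclusive convention so a
#' read/write round trip is the identity on the standard fields.
#'
#' @param hits `data.frame` containing the 12 standard columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialize a tree as Newick text
#'
#' @param tree A `phylo` object (e.g. from [upgma_dendrogram]); labels
#'   containing whitespace or Newick metacharacters are quoted.
#' @param path Optional path; when given the text is also written there.
#' @return The Newick string (terminal semicolon included).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  # write.tree mangles labels with spaces/metacharacters; swap them for
  # placeholders and substitute quoted originals back into the text
  needs_quote <- grepl("[\\s(),:;'\\[\\]]", tree$tip.label, perl = TRUE)
  originals <- tree$tip.label[needs_quote]
  placeholders <- sprintf("xQLBLx%dx", seq_along(originals))
  tree$tip.label[needs_quote] <- placeholders
  txt <- ape::write.tree(tree)
  for (i in seq_along(originals)) {
    txt <- sub(placeholders[i],
               paste0("'", gsub("'", "''", originals[i]), "'"),
               txt, fixed = TRUE)
  }
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' Read an intensity table and its metadata from TSV
#'
#' The intensity file has a header row (`protein_id` then one column per
#' replicate) with blank cells marking missing values; the optional
#' metadata file has columns `protein_id`, `origin`, `category`,
#' `region`, `first_detection`.
#'
#' @param intensity_path,meta_path File paths (`meta_path` optional).
#' @return An [intensity_table].
#' @export
read_intensity_table <- function(intensity_path, meta_path = NULL) {
  tab <- utils::read.table(intensity_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  meta <- if (!is.null(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  intensity_table(m, meta)
}

#' Write per-protein copy estimates as TSV
#'
#' @param proteome A `particle_proteome` ([normalize_to_anchor]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_copy_estimates <- function(proteome, path) {
  stopifnot(inherits(proteome, "particle_proteome"))
  per_rep <- as.data.frame(proteome$copies)
  names(per_rep) <- paste0("copies_", names(per_rep))
  out <- cbind(proteome$estimates[, "protein_id", drop = FALSE], per_rep,
               proteome$estimates[, setdiff(names(proteome$estimates),
                                            "protein_id"), drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' One declarative bundle of every threshold the pipeline applies, with
#' the defaults used throughout: RBH e-value cutoff 1e-15, screening
#' e-value cutoff 1e-10, length-filter fraction 0.8, host-protein CV
#' threshold 36 percent, anchor copy number 5040.
#'
#' @param evalue_rbh,evalue_screen Strict e-value cutoffs.
#' @param length_fraction Length-filter fraction in `(0, 1]`.
#' @param cv_threshold Percent CV threshold for host-protein flags.
#' @param anchor_copies Anchor (MCP) copies per particle.
#' @param seed Integer seed for the simulators.
#' @param outdir Output directory for [run_pipeline].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_rbh = 1e-15, evalue_screen = 1e-10,
                            length_fraction = 0.8, cv_threshold = 36,
                            anchor_copies = 5040, seed = 1L,
                            outdir = ".") {
  num <- c(evalue_rbh = evalue_rbh, evalue_screen = evalue_screen,
           length_fraction = length_fraction,
           cv_threshold = cv_threshold, anchor_copies = anchor_copies)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all thresholds must be positive: ",
         paste(names(num)[!is.finite(num) | num <= 0], collapse = ", "),
         call. = FALSE)
  }
  structure(list(evalue_rbh = evalue_rbh, evalue_screen = evalue_screen,
                 length_fraction = length_fraction,
                 cv_threshold = cv_threshold,
                 anchor_copies = anchor_copies,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Run the simulate-then-screen pipeline end to end
#'
#' Generates a synthetic metagenome with planted truth, runs the lyase
#' screen on it with the configured thresholds, and writes all artifacts
#' (contig FASTA, hit tables, calls TSV, station summary TSV, placement
#' FASTA, `truth.json`, and a log of the applied parameters) into
#' `config$outdir`.
#'
#' @param config A [pipeline_config].
#' @param ... Passed on to [simulate_metagenome] (e.g. `n_stations`,
#'   `viral_fraction`).
#' @return Invisibly, a list with `calls`, `summary` and the simulation
#'   object `sim`.
#' @export
run_pipeline <- function(config = pipeline_config(), ...) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$outdir, f)

  sim <- simulate_metagenome(seed = config$seed, ...)
  write_fasta(sim$contigs, path("contigs.fasta"))
  write_hit_table(sim$lyase_hits, path("lyase_hits.tsv"))
  write_hit_table(sim$ncvog_hits, path("ncvog_hits.tsv"))
  utils::write.table(sim$references, path("references.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, path("truth.json"), dataframe = "rows",
                       na = "null")

  calls <- screen_contigs(sim$contigs, sim$lyase_hits, sim$ncvog_hits,
                          sim$ref_lengths, sim$ref_families,
                          contig_meta = sim$contig_meta,
                          evalue_max = config$evalue_screen,
                          min_fraction = config$length_fraction)
  utils::write.table(calls, path("lyase_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- station_summaries(calls)
  utils::write.table(summ, path("station_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_placement_queries(calls, path("placement_queries.fasta"))

  log <- c(sprintf("stage=screen evalue_screen=%g length_fraction=%g",
                   config$evalue_screen, config$length_fraction),
           sprintf("contigs_in=%d lyase_contigs=%d viral=%d",
                   length(sim$contigs), nrow(calls), sum(calls$viral)))
  writeLines(log, path("pipeline.log"))
  invisible(list(calls = calls, summary = summ, sim = sim))
}
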