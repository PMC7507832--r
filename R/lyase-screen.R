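# Rule-based screen for virus-encoded polysaccharide lyases on assembled
# metagenomic contigs: translated-search lyase detection, NCVOG-based
# viral-origin calls with family assignment, excision and translation of
# the lyase region, a minimum-length filter against the reference set,
# and per-station summaries with abundance normalization.

#' Contigs carrying a polysaccharide lyase hit
#'
#' @param hits `data.frame` of translated-search hits against the lyase
#'   reference set, with columns `qseqid` (contig) and `evalue` (e.g. from
#'   [read_hit_table]).
#' @param evalue_max E-value cutoff; hits pass with `evalue < evalue_max`
#'   (strict).
#' @return Sorted character vector of contig ids with at least one
#'   passing hit.
#' @export
find_lyase_contigs <- function(hits, evalue_max = 1e-10) {
  stopifnot(is.data.frame(hits),
            all(c("qseqid", "evalue") %in% names(hits)))
  sort(unique(hits$qseqid[hits$evalue < evalue_max]))
}

#' Viral-origin call and family assignment for one contig
#'
#' A contig is termed viral if it carries at least one hit to an NCVOG
#' (giant-virus orthologous group) marker passing the e-value cutoff
#' (strict `<`); the best passing hit (minimum e-value, ties by maximum
#' bitscore, then lexicographic reference id) assigns the putative viral
#' family.
#'
#' @param contig_id Contig identifier.
#' @param ncvog_hits `data.frame` of NCVOG hits with columns `qseqid`,
#'   `sseqid`, `evalue`, `bitscore`; rows for other contigs are ignored.
#' @param ref_families Named character vector mapping NCVOG reference id
#'   to viral family.
#' @param evalue_max E-value cutoff.
#' @return List with `viral` (logical), `family` (family label or
#'   `NA_character_`), `best_ncvog` (list with `ref_id`, `evalue`, or
#'   `NULL`).
#' @export
call_viral <- function(contig_id, ncvog_hits, ref_families,
                       evalue_max = 1e-10) {
  h <- ncvog_hits[ncvog_hits$qseqid == contig_id &
                    ncvog_hits$evalue < evalue_max, , drop = FALSE]
  if (!nrow(h)) {
    return(list(viral = FALSE, family = NA_character_, best_ncvog = NULL))
  }
  h <- h[order(h$evalue, -h$bitscore, h$sseqid), , drop = FALSE]
  best <- h[1L, ]
  fam <- ref_families[best$sseqid]
  if (is.null(fam) || is.na(fam)) {
    stop("NCVOG reference '", best$sseqid,
         "' lacks a family annotation", call. = FALSE)
  }
  list(viral = TRUE, family = unname(fam),
       best_ncvog = list(ref_id = best$sseqid, evalue = best$evalue))
}

# Merge 0-based half-open intervals that overlap; returns a data.frame of
# merged intervals with the row index of the highest-bitscore member hit.
merge_overlapping <- function(starts, ends, bitscores) {
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]; bitscores <- bitscores[ord]
  group <- integer(length(starts))
  g <- 1L
  group[1L] <- g
  cur_end <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] < cur_end) {        # strict overlap joins the group
      group[i] <- g
      cur_end <- max(cur_end, ends[i])
    } else {
      g <- g + 1L
      group[i] <- g
      cur_end <- ends[i]
    }
  }
  do.call(rbind, lapply(split(seq_along(group), group), function(ix) {
    dom <- ix[which.max(bitscores[ix])]
    data.frame(start = min(starts[ix]), end = max(ends[ix]),
               dominant = ord[dom], n_hits = length(ix))
  }))
}

#' Excise lyase regions from a contig and translate them
#'
#' Passing hits on the same strand whose nucleotide intervals overlap are
#' merged into one region. The merged region is trimmed so that its
#' length is a multiple of 3 in the reading frame of the region's
#' highest-bitscore hit: on the forward strand the frame is anchored at
#' that hit's start, on the reverse strand at its end. Reverse-strand
#' regions are reverse-complemented before translation with the standard
#' genetic code; internal stop codons are retained as `*`. Hits merged
#' into one region whose frames conflict with the dominant hit trigger a
#' warning and the dominant frame wins.
#'
#' @param contig Nucleotide sequence of the contig (character string,
#'   ACGTN alphabet).
#' @param hits `data.frame` of passing hits for this contig with columns
#'   `contig_start`, `contig_end` (0-based half-open, forward strand),
#'   `frame` (sign gives the strand), `bitscore`.
#' @return A list of loci, each a list with `start`, `end` (0-based
#'   half-open, after frame trimming), `strand` (`"+"`/`"-"`), `frame`,
#'   `peptide` (amino-acid string), `n_hits`. Ordered by region start.
#' @export
excise_and_translate <- function(contig, hits) {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig),
            nrow(hits) >= 1L)
  loci <- list()
  for (strand in c(1, -1)) {
    h <- hits[sign(hits$frame) == strand, , drop = FALSE]
    if (!nrow(h)) next
    merged <- merge_overlapping(h$contig_start, h$contig_end, h$bitscore)
    for (i in seq_len(nrow(merged))) {
      dom <- h[merged$dominant[i], ]
      in_region <- h$contig_start < merged$end[i] &
        h$contig_end > merged$start[i]
      if (any(h$frame[in_region] != dom$frame)) {
        warning("conflicting frames among overlapping hits on contig ",
                "region [", merged$start[i], ",", merged$end[i],
                "); keeping highest-bitscore frame ", dom$frame,
                call. = FALSE)
      }
      s <- merged$start[i]; e <- merged$end[i]
      if (strand > 0) {
        s <- s + (dom$contig_start - s) %% 3L
        e <- e - (e - s) %% 3L
      } else {
        e <- e - (e - dom$contig_end) %% 3L
        s <- s + (e - s) %% 3L
      }
      nt <- substr(contig, s + 1L, e)
      dna <- Biostrings::DNAString(nt)
      if (strand < 0) dna <- Biostrings::reverseComplement(dna)
      pep <- as.character(Biostrings::translate(
        dna, no.init.codon = TRUE, if.fuzzy.codon = "X"))
      loci[[length(loci) + 1L]] <- list(
        start = s, end = e,
        strand = if (strand > 0) "+" else "-",
        frame = dom$frame,
        peptide = pep,
        n_hits = merged$n_hits[i])
    }
  }
  loci[order(vapply(loci, `[[`, numeric(1), "start"))]
}

#' Minimum-length filter against the reference lyase set
#'
#' A translated lyase passes if it is strictly longer than `fraction`
#' times the length of the shortest biochemically characterized reference
#' lyase.
#'
#' @param peptide Amino-acid string (or its length as a number).
#' @param reference_lengths Numeric vector of reference peptide lengths
#'   (aa); must be non-empty.
#' @param fraction Length fraction; default 0.8.
#' @return Logical.
#' @export
length_filter <- function(peptide, reference_lengths, fraction = 0.8) {
  if (!length(reference_lengths)) {
    stop("reference set is empty", call. = FALSE)
  }
  len <- if (is.character(peptide)) nchar(peptide) else peptide
  len > fraction * min(reference_lengths)
}

#' Run the full lyase screen over a set of contigs
#'
#' Applies [find_lyase_contigs], [call_viral], [excise_and_translate] and
#' [length_filter] to every contig, reporting one row per contig (the
#' highest-bitscore locus) together with the number of distinct loci.
#'
#' @param contigs Named character vector of contig sequences, or a
#'   `data.frame` from [read_fasta].
#' @param lyase_hits,ncvog_hits Hit tables ([read_hit_table]) against the
#'   lyase references and the NCVOG markers.
#' @param ref_lengths Named numeric vector of reference lyase peptide
#'   lengths (aa).
#' @param ref_families Named character vector mapping NCVOG reference ids
#'   to viral families.
#' @param contig_meta Optional `data.frame` with columns `contig_id`,
#'   `station`, `depth`, `size_fraction`.
#' @param evalue_max E-value cutoff applied to both searches.
#' @param min_fraction Length-filter fraction.
#' @return `data.frame` of class `lyase_calls`: one row per lyase-positive
#'   contig with columns `contig_id`, `station`, `depth`, `size_fraction`,
#'   `viral`, `assigned_family`, `best_ncvog_id`, `best_ncvog_evalue`,
#'   `region_start`, `region_end`, `strand`, `frame`, `peptide`,
#'   `peptide_length`, `passes_length_filter`, `n_loci`.
#' @export
screen_contigs <- function(contigs, lyase_hits, ncvog_hits, ref_lengths,
                           ref_families, contig_meta = NULL,
                           evalue_max = 1e-10, min_fraction = 0.8) {
  if (is.data.frame(contigs)) {
    contigs <- stats::setNames(contigs$sequence, contigs$id)
  }
  ids <- find_lyase_contigs(lyase_hits, evalue_max)
  rows <- lapply(ids, function(cid) {
    h <- lyase_hits[lyase_hits$qseqid == cid &
                      lyase_hits$evalue < evalue_max, , drop = FALSE]
    loci <- excise_and_translate(contigs[[cid]], h)
    best <- loci[[which.max(vapply(loci, function(l) {
      max(h$bitscore[h$contig_start >= l$start - 2 &
                       h$contig_end <= l$end + 2])
    }, numeric(1)))]]
    vc <- call_viral(cid, ncvog_hits, ref_families, evalue_max)
    data.frame(
      contig_id = cid,
      viral = vc$viral,
      assigned_family = if (vc$viral) vc$family else NA_character_,
      best_ncvog_id = if (vc$viral) vc$best_ncvog$ref_id else NA_character_,
      best_ncvog_evalue = if (vc$viral) vc$best_ncvog$evalue else NA_real_,
      region_start = best$start, region_end = best$end,
      strand = best$strand, frame = best$frame,
      peptide = best$peptide,
      peptide_length = nchar(best$peptide),
      passes_length_filter = length_filter(best$peptide, ref_lengths,
                                           min_fraction),
      n_loci = length(loci),
      stringsAsFactors = FALSE)
  })
  calls <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(contig_meta) && nrow(calls)) {
    idx <- match(calls$contig_id, contig_meta$contig_id)
    for (col in intersect(c("station", "depth", "size_fraction"),
                          names(contig_meta))) {
      calls[[col]] <- contig_meta[[col]][idx]
    }
  }
  class(calls) <- c("lyase_calls", class(calls))
  calls
}

#' Per-station summaries of viral lyase contribution
#'
#' Pools contigs from all depths and size fractions at each station and
#' reports the fraction of lyase-bearing contigs of putative viral
#' origin, plus the per-family breakdown.
#'
#' @param calls Lyase calls ([screen_contigs]) with a `station` column.
#' @return `data.frame` with columns `station`, `total_lyase_contigs`,
#'   `viral_lyase_contigs`, `percent_viral`; the per-family counts are
#'   attached as attribute `"families"` (`data.frame` with `station`,
#'   `family`, `count`).
#' @export
station_summaries <- function(calls) {
  stopifnot("station" %in% names(calls))
  stations <- sort(unique(calls$station))
  out <- do.call(rbind, lapply(stations, function(s) {
    sub <- calls[calls$station == s, , drop = FALSE]
    data.frame(station = s,
               total_lyase_contigs = nrow(sub),
               viral_lyase_contigs = sum(sub$viral),
               percent_viral = 100 * sum(sub$viral) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  fams <- calls[calls$viral, c("station", "assigned_family"), drop = FALSE]
  fam_tab <- if (nrow(fams)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(fams))),
                            by = list(station = fams$station,
                                      family = fams$assigned_family),
                            FUN = sum)
    agg[order(agg$station, agg$family), , drop = FALSE]
  } else {
    data.frame(station = character(0), family = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  attr(out, "families") <- fam_tab
  rownames(out) <- NULL
  out
}

#' Reads-per-kilobase-per-million normalization
#'
#' `raw * 1e9 / (feature_length_nt * library_size)`: mapped-read counts
#' normalized by feature length (nt) and sequencing depth.
#'
#' @param raw_count Mapped reads (`>= 0`).
#' @param feature_length_nt Feature length in nucleotides (`> 0`).
#' @param library_size Total mapped reads in the library (`> 0`).
#' @return Normalized abundance (RPKM).
#' @export
normalize_counts <- function(raw_count, feature_length_nt, library_size) {
  if (any(feature_length_nt <= 0) || any(library_size <= 0)) {
    stop("feature length and library size must be positive", call. = FALSE)
  }
  if (any(raw_count < 0)) stop("counts must be >= 0", call. = FALSE)
  raw_count * 1e9 / (feature_length_nt * library_size)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classical fixed-effects one-way analysis of variance across groups of
#' normalized abundances, with Tukey honest-significant-difference
#' pairwise comparisons at the given confidence level.
#'
#' @param groups Named list of numeric vectors; at least two groups, each
#'   with at least two values.
#' @param conf_level Confidence level for the Tukey intervals.
#' @return List with `f_statistic`, `p_value`, `tukey` (`data.frame` with
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`), and the fitted `aov`
#'   object as `fit`.
#' @export
group_comparison <- function(groups, conf_level = 0.95) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  list(
    f_statistic = tab[["F value"]][1L],
    p_value = tab[["Pr(>F)"]][1L],
    tukey = data.frame(comparison = rownames(tk),
                       diff = tk[, "diff"], lwr = tk[, "lwr"],
                       upr = tk[, "upr"], p_adj = tk[, "p adj"],
                       row.names = NULL, stringsAsFactors = FALSE),
    fit = fit)
}

#' Write length-filtered viral lyase peptides as placement queries
#'
#' Emits a peptide FASTA (headers `contig_id|family|station`) of the
#' viral calls passing the length filter, ready for external alignment
#' and phylogenetic placement.
#'
#' @param calls Lyase calls ([screen_contigs]).
#' @param path Output FASTA path.
#' @return Invisibly, the number of records written.
#' @export
export_placement_queries <- function(calls, path) {
  keep <- calls$viral & calls$passes_length_filter
  sub <- calls[keep, , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(sub))) {
    station <- if ("station" %in% names(sub)) sub$station[i] else "NA"
    lines <- c(lines,
               paste0(">", sub$contig_id[i], "|", sub$assigned_family[i],
                      "|", station),
               sub$peptide[i])
  }
  writeLines(lines, path)
  invisible(nrow(sub))
}
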