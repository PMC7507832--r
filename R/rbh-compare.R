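# Reciprocal-best-hit (RBH) orthology between virus proteomes, restriction
# to packaged<->packaged pairs, graph clustering of pairs into ortholog
# components, and presence/absence clustering of viruses.

#' Best hit per query from a pairwise search hit table
#'
#' Selects, for every query with at least one hit passing the e-value
#' cutoff (strict `<`), the subject with the maximal bitscore. Multiple
#' HSPs for one query/subject pair are first collapsed to the single
#' highest-bitscore record. Ties are broken deterministically: higher
#' bitscore, then lower e-value, then lexicographically smallest subject
#' id.
#'
#' @param hits `data.frame` of hit records with columns `qseqid`,
#'   `sseqid`, `evalue`, `bitscore` (the standard 12-column tabular layout
#'   from [read_hit_table] works directly).
#' @param evalue_max E-value cutoff; records with `evalue < evalue_max`
#'   are eligible.
#' @return `data.frame` with one row per query: `query`, `subject`,
#'   `bitscore`, `evalue`. Queries with no passing hit are absent.
#' @export
best_hits <- function(hits, evalue_max = 1e-15) {
  stopifnot(is.data.frame(hits),
            all(c("qseqid", "sseqid", "evalue", "bitscore") %in% names(hits)))
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(query = character(0), subject = character(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # rank within query: bitscore desc, evalue asc, subject lexicographic;
  # this also collapses multiple HSPs per query/subject pair to the best.
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$qseqid)
  out <- data.frame(query = hits$qseqid[first],
                    subject = hits$sseqid[first],
                    bitscore = hits$bitscore[first],
                    evalue = hits$evalue[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reciprocal best-hit pairs between two proteomes
#'
#' A pair (a, b) is emitted iff b is a's best hit in the second proteome
#' and a is b's best hit in the first. Pairs are stored in canonical
#' genome order (lexicographic by virus id) and are semantically
#' unordered.
#'
#' @param bh_ab,bh_ba Best-hit maps from [best_hits] for the two orderings
#'   of one genome pair.
#' @param virus_a,virus_b Genome identifiers for the query side of
#'   `bh_ab` and `bh_ba` respectively.
#' @return `data.frame` with columns `virus_a`, `virus_b`, `protein_a`,
#'   `protein_b`, `bitscore_ab`, `bitscore_ba`, `max_evalue`, sorted by
#'   `protein_a`.
#' @export
reciprocal_pairs <- function(bh_ab, bh_ba, virus_a = "A", virus_b = "B") {
  idx <- match(bh_ab$subject, bh_ba$query)
  keep <- !is.na(idx) & bh_ba$subject[idx] == bh_ab$query
  a <- bh_ab$query[keep]
  b <- bh_ab$subject[keep]
  out <- data.frame(
    virus_a = rep(virus_a, length(a)), virus_b = rep(virus_b, length(a)),
    protein_a = a, protein_b = b,
    bitscore_ab = bh_ab$bitscore[keep],
    bitscore_ba = bh_ba$bitscore[idx][keep],
    max_evalue = pmax(bh_ab$evalue[keep], bh_ba$evalue[idx][keep]),
    stringsAsFactors = FALSE
  )
  if (virus_a > virus_b) {
    out <- data.frame(
      virus_a = out$virus_b, virus_b = out$virus_a,
      protein_a = out$protein_b, protein_b = out$protein_a,
      bitscore_ab = out$bitscore_ba, bitscore_ba = out$bitscore_ab,
      max_evalue = out$max_evalue, stringsAsFactors = FALSE)
  }
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict RBH pairs to proteins packaged by both viruses
#'
#' @param pairs RBH pairs from [reciprocal_pairs].
#' @param packaged_a,packaged_b Character vectors of packaged protein ids
#'   for the viruses named in the pairs' `virus_a`/`virus_b` columns.
#' @return The subset of `pairs` with `protein_a` in `packaged_a` and
#'   `protein_b` in `packaged_b`.
#' @export
packaged_rbh <- function(pairs, packaged_a, packaged_b) {
  keep <- pairs$protein_a %in% packaged_a & pairs$protein_b %in% packaged_b
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of each virus's packaged proteome shared with every other
#'
#' Row-normalized, hence asymmetric: entry (v, w) is 100 times the number
#' of packaged RBH pairs between v and w divided by the number of proteins
#' packaged by v. The diagonal is 100 by convention.
#'
#' @param pair_counts Symmetric numeric matrix of packaged RBH pair counts
#'   with matching virus dimnames.
#' @param proteome_sizes Named numeric vector: packaged-proteome size per
#'   virus; all `> 0`.
#' @return Numeric matrix of percentages.
#' @export
shared_fraction_matrix <- function(pair_counts, proteome_sizes) {
  stopifnot(is.matrix(pair_counts),
            !is.null(rownames(pair_counts)),
            identical(rownames(pair_counts), colnames(pair_counts)))
  viruses <- rownames(pair_counts)
  sizes <- proteome_sizes[viruses]
  if (any(is.na(sizes)) || any(sizes <= 0)) {
    stop("every virus needs a positive packaged-proteome size",
         call. = FALSE)
  }
  out <- sweep(pair_counts, 1L, sizes, `/`) * 100
  diag(out) <- 100
  out
}

#' Cluster RBH pairs into ortholog components
#'
#' Treats each RBH pair as an undirected edge between (virus, protein)
#' nodes and returns the connected components; each component is one
#' clusterable ortholog feature. Cluster ids are deterministic: the
#' lexicographically smallest member label of the component.
#'
#' @param pairs RBH pairs ([reciprocal_pairs]), possibly concatenated over
#'   many genome pairs.
#' @return `data.frame` with columns `cluster_id`, `virus`, `protein`,
#'   sorted by cluster id then member.
#' @export
cluster_components <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(cluster_id = character(0), virus = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  node_a <- paste(pairs$virus_a, pairs$protein_a, sep = "|")
  node_b <- paste(pairs$virus_b, pairs$protein_b, sep = "|")
  g <- igraph::graph_from_edgelist(cbind(node_a, node_b), directed = FALSE)
  comp <- igraph::components(g)
  members <- igraph::V(g)$name
  cluster_of <- comp$membership
  ids <- vapply(split(members, cluster_of), function(m) min(m),
                character(1))
  labels <- ids[as.character(cluster_of)]
  parts <- strsplit(members, "|", fixed = TRUE)
  out <- data.frame(
    cluster_id = unname(labels),
    virus = vapply(parts, `[[`, character(1), 1L),
    protein = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cluster_id, out$virus, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Virus x ortholog-cluster presence/absence matrix
#'
#' @param clusters Output of [cluster_components].
#' @param viruses Optional character vector fixing the row set and order;
#'   defaults to the viruses present in `clusters`.
#' @return 0/1 integer matrix, rows = viruses, columns = cluster ids.
#' @export
presence_matrix <- function(clusters, viruses = NULL) {
  if (is.null(viruses)) viruses <- sort(unique(clusters$virus))
  ids <- sort(unique(clusters$cluster_id))
  m <- matrix(0L, nrow = length(viruses), ncol = length(ids),
              dimnames = list(viruses, ids))
  if (nrow(clusters)) {
    keep <- clusters$virus %in% viruses
    m[cbind(clusters$virus[keep], clusters$cluster_id[keep])] <- 1L
  }
  m
}

#' Bray-Curtis dissimilarity between presence/absence rows
#'
#' On 0/1 data Bray-Curtis equals the Sorensen-Dice dissimilarity
#' `1 - 2|A intersect B| / (|A| + |B|)`. Two all-zero rows are defined as
#' identical (dissimilarity 0) with a warning, since the ratio is
#' otherwise 0/0.
#'
#' @param matrix 0/1 matrix with at least two rows (viruses).
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis_presence <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L)
  if (!all(matrix %in% c(0, 1))) {
    stop("presence matrix must be 0/1", call. = FALSE)
  }
  d <- as.matrix(suppressWarnings(vegan::vegdist(matrix, method = "bray")))
  zero <- rowSums(matrix) == 0
  if (sum(zero) >= 1L) {
    warning("all-zero rows present; pairwise dissimilarity between two ",
            "all-zero rows is defined as 0", call. = FALSE)
    d[zero, zero] <- 0
  }
  d[is.nan(d)] <- 1   # one empty row vs a non-empty one shares nothing
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram from a dissimilarity matrix
#'
#' Agglomerates by unweighted average linkage and returns an ultrametric
#' tree whose leaf depths equal half the merge heights (so the cophenetic
#' distance between two leaves is their merge height).
#'
#' @param dissimilarity Square symmetric numeric matrix with zero
#'   diagonal and dimnames, or a `dist` object.
#' @param method Agglomeration method passed to [stats::hclust];
#'   `"average"` (UPGMA) by default.
#' @return An [ape::as.phylo] tree (class `phylo`); serialize with
#'   [write_newick].
#' @export
upgma_dendrogram <- function(dissimilarity, method = "average") {
  if (inherits(dissimilarity, "dist")) {
    d <- dissimilarity
  } else {
    stopifnot(is.matrix(dissimilarity))
    if (!isSymmetric(unname(dissimilarity))) {
      stop("dissimilarity matrix must be symmetric", call. = FALSE)
    }
    d <- stats::as.dist(dissimilarity)
  }
  hc <- stats::hclust(d, method = method)
  ape::as.phylo(hc)
}

#' Tally RBH pairs shared within vs between viral families
#'
#' @param pairs RBH pairs ([reciprocal_pairs]).
#' @param family_map Named character vector mapping virus id to family
#'   label; every virus appearing in `pairs` must be present.
#' @return List with integer elements `within` and `between`.
#' @export
within_between_tally <- function(pairs, family_map) {
  viruses <- unique(c(pairs$virus_a, pairs$virus_b))
  missing <- setdiff(viruses, names(family_map))
  if (length(missing)) {
    stop("missing family label for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  within <- family_map[pairs$virus_a] == family_map[pairs$virus_b]
  list(within = sum(within), between = sum(!within))
}
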