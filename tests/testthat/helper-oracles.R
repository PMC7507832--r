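# Independent oracles used across the suite. Each reimplements the checked
# operation by direct enumeration, unrelated to the package's code path.

# Exhaustive RBH oracle: for every (a, b) protein pair, check directly that
# b is a's single best passing hit and vice versa, scanning all records.
oracle_rbh <- function(hits_ab, hits_ba, evalue_max = 1e-15) {
  best_of <- function(hits, q) {
    h <- hits[hits$qseqid == q & hits$evalue < evalue_max, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    # collapse HSPs: best record per subject
    subs <- unique(h$sseqid)
    rec <- do.call(rbind, lapply(subs, function(s) {
      hs <- h[h$sseqid == s, , drop = FALSE]
      hs[order(-hs$bitscore, hs$evalue)[1L], ]
    }))
    rec <- rec[order(-rec$bitscore, rec$evalue, rec$sseqid), , drop = FALSE]
    rec$sseqid[1L]
  }
  qs <- unique(hits_ab$qseqid)
  out <- list()
  for (a in qs) {
    b <- best_of(hits_ab, a)
    if (is.na(b)) next
    if (identical(best_of(hits_ba, b), a)) {
      out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (!length(out)) return(matrix(character(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1L]), , drop = FALSE]
}

# Random hit-table instance for the RBH equivalence property.
random_hit_table <- function(n_q, n_s, n_hits, qprefix, sprefix) {
  data.frame(
    qseqid = paste0(qprefix, sample.int(n_q, n_hits, replace = TRUE)),
    sseqid = paste0(sprefix, sample.int(n_s, n_hits, replace = TRUE)),
    pident = round(runif(n_hits, 30, 100), 1),
    length = sample(50:500, n_hits, replace = TRUE),
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 10^runif(n_hits, -60, -5),
    bitscore = round(runif(n_hits, 40, 400), 1),
    stringsAsFactors = FALSE)
}

# Sorensen-Dice dissimilarity, closed form on 0/1 rows.
oracle_dice <- function(x, y) {
  inter <- sum(x == 1 & y == 1)
  tot <- sum(x) + sum(y)
  if (tot == 0) return(0)
  1 - 2 * inter / tot
}

# Naive step-by-step UPGMA: repeatedly merge the closest pair of clusters,
# recomputing distances as unweighted averages over all member pairs, and
# record the cophenetic distance (merge height) between leaves.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  cdist <- function(ci, cj) {
    mean(d[clusters[[ci]], clusters[[cj]], drop = FALSE])
  }
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        dd <- cdist(i, j)
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    mi <- clusters[[best[1L]]]; mj <- clusters[[best[2L]]]
    coph[mi, mj] <- bestd
    coph[mj, mi] <- bestd
    clusters[[best[1L]]] <- c(mi, mj)
    active[best[2L]] <- FALSE
  }
  coph
}

# Pairwise RBH over every unordered virus pair of a simulated proteome set.
all_reciprocal_pairs <- function(tabs, viruses, evalue_max = 1e-15) {
  out <- list()
  for (i in seq_along(viruses)[-length(viruses)]) {
    for (j in (i + 1L):length(viruses)) {
      v <- viruses[i]; w <- viruses[j]
      out[[length(out) + 1L]] <- reciprocal_pairs(
        best_hits(tabs[[paste(v, w, sep = "|")]], evalue_max),
        best_hits(tabs[[paste(w, v, sep = "|")]], evalue_max),
        v, w)
    }
  }
  do.call(rbind, out)
}
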