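# Generators for synthetic inputs with planted ground truth: virus
# proteomes with planted ortholog families, pairwise hit tables with a
# controllable score structure, label-free intensity tables with planted
# copies-per-particle, and metagenomes with planted lyase/viral contigs.
# Every generator is a pure function of its parameters and seed.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# One fixed codon per amino acid (the first codon for each residue in the
# standard code, reading the table in TCAG order); used for reverse
# translation when planting peptide-coding loci.
REVERSE_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "TTA", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

random_peptide <- function(len) {
  paste(sample(AMINO_ACIDS, len, replace = TRUE), collapse = "")
}

mutate_peptide <- function(pep, rate) {
  if (rate <= 0) return(pep)
  chars <- strsplit(pep, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(AMINO_ACIDS, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Reverse-translate a peptide with a fixed codon table
#'
#' Deterministic reverse translation using one fixed codon per amino acid
#' (the first codon for each residue in the standard code); used by the
#' metagenome simulator to plant peptide-coding loci whose translation
#' round-trips exactly.
#'
#' @param peptide Amino-acid string over the 20 standard residues.
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  bad <- setdiff(chars, names(REVERSE_CODON))
  if (length(bad)) {
    stop("cannot reverse-translate residue(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste(REVERSE_CODON[chars], collapse = "")
}

#' Simulate virus proteomes with planted ortholog families
#'
#' Each virus receives `n_background` unrelated random peptides
#' (i.i.d. uniform over the 20 amino acids, lengths 100-600) plus, for
#' every unordered pair of viruses, planted one-to-one orthologs realized
#' as point-mutated copies of a common base peptide:
#' `orthologs_within_pair` groups when the two viruses share a family and
#' `orthologs_between_pair` when they do not. Packaged flags are drawn
#' per protein with probability `packaged_fraction`.
#'
#' @param n_viruses Number of viruses (`>= 2`).
#' @param n_families Number of viral families (round-robin assignment).
#' @param orthologs_within_pair,orthologs_between_pair Planted ortholog
#'   groups per within-family / between-family virus pair.
#' @param packaged_fraction Probability a protein is packaged.
#' @param n_background Unrelated proteins per virus.
#' @param mutation_rate Per-residue substitution rate between ortholog
#'   copies.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `proteomes` (named list of named peptide vectors),
#'   `packaged` (named list of packaged protein ids), `families` (named
#'   character vector virus -> family), and `truth` (`data.frame` with
#'   `group_id`, `virus`, `protein_id`, `packaged`, one row per planted
#'   ortholog copy).
#' @export
simulate_virus_proteomes <- function(n_viruses = 6, n_families = 3,
                                     orthologs_within_pair = 4,
                                     orthologs_between_pair = 1,
                                     packaged_fraction = 0.6,
                                     n_background = 15,
                                     mutation_rate = 0.02,
                                     seed = 1L) {
  stopifnot(n_viruses >= 2)
  set.seed(seed)
  viruses <- sprintf("V%02d", seq_len(n_viruses))
  families <- stats::setNames(
    sprintf("F%02d", rep_len(seq_len(n_families), n_viruses)), viruses)

  proteomes <- stats::setNames(
    replicate(n_viruses, character(0), simplify = FALSE), viruses)
  counter <- stats::setNames(integer(n_viruses), viruses)
  next_id <- function(v) {
    counter[[v]] <<- counter[[v]] + 1L
    sprintf("%s_p%03d", v, counter[[v]])
  }

  truth <- list()
  gid <- 0L
  for (i in seq_len(n_viruses - 1L)) {
    for (j in (i + 1L):n_viruses) {
      v <- viruses[i]; w <- viruses[j]
      n_orth <- if (families[[v]] == families[[w]]) {
        orthologs_within_pair
      } else {
        orthologs_between_pair
      }
      for (g in seq_len(n_orth)) {
        gid <- gid + 1L
        base <- random_peptide(sample(100:600, 1L))
        pv <- next_id(v); pw <- next_id(w)
        proteomes[[v]][[pv]] <- mutate_peptide(base, mutation_rate)
        proteomes[[w]][[pw]] <- mutate_peptide(base, mutation_rate)
        truth[[length(truth) + 1L]] <- data.frame(
          group_id = sprintf("OG%04d", gid),
          virus = c(v, w), protein_id = c(pv, pw),
          packaged = stats::runif(2) < packaged_fraction,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (v in viruses) {
    for (b in seq_len(n_background)) {
      pid <- next_id(v)
      proteomes[[v]][[pid]] <- random_peptide(sample(100:600, 1L))
    }
  }
  truth <- do.call(rbind, truth)
  packaged <- lapply(viruses, function(v) {
    planted <- truth$protein_id[truth$virus == v & truth$packaged]
    background <- setdiff(names(proteomes[[v]]),
                          truth$protein_id[truth$virus == v])
    c(planted, background[stats::runif(length(background)) <
                            packaged_fraction])
  })
  names(packaged) <- viruses
  list(proteomes = proteomes, packaged = packaged, families = families,
       truth = truth)
}

empty_hit_table <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

hit_row <- function(q, s, pident, len, qstart, qend, sstart, send,
                    evalue, bits) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = as.integer(round(len * (100 - pident) / 100)),
             gapopen = 0L, qstart = qstart, qend = qend,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = round(bits, 1), stringsAsFactors = FALSE)
}

#' Simulate pairwise search hit tables from planted orthology
#'
#' For every ordered pair of viruses, emits 12-column tabular hit records:
#' each planted ortholog pair receives a bitscore drawn from
#' `Normal(match_bits_per_aa * length, noise_sd)` with a tiny e-value, the
#' same score being used in both directions; optional decoy hits between
#' non-orthologous proteins receive `Normal(decoy_bits_mean, noise_sd)`
#' scores at a passing but larger e-value.
#'
#' @param sim Output of [simulate_virus_proteomes].
#' @param match_bits_per_aa Mean bitscore per aligned residue for true
#'   ortholog pairs.
#' @param decoy_bits_mean Mean bitscore of decoy hits.
#' @param noise_sd Gaussian bitscore noise.
#' @param decoys_per_pair Decoy hit records per ordered virus pair.
#' @param seed Integer seed.
#' @return Named list of hit tables, one per ordered pair, names
#'   `"V1|V2"`.
#' @export
simulate_hit_tables <- function(sim, match_bits_per_aa = 2,
                                decoy_bits_mean = 60, noise_sd = 0,
                                decoys_per_pair = 0, seed = 1L) {
  set.seed(seed)
  viruses <- names(sim$proteomes)
  tables <- list()
  for (v in viruses) for (w in viruses) {
    if (v != w) tables[[paste(v, w, sep = "|")]] <- empty_hit_table()
  }
  add <- function(key, row) tables[[key]] <<- rbind(tables[[key]], row)

  for (g in split(sim$truth, sim$truth$group_id)) {
    for (i in seq_len(nrow(g) - 1L)) for (j in (i + 1L):nrow(g)) {
      v <- g$virus[i]; w <- g$virus[j]
      if (v == w) next
      pv <- g$protein_id[i]; pw <- g$protein_id[j]
      len <- nchar(sim$proteomes[[v]][[pv]])
      bits <- stats::rnorm(1, match_bits_per_aa * len, noise_sd)
      add(paste(v, w, sep = "|"),
          hit_row(pv, pw, 98, len, 1L, len, 1L, len, 1e-50, bits))
      add(paste(w, v, sep = "|"),
          hit_row(pw, pv, 98, len, 1L, len, 1L, len, 1e-50, bits))
    }
  }
  if (decoys_per_pair > 0) {
    orth <- paste(sim$truth$virus, sim$truth$protein_id)
    for (v in viruses) for (w in viruses) {
      if (v == w) next
      key <- paste(v, w, sep = "|")
      qs <- sample(names(sim$proteomes[[v]]), decoys_per_pair,
                   replace = TRUE)
      ss <- sample(names(sim$proteomes[[w]]), decoys_per_pair,
                   replace = TRUE)
      for (d in seq_len(decoys_per_pair)) {
        if (paste(v, qs[d]) %in% orth && paste(w, ss[d]) %in% orth) next
        bits <- stats::rnorm(1, decoy_bits_mean, noise_sd)
        add(key, hit_row(qs[d], ss[d], 40, 80L, 1L, 80L, 1L, 80L,
                         1e-20, bits))
      }
    }
  }
  tables
}

#' Simulate a label-free MS1 intensity table with planted copy numbers
#'
#' `I(p, r) = scale_r * copies(p) * exp(eps)`, `eps ~ Normal(0, sigma^2)`,
#' with a random per-replicate scale factor; entries are dropped with
#' probability `missing_prob` (the anchor is never dropped, so every
#' replicate retains its normalization reference).
#'
#' @param planted_copies Named numeric vector of true copies-per-particle,
#'   containing `anchor_id` with value `anchor_copies`.
#' @param anchor_id,anchor_copies The anchor protein and its structurally
#'   fixed copy number.
#' @param lognormal_sigma Multiplicative log-normal noise sigma.
#' @param missing_prob Per-entry missingness probability.
#' @param n_replicates Number of replicate runs.
#' @param seed Integer seed.
#' @param meta Optional metadata `data.frame` passed to
#'   [intensity_table].
#' @return An [intensity_table]; the per-replicate scale factors are
#'   attached as attribute `"scales"`.
#' @export
simulate_intensity_table <- function(planted_copies, anchor_id,
                                     anchor_copies = 5040,
                                     lognormal_sigma = 0,
                                     missing_prob = 0,
                                     n_replicates = 3L, seed = 1L,
                                     meta = NULL) {
  stopifnot(anchor_id %in% names(planted_copies))
  if (planted_copies[[anchor_id]] != anchor_copies) {
    stop("planted_copies[anchor_id] must equal anchor_copies",
         call. = FALSE)
  }
  set.seed(seed)
  scales <- exp(stats::rnorm(n_replicates, log(1e3), 0.5))
  n <- length(planted_copies)
  eps <- matrix(stats::rnorm(n * n_replicates, 0, lognormal_sigma),
                nrow = n)
  m <- outer(unname(planted_copies), scales) * exp(eps)
  dimnames(m) <- list(names(planted_copies),
                      paste0("rep", seq_len(n_replicates)))
  if (missing_prob > 0) {
    drop <- matrix(stats::runif(n * n_replicates) < missing_prob,
                   nrow = n)
    drop[names(planted_copies) == anchor_id, ] <- FALSE
    m[drop] <- NA_real_
  }
  out <- intensity_table(m, meta)
  attr(out, "scales") <- scales
  out
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# sample() treats a length-1 numeric as 1:n; this always picks one element
pick1 <- function(v) v[sample.int(length(v), 1L)]

#' Simulate a multi-station metagenome with planted lyase contigs
#'
#' Builds a reference set of lyase peptides, then per station plants
#' `lyase_contigs_per_station` contigs each embedding the exact
#' reverse-translated peptide of one reference at a random locus, strand
#' and frame; a fraction of them additionally embed an NCVOG marker locus
#' and are labelled viral with a planted family. Decoy contigs carry no
#' true locus; a third of them receive a near-threshold lyase hit whose
#' e-value fails the cutoff. Hit tables are emitted directly with
#' e-values far below threshold for true loci (1e-30 lyase, 1e-25 NCVOG)
#' and above it (1e-8) for decoy hits.
#'
#' @param n_stations Number of stations.
#' @param lyase_contigs_per_station Planted lyase contigs per station.
#' @param viral_fraction Fraction of lyase contigs per station that are
#'   viral (`round(viral_fraction * lyase_contigs_per_station)` planted
#'   exactly).
#' @param decoy_contigs Total decoy contigs without a true lyase locus.
#' @param n_refs Reference lyase peptides (lengths 250-400 aa).
#' @param families Viral family labels NCVOG markers are drawn from.
#' @param depths Depth labels cycled over contigs within a station.
#' @param seed Integer seed.
#' @return List with `contigs` (named character), `contig_meta`
#'   (`data.frame`: `contig_id`, `station`, `depth`, `size_fraction`),
#'   `lyase_hits`, `ncvog_hits` (hit tables with internal 0-based
#'   half-open `contig_start`/`contig_end` and `frame` columns),
#'   `ref_lengths`, `ref_families`, `references` (`data.frame` of the
#'   lyase reference set), and `truth` (`data.frame`: `contig_id`,
#'   `station`, `is_lyase`, `is_viral`, `family`, `start`, `end`,
#'   `strand`, `frame`, `peptide`).
#' @export
simulate_metagenome <- function(n_stations = 3,
                                lyase_contigs_per_station = 10,
                                viral_fraction = 0.2,
                                decoy_contigs = 60,
                                n_refs = 8,
                                families = c("Phycodnaviridae",
                                             "Mimiviridae",
                                             "Marseilleviridae",
                                             "Pandoraviridae"),
                                depths = c("SRF", "DCM", "MES"),
                                seed = 1L) {
  stopifnot(n_refs >= 1, n_stations >= 1)
  set.seed(seed)

  refs <- data.frame(
    ref_id = sprintf("PL%02d", seq_len(n_refs)),
    length = sample(250:400, n_refs, replace = TRUE),
    family = sample(paste0("PL", 1:10), n_refs, replace = TRUE),
    substrate = sample(c("pectate", "alginate", "chondroitin"),
                       n_refs, replace = TRUE),
    stringsAsFactors = FALSE)
  ref_peps <- stats::setNames(
    vapply(refs$length, random_peptide, character(1)), refs$ref_id)
  ncvog_ids <- sprintf("NCVOG%04d", seq_along(families) * 10L)
  ref_families <- stats::setNames(families, ncvog_ids)

  contigs <- character(0)
  meta <- list(); truth <- list()
  lyase_hits <- empty_hit_table(); ncvog_hits <- empty_hit_table()
  n_viral <- round(viral_fraction * lyase_contigs_per_station)

  plant <- function(contig, peptide, pos, strand) {
    orf <- reverse_translate(peptide)
    if (strand < 0) {
      orf <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(orf)))
    }
    paste0(substr(contig, 1, pos), orf,
           substr(contig, pos + nchar(orf) + 1L, nchar(contig)))
  }

  cid <- 0L
  for (s in seq_len(n_stations)) {
    station <- sprintf("ST%03d", s)
    for (i in seq_len(lyase_contigs_per_station)) {
      cid <- cid + 1L
      id <- sprintf("%s_c%04d", station, cid)
      ref <- pick1(refs$ref_id)
      pep <- ref_peps[[ref]]
      orf_len <- 3L * nchar(pep)
      clen <- orf_len + pick1(600:1500)
      seqnt <- random_dna(clen)
      is_viral <- i <= n_viral
      mlen <- 360L                      # 120-aa NCVOG marker locus
      # viral contigs reserve the left flank for the marker
      pos <- if (is_viral) {
        pick1(mlen:(clen - orf_len))    # 0-based insertion offset
      } else {
        pick1(0:(clen - orf_len))
      }
      strand <- if (stats::runif(1) < 0.5) 1L else -1L
      seqnt <- plant(seqnt, pep, pos, strand)
      start0 <- pos; end0 <- pos + orf_len
      frame <- if (strand > 0) {
        (start0 %% 3L) + 1L
      } else {
        -(((clen - end0) %% 3L) + 1L)
      }
      fam <- NA_character_
      if (is_viral) {
        marker <- pick1(ncvog_ids)
        fam <- unname(ref_families[[marker]])
        mpep <- random_peptide(120L)
        mpos <- pick1(0:(start0 - mlen))
        seqnt <- plant(seqnt, mpep, mpos, 1L)
        ncvog_hits <- rbind(ncvog_hits, hit_row(
          id, marker, 95, nchar(mpep), mpos + 1L, mpos + mlen,
          1L, nchar(mpep), 1e-25, 2 * nchar(mpep)))
      }
      if (strand > 0) {
        lyase_hits <- rbind(lyase_hits, hit_row(
          id, ref, 98, nchar(pep), start0 + 1L, end0, 1L, nchar(pep),
          1e-30, 2 * nchar(pep)))
      } else {
        lyase_hits <- rbind(lyase_hits, hit_row(
          id, ref, 98, nchar(pep), end0, start0 + 1L, 1L, nchar(pep),
          1e-30, 2 * nchar(pep)))
      }
      contigs[[id]] <- seqnt
      meta[[length(meta) + 1L]] <- data.frame(
        contig_id = id, station = station,
        depth = depths[((i - 1L) %% length(depths)) + 1L],
        size_fraction = "0.22-3", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        contig_id = id, station = station, is_lyase = TRUE,
        is_viral = is_viral, family = fam, start = start0, end = end0,
        strand = if (strand > 0) "+" else "-", frame = frame,
        peptide = pep, stringsAsFactors = FALSE)
    }
  }
  for (d in seq_len(decoy_contigs)) {
    cid <- cid + 1L
    station <- sprintf("ST%03d", ((d - 1L) %% n_stations) + 1L)
    id <- sprintf("%s_d%04d", station, cid)
    clen <- pick1(1200:2500)
    contigs[[id]] <- random_dna(clen)
    if (d %% 3L == 0L) {   # near-threshold hit that fails the cutoff
      ref <- pick1(refs$ref_id)
      lyase_hits <- rbind(lyase_hits, hit_row(
        id, ref, 35, 90L, 10L, 279L, 1L, 90L, 1e-8, 60))
    }
    meta[[length(meta) + 1L]] <- data.frame(
      contig_id = id, station = station,
      depth = depths[((d - 1L) %% length(depths)) + 1L],
      size_fraction = "0.22-3", stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      contig_id = id, station = station, is_lyase = FALSE,
      is_viral = FALSE, family = NA_character_, start = NA_integer_,
      end = NA_integer_, strand = NA_character_, frame = NA_integer_,
      peptide = NA_character_, stringsAsFactors = FALSE)
  }

  finalize_hits <- function(h, lens) {
    forward <- h$qstart <= h$qend
    h$contig_start <- ifelse(forward, h$qstart - 1L, h$qend - 1L)
    h$contig_end <- ifelse(forward, h$qend, h$qstart)
    L <- lens[h$qseqid]
    h$frame <- ifelse(forward, (h$contig_start %% 3L) + 1L,
                      -(((L - h$contig_end) %% 3L) + 1L))
    h
  }
  lens <- vapply(contigs, nchar, integer(1))
  list(contigs = contigs,
       contig_meta = do.call(rbind, meta),
       lyase_hits = finalize_hits(lyase_hits, lens),
       ncvog_hits = finalize_hits(ncvog_hits, lens),
       ref_lengths = stats::setNames(refs$length, refs$ref_id),
       ref_families = ref_families,
       references = refs,
       truth = do.call(rbind, truth))
}
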