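hitrow <- function(contig, ref, start0, end0, frame, bits = 500,
                   evalue = 1e-30) {
  data.frame(qseqid = contig, sseqid = ref, evalue = evalue,
             bitscore = bits, contig_start = start0, contig_end = end0,
             frame = frame, stringsAsFactors = FALSE)
}

test_that("lyase contig detection applies a strict e-value cutoff", {
  hits <- data.frame(qseqid = c("c1", "c2", "c3"), sseqid = "PL01",
                     evalue = c(1e-12, 1e-10, 1e-9),
                     stringsAsFactors = FALSE)
  expect_identical(find_lyase_contigs(hits), "c1")   # 1e-10 is not < 1e-10
  expect_identical(find_lyase_contigs(hits, evalue_max = 1e-9),
                   c("c1", "c2"))
})

test_that("viral calls pick the minimum-evalue NCVOG hit for family", {
  fams <- c(N1 = "Mimiviridae", N2 = "Phycodnaviridae")
  none <- call_viral("c1", data.frame(qseqid = character(0),
                                      sseqid = character(0),
                                      evalue = numeric(0),
                                      bitscore = numeric(0)), fams)
  expect_false(none$viral)
  expect_true(is.na(none$family))

  hits <- data.frame(qseqid = "c1", sseqid = c("N1", "N2"),
                     evalue = c(1e-30, 1e-20), bitscore = c(100, 200),
                     stringsAsFactors = FALSE)
  vc <- call_viral("c1", hits, fams)
  expect_true(vc$viral)
  expect_identical(vc$family, "Mimiviridae")
  expect_identical(vc$best_ncvog$ref_id, "N1")
  # boundary: exactly at the cutoff is excluded
  at <- data.frame(qseqid = "c1", sseqid = "N1", evalue = 1e-10,
                   bitscore = 50, stringsAsFactors = FALSE)
  expect_false(call_viral("c1", at, fams)$viral)
  # passing hit without family annotation errors by name
  expect_error(call_viral("c1", data.frame(qseqid = "c1", sseqid = "NX",
                                           evalue = 1e-30, bitscore = 1),
                          fams), "NX")
})

test_that("excision translates planted codons on either strand", {
  pep <- "MKLV"
  orf <- reverse_translate(pep)
  contig <- paste0("GG", orf, "AACCT")
  loci <- excise_and_translate(contig, hitrow("c", "r", 2L, 2L + 12L, 3L))
  expect_length(loci, 1)
  expect_identical(loci[[1]]$peptide, pep)
  # same codons on the reverse strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  s <- nchar(contig) - (2L + 12L)
  loci_rc <- excise_and_translate(rc, hitrow("c", "r", s, s + 12L, -1L))
  expect_identical(loci_rc[[1]]$peptide, pep)
  expect_identical(loci_rc[[1]]$strand, "-")
})

test_that("overlapping same-strand hits merge into one trimmed region", {
  set.seed(3)
  contig <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                  collapse = "")
  hits <- rbind(hitrow("c", "r1", 0L, 30L, 1L, bits = 900),
                hitrow("c", "r2", 18L, 60L, 1L, bits = 400))
  loci <- excise_and_translate(contig, hits)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$start, 0)
  expect_equal(loci[[1]]$end, 60)
  expect_identical(nchar(loci[[1]]$peptide), 20L)
  # non-overlapping hits stay separate loci
  apart <- rbind(hitrow("c", "r1", 0L, 30L, 1L),
                 hitrow("c", "r2", 45L, 75L, 1L))
  expect_length(excise_and_translate(contig, apart), 2)
  # conflicting frames: dominant wins with a warning
  conflict <- rbind(hitrow("c", "r1", 0L, 30L, 1L, bits = 900),
                    hitrow("c", "r2", 10L, 40L, 2L, bits = 100))
  expect_warning(loci <- excise_and_translate(contig, conflict),
                 "conflicting")
  expect_identical(loci[[1]]$frame, 1L)
})

test_that("length filter is strict and monotone", {
  expect_true(length_filter(strrep("A", 241), 300))
  expect_false(length_filter(strrep("A", 240), 300))
  expect_true(length_filter("A", c(300, 500), fraction = 0))
  expect_error(length_filter("AAA", numeric(0)), "empty")
  # monotone in peptide length, anti-monotone in fraction
  lens <- c(100, 150, 200, 240, 241, 300)
  passes <- vapply(lens, function(l) length_filter(l, 300), logical(1))
  expect_true(all(diff(passes) >= 0))
  fr <- c(0.2, 0.5, 0.8, 0.95)
  passes_f <- vapply(fr, function(f) length_filter(200, 300, f),
                     logical(1))
  expect_true(all(diff(passes_f) <= 0))
})

test_that("screen recovers planted truth perfectly on a synthetic metagenome", {
  mg <- simulate_metagenome(n_stations = 3, lyase_contigs_per_station = 10,
                            viral_fraction = 0.2, decoy_contigs = 30,
                            seed = 77)
  calls <- screen_contigs(mg$contigs, mg$lyase_hits, mg$ncvog_hits,
                          mg$ref_lengths, mg$ref_families,
                          contig_meta = mg$contig_meta)
  truth <- mg$truth
  # lyase call: sensitivity and specificity 1
  expect_setequal(calls$contig_id, truth$contig_id[truth$is_lyase])
  # viral call and family assignment match planted truth
  tl <- truth[match(calls$contig_id, truth$contig_id), ]
  expect_identical(calls$viral, tl$is_viral)
  expect_identical(calls$assigned_family, tl$family)
  # excised peptides equal planted peptides
  expect_identical(calls$peptide, tl$peptide)
  expect_identical(calls$strand, tl$strand)
  # screening is order-independent
  perm <- sample(nrow(mg$lyase_hits))
  calls2 <- screen_contigs(mg$contigs, mg$lyase_hits[perm, ],
                           mg$ncvog_hits, mg$ref_lengths,
                           mg$ref_families,
                           contig_meta = mg$contig_meta)
  expect_equal(calls, calls2)
})

test_that("station summaries pool depths and report viral percentages", {
  calls <- data.frame(
    contig_id = paste0("c", 1:10), station = "ST1",
    viral = c(rep(TRUE, 2), rep(FALSE, 8)),
    assigned_family = c("Mimiviridae", "Phycodnaviridae", rep(NA, 8)),
    stringsAsFactors = FALSE)
  s <- station_summaries(calls)
  expect_equal(s$percent_viral, 20)
  expect_identical(s$viral_lyase_contigs, 2L)
  fams <- attr(s, "families")
  expect_identical(nrow(fams), 2L)
  # a station with no viral contigs is still reported at 0 percent
  calls$viral <- FALSE
  calls$assigned_family <- NA_character_
  s0 <- station_summaries(calls)
  expect_equal(s0$percent_viral, 0)
  expect_identical(s0$total_lyase_contigs, 10L)
})

test_that("RPKM normalization scales as expected", {
  expect_equal(normalize_counts(1000, 1000, 1e6), 1000)
  expect_equal(normalize_counts(0, 1000, 1e6), 0)
  expect_equal(normalize_counts(500, 800, 2e6),
               normalize_counts(500, 800, 1e6) / 2)
  expect_error(normalize_counts(10, 0, 1e6), "positive")
})

test_that("group comparison reduces to classical one-way ANOVA", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- group_comparison(g)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  # two groups: F equals t^2 from the pooled-variance t test
  set.seed(6)
  x <- rnorm(8); y <- rnorm(8, 1)
  res2 <- group_comparison(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$f_statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)
  expect_identical(nrow(res2$tukey), 1L)
  expect_error(group_comparison(list(a = 1:3)), "groups")
})

test_that("null rejection rate of the ANOVA is near the nominal level", {
  set.seed(12)
  rej <- mean(replicate(1000, {
    g <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
    group_comparison(g)$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("placement-query export writes filtered viral peptides", {
  mg <- simulate_metagenome(seed = 13, decoy_contigs = 5)
  calls <- screen_contigs(mg$contigs, mg$lyase_hits, mg$ncvog_hits,
                          mg$ref_lengths, mg$ref_families,
                          contig_meta = mg$contig_meta)
  path <- tempfile(fileext = ".fasta")
  n <- export_placement_queries(calls, path)
  expect_identical(n, sum(calls$viral & calls$passes_length_filter))
  fa <- read_fasta(path)
  expect_identical(nrow(fa), n)
  expect_true(all(grepl("\\|", fa$id)))
  # zero passing records still writes a valid (empty) file
  none <- calls[calls$viral & FALSE, ]
  path0 <- tempfile(fileext = ".fasta")
  expect_identical(export_placement_queries(none, path0), 0L)
  expect_identical(nrow(read_fasta(path0)), 0L)
})
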