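# Reference data for the AaV packaged proteome: the 43 virus-encoded
# proteins detected in purified particles, with their functional category,
# genome region, transcriptome first-detection label, and the number of
# proteomic runs each was found in.

#' The 43 proteins packaged within the AaV particle
#'
#' Reference table of the virus-encoded proteins detected by shotgun
#' proteomics of purified Aureococcus anophagefferens Virus particles.
#' Regions are thirds of the linear 371-kbp genome (`TerminalA`,
#' `Central`, `TerminalB`); `samples_found_in` is the number of the three
#' biological-replicate runs the protein was detected in;
#' `first_detection` is the infection time point at which the encoding
#' gene's transcript was first observed.
#'
#' @return A `data.frame` with columns `protein_id` (AaV gene number),
#'   `accession`, `category`, `region`, `first_detection`,
#'   `samples_found_in`, `origin` (all `"virus"`).
#' @examples
#' nrow(aav_packaged_proteins())  # 43
#' @export
aav_packaged_proteins <- function() {
  rec <- function(id, acc, cat, reg, fd, n) {
    data.frame(protein_id = id, accession = acc, category = cat,
               region = reg, first_detection = fd,
               samples_found_in = n, origin = "virus",
               stringsAsFactors = FALSE)
  }
  rows <- list(
    rec("AaV_096", "YP_009052173", "Structural",     "TerminalA", "5 min",  3L),
    rec("AaV_247", "YP_009052321", "Structural",     "Central",   "12 h",   1L),
    rec("AaV_174", "YP_009052248", "Transcription",  "Central",   "6 h",    1L),
    rec("AaV_180", "YP_009052254", "Transcription",  "Central",   "12 h",   1L),
    rec("AaV_211", "YP_009052285", "Transcription",  "Central",   "5 min",  1L),
    rec("AaV_222", "YP_009052296", "Transcription",  "Central",   "12 h",   1L),
    rec("AaV_242", "YP_009052316", "Transcription",  "Central",   "6 h",    1L),
    rec("AaV_269", "YP_009052343", "Transcription",  "TerminalB", "5 min",  1L),
    rec("AaV_038", "YP_009052116", "Polysaccharide", "TerminalA", "6 h",    3L),
    rec("AaV_024", "YP_009052102", "Polysaccharide", "TerminalA", "5 min",  3L),
    rec("AaV_078", "YP_009052156", "Polysaccharide", "TerminalA", "5 min",  2L),
    rec("AaV_274", "YP_009052348", "Polysaccharide", "TerminalB", "5 min",  1L),
    rec("AaV_276", "YP_009052350", "Polysaccharide", "TerminalB", "6 h",    3L),
    rec("AaV_386", "YP_009052454", "Polysaccharide", "TerminalB", "12 h",   3L),
    rec("AaV_314", "YP_009052388", "Polysaccharide", "TerminalB", "6 h",    3L),
    rec("AaV_158", "YP_009052233", "Other",          "Central",   "12 h",   2L),
    rec("AaV_281", "YP_009052355", "Other",          "TerminalB", "12 h",   1L),
    rec("AaV_306", "YP_009052380", "Other",          "TerminalB", "5 min",  1L),
    rec("AaV_052", "YP_009052130", "Hypothetical",   "TerminalA", "5 min",  3L),
    rec("AaV_062", "YP_009052140", "Hypothetical",   "TerminalA", "5 min",  3L),
    rec("AaV_074", "YP_009052152", "Hypothetical",   "TerminalA", "12 h",   1L),
    rec("AaV_080", "YP_009052158", "Hypothetical",   "TerminalA", "5 min",  3L),
    rec("AaV_081", "YP_009052159", "Hypothetical",   "TerminalA", "1 h",    1L),
    rec("AaV_091", "YP_009052169", "Hypothetical",   "TerminalA", "5 min",  2L),
    rec("AaV_103", "YP_009052180", "Hypothetical",   "TerminalA", "1 h",    1L),
    rec("AaV_107", "YP_009052184", "Hypothetical",   "TerminalA", "5 min",  1L),
    rec("AaV_136", "YP_009052212", "Hypothetical",   "Central",   "12 h",   3L),
    rec("AaV_144", "YP_009052220", "Hypothetical",   "Central",   "30 min", 1L),
    rec("AaV_166", "YP_009052241", "Hypothetical",   "Central",   "12 h",   1L),
    rec("AaV_175", "YP_009052249", "Hypothetical",   "Central",   "30 min", 3L),
    rec("AaV_182", "YP_009052256", "Hypothetical",   "Central",   "12 h",   1L),
    rec("AaV_214", "YP_009052288", "Hypothetical",   "Central",   "30 min", 3L),
    rec("AaV_225", "YP_009052299", "Hypothetical",   "Central",   "5 min",  2L),
    rec("AaV_231", "YP_009052305", "Hypothetical",   "Central",   "21 h",   3L),
    rec("AaV_232", "YP_009052306", "Hypothetical",   "Central",   "1 h",    3L),
    rec("AaV_250", "YP_009052324", "Hypothetical",   "Central",   "12 h",   1L),
    rec("AaV_260", "YP_009052334", "Hypothetical",   "Central",   "30 min", 1L),
    rec("AaV_279", "YP_009052353", "Hypothetical",   "TerminalB", "12 h",   1L),
    rec("AaV_286", "YP_009052360", "Hypothetical",   "TerminalB", "5 min",  1L),
    rec("AaV_304", "YP_009052378", "Hypothetical",   "TerminalB", "5 min",  1L),
    rec("AaV_328", "YP_009052402", "Hypothetical",   "TerminalB", "12 h",   1L),
    rec("AaV_329", "YP_009052403", "Hypothetical",   "TerminalB", "5 min",  1L),
    rec("AaV_382", "YP_009052450", "Hypothetical",   "TerminalB", "5 h",    1L)
  )
  do.call(rbind, rows)
}

#' Build a detection-pattern intensity table from per-protein run counts
#'
#' Expands a metadata table carrying a `samples_found_in` column into an
#' [intensity_table] with unit intensities in the first n of
#' `n_replicates` runs and missing values elsewhere. Only detection
#' patterns (not magnitudes) are meaningful in the result; it exists so
#' detection, region, and category summaries can be run on reference
#' tables that record counts rather than raw intensities.
#'
#' @param meta `data.frame` with `protein_id` and `samples_found_in`
#'   columns (e.g. [aav_packaged_proteins()]).
#' @param n_replicates Total number of replicate runs.
#' @return An [intensity_table].
#' @export
detection_table <- function(meta, n_replicates = 3L) {
  stopifnot(is.data.frame(meta),
            all(c("protein_id", "samples_found_in") %in% names(meta)),
            all(meta$samples_found_in <= n_replicates))
  m <- matrix(NA_real_, nrow = nrow(meta), ncol = n_replicates,
              dimnames = list(meta$protein_id,
                              paste0("run", seq_len(n_replicates))))
  for (i in seq_len(nrow(meta))) {
    n <- meta$samples_found_in[i]
    if (n > 0) m[i, seq_len(n)] <- 1
  }
  intensity_table(m, meta)
}
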