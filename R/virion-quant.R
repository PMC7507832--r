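# MCP-anchored per-virion quantification of label-free MS1 intensities.
#
# The capsid reconstruction fixes the number of major capsid protein (MCP)
# copies per particle; scaling every protein's MS1 intensity by the ratio
# of the anchor's known copy number to the anchor's intensity in the same
# replicate converts intensities to copies-per-particle. Missingness is
# carried explicitly: no imputation is performed.

#' Construct a label-free intensity table
#'
#' @param intensities Numeric matrix, proteins in rows (rownames =
#'   protein ids) and replicate runs in columns (colnames = replicate
#'   ids); `NA` marks a protein not detected in that run. All present
#'   values must be `>= 0`.
#' @param meta Optional per-protein metadata `data.frame` with columns
#'   `protein_id` and any of `origin` ("virus"/"host"),
#'   `category` (e.g. Structural, Transcription, Polysaccharide, Other,
#'   Hypothetical), `region` (genome region label), `first_detection`
#'   (pass-through transcriptome label). Rows are matched to the matrix by
#'   `protein_id`.
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(intensities, meta = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (ncol(intensities) < 1L) {
    stop("at least one replicate column is required", call. = FALSE)
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must have protein rownames and replicate colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(intensities))) {
    stop("duplicate protein ids in intensity matrix", call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative where present", call. = FALSE)
  }
  if (!is.null(meta)) {
    if (!is.data.frame(meta) || !"protein_id" %in% names(meta)) {
      stop("meta must be a data.frame with a protein_id column",
           call. = FALSE)
    }
    missing_meta <- setdiff(rownames(intensities), meta$protein_id)
    if (length(missing_meta)) {
      stop("meta lacks rows for: ", paste(missing_meta, collapse = ", "),
           call. = FALSE)
    }
    meta <- meta[match(rownames(intensities), meta$protein_id), ,
                 drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(intensities = intensities, meta = meta),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d replicates (%s metadata)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (is.null(x$meta)) "no" else "with"))
  invisible(x)
}

meta_column <- function(table, column, default = NULL) {
  if (!is.null(table$meta) && column %in% names(table$meta)) {
    return(table$meta[[column]])
  }
  default
}

virus_mask <- function(table) {
  origin <- meta_column(table, "origin")
  if (is.null(origin)) rep(TRUE, nrow(table$intensities)) else origin == "virus"
}

#' Coefficient of variation, percent
#'
#' Sample standard deviation (`n - 1` denominator) over the mean, times
#' 100, after dropping missing values. Undefined (`NA`) with fewer than two
#' observed values or a non-positive mean.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return A percentage, or `NA_real_` when undefined.
#' @examples
#' cv_percent(c(10, 20, 30))  # 50
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Convert MS1 intensities to copies-per-particle via a structural anchor
#'
#' For every protein i and replicate r in which both i and the anchor are
#' detected, `copies(i, r) = anchor_copies * I(i, r) / I(anchor, r)`.
#' Per-protein estimates are then the arithmetic mean over the replicates
#' where the protein was detected, with dispersion reported as the
#' percent coefficient of variation ([cv_percent]). Replicates in which the
#' anchor itself is undetected carry no usable scale and are excluded with
#' a warning. Host proteins are additionally flagged via
#' [flag_putative_contaminants].
#'
#' @param table An [intensity_table].
#' @param anchor_id Protein id of the anchor (the MCP).
#' @param anchor_copies Structurally determined copies of the anchor per
#'   particle (5040 for a T = 169 capsid); integer `>= 1`.
#' @param cv_threshold Percent CV below which a host protein detected in
#'   every replicate is considered possibly packaged rather than a
#'   putative contaminant.
#' @return An object of class `particle_proteome`: a list with
#'   `anchor_id`, `anchor_copies`, `copies` (matrix of per-replicate
#'   copies), `estimates` (data.frame with `protein_id`, `mean_copies`,
#'   `cv_percent`, `n_detected`, and for host proteins `flag`), and
#'   `host_flags` (named character vector).
#' @examples
#' m <- matrix(c(1e6, 500, 1e6, 450), nrow = 2,
#'             dimnames = list(c("MCP", "p1"), c("r1", "r2")))
#' pp <- normalize_to_anchor(intensity_table(m), "MCP", 5040)
#' pp$estimates
#' @export
normalize_to_anchor <- function(table, anchor_id, anchor_copies = 5040L,
                                cv_threshold = 36) {
  stopifnot(inherits(table, "intensity_table"))
  if (length(anchor_copies) != 1L || is.na(anchor_copies) ||
      anchor_copies < 1) {
    stop("anchor_copies must be a single value >= 1", call. = FALSE)
  }
  intens <- table$intensities
  if (!anchor_id %in% rownames(intens)) {
    stop("anchor protein '", anchor_id, "' not present in table",
         call. = FALSE)
  }
  anchor_row <- intens[anchor_id, ]
  if (all(is.na(anchor_row))) {
    stop("anchor protein '", anchor_id,
         "' is not detected in any replicate", call. = FALSE)
  }
  if (any(anchor_row == 0, na.rm = TRUE)) {
    stop("invalid anchor: zero intensity for '", anchor_id,
         "' in replicate ",
         paste(colnames(intens)[which(anchor_row == 0)], collapse = ", "),
         call. = FALSE)
  }
  usable <- !is.na(anchor_row)
  if (!all(usable)) {
    warning("anchor undetected in replicate(s) ",
            paste(colnames(intens)[!usable], collapse = ", "),
            "; excluded from all per-replicate estimates", call. = FALSE)
  }
  intens <- intens[, usable, drop = FALSE]
  anchor_row <- anchor_row[usable]
  copies <- sweep(intens, 2L, anchor_row, `/`) * anchor_copies

  n_detected <- rowSums(!is.na(copies))
  mean_copies <- ifelse(n_detected > 0, rowMeans(copies, na.rm = TRUE),
                        NA_real_)
  cvs <- apply(copies, 1L, cv_percent)
  estimates <- data.frame(
    protein_id = rownames(copies),
    mean_copies = unname(mean_copies),
    cv_percent = unname(cvs),
    n_detected = unname(as.integer(n_detected)),
    stringsAsFactors = FALSE
  )

  origin <- meta_column(table, "origin")
  host_flags <- character(0)
  if (!is.null(origin)) {
    host_idx <- which(origin == "host")
    if (length(host_idx)) {
      host_flags <- flag_putative_contaminants(
        estimates[host_idx, , drop = FALSE],
        n_replicates = ncol(copies),
        cv_threshold_percent = cv_threshold)
    }
    estimates$flag <- NA_character_
    estimates$flag[host_idx] <- unname(host_flags[
      estimates$protein_id[host_idx]])
  }

  structure(list(
    anchor_id = anchor_id,
    anchor_copies = anchor_copies,
    copies = copies,
    estimates = estimates,
    host_flags = host_flags,
    meta = table$meta
  ), class = "particle_proteome")
}

#' @export
print.particle_proteome <- function(x, ...) {
  cat(sprintf(
    "particle_proteome: %d proteins anchored to %s (%d copies/particle)\n",
    nrow(x$estimates), x$anchor_id, x$anchor_copies))
  cat(sprintf("  replicates used: %d\n", ncol(x$copies)))
  invisible(x)
}

#' @export
summary.particle_proteome <- function(object, ...) {
  est <- object$estimates
  cat(sprintf("Per-particle proteome anchored to %s = %d copies\n",
              object$anchor_id, object$anchor_copies))
  cat(sprintf("  proteins detected (>= 1 replicate): %d\n",
              sum(est$n_detected > 0)))
  cat(sprintf("  detected in all %d replicates: %d\n",
              ncol(object$copies),
              sum(est$n_detected == ncol(object$copies))))
  cat(sprintf("  median copies/particle: %.1f\n",
              stats::median(est$mean_copies, na.rm = TRUE)))
  if (length(object$host_flags)) {
    cat("  host-protein flags:\n")
    print(table(object$host_flags))
  }
  invisible(est)
}

#' Summarize in how many replicates each protein was detected
#'
#' @param table An [intensity_table].
#' @return A list with `counts` (named integer vector: number of proteins
#'   detected in exactly n replicates, for n >= 1) and `total` (proteins
#'   detected in at least one replicate).
#' @export
detection_summary <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  n_det <- rowSums(!is.na(table$intensities))
  n_det <- n_det[n_det > 0]
  counts <- table(factor(n_det, levels = seq_len(ncol(table$intensities))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, total = length(n_det))
}

#' Tabulate virus proteins by genome region
#'
#' @param table An [intensity_table] whose metadata carries a `region`
#'   label for every virus protein.
#' @param regions Allowed region labels.
#' @return Named integer vector of counts per region (in `regions` order).
#' @export
region_tabulation <- function(table,
                              regions = c("TerminalA", "Central",
                                          "TerminalB")) {
  stopifnot(inherits(table, "intensity_table"))
  region <- meta_column(table, "region")
  if (is.null(region)) stop("no region metadata present", call. = FALSE)
  keep <- virus_mask(table)
  region <- region[keep]
  ids <- rownames(table$intensities)[keep]
  bad <- which(is.na(region) | !region %in% regions)
  if (length(bad)) {
    stop("unknown genome region '", region[bad[1L]], "' for protein ",
         ids[bad[1L]], call. = FALSE)
  }
  counts <- table(factor(region, levels = regions))
  stats::setNames(as.integer(counts), regions)
}

# Round half away from zero, the convention used for reported percentages
# (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Percentage of virus proteins in a functional category
#'
#' @param table An [intensity_table] with `category` metadata.
#' @param category Category label to count.
#' @return Integer percent, rounded half-up; `NA` for an empty table.
#' @export
category_fraction <- function(table, category) {
  stopifnot(inherits(table, "intensity_table"))
  cats <- meta_column(table, "category")
  if (is.null(cats)) stop("no category metadata present", call. = FALSE)
  cats <- cats[virus_mask(table)]
  if (!length(cats)) return(NA_real_)
  round_half_up(100 * sum(cats == category) / length(cats))
}

#' Flag host proteins as putative contaminants or possibly packaged
#'
#' A host protein detected in all replicates with a CV below the threshold
#' behaves like a consistently co-purifying (hence possibly packaged)
#' component; one detected in all replicates with high dispersion is a
#' putative contaminant; fewer than all replicates is insufficient
#' evidence either way.
#'
#' @param estimates `data.frame` with columns `protein_id`, `cv_percent`,
#'   `n_detected` (as produced by [normalize_to_anchor]).
#' @param n_replicates Number of replicates in the experiment.
#' @param cv_threshold_percent CV threshold (percent).
#' @return Named character vector: `"possibly packaged"`,
#'   `"putative contaminant"`, or `"insufficient evidence"`.
#' @export
flag_putative_contaminants <- function(estimates, n_replicates,
                                       cv_threshold_percent = 36) {
  flags <- ifelse(
    estimates$n_detected < n_replicates,
    "insufficient evidence",
    ifelse(!is.na(estimates$cv_percent) &
             estimates$cv_percent < cv_threshold_percent,
           "possibly packaged", "putative contaminant"))
  stats::setNames(flags, estimates$protein_id)
}
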