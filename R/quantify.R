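#' Reads per kilobase of transcript per million mapped reads
#'
#' Normalizes a raw read count to RPKM:
#' \deqn{RPKM = 10^9 \cdot C / (N \cdot L)}
#' where `C` is the mapped-read count for the transcript, `L` its length in
#' base pairs and `N` the total number of mapped reads in the library.
#'
#' @param read_count Non-negative integer vector of mapped reads per
#'   transcript.
#' @param length_bp Positive integer vector of transcript lengths (bp).
#' @param total_mapped Positive library size (total mapped reads); scalar or
#'   vector recycled against `read_count`.
#' @return Numeric vector of RPKM values.
#' @examples
#' compute_rpkm(1000, 1000, 1e6)  # 1000
#' compute_rpkm(250, 2000, 5e6)   # 25
#' @export
compute_rpkm <- function(read_count, length_bp, total_mapped) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1")
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  1e9 * as.double(read_count) / (as.double(total_mapped) * as.double(length_bp))
}

#' Add an RPKM column to a transcript count table
#'
#' @param counts Data frame with columns `transcript_id`, `length_bp`,
#'   `read_count` (and optionally `cluster_id`).
#' @param total_mapped Library size; `NULL` (default) uses the column sum of
#'   `read_count`.
#' @return The input with an `rpkm` column appended.
#' @export
quantify_counts <- function(counts, total_mapped = NULL) {
  req <- c("transcript_id", "length_bp", "read_count")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("counts table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(total_mapped)) total_mapped <- sum(counts$read_count)
  counts$rpkm <- compute_rpkm(counts$read_count, counts$length_bp,
                              total_mapped)
  counts
}

#' Filter transcripts below an expression cutoff
#'
#' Retains entries with RPKM strictly greater than `threshold`. The default
#' of 10 RPKM corresponds to roughly three transcript copies per cell and
#' separates physiologically relevant expression from leaky transcription.
#'
#' @param quants Data frame with an `rpkm` column.
#' @param threshold Strict lower RPKM bound (default 10).
#' @return The retained rows, input order preserved.
#' @export
apply_expression_cutoff <- function(quants, threshold = 10) {
  if (!"rpkm" %in% names(quants)) stop("quants must carry an rpkm column")
  quants[quants$rpkm > threshold, , drop = FALSE]
}

#' Abundance-category profile of a transcriptome
#'
#' Assigns each transcript to the highest abundance category whose lower
#' count limit does not exceed its read count, then reports the number of
#' distinct entries and the share of total transcript counts per category.
#' The top category is unbounded above.
#'
#' @param quants Data frame with a `read_count` column.
#' @param bin_lower_limits Strictly ascending numeric vector of category
#'   lower limits; the first limit must not exceed the smallest count of
#'   interest.
#' @return Data frame with columns `bin_lower`, `n_entries`, `count_share`;
#'   `count_share` sums to 1.
#' @export
abundance_profile <- function(quants, bin_lower_limits) {
  if (nrow(quants) == 0L) stop("empty input: no transcripts to profile")
  if (is.unsorted(bin_lower_limits, strictly = TRUE))
    stop("bin_lower_limits must be strictly ascending")
  cnt <- quants$read_count
  bin <- findInterval(cnt, bin_lower_limits)
  if (any(bin == 0L))
    stop("some counts fall below the first bin lower limit")
  n_entries <- tabulate(bin, nbins = length(bin_lower_limits))
  sums <- vapply(seq_along(bin_lower_limits),
                 function(b) sum(cnt[bin == b]), numeric(1))
  data.frame(bin_lower = bin_lower_limits,
             n_entries = n_entries,
             count_share = sums / sum(cnt))
}

#' Detection and dynamic-range summary
#'
#' A transcript is detected when at least one read maps to it. Minimum and
#' maximum RPKM are taken over detected entries only; dynamic range is
#' reported in orders of magnitude (log10 of max/min).
#'
#' @param quants Data frame with `read_count` and `rpkm` columns.
#' @return List with `n_detected`, `min_rpkm`, `max_rpkm`,
#'   `log10_dynamic_range`.
#' @export
expression_summary <- function(quants) {
  det <- quants[quants$read_count > 0, , drop = FALSE]
  if (nrow(det) == 0L) stop("no detected transcript (all read counts zero)")
  mn <- min(det$rpkm); mx <- max(det$rpkm)
  list(n_detected = nrow(det), min_rpkm = mn, max_rpkm = mx,
       log10_dynamic_range = log10(mx / mn))
}

#' Percentage of a reference catalogue detected in a library
#'
#' @param n_detected Number of reference entries with at least one mapped
#'   read.
#' @param n_reference Size of the reference catalogue.
#' @return Percentage (0-100).
#' @export
detected_percent <- function(n_detected, n_reference) {
  if (n_reference < 1) stop("n_reference must be >= 1")
  100 * n_detected / n_reference
}
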