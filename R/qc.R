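#' Cohort mean and standard deviation of per-sample sequencing statistics
#'
#' Summarises a table of per-sample sequencing metrics (read counts, aligned
#' and high-quality read percentages, mean depth, ...) by the arithmetic mean
#' and sample (n - 1) standard deviation of every numeric column, reported
#' at 2 decimals.
#'
#' Reporting convention: 2 decimals, with exact half-way ties at the final
#' decimal rounded toward zero (summaries of values that are themselves
#' printed at 2 decimals regularly produce such ties, and IEEE half-even
#' rounding would let the reported digit depend on floating-point dust).
#'
#' @param stats data frame with one row per sample; non-numeric columns
#'   (ids, sex, site labels) are ignored.
#' @return data frame with columns `field`, `mean`, `sd`.
#' @export
cohort_summary <- function(stats) {
  stats <- as.data.frame(stats)
  if (nrow(stats) < 2L) stop("cohort_summary needs at least 2 samples")
  num <- vapply(stats, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns to summarise")
  round2 <- function(x) {
    y <- abs(x) * 100
    up <- (y - floor(y)) > 0.5 + 1e-9
    sign(x) * (floor(y) + up) / 100
  }
  data.frame(
    field = names(stats)[num],
    mean = round2(vapply(stats[num], mean, numeric(1))),
    sd = round2(vapply(stats[num], stats::sd, numeric(1))),
    row.names = NULL
  )
}

#' Breadth of coverage at depth thresholds
#'
#' Counts bases whose depth clears each threshold. A threshold of 0 is read
#' as "strictly greater than 0x"; every other threshold as "at least t x".
#'
#' @param depths numeric vector of per-base (or per-window) depth values.
#' @param thresholds non-negative depth thresholds, sorted ascending.
#' @return data frame with columns `threshold`, `n_bases`, `fraction`
#'   (fraction of the assessed bases).
#' @export
breadth_of_coverage <- function(depths, thresholds) {
  if (any(thresholds < 0)) stop("thresholds must be non-negative")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  n <- vapply(thresholds, function(t) {
    if (t == 0) sum(depths > 0) else sum(depths >= t)
  }, numeric(1))
  data.frame(threshold = thresholds, n_bases = n,
             fraction = n / length(depths))
}

#' Mean depth in non-overlapping genomic windows
#'
#' Tiles a per-base depth track with fixed-size windows and reports the mean
#' depth of each; the trailing partial window is reported with its true
#' width. Window coordinates are 0-based half-open.
#'
#' @param depths per-base depth values of one chromosome, base 1 first.
#' @param window_size window width in bp, > 0.
#' @param chrom chromosome label for the output.
#' @return data frame with columns `chrom`, `start`, `end`, `mean_depth`.
#' @export
depth_per_window <- function(depths, window_size, chrom = "chr1") {
  if (window_size <= 0) stop("window_size must be positive")
  len <- length(depths)
  if (len == 0L) stop("empty depth track")
  start <- seq.int(0L, len - 1L, by = window_size)
  end <- pmin(start + window_size, len)
  grp <- rep(seq_along(start), times = end - start)
  data.frame(chrom = chrom, start = start, end = end,
             mean_depth = as.numeric(tapply(depths, grp, mean)),
             row.names = NULL)
}

#' Read a per-sample sequencing statistics table
#'
#' Thin TSV reader for the table consumed by [cohort_summary()]; numbers
#' with thousands separators ("1,234") are accepted.
#'
#' @param path TSV file with a header row.
#' @return data frame.
#' @export
read_sample_stats <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    if (is.character(x[[j]])) {
      v <- suppressWarnings(as.numeric(gsub(",", "", x[[j]], fixed = TRUE)))
      if (!anyNA(v)) x[[j]] <- v
    }
  }
  x
}
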