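#' Per-SNP Fst between two sample groups
#'
#' The default estimator is Weir & Cockerham's (1984) variance-component
#' estimator theta = a / (a + b + c) for two populations, computed per SNP
#' from sample sizes, allele frequencies and observed heterozygosities.
#' Negative estimates are reported as computed, never clipped. Hudson's
#' estimator (Bhatia et al. 2013 formulation) is available for sensitivity
#' analysis.
#'
#' Sites where either group has fewer than 2 samples with non-missing calls
#' are skipped (dropped from the output and counted in attribute
#' `n_skipped`). Sites that are monomorphic across both groups have a zero
#' denominator and yield `NaN`.
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b disjoint sample id (or index) vectors.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return data frame with columns `chrom`, `pos`, `fst`, and attribute
#'   `n_skipped`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
snp_fst <- function(gm, group_a, group_b, estimator = c("wc", "hudson")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  estimator <- match.arg(estimator)
  ia <- resolve_samples(gm, group_a)
  ib <- resolve_samples(gm, group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need at least 2 samples")
  }
  if (length(intersect(ia, ib))) stop("groups must be disjoint")

  ga <- gm$calls[ia, , drop = FALSE]
  gb <- gm$calls[ib, , drop = FALSE]
  n1 <- colSums(!is.na(ga))
  n2 <- colSums(!is.na(gb))
  ok <- n1 >= 2L & n2 >= 2L
  n_skipped <- sum(!ok)

  p1 <- colMeans(ga, na.rm = TRUE) / 2
  p2 <- colMeans(gb, na.rm = TRUE) / 2
  h1 <- colMeans(ga == 1L, na.rm = TRUE)
  h2 <- colMeans(gb == 1L, na.rm = TRUE)

  if (estimator == "wc") {
    comp <- wc_components(n1, n2, p1, p2, h1, h2)
    out <- data.frame(chrom = gm$chrom, pos = gm$pos,
                      fst = comp$a / comp$d, a = comp$a, d = comp$d)[ok, ]
  } else {
    fst <- hudson_fst(2 * n1, 2 * n2, p1, p2)
    out <- data.frame(chrom = gm$chrom, pos = gm$pos, fst = fst)[ok, ]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "estimator") <- estimator
  out
}

# Weir & Cockerham (1984), r = 2 populations, vectorised over sites.
# n1, n2: diploid sample sizes; p1, p2: alt-allele frequencies;
# h1, h2: observed heterozygote fractions.
wc_theta <- function(n1, n2, p1, p2, h1, h2) {
  comp <- wc_components(n1, n2, p1, p2, h1, h2)
  comp$a / comp$d
}

# among-population variance component (a) and total (a + b + c)
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, d = a + b + c)
}

# Hudson estimator per Bhatia et al. (2013); m1, m2 are allele counts.
hudson_fst <- function(m1, m2, p1, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

resolve_samples <- function(gm, grp) {
  if (is.logical(grp)) grp <- which(grp)
  if (is.character(grp)) {
    idx <- match(grp, gm$sample_ids)
    if (anyNA(idx)) stop("unknown sample id: ", grp[is.na(idx)][1])
    idx
  } else {
    as.integer(grp)
  }
}

#' Windowed mean Fst (mFst)
#'
#' Arithmetic mean of the per-SNP Fst estimates falling in each window
#' (the window statistic of a differentiation scan). Windows with fewer
#' usable SNPs than `spec$min_snps` carry `NA`. Windows with
#' `mfst > high_threshold` are flagged as highly differentiated.
#'
#' @param fst per-SNP table from [snp_fst()].
#' @param windows window table from [make_windows()].
#' @param spec the [window_spec()] used to build `windows`.
#' @param high_threshold flag threshold (default 0.9).
#' @param ratio_of_averages when TRUE, compute the window statistic as the
#'   ratio of the summed Weir-Cockerham variance components
#'   (`sum(a) / sum(a + b + c)`) instead of the mean of per-SNP ratios;
#'   requires a `fst` table produced with `estimator = "wc"`. The mean of
#'   per-SNP ratios is the primary definition.
#' @return data frame with columns `chrom`, `start`, `end`, `n_snps`,
#'   `mfst`, `high_fst`.
#' @export
window_mfst <- function(fst, windows, spec = window_spec(),
                        high_threshold = 0.9, ratio_of_averages = FALSE) {
  if (ratio_of_averages && !all(c("a", "d") %in% names(fst))) {
    stop("ratio-of-averages windowing needs the Weir-Cockerham components; ",
         "run snp_fst(..., estimator = \"wc\")")
  }
  usable <- is.finite(fst$fst)
  f <- fst[usable, , drop = FALSE]
  rng <- window_site_range(windows, f$chrom, f$pos)
  n_snps <- pmax(rng[, "last"] - rng[, "first"] + 1L, 0L)
  mfst <- if (ratio_of_averages) {
    window_sums(f$a, rng) / window_sums(f$d, rng)
  } else {
    ifelse(n_snps > 0, window_sums(f$fst, rng) / n_snps, NA_real_)
  }
  mfst[n_snps < spec$min_snps] <- NA_real_
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = n_snps, mfst = mfst,
             high_fst = !is.na(mfst) & mfst > high_threshold)
}

#' Genome-wide Fst from a per-SNP table
#'
#' Two conventions are supported. `"mean"` is the arithmetic mean of the
#' per-SNP ratio estimates, consistent with the windowed mFst statistic;
#' it carries a downward Jensen-type bias because the expectation of a
#' ratio is not the ratio of expectations (under a Balding-Nichols model
#' with F = 0.25 and 50+50 samples the bias is about -0.07). `"weighted"`
#' is the multi-locus Weir-Cockerham estimator - the ratio of the summed
#' among-population variance component to the summed total - which is the
#' standard genome-wide estimate and recovers the differentiation
#' parameter; it requires a table produced with `estimator = "wc"`.
#'
#' @param fst per-SNP table from [snp_fst()].
#' @param method `"mean"` or `"weighted"`.
#' @return a single Fst value.
#' @export
overall_fst <- function(fst, method = c("mean", "weighted")) {
  method <- match.arg(method)
  ok <- is.finite(fst$fst)
  if (method == "mean") {
    mean(fst$fst[ok])
  } else {
    if (!all(c("a", "d") %in% names(fst))) {
      stop("weighted overall Fst needs the Weir-Cockerham components")
    }
    sum(fst$a[ok]) / sum(fst$d[ok])
  }
}

#' One-call windowed Fst scan between two groups
#'
#' [snp_fst()] + [make_windows()] + [window_mfst()], plus the genome-wide
#' overall Fst defined, consistently with the window statistic, as the mean
#' of the per-SNP estimates.
#'
#' @inheritParams snp_fst
#' @param chrom_lengths named chromosome lengths; defaults as in
#'   [hp_scan()].
#' @param spec a [window_spec()].
#' @param high_threshold see [window_mfst()].
#' @return list of class `fst_scan` with elements `overall` (mean per-SNP
#'   Fst), `snp` (per-SNP table) and `windows` (mFst table).
#' @export
fst_scan <- function(gm, group_a, group_b, chrom_lengths = NULL,
                     spec = window_spec(), estimator = c("wc", "hudson"),
                     high_threshold = 0.9) {
  if (is.null(chrom_lengths)) chrom_lengths <- gm_chrom_lengths(gm)
  snp <- snp_fst(gm, group_a, group_b, estimator)
  w <- make_windows(chrom_lengths, spec)
  mf <- window_mfst(snp, w, spec, high_threshold)
  structure(list(overall = overall_fst(snp, "mean"),
                 overall_weighted = if (attr(snp, "estimator") == "wc")
                   overall_fst(snp, "weighted") else NA_real_,
                 snp = snp, windows = mf),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf("fst_scan: overall Fst (mean per-SNP) = %.4f\n", x$overall))
  cat("  SNPs used:", sum(is.finite(x$snp$fst)),
      "; windows:", nrow(x$windows),
      "; high-differentiation windows:", sum(x$windows$high_fst), "\n")
  invisible(x)
}
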