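#' Sliding-window specification
#'
#' Genome windows used by the heterozygosity and Fst scans: 0.5-Mb windows
#' advancing by half their size (50% overlap) by default.
#'
#' @param size window size in bp (default 500,000).
#' @param step distance between successive window starts in bp (default
#'   250,000); must satisfy `0 < step <= size`.
#' @param min_snps minimum SNPs for a window to carry a statistic
#'   (default 10); windows below the floor are kept in the output with an
#'   `NA` statistic.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(size = 5e5, step = 2.5e5, min_snps = 10L) {
  if (!(step > 0 && step <= size)) stop("need 0 < step <= size")
  if (min_snps < 0) stop("min_snps must be >= 0")
  structure(list(size = size, step = step, min_snps = as.integer(min_snps)),
            class = "window_spec")
}

#' Enumerate sliding windows over chromosomes
#'
#' Windows start at 0-based offsets 0, step, 2*step, ... on each chromosome;
#' each is half-open `[start, start + size)` clipped at the chromosome end,
#' and a window is emitted iff its start lies inside the chromosome.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param spec a [window_spec()].
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
make_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), length(chrom_lengths) > 0,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq.int(0, len - 1, by = spec$step)
    start <- start[start < len]
    data.frame(chrom = ch, start = start,
               end = pmin(start + spec$size, len))
  })
  do.call(rbind, out)
}

# index SNPs into windows: returns per-window first/last index into the
# chromosome-sorted position vector (0 count when none)
window_site_range <- function(windows, chrom, pos) {
  first <- integer(nrow(windows))
  last <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(chrom == ch)
    p0 <- pos[si] - 1   # 1-based position -> 0-based offset
    # first site with p0 >= start, last with p0 < end
    first[wi] <- si[1] - 1 + findInterval(windows$start[wi] - 0.5, p0) + 1
    last[wi] <- si[1] - 1 + findInterval(windows$end[wi] - 0.5, p0)
    none <- last[wi] < first[wi]
    first[wi][none] <- 1L
    last[wi][none] <- 0L
    if (!length(si)) {
      first[wi] <- 1L
      last[wi] <- 0L
    }
  }
  cbind(first = first, last = last)
}

# per-window sums of a per-site vector via a zero-padded cumulative sum
window_sums <- function(v, rng) {
  cs <- c(0, cumsum(v))
  out <- cs[rng[, "last"] + 1L] - cs[rng[, "first"]]
  out[rng[, "last"] < rng[, "first"]] <- 0
  out
}

#' Windowed pooled heterozygosity (Hp)
#'
#' For every SNP the major allele is whichever of ref/alt is more frequent
#' among non-missing calls (ties break to ref); allele counts are
#' `2 * homozygotes + heterozygotes`. Per window the counts are summed over
#' SNPs and pooled heterozygosity is
#' `Hp = 2 * sum_maj * sum_min / (sum_maj + sum_min)^2`,
#' which lies in [0, 0.5]. Windows with fewer than `spec$min_snps` SNPs (or
#' zero total allele count) carry `NA`.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param windows window table from [make_windows()].
#' @param spec the [window_spec()] used to build `windows`.
#' @param samples optional sample subset (ids or indices).
#' @return data frame with columns `chrom`, `start`, `end`, `n_snps`,
#'   `sum_maj`, `sum_min`, `hp` (and `zhp`, `outlier` after
#'   [normalize_hp()]).
#' @export
pooled_het <- function(gm, windows, spec = window_spec(), samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ac <- allele_counts(gm, samples)
  n_maj <- pmax(ac["ref", ], ac["alt", ])
  n_min <- pmin(ac["ref", ], ac["alt", ])

  rng <- window_site_range(windows, gm$chrom, gm$pos)
  sum_maj <- window_sums(as.numeric(n_maj), rng)
  sum_min <- window_sums(as.numeric(n_min), rng)
  n_snps <- pmax(rng[, "last"] - rng[, "first"] + 1L, 0L)

  tot <- sum_maj + sum_min
  hp <- ifelse(tot > 0, 2 * sum_maj * sum_min / tot^2, NA_real_)
  hp[n_snps < spec$min_snps] <- NA_real_
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = n_snps,
             sum_maj = sum_maj, sum_min = sum_min, hp = hp)
}

#' Standardise window Hp into ZHp
#'
#' `ZHp = (Hp - mu_Hp) / sigma_Hp`, where the mean and sample (n - 1)
#' standard deviation are taken genome-wide over all windows with a defined
#' Hp. Windows with `|ZHp| > 3` are flagged as outliers.
#'
#' @param het window table from [pooled_het()].
#' @param outlier_z absolute ZHp above which a window is flagged
#'   (default 3).
#' @return `het` with `zhp` and `outlier` columns added, and attributes
#'   `mu_hp` / `sigma_hp` recording the normalisation.
#' @export
normalize_hp <- function(het, outlier_z = 3) {
  ok <- !is.na(het$hp)
  if (sum(ok) < 2L) stop("need at least 2 windows with defined Hp")
  mu <- mean(het$hp[ok])
  sigma <- stats::sd(het$hp[ok])
  if (sigma == 0) stop("all window Hp values are identical; ZHp undefined")
  het$zhp <- (het$hp - mu) / sigma
  het$outlier <- !is.na(het$zhp) & abs(het$zhp) > outlier_z
  attr(het, "mu_hp") <- mu
  attr(het, "sigma_hp") <- sigma
  het
}

#' One-call pooled-heterozygosity scan
#'
#' Convenience wrapper: [make_windows()] + [pooled_het()] + [normalize_hp()].
#'
#' @inheritParams pooled_het
#' @param chrom_lengths named chromosome lengths; defaults to the
#'   `chrom_lengths` attribute of `gm` (set by the simulator), else the
#'   largest observed position per chromosome.
#' @param spec a [window_spec()].
#' @return see [normalize_hp()].
#' @export
hp_scan <- function(gm, chrom_lengths = NULL, spec = window_spec(),
                    samples = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- gm_chrom_lengths(gm)
  w <- make_windows(chrom_lengths, spec)
  normalize_hp(pooled_het(gm, w, spec, samples))
}

gm_chrom_lengths <- function(gm) {
  cl <- attr(gm, "chrom_lengths")
  if (!is.null(cl)) return(cl)
  vapply(split(gm$pos, gm$chrom)[unique(gm$chrom)], max, numeric(1))
}
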