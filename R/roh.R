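#' Runs-of-homozygosity detection configuration
#'
#' Parameters of the SNP-scanning-window ROH caller. The stringency grid of
#' interest varies `window_snps` over {5, 10, 20} and `max_het_per_window`
#' over {1, 2, 3}; segments must span at least 1 Mb with no inter-SNP gap
#' above 500 kb.
#'
#' @param window_snps SNPs per scanning window (default 20).
#' @param max_het_per_window heterozygous calls tolerated per scanning
#'   window (default 3); must be smaller than `window_snps`.
#' @param min_length minimum reported segment span in bp (default 1e6).
#' @param max_gap maximum inter-SNP gap inside a segment in bp
#'   (default 5e5).
#' @param hit_fraction fraction of covering scanning windows that must be
#'   homozygous-compatible for a SNP to be run-eligible (default 0.05).
#' @param min_snps_per_segment minimum SNPs in a reported segment
#'   (default 25).
#' @param max_missing_per_window missing calls tolerated per scanning
#'   window (default 5).
#' @return list of class `roh_config`.
#' @export
roh_config <- function(window_snps = 20L, max_het_per_window = 3L,
                       min_length = 1e6, max_gap = 5e5,
                       hit_fraction = 0.05, min_snps_per_segment = 25L,
                       max_missing_per_window = 5L) {
  if (!(window_snps > max_het_per_window && max_het_per_window >= 0)) {
    stop("need window_snps > max_het_per_window >= 0")
  }
  if (min_length <= 0 || max_gap <= 0) {
    stop("min_length and max_gap must be positive")
  }
  if (!(hit_fraction > 0 && hit_fraction <= 1)) {
    stop("hit_fraction must be in (0, 1]")
  }
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 min_length = min_length, max_gap = max_gap,
                 hit_fraction = hit_fraction,
                 min_snps_per_segment = as.integer(min_snps_per_segment),
                 max_missing_per_window = as.integer(max_missing_per_window)),
            class = "roh_config")
}

#' Detect runs of homozygosity for one sample
#'
#' Scanning windows of `window_snps` consecutive SNPs slide one SNP at a
#' time along each chromosome. A window is homozygous-compatible iff it
#' holds at most `max_het_per_window` heterozygous and at most
#' `max_missing_per_window` missing calls. Each SNP scores the fraction of
#' covering windows that are compatible; SNPs at or above `hit_fraction`
#' are run-eligible. Maximal stretches of consecutive run-eligible SNPs are
#' split wherever adjacent SNPs lie more than `max_gap` apart, and the
#' remaining candidates are reported when they span at least `min_length`
#' and contain at least `min_snps_per_segment` SNPs. Segment coordinates
#' are the outermost SNP positions, so length is SNP span.
#'
#' @param gm a [genotype_matrix()].
#' @param sample one sample id or index.
#' @param cfg a [roh_config()].
#' @return data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `length`, `n_snps`, `n_het`.
#' @export
detect_roh <- function(gm, sample, cfg = roh_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "roh_config"))
  si <- resolve_samples(gm, sample)
  if (length(si) != 1L) stop("detect_roh handles one sample at a time")
  sid <- gm$sample_ids[si]
  calls <- gm$calls[si, ]

  segs <- list()
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    x <- calls[idx]
    p <- gm$pos[idx]
    m <- length(x)
    w <- cfg$window_snps
    if (m < w) {
      warning("chromosome ", ch, " has fewer SNPs (", m,
              ") than the scanning window (", w, "); no segments called")
      next
    }
    het <- as.integer(!is.na(x) & x == 1L)
    mis <- as.integer(is.na(x))
    chet <- c(0L, cumsum(het))
    cmis <- c(0L, cumsum(mis))
    nw <- m - w + 1L
    i <- seq_len(nw)
    compat <- (chet[i + w] - chet[i]) <= cfg$max_het_per_window &
      (cmis[i + w] - cmis[i]) <= cfg$max_missing_per_window

    # windows covering SNP j are those starting in [j - w + 1, j]
    ccomp <- c(0L, cumsum(as.integer(compat)))
    j <- seq_len(m)
    lo <- pmax(j - w + 1L, 1L)
    hi <- pmin(j, nw)
    n_cover <- hi - lo + 1L
    n_ok <- ccomp[hi + 1L] - ccomp[lo]
    eligible <- n_ok / n_cover >= cfg$hit_fraction

    segs[[ch]] <- candidate_segments(eligible, p, x, cfg, sid, ch)
  }
  out <- do.call(rbind, c(segs, list(empty_roh_table())))
  rownames(out) <- NULL
  out
}

# split eligible stretches at large gaps and apply segment-level filters
candidate_segments <- function(eligible, p, x, cfg, sid, ch) {
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- list()
  for (k in which(r$values)) {
    a <- starts[k]
    b <- ends[k]
    # split at gaps > max_gap
    cut <- which(diff(p[a:b]) > cfg$max_gap)
    bounds <- c(a - 1L, a - 1L + cut, b)
    for (q in seq_len(length(bounds) - 1L)) {
      s <- bounds[q] + 1L
      e <- bounds[q + 1L]
      span <- p[e] - p[s]
      n_snp <- e - s + 1L
      if (span >= cfg$min_length && n_snp >= cfg$min_snps_per_segment) {
        res[[length(res) + 1L]] <- data.frame(
          sample_id = sid, chrom = ch, start = p[s], end = p[e],
          length = span, n_snps = n_snp,
          n_het = sum(x[s:e] == 1L, na.rm = TRUE))
      }
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

empty_roh_table <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(), length = numeric(),
             n_snps = integer(), n_het = integer())
}

#' Froh genomic inbreeding coefficients
#'
#' Froh is the summed length of a sample's ROH segments divided by an
#' explicit denominator - the genome length assessed (e.g. assembly length
#' or the span covered by SNP data). The denominator is a required input
#' because the choice materially changes Froh and no convention is
#' universal.
#'
#' @param segments ROH table from [detect_roh()] (may hold several
#'   samples).
#' @param denominator genome length in bp, > 0.
#' @param samples optional full sample-id vector so that samples with zero
#'   segments appear with Froh 0; defaults to the samples present in
#'   `segments`.
#' @return data frame of class `froh_result` with columns `sample_id`,
#'   `n_segments`, `total_length`, `mean_length`, `denominator`, `froh`.
#' @export
froh <- function(segments, denominator, samples = NULL) {
  if (!is.numeric(denominator) || length(denominator) != 1 ||
      denominator <= 0) {
    stop("denominator must be a single positive length in bp")
  }
  if (is.null(samples)) samples <- unique(segments$sample_id)
  out <- do.call(rbind, lapply(samples, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    n <- nrow(seg)
    tot <- sum(seg$length)
    data.frame(sample_id = s, n_segments = n, total_length = tot,
               mean_length = if (n > 0) tot / n else 0,
               denominator = denominator, froh = tot / denominator)
  }))
  rownames(out) <- NULL
  class(out) <- c("froh_result", "data.frame")
  out
}

#' @export
print.froh_result <- function(x, ...) {
  y <- data.frame(sample_id = x$sample_id, n_segments = x$n_segments,
                  total_kb = sprintf("%.2f", x$total_length / 1000),
                  mean_kb = sprintf("%.2f", x$mean_length / 1000),
                  froh = sprintf("%.2f", x$froh))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' ROH stringency grid
#'
#' The nine caller configurations obtained by crossing scanning-window
#' sizes {5, 10, 20} SNPs with heterozygote allowances {1, 2, 3}; other
#' parameters are shared.
#'
#' @param window_snps,max_het vectors to cross.
#' @param ... further arguments passed to [roh_config()].
#' @return list of [roh_config()] objects named `"w<snps>_h<het>"`.
#' @export
roh_grid <- function(window_snps = c(5L, 10L, 20L), max_het = c(1L, 2L, 3L),
                     ...) {
  grid <- expand.grid(window_snps = window_snps, max_het = max_het)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    roh_config(window_snps = grid$window_snps[i],
               max_het_per_window = grid$max_het[i], ...)
  })
  names(out) <- sprintf("w%d_h%d", grid$window_snps, grid$max_het)
  out
}

#' Froh under a grid of ROH stringencies
#'
#' Runs [detect_roh()] + [froh()] for every configuration in the grid and
#' stacks the results; the (20 SNPs, 3 het) cell - the headline stringency -
#' is flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param grid list of [roh_config()]s, e.g. from [roh_grid()].
#' @param denominator see [froh()].
#' @param samples sample ids to analyse; defaults to all samples of `gm`.
#' @return data frame with columns `window_snps`, `max_het`, `headline`
#'   plus the [froh()] columns.
#' @export
stringency_sweep <- function(gm, grid = roh_grid(), denominator,
                             samples = NULL) {
  stopifnot(length(grid) >= 1)
  if (is.null(samples)) samples <- gm$sample_ids
  out <- lapply(grid, function(cfg) {
    segs <- do.call(rbind, c(lapply(samples, function(s) {
      detect_roh(gm, s, cfg)
    }), list(empty_roh_table())))
    fr <- froh(segs, denominator, samples = samples)
    cbind(window_snps = cfg$window_snps, max_het = cfg$max_het_per_window,
          headline = cfg$window_snps == 20L && cfg$max_het_per_window == 3L,
          as.data.frame(fr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
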