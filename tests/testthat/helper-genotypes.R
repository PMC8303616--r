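# builders and independent brute-force oracles used across the suite

# quick genotype matrix: calls is samples x variants (0/1/2/NA)
make_gm <- function(calls, pos = NULL, chrom = NULL, ref = NULL, alt = NULL,
                    qual = NULL, depth = NULL, sex = NULL, population = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  genotype_matrix(calls, chrom = chrom, pos = pos, ref = ref, alt = alt,
                  qual = qual, depth = depth, sex = sex,
                  population = population)
}

# genotype matrix reconstructed from the 47-marker sex-discordant fixture:
# the female homozygote is taken as REF, the extra male allele as ALT
sex_fixture_gm <- function(n_female = 6, n_male = 6) {
  tab <- read.delim(test_path_extdata("amh_sex_markers.tsv"))
  ref <- substr(tab$female_genotype, 1, 1)
  alt_candidates <- cbind(substr(tab$male_genotype, 1, 1),
                          substr(tab$male_genotype, 2, 2))
  alt <- ifelse(alt_candidates[, 1] != ref, alt_candidates[, 1],
                alt_candidates[, 2])
  m <- nrow(tab)
  calls <- rbind(matrix(0L, n_female, m), matrix(1L, n_male, m))
  genotype_matrix(calls, chrom = rep("chr8", m), pos = tab$pos,
                  ref = ref, alt = alt,
                  sex = rep(c("female", "male"), c(n_female, n_male)))
}

test_path_extdata <- function(file) {
  system.file("extdata", file, package = "popgenscan", mustWork = TRUE)
}

# brute-force sliding-window enumeration: loop every candidate start
bf_windows <- function(chrom_lengths, size, step) {
  out <- NULL
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    start <- 0
    while (start < len) {
      out <- rbind(out, data.frame(chrom = ch, start = start,
                                   end = min(start + size, len)))
      start <- start + step
    }
  }
  out
}

# direct scalar evaluation of the Weir & Cockerham (1984) two-population
# estimator from genotype count triples (n_hom_ref, n_het, n_hom_alt)
wc_fst_oracle <- function(counts_a, counts_b) {
  freqs <- function(cnt) {
    n <- sum(cnt)
    p <- (2 * cnt[3] + cnt[2]) / (2 * n)
    list(n = n, p = p, h = cnt[2] / n)
  }
  x <- freqs(counts_a)
  y <- freqs(counts_b)
  r <- 2
  nbar <- (x$n + y$n) / r
  nc <- (r * nbar - (x$n^2 + y$n^2) / (r * nbar)) / (r - 1)
  pbar <- (x$n * x$p + y$n * y$p) / (r * nbar)
  s2 <- (x$n * (x$p - pbar)^2 + y$n * (y$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (x$n * x$h + y$n * y$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# exhaustive ROH scanner: enumerate every scanning window and apply the
# rule set literally, plain loops throughout
bf_roh <- function(calls, pos, cfg, sample_id = "S", chrom = "chr1") {
  m <- length(calls)
  w <- cfg$window_snps
  if (m < w) return(NULL)
  nw <- m - w + 1
  compat <- logical(nw)
  for (i in seq_len(nw)) {
    win <- calls[i:(i + w - 1)]
    compat[i] <- sum(win == 1, na.rm = TRUE) <= cfg$max_het_per_window &&
      sum(is.na(win)) <= cfg$max_missing_per_window
  }
  eligible <- logical(m)
  for (j in seq_len(m)) {
    cover <- intersect(seq_len(nw), (j - w + 1):j)
    eligible[j] <- mean(compat[cover]) >= cfg$hit_fraction
  }
  segs <- NULL
  emit <- function(s, e) {
    if (pos[e] - pos[s] >= cfg$min_length &&
        e - s + 1 >= cfg$min_snps_per_segment) {
      segs <<- rbind(segs, data.frame(
        sample_id = sample_id, chrom = chrom, start = pos[s], end = pos[e],
        length = pos[e] - pos[s], n_snps = e - s + 1,
        n_het = sum(calls[s:e] == 1, na.rm = TRUE)))
    }
  }
  j <- 1
  while (j <= m) {
    if (!eligible[j]) {
      j <- j + 1
      next
    }
    k <- j
    while (k < m && eligible[k + 1]) k <- k + 1
    s <- j
    for (t in seq(j, k)) {
      if (t > s && pos[t] - pos[t - 1] > cfg$max_gap) {
        emit(s, t - 1)
        s <- t
      }
    }
    emit(s, k)
    j <- k + 1
  }
  segs
}

# random ROH test instance: mixture of homozygous stretches and noisy
# background over 100-300 SNPs
random_roh_instance <- function(seed) {
  set.seed(seed)
  m <- sample(100:300, 1)
  pos <- sort(sample.int(5e6, m))
  calls <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                  prob = c(0.45, 0.25, 0.25, 0.05))
  # embed a mostly homozygous stretch to exercise segment logic
  a <- sample.int(m - 50, 1)
  b <- min(m, a + sample(30:120, 1))
  stretch <- sample(c(0L, 2L), b - a + 1, replace = TRUE)
  flip <- runif(b - a + 1) < 0.03
  stretch[flip] <- 1L
  calls[a:b] <- stretch
  list(calls = calls, pos = pos)
}
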