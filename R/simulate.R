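#' Configuration for the two-population genotype simulator
#'
#' Describes a Balding-Nichols two-population study: per-site ancestral
#' allele frequencies are drawn uniformly from `ancestral_freq_range`, each
#' population's frequency is Beta-distributed around the ancestral value
#' with variance `p0 * (1 - p0) * fst_param`, and diploid genotypes are
#' binomial draws from the population frequency. On top of that neutral
#' background the simulator plants long homozygous tracts (for ROH
#' detection) and one sex-linked locus where every male is heterozygous and
#' every female homozygous reference.
#'
#' The defaults emulate the structure of a two-cohort study of strongly
#' diverged populations: a small sexed cohort of 12 diploids plus a large
#' unsexed cohort of 200, differentiation `fst_param = 0.24`, a 47-marker
#' sex-linked locus, and three planted homozygous tracts of 2-3 Mb.
#'
#' @param seed integer random seed; the full output is reproducible from it.
#' @param n_chrom number of chromosomes (all of length `chrom_length`).
#' @param chrom_length chromosome length in bp.
#' @param n_snps total SNP count, split evenly across chromosomes.
#' @param pop_sizes two diploid sample counts, populations `popA`, `popB`.
#' @param fst_param Balding-Nichols differentiation parameter F in [0, 1);
#'   the expected genome-wide Fst between the two populations.
#' @param ancestral_freq_range interval within (0, 1) for ancestral
#'   alternate-allele frequencies.
#' @param missing_rate per-genotype missingness applied uniformly outside
#'   planted features, in [0, 1).
#' @param depth_mean,depth_dispersion negative-binomial mean (x) and size
#'   parameter of the per-genotype read depth model.
#' @param qual_range interval for uniform per-site quality scores.
#' @param roh_plants data frame (`sample`, `chrom`, `start`, `end`) of
#'   homozygous tracts to force, or NULL; tracts of one sample must not
#'   overlap.
#' @param sex_locus list (`chrom`, `start`, `end`, `n_markers`) describing
#'   the planted sex-linked locus, or NULL.
#' @param sex optional per-sample sex labels; by default the first
#'   population is split half female / half male and the second is unknown.
#' @return A list of class `sim_config`.
#' @seealso [simulate_genotypes()]
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 5L,
                       chrom_length = 3e7,
                       n_snps = 5000L,
                       pop_sizes = c(12L, 200L),
                       fst_param = 0.24,
                       ancestral_freq_range = c(0.05, 0.95),
                       missing_rate = 0.05,
                       depth_mean = 26,
                       depth_dispersion = 8,
                       qual_range = c(30, 60),
                       roh_plants = default_roh_plants(),
                       sex_locus = default_sex_locus(),
                       sex = NULL) {
  stopifnot(length(pop_sizes) == 2, all(pop_sizes >= 1))
  if (fst_param < 0 || fst_param >= 1) stop("fst_param must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  per_chrom <- snps_per_chrom(n_snps, n_chrom)
  if (any(per_chrom > chrom_length)) {
    stop("n_snps exceeds the positions available on a chromosome")
  }
  ids <- c(sprintf("A%02d", seq_len(pop_sizes[1])),
           sprintf("B%03d", seq_len(pop_sizes[2])))
  if (is.null(sex)) {
    nf <- floor(pop_sizes[1] / 2)
    sex <- c(rep("female", nf), rep("male", pop_sizes[1] - nf),
             rep("unknown", pop_sizes[2]))
  }
  stopifnot(length(sex) == sum(pop_sizes))
  if (!is.null(roh_plants)) {
    roh_plants <- as.data.frame(roh_plants)
    stopifnot(all(c("sample", "chrom", "start", "end") %in% names(roh_plants)))
    if (!all(roh_plants$sample %in% ids)) {
      stop("roh_plants refers to unknown sample ids")
    }
    if (any(roh_plants$start >= roh_plants$end) ||
        any(roh_plants$end > chrom_length) || any(roh_plants$start < 0)) {
      stop("roh_plants tracts must lie inside their chromosome")
    }
    for (key in split(roh_plants, paste(roh_plants$sample, roh_plants$chrom))) {
      key <- key[order(key$start), ]
      if (nrow(key) > 1 && any(key$start[-1] < key$end[-nrow(key)])) {
        stop("planted ROH tracts of one sample must not overlap")
      }
    }
  }
  if (!is.null(sex_locus)) {
    stopifnot(all(c("chrom", "start", "end", "n_markers") %in% names(sex_locus)),
              sex_locus$start >= 0, sex_locus$end <= chrom_length,
              sex_locus$start < sex_locus$end, sex_locus$n_markers >= 1)
  }
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, n_snps = as.integer(n_snps),
                 pop_sizes = as.integer(pop_sizes), fst_param = fst_param,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, qual_range = qual_range,
                 roh_plants = roh_plants, sex_locus = sex_locus,
                 sample_ids = ids, sex = sex),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_roh_plants <- function() {
  data.frame(sample = c("A01", "A02", "A03"),
             chrom = c("chr1", "chr3", "chr4"),
             start = c(5e6, 10e6, 2e6),
             end = c(7.5e6, 12e6, 5e6))
}

#' @rdname sim_config
#' @export
default_sex_locus <- function() {
  list(chrom = "chr2", start = 12.87e6, end = 12.89e6, n_markers = 47L)
}

snps_per_chrom <- function(n_snps, n_chrom) {
  base <- n_snps %/% n_chrom
  extra <- n_snps %% n_chrom
  base + c(rep(1L, extra), rep(0L, n_chrom - extra))
}

#' Simulate a two-population genotype dataset
#'
#' Draws a genotype matrix under the Balding-Nichols model described in
#' [sim_config()], forces the planted homozygous tracts and sex-linked
#' markers, applies uniform missingness outside planted features, and
#' attaches a negative-binomial depth matrix and uniform site qualities.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_result` with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix()] carrying attributes `seed`,
#'       `config_digest` and `chrom_lengths` (picked up by [write_vcf()]).}
#'     \item{truth}{a list: `sites` (per-site ancestral and population
#'       alternate-allele frequencies, sex-marker flag), `roh_plants`,
#'       `sex_marker_pos`, `depth` (the raw depth draws), `config`.}
#'   }
#' @export
simulate_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  per_chrom <- snps_per_chrom(cfg$n_snps, cfg$n_chrom)

  chrom <- rep(chroms, per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(cfg$chrom_length, k))
  }), use.names = FALSE)

  # dedicated sex-linked markers are added on top of the background set
  sex_pos <- integer(0)
  if (!is.null(cfg$sex_locus)) {
    sl <- cfg$sex_locus
    span <- seq.int(ceiling(sl$start + 1), floor(sl$end))
    avail <- setdiff(span, pos[chrom == sl$chrom])
    if (length(avail) < sl$n_markers) {
      stop("sex locus interval too small for n_markers")
    }
    sex_pos <- sort(sample(avail, sl$n_markers))
    ins_chrom <- c(chrom, rep(sl$chrom, sl$n_markers))
    ins_pos <- c(pos, sex_pos)
    ord <- order(match(ins_chrom, chroms), ins_pos)
    chrom <- ins_chrom[ord]
    pos <- ins_pos[ord]
  }
  m <- length(pos)
  is_sex_marker <- chrom == if (is.null(cfg$sex_locus)) "" else
    cfg$sex_locus$chrom
  is_sex_marker <- is_sex_marker & pos %in% sex_pos

  # Balding-Nichols frequencies
  rng <- cfg$ancestral_freq_range
  p0 <- stats::runif(m, rng[1], rng[2])
  f <- cfg$fst_param
  if (f == 0) {
    p1 <- p0
    p2 <- p0
  } else {
    shape_scale <- (1 - f) / f
    p1 <- stats::rbeta(m, p0 * shape_scale, (1 - p0) * shape_scale)
    p2 <- stats::rbeta(m, p0 * shape_scale, (1 - p0) * shape_scale)
  }

  n1 <- cfg$pop_sizes[1]
  n2 <- cfg$pop_sizes[2]
  n <- n1 + n2
  calls <- matrix(NA_integer_, n, m)
  calls[seq_len(n1), ] <- stats::rbinom(n1 * m, 2L, rep(p1, each = n1))
  calls[n1 + seq_len(n2), ] <- stats::rbinom(n2 * m, 2L, rep(p2, each = n2))

  population <- rep(c("popA", "popB"), c(n1, n2))
  pop_freq <- rbind(p1, p2)[match(population, c("popA", "popB")), ,
                            drop = FALSE]

  planted <- matrix(FALSE, n, m)

  if (any(is_sex_marker)) {
    midx <- which(is_sex_marker)
    male <- cfg$sex == "male"
    female <- cfg$sex == "female"
    calls[male, midx] <- 1L
    calls[female, midx] <- 0L
    planted[male | female, midx] <- TRUE
  }

  if (!is.null(cfg$roh_plants)) {
    for (i in seq_len(nrow(cfg$roh_plants))) {
      pl <- cfg$roh_plants[i, ]
      s <- match(pl$sample, cfg$sample_ids)
      idx <- which(chrom == pl$chrom & pos >= pl$start & pos <= pl$end)
      if (length(idx)) {
        calls[s, idx] <- ifelse(pop_freq[s, idx] > 0.5, 2L, 0L)
        planted[s, idx] <- TRUE
      }
    }
  }

  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m) & !planted
    calls[drop] <- NA_integer_
  }

  depth <- matrix(stats::rnbinom(n * m, size = cfg$depth_dispersion,
                                 mu = cfg$depth_mean), n, m)
  qual <- stats::runif(m, cfg$qual_range[1], cfg$qual_range[2])

  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "",
                USE.NAMES = FALSE)

  gm <- genotype_matrix(calls = calls, chrom = chrom, pos = pos,
                        ref = ref, alt = alt,
                        qual = qual, depth = depth,
                        sample_ids = cfg$sample_ids, sex = cfg$sex,
                        population = population)
  attr(gm, "seed") <- cfg$seed
  attr(gm, "config_digest") <- config_digest(cfg)
  attr(gm, "chrom_lengths") <- stats::setNames(
    rep(cfg$chrom_length, cfg$n_chrom), chroms)

  truth <- list(
    sites = data.frame(chrom = chrom, pos = pos, p_ancestral = p0,
                       p_popA = p1, p_popB = p2,
                       sex_marker = is_sex_marker),
    roh_plants = cfg$roh_plants,
    sex_marker_pos = sex_pos,
    depth = depth,
    config = cfg
  )
  structure(list(genotypes = gm, truth = truth), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("simulated two-population dataset (seed ", x$truth$config$seed,
      ", F = ", x$truth$config$fst_param, ")\n", sep = "")
  print(x$genotypes)
  if (length(x$truth$sex_marker_pos)) {
    cat("  planted sex-linked markers:", length(x$truth$sex_marker_pos), "\n")
  }
  if (!is.null(x$truth$roh_plants)) {
    cat("  planted homozygous tracts:", nrow(x$truth$roh_plants), "\n")
  }
  invisible(x)
}

# stable digest of a configuration, recorded in VCF headers and manifests
config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
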