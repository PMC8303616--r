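#' Screen for perfectly sex-discordant markers
#'
#' A marker is sex-discordant when every non-missing call of one sex is
#' heterozygous while every non-missing call of the other sex is the same
#' homozygote, and both sexes reach the per-sex call-rate threshold. The
#' default threshold of 1 demands the perfect pattern: no missing calls in
#' either sex. This is the XY-like signature of a sex-determining locus
#' (e.g. the male-heterozygous *amh* pattern in esocids).
#'
#' Genotype strings are printed from the site alleles: homozygotes as the
#' doubled allele, heterozygotes with the alternate allele first.
#'
#' @param gm a [genotype_matrix()] with `sex` assigned for every sample and
#'   both sexes represented.
#' @param min_call_rate_per_sex fraction of samples of each sex that must
#'   have a non-missing call (default 1).
#' @param region optional restriction, a list or vector
#'   `(chrom, start, end)` with 1-based inclusive bounds.
#' @return data frame with columns `chrom`, `pos`, `female_genotype`,
#'   `male_genotype`, `pattern` (one of `"all-male-het/all-female-hom"`,
#'   `"all-female-het/all-male-hom"`).
#' @export
find_sex_discordant <- function(gm, min_call_rate_per_sex = 1,
                                region = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$sex)) stop("sample sex labels are required")
  fem <- which(gm$sex == "female")
  mal <- which(gm$sex == "male")
  if (!length(fem) || !length(mal)) {
    stop("both sexes must be represented among the samples")
  }

  keep <- rep(TRUE, n_variants(gm))
  if (!is.null(region)) {
    region <- as.list(region)
    names(region)[1:3] <- c("chrom", "start", "end")
    keep <- gm$chrom == region$chrom &
      gm$pos >= as.numeric(region$start) & gm$pos <= as.numeric(region$end)
  }

  gf <- gm$calls[fem, , drop = FALSE]
  gmale <- gm$calls[mal, , drop = FALSE]
  cr_f <- colMeans(!is.na(gf))
  cr_m <- colMeans(!is.na(gmale))
  n_f <- colSums(!is.na(gf))
  n_m <- colSums(!is.na(gmale))

  all_het <- function(g, n) colSums(g == 1L, na.rm = TRUE) == n & n > 0
  same_hom <- function(g, n) {
    hom_ref <- colSums(g == 0L, na.rm = TRUE) == n
    hom_alt <- colSums(g == 2L, na.rm = TRUE) == n
    (hom_ref | hom_alt) & n > 0
  }

  male_het <- all_het(gmale, n_m) & same_hom(gf, n_f)
  female_het <- all_het(gf, n_f) & same_hom(gmale, n_m)
  hit <- keep & cr_f >= min_call_rate_per_sex &
    cr_m >= min_call_rate_per_sex & (male_het | female_het)

  idx <- which(hit)
  geno_str <- function(call, ref, alt) {
    ifelse(call == 0L, paste0(ref, ref),
           ifelse(call == 2L, paste0(alt, alt), paste0(alt, ref)))
  }
  fem_call <- vapply(idx, function(j) {
    v <- gf[, j]
    v[!is.na(v)][1]
  }, integer(1))
  mal_call <- vapply(idx, function(j) {
    v <- gmale[, j]
    v[!is.na(v)][1]
  }, integer(1))
  data.frame(
    chrom = gm$chrom[idx], pos = gm$pos[idx],
    female_genotype = geno_str(fem_call, gm$ref[idx], gm$alt[idx]),
    male_genotype = geno_str(mal_call, gm$ref[idx], gm$alt[idx]),
    pattern = ifelse(male_het[idx], "all-male-het/all-female-hom",
                     "all-female-het/all-male-hom")
  )
}

#' Fst between the sexes
#'
#' Runs the windowed Fst scan of [fst_scan()] with groups defined by the
#' sample sex labels: overall Fst (mean of per-SNP Weir-Cockerham
#' estimates), the per-SNP table, and windowed mFst.
#'
#' @param gm a [genotype_matrix()] with at least two samples of each sex.
#' @inheritParams fst_scan
#' @return see [fst_scan()].
#' @export
sex_fst <- function(gm, chrom_lengths = NULL, spec = window_spec(),
                    estimator = c("wc", "hudson"), high_threshold = 0.9) {
  if (is.null(gm$sex)) stop("sample sex labels are required")
  fst_scan(gm,
           group_a = which(gm$sex == "female"),
           group_b = which(gm$sex == "male"),
           chrom_lengths = chrom_lengths, spec = spec,
           estimator = estimator, high_threshold = high_threshold)
}
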