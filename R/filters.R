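#' Site-filter configuration
#'
#' Thresholds for the standard SNP retention rules: per-genotype depth,
#' site quality, call rate and monomorphic removal.
#'
#' @param min_genotype_depth genotypes with read depth below this (x) are set
#'   to missing; default 10. Ignored when the matrix carries no depth.
#' @param min_site_qual sites with quality score below this are removed;
#'   default 20.
#' @param min_call_rate sites where fewer than this fraction of samples have
#'   a non-missing call (after depth masking) are removed; default 0.9.
#'   Computed over all samples, not per population.
#' @param drop_monomorphic remove sites where all non-missing calls are the
#'   same homozygote; default TRUE.
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(min_genotype_depth = 10,
                               min_site_qual = 20,
                               min_call_rate = 0.9,
                               drop_monomorphic = TRUE) {
  if (!is.numeric(min_call_rate) || length(min_call_rate) != 1 ||
      is.na(min_call_rate) || min_call_rate < 0 || min_call_rate > 1) {
    stop("min_call_rate must be a single number in [0, 1]")
  }
  structure(list(min_genotype_depth = min_genotype_depth,
                 min_site_qual = min_site_qual,
                 min_call_rate = min_call_rate,
                 drop_monomorphic = isTRUE(drop_monomorphic)),
            class = "site_filter_config")
}

#' Apply site filters to a genotype matrix
#'
#' Rules are applied in a fixed order: (1) genotypes below the depth
#' threshold become missing, (2) low-quality sites are removed, (3) sites
#' below the call-rate threshold are removed, (4) monomorphic sites are
#' removed. Depth masking therefore feeds into the call-rate and
#' monomorphic decisions, the conservative reading of the rule set.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [site_filter_config()].
#' @return A list of class `site_filter_result` with elements `genotypes`
#'   (the filtered matrix) and `report` (named counts: `n_input`,
#'   `depth_masked_calls`, `low_qual`, `low_call_rate`, `monomorphic`,
#'   `n_retained`).
#' @export
apply_site_filters <- function(gm, cfg = site_filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!inherits(cfg, "site_filter_config")) {
    cfg <- do.call(site_filter_config, as.list(cfg))
  }
  if (n_variants(gm) == 0L) stop("genotype matrix has no variants")

  n_input <- n_variants(gm)
  masked <- 0L
  if (!is.null(gm$depth) && !is.null(cfg$min_genotype_depth)) {
    low <- !is.na(gm$depth) & gm$depth < cfg$min_genotype_depth &
      !is.na(gm$calls)
    masked <- sum(low)
    gm$calls[low] <- NA_integer_
  }

  keep <- rep(TRUE, n_input)
  low_qual <- 0L
  if (!is.null(gm$qual) && !is.null(cfg$min_site_qual)) {
    fail <- keep & !is.na(gm$qual) & gm$qual < cfg$min_site_qual
    low_qual <- sum(fail)
    keep[fail] <- FALSE
  }

  call_rate <- colMeans(!is.na(gm$calls))
  fail <- keep & call_rate < cfg$min_call_rate
  low_cr <- sum(fail)
  keep[fail] <- FALSE

  mono <- 0L
  if (cfg$drop_monomorphic) {
    n_het <- colSums(gm$calls == 1L, na.rm = TRUE)
    n_hom_ref <- colSums(gm$calls == 0L, na.rm = TRUE)
    n_hom_alt <- colSums(gm$calls == 2L, na.rm = TRUE)
    n_called <- n_het + n_hom_ref + n_hom_alt
    is_mono <- n_het == 0L & (n_hom_ref == n_called | n_hom_alt == n_called)
    fail <- keep & is_mono
    mono <- sum(fail)
    keep[fail] <- FALSE
  }

  out <- gm[, which(keep)]
  report <- c(n_input = n_input, depth_masked_calls = masked,
              low_qual = low_qual, low_call_rate = low_cr,
              monomorphic = mono, n_retained = sum(keep))
  structure(list(genotypes = out, report = report),
            class = "site_filter_result")
}

#' @export
print.site_filter_result <- function(x, ...) {
  r <- x$report
  cat("site filtering:", r[["n_input"]], "->", r[["n_retained"]], "sites\n")
  cat("  genotypes masked for depth:", r[["depth_masked_calls"]], "\n")
  cat("  removed: low_qual=", r[["low_qual"]],
      ", low_call_rate=", r[["low_call_rate"]],
      ", monomorphic=", r[["monomorphic"]], "\n", sep = "")
  invisible(x)
}

#' Transition/transversion ratio
#'
#' Classifies each site by its ref/alt allele pair (genotypes are not
#' consulted): A<->G and C<->T are transitions, every other pair a
#' transversion. A set with zero transversions has no defined ratio and
#' raises an error of class `popgenscan_undefined_ratio`.
#'
#' @param gm a [genotype_matrix()] with at least one variant.
#' @return The ratio of transition to transversion site counts.
#' @export
titv_ratio <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_variants(gm) < 1L) stop("genotype matrix has no variants")
  pair <- paste0(pmin(gm$ref, gm$alt), pmax(gm$ref, gm$alt))
  ti <- sum(pair %in% c("AG", "CT"))
  tv <- length(pair) - ti
  if (tv == 0L) {
    stop(structure(
      class = c("popgenscan_undefined_ratio", "error", "condition"),
      list(message = "Ti/Tv undefined: no transversion sites",
           call = sys.call(-1))))
  }
  ti / tv
}
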