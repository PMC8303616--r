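#' Genotype principal component analysis
#'
#' PCA of the sample-by-SNP alternate-allele dosage matrix for population
#' structure. Missing calls are mean-imputed per site, sites are mean
#' centered, and (optionally) scaled by `1 / sqrt(p * (1 - p))` with `p`
#' the alternate-allele frequency (Patterson scaling). Monomorphic sites
#' (zero variance after imputation) are dropped before decomposition.
#'
#' The sign of each component is fixed by forcing its largest-magnitude
#' SNP loading to be positive, so output is reproducible across runs and
#' sample orderings.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples and at least 2
#'   polymorphic sites.
#' @param k number of components to return; must be `< n_samples`.
#' @param scaling `"center"` (default) or `"patterson"`.
#' @return object of class `genotype_pca`: list with `scores` (samples x k
#'   coordinate matrix), `var_explained` (fraction of total genotypic
#'   variance per component, non-increasing, summing to <= 1), `loadings`
#'   (sites x k), `n_sites_used`.
#' @export
genotype_pca <- function(gm, k = 2L, scaling = c("center", "patterson")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  scaling <- match.arg(scaling)
  n <- n_samples(gm)
  if (n < 2L) stop("need at least 2 samples")
  if (k >= n) stop("k must be smaller than the number of samples")

  x <- gm$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- mu[nas[, 2]]

  v <- apply(x, 2, stats::var)
  poly <- v > 0 & !is.na(v)
  if (sum(poly) < 2L) stop("need at least 2 polymorphic sites")
  x <- x[, poly, drop = FALSE]
  mu <- mu[poly]
  x <- sweep(x, 2, mu)
  if (scaling == "patterson") {
    p <- mu / 2
    x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  }

  sv <- svd(x, nu = k, nv = k)
  # fix signs: largest |loading| positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- gm$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))

  structure(list(scores = scores,
                 var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 loadings = sv$v,
                 n_sites_used = sum(poly)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype PCA:", nrow(x$scores), "samples,", x$n_sites_used,
      "polymorphic sites\n")
  cat("variance explained:",
      paste(sprintf("%s=%.1f%%", colnames(x$scores),
                    100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
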