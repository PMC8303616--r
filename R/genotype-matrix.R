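#' Construct a biallelic SNP genotype matrix
#'
#' The central data container of the package: an n-samples by n-variants
#' matrix of diploid genotype calls at biallelic SNPs, together with variant
#' coordinates, alleles, site quality and optional per-genotype read depth.
#'
#' Calls are coded by alternate-allele dosage: `0` = homozygous reference,
#' `1` = heterozygous, `2` = homozygous alternate, `NA` = missing. Phase is
#' never retained; `0/1` and `1/0`, phased or unphased, are the same call.
#'
#' @param calls integer matrix, samples in rows, variants in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param chrom character vector of chromosome names, one per variant.
#'   Variants of one chromosome must be contiguous.
#' @param pos integer vector of 1-based variant positions (bp), strictly
#'   increasing within each chromosome.
#' @param ref,alt single-character reference / alternate alleles in
#'   `A`, `C`, `G`, `T`; `ref != alt` at every site.
#' @param qual optional numeric per-variant site quality score.
#' @param depth optional numeric matrix of per-genotype read depth, same
#'   dimensions as `calls`.
#' @param sample_ids character vector of sample labels; defaults to the row
#'   names of `calls`.
#' @param sex optional per-sample label in `"female"`, `"male"`, `"unknown"`.
#' @param population optional per-sample population label.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `chrom`, `pos`, `ref`, `alt`, `qual`, `depth`, `sample_ids`,
#'   `sex`, `population`.
#' @seealso [read_vcf()], [simulate_genotypes()], [apply_site_filters()]
#' @export
genotype_matrix <- function(calls, chrom, pos, ref, alt,
                            qual = NULL, depth = NULL,
                            sample_ids = rownames(calls),
                            sex = NULL, population = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_samples <- nrow(calls)
  n_var <- ncol(calls)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(n_samples))
  }
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))

  if (length(chrom) != n_var || length(pos) != n_var ||
      length(ref) != n_var || length(alt) != n_var) {
    stop("chrom, pos, ref and alt must each have one entry per variant")
  }
  if (length(sample_ids) != n_samples || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique and match the number of call rows")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("calls must be 0 (hom ref), 1 (het), 2 (hom alt) or NA")
  }
  nt <- c("A", "C", "G", "T")
  if (n_var > 0L) {
    if (!all(ref %in% nt) || !all(alt %in% nt)) {
      stop("ref and alt must be single nucleotides in A, C, G, T")
    }
    if (any(ref == alt)) stop("ref and alt must differ at every site")
    if (anyNA(pos)) stop("pos must not contain NA")
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      if (any(diff(idx) != 1L)) {
        stop("variants of chromosome '", ch, "' are not contiguous")
      }
      if (is.unsorted(pos[idx], strictly = TRUE)) {
        stop("pos must be strictly increasing within chromosome '", ch, "'")
      }
    }
  }
  if (!is.null(qual)) {
    qual <- as.numeric(qual)
    if (length(qual) != n_var) stop("qual must have one entry per variant")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(calls))) {
      stop("depth must have the same dimensions as calls")
    }
  }
  if (!is.null(sex)) {
    sex <- as.character(sex)
    if (length(sex) != n_samples) stop("sex must have one entry per sample")
    if (!all(sex %in% c("female", "male", "unknown"))) {
      stop("sex labels must be 'female', 'male' or 'unknown'")
    }
  }
  if (!is.null(population)) {
    population <- as.character(population)
    if (length(population) != n_samples) {
      stop("population must have one entry per sample")
    }
  }
  rownames(calls) <- sample_ids
  if (!is.null(depth)) rownames(depth) <- sample_ids

  structure(
    list(calls = calls, chrom = chrom, pos = pos, ref = ref, alt = alt,
         qual = qual, depth = depth, sample_ids = sample_ids,
         sex = sex, population = population),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_variants(x),
      "biallelic SNPs on", length(unique(x$chrom)), "chromosome(s)\n")
  if (!is.null(x$sex)) {
    cat("  sex:", paste(names(table(x$sex)), table(x$sex),
                        sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$population)) {
    cat("  population:", paste(names(table(x$population)), table(x$population),
                               sep = "=", collapse = ", "), "\n")
  }
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  af <- alt_allele_freq(object)
  out <- list(
    n_samples = n_samples(object),
    n_variants = n_variants(object),
    chromosomes = unique(object$chrom),
    missing_rate = mean(is.na(object$calls)),
    maf = pmin(af, 1 - af)
  )
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", x$n_samples, "samples,", x$n_variants,
      "variants,", length(x$chromosomes), "chromosome(s)\n")
  cat(sprintf("missing call rate: %.4f\n", x$missing_rate))
  if (length(x$maf)) {
    cat("minor allele frequency:\n")
    print(summary(x$maf))
  }
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return An integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' `i` selects samples, `j` selects variants; both follow the usual matrix
#' indexing conventions. Variant subsets must preserve the sorted,
#' contiguous-chromosome layout.
#'
#' @param x a [genotype_matrix()].
#' @param i,j sample / variant indices.
#' @param ... unused.
#' @return A `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stop("unknown sample id in subset")
  genotype_matrix(
    calls = x$calls[i, j, drop = FALSE],
    chrom = x$chrom[j], pos = x$pos[j], ref = x$ref[j], alt = x$alt[j],
    qual = if (!is.null(x$qual)) x$qual[j],
    depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
    sample_ids = x$sample_ids[i],
    sex = if (!is.null(x$sex)) x$sex[i],
    population = if (!is.null(x$population)) x$population[i]
  )
}

#' Per-site allele counts and frequencies
#'
#' Counts are diploid allele counts over non-missing calls:
#' ref count `= 2 * #hom_ref + #het`, alt count `= 2 * #hom_alt + #het`.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional sample ids or indices to restrict to.
#' @return `allele_counts()`: a matrix with rows `ref` and `alt`;
#'   `alt_allele_freq()`: a numeric vector (NaN where all calls missing).
#' @export
allele_counts <- function(gm, samples = NULL) {
  calls <- gm$calls
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, gm$sample_ids)
    calls <- calls[samples, , drop = FALSE]
  }
  n_ref <- 2L * colSums(calls == 0L, na.rm = TRUE) +
    colSums(calls == 1L, na.rm = TRUE)
  n_alt <- 2L * colSums(calls == 2L, na.rm = TRUE) +
    colSums(calls == 1L, na.rm = TRUE)
  rbind(ref = n_ref, alt = n_alt)
}

#' @rdname allele_counts
#' @export
alt_allele_freq <- function(gm, samples = NULL) {
  ac <- allele_counts(gm, samples)
  ac["alt", ] / colSums(ac)
}
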