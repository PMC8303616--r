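#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzip/bgzip) and returns the biallelic-SNP
#' genotype matrix plus a report of records that were excluded. Records are
#' never silently dropped: indels, multiallelic sites and other non-SNP
#' records are counted in the report.
#'
#' @param path path to a VCF file with GT genotype fields; per-genotype DP
#'   is read when present.
#' @param require_biallelic_snp keep only records whose REF and ALT are
#'   single distinct nucleotides with exactly one ALT allele (default TRUE).
#'   When FALSE the file must already contain only such records.
#' @param sex,population optional per-sample annotations passed through to
#'   [genotype_matrix()] (named by sample id, or in file sample order).
#'
#' @return A list of class `vcf_import` with elements `genotypes`
#'   (a [genotype_matrix()]) and `report` (named counts of excluded
#'   records: `indel`, `multiallelic`, `other`).
#' @export
read_vcf <- function(path, require_biallelic_snp = TRUE,
                     sex = NULL, population = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  check_vcf_shape(path)

  x <- vcfR::read.vcfR(path, verbose = FALSE)
  n_smp <- ncol(x@gt) - 1L
  if (is.na(n_smp) || n_smp < 1L) stop("VCF has no sample columns: ", path)

  fix <- vcfR::getFIX(x)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  nt <- c("A", "C", "G", "T")

  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & ref %in% nt & alt %in% nt
  indel <- !multi & !snp &
    grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt) &
    (nchar(ref) > 1L | nchar(alt) > 1L)
  other <- !multi & !snp & !indel
  report <- c(indel = sum(indel), multiallelic = sum(multi),
              other = sum(other))

  if (require_biallelic_snp) {
    keep <- which(snp)
  } else {
    if (!all(snp)) {
      stop("VCF contains non-biallelic-SNP records; set require_biallelic_snp")
    }
    keep <- seq_along(snp)
  }

  gt <- vcfR::extract.gt(x, element = "GT")
  calls <- t(gt_to_calls(gt[keep, , drop = FALSE]))
  colnames(calls) <- NULL
  depth <- NULL
  fmt <- x@gt[, "FORMAT"]
  if (length(fmt) && any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- vcfR::extract.gt(x, element = "DP", as.numeric = TRUE)
    depth <- t(dp[keep, , drop = FALSE])
    colnames(depth) <- NULL
  }
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))

  gm <- genotype_matrix(
    calls = calls,
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    qual = qual, depth = depth,
    sample_ids = colnames(x@gt)[-1L],
    sex = reorder_annotation(sex, colnames(x@gt)[-1L]),
    population = reorder_annotation(population, colnames(x@gt)[-1L])
  )
  structure(list(genotypes = gm, report = report), class = "vcf_import")
}

#' @export
print.vcf_import <- function(x, ...) {
  print(x$genotypes)
  cat("excluded records:",
      paste(names(x$report), x$report, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# cheap structural scan: every data line must carry the header's column count
check_vcf_shape <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("VCF is missing the #CHROM header line: ", path)
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10L) stop("VCF has no sample columns: ", path)
  body <- which(!startsWith(lines, "#"))
  if (length(body)) {
    cnt <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[cnt != n_fields]
    if (length(bad)) {
      stop("malformed VCF line ", bad[1], " in ", path, ": expected ",
           n_fields, " tab-separated fields, found ",
           cnt[match(bad[1], body)])
    }
  }
  invisible(TRUE)
}

# GT strings -> dosage codes; phase-insensitive, unknown alleles -> NA
gt_to_calls <- function(gt) {
  a <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(a), ncol(a), dimnames = dimnames(a))
  out[a %in% c("0/0", "0")] <- 0L
  out[a %in% c("0/1", "1/0")] <- 1L
  out[a %in% c("1/1", "1")] <- 2L
  out
}

reorder_annotation <- function(ann, ids) {
  if (is.null(ann)) return(NULL)
  if (!is.null(names(ann))) {
    if (!all(ids %in% names(ann))) stop("annotation is missing some sample ids")
    ann <- ann[ids]
  }
  unname(ann)
}

#' Write a genotype matrix as VCF
#'
#' Emits plain-text VCF 4.2 with GT (and DP when depth is present) fields.
#' Output is deterministic: the same matrix always produces byte-identical
#' files. Simulation provenance (seed, configuration digest) stored as
#' attributes `seed` / `config_digest` on `gm` is recorded in the header.
#'
#' @param gm a [genotype_matrix()]; an empty matrix yields a header-only VCF.
#' @param path output file path.
#' @param chrom_lengths optional named vector of chromosome lengths for the
#'   `##contig` header lines; defaults to attribute `chrom_lengths` of `gm`,
#'   else the largest observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(chrom_lengths)) chrom_lengths <- attr(gm, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(gm$pos, gm$chrom)[unique(gm$chrom)],
                            max, numeric(1))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=popgenscan_", as.character(utils::packageVersion("popgenscan")))
  )
  if (!is.null(attr(gm, "seed"))) {
    hdr <- c(hdr, paste0("##popgenscan_seed=", attr(gm, "seed")))
  }
  if (!is.null(attr(gm, "config_digest"))) {
    hdr <- c(hdr, paste0("##popgenscan_config_digest=", attr(gm, "config_digest")))
  }
  hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                        as.integer(chrom_lengths)))
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_dp <- !is.null(gm$depth)
  if (has_dp) {
    hdr <- c(hdr,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$sample_ids),
                      collapse = "\t"))

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (n_variants(gm) > 0L) {
    gt <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L], nrow = nrow(gm$calls))
    gt[is.na(gm$calls)] <- "./."
    if (has_dp) {
      dp <- matrix(as.character(as.integer(gm$depth)), nrow = nrow(gm$depth))
      dp[is.na(gm$depth)] <- "."
      gt <- matrix(paste(gt, dp, sep = ":"), nrow = nrow(gt))
    }
    qual <- if (is.null(gm$qual)) rep(".", n_variants(gm)) else
      ifelse(is.na(gm$qual), ".", formatC(gm$qual, format = "g", digits = 6))
    body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, qual, ".", ".",
                  if (has_dp) "GT:DP" else "GT", sep = "\t")
    smp <- apply(gt, 2, paste, collapse = "\t")
    writeLines(paste(body, smp, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}
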