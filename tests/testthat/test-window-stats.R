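test_that("make_windows emits clipped half-open sliding windows", {
  w <- make_windows(c(chr1 = 1.2e6))
  expect_equal(w$start, c(0, 2.5e5, 5e5, 7.5e5, 1e6))
  expect_equal(w$end[5], 1.2e6)
  # every start below the chromosome length is emitted, clipped at the end
  expect_equal(make_windows(c(chrA = 4e5)),
               data.frame(chrom = "chrA", start = c(0, 2.5e5),
                          end = c(4e5, 4e5)))
})

test_that("make_windows equals brute-force enumeration on random lengths", {
  set.seed(17)
  for (i in 1:25) {
    lens <- setNames(sample.int(5e6, 3), c("c1", "c2", "c3"))
    size <- sample.int(8e5, 1)
    step <- sample.int(size, 1)
    spec <- window_spec(size, step, 0)
    expect_equal(make_windows(lens, spec), bf_windows(lens, size, step))
  }
  expect_error(window_spec(size = 100, step = 200), "step")
})

test_that("pooled heterozygosity follows 2*maj*min/(maj+min)^2", {
  # one window; symmetric counts give the 0.5 maximum
  gm <- make_gm(rbind(c(0, 2), c(2, 0)), pos = c(100, 200))
  w <- data.frame(chrom = "chr1", start = 0, end = 1000)
  hp <- pooled_het(gm, w, window_spec(1000, 1000, 1))
  expect_equal(hp$sum_maj, hp$sum_min)
  expect_equal(hp$hp, 0.5)

  # no minor alleles anywhere -> hp 0
  gm0 <- make_gm(rbind(c(0, 0), c(0, 0)), pos = c(100, 200))
  expect_equal(pooled_het(gm0, w, window_spec(1000, 1000, 1))$hp, 0)

  # a 12-sample, 88-SNP window engineered to the published allele-count
  # sums (sum_maj 1366, sum_min 746) must give Hp by direct arithmetic
  mins <- c(rep(9L, 42), rep(8L, 46))       # minor counts per site, sum 746
  calls88 <- vapply(mins, function(k) c(rep(1L, k), rep(0L, 12 - k)),
                    integer(12))
  gm88 <- make_gm(calls88, pos = seq(1000, 88000, by = 1000))
  w88 <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  hp88 <- pooled_het(gm88, w88, window_spec(1e5, 1e5, 1))
  expect_equal(hp88$sum_maj, 1366)
  expect_equal(hp88$sum_min, 746)
  expect_equal(hp88$hp, 2 * 1366 * 746 / (1366 + 746)^2)
})

test_that("hp is invariant under ref/alt relabeling and bounded by 0.5", {
  set.seed(23)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 12 * 200, TRUE,
                         prob = c(.4, .3, .25, .05)), 12, 200)
  gm <- make_gm(calls, pos = sort(sample.int(2e6, 200)))
  spec <- window_spec(5e5, 2.5e5, 5)
  w <- make_windows(c(chr1 = 2e6), spec)
  hp1 <- pooled_het(gm, w, spec)
  swapped <- make_gm(2L - calls, pos = gm$pos, ref = gm$alt, alt = gm$ref)
  hp2 <- pooled_het(swapped, w, spec)
  expect_equal(hp1$hp, hp2$hp)
  ok <- !is.na(hp1$hp)
  expect_true(all(hp1$hp[ok] >= 0 & hp1$hp[ok] <= 0.5))
  expect_true(all(hp1$sum_maj >= hp1$sum_min))
})

test_that("every interior SNP falls in exactly two 50%-overlap windows", {
  set.seed(31)
  spec <- window_spec(5e5, 2.5e5, 1)
  len <- c(chr1 = 3e6)
  pos <- sort(sample.int(3e6, 300))
  gm <- make_gm(matrix(1L, 2, 300), pos = pos)
  w <- make_windows(len, spec)
  hp <- pooled_het(gm, w, spec)
  cover <- vapply(pos, function(p) {
    sum(w$start <= p - 1 & p - 1 < w$end)
  }, numeric(1))
  interior <- pos - 1 >= spec$step & pos - 1 < len - spec$step
  expect_true(all(cover[interior] == 2))
  expect_equal(sum(hp$n_snps), sum(cover))
})

test_that("ZHp standardises window Hp to mean 0, sd 1, and flags |z|>3", {
  het <- data.frame(chrom = "chr1", start = 0:2, end = 1:3, n_snps = 10,
                    sum_maj = 1, sum_min = 1, hp = c(0.1, 0.2, 0.3))
  z <- normalize_hp(het)
  expect_equal(z$zhp, c(-1, 0, 1))
  expect_equal(attr(z, "mu_hp"), 0.2)
  expect_equal(attr(z, "sigma_hp"), 0.1)

  het$hp <- rep(0.2, 3)
  expect_error(normalize_hp(het), "identical")

  set.seed(7)
  sim <- simulate_genotypes(sim_config(seed = 2, n_chrom = 2,
                                       chrom_length = 8e6, n_snps = 2000,
                                       pop_sizes = c(8, 8), roh_plants = NULL,
                                       sex_locus = NULL))
  hp <- hp_scan(sim$genotypes)
  ok <- !is.na(hp$zhp)
  expect_equal(mean(hp$zhp[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(hp$zhp[ok]), 1, tolerance = 1e-9)
})

test_that("Weir-Cockerham per-SNP Fst matches the hand-coded oracle", {
  # pA = 0.75, pB = 0.25 with Hardy-Weinberg heterozygote counts, n = 4 each
  a <- c(rep(2L, 2), rep(1L, 2))        # counts: 0 hom_ref, 2 het, 2 hom_alt
  b <- c(rep(0L, 2), rep(1L, 2))        # mirrored
  gm <- make_gm(cbind(c(a, b)), pos = 100)
  fst <- snp_fst(gm, 1:4, 5:8)
  expect_equal(fst$fst,
               wc_fst_oracle(c(0, 2, 2), c(2, 2, 0)))

  # random genotype configurations against the oracle
  set.seed(77)
  for (i in 1:50) {
    ca <- matrix(sample(c(0L, 1L, 2L), 12, TRUE), 6, 2)
    cb <- matrix(sample(c(0L, 1L, 2L), 16, TRUE), 8, 2)
    gm2 <- make_gm(rbind(ca, cb), pos = c(10, 20))
    got <- snp_fst(gm2, 1:6, 7:14)$fst
    want <- vapply(1:2, function(j) {
      wc_fst_oracle(tabulate(ca[, j] + 1L, 3), tabulate(cb[, j] + 1L, 3))
    }, numeric(1))
    expect_equal(got, want)
    expect_true(all(got[is.finite(got)] <= 1))
  }
})

test_that("fixed opposite alleles give Fst exactly 1; identical groups <= 0", {
  gm <- make_gm(rbind(matrix(0L, 6, 5), matrix(2L, 6, 5)))
  fst <- snp_fst(gm, 1:6, 7:12)
  expect_equal(fst$fst, rep(1, 5))

  set.seed(5)
  same <- matrix(sample(c(0L, 1L, 2L), 10, TRUE), 5, 2)
  gm2 <- make_gm(rbind(same, same))
  fst2 <- snp_fst(gm2, 1:5, 6:10)
  expect_true(all(fst2$fst[is.finite(fst2$fst)] <= 0))
})

test_that("sites without 2 called samples per group are skipped and counted", {
  calls <- rbind(c(0L, NA), c(0L, NA), c(2L, 1L), c(2L, 1L))
  gm <- make_gm(calls)
  fst <- snp_fst(gm, 1:2, 3:4)
  expect_equal(nrow(fst), 1L)
  expect_equal(attr(fst, "n_skipped"), 1L)
  expect_error(snp_fst(gm, 1, 2:4), "at least 2")
})

test_that("window mFst is the arithmetic mean of per-SNP values", {
  fst <- data.frame(chrom = "chr1", pos = c(100, 200), fst = c(0.2, 0.4))
  w <- data.frame(chrom = "chr1", start = 0, end = 1000)
  mf <- window_mfst(fst, w, window_spec(1000, 1000, 1))
  expect_equal(mf$mfst, 0.3)
  expect_false(mf$high_fst)

  set.seed(13)
  pos <- sort(sample.int(2e6, 150))
  fst2 <- data.frame(chrom = "chr1", pos = pos, fst = runif(150, -0.05, 1))
  spec <- window_spec(5e5, 2.5e5, 1)
  w2 <- make_windows(c(chr1 = 2e6), spec)
  mf2 <- window_mfst(fst2, w2, spec)
  brute <- vapply(seq_len(nrow(w2)), function(i) {
    inw <- pos - 1 >= w2$start[i] & pos - 1 < w2$end[i]
    if (any(inw)) mean(fst2$fst[inw]) else NA_real_
  }, numeric(1))
  expect_equal(mf2$mfst, brute)
})

test_that("genome-wide weighted W&C Fst recovers the simulated F", {
  cfg <- sim_config(seed = 19, n_chrom = 2, chrom_length = 2e7,
                    n_snps = 5000, pop_sizes = c(50, 50), fst_param = 0.25,
                    missing_rate = 0, roh_plants = NULL, sex_locus = NULL)
  gm <- simulate_genotypes(cfg)$genotypes
  fst <- snp_fst(gm, 1:50, 51:100)
  expect_lt(abs(overall_fst(fst, "weighted") - 0.25), 0.03)
  # the mean of per-SNP ratios is systematically below the weighted estimate
  expect_lt(overall_fst(fst, "mean"), overall_fst(fst, "weighted"))
})
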