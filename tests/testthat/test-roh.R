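test_that("roh_config enforces its parameter constraints", {
  expect_error(roh_config(window_snps = 3, max_het_per_window = 3), ">")
  expect_error(roh_config(min_length = 0), "positive")
  expect_error(roh_config(hit_fraction = 0), "hit_fraction")
  expect_length(roh_grid(), 9L)
})

test_that("an all-heterozygous sample yields no segments", {
  gm <- make_gm(matrix(1L, 2, 200), pos = seq(1e4, 2e6, length.out = 200))
  expect_equal(nrow(detect_roh(gm, 1, roh_config())), 0L)
})

test_that("an ideal homozygous chromosome yields one spanning segment", {
  pos <- as.integer(seq(10000, 2e6, length.out = 200))
  gm <- make_gm(matrix(0L, 2, 200), pos = pos)
  seg <- detect_roh(gm, 1, roh_config())
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, pos[1])
  expect_equal(seg$end, pos[200])
  expect_equal(seg$n_snps, 200L)
  expect_equal(seg$length, pos[200] - pos[1])
})

test_that("segments split at gaps above max_gap and honour min_length", {
  pos <- c(seq(1e4, 1.5e6, length.out = 100),
           seq(2.2e6, 3.7e6, length.out = 100))  # 700 kb gap in the middle
  gm <- make_gm(matrix(0L, 2, 200), pos = as.integer(pos))
  seg <- detect_roh(gm, 1, roh_config())
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$length >= 1e6))
  expect_true(all(seg$end[1] <= 1.5e6, seg$start[2] >= 2.2e6))
})

test_that("detect_roh equals the exhaustive scanner on random instances", {
  grid <- roh_grid(min_length = 2e5, min_snps_per_segment = 10)
  for (seed in 1:25) {
    inst <- random_roh_instance(seed)
    gm <- make_gm(rbind(inst$calls, inst$calls), pos = inst$pos)
    for (cfg in grid) {
      got <- detect_roh(gm, 1, cfg)
      want <- bf_roh(inst$calls, inst$pos, cfg, sample_id = "S1")
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        rownames(want) <- NULL
        expect_equal(got, want)
      }
    }
  }
})

test_that("reported segments never overlap and satisfy the length/gap rules", {
  cfg <- roh_config(min_length = 2e5, min_snps_per_segment = 10)
  for (seed in 26:40) {
    inst <- random_roh_instance(seed)
    gm <- make_gm(rbind(inst$calls, inst$calls), pos = inst$pos)
    seg <- detect_roh(gm, 1, cfg)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
    }
    expect_true(all(seg$length >= cfg$min_length))
    for (i in seq_len(nrow(seg))) {
      inside <- inst$pos[inst$pos >= seg$start[i] & inst$pos <= seg$end[i]]
      expect_true(all(diff(inside) <= cfg$max_gap))
    }
  }
})

test_that("froh divides summed segment length by the explicit denominator", {
  segs <- data.frame(sample_id = "X", chrom = "chr1", start = 0, end = 5e7,
                     length = 5e7, n_snps = 100L, n_het = 0L)
  fr <- froh(segs, denominator = 1e9)
  expect_equal(fr$froh, 0.05)
  expect_equal(fr$mean_length, 5e7)
  fr0 <- froh(segs[0, ], denominator = 1e9, samples = "Y")
  expect_equal(fr0$froh, 0)
  expect_equal(fr0$mean_length, 0)
  expect_error(froh(segs, denominator = 0), "positive")
})

test_that("a one-config sweep equals direct detection plus froh", {
  sim <- simulate_genotypes(sim_config(
    seed = 21, n_chrom = 1, chrom_length = 1e7, n_snps = 1500,
    pop_sizes = c(3, 3), fst_param = 0, ancestral_freq_range = c(0.2, 0.8),
    missing_rate = 0,
    roh_plants = data.frame(sample = "A01", chrom = "chr1",
                            start = 2e6, end = 4e6),
    sex_locus = NULL))
  gm <- sim$genotypes
  cfg <- roh_config()
  sweep <- stringency_sweep(gm, list(only = cfg), denominator = 1e7)
  segs <- do.call(rbind, lapply(gm$sample_ids, function(s) {
    detect_roh(gm, s, cfg)
  }))
  direct <- froh(segs, 1e7, samples = gm$sample_ids)
  expect_equal(sweep$froh, direct$froh)
  expect_equal(sweep$n_segments, direct$n_segments)
  expect_true(all(sweep$window_snps == 20))
})

test_that("stringency never relaxes: fewer allowed hets cannot add ROH length", {
  for (seed in 41:50) {
    inst <- random_roh_instance(seed)
    gm <- make_gm(rbind(inst$calls, inst$calls), pos = inst$pos)
    for (w in c(5L, 10L, 20L)) {
      tot <- vapply(1:3, function(h) {
        cfg <- roh_config(window_snps = w, max_het_per_window = h,
                          min_length = 2e5, min_snps_per_segment = 10)
        sum(detect_roh(gm, 1, cfg)$length)
      }, numeric(1))
      expect_true(!is.unsorted(tot))  # h = 1, 2, 3 nondecreasing
    }
  }
})

test_that("an all-homozygous sample gets identical froh across the grid", {
  pos <- as.integer(seq(1e4, 3e6, length.out = 300))
  gm <- make_gm(matrix(2L, 2, 300), pos = pos)
  sweep <- stringency_sweep(gm, roh_grid(), denominator = 3e6,
                            samples = gm$sample_ids[1])
  expect_equal(length(unique(sweep$froh)), 1L)
})

test_that("chromosomes with fewer SNPs than the window warn and yield nothing", {
  gm <- make_gm(matrix(0L, 2, 5), pos = c(1, 2, 3, 4, 5) * 1e5)
  expect_warning(seg <- detect_roh(gm, 1, roh_config(window_snps = 10,
                                                     max_het_per_window = 1)),
                 "fewer SNPs")
  expect_equal(nrow(seg), 0L)
})

test_that("planted tract fractions are recovered by froh within 0.01", {
  denom <- 2e8   # 4 chromosomes of 50 Mb
  for (f in c(0.01, 0.05)) {
    tot <- f * denom
    n_tr <- max(1, round(tot / 2.5e6))
    plants <- data.frame(sample = "A01", chrom = paste0("chr", seq_len(n_tr)),
                         start = 1e7, end = 1e7 + tot / n_tr)
    cfg <- sim_config(seed = 100 + round(100 * f), n_chrom = 4,
                      chrom_length = 5e7, n_snps = 20000,
                      pop_sizes = c(3, 3), fst_param = 0,
                      ancestral_freq_range = c(0.2, 0.8),
                      missing_rate = 0.02, roh_plants = plants,
                      sex_locus = NULL)
    gm <- simulate_genotypes(cfg)$genotypes
    fr <- froh(detect_roh(gm, "A01", roh_config()), denom, samples = "A01")
    expect_lt(abs(fr$froh - f), 0.01)
    # an unplanted sample stays clean
    fr0 <- froh(detect_roh(gm, "B001", roh_config()), denom, samples = "B001")
    expect_equal(fr0$froh, 0)
  }
})
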