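# F_ROH, F_ROHOAR, length-category decomposition and distribution summary.

seg_row <- function(sample_id, chrom, start, end) {
  data.frame(sample_id = sample_id, chrom = as.integer(chrom),
             start_bp = start, end_bp = end,
             n_snp = 50L, start_snp = "a", end_snp = "b",
             length_bp = end - start, length_mb = (end - start) / 1e6,
             stringsAsFactors = FALSE)
}

test_that("samples without ROH get F_ROH = 0", {
  ext <- autosome_extent(data.frame(chrom = 1L, pos_bp = c(1, 1e8)))
  rep <- compute_froh(seg_row("S1", 1, 1e6, 2e6)[0, ], ext,
                      samples = c("A", "B"))
  expect_equal(rep$per_sample$F_ROH, c(0, 0))
  expect_equal(rep$per_sample$n_roh, c(0L, 0L))
})

test_that("a segment covering the whole extent gives F_ROH = F_ROHOAR = 1", {
  ext <- autosome_extent(data.frame(chrom = 1L, pos_bp = c(1e6, 9e6)))
  rep <- compute_froh(seg_row("S1", 1, 1e6, 9e6), ext, samples = "S1")
  expect_equal(rep$per_sample$F_ROH, 1)
  expect_equal(rep$per_sample_chrom$F_ROHOAR, 1)
})

test_that("length-category F_ROH decomposes a hand-computed case", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8))
  segs <- rbind(seg_row("S1", 1, 10e6, 13e6),   # 3 Mb -> bin 1-5
                seg_row("S1", 1, 50e6, 57e6))   # 7 Mb -> bin 5-10
  rep <- compute_froh(segs, ext, samples = "S1")
  ps <- rep$per_sample
  expect_equal(ps$F_ROH, 0.10)
  expect_equal(ps$`F_ROH_1-5Mb`, 0.03)
  expect_equal(ps$`F_ROH_5-10Mb`, 0.07)
  expect_equal(ps$`F_ROH_10-20Mb`, 0)
})

test_that("category and chromosome decompositions are conserved exactly", {
  set.seed(8)
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8, "2" = 8e7,
                                                 "3" = 6e7))
  samples <- paste0("S", 1:6)
  segs <- do.call(rbind, lapply(1:40, function(i) {
    ch <- sample(1:3, 1)
    start <- runif(1, 1, 5e7)
    seg_row(sample(samples, 1), ch, start, start + runif(1, 1.1e6, 3e7))
  }))
  rep <- compute_froh(segs, ext, samples)
  ps <- rep$per_sample
  cat_cols <- grep("^F_ROH_", names(ps), value = TRUE)
  expect_equal(rowSums(ps[, cat_cols, drop = FALSE]), ps$F_ROH,
               ignore_attr = TRUE)
  loar_sum <- rowsum(rep$per_sample_chrom$L_ROHOAR,
                     rep$per_sample_chrom$sample_id)
  expect_equal(loar_sum[match(ps$sample_id[ps$L_ROH > 0], rownames(loar_sum)),
                        1],
               ps$L_ROH[ps$L_ROH > 0], ignore_attr = TRUE)
})

test_that("F_ROH is invariant to chromosome relabeling", {
  ext1 <- autosome_extent(NULL, chrom_lengths = c("1" = 5e7, "2" = 5e7))
  ext2 <- autosome_extent(NULL, chrom_lengths = c("7" = 5e7, "9" = 5e7))
  s1 <- rbind(seg_row("S1", 1, 1e6, 4e6), seg_row("S1", 2, 1e6, 9e6))
  s2 <- rbind(seg_row("S1", 7, 1e6, 4e6), seg_row("S1", 9, 1e6, 9e6))
  expect_equal(compute_froh(s1, ext1, "S1")$per_sample$F_ROH,
               compute_froh(s2, ext2, "S1")$per_sample$F_ROH)
})

test_that("segments on unknown chromosomes are rejected", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 5e7))
  expect_error(compute_froh(seg_row("S1", 2, 1e6, 3e6), ext, "S1"),
               "absent")
})

test_that("distribution summary handles a single-animal cohort", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8))
  smry <- summarize_distribution(seg_row("S1", 1, 1e6, 3e6), ext, "S1")
  expect_equal(smry$overall$mean_roh_per_animal, 1)
  expect_equal(smry$per_bin$pct_of_roh[1], 100)
  expect_equal(sum(smry$per_bin$pct_of_roh), 100)
})

test_that("bin percentages split evenly for one segment per category", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8))
  segs <- rbind(seg_row("S1", 1, 0, 2e6), seg_row("S2", 1, 10e6, 16e6),
                seg_row("S3", 1, 30e6, 42e6), seg_row("S1", 1, 60e6, 85e6))
  smry <- summarize_distribution(segs, ext, paste0("S", 1:3))
  expect_equal(smry$per_bin$pct_of_roh, rep(25, 4))
  expect_equal(sum(smry$per_bin$pct_of_roh), 100)
})

test_that("coefficient of variation is reported in percent", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8))
  segs <- rbind(seg_row("S1", 1, 0, 2e6), seg_row("S2", 1, 0, 6e6))
  smry <- summarize_distribution(segs, ext, c("S1", "S2"))
  row <- smry$froh_stats[smry$froh_stats$coefficient == "F_ROH", ]
  v <- c(2e6, 6e6) / 1e8
  expect_equal(row$cv_pct, 100 * sd(v) / mean(v))
  expect_equal(row$n_animals, 2L)
})

test_that("per-category statistics cover only animals with ROH in the bin", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8))
  segs <- rbind(seg_row("S1", 1, 0, 2e6), seg_row("S2", 1, 0, 3e6),
                seg_row("S3", 1, 10e6, 16e6))
  smry <- summarize_distribution(segs, ext, paste0("S", 1:4))
  st <- smry$froh_stats
  expect_equal(st$n_animals[st$coefficient == "F_ROH_1-5Mb"], 2L)
  expect_equal(st$n_animals[st$coefficient == "F_ROH_5-10Mb"], 1L)
  expect_equal(st$n_animals[st$coefficient == "F_ROH"], 3L)
  expect_equal(st$mean[st$coefficient == "F_ROH_1-5Mb"],
               mean(c(2e6, 3e6) / 1e8))
})

test_that("zero or negative cohort size is rejected", {
  ext <- autosome_extent(NULL, chrom_lengths = c("1" = 1e8))
  expect_error(summarize_distribution(seg_row("S1", 1, 0, 2e6), ext,
                                      character(0)), "positive")
})
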