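# SNP incidence, top-percentile hotspot calling, gene counting and
# recombination rates.

mk_map <- function(pos, chrom = 1L) {
  data.frame(chrom = rep_len(as.integer(chrom), length(pos)),
             id = paste0("s", seq_along(pos)), pos_bp = pos,
             stringsAsFactors = FALSE)
}

seg_row <- function(sample_id, chrom, start, end) {
  data.frame(sample_id = sample_id, chrom = as.integer(chrom),
             start_bp = start, end_bp = end, n_snp = 10L,
             start_snp = "a", end_snp = "b", length_bp = end - start,
             length_mb = (end - start) / 1e6, stringsAsFactors = FALSE)
}

test_that("incidence counts animals whose ROH span each marker", {
  map <- mk_map(seq(1e6, 5e6, by = 1e6))
  segs <- rbind(seg_row("A", 1, 1.5e6, 3.5e6),
                seg_row("B", 1, 2e6, 3e6),
                seg_row("C", 1, 3e6, 4.9e6))
  tr <- snp_incidence(segs, map, n_samples = 10)
  expect_equal(tr$n_covered, c(0L, 2L, 3L, 1L, 0L))
  expect_equal(tr$incidence_pct[3], 30)
})

test_that("a sample contributes at most one count per marker", {
  map <- mk_map(c(1e6, 2e6))
  segs <- rbind(seg_row("A", 1, 0.5e6, 2.5e6), seg_row("A", 1, 0.9e6, 1.1e6))
  tr <- snp_incidence(segs, map, n_samples = 4)
  expect_equal(tr$n_covered, c(1L, 1L))
})

test_that("zero segments give zero incidence; full sharing gives 100%", {
  map <- mk_map(c(1e6, 2e6))
  tr0 <- snp_incidence(seg_row("A", 1, 0, 1)[0, ], map, 5)
  expect_equal(tr0$incidence_pct, c(0, 0))
  segs <- do.call(rbind, lapply(paste0("S", 1:5), seg_row,
                                chrom = 1, start = 0.5e6, end = 2.5e6))
  tr1 <- snp_incidence(segs, map, 5)
  expect_equal(tr1$incidence_pct, c(100, 100))
})

test_that("segments off the marker map are rejected", {
  expect_error(snp_incidence(seg_row("A", 9, 1, 2), mk_map(c(1e6)), 3),
               "absent")
})

test_that("a single high marker forms a length-0 single-SNP region", {
  map <- mk_map(seq(1e6, 100e6, length.out = 200))
  segs <- seg_row("A", 1, map$pos_bp[50] - 1, map$pos_bp[50] + 1)
  tr <- snp_incidence(segs, map, 10)
  reg <- call_hotspots(tr, 0.01)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_snp, 1L)
  expect_equal(reg$length_bp, 0)
  fmt <- format_hotspot_table(
    annotate_hotspots(reg, gmap = genetic_map(
      data.frame(chrom = 1L, pos_bp = c(1, 2e8), cM = c(0, 200)))))
  expect_equal(fmt$cM_per_Mb, "/")
})

test_that("uniform incidence selects everything into one region per chromosome", {
  map <- rbind(mk_map(c(1e6, 2e6, 3e6), 1L), mk_map(c(1e6, 2e6), 2L))
  segs <- rbind(seg_row("A", 1, 0, 4e6), seg_row("A", 2, 0, 3e6))
  tr <- snp_incidence(segs, map, 1)
  reg <- call_hotspots(tr, 0.01)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$chrom, c(1L, 2L))
  expect_equal(sum(reg$n_snp), nrow(map))
})

test_that("an all-zero track yields no hotspot regions", {
  map <- mk_map(seq(1e6, 10e6, by = 1e6))
  tr <- snp_incidence(seg_row("A", 1, 0, 1)[0, ], map, 5)
  reg <- call_hotspots(tr, 0.01)
  expect_equal(nrow(reg), 0L)
})

test_that("selected-marker count is conserved by region merging", {
  set.seed(12)
  map <- mk_map(sort(sample.int(1e8, 500)))
  segs <- do.call(rbind, lapply(1:30, function(i) {
    s <- runif(1, 1, 9e7); seg_row(paste0("S", sample(1:10, 1)), 1, s,
                                   s + runif(1, 1e6, 8e6))
  }))
  tr <- snp_incidence(segs, map, 10)
  for (top in c(0.01, 0.05, 0.2)) {
    reg <- call_hotspots(tr, top)
    thr <- attr(reg, "threshold_pct")
    expect_equal(sum(reg$n_snp),
                 sum(tr$incidence_pct >= thr & tr$incidence_pct > 0))
  }
})

test_that("hotspot calling is invariant to marker-order permutation", {
  set.seed(3)
  map <- mk_map(sort(sample.int(1e8, 300)))
  segs <- seg_row("A", 1, 2e7, 3e7)
  shuf <- sample.int(nrow(map))
  tr1 <- snp_incidence(segs, map, 4)
  tr2 <- snp_incidence(segs, map[shuf, ], 4)
  expect_equal(call_hotspots(tr1), call_hotspots(tr2))
})

test_that("top_fraction outside (0,1) is rejected", {
  tr <- snp_incidence(seg_row("A", 1, 0, 2e6), mk_map(c(1e6)), 2)
  expect_error(call_hotspots(tr, 0), "top_fraction")
  expect_error(call_hotspots(tr, 1), "top_fraction")
})

test_that("gene counting uses closed-interval overlap", {
  region <- list(chrom = 1L, start_bp = 1e6, stop_bp = 2e6)
  expect_equal(count_genes(region, NULL), 0L)
  ann <- data.frame(
    chrom = c(1L, 1L, 1L, 1L, 1L, 2L),
    start_bp = c(1.2e6, 1.5e6, 1.9e6, 2e6, 3e6, 1.2e6),
    end_bp = c(1.3e6, 1.6e6, 2.4e6, 2.2e6, 3.5e6, 1.3e6),
    gene_id = paste0("g", 1:6), stringsAsFactors = FALSE)
  # two inside, one straddling the boundary -> 3 ... plus the abutting gene
  expect_equal(count_genes(region, ann[c(1, 2, 3, 5), ]), 3L)
  # gene starting exactly at the region stop is counted (closed intervals)
  expect_equal(count_genes(region, ann), 4L)
})

test_that("recombination rate interpolates the genetic map piecewise", {
  gm <- genetic_map(data.frame(chrom = 1L, pos_bp = c(0, 2e6, 4e6),
                               cM = c(0, 1, 3)))
  expect_equal(region_recomb_rate(list(chrom = 1L, start_bp = 1e6,
                                       stop_bp = 3e6), gm), 0.75)
  uni <- genetic_map(data.frame(chrom = 1L, pos_bp = c(0, 1e8),
                                cM = c(0, 100)))
  expect_equal(region_recomb_rate(list(chrom = 1L, start_bp = 5e6,
                                       stop_bp = 42e6), uni), 1.0)
  expect_true(is.na(region_recomb_rate(list(chrom = 1L, start_bp = 1e6,
                                            stop_bp = 1e6), uni)))
  expect_error(region_recomb_rate(list(chrom = 5L, start_bp = 1e6,
                                       stop_bp = 3e6), uni), "absent")
})

test_that("a tract shared by 30% of samples is called as one clean hotspot", {
  sim <- simulate_cohort(sim_config(
    n_samples = 50, n_chromosomes = 4, markers_per_chromosome = 2000,
    target_F = 0, error_rate = 0, missing_rate = 0.01,
    hotspot = list(chrom = 2, start_bp = 40e6, end_bp = 43e6,
                   carrier_fraction = 0.3), seed = 404))
  fit <- roh(sim$genotypes, qc = qc_params(min_hwe_p = 0))
  hs <- roh_hotspots(fit)
  reg <- hs$regions
  on2 <- reg[reg$chrom == 2L, , drop = FALSE]
  expect_equal(nrow(on2), 1L)
  mk <- fit$genotypes$map
  int_idx <- mk$chrom == 2L & mk$pos_bp >= 40e6 & mk$pos_bp <= 43e6
  covered <- mk$chrom == 2L & mk$pos_bp >= on2$start_bp &
    mk$pos_bp <= on2$stop_bp
  expect_gte(sum(int_idx & covered) / sum(int_idx), 0.9)
})
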