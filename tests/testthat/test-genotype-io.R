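# PED/MAP and BED/BIM/FAM parsing, coding conventions, genetic map and
# ROH-table round trips.

write_tiny_ped <- function(dir, ped_lines, map_lines) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  c(ped = ped, map = map)
}

test_that("PED alleles are recoded to minor-allele dosage with lexicographic ties", {
  d <- withr::local_tempdir()
  p <- write_tiny_ped(d,
    c("F1 S1 0 0 0 -9 A A",
      "F2 S2 0 0 0 -9 A G",
      "F3 S3 0 0 0 -9 G G"),
    "1 snp1 0 1000")
  g <- read_ped_map(p["ped"], p["map"])
  # counts tie 3:3 -> minor is lexicographically smaller allele A
  expect_equal(unname(g$calls[, 1]), c(2L, 1L, 0L))
  expect_equal(g$samples, c("S1", "S2", "S3"))
})

test_that("homozygote for the only observed allele has dosage 2; 0 0 is missing", {
  d <- withr::local_tempdir()
  p <- write_tiny_ped(d,
    c("F1 S1 0 0 0 -9 A A C C",
      "F2 S2 0 0 0 -9 0 0 C T"),
    c("1 snp1 0 1000", "1 snp2 0 2000"))
  g <- read_ped_map(p["ped"], p["map"])
  # snp1: only A observed; the unobserved allele is "minor" -> S1 dosage is
  # homozygous-major (0 copies of the minor allele), S2 missing
  expect_true(is.na(g$calls["S2", "snp1"]))
  expect_false(is.na(g$calls["S1", "snp1"]))
  expect_equal(unname(g$calls[, "snp2"]), c(0L, 1L))
})

test_that("PED format errors are caught", {
  d <- withr::local_tempdir()
  p <- write_tiny_ped(d, "F1 S1 0 0 0 -9 A A", # one marker in PED
                      c("1 snp1 0 1000", "1 snp2 0 2000"))
  expect_error(read_ped_map(p["ped"], p["map"]), "mismatch")
  p2 <- write_tiny_ped(d,
    c("F1 S1 0 0 0 -9 A A", "F2 S2 0 0 0 -9 C G", "F3 S3 0 0 0 -9 T T"),
    "1 snp1 0 1000")
  expect_error(read_ped_map(p2["ped"], p2["map"]), ">2 distinct alleles")
})

test_that("non-autosomal markers are dropped and markers sorted by position", {
  d <- withr::local_tempdir()
  p <- write_tiny_ped(d,
    "F1 S1 0 0 0 -9 A G C C T T A A",
    c("1 snp_b 0 5000", "X snp_x 0 100", "1 snp_a 0 1000", "0 snp_u 0 1")
  )
  expect_message(g <- read_ped_map(p["ped"], p["map"]), "2 non-autosomal")
  expect_equal(g$map$id, c("snp_a", "snp_b"))
  expect_equal(g$map$pos_bp, c(1000, 5000))
})

test_that("duplicate positions within a chromosome are rejected", {
  expect_error(make_geno(matrix(0L, 1, 2), pos = c(100, 100)), "duplicate")
})

test_that("BED/BIM/FAM round trip is call-identical and byte-stable", {
  set.seed(42)
  n <- 20; m <- 100
  p <- runif(m, 0.1, 0.45)
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n)
  calls[runif(n * m) < 0.04] <- NA
  # canonicalize to observed-minor coding (what the readers guarantee)
  dos <- colSums(calls, na.rm = TRUE); nob <- colSums(!is.na(calls))
  flip <- dos > 2 * nob - dos
  calls[, flip] <- 2L - calls[, flip]
  g <- make_geno(calls, pos = sort(sample.int(5e6, m)))

  d <- withr::local_tempdir()
  prefix <- file.path(d, "rt")
  write_bed_bim_fam(g, prefix)
  g2 <- read_bed_bim_fam(prefix)
  expect_equal(g2$calls, g$calls, ignore_attr = FALSE)
  expect_equal(g2$samples, g$samples)
  write_bed_bim_fam(g2, file.path(d, "rt2"))
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 1e6),
                   readBin(file.path(d, "rt2.bed"), "raw", 1e6))
})

test_that("PLINK missing code 01 decodes to NA", {
  g <- make_geno(matrix(c(0L, NA, 1L, 0L), 2, 2),
                 pos = c(1000, 2000))
  d <- withr::local_tempdir()
  prefix <- file.path(d, "na")
  write_bed_bim_fam(g, prefix)
  g2 <- read_bed_bim_fam(prefix)
  expect_true(is.na(g2$calls[2, 1]))
  expect_equal(g2$calls, g$calls)
})

test_that("bad BED magic bytes raise a format error", {
  d <- withr::local_tempdir()
  prefix <- file.path(d, "bad")
  g <- make_geno(matrix(0L, 2, 2), pos = c(1, 2))
  write_bed_bim_fam(g, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_bed_bim_fam(prefix), "magic")
})

test_that("PED/MAP and BED/BIM/FAM readers agree on random cohorts", {
  for (seed in c(3, 17, 29)) {
    g <- random_roh_fixture(seed, n_samples = 4, n_markers = 120)
    d <- withr::local_tempdir()
    write_ped_map(g, file.path(d, "x"))
    write_bed_bim_fam(g, file.path(d, "x"))
    ga <- read_ped_map(file.path(d, "x.ped"), file.path(d, "x.map"))
    gb <- read_bed_bim_fam(file.path(d, "x"))
    expect_equal(ga$calls, gb$calls)
    expect_equal(ga$map$pos_bp, gb$map$pos_bp)
    expect_equal(ga$samples, gb$samples)
  }
})

test_that("genetic map loads, validates and is order-invariant", {
  d <- withr::local_tempdir()
  f <- file.path(d, "gmap.tsv")
  rows <- c("1\t0\t0", "1\t1000000\t1", "2\t100\t0", "2\t2000000\t2.5")
  writeLines(rows, f)
  gm <- read_genetic_map(f)
  expect_s3_class(gm, "genetic_map")
  expect_equal(interpolate_cm(gm, 1, 5e5), 0.5)

  writeLines(rev(rows), f)
  gm2 <- read_genetic_map(f)
  expect_equal(as.data.frame(gm2), as.data.frame(gm))

  writeLines(c("1\t0\t0"), f)
  expect_error(read_genetic_map(f), "fewer than 2")

  writeLines(c("1\t0\t1", "1\t1000\t0.5"), f)
  expect_error(read_genetic_map(f), "cM decreases.*1000")
})

test_that("ROH table writes PLINK .hom-style rows and round-trips", {
  seg <- data.frame(sample_id = "S1", chrom = 2L, start_bp = 1e6,
                    end_bp = 2540000, n_snp = 55L,
                    start_snp = "a", end_snp = "b",
                    length_bp = 1540000, length_mb = 1.54,
                    stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  f <- file.path(d, "out.hom")
  write_roh_table(seg, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$KB, 1540.0)
  back <- read_roh_table(f)
  expect_equal(back, seg)

  write_roh_table(seg[0, ], f)
  expect_equal(length(readLines(f)), 1L)  # header only
  expect_equal(nrow(read_roh_table(f)), 0L)
})
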