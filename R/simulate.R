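#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a medium-density ovine SNP-array cohort: 26 autosomes
#' of 100 Mb with 2000 markers each (52,000 markers genome-wide, one per
#' 50 kb on average), Hardy-Weinberg background genotypes with per-marker
#' minor allele frequencies drawn Uniform(0.05, 0.5), a uniform 1 cM/Mb
#' genetic map, and planted autozygous tracts whose genetic lengths follow
#' the exponential distribution Exp(mean 100/(2 g)) cM expected for
#' autozygosity coalescing g generations back. Genotyping error flips a
#' homozygous call inside a planted tract to a heterozygote with
#' probability `error_rate`; every call is set missing with probability
#' `missing_rate`.
#'
#' @param n_samples cohort size.
#' @param n_chromosomes number of autosomes.
#' @param markers_per_chromosome markers per autosome.
#' @param chromosome_length_bp autosome length (bp).
#' @param maf_range range of the uniform per-marker allele-frequency draw.
#' @param target_F fraction of each genome to cover with planted autozygous
#'   tracts (0 disables planting).
#' @param generation_depth g controlling tract genetic lengths,
#'   Exp(mean 100/(2 g)) cM.
#' @param error_rate per-call probability that a homozygote inside a
#'   planted tract is mis-called as a heterozygote.
#' @param missing_rate per-call missingness probability.
#' @param cm_per_mb uniform genetic-map rate.
#' @param hotspot optional list `(chrom, start_bp, end_bp, carrier_fraction)`
#'   forcing a shared autozygous tract into that fraction of samples.
#' @param seed RNG seed; a fixed seed makes the cohort fully reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200L, n_chromosomes = 26L,
                       markers_per_chromosome = 2000L,
                       chromosome_length_bp = 1e8,
                       maf_range = c(0.05, 0.5), target_F = 0.05,
                       generation_depth = 6, error_rate = 0.001,
                       missing_rate = 0.02, cm_per_mb = 1,
                       hotspot = NULL, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              chromosome_length_bp = chromosome_length_bp,
              maf_range = maf_range, target_F = target_F,
              generation_depth = generation_depth, error_rate = error_rate,
              missing_rate = missing_rate, cm_per_mb = cm_per_mb,
              hotspot = hotspot, seed = as.integer(seed))
  stopifnot(cfg$n_samples > 0, cfg$n_chromosomes > 0,
            cfg$markers_per_chromosome > 1,
            cfg$target_F >= 0, cfg$target_F <= 1,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1)
  if (!is.null(hotspot))
    stopifnot(all(c("chrom", "start_bp", "end_bp", "carrier_fraction")
                  %in% names(hotspot)))
  structure(cfg, class = "sim_config")
}

# draw non-overlapping tracts for one sample until the autozygous fraction
# reaches target; returns a data.frame(chrom, start_bp, end_bp)
.draw_tracts <- function(cfg, existing, total_bp) {
  tracts <- existing
  covered <- if (nrow(tracts)) sum(tracts$end_bp - tracts$start_bp) else 0
  target_bp <- cfg$target_F * total_bp
  tries <- 0L
  while (covered < target_bp) {
    len_cm <- stats::rexp(1, rate = 2 * cfg$generation_depth / 100)
    len_bp <- max(1, round(len_cm / cfg$cm_per_mb * 1e6))
    len_bp <- min(len_bp, cfg$chromosome_length_bp - 1)
    ch <- sample.int(cfg$n_chromosomes, 1)
    start <- sample.int(cfg$chromosome_length_bp - len_bp, 1)
    end <- start + len_bp
    clash <- nrow(tracts) && any(tracts$chrom == ch &
                                   tracts$start_bp <= end &
                                   tracts$end_bp >= start)
    if (clash) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("target_F infeasible: could not place non-overlapping tracts")
      next
    }
    tracts <- rbind(tracts, data.frame(chrom = ch, start_bp = start,
                                       end_bp = end))
    covered <- covered + len_bp
  }
  tracts
}

# recode to observed-minor dosage so the matrix round-trips exactly through
# the PED/BED readers (tie broken toward the lexicographically smaller label)
.canonicalize_minor <- function(calls, map) {
  n_obs <- colSums(!is.na(calls))
  dos <- colSums(calls, na.rm = TRUE)
  flip <- dos > (2 * n_obs - dos) |
    (dos == (2 * n_obs - dos) & map$a1 > map$a2)
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip, drop = FALSE]
    tmp <- map$a1[flip]
    map$a1[flip] <- map$a2[flip]
    map$a2[flip] <- tmp
  }
  list(calls = calls, map = map)
}

#' Simulate a genotype cohort with planted autozygous tracts
#'
#' Background genotypes are drawn marker-independently from Hardy-Weinberg
#' proportions at the marker's allele frequency. Within a planted tract the
#' sample is autozygous: one haplotype is drawn (allele with probability p
#' per marker) and doubled. Genotyping error then flips tract homozygotes
#' to heterozygotes with probability `error_rate`, and every call is set
#' missing with probability `missing_rate`. Marker positions are drawn
#' uniformly (without replacement, hence deduplicated) and sorted. The
#' genetic map is uniform at `cm_per_mb`.
#'
#' @param cfg a [sim_config].
#' @return list of class `sim_cohort`: `genotypes` (a [genotype_matrix]),
#'   `gmap` (a `genetic_map`), `truth` (list with `tracts` — one row per
#'   planted tract: `sample_id`, `chrom`, `start_bp`, `end_bp` — and
#'   `per_sample` with the true autozygous fraction `F_true`),
#'   `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  m_per <- cfg$markers_per_chromosome
  n_chr <- cfg$n_chromosomes
  len <- cfg$chromosome_length_bp
  total_bp <- n_chr * len
  samples <- sprintf("sim%04d", seq_len(n))

  pos <- integer(0); chrom <- integer(0)
  for (ch in seq_len(n_chr)) {
    pos <- c(pos, sort(sample.int(len, m_per)))
    chrom <- c(chrom, rep.int(ch, m_per))
  }
  m <- length(pos)
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  map <- data.frame(chrom = chrom,
                    id = paste0("snp", chrom, "_", pos),
                    pos_bp = as.numeric(pos), cM = 0,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)

  calls <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)

  # planted tracts: optional shared hotspot tract first, then per-sample
  # random tracts rejected on overlap
  tracts_by_sample <- rep(list(data.frame(chrom = integer(),
                                          start_bp = numeric(),
                                          end_bp = numeric())), n)
  if (!is.null(cfg$hotspot)) {
    hs <- cfg$hotspot
    n_car <- ceiling(hs$carrier_fraction * n)
    carriers <- sample.int(n, n_car)
    for (s in carriers)
      tracts_by_sample[[s]] <- data.frame(chrom = as.integer(hs$chrom),
                                          start_bp = hs$start_bp,
                                          end_bp = hs$end_bp)
  }
  if (cfg$target_F >= 0.999) {
    for (s in seq_len(n))
      tracts_by_sample[[s]] <- data.frame(chrom = seq_len(n_chr),
                                          start_bp = 1,
                                          end_bp = len)
  } else if (cfg$target_F > 0 || !is.null(cfg$hotspot)) {
    for (s in seq_len(n))
      tracts_by_sample[[s]] <- .draw_tracts(cfg, tracts_by_sample[[s]],
                                            total_bp)
  }

  for (s in seq_len(n)) {
    tr <- tracts_by_sample[[s]]
    for (k in seq_len(nrow(tr))) {
      idx <- which(map$chrom == tr$chrom[k] & map$pos_bp >= tr$start_bp[k] &
                     map$pos_bp <= tr$end_bp[k])
      if (!length(idx)) next
      hap <- stats::rbinom(length(idx), 1L, p[idx])
      g <- 2L * hap
      if (cfg$error_rate > 0) {
        flip <- stats::runif(length(idx)) < cfg$error_rate
        g[flip] <- 1L
      }
      calls[s, idx] <- g
    }
  }
  if (cfg$missing_rate > 0)
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_

  cc <- .canonicalize_minor(calls, map)
  geno <- genotype_matrix(cc$calls, cc$map, samples)

  gmap <- genetic_map(data.frame(
    chrom = rep(seq_len(n_chr), each = 2),
    pos_bp = rep(c(1, len), n_chr),
    cM = rep(c(0, cfg$cm_per_mb * (len - 1) / 1e6), n_chr)))

  tr_all <- do.call(rbind, lapply(seq_len(n), function(s) {
    tr <- tracts_by_sample[[s]]
    if (nrow(tr)) cbind(sample_id = samples[s], tr,
                        stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(tr_all))
    tr_all <- data.frame(sample_id = character(), chrom = integer(),
                         start_bp = numeric(), end_bp = numeric())
  f_true <- vapply(tracts_by_sample, function(tr)
    if (nrow(tr)) sum(tr$end_bp - tr$start_bp) / total_bp else 0, numeric(1))
  truth <- list(tracts = tr_all,
                per_sample = data.frame(sample_id = samples, F_true = f_true,
                                        stringsAsFactors = FALSE))
  structure(list(genotypes = geno, gmap = gmap, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$genotypes$samples), "samples,",
      nrow(x$genotypes$map), "markers,",
      nrow(x$truth$tracts), "planted tracts\n")
  cat(sprintf("  mean true autozygosity F_true = %.4f\n",
              mean(x$truth$per_sample$F_true)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes PED/MAP and BED/BIM/FAM genotypes, the genetic map as TSV
#' (chrom, bp, cM) and the planted-tract truth as TSV.
#'
#' @param sim a `sim_cohort`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_cohort <- function(sim, prefix) {
  write_ped_map(sim$genotypes, prefix)
  write_bed_bim_fam(sim$genotypes, prefix)
  gm <- sim$gmap
  utils::write.table(
    data.frame(gm$chrom, format(gm$pos_bp, scientific = FALSE, trim = TRUE),
               gm$cM),
    paste0(prefix, ".gmap.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$tracts, paste0(prefix, ".truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Generate a synthetic gene annotation inside given intervals
#'
#' Emits `k` non-overlapping genes uniformly inside each supplied interval;
#' used to build annotation fixtures with known overlap counts.
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp`, `k`
#'   (genes per interval).
#' @param gene_length_bp fixed gene length.
#' @return gene annotation data.frame (`chrom`, `start_bp`, `end_bp`,
#'   `gene_id`), sorted.
#' @export
simulate_gene_bed <- function(intervals, gene_length_bp = 10000) {
  rows <- list()
  gi <- 0L
  for (i in seq_len(nrow(intervals))) {
    k <- intervals$k[i]
    if (k == 0) next
    span <- intervals$end_bp[i] - intervals$start_bp[i]
    starts <- intervals$start_bp[i] +
      floor((seq_len(k) - 1) * span / k)
    for (s in starts) {
      gi <- gi + 1L
      rows[[gi]] <- data.frame(
        chrom = intervals$chrom[i], start_bp = s,
        end_bp = min(s + gene_length_bp, intervals$end_bp[i]),
        gene_id = paste0("gene", gi), stringsAsFactors = FALSE)
    }
  }
  if (!gi) return(data.frame(chrom = integer(), start_bp = numeric(),
                             end_bp = numeric(), gene_id = character()))
  ann <- do.call(rbind, rows)
  ann[order(ann$chrom, ann$start_bp), , drop = FALSE]
}
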