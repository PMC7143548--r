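#' Quality-control parameters
#'
#' Default thresholds for SNP-array QC: per-marker call rate >= 0.95,
#' minor allele frequency >= 0.01, exact Hardy-Weinberg p > 1e-6, and
#' per-sample call rate > 0.9.
#'
#' @param min_snp_call_rate markers with call rate strictly below this are
#'   removed.
#' @param min_maf markers with minor allele frequency strictly below this are
#'   removed.
#' @param min_hwe_p markers with exact HWE p-value <= this are removed.
#' @param min_sample_call_rate samples with call rate <= this are removed.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_snp_call_rate = 0.95, min_maf = 0.01,
                      min_hwe_p = 1e-6, min_sample_call_rate = 0.9) {
  p <- list(min_snp_call_rate = min_snp_call_rate, min_maf = min_maf,
            min_hwe_p = min_hwe_p, min_sample_call_rate = min_sample_call_rate)
  if (any(unlist(p) < 0 | unlist(p) > 1))
    stop("QC thresholds must lie in [0, 1]")
  structure(p, class = "qc_params")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts at a biallelic marker,
#' conditioning on the observed allele counts: the p-value is the sum of the
#' conditional probabilities of all heterozygote counts whose probability
#' does not exceed that of the observed count.
#'
#' Probabilities are computed by the standard recurrence over heterozygote
#' counts (numerically stable, normalized at the end). Configurations whose
#' probability is within a relative 1e-10 of the observed one are treated as
#' tied and included, so exact mathematical ties are never split by
#' floating-point rounding.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  a <- as.integer(n_hom_ref); b <- as.integer(n_het); c <- as.integer(n_hom_alt)
  if (any(c(a, b, c) < 0)) stop("genotype counts must be non-negative")
  n <- a + b + c
  if (n == 0) stop("HWE test undefined: no genotypes observed")
  n1 <- 2L * a + b           # copies of the "ref" allele
  n2 <- 2L * c + b
  nr <- min(n1, n2)          # rare-allele copies
  if (nr == 0) return(1.0)   # monomorphic: single possible configuration

  # heterozygote counts share the parity of the rare allele count
  hs <- seq(nr %% 2L, nr, by = 2L)
  # recurrence: P(h+2)/P(h) = (nr-h)(nc-h) / ((h+2)(h+1)) with nc = common
  # allele copies; work in log space from the smallest h upward
  nc <- 2L * n - nr
  logp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    logp[i] <- logp[i - 1] +
      log(nr - h) + log(nc - h) - log(h + 2) - log(h + 1)
  }
  logp <- logp - max(logp)
  p_h <- exp(logp)
  p_h <- p_h / sum(p_h)
  obs <- p_h[match(b, hs)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p_h[p_h <= obs * (1 + 1e-10)]))
}

#' Genotype counts per marker
#'
#' @param geno a [genotype_matrix].
#' @return integer matrix with rows `n0`, `n1`, `n2` (dosage 0/1/2 counts)
#'   and one column per marker.
#' @export
genotype_counts <- function(geno) {
  cc <- geno$calls
  rbind(n0 = colSums(cc == 0L, na.rm = TRUE),
        n1 = colSums(cc == 1L, na.rm = TRUE),
        n2 = colSums(cc == 2L, na.rm = TRUE))
}

#' Apply marker and sample quality control
#'
#' Filter order: (1) samples with call rate <= `min_sample_call_rate` are
#' removed; (2) on the surviving samples, markers are removed when the call
#' rate is below `min_snp_call_rate`, the minor allele frequency is below
#' `min_maf`, or the exact HWE p-value is <= `min_hwe_p`. Each removed
#' marker is tallied under the first criterion (in that order) it fails.
#'
#' @param geno a [genotype_matrix].
#' @param params a [qc_params] list.
#' @return list with elements `genotypes` (filtered [genotype_matrix]) and
#'   `report` (class `qc_report`: per-criterion removal counts and surviving
#'   dimensions).
#' @export
apply_qc <- function(geno, params = qc_params()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n_in <- length(geno$samples)
  m_in <- nrow(geno$map)

  sample_cr <- rowMeans(!is.na(geno$calls))
  drop_sample <- sample_cr <= params$min_sample_call_rate
  if (all(drop_sample)) stop("empty cohort: all samples fail call-rate QC")
  cc <- geno$calls[!drop_sample, , drop = FALSE]

  n_srv <- nrow(cc)
  n_obs <- colSums(!is.na(cc))
  call_rate <- n_obs / n_srv
  n1 <- colSums(cc == 1L, na.rm = TRUE)
  n2 <- colSums(cc == 2L, na.rm = TRUE)
  dos <- 2L * n2 + n1
  maf <- ifelse(n_obs > 0, pmin(dos, 2 * n_obs - dos) / (2 * n_obs), 0)

  fail_cr <- call_rate < params$min_snp_call_rate
  fail_maf <- !fail_cr & maf < params$min_maf
  rest <- which(!fail_cr & !fail_maf & n_obs > 0)
  n0 <- n_obs - n1 - n2
  hwe_p <- rep(NA_real_, length(call_rate))
  hwe_p[rest] <- vapply(rest, function(j) hwe_exact_p(n0[j], n1[j], n2[j]),
                        numeric(1))
  fail_hwe <- !fail_cr & !fail_maf & !is.na(hwe_p) & hwe_p <= params$min_hwe_p

  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop("empty cohort: all markers removed by QC")

  out <- genotype_matrix(cc[, keep, drop = FALSE],
                         geno$map[keep, , drop = FALSE],
                         geno$samples[!drop_sample])
  if (!is.null(geno$fam)) out$fam <- geno$fam[!drop_sample, , drop = FALSE]
  report <- structure(list(
    n_samples_in = n_in, n_markers_in = m_in,
    samples_removed_call_rate = sum(drop_sample),
    markers_removed_call_rate = sum(fail_cr),
    markers_removed_maf = sum(fail_maf),
    markers_removed_hwe = sum(fail_hwe),
    n_samples_out = length(out$samples), n_markers_out = nrow(out$map),
    params = params), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples: %d -> %d (removed %d by call rate <= %.3g)\n",
              x$n_samples_in, x$n_samples_out, x$samples_removed_call_rate,
              x$params$min_sample_call_rate))
  cat(sprintf("  markers: %d -> %d\n", x$n_markers_in, x$n_markers_out))
  cat(sprintf("    removed: %d call rate, %d MAF, %d HWE\n",
              x$markers_removed_call_rate, x$markers_removed_maf,
              x$markers_removed_hwe))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  keys <- c("n_samples_in", "n_markers_in", "samples_removed_call_rate",
            "markers_removed_call_rate", "markers_removed_maf",
            "markers_removed_hwe", "n_samples_out", "n_markers_out")
  utils::write.table(data.frame(key = keys,
                                value = unlist(report[keys])),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
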