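# Fixture builders shared across the suite. Everything is generated in code;
# no on-disk test data.

# Quick genotype_matrix from a call matrix and positions on one or more
# chromosomes.
make_geno <- function(calls, pos, chrom = 1L, samples = NULL) {
  calls <- rbind(calls)
  m <- ncol(calls)
  if (length(chrom) == 1L) chrom <- rep.int(chrom, m)
  map <- data.frame(chrom = as.integer(chrom),
                    id = paste0("m", seq_len(m), "_", chrom),
                    pos_bp = as.numeric(pos), stringsAsFactors = FALSE)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  genotype_matrix(calls, map, samples)
}

# Random genotype fixture with homozygous stretches planted so that the
# detector has real work to do; used for oracle-equivalence checks.
random_roh_fixture <- function(seed, n_samples = NULL, n_markers = NULL,
                               n_chrom = NULL) {
  set.seed(seed)
  if (is.null(n_samples)) n_samples <- sample(1:5, 1)
  if (is.null(n_markers)) n_markers <- sample(150:500, 1)
  if (is.null(n_chrom)) n_chrom <- sample(1:2, 1)
  per <- ceiling(n_markers / n_chrom)
  chrom <- rep(seq_len(n_chrom), each = per)[seq_len(n_markers)]
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(ix)
    sort(sample.int(25000L * length(ix), length(ix)))))
  calls <- matrix(sample(c(0L, 1L, 2L, NA), n_samples * n_markers,
                         replace = TRUE,
                         prob = c(0.45, 0.12, 0.38, 0.05)),
                  nrow = n_samples)
  # plant 0-3 homozygous stretches per sample
  for (s in seq_len(n_samples)) {
    for (k in seq_len(sample(0:3, 1))) {
      len <- sample(40:120, 1)
      a <- sample(seq_len(max(1, n_markers - len)), 1)
      calls[s, a:(a + len - 1)] <- sample(c(0L, 2L), len, replace = TRUE)
    }
  }
  make_geno(calls, pos, chrom)
}

# random detection parameters exercising different boundary regimes
random_roh_params <- function(seed) {
  set.seed(seed + 7919L)
  roh_params(window_snp = sample(c(10L, 25L, 50L), 1),
             window_max_het = sample(0:1, 1) + 1L,
             window_max_missing = sample(2:5, 1),
             window_hit_threshold = sample(c(0.02, 0.05, 0.1), 1),
             min_snp = sample(c(15L, 25L, 40L), 1),
             min_length_kb = sample(c(200, 500, 1000), 1),
             max_gap_kb = sample(c(250, 1000), 1),
             max_density_kb_per_snp = sample(c(60, 100), 1))
}

# Independent HWE oracle: direct enumeration of all heterozygote counts via
# log-factorials (no recurrence), same tie rule as the implementation.
hwe_oracle <- function(a, b, c) {
  n <- a + b + c
  n1 <- 2 * a + b
  n2 <- 2 * c + b
  nr <- min(n1, n2)
  if (nr == 0) return(1.0)
  hs <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hs, function(h) {
    hr <- (nr - h) / 2      # rare homozygotes
    hc <- (n - h - hr)      # common homozygotes
    h * log(2) + lgamma(n + 1) -
      (lgamma(hr + 1) + lgamma(h + 1) + lgamma(hc + 1))
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(b, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# a cohort in exact HWE proportions with MAF 0.5 and complete calls
balanced_geno <- function(n_samples = 100, n_markers = 60,
                          spacing = 20000) {
  stopifnot(n_samples %% 4 == 0)
  col <- rep(c(0L, 1L, 1L, 2L), n_samples / 4)
  calls <- matrix(col, nrow = n_samples, ncol = n_markers)
  # stagger rows so samples are not identical
  for (j in seq_len(n_markers)) calls[, j] <- col[((seq_len(n_samples) + j) %%
                                                     n_samples) + 1]
  make_geno(calls, pos = seq(1, by = spacing, length.out = n_markers))
}
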