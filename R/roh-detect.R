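#' Parameters for scanning-window ROH detection
#'
#' Defaults follow the PLINK `--homozyg` criteria customarily used for
#' medium-density ovine arrays: minimum run length 1 Mb, at least 40 SNPs per
#' run, at most one heterozygote and five missing calls per 50-SNP scanning
#' window, maximum density 100 kb/SNP, and a maximum gap of 1 Mb between
#' consecutive SNPs in a run.
#'
#' @param window_snp scanning-window size in markers.
#' @param window_max_het maximum heterozygous calls per qualifying window.
#' @param window_max_missing maximum missing calls per qualifying window.
#' @param window_hit_threshold minimum fraction of qualifying windows
#'   covering a marker for it to be run-eligible (compared with `>=`).
#' @param min_snp minimum markers per reported run.
#' @param min_length_kb minimum run length in kb (length = end - start).
#' @param max_gap_kb maximum gap between consecutive run markers, kb.
#' @param max_density_kb_per_snp maximum kb per SNP within a run.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_max_het = 1L,
                       window_max_missing = 5L, window_hit_threshold = 0.05,
                       min_snp = 40L, min_length_kb = 1000,
                       max_gap_kb = 1000, max_density_kb_per_snp = 100) {
  p <- list(window_snp = as.integer(window_snp),
            window_max_het = as.integer(window_max_het),
            window_max_missing = as.integer(window_max_missing),
            window_hit_threshold = window_hit_threshold,
            min_snp = as.integer(min_snp), min_length_kb = min_length_kb,
            max_gap_kb = max_gap_kb,
            max_density_kb_per_snp = max_density_kb_per_snp)
  if (any(unlist(p) <= 0)) stop("all ROH parameters must be positive")
  if (p$window_max_het >= p$window_snp)
    stop("window_max_het must be smaller than window_snp")
  structure(p, class = "roh_params")
}

# Run-eligibility of each marker of one sample on one chromosome:
# slide a window of `w` consecutive markers; a window qualifies when it has
# <= max_het heterozygotes and <= max_miss missing calls; a marker is
# eligible when (qualifying windows covering it) / (windows covering it)
# >= threshold. Cumulative sums make this O(m).
.marker_eligible <- function(g, pos, p) {
  m <- length(g)
  w <- min(p$window_snp, m)
  nw <- m - w + 1L
  het <- cumsum(c(0L, !is.na(g) & g == 1L))
  mis <- cumsum(c(0L, is.na(g)))
  hc <- het[(w + 1L):(m + 1L)] - het[1:nw]
  mc <- mis[(w + 1L):(m + 1L)] - mis[1:nw]
  qual <- cumsum(c(0L, hc <= p$window_max_het & mc <= p$window_max_missing))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  hits <- qual[hi + 1L] - qual[lo]
  hits / (hi - lo + 1L) >= p$window_hit_threshold
}

# Split maximal TRUE stretches at large gaps and apply the run filters.
.stretches_to_segments <- function(eligible, pos, ids, p) {
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    gaps <- diff(pos[idx])
    cut_after <- which(gaps > p$max_gap_kb * 1000)
    piece_start <- c(idx[1], idx[cut_after + 1L])
    piece_end <- c(idx[cut_after], idx[length(idx)])
    for (q in seq_along(piece_start)) {
      a <- piece_start[q]; b <- piece_end[q]
      ns <- b - a + 1L
      len_bp <- pos[b] - pos[a]
      if (ns < p$min_snp) next
      if (len_bp / 1000 < p$min_length_kb) next
      if ((len_bp / 1000) / ns > p$max_density_kb_per_snp) next
      out[[length(out) + 1L]] <- list(a = a, b = b, ns = ns, len = len_bp)
    }
  }
  out
}

#' Detect runs of homozygosity
#'
#' PLINK-style scanning-window ROH detection. For every sample and
#' chromosome, a window of `window_snp` consecutive markers slides one
#' marker at a time; a window qualifies when it contains at most
#' `window_max_het` heterozygotes and `window_max_missing` missing calls.
#' Each marker's hit rate is the fraction of windows covering it that
#' qualify; markers with hit rate >= `window_hit_threshold` are
#' run-eligible. Maximal stretches of consecutive run-eligible markers are
#' split at inter-marker gaps larger than `max_gap_kb` and then filtered by
#' `min_snp`, `min_length_kb` and `max_density_kb_per_snp`. Chromosomes
#' with fewer than `window_snp` markers use a single window of all
#' available markers.
#'
#' @param geno a QC-passed [genotype_matrix] (markers sorted).
#' @param params a [roh_params] list.
#' @return data.frame of segments sorted by (sample, chromosome, start):
#'   `sample_id`, `chrom`, `start_bp`, `end_bp` (positions of the first and
#'   last marker of the run), `n_snp`, `start_snp`, `end_snp`,
#'   `length_bp = end_bp - start_bp`, `length_mb`.
#' @export
detect_roh <- function(geno, params = roh_params()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno$calls) == 0 || ncol(geno$calls) == 0)
    stop("empty genotype matrix")
  map <- geno$map
  if (is.unsorted(order(map$chrom, map$pos_bp)))
    stop("markers must be sorted by (chromosome, position)")
  chroms <- unique(map$chrom)
  res <- vector("list", length(chroms) * length(geno$samples))
  ri <- 0L
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    pos <- map$pos_bp[sel]
    ids <- map$id[sel]
    for (s in seq_along(geno$samples)) {
      g <- geno$calls[s, sel]
      elig <- .marker_eligible(g, pos, params)
      segs <- .stretches_to_segments(elig, pos, ids, params)
      if (!length(segs)) next
      ri <- ri + 1L
      res[[ri]] <- data.frame(
        sample_id = geno$samples[s], chrom = ch,
        start_bp = pos[vapply(segs, function(x) x$a, integer(1))],
        end_bp = pos[vapply(segs, function(x) x$b, integer(1))],
        n_snp = vapply(segs, function(x) as.integer(x$ns), integer(1)),
        start_snp = ids[vapply(segs, function(x) x$a, integer(1))],
        end_snp = ids[vapply(segs, function(x) x$b, integer(1))],
        stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L) return(.empty_segments())
  seg <- do.call(rbind, res[seq_len(ri)])
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg$length_mb <- seg$length_bp / 1e6
  seg <- seg[order(match(seg$sample_id, geno$samples), seg$chrom,
                   seg$start_bp), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Brute-force ROH detection (test oracle)
#'
#' A direct, non-incremental evaluation of the [detect_roh()] contract:
#' every window is enumerated explicitly, per-marker hit rates are computed
#' by scanning all windows, stretches are assembled marker by marker, and
#' the run filters are applied segment by segment. Intended for small
#' instances in tests only.
#'
#' @inheritParams detect_roh
#' @return same layout as [detect_roh()].
#' @export
brute_force_roh <- function(geno, params = roh_params()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno$calls) == 0 || ncol(geno$calls) == 0)
    stop("empty genotype matrix")
  map <- geno$map
  rows <- list()
  for (s in seq_along(geno$samples)) {
    for (ch in unique(map$chrom)) {
      sel <- which(map$chrom == ch)
      g <- geno$calls[s, sel]
      pos <- map$pos_bp[sel]
      ids <- map$id[sel]
      m <- length(g)
      w <- min(params$window_snp, m)
      win_start <- seq_len(m - w + 1L)
      qual <- logical(length(win_start))
      for (i in win_start) {
        win <- g[i:(i + w - 1L)]
        qual[i] <- sum(win == 1L, na.rm = TRUE) <= params$window_max_het &&
          sum(is.na(win)) <= params$window_max_missing
      }
      eligible <- logical(m)
      for (j in seq_len(m)) {
        covering <- win_start[win_start <= j & win_start + w - 1L >= j]
        eligible[j] <- mean(qual[covering]) >= params$window_hit_threshold
      }
      # assemble stretches marker by marker, breaking at ineligible markers
      # and at gaps > max_gap
      run <- integer(0)
      flush <- function(run) {
        if (length(run) >= params$min_snp) {
          len_bp <- pos[run[length(run)]] - pos[run[1]]
          if (len_bp / 1000 >= params$min_length_kb &&
              (len_bp / 1000) / length(run) <= params$max_density_kb_per_snp)
            return(list(list(a = run[1], b = run[length(run)])))
        }
        list()
      }
      for (j in seq_len(m)) {
        if (!eligible[j]) {
          rows <- c(rows, lapply(flush(run), function(x)
            .bf_row(geno$samples[s], ch, pos, ids, x)))
          run <- integer(0)
        } else {
          if (length(run) &&
              pos[j] - pos[run[length(run)]] > params$max_gap_kb * 1000) {
            rows <- c(rows, lapply(flush(run), function(x)
              .bf_row(geno$samples[s], ch, pos, ids, x)))
            run <- integer(0)
          }
          run <- c(run, j)
        }
      }
      rows <- c(rows, lapply(flush(run), function(x)
        .bf_row(geno$samples[s], ch, pos, ids, x)))
    }
  }
  if (!length(rows)) return(.empty_segments())
  seg <- do.call(rbind, rows)
  seg <- seg[order(match(seg$sample_id, geno$samples), seg$chrom,
                   seg$start_bp), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

.bf_row <- function(sample_id, ch, pos, ids, x) {
  data.frame(sample_id = sample_id, chrom = ch,
             start_bp = pos[x$a], end_bp = pos[x$b],
             n_snp = x$b - x$a + 1L,
             start_snp = ids[x$a], end_snp = ids[x$b],
             length_bp = pos[x$b] - pos[x$a],
             length_mb = (pos[x$b] - pos[x$a]) / 1e6,
             stringsAsFactors = FALSE)
}
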