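#' Autosomal extent covered by markers
#'
#' The denominator of the genomic inbreeding coefficient: per chromosome,
#' L_OAR is the span from the first to the last QC-passing marker (or a
#' user-supplied nominal chromosome length); L_AUT is the sum over
#' autosomes.
#'
#' @param map marker map data.frame (`chrom`, `pos_bp`), typically
#'   `geno$map` after QC.
#' @param chrom_lengths optional named numeric vector of nominal chromosome
#'   lengths (bp), names = chromosome labels; overrides the marker span.
#' @return list of class `autosome_extent` with `per_chrom` (data.frame
#'   `chrom`, `L_OAR`) and `L_AUT`.
#' @export
autosome_extent <- function(map, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    sp <- lapply(split(map$pos_bp, map$chrom), range)
    per <- data.frame(chrom = as.integer(names(sp)),
                      L_OAR = vapply(sp, function(r) r[2] - r[1], numeric(1)))
  } else {
    per <- data.frame(chrom = as.integer(names(chrom_lengths)),
                      L_OAR = as.numeric(chrom_lengths))
  }
  per <- per[order(per$chrom), , drop = FALSE]
  rownames(per) <- NULL
  if (any(per$L_OAR <= 0)) stop("non-positive chromosome extent")
  structure(list(per_chrom = per, L_AUT = sum(per$L_OAR)),
            class = "autosome_extent")
}

#' Default ROH length categories (Mb)
#'
#' Left-closed bins 1-5, 5-10, 10-20 and >20 Mb, the scheme customarily
#' used to stratify present-day versus ancient inbreeding on medium-density
#' arrays.
#'
#' @param breaks_mb increasing numeric vector of bin edges in Mb; the last
#'   bin is open-ended.
#' @return list of class `length_scheme` with `breaks_mb` and `labels`.
#' @export
length_scheme <- function(breaks_mb = c(1, 5, 10, 20)) {
  if (is.unsorted(breaks_mb, strictly = TRUE))
    stop("length-category breaks must be strictly increasing")
  n <- length(breaks_mb)
  labels <- c(paste0(breaks_mb[-n], "-", breaks_mb[-1], "Mb"),
              paste0(">", breaks_mb[n], "Mb"))
  structure(list(breaks_mb = breaks_mb, labels = labels),
            class = "length_scheme")
}

.bin_of <- function(length_mb, scheme) {
  cut(length_mb, breaks = c(scheme$breaks_mb, Inf), labels = scheme$labels,
      right = FALSE, include.lowest = FALSE)
}

#' Per-sample genomic inbreeding coefficients from ROH
#'
#' F_ROH = L_ROH / L_AUT, where L_ROH is the summed length of a sample's
#' ROH and L_AUT the autosomal extent covered by markers. Per length
#' category, F_ROH is restricted to segments falling in the bin; per
#' chromosome, F_ROHOAR = L_ROHOAR / L_OAR.
#'
#' @param segments ROH data.frame from [detect_roh()].
#' @param extent an [autosome_extent].
#' @param samples character vector of all cohort sample ids (so that samples
#'   without any ROH appear with F_ROH = 0).
#' @param scheme a [length_scheme] for the per-category columns.
#' @return list of class `inbreeding_report`:
#'   `per_sample` (data.frame: `sample_id`, `n_roh`, `L_ROH` bp, `F_ROH`,
#'   one `F_ROH_<bin>` column per category), `per_sample_chrom` (long
#'   data.frame: `sample_id`, `chrom`, `L_ROHOAR`, `F_ROHOAR`), `extent`,
#'   `scheme`.
#' @export
compute_froh <- function(segments, extent, samples, scheme = length_scheme()) {
  stopifnot(inherits(extent, "autosome_extent"))
  if (nrow(segments) > 0 &&
      !all(segments$chrom %in% extent$per_chrom$chrom))
    stop("segment chromosome absent from autosome extent")
  samples <- as.character(samples)
  idx <- match(segments$sample_id, samples)
  if (nrow(segments) > 0 && anyNA(idx))
    stop("segment sample absent from cohort sample list")

  L <- segments$length_bp
  n_roh <- as.integer(tabulate(idx, nbins = length(samples)))
  L_ROH <- numeric(length(samples))
  if (nrow(segments) > 0) {
    agg <- rowsum(L, idx)
    L_ROH[as.integer(rownames(agg))] <- agg[, 1]
  }
  per <- data.frame(sample_id = samples, n_roh = n_roh, L_ROH = L_ROH,
                    F_ROH = L_ROH / extent$L_AUT, stringsAsFactors = FALSE)

  bins <- .bin_of(segments$length_mb, scheme)
  for (b in scheme$labels) {
    in_b <- !is.na(bins) & bins == b
    Lb <- numeric(length(samples))
    if (any(in_b)) {
      agg <- rowsum(L[in_b], idx[in_b])
      Lb[as.integer(rownames(agg))] <- agg[, 1]
    }
    per[[paste0("F_ROH_", b)]] <- Lb / extent$L_AUT
  }

  psc <- .empty_psc()
  if (nrow(segments) > 0) {
    key <- paste(idx, segments$chrom, sep = ":")
    agg <- rowsum(L, key)
    parts <- strsplit(rownames(agg), ":", fixed = TRUE)
    si <- as.integer(vapply(parts, `[[`, "", 1))
    ch <- as.integer(vapply(parts, `[[`, "", 2))
    loar <- extent$per_chrom$L_OAR[match(ch, extent$per_chrom$chrom)]
    psc <- data.frame(sample_id = samples[si], chrom = ch,
                      L_ROHOAR = agg[, 1], F_ROHOAR = agg[, 1] / loar,
                      stringsAsFactors = FALSE)
    psc <- psc[order(match(psc$sample_id, samples), psc$chrom), ,
               drop = FALSE]
    rownames(psc) <- NULL
  }
  structure(list(per_sample = per, per_sample_chrom = psc, extent = extent,
                 scheme = scheme), class = "inbreeding_report")
}

.empty_psc <- function() {
  data.frame(sample_id = character(), chrom = integer(),
             L_ROHOAR = numeric(), F_ROHOAR = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.inbreeding_report <- function(x, ...) {
  cat("Inbreeding report:", nrow(x$per_sample), "samples\n")
  cat(sprintf("  mean F_ROH = %.4f (L_AUT = %.1f Mb)\n",
              mean(x$per_sample$F_ROH), x$extent$L_AUT / 1e6))
  invisible(x)
}

#' Cohort-level ROH distribution summary
#'
#' Descriptive statistics of the detected runs: totals, per-animal means,
#' the share of runs per length category with the mean per-animal summed
#' length, per-chromosome counts and coverage (mean ROH length among
#' animals having ROH on that chromosome, divided by the chromosome
#' length), and the per-column summary (mean, median, min, max, coefficient
#' of variation in percent, number of animals with at least one run in the
#' category) of each F_ROH column.
#'
#' @param segments ROH data.frame from [detect_roh()].
#' @param extent an [autosome_extent].
#' @param samples cohort sample ids.
#' @param scheme a [length_scheme].
#' @return list of class `roh_summary` with elements `overall`, `per_bin`,
#'   `per_chrom` and `froh_stats`.
#' @export
summarize_distribution <- function(segments, extent, samples,
                                   scheme = length_scheme()) {
  n_samples <- length(samples)
  if (n_samples <= 0) stop("n_samples must be positive")
  rep <- compute_froh(segments, extent, samples, scheme)
  per <- rep$per_sample

  overall <- list(
    n_roh_total = nrow(segments),
    mean_roh_per_animal = nrow(segments) / n_samples,
    mean_roh_length_mb = if (nrow(segments)) mean(segments$length_mb) else 0,
    mean_total_length_mb = mean(per$L_ROH) / 1e6,
    max_total_length_mb = max(per$L_ROH) / 1e6)

  bins <- .bin_of(segments$length_mb, scheme)
  cnt <- table(factor(bins, levels = scheme$labels))
  per_bin <- data.frame(
    bin = scheme$labels,
    n_roh = as.integer(cnt),
    pct_of_roh = if (nrow(segments)) 100 * as.integer(cnt) / nrow(segments)
                 else rep(0, length(scheme$labels)),
    mean_sum_mb_per_animal = vapply(scheme$labels, function(b) {
      in_b <- !is.na(bins) & bins == b
      sum(segments$length_bp[in_b]) / n_samples / 1e6
    }, numeric(1)), stringsAsFactors = FALSE)
  rownames(per_bin) <- NULL

  pc <- extent$per_chrom
  per_chrom <- data.frame(chrom = pc$chrom, n_roh = 0L,
                          pct_coverage = 0, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    tab <- table(factor(segments$chrom, levels = pc$chrom))
    per_chrom$n_roh <- as.integer(tab)
    for (i in seq_len(nrow(pc))) {
      sub <- segments[segments$chrom == pc$chrom[i], , drop = FALSE]
      if (nrow(sub)) {
        per_animal <- rowsum(sub$length_bp, sub$sample_id)
        per_chrom$pct_coverage[i] <- 100 * mean(per_animal) / pc$L_OAR[i]
      }
    }
  }

  froh_cols <- c(grep("^F_ROH_", names(per), value = TRUE), "F_ROH")
  froh_stats <- do.call(rbind, lapply(froh_cols, function(cl) {
    v <- per[[cl]]
    has <- v > 0
    vv <- v[has]
    if (!length(vv)) vv <- 0
    data.frame(coefficient = cl, mean = mean(vv), median = stats::median(vv),
               min = min(vv), max = max(vv),
               cv_pct = if (mean(vv) > 0) 100 * stats::sd(vv) / mean(vv)
                        else NA_real_,
               n_animals = sum(has), stringsAsFactors = FALSE)
  }))
  rownames(froh_stats) <- NULL

  structure(list(overall = overall, per_bin = per_bin,
                 per_chrom = per_chrom, froh_stats = froh_stats),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  o <- x$overall
  cat("ROH distribution summary\n")
  cat(sprintf("  %d ROH total; %.2f per animal; mean length %.2f Mb\n",
              o$n_roh_total, o$mean_roh_per_animal, o$mean_roh_length_mb))
  cat(sprintf("  mean total length %.2f Mb/animal (max %.2f)\n",
              o$mean_total_length_mb, o$max_total_length_mb))
  cat("\nPer length category:\n")
  print(x$per_bin, row.names = FALSE)
  cat("\nF_ROH statistics:\n")
  print(x$froh_stats, row.names = FALSE)
  invisible(x)
}
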