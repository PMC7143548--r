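#' Per-marker ROH incidence across a cohort
#'
#' For every QC-passing marker, the number of animals whose detected ROH
#' span it (a marker at position p is covered by a segment when
#' start_bp <= p <= end_bp; each animal contributes at most one count per
#' marker), and the incidence as a percentage of the cohort.
#'
#' @param segments ROH data.frame from [detect_roh()].
#' @param map marker map data.frame (`chrom`, `id`, `pos_bp`), sorted.
#' @param n_samples cohort size.
#' @return data.frame of class `incidence_track`: `chrom`, `id`, `pos_bp`,
#'   `n_covered`, `incidence_pct`.
#' @export
snp_incidence <- function(segments, map, n_samples) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (nrow(segments) > 0 && !all(segments$chrom %in% map$chrom))
    stop("segment chromosome absent from marker map")
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  n_cov <- integer(nrow(map))
  if (nrow(segments) > 0) {
    # per chromosome, locate each segment's marker span by binary search;
    # per-sample de-duplication via a difference array per sample
    for (ch in unique(segments$chrom)) {
      mi <- which(map$chrom == ch)
      pos <- map$pos_bp[mi]
      sub <- segments[segments$chrom == ch, , drop = FALSE]
      a <- findInterval(sub$start_bp, pos, left.open = TRUE) + 1L
      b <- findInterval(sub$end_bp, pos)
      valid <- a <= b
      sub <- sub[valid, , drop = FALSE]; a <- a[valid]; b <- b[valid]
      if (!nrow(sub)) next
      cover <- integer(length(pos))
      for (sid in unique(sub$sample_id)) {
        ss <- sub$sample_id == sid
        diffarr <- integer(length(pos) + 1L)
        for (k in which(ss)) {
          diffarr[a[k]] <- diffarr[a[k]] + 1L
          diffarr[b[k] + 1L] <- diffarr[b[k] + 1L] - 1L
        }
        cover <- cover + as.integer(cumsum(diffarr[-length(diffarr)]) > 0L)
      }
      n_cov[mi] <- cover
    }
  }
  if (any(n_cov > n_samples))
    stop("marker coverage exceeds cohort size (overlapping segments?)")
  out <- data.frame(chrom = map$chrom, id = map$id, pos_bp = map$pos_bp,
                    n_covered = n_cov,
                    incidence_pct = 100 * n_cov / n_samples,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("incidence_track", "data.frame")
  out
}

#' Call ROH hotspots (islands) from an incidence track
#'
#' Markers in the top `top_fraction` of incidence are selected by the
#' nearest-rank percentile rule: the threshold is the smallest incidence
#' attained by the top `ceiling(top_fraction * n_markers)` markers, and all
#' markers at or above it are selected (ties included). Zero-incidence
#' markers are never selected, so an all-zero track yields no hotspots.
#' Consecutive selected markers on a chromosome (no non-selected QC-passing
#' marker between them) merge into one region; region coordinates are the
#' first and last selected marker positions and the region length is
#' stop - start (a single-marker region has length 0).
#'
#' @param track an `incidence_track` from [snp_incidence()].
#' @param top_fraction fraction of markers defining a hotspot, in (0, 1).
#' @return data.frame of class `hotspot_regions`: `chrom`, `start_bp`,
#'   `stop_bp`, `length_bp`, `n_snp`.
#' @export
call_hotspots <- function(track, top_fraction = 0.01) {
  if (nrow(track) == 0) stop("empty incidence track")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  k <- ceiling(top_fraction * nrow(track))
  thr <- sort(track$incidence_pct, decreasing = TRUE)[k]
  sel <- track$incidence_pct >= thr & track$incidence_pct > 0
  regions <- .empty_hotspots()
  if (any(sel)) {
    # merge runs of consecutive selected markers within each chromosome
    idx <- which(sel)
    new_chrom <- c(TRUE, track$chrom[idx[-1]] != track$chrom[idx[-length(idx)]])
    new_run <- c(TRUE, diff(idx) != 1L) | new_chrom
    run_id <- cumsum(new_run)
    first <- idx[!duplicated(run_id)]
    last <- idx[!duplicated(run_id, fromLast = TRUE)]
    regions <- data.frame(
      chrom = track$chrom[first],
      start_bp = track$pos_bp[first], stop_bp = track$pos_bp[last],
      length_bp = track$pos_bp[last] - track$pos_bp[first],
      n_snp = last - first + 1L, stringsAsFactors = FALSE)
    rownames(regions) <- NULL
  }
  attr(regions, "threshold_pct") <- if (any(sel)) thr else NA_real_
  class(regions) <- c("hotspot_regions", "data.frame")
  regions
}

.empty_hotspots <- function() {
  data.frame(chrom = integer(), start_bp = numeric(), stop_bp = numeric(),
             length_bp = numeric(), n_snp = integer(),
             stringsAsFactors = FALSE)
}

#' Count annotated genes overlapping a region
#'
#' Closed-interval overlap: a gene whose interval touches the region at a
#' single base (including exact abutment) is counted.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start_bp`,
#'   `stop_bp`.
#' @param annotation gene annotation data.frame from [read_gene_bed()];
#'   `NULL` or empty counts as 0.
#' @return integer gene count.
#' @export
count_genes <- function(region, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0) return(0L)
  sum(annotation$chrom == region$chrom &
        annotation$start_bp <= region$stop_bp &
        annotation$end_bp >= region$start_bp)
}

#' Mean recombination rate over a region
#'
#' (cM(stop) - cM(start)) / (length in Mb), with genetic positions obtained
#' by linear interpolation between map anchors (constant extrapolation
#' outside). Undefined (`NA`) for zero-length regions; rendered "/" in the
#' formatted hotspot table.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start_bp`,
#'   `stop_bp`.
#' @param gmap a `genetic_map`.
#' @return cM/Mb, or `NA` when the region has zero length.
#' @export
region_recomb_rate <- function(region, gmap) {
  if (region$stop_bp - region$start_bp <= 0) return(NA_real_)
  cm <- interpolate_cm(gmap, region$chrom, c(region$start_bp, region$stop_bp))
  (cm[2] - cm[1]) / ((region$stop_bp - region$start_bp) / 1e6)
}

#' Annotate hotspot regions with gene counts and recombination rates
#'
#' @param regions `hotspot_regions` from [call_hotspots()].
#' @param annotation optional gene annotation ([read_gene_bed()]).
#' @param gmap optional `genetic_map`.
#' @return the regions with added `n_genes` and/or `recomb_cM_per_Mb`
#'   columns.
#' @export
annotate_hotspots <- function(regions, annotation = NULL, gmap = NULL) {
  if (!is.null(annotation))
    regions$n_genes <- vapply(seq_len(nrow(regions)), function(i)
      count_genes(regions[i, ], annotation), integer(1))
  if (!is.null(gmap))
    regions$recomb_cM_per_Mb <- vapply(seq_len(nrow(regions)), function(i)
      region_recomb_rate(regions[i, ], gmap), numeric(1))
  regions
}

#' Format a hotspot table for output
#'
#' Columns mirror the conventional hotspot report: No., chromosome, start,
#' stop, length, SNPs, genes (if annotated), cM/Mb (if a genetic map was
#' given; "/" for zero-length regions where the rate is undefined).
#'
#' @param regions annotated `hotspot_regions`.
#' @return character-formatted data.frame ready for `write.table`.
#' @export
format_hotspot_table <- function(regions) {
  out <- data.frame(
    No. = seq_len(nrow(regions)), OAR = regions$chrom,
    Start_bp = format(regions$start_bp, scientific = FALSE, trim = TRUE),
    Stop_bp = format(regions$stop_bp, scientific = FALSE, trim = TRUE),
    Length_bp = format(regions$length_bp, scientific = FALSE, trim = TRUE),
    SNPs = regions$n_snp, stringsAsFactors = FALSE)
  if ("n_genes" %in% names(regions)) out$Genes <- regions$n_genes
  if ("recomb_cM_per_Mb" %in% names(regions))
    out$cM_per_Mb <- ifelse(is.na(regions$recomb_cM_per_Mb), "/",
                            format(round(regions$recomb_cM_per_Mb, 2)))
  if (nrow(regions) == 0) out <- out[0, , drop = FALSE]
  out
}
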