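#' Fit the ROH model: QC, run detection and genomic inbreeding
#'
#' The package's main entry point. Applies array quality control, detects
#' runs of homozygosity with the scanning-window algorithm, computes the
#' autosomal extent covered by the surviving markers and derives the
#' genomic inbreeding coefficients F_ROH (overall, per length category and
#' per chromosome).
#'
#' @param genotypes a [genotype_matrix] (from [read_ped_map()],
#'   [read_bed_bim_fam()] or [simulate_cohort()]).
#' @param qc a [qc_params] list, or `NULL` to skip quality control.
#' @param params a [roh_params] list.
#' @param scheme a [length_scheme] for the F_ROH length categories.
#' @param chrom_lengths optional nominal chromosome lengths for the F_ROH
#'   denominator (default: span of QC-passing markers).
#' @return object of class `roh`: list with `genotypes` (post-QC),
#'   `qc_report`, `segments`, `extent`, `inbreeding`
#'   (an `inbreeding_report`), `params`, `scheme`, `call`.
#' @seealso [summary.roh()], [coef.roh()], [roh_hotspots()],
#'   [roh_demography()]
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 20, n_chromosomes = 2,
#'                                   markers_per_chromosome = 500,
#'                                   target_F = 0.1, seed = 7))
#' fit <- roh(sim$genotypes)
#' fit
#' head(coef(fit))
#' @export
roh <- function(genotypes, qc = qc_params(), params = roh_params(),
                scheme = length_scheme(), chrom_lengths = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  qc_report <- NULL
  if (!is.null(qc)) {
    qcd <- apply_qc(genotypes, qc)
    genotypes <- qcd$genotypes
    qc_report <- qcd$report
  }
  segments <- detect_roh(genotypes, params)
  extent <- autosome_extent(genotypes$map, chrom_lengths)
  inb <- compute_froh(segments, extent, genotypes$samples, scheme)
  structure(list(genotypes = genotypes, qc_report = qc_report,
                 segments = segments, extent = extent, inbreeding = inb,
                 params = params, scheme = scheme,
                 call = match.call()),
            class = "roh")
}

#' @export
print.roh <- function(x, ...) {
  cat("ROH analysis\n")
  cat("  cohort:", length(x$genotypes$samples), "samples,",
      nrow(x$genotypes$map), "QC-passing markers on",
      nrow(x$extent$per_chrom), "autosomes\n")
  cat("  segments:", nrow(x$segments), "\n")
  cat(sprintf("  mean F_ROH: %.4f\n", mean(x$inbreeding$per_sample$F_ROH)))
  invisible(x)
}

#' Summarize a fitted ROH analysis
#'
#' @param object an object of class `roh`.
#' @param ... unused.
#' @return a `roh_summary` (see [summarize_distribution()]).
#' @export
summary.roh <- function(object, ...) {
  summarize_distribution(object$segments, object$extent,
                         object$genotypes$samples, object$scheme)
}

#' Per-sample genomic inbreeding coefficients
#'
#' @param object an object of class `roh`.
#' @param ... unused.
#' @return named numeric vector of F_ROH, one entry per sample.
#' @export
coef.roh <- function(object, ...) {
  stats::setNames(object$inbreeding$per_sample$F_ROH,
                  object$inbreeding$per_sample$sample_id)
}

#' Plot a fitted ROH analysis
#'
#' `which = 1`: ROH count per chromosome; `which = 2`: percent of each
#' chromosome covered by ROH (mean over animals having ROH there);
#' `which = 3`: histogram of per-sample F_ROH.
#'
#' @param x an object of class `roh`.
#' @param which subset of plots to draw.
#' @param ... passed to the underlying graphics calls.
#' @export
plot.roh <- function(x, which = c(1, 2, 3), ...) {
  smry <- summary(x)
  old <- graphics::par(mfrow = c(length(which), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  if (1 %in% which)
    graphics::barplot(smry$per_chrom$n_roh,
                      names.arg = smry$per_chrom$chrom,
                      xlab = "Chromosome", ylab = "ROH count", ...)
  if (2 %in% which)
    graphics::barplot(smry$per_chrom$pct_coverage,
                      names.arg = smry$per_chrom$chrom,
                      xlab = "Chromosome", ylab = "% covered by ROH", ...)
  if (3 %in% which)
    graphics::hist(coef(x), xlab = expression(F[ROH]), main = "", ...)
  invisible(x)
}

#' Hotspot scan on a fitted ROH analysis
#'
#' Computes the per-marker ROH incidence track, calls top-percentile
#' hotspot regions and annotates them with gene counts and recombination
#' rates when an annotation / genetic map is supplied.
#'
#' @param fit an object of class `roh`.
#' @param top_fraction fraction of markers defining a hotspot.
#' @param annotation optional gene annotation ([read_gene_bed()]).
#' @param gmap optional `genetic_map`.
#' @return list with `track` (the `incidence_track`) and `regions`
#'   (annotated `hotspot_regions`).
#' @export
roh_hotspots <- function(fit, top_fraction = 0.01, annotation = NULL,
                         gmap = NULL) {
  stopifnot(inherits(fit, "roh"))
  track <- snp_incidence(fit$segments, fit$genotypes$map,
                         length(fit$genotypes$samples))
  regions <- call_hotspots(track, top_fraction)
  regions <- annotate_hotspots(regions, annotation, gmap)
  list(track = track, regions = regions)
}

#' TMRCA classification of a fitted ROH analysis
#'
#' Converts each segment to genetic length via the map and tallies the
#' TMRCA length classes.
#'
#' @param fit an object of class `roh`.
#' @param gmap a `genetic_map`.
#' @param scheme a [tmrca_scheme].
#' @return a `demography_table` (see [classify_segments()]).
#' @export
roh_demography <- function(fit, gmap, scheme = tmrca_scheme()) {
  stopifnot(inherits(fit, "roh"))
  classify_segments(fit$segments, gmap, scheme,
                    n_samples = length(fit$genotypes$samples))
}
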