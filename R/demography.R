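#' TMRCA length-class scheme
#'
#' Genetic-length classes for dating autozygosity. An autozygous tract of
#' genetic length l cM has expected time to the most recent common ancestor
#' of about 100/(2 l) generations, so longer tracts reflect more recent
#' common ancestry. The default classes are the ones conventionally used
#' for sheep array data: > 10 cM ("<5 generations"), (5, 10] ("5-10"),
#' (2.5, 5] ("10-20"), (1.25, 2.5] ("20-40") and <= 1.25 cM
#' ("unresolved", beyond the resolution of a medium-density array).
#' Classes are left-open/right-closed in cM.
#'
#' @param breaks_cm strictly decreasing vector of class boundaries (cM).
#' @param labels one label per class, youngest first, plus a final label
#'   for tracts at or below the smallest boundary.
#' @return list of class `tmrca_scheme`.
#' @export
tmrca_scheme <- function(breaks_cm = c(10, 5, 2.5, 1.25),
                         labels = c("<5 generations", "5-10 generations",
                                    "10-20 generations", "20-40 generations",
                                    "unresolved")) {
  if (is.unsorted(rev(breaks_cm), strictly = TRUE))
    stop("class boundaries must be strictly decreasing")
  if (length(labels) != length(breaks_cm) + 1L)
    stop("need one label per class plus one for the residual class")
  if (anyDuplicated(labels)) stop("class labels must be unique")
  structure(list(breaks_cm = breaks_cm, labels = labels),
            class = "tmrca_scheme")
}

#' Genetic length of ROH segments
#'
#' cM(end) - cM(start) by linear interpolation in the genetic map
#' (constant extrapolation outside the anchors).
#'
#' @param segments ROH data.frame from [detect_roh()].
#' @param gmap a `genetic_map` covering every segment chromosome.
#' @return numeric vector of genetic lengths (cM), one per segment.
#' @export
genetic_length <- function(segments, gmap) {
  vapply(seq_len(nrow(segments)), function(i) {
    cm <- interpolate_cm(gmap, segments$chrom[i],
                         c(segments$start_bp[i], segments$end_bp[i]))
    cm[2] - cm[1]
  }, numeric(1))
}

#' Expected TMRCA of an autozygous tract
#'
#' For a tract of genetic length l cM, the expected number of generations
#' to the common ancestor of the two haplotypes is g = 100 / (2 l).
#'
#' @param length_cM positive genetic length(s) in cM.
#' @return expected generations (same length as input).
#' @export
expected_generations <- function(length_cM) {
  if (any(length_cM <= 0)) stop("genetic length must be positive")
  100 / (2 * length_cM)
}

#' Classify ROH segments into TMRCA length classes
#'
#' Each segment is assigned the unique class containing its genetic length
#' (left-open/right-closed boundaries).
#'
#' @param segments ROH data.frame from [detect_roh()].
#' @param gmap a `genetic_map`.
#' @param scheme a [tmrca_scheme].
#' @param n_samples optional cohort size for the per-animal mean column;
#'   defaults to the number of distinct samples in `segments`.
#' @return data.frame of class `demography_table`: `class`, `min_cM`,
#'   `n_roh`, `mean_per_animal`, `fraction`.
#' @export
classify_segments <- function(segments, gmap, scheme = tmrca_scheme(),
                              n_samples = NULL) {
  if (is.null(n_samples))
    n_samples <- length(unique(segments$sample_id))
  lens <- if (nrow(segments)) genetic_length(segments, gmap) else numeric(0)
  breaks <- c(Inf, scheme$breaks_cm, -Inf)
  cls <- character(length(lens))
  for (i in seq_along(scheme$labels))
    cls[lens <= breaks[i] & lens > breaks[i + 1]] <- scheme$labels[i]
  cnt <- table(factor(cls, levels = scheme$labels))
  out <- data.frame(
    class = scheme$labels,
    min_cM = c(scheme$breaks_cm, 0),
    n_roh = as.integer(cnt),
    mean_per_animal = if (n_samples > 0) as.integer(cnt) / n_samples
                      else NA_real_,
    fraction = if (length(lens)) as.integer(cnt) / length(lens) else 0,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("demography_table", "data.frame")
  out
}
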