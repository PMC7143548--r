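#' Construct a genotype matrix object
#'
#' Container for diploid autosomal SNP genotypes coded as minor-allele dosage.
#' Calls are integers in \{0, 1, 2\} (1 = heterozygote, 0/2 the two
#' homozygotes) with `NA` for missing. Markers are kept sorted by
#' (chromosome, position); duplicate positions within a chromosome are
#' rejected.
#'
#' @param calls integer matrix, samples in rows, markers in columns; values
#'   0/1/2 or `NA`.
#' @param map data.frame with one row per marker: `chrom` (integer autosome
#'   label), `id` (marker name), `pos_bp` (1-based physical position),
#'   optionally `cM` (genetic position) and allele labels `a1` (minor),
#'   `a2` (major).
#' @param samples character vector of sample identifiers (row order of
#'   `calls`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `map`, `samples`.
#' @export
genotype_matrix <- function(calls, map, samples = rownames(calls)) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "id", "pos_bp") %in% names(map)))
  if (!"a1" %in% names(map)) map$a1 <- "A"
  if (!"a2" %in% names(map)) map$a2 <- "B"
  if (nrow(map) != ncol(calls))
    stop("marker map has ", nrow(map), " rows but calls has ", ncol(calls),
         " columns")
  if (length(samples) != nrow(calls))
    stop("sample ids do not match call matrix rows")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  dup <- stats::ave(map$pos_bp, map$chrom, FUN = function(x) duplicated(x))
  if (any(dup > 0))
    stop("duplicate marker positions within a chromosome: ",
         paste(map$id[dup > 0][seq_len(min(3, sum(dup > 0)))], collapse = ", "))
  rownames(map) <- NULL
  dimnames(calls) <- list(samples, map$id)
  structure(list(calls = calls, map = map, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$samples), "samples x", nrow(x$map),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Coerce chromosome labels to autosome integers; X/Y/MT/0/unplaced -> NA.
.autosome_label <- function(chrom) {
  suppressWarnings(n <- as.integer(as.character(chrom)))
  n[!is.na(n) & n <= 0L] <- NA_integer_
  n
}

# Drop non-autosomal markers from a parsed map, reporting the count.
.drop_non_autosomes <- function(map) {
  auto <- .autosome_label(map$chrom)
  dropped <- sum(is.na(auto))
  if (dropped > 0)
    message(dropped, " non-autosomal/unplaced marker(s) dropped")
  map$chrom <- auto
  map[!is.na(auto), , drop = FALSE]
}

# Per-marker minor/major alleles and dosage recoding from two allele-character
# vectors. Ties in allele counts are broken lexicographically (smaller label
# is "minor"); the choice cannot affect hom/het status.
.recode_biallelic <- function(al1, al2, marker_id) {
  miss <- al1 == "0" | al2 == "0"
  obs <- c(al1[!miss], al2[!miss])
  alleles <- sort(unique(obs))
  if (length(alleles) > 2)
    stop("marker ", marker_id, " has >2 distinct alleles: ",
         paste(alleles, collapse = ","))
  if (length(alleles) == 0) {
    return(list(calls = rep(NA_integer_, length(al1)), a1 = "0", a2 = "0"))
  }
  if (length(alleles) == 1) alleles <- c(alleles, "0")
  cnt1 <- sum(obs == alleles[1])
  cnt2 <- sum(obs == alleles[2])
  # lexicographic tie-break: alleles is sorted, so on a tie alleles[1] wins
  minor <- if (cnt2 < cnt1) alleles[2] else alleles[1]
  major <- setdiff(alleles, minor)
  calls <- (al1 == minor) + (al2 == minor)
  calls[miss] <- NA_integer_
  list(calls = as.integer(calls), a1 = minor, a2 = major)
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a PED/MAP pair, recodes each marker to minor-allele dosage
#' (ties in allele counts broken lexicographically), converts `0 0` alleles
#' to missing, drops non-autosomal markers and sorts markers by
#' (chromosome, position).
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return A [genotype_matrix].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  if (ncol(map) != 4) stop("MAP file must have 4 columns")
  names(map) <- c("chrom", "id", "cM", "pos_bp")
  map$pos_bp <- as.numeric(map$pos_bp)
  n_mark <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * n_mark
  nf <- lengths(fields)
  if (any(nf != want))
    stop("PED allele count mismatch: expected ", want, " fields, found ",
         nf[which(nf != want)[1]], " on line ", which(nf != want)[1])
  ped <- do.call(rbind, fields)
  samples <- ped[, 2]
  fam <- data.frame(fid = ped[, 1], iid = ped[, 2], pat = ped[, 3],
                    mat = ped[, 4], sex = ped[, 5], pheno = ped[, 6],
                    stringsAsFactors = FALSE)

  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_mark)
  a1 <- a2 <- character(n_mark)
  for (j in seq_len(n_mark)) {
    rec <- .recode_biallelic(ped[, 6 + 2 * j - 1], ped[, 6 + 2 * j], map$id[j])
    calls[, j] <- rec$calls
    a1[j] <- rec$a1
    a2[j] <- rec$a2
  }
  map$a1 <- a1
  map$a2 <- a2
  map <- map[, c("chrom", "id", "pos_bp", "cM", "a1", "a2")]
  keep <- !is.na(.autosome_label(map$chrom))
  map2 <- .drop_non_autosomes(map)
  g <- genotype_matrix(calls[, keep, drop = FALSE], map2, samples)
  g$fam <- fam
  g
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param geno a [genotype_matrix].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(geno, prefix) {
  map <- geno$map
  cm <- if ("cM" %in% names(map)) map$cM else 0
  cm[is.na(cm)] <- 0
  utils::write.table(
    data.frame(map$chrom, map$id, cm, format(map$pos_bp, scientific = FALSE,
                                             trim = TRUE)),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  fam <- geno$fam
  if (is.null(fam))
    fam <- data.frame(fid = geno$samples, iid = geno$samples, pat = "0",
                      mat = "0", sex = "0", pheno = "-9",
                      stringsAsFactors = FALSE)
  n <- length(geno$samples)
  m <- nrow(map)
  # allele strings per call code: 0 -> a2 a2, 1 -> a1 a2, 2 -> a1 a1, NA -> 0 0
  out <- matrix("0", nrow = n, ncol = 2 * m)
  for (j in seq_len(m)) {
    cj <- geno$calls[, j]
    s1 <- ifelse(is.na(cj), "0", ifelse(cj >= 1, map$a1[j], map$a2[j]))
    s2 <- ifelse(is.na(cj), "0", ifelse(cj == 2, map$a1[j], map$a2[j]))
    out[, 2 * j - 1] <- s1
    out[, 2 * j] <- s2
  }
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  writeLines(paste(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex, fam$pheno,
                   apply(out, 1, paste, collapse = " ")), con)
  invisible(prefix)
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Reads the SNP-major PLINK 1 binary format (magic bytes `0x6c 0x1b 0x01`)
#' and recodes to minor-allele dosage with the same semantics as
#' [read_ped_map()]: the minor allele is determined from observed counts
#' (lexicographic tie-break), missing calls become `NA`, non-autosomal
#' markers are dropped and markers are sorted by (chromosome, position).
#'
#' @param prefix path prefix shared by `.bed`, `.bim` and `.fam`.
#' @return A [genotype_matrix].
#' @export
read_bed_bim_fam <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam"))
    if (!file.exists(paste0(prefix, ext)))
      stop("file not found: ", paste0(prefix, ext))
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cM", "pos_bp",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"),
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01))
    stop("bad BED magic bytes (expected PLINK v1.00 SNP-major): ", bed_path)
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + bpm * m)
    stop("BED file size inconsistent with BIM/FAM dimensions")
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, sample-fastest within each marker's byte block
  codes <- matrix(0L, nrow = 4 * bpm, ncol = m)
  block <- matrix(body, nrow = bpm, ncol = m)
  for (k in 0:3) {
    codes[seq_len(bpm) * 4 - 3 + k, ] <- block %% 4L
    block <- block %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies A1, 10 -> het, 11 -> 0 copies A1, 01 -> missing
  d_a1 <- matrix(NA_integer_, n, m)
  d_a1[codes == 0L] <- 2L
  d_a1[codes == 2L] <- 1L
  d_a1[codes == 3L] <- 0L

  # recode each marker to observed-minor dosage
  cnt_a1 <- colSums(d_a1, na.rm = TRUE)
  n_obs <- colSums(!is.na(d_a1))
  flip <- cnt_a1 > (2 * n_obs - cnt_a1) |
    (cnt_a1 == (2 * n_obs - cnt_a1) & bim$a1 > bim$a2)
  flip[bim$a2 == "0"] <- FALSE
  if (any(flip)) {
    d_a1[, flip] <- 2L - d_a1[, flip, drop = FALSE]
    tmp <- bim$a1[flip]
    bim$a1[flip] <- bim$a2[flip]
    bim$a2[flip] <- tmp
  }
  keep <- !is.na(.autosome_label(bim$chrom))
  bim2 <- .drop_non_autosomes(bim[, c("chrom", "id", "pos_bp", "cM",
                                      "a1", "a2")])
  g <- genotype_matrix(d_a1[, keep, drop = FALSE], bim2, fam$iid)
  g$fam <- fam
  g
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' Writes the v1.00 SNP-major binary format with A1 = the stored minor
#' allele, so that a write/read cycle is byte-stable.
#'
#' @param geno a [genotype_matrix].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bed_bim_fam <- function(geno, prefix) {
  map <- geno$map
  cm <- if ("cM" %in% names(map)) map$cM else 0
  cm[is.na(cm)] <- 0
  utils::write.table(
    data.frame(map$chrom, map$id, cm,
               format(map$pos_bp, scientific = FALSE, trim = TRUE),
               map$a1, map$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  fam <- geno$fam
  if (is.null(fam))
    fam <- data.frame(fid = geno$samples, iid = geno$samples, pat = "0",
                      mat = "0", sex = "0", pheno = "-9",
                      stringsAsFactors = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  n <- length(geno$samples)
  m <- nrow(map)
  bpm <- ceiling(n / 4)
  # dosage-of-A1 -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, nrow = 4 * bpm, ncol = m)  # pad + NA -> 01
  cc <- geno$calls
  codes <- matrix(1L, nrow = n, ncol = m)
  codes[!is.na(cc) & cc == 2L] <- 0L
  codes[!is.na(cc) & cc == 1L] <- 2L
  codes[!is.na(cc) & cc == 0L] <- 3L
  code[seq_len(n), ] <- codes
  # pad samples beyond n with 00 per PLINK convention
  if (4 * bpm > n) code[(n + 1):(4 * bpm), ] <- 0L
  i1 <- seq(1, 4 * bpm, by = 4)
  packed <- code[i1, , drop = FALSE] + 4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] + 64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}

#' Read a genetic map
#'
#' Tab-separated columns: chromosome, physical position (bp), genetic
#' position (cM). Anchors are sorted per chromosome and validated: at least
#' two anchors per chromosome, strictly increasing bp, non-decreasing cM.
#'
#' @param path path to the map file.
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `chrom`, `pos_bp`, `cM`.
#' @export
read_genetic_map <- function(path) {
  gm <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos_bp", "cM"),
                          colClasses = c("character", "numeric", "numeric"))
  gm$chrom <- .autosome_label(gm$chrom)
  if (anyNA(gm$chrom)) stop("genetic map has non-autosomal chromosome labels")
  genetic_map(gm)
}

#' Construct/validate a genetic map from a data.frame
#'
#' @param gm data.frame with columns `chrom`, `pos_bp`, `cM`.
#' @return Validated `genetic_map` object (sorted by chromosome, position).
#' @export
genetic_map <- function(gm) {
  gm <- gm[order(gm$chrom, gm$pos_bp), , drop = FALSE]
  rownames(gm) <- NULL
  for (ch in unique(gm$chrom)) {
    sub <- gm[gm$chrom == ch, ]
    if (nrow(sub) < 2)
      stop("chromosome ", ch, " has fewer than 2 map anchors; ",
           "interpolation impossible")
    if (any(diff(sub$pos_bp) <= 0))
      stop("duplicate or non-increasing bp anchors on chromosome ", ch)
    dec <- which(diff(sub$cM) < 0)
    if (length(dec))
      stop("cM decreases with bp on chromosome ", ch, " at anchor bp=",
           format(sub$pos_bp[dec[1] + 1], scientific = FALSE))
  }
  class(gm) <- c("genetic_map", "data.frame")
  gm
}

#' Interpolate genetic positions (cM) at physical positions
#'
#' Linear interpolation between map anchors; constant extrapolation beyond
#' the outermost anchors.
#'
#' @param gmap a `genetic_map`.
#' @param chrom chromosome label (single value).
#' @param pos_bp numeric vector of physical positions.
#' @return numeric vector of cM positions.
#' @export
interpolate_cm <- function(gmap, chrom, pos_bp) {
  sub <- gmap[gmap$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("chromosome ", chrom, " absent from genetic map")
  stats::approx(sub$pos_bp, sub$cM, xout = pos_bp, rule = 2)$y
}

#' Read a gene annotation (BED-like, 4 columns)
#'
#' Columns: chromosome, start, end, gene id. Intervals are treated as closed
#' in the package's 1-based coordinate convention; rows are sorted by
#' (chromosome, start).
#'
#' @param path path to the annotation file.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  ann <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start_bp", "end_bp",
                                         "gene_id"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  ann$chrom <- .autosome_label(ann$chrom)
  if (any(ann$start_bp > ann$end_bp))
    stop("malformed gene interval (start > end)")
  ann <- ann[order(ann$chrom, ann$start_bp), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# canonical empty segment table
.empty_segments <- function() {
  data.frame(sample_id = character(), chrom = integer(),
             start_bp = numeric(), end_bp = numeric(), n_snp = integer(),
             start_snp = character(), end_snp = character(),
             length_bp = numeric(), length_mb = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a ROH segment table (PLINK .hom style)
#'
#' Columns: FID, IID, CHR, SNP1, SNP2, POS1, POS2, KB, NSNP, with
#' KB = (POS2 - POS1)/1000 following the package-wide end - start length
#' convention.
#'
#' @param segments ROH segment data.frame as returned by [detect_roh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_table <- function(segments, path) {
  out <- data.frame(
    FID = segments$sample_id, IID = segments$sample_id,
    CHR = segments$chrom,
    SNP1 = if ("start_snp" %in% names(segments)) segments$start_snp else NA,
    SNP2 = if ("end_snp" %in% names(segments)) segments$end_snp else NA,
    POS1 = format(segments$start_bp, scientific = FALSE, trim = TRUE),
    POS2 = format(segments$end_bp, scientific = FALSE, trim = TRUE),
    KB = (segments$end_bp - segments$start_bp) / 1000,
    NSNP = segments$n_snp, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ROH segment table written by [write_roh_table()]
#'
#' @param path path to the `.hom`-style TSV.
#' @return ROH segment data.frame (see [detect_roh()]).
#' @export
read_roh_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(.empty_segments())
  seg <- data.frame(
    sample_id = as.character(tab$IID), chrom = as.integer(tab$CHR),
    start_bp = as.numeric(tab$POS1), end_bp = as.numeric(tab$POS2),
    n_snp = as.integer(tab$NSNP),
    start_snp = as.character(tab$SNP1), end_snp = as.character(tab$SNP2),
    stringsAsFactors = FALSE)
  seg$length_bp <- seg$end_bp - seg$start_bp
  seg$length_mb <- seg$length_bp / 1e6
  seg
}
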