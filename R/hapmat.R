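#' Polarized haplotype matrix
#'
#' The substrate of every statistic in the package: a binary matrix of phased
#' haplotypes (rows) by segregating sites (columns), polarized so that 0 is
#' the ancestral and 1 the derived allele, together with strictly increasing
#' physical positions (0-based, in bp) and the length of the locus the sites
#' were sampled from.
#'
#' @param alleles integer/numeric matrix of 0/1, n_haplotypes x n_sites.
#' @param positions numeric vector of 0-based physical positions (bp),
#'   strictly increasing, all in `[0, locus_length)`.
#' @param locus_length locus length in bp (> 0).
#' @param sample_labels optional character vector of haplotype identifiers.
#' @return An object of class `hapmat`.
#' @examples
#' m <- haplotype_matrix(matrix(c(0, 1, 1, 0), 2, 2), c(100, 500), 1000)
#' n_sites(m)
#' @export
haplotype_matrix <- function(alleles, positions, locus_length,
                             sample_labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  locus_length <- as.numeric(locus_length)
  if (length(locus_length) != 1L || is.na(locus_length) || locus_length <= 0)
    stop("`locus_length` must be a single positive number", call. = FALSE)
  if (ncol(alleles) != length(positions))
    stop("`positions` length (", length(positions),
         ") does not match the number of sites (", ncol(alleles), ")",
         call. = FALSE)
  if (nrow(alleles) < 2L)
    stop("a haplotype matrix needs at least 2 haplotypes", call. = FALSE)
  if (length(positions) && (anyNA(positions) ||
      any(positions < 0) || any(positions >= locus_length)))
    stop("positions must lie in [0, locus_length)", call. = FALSE)
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (length(alleles) && (anyNA(alleles) || !all(alleles == 0L | alleles == 1L)))
    stop("alleles must be 0 (ancestral) or 1 (derived) with no missing values",
         call. = FALSE)
  if (!is.null(sample_labels) && length(sample_labels) != nrow(alleles))
    stop("`sample_labels` must have one entry per haplotype", call. = FALSE)
  structure(
    list(alleles = alleles, positions = positions,
         locus_length = locus_length, sample_labels = sample_labels),
    class = "hapmat"
  )
}

#' @export
print.hapmat <- function(x, ...) {
  cat("<hapmat> ", n_haplotypes(x), " haplotypes x ", n_sites(x),
      " sites, locus ", format(x$locus_length, big.mark = ","), " bp\n",
      sep = "")
  invisible(x)
}

#' @rdname haplotype_matrix
#' @param x a `hapmat`.
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' @rdname haplotype_matrix
#' @export
n_sites <- function(x) ncol(x$alleles)

#' Derived allele frequency of every site
#' @param x a `hapmat`.
#' @return numeric vector of per-site derived allele frequencies.
#' @export
site_daf <- function(x) {
  if (n_sites(x) == 0L) return(numeric(0))
  colMeans(x$alleles)
}

#' Restrict a haplotype matrix to a physical window
#'
#' Keeps sites with position in `[start, end)` (0-based half-open). The
#' returned object keeps the original coordinates and locus length so window
#' slices remain addressable in locus coordinates.
#'
#' @param x a `hapmat`.
#' @param start,end window bounds in bp, half-open.
#' @return a `hapmat` with the subset of sites.
#' @export
window_slice <- function(x, start, end) {
  keep <- which(x$positions >= start & x$positions < end)
  haplotype_matrix(x$alleles[, keep, drop = FALSE], x$positions[keep],
                   x$locus_length, x$sample_labels)
}

#' Focal-site context: derived and ancestral backgrounds
#'
#' Splits the sample at a focal site into the haplotypes carrying the derived
#' allele (the derived background) and those carrying the ancestral allele.
#' Background-contrast statistics are defined only for focal variants with
#' derived allele frequency in `[0.25, 0.95]`; outside that range
#' `computable` is `FALSE` and the per-site statistics return `NA` (a
#' not-computable marker distinct from a true 0).
#'
#' @param x a `hapmat`.
#' @param focal_index column index of the focal site.
#' @param daf_range inclusive bounds on the focal derived allele frequency.
#' @return a list of class `focal_context` with elements `focal_index`,
#'   `derived_carriers`, `ancestral_carriers`, `focal_daf`, `computable`.
#' @export
focal_context <- function(x, focal_index, daf_range = c(0.25, 0.95)) {
  stopifnot(inherits(x, "hapmat"))
  if (focal_index < 1L || focal_index > n_sites(x))
    stop("`focal_index` out of range", call. = FALSE)
  col <- x$alleles[, focal_index]
  daf <- mean(col)
  structure(
    list(focal_index = as.integer(focal_index),
         derived_carriers = which(col == 1L),
         ancestral_carriers = which(col == 0L),
         focal_daf = daf,
         computable = daf >= daf_range[1] && daf <= daf_range[2]),
    class = "focal_context"
  )
}

# Internal: sites (column indices) within half-span of a centre, optionally
# excluding the focal column itself.
.flank_indices <- function(x, center_bp, halfspan_bp, exclude = integer(0)) {
  idx <- which(x$positions >= center_bp - halfspan_bp &
               x$positions < center_bp + halfspan_bp)
  setdiff(idx, exclude)
}
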