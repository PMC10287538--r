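#' hapDAF: haplotype-derived allele frequency
#'
#' Compares the frequency of shared flanking variants on the derived versus
#' the ancestral background of a focal variant. During a sweep, variants
#' linked to the adaptive allele hitchhike to high frequency on the derived
#' background, so shared flanking variants are more common there. A flanking
#' variant i (with background frequencies `f_di`, `f_ai`) qualifies when all
#' of: (1) it is present on at least one derived and one ancestral
#' background, (2) `f_di > f_ai`, (3) `f_ai < fa_max`, and
#' (4) `f_di + f_ai > sum_min`; all inequalities strict. The statistic is the
#' mean of `f_di^2 - f_ai^2` over qualifying variants, 0 when none qualify.
#'
#' Two threshold presets define the two variants: `hapdaf_o`
#' (`fa_max = sum_min = 0.25`), tuned for older incomplete sweeps, and
#' `hapdaf_s` (`fa_max = sum_min = 0.1`), tuned for incomplete sweeps from
#' standing variation.
#'
#' @param x a [haplotype_matrix()].
#' @param context a [focal_context()]; when the focal derived allele frequency
#'   is outside `[0.25, 0.95]` the statistic is not computable and `NA` is
#'   returned (distinct from a true 0).
#' @param halfspan_bp half-width of the window around the focal site, used
#'   when `window` is not given. Default 25 kb.
#' @param fa_max strict upper bound on the ancestral-background frequency.
#' @param sum_min strict lower bound on `f_di + f_ai`.
#' @param window optional `c(start, end)` half-open window in bp overriding
#'   the focal-centred window (the feature pipeline passes its nested window).
#' @return a single unstandardized value, or `NA` if not computable.
#' @examples
#' # one flanking variant on 4/5 derived and 1/5 ancestral backgrounds
#' al <- cbind(rep(c(1, 0), each = 5), c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0))
#' m <- haplotype_matrix(al, c(100, 200), 1000)
#' hapdaf(m, focal_context(m, 1))  # (0.8^2 - 0.2^2) / 1 = 0.6
#' @export
hapdaf <- function(x, context, halfspan_bp = 25000, fa_max = 0.25,
                   sum_min = 0.25, window = NULL) {
  if (!context$computable) return(NA_real_)
  fl <- .flank_of(x, context, halfspan_bp, window)
  if (!length(fl)) return(0)
  cd <- .carrier_counts(x, context$derived_carriers, fl)
  ca <- .carrier_counts(x, context$ancestral_carriers, fl)
  fd <- cd / length(context$derived_carriers)
  fa <- ca / length(context$ancestral_carriers)
  ok <- cd >= 1L & ca >= 1L & fd > fa & fa < fa_max & (fd + fa) > sum_min
  if (!any(ok)) return(0)
  mean(fd[ok]^2 - fa[ok]^2)
}

#' @rdname hapdaf
#' @export
hapdaf_o <- function(x, context, halfspan_bp = 25000, window = NULL) {
  hapdaf(x, context, halfspan_bp, fa_max = 0.25, sum_min = 0.25,
         window = window)
}

#' @rdname hapdaf
#' @export
hapdaf_s <- function(x, context, halfspan_bp = 25000, window = NULL) {
  hapdaf(x, context, halfspan_bp, fa_max = 0.1, sum_min = 0.1,
         window = window)
}

#' Sratio: segregating-sites ratio between backgrounds
#'
#' Ratio of the number of sites segregating among ancestral-background
#' haplotypes to the number segregating among derived-background haplotypes
#' in a window around the focal variant (`S_a / S_d`). Sweeps deplete
#' variation on the derived background, inflating the ratio. Not computable
#' (`NA`) when `S_d = 0` or when the focal frequency is out of range; no
#' pseudocount is used, to avoid unbounded artifacts in low-diversity
#' windows.
#'
#' @inheritParams hapdaf
#' @return `S_a / S_d`, or `NA` if not computable.
#' @export
sratio <- function(x, context, halfspan_bp = 25000, window = NULL) {
  if (!context$computable) return(NA_real_)
  fl <- .flank_of(x, context, halfspan_bp, window)
  if (!length(fl)) return(NA_real_)
  nd <- length(context$derived_carriers)
  na <- length(context$ancestral_carriers)
  cd <- .carrier_counts(x, context$derived_carriers, fl)
  ca <- .carrier_counts(x, context$ancestral_carriers, fl)
  s_d <- sum(cd > 0L & cd < nd)
  s_a <- sum(ca > 0L & ca < na)
  if (s_d == 0L) return(NA_real_)
  s_a / s_d
}

#' lowfreq / highfreq: frequency spectrum on the derived background
#'
#' Looks for an excess of low- (`lowfreq`) or high-frequency (`highfreq`)
#' derived alleles among the haplotypes carrying the focal derived allele,
#' treating the derived background as if the focal allele were fixed there —
#' the same distortions Tajima's D and Fay and Wu's H react to, but
#' standardized empirically instead of by theory. With `f_ddi` the frequency
#' of flanking derived allele i among derived-background haplotypes only:
#' `lowfreq` averages `(1 - f_ddi)^2` over variants with `0 < f_ddi < 0.25`
#' and `highfreq` averages `f_ddi^2` over variants with `f_ddi > 0.25` (both
#' cutoffs strict). The flanking derived allele must be present on at least
#' one derived background (`f_ddi > 0`); otherwise absent alleles would
#' contribute maximal terms everywhere. Returns 0 when no variant qualifies,
#' `NA` when the focal site is out of the `[0.25, 0.95]` frequency range.
#'
#' @inheritParams hapdaf
#' @return a single unstandardized value, or `NA` if not computable.
#' @export
lowfreq <- function(x, context, halfspan_bp = 25000, window = NULL) {
  .freq_stat(x, context, halfspan_bp, window, high = FALSE)
}

#' @rdname lowfreq
#' @export
highfreq <- function(x, context, halfspan_bp = 25000, window = NULL) {
  .freq_stat(x, context, halfspan_bp, window, high = TRUE)
}

.freq_stat <- function(x, context, halfspan_bp, window, high) {
  if (!context$computable) return(NA_real_)
  fl <- .flank_of(x, context, halfspan_bp, window)
  if (!length(fl)) return(0)
  fdd <- .carrier_counts(x, context$derived_carriers, fl) /
    length(context$derived_carriers)
  ok <- if (high) fdd > 0.25 else fdd > 0 & fdd < 0.25
  if (!any(ok)) return(0)
  if (high) mean(fdd[ok]^2) else mean((1 - fdd[ok])^2)
}

.flank_of <- function(x, context, halfspan_bp, window) {
  if (is.null(window)) {
    center <- x$positions[context$focal_index]
    .flank_indices(x, center, halfspan_bp, exclude = context$focal_index)
  } else {
    idx <- which(x$positions >= window[1L] & x$positions < window[2L])
    setdiff(idx, context$focal_index)
  }
}

.carrier_counts <- function(x, rows, cols) {
  if (length(rows) == 1L) as.integer(x$alleles[rows, cols])
  else colSums(x$alleles[rows, cols, drop = FALSE])
}
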