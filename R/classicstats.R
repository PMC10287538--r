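# Extended-haplotype machinery shared by iHS and nSL.
#
# EHH at distance d from the focal site is the probability that two
# haplotypes drawn from the background are identical over every site between
# the focal site and d. It is computed by refining a partition of the
# background haplotypes site by site outward from the focal site; pair counts
# of the partition give EHH directly.

# Walk outward from the focal column over `cols` (ordered by increasing
# distance); returns the vector of pair counts still identical after each
# successive site. n_pairs0 = all pairs (EHH = 1 at the focal site itself).
# Partition refinement is in C++ (ehh_pair_walk_cpp); this is the hot loop
# of iHS/nSL.
.ehh_pair_walk <- function(alleles, rows, cols) {
  ehh_pair_walk_cpp(alleles, as.integer(rows), as.integer(cols))
}

# Integrated EHH on one side of the focal site for one background.
# Trapezoid integration over `dist` (bp or cM), truncated after the first
# site where EHH drops below `cutoff`, or at the window edge.
.ihh_side <- function(alleles, rows, cols, dist, cutoff) {
  np <- length(rows) * (length(rows) - 1L) / 2
  if (np == 0) return(list(ihh = 0, hit_cutoff = TRUE))
  if (!length(cols)) return(list(ihh = 0, hit_cutoff = FALSE))
  pairs <- .ehh_pair_walk(alleles, rows, cols)
  ehh <- pairs / np
  x <- c(0, dist)
  y <- c(1, ehh)
  stop_at <- which(ehh < cutoff)
  last <- if (length(stop_at)) stop_at[1L] + 1L else length(y)
  ihh <- sum(diff(x[1:last]) * (y[1:(last - 1L)] + y[2:last]) / 2)
  list(ihh = ihh, hit_cutoff = length(stop_at) > 0L)
}

.ihh_background <- function(x, rows, context, window, map, cutoff) {
  f <- context$focal_index
  fpos <- x$positions[f]
  idx <- which(x$positions >= window[1L] & x$positions < window[2L])
  left <- rev(idx[idx < f])
  right <- idx[idx > f]
  posval <- if (is.null(map)) x$positions else genetic_pos(map, x$positions)
  fp <- if (is.null(map)) fpos else genetic_pos(map, fpos)
  l <- .ihh_side(x$alleles, rows, left, abs(posval[left] - fp), cutoff)
  r <- .ihh_side(x$alleles, rows, right, abs(posval[right] - fp), cutoff)
  list(ihh = l$ihh + r$ihh, hit_cutoff = l$hit_cutoff || r$hit_cutoff)
}

#' iHS: integrated haplotype score (unstandardized)
#'
#' Integrates the decay of extended haplotype homozygosity away from the
#' focal site separately on the derived and ancestral backgrounds (trapezoid
#' rule, truncated where EHH drops below `cutoff` or at the window edge) and
#' returns `ln(iHH_derived / iHH_ancestral)`. The orientation is chosen so a
#' sweep on the derived background — long derived haplotypes, slow EHH decay
#' — gives positive values, consistent with the package-wide sign convention
#' (DIND and Sratio are ancestral/derived ratios for the same reason).
#' Integration is over genetic distance (cM) when `map` is given, physical
#' distance otherwise. Standardization happens downstream through
#' [build_norms()], like every per-SNP statistic.
#'
#' @inheritParams hapdaf
#' @param map optional [genetic_map()].
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return unstandardized value, `NA` when a background has fewer than 2
#'   haplotypes or an integral is zero. Attribute `edge_truncated` flags
#'   walks that hit the window edge before the EHH cutoff.
#' @export
ihs <- function(x, context, halfspan_bp = 25000, map = NULL, window = NULL,
                cutoff = 0.05) {
  if (!context$computable) return(NA_real_)
  if (is.null(window)) {
    fpos <- x$positions[context$focal_index]
    window <- c(fpos - halfspan_bp, fpos + halfspan_bp)
  }
  if (length(context$derived_carriers) < 2L ||
      length(context$ancestral_carriers) < 2L) return(NA_real_)
  d <- .ihh_background(x, context$derived_carriers, context, window, map,
                       cutoff)
  a <- .ihh_background(x, context$ancestral_carriers, context, window, map,
                       cutoff)
  if (d$ihh <= 0 || a$ihh <= 0) return(NA_real_)
  out <- log(d$ihh / a$ihh)
  attr(out, "edge_truncated") <- !(d$hit_cutoff && a$hit_cutoff)
  out
}

#' nSL: number of segregating sites by length (unstandardized)
#'
#' For each background, the mean over haplotype pairs of the length — counted
#' in segregating sites — of the longest stretch of identity containing the
#' focal site, truncated at the window (or matrix) edge. Returns
#' `ln(SL_derived / SL_ancestral)`: identical derived haplotypes give large
#' positive values (sweep-positive sign convention, see [ihs()]). Map-free by
#' construction.
#'
#' @inheritParams ihs
#' @return unstandardized value, `NA` when a background has < 2 haplotypes.
#' @export
nsl <- function(x, context, halfspan_bp = 25000, window = NULL) {
  if (!context$computable) return(NA_real_)
  if (is.null(window)) {
    fpos <- x$positions[context$focal_index]
    window <- c(fpos - halfspan_bp, fpos + halfspan_bp)
  }
  if (length(context$derived_carriers) < 2L ||
      length(context$ancestral_carriers) < 2L) return(NA_real_)
  sl_d <- .mean_shared_length(x, context$derived_carriers,
                              context$focal_index, window)
  sl_a <- .mean_shared_length(x, context$ancestral_carriers,
                              context$focal_index, window)
  log(sl_d / sl_a)
}

# mean pairwise shared-haplotype length in segregating-site units around the
# focal site; the focal site itself counts 1 (all background pairs share it)
.mean_shared_length <- function(x, rows, f, window) {
  np <- length(rows) * (length(rows) - 1L) / 2
  idx <- which(x$positions >= window[1L] & x$positions < window[2L])
  left <- rev(idx[idx < f])
  right <- idx[idx > f]
  tot <- np
  if (length(left))
    tot <- tot + sum(.ehh_pair_walk(x$alleles, rows, left))
  if (length(right))
    tot <- tot + sum(.ehh_pair_walk(x$alleles, rows, right))
  tot / np
}

#' DIND: derived intra-allelic nucleotide diversity (unstandardized)
#'
#' Ratio of pairwise nucleotide diversity computed among ancestral-background
#' haplotypes to that among derived-background haplotypes over the window
#' (`pi_ancestral / pi_derived`); a sweep depletes derived-background
#' diversity, so large values indicate selection.
#'
#' @inheritParams hapdaf
#' @return unstandardized value, `NA` when `pi_derived = 0` or a background
#'   has < 2 haplotypes.
#' @export
dind <- function(x, context, halfspan_bp = 25000, window = NULL) {
  if (!context$computable) return(NA_real_)
  fl <- .flank_of(x, context, halfspan_bp, window)
  if (!length(fl)) return(NA_real_)
  nd <- length(context$derived_carriers)
  na <- length(context$ancestral_carriers)
  if (nd < 2L || na < 2L) return(NA_real_)
  cd <- .carrier_counts(x, context$derived_carriers, fl)
  ca <- .carrier_counts(x, context$ancestral_carriers, fl)
  pi_d <- sum(cd * (nd - cd)) / (nd * (nd - 1) / 2)
  pi_a <- sum(ca * (na - ca)) / (na * (na - 1) / 2)
  if (pi_d == 0) return(NA_real_)
  pi_a / pi_d
}

#' SAFE and iSAFE scores for favored-mutation localization
#'
#' SAFE scores each variant by contrasting its haplotype-allele-frequency
#' weighting with its haplotype support: with `HAF(h)` the sum over sites of
#' the derived-allele count of every derived allele carried by haplotype `h`,
#' `phi(m)` is the fraction of total HAF carried by the haplotypes containing
#' `m`, `kappa(m)` the fraction of distinct haplotypes containing `m`, and
#' `SAFE(m) = (phi - kappa) / sqrt(f (1 - f))` with `f` the derived allele
#' frequency of `m`. iSAFE applies SAFE in overlapping 300-SNP windows (step
#' 150) and averages each variant's window scores weighted by the window's
#' maximum SAFE score.
#'
#' Following the recommendation of SAFE's authors, windows with fewer than
#' 300 SNPs
#' use plain SAFE; `safe_or_isafe()` applies that rule and reports which
#' branch was taken.
#'
#' @param x a [haplotype_matrix()].
#' @param window optional `c(start, end)` half-open window in bp; default the
#'   whole matrix.
#' @param snp_threshold SNP count at and above which iSAFE is used.
#' @return a tibble with columns `site` (column index in `x`), `pos`, `daf`,
#'   `score`, plus attribute `method` ("SAFE" or "iSAFE").
#' @export
safe_or_isafe <- function(x, window = NULL, snp_threshold = 300L) {
  idx <- if (is.null(window)) seq_len(n_sites(x))
         else which(x$positions >= window[1L] & x$positions < window[2L])
  if (length(idx) < 2L)
    stop("SAFE needs at least 2 SNPs in the window", call. = FALSE)
  method <- if (length(idx) < snp_threshold) "SAFE" else "iSAFE"
  scores <- if (method == "SAFE") .safe_scores(x$alleles[, idx, drop = FALSE])
            else .isafe_scores(x$alleles[, idx, drop = FALSE])
  out <- tibble::tibble(site = idx, pos = x$positions[idx],
                        daf = colMeans(x$alleles[, idx, drop = FALSE]),
                        score = scores)
  attr(out, "method") <- method
  out
}

.row_keys <- function(A) {
  do.call(paste0, lapply(seq_len(ncol(A)), function(j) A[, j]))
}

.safe_scores <- function(A) {
  n <- nrow(A)
  counts <- colSums(A)
  haf <- as.numeric(A %*% counts)
  total_haf <- sum(haf)
  uniq <- !duplicated(.row_keys(A))
  n_uniq <- sum(uniq)
  phi <- as.numeric(crossprod(A, haf)) / total_haf
  kappa <- colSums(A[uniq, , drop = FALSE] > 0L) / n_uniq
  f <- counts / n
  denom <- sqrt(f * (1 - f))
  sc <- (phi - kappa) / denom
  sc[denom == 0] <- 0
  sc
}

.isafe_scores <- function(A, size = 300L, step = 150L) {
  s <- ncol(A)
  starts <- unique(c(seq(1L, max(s - size + 1L, 1L), by = step),
                     max(s - size + 1L, 1L)))
  acc <- numeric(s)
  wsum <- numeric(s)
  for (st in starts) {
    cols <- st:min(st + size - 1L, s)
    sc <- .safe_scores(A[, cols, drop = FALSE])
    w <- max(max(sc), 0) + 1e-9
    acc[cols] <- acc[cols] + w * sc
    wsum[cols] <- wsum[cols] + w
  }
  acc / wsum
}

#' HAF summary: mean of the top 10% of haplotype allele frequency scores
#'
#' The HAF score of a haplotype is the sum over window sites of the
#' derived-allele count of each derived allele it carries. Only the top 10%
#' of haplotype scores (`ceiling(0.1 n)` haplotypes) are averaged, which
#' carries a better signal for incomplete sweeps; one value is taken per
#' locus.
#'
#' @inheritParams safe_or_isafe
#' @return a single value (`0` for a window with no sites).
#' @export
haf_top <- function(x, window = NULL) {
  idx <- if (is.null(window)) seq_len(n_sites(x))
         else which(x$positions >= window[1L] & x$positions < window[2L])
  if (!length(idx)) return(0)
  A <- x$alleles[, idx, drop = FALSE]
  haf <- as.numeric(A %*% colSums(A))
  k <- ceiling(0.1 * length(haf))
  mean(sort(haf, decreasing = TRUE)[seq_len(k)])
}

#' H12 with an 80% haplotype-identity threshold
#'
#' Classic H12 squares the summed frequencies of the two most common
#' haplotype classes and adds the squared frequencies of the rest; this
#' variant forms the classes by greedy clustering at >= 80% pairwise identity
#' (fraction of matching alleles over window SNPs) so that recombined or
#' mutated copies of a sweeping haplotype still cluster together. Seeds are
#' taken in order of descending haplotype multiplicity, with ties broken by
#' the lexicographic order of the haplotype strings (content-based, so the
#' statistic is invariant to haplotype row order); each haplotype joins the
#' first seed it matches at >= the identity threshold. One value is taken per locus. With the threshold
#' raised to 1 this reduces exactly to H12 on identical haplotype classes.
#'
#' @inheritParams safe_or_isafe
#' @param identity identity threshold in `(0, 1]` (default 0.8).
#' @return H12 in `(0, 1]`; `NA` for a window with 0 SNPs.
#' @export
h12_80 <- function(x, window = NULL, identity = 0.8) {
  idx <- if (is.null(window)) seq_len(n_sites(x))
         else which(x$positions >= window[1L] & x$positions < window[2L])
  if (!length(idx)) return(NA_real_)
  A <- x$alleles[, idx, drop = FALSE]
  n <- nrow(A)
  key <- .row_keys(A)
  tab <- table(key)
  first_occ <- vapply(names(tab), function(k) which(key == k)[1L], 0L)
  # ties in multiplicity break by haplotype content (lexicographic), keeping
  # the clustering invariant to haplotype row order
  ord <- order(-as.integer(tab), names(tab))
  uniq_keys <- names(tab)[ord]
  uniq_mat <- A[first_occ[ord], , drop = FALSE]
  counts <- as.integer(tab)[ord]

  seed_rows <- integer(0)
  cluster_n <- integer(0)
  for (i in seq_along(uniq_keys)) {
    placed <- FALSE
    for (cl in seq_along(seed_rows)) {
      idshare <- mean(uniq_mat[i, ] == uniq_mat[seed_rows[cl], ])
      if (idshare >= identity) {
        cluster_n[cl] <- cluster_n[cl] + counts[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seed_rows <- c(seed_rows, i)
      cluster_n <- c(cluster_n, counts[i])
    }
  }
  p <- sort(cluster_n / n, decreasing = TRUE)
  p1 <- p[1L]
  p2 <- if (length(p) >= 2L) p[2L] else 0
  (p1 + p2)^2 + sum(p[-(1:2)][p[-(1:2)] > 0]^2, na.rm = TRUE)
}
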