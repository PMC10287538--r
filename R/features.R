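#' Feature-tensor geometry
#'
#' The classifier summarizes a locus as 11 statistics over 21 center points
#' spaced at 10-kb intervals, each with nested windows of five sizes (50,
#' 100, 200, 500 and 1,000 kb) around the center point — 105 windows in all.
#' The defaults describe the reference 1.2-Mb locus; every element scales for
#' fixture-sized loci (tests use a x0.1 world).
#'
#' @param locus_length locus length in bp.
#' @param n_centers number of center points.
#' @param center_spacing spacing between centers, bp.
#' @param window_sizes nested window sizes, bp, increasing.
#' @return a list of class `feature_geometry`.
#' @export
feature_geometry <- function(locus_length = 1200000, n_centers = 21L,
                             center_spacing = 10000,
                             window_sizes = c(50000, 100000, 200000,
                                              500000, 1000000)) {
  g <- structure(list(locus_length = locus_length,
                      n_centers = as.integer(n_centers),
                      center_spacing = center_spacing,
                      window_sizes = sort(window_sizes)),
                 class = "feature_geometry")
  center_points(g)  # validates feasibility
  g
}

#' Center points of the nested-window grid
#'
#' Centers are symmetric about the locus midpoint with the configured
#' spacing, placed so that the largest window always lies inside the locus
#' (for the default 1.2-Mb geometry: 500,000 to 700,000 bp in 10-kb steps).
#'
#' @param geometry a [feature_geometry()].
#' @return numeric vector of center positions (bp).
#' @export
center_points <- function(geometry) {
  mid <- geometry$locus_length / 2
  half_span <- (geometry$n_centers - 1L) / 2 * geometry$center_spacing
  centers <- mid + seq(-half_span, half_span,
                       length.out = geometry$n_centers)
  max_half <- max(geometry$window_sizes) / 2
  if (centers[1L] - max_half < 0 ||
      centers[length(centers)] + max_half > geometry$locus_length)
    stop("locus too short for the largest window at ", geometry$n_centers,
         " centers; shrink the geometry", call. = FALSE)
  centers
}

#' Default statistic row order (interleaved)
#'
#' Classification improves when statistics that summarize the data
#' differently are interspersed among the tensor rows rather than grouped,
#' so the default alternates haplotype-structure, SFS and derived-background
#' -diversity statistics. Any permutation of the 11 names is accepted by
#' [assemble()].
#'
#' @return character vector of the 11 statistic names.
#' @export
default_row_order <- function() {
  c("ihs", "hapdaf_o", "dind", "nsl", "hapdaf_s", "sratio", "isafe",
    "lowfreq", "haf", "highfreq", "h12")
}

.PER_SNP_STATS <- c("hapdaf_o", "hapdaf_s", "sratio", "lowfreq", "highfreq",
                    "dind", "ihs", "nsl")

# ---------------------------------------------------------------------------
# Fast per-focal profiles.
#
# All derived/ancestral background statistics of a focal site reduce to sums
# over flanking sites of simple per-site terms: with cd_j the number of
# derived-background haplotypes carrying the derived allele at flanking site
# j and ca_j the ancestral-background count, every term is a function of
# (cd_j, ca_j). Cumulative sums in position order turn any window into an
# O(1) range query. iHS/nSL need ordered outward walks; their EHH pair-count
# curves and cumulative integrals are precomputed per focal site and then
# truncated per window.

.focal_profile <- function(x, f, cd, ehh_cutoff = 0.05, map = NULL) {
  pos <- x$positions
  S <- length(pos)
  n <- n_haplotypes(x)
  cs <- attr(cd, "colsums")
  nd <- attr(cd, "nd")
  na <- n - nd
  ca <- cs - cd

  fd <- cd / nd
  fa <- ca / na
  fdd <- fd

  term_o <- fd^2 - fa^2
  q_o <- cd >= 1L & ca >= 1L & fd > fa & fa < 0.25 & (fd + fa) > 0.25
  q_s <- cd >= 1L & ca >= 1L & fd > fa & fa < 0.1 & (fd + fa) > 0.1
  q_lo <- fdd > 0 & fdd < 0.25
  q_hi <- fdd > 0.25
  seg_a <- ca > 0L & ca < na
  seg_d <- cd > 0L & cd < nd

  z <- function(v) { v[f] <- 0; cumsum(v) }
  prof <- list(
    f = f, nd = nd, na = na, daf = nd / n,
    hd_o_t = z(term_o * q_o), hd_o_k = z(as.numeric(q_o)),
    hd_s_t = z(term_o * q_s), hd_s_k = z(as.numeric(q_s)),
    lo_t = z((1 - fdd)^2 * q_lo), lo_k = z(as.numeric(q_lo)),
    hi_t = z(fdd^2 * q_hi), hi_k = z(as.numeric(q_hi)),
    seg_a = z(as.numeric(seg_a)), seg_d = z(as.numeric(seg_d)),
    pi_d = z(cd * (nd - cd)), pi_a = z(ca * (na - ca))
  )

  # EHH walks (both directions, both backgrounds) over the whole locus
  rows_d <- which(x$alleles[, f] == 1L)
  rows_a <- which(x$alleles[, f] == 0L)
  posval <- if (is.null(map)) pos else genetic_pos(map, pos)
  left <- rev(seq_len(f - 1L))
  right <- if (f < S) (f + 1L):S else integer(0)
  walk <- function(rows, cols) {
    np <- length(rows) * (length(rows) - 1L) / 2
    if (np == 0 || !length(cols))
      return(list(np = np, pairs = numeric(0), integ = numeric(0),
                  kcut = 0L, cump = numeric(0)))
    pairs <- .ehh_pair_walk(x$alleles, rows, cols)
    ehh <- pairs / np
    d <- abs(posval[cols] - posval[f])
    y <- c(1, ehh); xx <- c(0, d)
    integ <- cumsum(diff(xx) * (y[-length(y)] + y[-1L]) / 2)
    below <- which(ehh < ehh_cutoff)
    list(np = np, pairs = pairs, integ = integ,
         kcut = if (length(below)) below[1L] else length(ehh) + 1L,
         cump = cumsum(pairs))
  }
  prof$dl <- walk(rows_d, left); prof$dr <- walk(rows_d, right)
  prof$al <- walk(rows_a, left); prof$ar <- walk(rows_a, right)
  prof
}

# Evaluate one window [lo_idx, hi_idx] (site-index range containing f) on a
# profile; returns the 8 unstandardized per-SNP statistics.
.profile_eval <- function(p, lo_idx, hi_idx) {
  rng <- function(cum) cum[hi_idx] - if (lo_idx > 1L) cum[lo_idx - 1L] else 0
  k_o <- rng(p$hd_o_k); k_s <- rng(p$hd_s_k)
  k_lo <- rng(p$lo_k); k_hi <- rng(p$hi_k)
  hap_o <- if (k_o > 0) rng(p$hd_o_t) / k_o else 0
  hap_s <- if (k_s > 0) rng(p$hd_s_t) / k_s else 0
  lo <- if (k_lo > 0) rng(p$lo_t) / k_lo else 0
  hi <- if (k_hi > 0) rng(p$hi_t) / k_hi else 0
  s_d <- rng(p$seg_d); s_a <- rng(p$seg_a)
  sr <- if (s_d > 0) s_a / s_d else NA_real_
  pid <- rng(p$pi_d) / (p$nd * (p$nd - 1) / 2)
  pia <- rng(p$pi_a) / (p$na * (p$na - 1) / 2)
  dd <- if (p$nd >= 2 && p$na >= 2 && pid > 0) pia / pid else NA_real_

  kl <- p$f - lo_idx        # steps available to the left
  kr <- hi_idx - p$f        # and to the right
  side <- function(w, k) {
    if (w$np == 0 || k == 0L) return(0)
    w$integ[min(k, w$kcut, length(w$integ))]
  }
  ihh_d <- side(p$dl, kl) + side(p$dr, kr)
  ihh_a <- side(p$al, kl) + side(p$ar, kr)
  ihs_v <- if (p$nd >= 2 && p$na >= 2 && ihh_d > 0 && ihh_a > 0)
    log(ihh_d / ihh_a) else NA_real_

  slde <- function(w, k) if (w$np == 0 || k == 0L) 0
                         else w$cump[min(k, length(w$cump))]
  nsl_v <- if (p$nd >= 2 && p$na >= 2) {
    sl_d <- (p$dl$np + slde(p$dl, kl) + slde(p$dr, kr)) / p$dl$np
    sl_a <- (p$al$np + slde(p$al, kl) + slde(p$ar, kr)) / p$al$np
    log(sl_d / sl_a)
  } else NA_real_

  c(hapdaf_o = hap_o, hapdaf_s = hap_s, sratio = sr, lowfreq = lo,
    highfreq = hi, dind = dd, ihs = ihs_v, nsl = nsl_v)
}

# tibble-free per-window iSAFE summary for the batch paths: maximum SAFE
# (or iSAFE at >= 300 SNPs) score over the site-index range [lo, hi]
.safe_max <- function(x, lo, hi, snp_threshold = 300L) {
  if (hi - lo + 1L < 2L) return(NA_real_)
  A <- x$alleles[, lo:hi, drop = FALSE]
  sc <- if (ncol(A) < snp_threshold) .safe_scores(A) else .isafe_scores(A)
  max(sc)
}

# derived-background carrier counts for focal f at every site, with colsums
# and nd attached; uses a precomputed crossproduct when supplied
.cd_for_focal <- function(x, f, C = NULL, cs = NULL) {
  if (is.null(cs)) cs <- colSums(x$alleles)
  cd <- if (!is.null(C)) C[f, ] else {
    rows <- which(x$alleles[, f] == 1L)
    .carrier_counts(x, rows, seq_len(n_sites(x)))
  }
  attr(cd, "colsums") <- cs
  attr(cd, "nd") <- cs[f]
  cd
}

# expanded norms lookup: env[[key]] -> list(mean, sd) with 50-bin vectors for
# DAF-binned entries or scalars otherwise; key = "<stat>|<size or NA>"
.norms_index <- function(norms) {
  env <- new.env(parent = emptyenv())
  keyf <- function(stat, size)
    paste0(stat, "|", ifelse(is.na(size), "NA",
                             format(size, scientific = FALSE, trim = TRUE)))
  grp <- split(seq_len(nrow(norms)),
               keyf(norms$statistic, norms$size))
  for (k in names(grp)) {
    rows <- norms[grp[[k]], , drop = FALSE]
    if (all(is.na(rows$bin_low))) {
      assign(k, list(mean = rows$mean[1L], sd = rows$sd[1L], binned = FALSE),
             envir = env)
    } else {
      mean50 <- sd50 <- rep(NA_real_, 50L)
      for (i in seq_len(nrow(rows))) {
        lo <- round(rows$bin_low[i] / 0.02) + 1L
        hi <- round(rows$bin_high[i] / 0.02)
        mean50[lo:hi] <- rows$mean[i]
        sd50[lo:hi] <- rows$sd[i]
      }
      assign(k, list(mean = mean50, sd = sd50, binned = TRUE), envir = env)
    }
  }
  attr(env, "keyf") <- keyf
  env
}

.norms_lookup <- function(idx, stat, size) {
  keyf <- attr(idx, "keyf")
  k <- keyf(stat, size)
  if (exists(k, envir = idx, inherits = FALSE))
    return(get(k, envir = idx, inherits = FALSE))
  k <- keyf(stat, NA_real_)
  if (exists(k, envir = idx, inherits = FALSE))
    return(get(k, envir = idx, inherits = FALSE))
  stop("no norms fitted for statistic '", stat, "' (size ", size, ")",
       call. = FALSE)
}

# ---------------------------------------------------------------------------

#' Assemble the feature tensor for one locus
#'
#' Computes the 11 statistics over every nested window, standardizes them
#' against neutral norms and lays them out as a matrix of 11 statistic rows
#' by `n_centers * n_sizes` window columns (center-major, then size).
#' Per-SNP statistics are standardized per focal variant by
#' derived-allele-frequency bin and averaged over all computable focal SNPs
#' in the window; the per-window iSAFE summary (the maximum per-SNP score,
#' with the SAFE fallback below 300 SNPs) is standardized per window size;
#' HAF and H12 take a single locus-level value broadcast across all columns.
#' Cells that are not computable (empty windows, undefined ratios) are
#' imputed with 0 — the neutral-standardized mean — and counted in the
#' `flags` attribute.
#'
#' @param x a [haplotype_matrix()].
#' @param norms a [build_norms()] object fitted on neutral simulations with
#'   matching geometry (see [norms_from_neutral()]).
#' @param geometry a [feature_geometry()]; defaults to the reference
#'   geometry scaled to `x$locus_length` only if it matches 1.2 Mb.
#' @param row_order permutation of the 11 statistic names
#'   ([default_row_order()]).
#' @param map optional [genetic_map()] for iHS.
#' @param locus_id identifier stored in the tensor metadata.
#' @return a `feature_tensor`: the values matrix with attributes
#'   `row_order`, `geometry`, `norms_provenance`, `n_imputed`, `flags`,
#'   `locus_id`.
#' @export
assemble <- function(x, norms, geometry = feature_geometry(),
                     row_order = default_row_order(), map = NULL,
                     locus_id = NULL) {
  stopifnot(inherits(x, "hapmat"), inherits(norms, "binned_norms"))
  if (!setequal(row_order, default_row_order()) ||
      length(row_order) != 11L)
    stop("`row_order` must be a permutation of the 11 statistic names",
         call. = FALSE)
  centers <- center_points(geometry)
  sizes <- geometry$window_sizes
  n_col <- length(centers) * length(sizes)
  idx <- .norms_index(norms)
  pos <- x$positions
  S <- n_sites(x)

  col_center <- rep(seq_along(centers), each = length(sizes))
  col_size <- rep(seq_along(sizes), times = length(centers))
  win_start <- centers[col_center] - sizes[col_size] / 2
  win_end <- centers[col_center] + sizes[col_size] / 2
  lo_idx <- findInterval(win_start - 0.5, pos) + 1L
  hi_idx <- findInterval(win_end - 0.5, pos)

  sums <- matrix(0, length(.PER_SNP_STATS), n_col,
                 dimnames = list(.PER_SNP_STATS, NULL))
  cnts <- matrix(0L, length(.PER_SNP_STATS), n_col,
                 dimnames = list(.PER_SNP_STATS, NULL))

  if (S > 0L) {
    daf <- site_daf(x)
    focal_set <- which(daf >= 0.25 & daf <= 0.95 &
                       pos >= min(win_start) & pos < max(win_end))
    cs <- colSums(x$alleles)
    C <- if (S <= 3000L) crossprod(x$alleles) else NULL
    for (f in focal_set) {
      cd <- .cd_for_focal(x, f, C, cs)
      prof <- .focal_profile(x, f, cd, map = map)
      inwin <- which(pos[f] >= win_start & pos[f] < win_end &
                     lo_idx <= hi_idx)
      if (!length(inwin)) next
      vals <- vapply(inwin, function(w)
        .profile_eval(prof, lo_idx[w], hi_idx[w]),
        stats::setNames(numeric(length(.PER_SNP_STATS)), .PER_SNP_STATS))
      bin <- daf_bin(prof$daf)
      for (si in seq_along(sizes)) {
        wsel <- which(col_size[inwin] == si)
        if (!length(wsel)) next
        for (st in .PER_SNP_STATS) {
          nm <- .norms_lookup(idx, st, sizes[si])
          m <- if (nm$binned) nm$mean[bin] else nm$mean
          s <- if (nm$binned) nm$sd[bin] else nm$sd
          v <- (vals[st, wsel] - m) / s
          ok <- is.finite(v)
          cols <- inwin[wsel][ok]
          sums[st, cols] <- sums[st, cols] + v[ok]
          cnts[st, cols] <- cnts[st, cols] + 1L
        }
      }
    }
  }

  values <- matrix(NA_real_, 11L, n_col,
                   dimnames = list(row_order, NULL))
  for (st in .PER_SNP_STATS)
    values[st, ] <- ifelse(cnts[st, ] > 0, sums[st, ] / cnts[st, ],
                           NA_real_)

  # per-window iSAFE summary (max per-SNP score; SAFE below 300 SNPs)
  isafe_raw <- vapply(seq_len(n_col), function(w) {
    .safe_max(x, lo_idx[w], hi_idx[w])
  }, 0)
  for (si in seq_along(sizes)) {
    nm <- .norms_lookup(idx, "isafe", sizes[si])
    sel <- which(col_size == si)
    values["isafe", sel] <- (isafe_raw[sel] - nm$mean) / nm$sd
  }

  # locus-level HAF and H12, broadcast across all windows
  nm <- .norms_lookup(idx, "haf", NA_real_)
  values["haf", ] <- (haf_top(x) - nm$mean) / nm$sd
  nm <- .norms_lookup(idx, "h12", NA_real_)
  h12v <- h12_80(x)
  values["h12", ] <- if (is.na(h12v)) NA_real_ else (h12v - nm$mean) / nm$sd

  flags <- !is.finite(values)
  values[flags] <- 0
  structure(values,
            class = "feature_tensor",
            row_order = row_order,
            geometry = geometry,
            norms_provenance = attr(norms, "provenance"),
            n_imputed = sum(flags), flags = flags,
            locus_id = locus_id)
}

#' @export
print.feature_tensor <- function(x, ...) {
  g <- attr(x, "geometry")
  cat("<feature_tensor> ", nrow(x), " statistics x ", ncol(x), " windows (",
      g$n_centers, " centers x ", length(g$window_sizes), " sizes), ",
      attr(x, "n_imputed"), " imputed cells\n", sep = "")
  invisible(x)
}

#' One window column of the feature tensor (reference path)
#'
#' Computes the 11 statistics for a single (center, size) window directly
#' from the per-SNP statistic functions. [assemble()] computes the same
#' quantities through cumulative-sum profiles for speed; this function is
#' the plain implementation and their agreement is a tested invariant.
#'
#' @inheritParams assemble
#' @param center window center (bp).
#' @param size window size (bp).
#' @return named numeric vector of the 11 standardized statistics (`NA`
#'   where not computable, before imputation).
#' @export
compute_window_stats <- function(x, center, size, norms, map = NULL) {
  idx <- .norms_index(norms)
  win <- c(center - size / 2, center + size / 2)
  sites <- which(x$positions >= win[1L] & x$positions < win[2L])
  daf <- site_daf(x)
  focal_set <- sites[daf[sites] >= 0.25 & daf[sites] <= 0.95]
  out <- stats::setNames(rep(NA_real_, 11L), default_row_order())

  acc <- stats::setNames(rep(0, length(.PER_SNP_STATS)), .PER_SNP_STATS)
  cnt <- stats::setNames(rep(0L, length(.PER_SNP_STATS)), .PER_SNP_STATS)
  for (f in focal_set) {
    ctx <- focal_context(x, f)
    raw <- c(hapdaf_o = hapdaf_o(x, ctx, window = win),
             hapdaf_s = hapdaf_s(x, ctx, window = win),
             sratio = sratio(x, ctx, window = win),
             lowfreq = lowfreq(x, ctx, window = win),
             highfreq = highfreq(x, ctx, window = win),
             dind = dind(x, ctx, window = win),
             ihs = as.numeric(ihs(x, ctx, map = map, window = win)),
             nsl = nsl(x, ctx, window = win))
    for (st in .PER_SNP_STATS) {
      nm <- .norms_lookup(idx, st, size)
      v <- if (nm$binned) {
        b <- daf_bin(ctx$focal_daf)
        (raw[st] - nm$mean[b]) / nm$sd[b]
      } else (raw[st] - nm$mean) / nm$sd
      if (is.finite(v)) {
        acc[st] <- acc[st] + v
        cnt[st] <- cnt[st] + 1L
      }
    }
  }
  for (st in .PER_SNP_STATS)
    out[st] <- if (cnt[st] > 0) acc[st] / cnt[st] else NA_real_

  if (length(sites) >= 2L) {
    nm <- .norms_lookup(idx, "isafe", size)
    out["isafe"] <- (max(safe_or_isafe(x, window = win)$score) - nm$mean) /
      nm$sd
  }
  nm <- .norms_lookup(idx, "haf", NA_real_)
  out["haf"] <- (haf_top(x) - nm$mean) / nm$sd
  nm <- .norms_lookup(idx, "h12", NA_real_)
  h <- h12_80(x)
  out["h12"] <- if (is.na(h)) NA_real_ else (h - nm$mean) / nm$sd
  out
}

#' Fit standardization norms from neutral simulations
#'
#' Computes unstandardized per-SNP statistics on neutral matrices in exactly
#' the windows the feature pipeline evaluates — every focal variant of each
#' (center, size) window of the geometry — and fits [build_norms()]-style
#' moments per statistic, per window size, per 2% derived-allele-frequency
#' bin (streamed as running moments, so fitting scales to many loci). The
#' per-window iSAFE summaries are fitted per window size and the locus-level
#' HAF/H12 values globally. Fitting on the pipeline's own window
#' distribution makes neutral feature columns mean-zero by construction.
#'
#' @param mats list of neutral `hapmat` objects.
#' @param geometry a [feature_geometry()].
#' @param map optional [genetic_map()].
#' @param min_per_bin minimum values per bin before pooling.
#' @param provenance description stored with the norms.
#' @param max_focal_per_locus per-locus cap on focal sites used (subsampled
#'   deterministically) to bound fitting cost.
#' @return a `binned_norms` object.
#' @export
norms_from_neutral <- function(mats, geometry, map = NULL, min_per_bin = 20,
                               provenance = "neutral simulations",
                               max_focal_per_locus = 200L) {
  stopifnot(length(mats) > 0)
  sizes <- geometry$window_sizes
  centers <- center_points(geometry)
  n_stat <- length(.PER_SNP_STATS)
  n_size <- length(sizes)
  cnt <- array(0, c(n_stat, n_size, 50L),
               dimnames = list(.PER_SNP_STATS, NULL, NULL))
  sm <- cnt; sm2 <- cnt
  isafe_vals <- vector("list", n_size)
  haf_vals <- numeric(0)
  h12_vals <- numeric(0)

  col_center <- rep(seq_along(centers), each = n_size)
  col_size <- rep(seq_len(n_size), times = length(centers))
  win_start <- centers[col_center] - sizes[col_size] / 2
  win_end <- centers[col_center] + sizes[col_size] / 2

  for (mi in seq_along(mats)) {
    x <- mats[[mi]]
    S <- n_sites(x)
    if (S == 0L) next
    pos <- x$positions
    daf <- site_daf(x)
    lo_idx <- findInterval(win_start - 0.5, pos) + 1L
    hi_idx <- findInterval(win_end - 0.5, pos)
    focal_set <- which(daf >= 0.25 & daf <= 0.95 &
                       pos >= min(win_start) & pos < max(win_end))
    if (length(focal_set) > max_focal_per_locus)
      focal_set <- focal_set[round(seq(1, length(focal_set),
                                       length.out = max_focal_per_locus))]
    cs <- colSums(x$alleles)
    C <- if (S <= 3000L) crossprod(x$alleles) else NULL
    for (f in focal_set) {
      cd <- .cd_for_focal(x, f, C, cs)
      prof <- .focal_profile(x, f, cd, map = map)
      b <- daf_bin(prof$daf)
      inwin <- which(pos[f] >= win_start & pos[f] < win_end &
                     lo_idx <= hi_idx)
      for (wi in inwin) {
        v <- .profile_eval(prof, lo_idx[wi], hi_idx[wi])
        si <- col_size[wi]
        fin <- which(is.finite(v))
        cnt[fin, si, b] <- cnt[fin, si, b] + 1
        sm[fin, si, b] <- sm[fin, si, b] + v[fin]
        sm2[fin, si, b] <- sm2[fin, si, b] + v[fin]^2
      }
    }
    for (si in seq_len(n_size)) {
      wsel <- which(col_size == si)
      vals <- vapply(wsel, function(wi)
        .safe_max(x, lo_idx[wi], hi_idx[wi]), 0)
      isafe_vals[[si]] <- c(isafe_vals[[si]], vals[is.finite(vals)])
    }
    haf_vals <- c(haf_vals, haf_top(x))
    h12v <- h12_80(x)
    if (is.finite(h12v)) h12_vals <- c(h12_vals, h12v)
  }

  rows <- list()
  for (sti in seq_len(n_stat)) for (si in seq_len(n_size)) {
    rows[[length(rows) + 1L]] <- .fit_daf_bins_moments(
      cnt[sti, si, ], sm[sti, si, ], sm2[sti, si, ],
      .PER_SNP_STATS[sti], sizes[si], min_per_bin)
  }
  scalar_row <- function(stat, size, v) {
    if (length(v) < 2L || stats::sd(v) == 0)
      stop("zero variance fitting norms for statistic '", stat,
           "' (pooled bin)", call. = FALSE)
    tibble::tibble(statistic = stat, size = size, bin_low = NA_real_,
                   bin_high = NA_real_, mean = mean(v), sd = stats::sd(v),
                   n = length(v))
  }
  for (si in seq_len(n_size))
    rows[[length(rows) + 1L]] <- scalar_row("isafe", sizes[si],
                                            isafe_vals[[si]])
  rows[[length(rows) + 1L]] <- scalar_row("haf", NA_real_, haf_vals)
  rows[[length(rows) + 1L]] <- scalar_row("h12", NA_real_, h12_vals)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("binned_norms", class(tibble::tibble())),
            provenance = provenance, version = 1L)
}

#' Mirror a feature tensor (locus-reversal augmentation)
#'
#' Reversing the physical coordinate of a locus yields an equally valid
#' simulated locus whose feature tensor has the center order reversed
#' (window sizes and statistic rows unchanged). Doubling a training set with
#' mirrored copies is a cheap, symmetry-exact augmentation for the
#' classifier.
#'
#' @param tensor a [assemble()] output.
#' @return the mirrored `feature_tensor`.
#' @export
mirror_tensor <- function(tensor) {
  new_col <- mirror_columns(attr(tensor, "geometry"))
  out <- tensor
  out[, new_col] <- unclass(tensor)
  at <- attributes(tensor)
  at$flags[, new_col] <- attr(tensor, "flags")
  attributes(out) <- at
  out
}

#' @rdname mirror_tensor
#' @param geometry a [feature_geometry()].
#' @return `mirror_columns`: the column permutation that realizes the
#'   mirror, usable with stacked tensor arrays (see [train_cnn()]'s
#'   `mirror_cols`).
#' @export
mirror_columns <- function(geometry) {
  ns <- length(geometry$window_sizes)
  ctr <- rep(seq_len(geometry$n_centers), each = ns)
  sz <- rep(seq_len(ns), times = geometry$n_centers)
  (geometry$n_centers - ctr) * ns + sz
}

#' Squash a feature tensor's heavy tails (log-modulus transform)
#'
#' Ratio-based statistics (DIND, Sratio) are unbounded and single extreme
#' cells can destabilize network training; `sign(x) * log(1 + |x|)` keeps
#' sign and ordering, is identity-like near 0 (where standardized neutral
#' values live) and compresses outliers. Applied identically at training and
#' prediction time by passing `squash = TRUE` end to end.
#'
#' @param tensor a [assemble()] output.
#' @return the squashed `feature_tensor`.
#' @export
squash_tensor <- function(tensor) {
  v <- sign(unclass(tensor)) * log1p(abs(unclass(tensor)))
  attributes(v) <- attributes(tensor)
  v
}
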