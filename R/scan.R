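#' Tile a chromosome into overlapping scan windows
#'
#' Windows of `window_bp` (default 1.2 Mb) starting at 0 with `step_bp`
#' steps (default 10 kb); the last window must fit inside the chromosome, so
#' for length L >= window the count is `floor((L - window)/step) + 1`.
#' Chromosomes shorter than one window yield an empty list with a warning.
#'
#' @param chrom_length chromosome length in bp.
#' @param window_bp,step_bp window size and step.
#' @return a tibble with columns `start`, `end` (0-based half-open),
#'   `center`.
#' @export
tile_windows <- function(chrom_length, window_bp = 1200000,
                         step_bp = 10000) {
  if (chrom_length < window_bp) {
    warning("chromosome (", chrom_length, " bp) shorter than one window (",
            window_bp, " bp); no scan windows")
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          center = numeric(0)))
  }
  starts <- seq(0, chrom_length - window_bp, by = step_bp)
  tibble::tibble(start = starts, end = starts + window_bp,
                 center = starts + window_bp / 2)
}

#' Scan a chromosome-scale haplotype matrix for sweeps
#'
#' Tiles the matrix, featurizes each window against the supplied norms and
#' geometry, and scores it with the trained model. Windows failing the
#' data-quality gates — fewer than `min_snps` SNPs in the scan window or
#' more than `max_imputed_frac` imputed tensor cells — are flagged
#' unclassifiable (`NA` probability) rather than classified from imputation
#' artifacts.
#'
#' @param x a chromosome-scale [haplotype_matrix()] (`locus_length` = the
#'   chromosome length).
#' @param model a trained `sweep_cnn`.
#' @param norms neutral [build_norms()] matching the model manifest.
#' @param geometry the per-window [feature_geometry()]; window size is
#'   `geometry$locus_length`, step is `geometry$center_spacing`.
#' @param map optional [genetic_map()] in chromosome coordinates.
#' @param threshold classification confidence threshold (default 0.5).
#' @param step_bp scan step between window starts; defaults to the feature
#'   geometry's center spacing (10 kb at reference scale).
#' @param chrom chromosome name for the output records.
#' @param min_snps minimum SNPs for a window to be classifiable.
#' @param max_imputed_frac maximum tolerated fraction of imputed cells.
#' @param preprocess optional function applied to each window's tensor
#'   before prediction (e.g. [squash_tensor()]); must match what the model
#'   was trained with.
#' @return a `scan_result` tibble: `chrom`, `start`, `end`, `center`,
#'   `prob`, `sweep` (logical at `threshold`), `n_snps`, `flagged`.
#' @export
scan_matrix <- function(x, model, norms, geometry, map = NULL,
                        threshold = 0.5, step_bp = geometry$center_spacing,
                        chrom = "1", min_snps = 2L,
                        max_imputed_frac = 0.2, preprocess = NULL) {
  stopifnot(inherits(x, "hapmat"), inherits(model, "sweep_cnn"))
  wins <- tile_windows(x$locus_length, geometry$locus_length, step_bp)
  n <- nrow(wins)
  probs <- rep(NA_real_, n)
  nsnp <- integer(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    sl <- window_slice(x, wins$start[i], wins$end[i])
    # re-base to window-local coordinates for the feature geometry
    loc <- haplotype_matrix(sl$alleles, sl$positions - wins$start[i],
                            geometry$locus_length)
    nsnp[i] <- n_sites(loc)
    if (nsnp[i] < min_snps) { flagged[i] <- TRUE; next }
    wmap <- if (!is.null(map)) .shift_map(map, wins$start[i]) else NULL
    ft <- assemble(loc, norms, geometry, row_order = model$manifest$row_order,
                   map = wmap, locus_id = sprintf("%s:%d", chrom,
                                                 as.integer(wins$start[i])))
    if (attr(ft, "n_imputed") / length(ft) > max_imputed_frac) {
      flagged[i] <- TRUE
      next
    }
    if (!is.null(preprocess)) ft <- preprocess(ft)
    probs[i] <- stats::predict(model, ft)
  }
  structure(tibble::tibble(
    chrom = chrom, start = wins$start, end = wins$end, center = wins$center,
    prob = probs, sweep = !is.na(probs) & probs >= threshold,
    n_snps = nsnp, flagged = flagged),
    class = c("scan_result", class(tibble::tibble())),
    threshold = threshold)
}

.shift_map <- function(map, offset) {
  if (length(map$pos_bp) < 2L) return(map)
  genetic_map(map$pos_bp - offset, map$cm, map$rate_cm_mb)
}

#' Genome scan from a VCF
#'
#' Reads each requested region with [read_vcf_region()] and runs
#' [scan_matrix()]. Regions that cannot be polarized (no usable ancestral
#' information) are skipped with a warning.
#'
#' @param vcf_path phased VCF path.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param ancestral ancestral source for [read_vcf_region()].
#' @inheritParams scan_matrix
#' @return a `scan_result` tibble.
#' @export
classify_genome <- function(vcf_path, chrom, chrom_length, model, norms,
                            geometry, ancestral = "AA", map = NULL,
                            threshold = 0.5,
                            step_bp = geometry$center_spacing,
                            preprocess = NULL) {
  region <- sprintf("%s:%d-%d", chrom, 1L, as.integer(chrom_length))
  x <- read_vcf_region(vcf_path, region, ancestral)
  if (n_sites(x) == 0L)
    stop("no polarizable biallelic SNPs in ", region, call. = FALSE)
  scan_matrix(x, model, norms, geometry, map = map, threshold = threshold,
              step_bp = step_bp, chrom = chrom, preprocess = preprocess)
}

#' Merge streaks of sweep-classified windows into regions
#'
#' Maximal runs of consecutive sweep-classified windows become one region
#' whose span is the union of the member windows; the peak is the center of
#' the member window with the highest probability (ties: leftmost). The
#' center-step interval (first to last member center) is also reported.
#'
#' @param scan a `scan_result`.
#' @param threshold optional override of the scan's classification threshold.
#' @return a tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `max_prob`, `peak`, `center_start`, `center_end`.
#' @export
merge_streaks <- function(scan, threshold = NULL) {
  sweep <- if (is.null(threshold)) scan$sweep
           else !is.na(scan$prob) & scan$prob >= threshold
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_windows = integer(0),
                          max_prob = numeric(0), peak = numeric(0),
                          center_start = numeric(0), center_end = numeric(0))
  if (!any(sweep)) return(empty)
  runs <- rle(sweep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    best <- idx[which.max(scan$prob[idx])]
    tibble::tibble(chrom = scan$chrom[idx[1L]],
                   start = min(scan$start[idx]), end = max(scan$end[idx]),
                   n_windows = length(idx),
                   max_prob = max(scan$prob[idx]),
                   peak = scan$center[best],
                   center_start = min(scan$center[idx]),
                   center_end = max(scan$center[idx]))
  })
  do.call(rbind, out)
}

#' Estimate the scan false discovery rate
#'
#' FDR = expected false-positive windows / positively classified windows,
#' with the expected false positives given by the model's validation FPR on
#' the matched demographic model. To respect the strong overlap of
#' 1.2-Mb windows stepped at 10 kb, the rate is computed on `n_sets` random
#' sets of windows spaced at least `spacing_bp` apart and averaged; sets
#' with zero positives are excluded with a warning.
#'
#' @param scan a `scan_result`.
#' @param model_fpr FPR (on neutral truth) from [evaluate()] under the
#'   matched demography.
#' @param n_sets number of independent window sets (default 100).
#' @param spacing_bp minimum center spacing within a set (default 1 Mb).
#' @param seed sampling seed.
#' @return the mean FDR (single number) with attribute `per_set`.
#' @export
estimate_fdr <- function(scan, model_fpr, n_sets = 100L,
                         spacing_bp = 1e6, seed = 1L) {
  usable <- which(!is.na(scan$prob))
  if (!length(usable)) stop("no classified windows", call. = FALSE)
  per_set <- withr::with_seed(seed, vapply(seq_len(n_sets), function(i) {
    ord <- sample(usable)
    chosen <- integer(0)
    for (w in ord) {
      if (!length(chosen) ||
          all(abs(scan$center[w] - scan$center[chosen]) >= spacing_bp))
        chosen <- c(chosen, w)
    }
    pos <- sum(scan$sweep[chosen])
    if (pos == 0L) return(NA_real_)
    (model_fpr * length(chosen)) / pos
  }, 0))
  bad <- sum(is.na(per_set))
  if (bad) warning(bad, " window set(s) had zero positives; excluded")
  if (all(is.na(per_set)))
    stop("no window set contained a positive classification", call. = FALSE)
  out <- mean(per_set, na.rm = TRUE)
  attr(out, "per_set") <- per_set
  out
}

#' Write scan results / regions as BED and TSV
#'
#' BED is 0-based half-open; the TSV carries probabilities and flags. A JSON
#' run manifest (seed, thresholds, package version) accompanies every run.
#'
#' @param scan a `scan_result` or [merge_streaks()] output.
#' @param prefix output path prefix (writes `<prefix>.bed`, `<prefix>.tsv`,
#'   `<prefix>.manifest.json`).
#' @param manifest named list merged into the run manifest.
#' @return invisibly, the written paths.
#' @export
write_scan <- function(scan, prefix, manifest = list()) {
  bed <- file.path(paste0(prefix, ".bed"))
  tsv <- file.path(paste0(prefix, ".tsv"))
  man <- file.path(paste0(prefix, ".manifest.json"))
  is_regions <- "n_windows" %in% names(scan)
  if (is_regions) {
    score <- pmin(pmax(round(scan$max_prob * 1000), 0), 1000)
    lines <- sprintf("%s\t%d\t%d\tregion_%d\t%d\t.", scan$chrom,
                     as.integer(scan$start), as.integer(scan$end),
                     seq_len(nrow(scan)), as.integer(score))
  } else {
    keep <- !is.na(scan$prob) & scan$sweep
    lines <- sprintf("%s\t%d\t%d\twin_%d\t%d\t.", scan$chrom[keep],
                     as.integer(scan$start[keep]),
                     as.integer(scan$end[keep]), which(keep),
                     as.integer(round(scan$prob[keep] * 1000)))
  }
  writeLines(lines, bed)
  utils::write.table(as.data.frame(scan), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(package = "sweepnet",
                              version = as.character(utils::packageVersion("sweepnet")),
                              date = as.character(Sys.Date())), manifest),
                       man, auto_unbox = TRUE)
  invisible(c(bed, tsv, man))
}
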