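#' Frequency-binned standardization against neutral simulations
#'
#' Every per-SNP statistic is standardized as
#' `(value - E_p[statistic]) / SD_p[statistic]`, where the mean and SD are
#' estimated from neutral simulations within the 2% derived-allele-frequency
#' bin `p` containing the focal variant (50 bins covering (0, 1]). This makes
#' values comparable across focal allele frequencies. `build_norms()` fits the
#' per-bin moments from a table of neutral values; bins with fewer than
#' `min_per_bin` values are pooled with their nearest neighbor bins until the
#' minimum is met (the SD of tiny samples is unstable).
#'
#' Three binning modes are supported through the optional columns of
#' `values`:
#' * `daf` present: 50 derived-allele-frequency bins, optionally further keyed
#'   by window `size` (the feature pipeline fits separate norms per nested
#'   window size);
#' * `size` present, `daf` absent: one bin per window size (used for the
#'   per-window iSAFE summary);
#' * neither: a single locus-level bin (used for HAF and H12, which take one
#'   value per locus).
#'
#' @param values a data frame with columns `statistic` (character), `value`
#'   (numeric) and optionally `daf`, `size`.
#' @param min_per_bin minimum number of values per bin before pooling.
#' @param provenance free-form description of the neutral dataset the norms
#'   were fitted on; carried along and checked by the classifier manifest.
#' @return a `binned_norms` object: a tibble with columns `statistic`,
#'   `size`, `bin_low`, `bin_high`, `mean`, `sd`, `n`.
#' @export
build_norms <- function(values, min_per_bin = 20, provenance = "unspecified") {
  stopifnot(is.data.frame(values),
            all(c("statistic", "value") %in% names(values)))
  values <- values[is.finite(values$value), , drop = FALSE]
  if (!nrow(values)) stop("no finite values to fit norms on", call. = FALSE)
  if (!"daf" %in% names(values)) values$daf <- NA_real_
  if (!"size" %in% names(values)) values$size <- NA_real_

  key <- paste(values$statistic,
               ifelse(is.na(values$size), "NA", as.character(values$size)),
               sep = "\r")
  groups <- split(values, key, drop = TRUE)
  rows <- lapply(groups, function(g) {
    stat <- g$statistic[1L]
    size <- g$size[1L]
    if (all(is.na(g$daf))) {
      if (nrow(g) < 2L || stats::sd(g$value) == 0)
        stop("zero variance fitting norms for statistic '", stat,
             "' (pooled bin)", call. = FALSE)
      tibble::tibble(statistic = stat, size = size, bin_low = NA_real_,
                     bin_high = NA_real_, mean = mean(g$value),
                     sd = stats::sd(g$value), n = nrow(g))
    } else {
      .fit_daf_bins(g$value, g$daf, stat, size, min_per_bin)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("binned_norms", class(out)),
            provenance = provenance, version = 1L)
}

# Fit the 50 2%-bin moments with nearest-neighbor pooling. Bins are pooled
# while they are sparse (< min_per_bin) or degenerate (zero variance, e.g.
# windows where a statistic is identically 0 for every focal variant of that
# frequency); only a statistic that is constant across all bins errors.
.fit_daf_bins <- function(value, daf, stat, size, min_per_bin) {
  ok <- !is.na(daf)
  value <- value[ok]; daf <- daf[ok]
  if (any(daf <= 0 | daf > 1))
    stop("derived allele frequencies must lie in (0, 1]", call. = FALSE)
  bin <- daf_bin(daf)
  counts <- tabulate(bin, nbins = 50L)
  sums <- vapply(1:50, function(b) sum(value[bin == b]), 0)
  sums2 <- vapply(1:50, function(b) sum(value[bin == b]^2), 0)
  .fit_daf_bins_moments(counts, sums, sums2, stat, size, min_per_bin)
}

# moments variant used by the streaming norms fitter
.fit_daf_bins_moments <- function(counts, sums, sums2, stat, size,
                                  min_per_bin) {
  lo <- 1:50; hi <- 1:50
  keep <- rep(TRUE, 50L)
  merged_sd <- function(b) {
    n <- counts[b]
    if (n < 2L) return(0)
    v <- (sums2[b] - sums[b]^2 / n) / (n - 1L)
    sqrt(max(v, 0))
  }
  repeat {
    act <- which(keep)
    if (length(act) <= 1L) break
    bad <- act[counts[act] < min_per_bin |
                 vapply(act, merged_sd, 0) <= 1e-12]
    if (!length(bad)) break
    b <- bad[1L]
    pos <- match(b, act)
    nb <- if (pos == 1L) act[2L]
          else if (pos == length(act)) act[pos - 1L]
          else if (counts[act[pos - 1L]] <= counts[act[pos + 1L]])
            act[pos - 1L]
          else act[pos + 1L]
    tgt <- min(b, nb); src <- max(b, nb)
    counts[tgt] <- counts[tgt] + counts[src]
    sums[tgt] <- sums[tgt] + sums[src]
    sums2[tgt] <- sums2[tgt] + sums2[src]
    hi[tgt] <- hi[src]
    keep[src] <- FALSE
  }
  act <- which(keep)
  edges <- seq(0, 1, by = 0.02)
  out <- lapply(act, function(b) {
    if (counts[b] < 2L || merged_sd(b) <= 1e-12)
      stop("zero variance fitting norms for statistic '", stat,
           "' in DAF bin (", edges[lo[b]], ", ", edges[hi[b] + 1L], "]",
           call. = FALSE)
    tibble::tibble(statistic = stat, size = size,
                   bin_low = edges[lo[b]], bin_high = edges[hi[b] + 1L],
                   mean = sums[b] / counts[b], sd = merged_sd(b),
                   n = counts[b])
  })
  do.call(rbind, out)
}

#' 2% derived-allele-frequency bin index
#'
#' Bins are half-open `(low, high]`: bin 1 is `(0, 0.02]`, bin 50 is
#' `(0.98, 1]`.
#'
#' @param daf derived allele frequencies in `(0, 1]`.
#' @return integer bin indices in `1:50`.
#' @export
daf_bin <- function(daf) {
  if (any(daf <= 0 | daf > 1))
    stop("derived allele frequencies must lie in (0, 1]", call. = FALSE)
  pmin(pmax(ceiling(daf / 0.02), 1L), 50L)
}

#' Standardize a statistic value against fitted norms
#'
#' Returns `(value - mean) / sd` using the bin of `norms` containing `daf`
#' (and matching `size` when the norms are size-keyed). `NA` values (the
#' not-computable marker) pass through as `NA`.
#'
#' @param value numeric vector of unstandardized values.
#' @param daf focal derived allele frequencies (in `(0, 1]`), or `NA` for
#'   locus/window-level statistics.
#' @param statistic statistic name present in `norms`.
#' @param norms a [build_norms()] object.
#' @param size window size key, or `NA` for unkeyed norms.
#' @return standardized values, same length as `value`.
#' @export
standardize <- function(value, daf, statistic, norms, size = NA_real_) {
  stopifnot(inherits(norms, "binned_norms"))
  rows <- norms[norms$statistic == statistic, , drop = FALSE]
  if (!nrow(rows))
    stop("no norms fitted for statistic '", statistic, "'", call. = FALSE)
  sized <- rows[if (is.na(size)) is.na(rows$size)
                else !is.na(rows$size) & rows$size == size, , drop = FALSE]
  if (!nrow(sized)) sized <- rows[is.na(rows$size), , drop = FALSE]
  if (!nrow(sized))
    stop("no norms for statistic '", statistic, "' at window size ", size,
         call. = FALSE)
  daf <- rep_len(as.numeric(daf), length(value))
  out <- rep(NA_real_, length(value))
  if (all(is.na(sized$bin_low))) {
    out <- (value - sized$mean[1L]) / sized$sd[1L]
  } else {
    if (any(!is.na(daf) & (daf <= 0 | daf > 1)))
      stop("derived allele frequencies must lie in (0, 1]", call. = FALSE)
    idx <- findInterval(daf, sized$bin_high, left.open = TRUE) + 1L
    idx <- pmin(pmax(idx, 1L), nrow(sized))
    ok <- !is.na(daf)
    out[ok] <- (value[ok] - sized$mean[idx[ok]]) / sized$sd[idx[ok]]
  }
  out[is.na(value)] <- NA_real_
  out
}

#' Persist / load norms as a versioned TSV
#'
#' The file carries a `# sweepnet_norms v1` header line and the provenance
#' string, then the tabular moments; serialization is deterministic.
#'
#' @param norms a [build_norms()] object.
#' @param path file path.
#' @return `write_norms` returns `path` invisibly; `read_norms` a
#'   `binned_norms`.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "binned_norms"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sweepnet_norms v", attr(norms, "version")),
               paste0("# provenance: ", attr(norms, "provenance"))), con)
  utils::write.table(as.data.frame(norms), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# sweepnet_norms v1", lines[1L]))
    stop("not a sweepnet norms file: ", path, call. = FALSE)
  provenance <- sub("^# provenance: ", "", lines[2L])
  tab <- utils::read.table(text = lines[-(1:2)], header = TRUE, sep = "\t")
  tab$size <- as.numeric(tab$size)
  tab$bin_low <- as.numeric(tab$bin_low)
  tab$bin_high <- as.numeric(tab$bin_high)
  structure(tibble::as_tibble(tab), class = c("binned_norms",
                                              class(tibble::tibble())),
            provenance = provenance, version = 1L)
}
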