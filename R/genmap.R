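#' Piecewise-linear genetic map
#'
#' Maps physical position (bp) to genetic position (cM) by linear
#' interpolation between anchor points; positions outside the anchors are
#' extrapolated with the terminal rates. With no anchors a uniform rate is
#' used. iHS integrates extended haplotype homozygosity over genetic distance
#' when a map is supplied, physical distance otherwise.
#'
#' @param pos_bp numeric vector of anchor physical positions (bp).
#' @param cm numeric vector of genetic positions (cM), non-decreasing.
#' @param rate_cm_mb uniform rate in cM/Mb used when no anchors are given.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(pos_bp = numeric(0), cm = numeric(0),
                        rate_cm_mb = 1) {
  stopifnot(length(pos_bp) == length(cm))
  if (length(cm) > 1L) {
    o <- order(pos_bp)
    pos_bp <- pos_bp[o]; cm <- cm[o]
    if (any(diff(cm) < 0))
      stop("genetic position must be non-decreasing in physical position",
           call. = FALSE)
  }
  structure(list(pos_bp = pos_bp, cm = cm, rate_cm_mb = rate_cm_mb),
            class = "genetic_map")
}

#' Read a genetic map from a two-column TSV
#'
#' Accepts either cumulative positions (`pos_bp`, `cM`) or a rate dialect
#' (`pos_bp`, `cM/Mb`), selected by `dialect`. Rate maps are converted to
#' cumulative cM assuming the rate applies from each anchor to the next.
#'
#' @param path TSV path with two numeric columns (header optional).
#' @param dialect `"cM"` (cumulative) or `"cM/Mb"` (per-interval rate).
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, dialect = c("cM", "cM/Mb")) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9.eE+-]+\\s", first)
  tab <- utils::read.table(path, header = has_header, sep = "\t")
  pos <- as.numeric(tab[[1L]])
  v <- as.numeric(tab[[2L]])
  if (dialect == "cM") return(genetic_map(pos, v))
  # rate dialect: integrate rate over intervals
  o <- order(pos)
  pos <- pos[o]; v <- v[o]
  cm <- c(0, cumsum(diff(pos) / 1e6 * v[-length(v)]))
  genetic_map(pos, cm)
}

#' Interpolate genetic position (cM) at physical positions
#' @param map a [genetic_map()].
#' @param pos_bp physical positions in bp.
#' @return genetic positions in cM.
#' @export
genetic_pos <- function(map, pos_bp) {
  if (length(map$pos_bp) < 2L) return(pos_bp / 1e6 * map$rate_cm_mb)
  stats::approx(map$pos_bp, map$cm, xout = pos_bp, rule = 2L)$y +
    # extend with terminal rates beyond the anchors rather than clamping
    .map_overhang(map, pos_bp)
}

.map_overhang <- function(map, pos_bp) {
  n <- length(map$pos_bp)
  lo_rate <- (map$cm[2L] - map$cm[1L]) /
    max(map$pos_bp[2L] - map$pos_bp[1L], 1)
  hi_rate <- (map$cm[n] - map$cm[n - 1L]) /
    max(map$pos_bp[n] - map$pos_bp[n - 1L], 1)
  out <- numeric(length(pos_bp))
  below <- pos_bp < map$pos_bp[1L]
  above <- pos_bp > map$pos_bp[n]
  out[below] <- (pos_bp[below] - map$pos_bp[1L]) * lo_rate
  out[above] <- (pos_bp[above] - map$pos_bp[n]) * hi_rate
  out
}
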