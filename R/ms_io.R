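#' Read ms-style simulator output
#'
#' Parses the classic Hudson `ms` text format (also emitted by msms, discoal,
#' and convertible from most simulators): replicates introduced by `//`, a
#' `segsites:` line, a `positions:` line with coordinates on `[0, 1)`, then
#' one 0/1 row per haplotype. Positions are rescaled to physical bp by
#' `locus_length` and rounded to the nearest bp; duplicates arising from the
#' rounding are jittered forward by +1 bp to keep positions strictly
#' increasing (downstream statistics need unique positions).
#'
#' @param con a file path or character vector of lines.
#' @param locus_length physical length in bp used to rescale the unit-interval
#'   positions.
#' @return a list of [haplotype_matrix()] objects, one per replicate.
#' @seealso [write_ms()]
#' @export
read_ms <- function(con, locus_length) {
  lines <- if (length(con) == 1L && file.exists(con)) readLines(con) else con
  starts <- which(startsWith(trimws(lines), "//"))
  if (!length(starts))
    stop("no ms replicate marker ('//') found in input", call. = FALSE)
  # sample size from the command-line echo header (ms/msms/discoal all put
  # nsam in the second field); used for zero-segsite replicates
  nsam <- NA_integer_
  if (starts[1L] > 1L) {
    head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    if (length(head_tok) >= 2L)
      nsam <- suppressWarnings(as.integer(head_tok[2L]))
  }
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(r) {
    .parse_ms_block(lines, bounds[r], bounds[r + 1L] - 1L, locus_length, nsam)
  })
}

.parse_ms_block <- function(lines, from, to, locus_length, nsam = NA_integer_) {
  block <- lines[from:to]
  seg_i <- grep("^segsites:", trimws(block))
  if (!length(seg_i))
    stop("malformed ms block starting at line ", from,
         ": missing 'segsites:' line", call. = FALSE)
  seg_i <- seg_i[1L]
  segsites <- suppressWarnings(
    as.integer(sub("^segsites:\\s*", "", trimws(block[seg_i]))))
  if (is.na(segsites))
    stop("malformed ms block at line ", from + seg_i - 1L,
         ": unparseable segsites", call. = FALSE)

  if (segsites == 0L) {
    # haplotype rows are absent for empty replicates; sample size comes from
    # the command-line echo header when available
    hap_rows <- grep("^[01]+$", trimws(block))
    n_hap <- if (length(hap_rows)) length(hap_rows)
             else if (!is.na(nsam)) nsam else 2L
    return(haplotype_matrix(matrix(integer(0), n_hap, 0), numeric(0),
                            locus_length))
  }

  pos_i <- grep("^positions:", trimws(block))
  if (!length(pos_i))
    stop("malformed ms block starting at line ", from,
         ": missing 'positions:' line", call. = FALSE)
  pos_i <- pos_i[1L]
  rel <- as.numeric(strsplit(trimws(sub("^positions:\\s*",
                                        "", trimws(block[pos_i]))),
                             "\\s+")[[1L]])
  if (length(rel) != segsites)
    stop("ms block at line ", from, ": ", length(rel),
         " positions but segsites: ", segsites, call. = FALSE)

  hap_lines <- trimws(block[-seq_len(pos_i)])
  hap_lines <- hap_lines[grepl("^[01]+$", hap_lines)]
  if (!length(hap_lines))
    stop("ms block at line ", from, ": no haplotype rows", call. = FALSE)
  widths <- nchar(hap_lines)
  if (any(widths != segsites))
    stop("ms block at line ", from, ": haplotype row width ",
         widths[widths != segsites][1L], " does not match segsites ",
         segsites, call. = FALSE)
  alleles <- matrix(as.integer(unlist(strsplit(hap_lines, ""),
                                      use.names = FALSE)),
                    nrow = length(hap_lines), byrow = TRUE)

  pos_bp <- round(rel * locus_length)
  pos_bp <- .dedupe_positions(pos_bp)
  pos_bp <- pmin(pos_bp, locus_length - 1)
  # a final clamp can re-collide at the right edge; re-jitter backwards
  while (anyDuplicated(pos_bp)) {
    d <- which(duplicated(pos_bp, fromLast = TRUE))
    pos_bp[d] <- pos_bp[d] - 1
  }
  haplotype_matrix(alleles, pos_bp, locus_length)
}

# push duplicates forward by +1 bp until strictly increasing
.dedupe_positions <- function(pos) {
  if (length(pos) > 1L) for (i in 2:length(pos)) {
    if (pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1
  }
  pos
}

#' Write haplotype matrices as ms-style text
#'
#' Inverse of [read_ms()]: emits one `//` block per matrix with positions
#' rescaled back to `[0, 1)`. `read_ms(write_ms(x), L)` is the identity on the
#' data model (exactly, because written positions are bp/locus_length and
#' rescaling is reversed before rounding has any effect).
#'
#' @param mats a `hapmat` or list of them.
#' @param path optional file to write; when `NULL` the lines are returned.
#' @param digits digits used for relative positions.
#' @return invisibly, the character vector of lines.
#' @export
write_ms <- function(mats, path = NULL, digits = 10) {
  if (inherits(mats, "hapmat")) mats <- list(mats)
  header <- c(paste("ms", n_haplotypes(mats[[1L]]), length(mats)), "", "")
  body <- unlist(lapply(mats, function(m) {
    rel <- m$positions / m$locus_length
    c("//",
      paste0("segsites: ", n_sites(m)),
      if (n_sites(m) > 0)
        paste0("positions: ",
               paste(formatC(rel, digits = digits, format = "f"),
                     collapse = " ")),
      if (n_sites(m) > 0)
        apply(m$alleles, 1L, paste, collapse = "")
      else
        rep(strrep("", 1L), 0L),
      "")
  }), use.names = FALSE)
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Flip site polarity at random (mispolarization injection)
#'
#' Models ancestral-state misassignment: each site's column is complemented
#' (0 becomes 1 and vice versa) independently with probability `rate`,
#' mimicking a derived/ancestral call made from a wrong outgroup base. Used
#' for robustness experiments at rates such as 0.1%, 1%, 5%, 10%.
#'
#' @param x a `hapmat`.
#' @param rate per-site flip probability in `[0, 1]`.
#' @param seed integer seed; the injection is deterministic given the seed.
#' @return a `hapmat` with flipped columns; the flipped site indices are kept
#'   in `attr(, "flipped")`.
#' @export
inject_mispolarization <- function(x, rate, seed) {
  stopifnot(inherits(x, "hapmat"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("`rate` must be a single number in [0, 1]", call. = FALSE)
  flip <- withr::with_seed(seed, stats::runif(n_sites(x)) < rate)
  alleles <- x$alleles
  if (any(flip)) alleles[, flip] <- 1L - alleles[, flip]
  out <- haplotype_matrix(alleles, x$positions, x$locus_length,
                          x$sample_labels)
  attr(out, "flipped") <- which(flip)
  out
}
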