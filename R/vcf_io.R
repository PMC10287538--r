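#' Read a phased, polarized haplotype matrix from a VCF region
#'
#' Loads biallelic SNPs from a phased VCF, polarizes alleles against an
#' ancestral-allele source, and returns a [haplotype_matrix()] in region-local
#' 0-based coordinates (VCF 1-based coordinates are converted at this
#' boundary only). The ancestral source is either the `AA` INFO tag
#' (`ancestral = "AA"`) or an ancestral FASTA whose sequence names match the
#' VCF chromosome names. Sites whose ancestral base matches the ALT allele
#' are flipped so 1 always means derived; sites whose ancestral base matches
#' neither REF nor ALT are dropped and counted, as are multiallelic sites and
#' sites with any missing genotype (the statistics assume complete binary
#' data, matching the simulation-trained models).
#'
#' @param vcf_path path to a VCF (plain or bgzipped; a tabix index is used for
#'   the region query when present, otherwise the file is read and subset).
#' @param region either a `GRanges` of length 1 or a string `"chr:start-end"`
#'   (1-based, inclusive).
#' @param ancestral `"AA"` to use the INFO/AA tag, or a path to an ancestral
#'   FASTA.
#' @return a `hapmat` whose positions are 0-based offsets from the region
#'   start; `locus_length` is the region width. Attributes `n_dropped`
#'   (named counts: `unmatched_ancestral`, `multiallelic`, `missing`) and
#'   `region` record what was filtered.
#' @export
read_vcf_region <- function(vcf_path, region, ancestral = "AA") {
  gr <- if (is.character(region)) .parse_region(region) else region
  vcf <- .read_vcf(vcf_path, gr)

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)

  multi <- n_alt != 1L
  alt <- rep(NA_character_, length(ref))
  alt[!multi] <- as.character(unlist(altl[!multi]))
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes found; the method requires phased haplotypes",
         call. = FALSE)
  missing_gt <- apply(gt, 1L, function(r) any(grepl("\\.", r)))

  anc <- .ancestral_alleles(vcf, rr, ancestral)
  anc <- toupper(anc)
  polarizable <- !is.na(anc) & (anc == ref | anc == alt)

  keep <- snp & !multi & !missing_gt & polarizable
  dropped <- c(
    unmatched_ancestral = sum(snp & !multi & !missing_gt & !polarizable),
    multiallelic = sum(multi | (!multi & !snp)),
    missing = sum(!multi & snp & missing_gt)
  )

  pos1 <- GenomicRanges::start(rr)[keep]
  gt <- gt[keep, , drop = FALSE]
  flip <- anc[keep] == alt[keep]

  # expand "a|b" into haplotype rows (sample-major, hap1 then hap2 per sample)
  alle <- .expand_phased_gt(gt)
  if (any(flip)) alle[, flip] <- 1L - alle[, flip]

  start0 <- GenomicRanges::start(gr) - 1L
  width <- GenomicRanges::width(gr)
  ord <- order(pos1)
  labels <- if (!is.null(colnames(gt)))
    paste0(rep(colnames(gt), each = 2L), c("_1", "_2"))
  out <- haplotype_matrix(alle[, ord, drop = FALSE],
                          .dedupe_positions(pos1[ord] - 1L - start0),
                          width,
                          sample_labels = labels)
  attr(out, "n_dropped") <- dropped
  attr(out, "region") <- sprintf("%s:%d-%d",
                                 as.character(GenomicRanges::seqnames(gr)),
                                 GenomicRanges::start(gr),
                                 GenomicRanges::end(gr))
  out
}

.parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("cannot parse region '", region, "'; expected chr:start-end",
         call. = FALSE)
  GenomicRanges::GRanges(m[2L],
                         IRanges::IRanges(as.integer(m[3L]),
                                          as.integer(m[4L])))
}

.read_vcf <- function(vcf_path, gr) {
  genome <- "unknown"
  indexed <- file.exists(paste0(vcf_path, ".tbi")) ||
    file.exists(paste0(vcf_path, ".csi"))
  if (indexed) {
    p <- VariantAnnotation::ScanVcfParam(which = gr)
    VariantAnnotation::readVcf(vcf_path, genome = genome, param = p)
  } else {
    vcf <- VariantAnnotation::readVcf(vcf_path, genome = genome)
    hit <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(vcf), gr,
                                ignore.strand = TRUE)
    vcf[hit, ]
  }
}

.ancestral_alleles <- function(vcf, rr, ancestral) {
  if (identical(ancestral, "AA")) {
    aa <- VariantAnnotation::info(vcf)$AA
    if (is.null(aa))
      stop("ancestral source 'AA' requested but the VCF has no INFO/AA tag",
           call. = FALSE)
    aa <- as.character(aa)
    substr(aa, 1L, 1L)
  } else if (is.character(ancestral) && file.exists(ancestral)) {
    fa <- Biostrings::readDNAStringSet(ancestral)
    names(fa) <- sub("\\s.*$", "", names(fa))
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    vapply(seq_along(pos), function(i) {
      sq <- fa[[chrom[i]]]
      if (is.null(sq) || pos[i] > length(sq)) return(NA_character_)
      as.character(Biostrings::subseq(sq, pos[i], pos[i]))
    }, character(1))
  } else {
    stop("missing ancestral source: pass \"AA\" or an existing FASTA path",
         call. = FALSE)
  }
}

.expand_phased_gt <- function(gt) {
  if (nrow(gt) == 0L)
    return(matrix(integer(0), nrow = 2L * ncol(gt), ncol = 0L))
  per_site <- lapply(seq_len(nrow(gt)), function(i) {
    as.integer(unlist(strsplit(gt[i, ], "|", fixed = TRUE),
                      use.names = FALSE))
  })
  do.call(cbind, per_site)
}

#' Write a haplotype matrix as a minimal phased VCF (fixture plumbing)
#'
#' Emits a small plain-text VCFv4.2 with biallelic A/G SNPs, phased diploid
#' genotypes (consecutive haplotype pairs become samples), and the ancestral
#' allele in the INFO/AA tag, so that matrices simulated in this package can
#' be round-tripped through [read_vcf_region()]. Requires an even number of
#' haplotypes.
#'
#' @param x a `hapmat`.
#' @param path output file path.
#' @param chrom chromosome name to write.
#' @param offset 1-based position of the locus start on `chrom`.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(x, path, chrom = "1", offset = 1L) {
  stopifnot(inherits(x, "hapmat"))
  n <- n_haplotypes(x)
  if (n %% 2L != 0L)
    stop("need an even number of haplotypes to form diploid samples",
         call. = FALSE)
  samples <- paste0("S", seq_len(n %/% 2L))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##contig=<ID=%s>", chrom),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(n_sites(x)), function(j) {
    col <- x$alleles[, j]
    gts <- paste(col[seq(1L, n, 2L)], col[seq(2L, n, 2L)], sep = "|")
    paste(c(chrom, format(x$positions[j] + offset, scientific = FALSE),
            ".", "A", "G", ".", "PASS", "AA=A", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
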