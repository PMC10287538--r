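test_that("haplotype_matrix enforces its invariants", {
  al <- matrix(c(0, 1, 1, 0), 2, 2)
  m <- haplotype_matrix(al, c(10, 20), 100)
  expect_s3_class(m, "hapmat")
  expect_equal(n_haplotypes(m), 2)
  expect_equal(n_sites(m), 2)
  expect_error(haplotype_matrix(al, c(20, 10), 100), "increasing")
  expect_error(haplotype_matrix(al, c(10, 100), 100), "locus_length")
  expect_error(haplotype_matrix(matrix(2, 2, 1), 5, 100), "0 .ancestral")
  expect_error(haplotype_matrix(al[1, , drop = FALSE], c(1, 2), 100),
               "at least 2")
  expect_error(haplotype_matrix(al, c(10), 100), "does not match")
})

test_that("read_ms rescales positions and preserves structure", {
  txt <- c("ms 4 1", "123 456", "", "//", "segsites: 2",
           "positions: 0.25 0.75", "01", "10", "11", "00")
  m <- read_ms(txt, 1000)[[1]]
  expect_equal(m$positions, c(250, 750))
  expect_equal(dim(m$alleles), c(4, 2))
  expect_equal(m$alleles[2, ], c(1, 0))
})

test_that("read_ms handles zero-segsite replicates via the header", {
  txt <- c("ms 5 1", "1 2 3", "", "//", "segsites: 0", "")
  m <- read_ms(txt, 1000)[[1]]
  expect_equal(n_sites(m), 0)
  expect_equal(n_haplotypes(m), 5)
})

test_that("read_ms reports malformed blocks", {
  expect_error(read_ms(c("ms 2 1", "", "//", "positions: 0.5", "0", "1"),
                       100), "segsites")
  expect_error(read_ms(c("ms 2 1", "", "//", "segsites: 2",
                         "positions: 0.1 0.5", "011", "100"), 100),
               "width")
  expect_error(read_ms(c("no marker here"), 100), "//")
})

test_that("ms round trip is the identity on the data model", {
  mats <- lapply(1:3, function(i) random_hapmat(6, 10, 5000, seed = 100 + i))
  back <- read_ms(write_ms(mats), 5000)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$alleles, mats[[i]]$alleles)
    expect_equal(back[[i]]$positions, mats[[i]]$positions)
    expect_equal(back[[i]]$locus_length, mats[[i]]$locus_length)
  }
})

test_that("duplicate ms positions are jittered to stay strictly increasing", {
  txt <- c("ms 2 1", "", "//", "segsites: 3",
           "positions: 0.10001 0.10002 0.5", "010", "101")
  m <- read_ms(txt, 1000)[[1]]  # both round to 100
  expect_equal(m$positions, c(100, 101, 500))
})

test_that("mispolarization injection flips whole columns at the given rate", {
  m <- random_hapmat(8, 30, 5000, seed = 5)
  expect_identical(inject_mispolarization(m, 0, seed = 1)$alleles, m$alleles)
  expect_equal(inject_mispolarization(m, 1, seed = 1)$alleles,
               1L - m$alleles)
  expect_error(inject_mispolarization(m, 1.5, seed = 1), "rate")

  big <- haplotype_matrix(matrix(0:1, 2, 10000), seq(0, 9999), 10000)
  flipped <- length(attr(inject_mispolarization(big, 0.1, seed = 9),
                         "flipped"))
  # binomial(10000, 0.1) 99% interval
  expect_gt(flipped, qbinom(0.005, 10000, 0.1))
  expect_lt(flipped, qbinom(0.995, 10000, 0.1))

  # determinism and haplotype preservation
  a <- inject_mispolarization(m, 0.3, seed = 4)
  b <- inject_mispolarization(m, 0.3, seed = 4)
  expect_identical(a$alleles, b$alleles)
  expect_equal(n_haplotypes(a), n_haplotypes(m))
})

test_that("two independent mispolarization rounds compose like 2r(1-r)", {
  big <- haplotype_matrix(matrix(0:1, 2, 20000), seq(0, 19999), 20000)
  r <- 0.2
  once <- inject_mispolarization(big, r, seed = 11)
  twice <- inject_mispolarization(once, r, seed = 22)
  net <- mean(twice$alleles[1, ] != big$alleles[1, ])
  expect_lt(abs(net - 2 * r * (1 - r)), 0.02)
})

test_that("VCF round trip polarizes against the AA tag", {
  m <- random_hapmat(8, 25, 10000, seed = 42)
  vcf <- file.path(tempdir(), "rt.vcf")
  write_vcf(m, vcf, chrom = "7", offset = 1)
  back <- read_vcf_region(vcf, "7:1-10000", ancestral = "AA")
  expect_equal(back$alleles, m$alleles, ignore_attr = TRUE)
  expect_equal(back$positions, m$positions)
})

test_that("VCF sites are flipped, dropped, or errored per the contract", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\t.\tA\tG\t.\tPASS\tAA=G\tGT\t0|1\t1|1",  # flip: AA = ALT
    "1\t200\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t0|0",  # identity
    "1\t300\t.\tA\tG\t.\tPASS\tAA=T\tGT\t0|1\t0|0",  # unmatched ancestral
    "1\t400\t.\tA\tG,C\t.\tPASS\tAA=A\tGT\t0|1\t0|2", # multiallelic
    "1\t500\t.\tA\tG\t.\tPASS\tAA=A\tGT\t.|1\t0|0")  # missing genotype
  vcf <- file.path(tempdir(), "polar.vcf")
  writeLines(lines, vcf)
  m <- read_vcf_region(vcf, "1:1-1000", ancestral = "AA")
  expect_equal(n_sites(m), 2)
  # AA=G flips GT 0|1,1|1 into derived = former REF
  expect_equal(m$alleles[, 1], c(1L, 0L, 0L, 0L))
  expect_equal(m$alleles[, 2], c(0L, 1L, 0L, 0L))
  drops <- attr(m, "n_dropped")
  expect_equal(unname(drops["unmatched_ancestral"]), 1)
  expect_equal(unname(drops["multiallelic"]), 1)
  expect_equal(unname(drops["missing"]), 1)

  unph <- sub("0\\|1\tGT", "0|1\tGT", lines)
  unph[6] <- "1\t100\t.\tA\tG\t.\tPASS\tAA=G\tGT\t0/1\t1|1"
  vcf2 <- file.path(tempdir(), "unphased.vcf")
  writeLines(unph, vcf2)
  expect_error(read_vcf_region(vcf2, "1:1-1000", "AA"), "phased")
})

test_that("ancestral FASTA polarization matches the AA tag path", {
  m <- random_hapmat(6, 10, 500, seed = 3)
  vcf <- file.path(tempdir(), "fa.vcf")
  write_vcf(m, vcf, chrom = "chrZ", offset = 1)
  fa <- file.path(tempdir(), "anc.fa")
  seq <- rep("A", 500)  # write_vcf uses REF=A, AA=A
  writeLines(c(">chrZ", paste(seq, collapse = "")), fa)
  via_fa <- read_vcf_region(vcf, "chrZ:1-500", ancestral = fa)
  via_aa <- read_vcf_region(vcf, "chrZ:1-500", ancestral = "AA")
  expect_equal(via_fa$alleles, via_aa$alleles)
  expect_error(read_vcf_region(vcf, "chrZ:1-500",
                               ancestral = "/nonexistent/anc.fa"),
               "ancestral")
})

test_that("genetic maps interpolate and read both dialects", {
  gm <- genetic_map(c(0, 1e6), c(0, 2))
  expect_equal(genetic_pos(gm, 5e5), 1)
  expect_error(genetic_map(c(0, 1e6), c(2, 0)), "non-decreasing")

  tsv <- file.path(tempdir(), "map.tsv")
  writeLines(c("pos\tcM", "0\t0", "1000000\t2"), tsv)
  expect_equal(genetic_pos(read_genetic_map(tsv, "cM"), 250000), 0.5)

  tsv2 <- file.path(tempdir(), "map2.tsv")
  writeLines(c("0\t2", "1000000\t2"), tsv2)  # 2 cM/Mb uniform
  gm2 <- read_genetic_map(tsv2, "cM/Mb")
  expect_equal(genetic_pos(gm2, 1e6), 2)
})
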