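# The hapDAF-o construction forced by the definitions: 10 haplotypes, focal
# at 0.5, one flanking variant on 4/5 derived and 1/5 ancestral backgrounds.
micro_hapdaf <- function() {
  al <- cbind(rep(c(1, 0), each = 5),
              c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0))
  haplotype_matrix(al, c(400, 600), 1000)
}

test_that("hapDAF micro-examples match the analytic values", {
  m <- micro_hapdaf()
  ctx <- focal_context(m, 1)
  expect_equal(hapdaf_o(m, ctx), (0.8^2 - 0.2^2) / 1)  # 0.60
  # hapDAF-s: f_ai = 0.2 >= 0.1 fails the ancestral-frequency criterion
  expect_equal(hapdaf_s(m, ctx), 0)
})

test_that("focal sites outside [0.25, 0.95] are not computable (NA, not 0)", {
  al <- cbind(c(1, rep(0, 9)), c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0))
  m <- haplotype_matrix(al, c(400, 600), 1000)
  ctx <- focal_context(m, 1)  # DAF 0.1
  expect_false(ctx$computable)
  expect_true(is.na(hapdaf_o(m, ctx)))
  expect_true(is.na(sratio(m, ctx)))
  expect_true(is.na(lowfreq(m, ctx)))
  expect_true(is.na(highfreq(m, ctx)))
})

test_that("lowfreq/highfreq frequency cutoffs are strict and analytic", {
  # one flanking derived allele on exactly 1 of 5 derived backgrounds
  al <- cbind(rep(c(1, 0), each = 5), c(1, rep(0, 9)))
  m <- haplotype_matrix(al, c(400, 600), 1000)
  expect_equal(lowfreq(m, focal_context(m, 1)), (1 - 0.2)^2)  # 0.64
  # on 2 of 5: f_dd = 0.4 is excluded by the strict < 0.25
  al2 <- cbind(rep(c(1, 0), each = 5), c(1, 1, rep(0, 8)))
  m2 <- haplotype_matrix(al2, c(400, 600), 1000)
  expect_equal(lowfreq(m2, focal_context(m2, 1)), 0)
  expect_equal(highfreq(m2, focal_context(m2, 1)), 0.4^2)
  # fixed on the derived background
  al3 <- cbind(rep(c(1, 0), each = 5), c(rep(1, 5), rep(0, 5)))
  m3 <- haplotype_matrix(al3, c(400, 600), 1000)
  expect_equal(highfreq(m3, focal_context(m3, 1)), 1)
  al4 <- cbind(rep(c(1, 0), each = 5), c(1, 1, 1, 1, 0, rep(0, 5)))
  m4 <- haplotype_matrix(al4, c(400, 600), 1000)
  expect_equal(highfreq(m4, focal_context(m4, 1)), 0.8^2)
})

test_that("sratio matches hand counts and flags S_d = 0", {
  # derived rows 1:5; 2 sites segregating on derived, 4 on ancestral
  al <- cbind(rep(c(1, 0), each = 5),
              c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0),   # seg both
              c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0),   # seg both
              c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0),   # seg anc only
              c(1, 1, 1, 1, 1, 0, 1, 0, 0, 0))   # fixed der, seg anc
  m <- haplotype_matrix(al, c(400, 450, 500, 550, 600), 1000)
  expect_equal(sratio(m, focal_context(m, 1)), 4 / 2)
  # identical segregation on both sides -> 1
  alsym <- cbind(rep(c(1, 0), each = 5),
                 c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0))
  msym <- haplotype_matrix(alsym, c(400, 600), 1000)
  expect_equal(sratio(msym, focal_context(msym, 1)), 1)
  # no derived-background variation -> not computable
  alz <- cbind(rep(c(1, 0), each = 5), c(rep(0, 5), 1, 0, 0, 0, 0))
  mz <- haplotype_matrix(alz, c(400, 600), 1000)
  expect_true(is.na(sratio(mz, focal_context(mz, 1))))
})

test_that("background-contrast statistics are invariant to row order", {
  withr::with_seed(31, {
    for (i in 1:20) {
      m <- random_hapmat(10, 15, 2000)
      daf <- site_daf(m)
      focal <- which(daf >= 0.25 & daf <= 0.95)[1]
      if (is.na(focal)) next
      perm <- sample(n_haplotypes(m))
      mp <- haplotype_matrix(m$alleles[perm, ], m$positions, m$locus_length)
      for (fn in list(hapdaf_o, hapdaf_s, sratio, lowfreq, highfreq, dind)) {
        expect_equal(fn(m, focal_context(m, focal)),
                     fn(mp, focal_context(mp, focal)))
      }
    }
  })
})

test_that("hapDAF lies in [0, 1] and freq statistics in their forced bands", {
  withr::with_seed(77, {
    for (i in 1:40) {
      m <- random_hapmat(12, 18, 2000)
      daf <- site_daf(m)
      for (focal in which(daf >= 0.25 & daf <= 0.95)) {
        ctx <- focal_context(m, focal)
        h <- hapdaf_o(m, ctx)
        expect_gte(h, 0); expect_lte(h, 1)
        lf <- lowfreq(m, ctx)
        if (!is.na(lf) && lf > 0) {
          expect_gt(lf, 0.5625); expect_lt(lf, 1)
        }
        hf <- highfreq(m, ctx)
        if (!is.na(hf) && hf > 0) {
          expect_gt(hf, 0.0625); expect_lte(hf, 1)
        }
        sr <- sratio(m, ctx)
        if (!is.na(sr)) expect_gte(sr, 0)
      }
    }
  })
})

test_that("DAF bins are 2% half-open intervals", {
  expect_equal(daf_bin(0.251), 13)  # (0.24, 0.26]
  expect_equal(daf_bin(0.02), 1)    # (0.00, 0.02]
  expect_equal(daf_bin(0.0201), 2)
  expect_equal(daf_bin(1), 50)
  expect_error(daf_bin(0), "\\(0, 1\\]")
  expect_error(daf_bin(1.01), "\\(0, 1\\]")
})

test_that("build_norms errors on zero variance and fits sane moments", {
  const <- data.frame(statistic = "s", value = rep(3, 5000),
                      daf = runif(5000, 0.01, 0.99))
  expect_error(build_norms(const), "zero variance")

  withr::with_seed(8, {
    daf <- runif(20000, 0.001, 1)
    vals <- data.frame(statistic = "s", value = rnorm(20000), daf = daf)
    nm <- build_norms(vals, min_per_bin = 20)
    expect_true(all(abs(nm$mean) < 0.2))
    expect_true(all(nm$sd > 0.8 & nm$sd < 1.2))
    expect_true(all(nm$n >= 20))
  })
})

test_that("sparse bins pool with neighbors until the minimum is met", {
  withr::with_seed(9, {
    # nearly all mass in (0.4, 0.6]; the tails must pool
    daf <- c(runif(5000, 0.4, 0.6), runif(30, 0.001, 0.4), runif(30, 0.6, 1))
    vals <- data.frame(statistic = "s", value = rnorm(5060), daf = daf)
    nm <- build_norms(vals, min_per_bin = 20)
    expect_true(all(nm$n >= 20))
    # bins tile (0, 1] without gaps
    expect_equal(nm$bin_low[1], 0)
    expect_equal(nm$bin_high[nrow(nm)], 1)
    expect_equal(nm$bin_low[-1], nm$bin_high[-nrow(nm)])
  })
})

test_that("standardize centers and scales by the containing bin", {
  vals <- data.frame(statistic = "s",
                     value = c(rnorm(500, 5, 2), rnorm(500, -1, 0.5)),
                     daf = c(runif(500, 0.05, 0.15), runif(500, 0.55, 0.65)))
  nm <- build_norms(vals, min_per_bin = 10)
  row <- nm[nm$bin_low <= 0.1 & nm$bin_high >= 0.1, ][1, ]
  expect_equal(standardize(row$mean, 0.095, "s", nm), 0)
  expect_equal(standardize(row$mean + row$sd, 0.095, "s", nm), 1)
  expect_error(standardize(1, 1.2, "s", nm), "\\(0, 1\\]")
  expect_error(standardize(1, 0.5, "unknown", nm), "no norms")
  expect_true(is.na(standardize(NA_real_, 0.5, "s", nm)))
})

test_that("standardizing the fitting set is self-consistent per bin", {
  withr::with_seed(13, {
    daf <- runif(30000, 0.001, 1)
    value <- rnorm(30000, mean = daf * 3, sd = 1 + daf)  # bin-dependent
    nm <- build_norms(data.frame(statistic = "s", value = value, daf = daf))
    z <- standardize(value, daf, "s", nm)
    bins <- daf_bin(daf)
    for (b in unique(bins)) {
      zb <- z[bins == b]
      if (length(zb) >= 200) {
        expect_lt(abs(mean(zb)), 0.15)
        expect_gt(sd(zb), 0.85); expect_lt(sd(zb), 1.15)
      }
    }
  })
})

test_that("norms serialize deterministically through the versioned TSV", {
  vals <- data.frame(statistic = rep(c("a", "b"), each = 3000),
                     value = rnorm(6000), daf = runif(6000, 0.01, 0.99))
  nm <- build_norms(vals, provenance = "unit-test")
  f <- file.path(tempdir(), "norms.tsv")
  write_norms(nm, f)
  back <- read_norms(f)
  expect_equal(as.data.frame(back), as.data.frame(nm), tolerance = 1e-12)
  expect_equal(attr(back, "provenance"), "unit-test")
  expect_identical(readLines(f)[1], "# sweepnet_norms v1")
})
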