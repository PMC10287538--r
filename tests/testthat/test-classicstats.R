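test_that("iHS is 0 under mirror symmetry and positive for a swept derived background", {
  # identical decay on both backgrounds: derived and ancestral blocks carry
  # mirrored flanking structure
  blk <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  al <- cbind(rep(c(1, 0), each = 4), rbind(blk, blk))
  m <- haplotype_matrix(al, c(400, 500, 600), 1000)
  expect_equal(as.numeric(ihs(m, focal_context(m, 1))), 0)

  # derived background all-identical, ancestral maximally diverse
  der <- matrix(0, 4, 4)
  anc <- rbind(c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  al2 <- cbind(rep(c(1, 0), each = 4), rbind(der, anc))
  m2 <- haplotype_matrix(al2, c(300, 400, 500, 600, 700), 1000)
  expect_gt(as.numeric(ihs(m2, focal_context(m2, 1))), 0)
})

test_that("nSL is 0 under symmetry and maximal for identical derived pair", {
  blk <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  al <- cbind(rep(c(1, 0), each = 4), rbind(blk, blk))
  m <- haplotype_matrix(al, c(400, 500, 600), 1000)
  expect_equal(nsl(m, focal_context(m, 1)), 0)

  al2 <- cbind(c(1, 1, 0, 0, 0, 0),
               rbind(c(0, 0), c(0, 0),
                     c(0, 1), c(1, 0), c(1, 1), c(0, 0)))
  m2 <- haplotype_matrix(al2, c(400, 500, 600), 1000)
  expect_gt(nsl(m2, focal_context(m2, 1)), 0)
})

test_that("DIND is the ancestral/derived diversity ratio", {
  # pi equal on both backgrounds -> 1
  blk <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  al <- cbind(rep(c(1, 0), each = 4), rbind(blk, blk))
  m <- haplotype_matrix(al, c(400, 500, 600), 1000)
  expect_equal(dind(m, focal_context(m, 1)), 1)

  # identical derived haplotypes -> pi_d = 0 -> not computable
  al2 <- cbind(rep(c(1, 0), each = 4), rbind(matrix(0, 4, 2), blk))
  m2 <- haplotype_matrix(al2, c(400, 500, 600), 1000)
  expect_true(is.na(dind(m2, focal_context(m2, 1))))
})

test_that("SAFE branch is taken under 300 SNPs and iSAFE at and above", {
  m299 <- random_hapmat(10, 320, 100000, seed = 61)
  m299$alleles <- m299$alleles[, 1:299]
  m299$positions <- m299$positions[1:299]
  sc <- safe_or_isafe(m299)
  expect_equal(attr(sc, "method"), "SAFE")
  m300 <- random_hapmat(10, 330, 100000, seed = 62)
  m300$alleles <- m300$alleles[, 1:300]
  m300$positions <- m300$positions[1:300]
  expect_equal(attr(safe_or_isafe(m300), "method"), "iSAFE")
  expect_error(safe_or_isafe(window_slice(m300, 0, 1)), "at least 2")
})

test_that("SAFE scores equal the independent kappa/phi oracle", {
  withr::with_seed(63, {
    for (i in 1:20) {
      m <- random_hapmat(10, 15, 3000)
      expect_equal(safe_or_isafe(m)$score, oracle_safe(m), tolerance = 1e-12)
    }
  })
})

test_that("HAF top-10% summary matches the definition", {
  # all haplotypes identical with d derived alleles -> every HAF = d * n
  n <- 10; d <- 4
  al <- rbind(matrix(1, n - 1, d), matrix(1, 1, d))
  al <- cbind(al, c(rep(0, n - 1), 1))  # one extra site to stay segregating
  m <- haplotype_matrix(al, c(10, 20, 30, 40, 50), 100)
  # HAF of the first 9 haplotypes: d sites at count 10 each + 0*1
  expect_equal(haf_top(m), d * n + 1 * 1)  # top hap also carries the singleton
  expect_equal(ceiling(0.1 * 10), 1)       # top-set size forced by ceil
  expect_equal(haf_top(window_slice(m, 90, 100)), 0)
  withr::with_seed(64, {
    for (i in 1:20) {
      r <- random_hapmat(10, 12, 2000)
      expect_equal(haf_top(r), oracle_haf_top(r))
    }
  })
})

test_that("H12 at 80% identity matches its closed forms", {
  # all identical
  m <- haplotype_matrix(matrix(rep(c(1, 0, 1), 4), 4, 3, byrow = TRUE),
                        c(1, 2, 3), 10)
  expect_equal(h12_80(m), 1)
  # two equal clusters, mutually < 80% identical
  a <- c(1, 1, 1, 1, 1); b <- c(0, 0, 0, 0, 0)
  m2 <- haplotype_matrix(rbind(a, a, b, b), c(1, 2, 3, 4, 5), 10)
  expect_equal(h12_80(m2), 1)  # (0.5 + 0.5)^2
  # n mutually <80%-identical singletons
  al <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1),
              c(1, 0, 1, 0, 1, 0))
  m3 <- haplotype_matrix(al, 1:6, 10)
  n <- 4
  expect_equal(h12_80(m3), (2 / n)^2 + (n - 2) / n^2)
  expect_true(is.na(h12_80(window_slice(m3, 7, 9))))
})

test_that("H12 at 100% identity reduces to classic H12 on exact classes", {
  withr::with_seed(65, {
    for (i in 1:15) {
      m <- random_hapmat(12, 10, 1000)
      key <- apply(m$alleles, 1, paste, collapse = "")
      p <- sort(as.numeric(table(key)) / 12, decreasing = TRUE)
      classic <- (p[1] + ifelse(length(p) > 1, p[2], 0))^2 +
        ifelse(length(p) > 2, sum(p[-(1:2)]^2), 0)
      expect_equal(h12_80(m, identity = 1), classic)
    }
  })
})

test_that("classic statistics are invariant to haplotype row order", {
  withr::with_seed(66, {
    for (i in 1:10) {
      m <- random_hapmat(10, 12, 2000)
      perm <- sample(10)
      mp <- haplotype_matrix(m$alleles[perm, ], m$positions, m$locus_length)
      expect_equal(haf_top(m), haf_top(mp))
      expect_equal(h12_80(m), h12_80(mp))
      daf <- site_daf(m)
      focal <- which(daf >= 0.25 & daf <= 0.95)[1]
      if (!is.na(focal)) {
        expect_equal(as.numeric(ihs(m, focal_context(m, focal))),
                     as.numeric(ihs(mp, focal_context(mp, focal))))
        expect_equal(nsl(m, focal_context(m, focal)),
                     nsl(mp, focal_context(mp, focal)))
      }
    }
  })
})

test_that("iHS integrates over genetic distance when a map is supplied", {
  m <- random_hapmat(10, 20, 10000, seed = 67)
  daf <- site_daf(m)
  focal <- which(daf >= 0.25 & daf <= 0.95)[3]
  ctx <- focal_context(m, focal)
  flat <- genetic_map(rate_cm_mb = 1)
  v0 <- as.numeric(ihs(m, ctx, halfspan_bp = 5000))
  v1 <- as.numeric(ihs(m, ctx, halfspan_bp = 5000, map = flat))
  # uniform map rescales both integrals equally -> identical log-ratio
  expect_equal(v0, v1, tolerance = 1e-9)
  # a sharply nonuniform map changes the weighting for at least one focal
  # site (it can coincide for focal sites whose EHH truncates immediately)
  warp <- genetic_map(c(0, 5000, 10000), c(0, 0.001, 10))
  daf <- site_daf(m)
  focals <- which(daf >= 0.25 & daf <= 0.95)
  changed <- vapply(focals, function(f) {
    cx <- focal_context(m, f)
    a <- as.numeric(ihs(m, cx, halfspan_bp = 5000))
    b <- as.numeric(ihs(m, cx, halfspan_bp = 5000, map = warp))
    !is.na(a) && !is.na(b) && !isTRUE(all.equal(a, b))
  }, TRUE)
  expect_true(any(changed))
})
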