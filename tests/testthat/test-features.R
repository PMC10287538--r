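test_that("center points fit the largest window symmetrically", {
  g <- feature_geometry()  # reference 1.2-Mb geometry
  cp <- center_points(g)
  expect_length(cp, 21)
  expect_equal(cp, seq(500000, 700000, by = 10000))
  # 1-Mb locus cannot host 21 centers with a 1-Mb window
  expect_error(feature_geometry(locus_length = 1000000), "too short")
  # but a single feasible center works
  g1 <- feature_geometry(locus_length = 1000000, n_centers = 1L)
  expect_equal(center_points(g1), 500000)
})

test_that("the assembled tensor has the contracted shape and broadcasts", {
  w <- fixture_world()
  ft <- assemble(w$neut_all[[420]], w$norms, w$geom)
  expect_s3_class(ft, "feature_tensor")
  expect_equal(dim(ft), c(11L, 105L))
  expect_setequal(rownames(ft), default_row_order())
  # HAF and H12 are locus-level values broadcast across all 105 windows
  expect_equal(length(unique(ft["haf", ])), 1L)
  expect_equal(length(unique(ft["h12", ])), 1L)
  # all cells finite after imputation
  expect_true(all(is.finite(ft)))
  # determinism
  expect_equal(unclass(assemble(w$neut_all[[420]], w$norms, w$geom)),
               unclass(ft))
})

test_that("row_order permutes rows exactly and rejects unknown names", {
  w <- fixture_world()
  m <- w$neut_all[[421]]
  base <- assemble(m, w$norms, w$geom)
  perm <- rev(default_row_order())
  swapped <- assemble(m, w$norms, w$geom, row_order = perm)
  expect_equal(unclass(swapped), unclass(base)[perm, ], ignore_attr = TRUE)
  expect_error(assemble(m, w$norms, w$geom,
                        row_order = c(default_row_order()[-1], "bogus")),
               "permutation")
})

test_that("tensor is invariant to haplotype row order", {
  w <- fixture_world()
  m <- w$neut_all[[422]]
  mp <- withr::with_seed(1, haplotype_matrix(
    m$alleles[sample(n_haplotypes(m)), ], m$positions, m$locus_length))
  expect_equal(unclass(assemble(mp, w$norms, w$geom)),
               unclass(assemble(m, w$norms, w$geom)), tolerance = 1e-12)
})

test_that("fast profile path agrees with the per-window reference path", {
  w <- fixture_world()
  for (i in c(423, 424)) {
    m <- w$neut_all[[i]]
    ft <- assemble(m, w$norms, w$geom)
    centers <- center_points(w$geom)
    for (ci in c(1L, 11L)) for (si in c(2L, 4L)) {
      ref <- compute_window_stats(m, centers[ci],
                                  w$geom$window_sizes[si], w$norms)
      col <- (ci - 1L) * 5L + si
      fast <- unclass(ft)[names(ref), col]
      fast[attr(ft, "flags")[names(ref), col]] <- NA_real_
      expect_equal(fast, ref, tolerance = 1e-9)
    }
  }
})

test_that("neutral feature columns are approximately centered at zero", {
  # The typical (90th-percentile) column deviation carries the full-scale
  # 0.2 bound. The worst cells at fixture scale are the 5-kb-window
  # hapDAF/highfreq columns, where ~12 SNPs per window couple the statistic
  # to SNP density: norms pool variants (weighting SNP-rich loci more)
  # while column means weight loci equally, a bias of up to ~0.4 SD that
  # shrinks as windows grow; those carry a looser absolute bound.
  w <- fixture_world()
  batch <- lapply(w$neut_all[241:440], function(m)
    unclass(assemble(m, w$norms, w$geom)))
  cube <- simplify2array(batch)           # 11 x 105 x n
  col_means <- apply(cube, c(1, 2), mean)
  expect_lt(abs(mean(col_means)), 0.05)
  expect_lt(quantile(abs(col_means), 0.9), 0.2)
  expect_lt(max(abs(col_means)), 0.5)
})

test_that("empty windows impute with zero and set flags", {
  # a locus with sites only at the far left edge leaves central windows empty
  al <- matrix(rbinom(40 * 8, 1, 0.5), 40, 8)
  al[1, ] <- 1L - al[2, ]  # guarantee segregation is plausible
  m <- haplotype_matrix(al, seq(100, 800, by = 100), 120000)
  w <- fixture_world()
  ft <- assemble(m, w$norms, w$geom)
  expect_true(all(is.finite(ft)))
  expect_gt(attr(ft, "n_imputed"), 0)
  flagged_cols <- attr(ft, "flags")["sratio", ]
  expect_true(any(flagged_cols))
  expect_true(all(unclass(ft)["sratio", flagged_cols] == 0))
})

test_that("mirroring the tensor is an involution matching locus reversal", {
  w <- fixture_world()
  ft <- assemble(w$neut_all[[425]], w$norms, w$geom)
  mm <- mirror_tensor(mirror_tensor(ft))
  expect_equal(unclass(mm), unclass(ft))
  # mirror maps window (center c, size s) to (n_centers + 1 - c, s)
  mt <- mirror_tensor(ft)
  ns <- length(w$geom$window_sizes)
  for (ci in c(1L, 5L, 21L)) for (si in 1:ns) {
    expect_equal(unclass(mt)[, (ci - 1L) * ns + si],
                 unclass(ft)[, (21L - ci) * ns + si])
  }
})

test_that("strong sweep fixtures push sweep-sensitive central columns up", {
  w <- fixture_world()
  sweeps <- lapply(1:12, function(i)
    w$sim_sweep(12000 + i, sweep_params(0, 0.5, 0, 0.95, w$Nwf)))
  central <- as.vector(outer((8:14 - 1) * 5, 1:5, "+"))  # middle centers
  stat_mean <- function(m, stat) {
    ftm <- unclass(assemble(m, w$norms, w$geom))
    mean(ftm[stat, central])
  }
  neut_ref <- sapply(w$neut_all[411:440], stat_mean, stat = "highfreq")
  sweep_vals <- sapply(sweeps, stat_mean, stat = "highfreq")
  expect_gt(mean(sweep_vals > quantile(neut_ref, 0.95)), 0.7)
  neut_h <- sapply(w$neut_all[411:440], stat_mean, stat = "hapdaf_o")
  sweep_h <- sapply(sweeps, stat_mean, stat = "hapdaf_o")
  expect_gt(mean(sweep_h), mean(neut_h))
})
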