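# Shared fixture world: a x0.1-scaled version of the reference setting
# (120-kb loci standing in for 1.2 Mb, feature geometry scaled with them,
# forward population N = 400 with population-scaled rates matching
# Ne = 10,000, selection strengths matching gamma = 2Ns in the tested
# range, sweep ages up to 0.125*4N). Built lazily once per test run and
# cached; every seed is fixed.

.world_cache <- new.env(parent = emptyenv())

world_geometry <- function() {
  feature_geometry(120000, 21L, 1000,
                   c(5000, 10000, 20000, 50000, 100000))
}

world_cnn_config <- function() {
  cnn_config(blocks = list(list(filters = 6, kernel = c(3, 5)),
                           list(filters = 6, kernel = c(3, 3)),
                           list(filters = 6, kernel = c(3, 3))),
             dense_units = 16, epochs = 120, lr = 1e-3, patience = 25)
}

fixture_world <- function() {
  if (!is.null(.world_cache$w)) return(.world_cache$w)
  # optional on-disk cache for interactive development (never set in CI)
  cache_file <- getOption("sweepnet.world_cache", NULL)
  if (!is.null(cache_file) && file.exists(cache_file)) {
    .world_cache$w <- readRDS(cache_file)
    return(.world_cache$w)
  }
  L <- 120000
  Nwf <- 400L
  geom <- world_geometry()
  cfg <- sim_config(locus_length = L, n_haplotypes = 100)
  swp_cfg <- sim_config(locus_length = L, n_haplotypes = 100,
                        tau_range = c(0, 0.125 * 4 * Nwf),
                        s_range = c(0.1, 0.8),
                        saf_range = c(0, 0.10), eaf_range = c(0.2, 1.0))

  neut_all <- simulate_neutral(cfg, seed = 1001, reps = 440)
  norms <- norms_from_neutral(neut_all[1:120], geom,
                              provenance = "fixture-world-v1")
  init_pool <- simulate_neutral(sim_config(locus_length = L,
                                           n_haplotypes = Nwf),
                                seed = 2002, reps = 16)

  w <- list(L = L, Nwf = Nwf, geom = geom, cfg = cfg, swp_cfg = swp_cfg,
            norms = norms, init_pool = init_pool, neut_all = neut_all)
  w$sim_sweep <- function(seed, params = NULL) {
    p <- if (is.null(params)) draw_sweep_params(w$swp_cfg, seed) else params
    simulate_sweep_wf(w$swp_cfg, p, seed = seed, wf_pop_size = w$Nwf,
                      init = w$init_pool[[seed %% length(w$init_pool) + 1L]])
  }
  w$ft <- function(m) squash_tensor(assemble(m, w$norms, w$geom))

  sweeps_train <- lapply(3000 + 1:250, w$sim_sweep)
  w$train_x <- c(lapply(neut_all[121:370], w$ft),
                 lapply(sweeps_train, w$ft))
  w$train_y <- rep(c("neutral", "sweep"), c(250, 250))
  w$model <- train_cnn(w$train_x, w$train_y, world_cnn_config(), seed = 42,
                       mirror_cols = mirror_columns(geom), n_models = 3L)
  w$neut_test <- lapply(neut_all[371:440], w$ft)  # 70 held-out neutrals
  .world_cache$w <- w
  if (!is.null(cache_file)) saveRDS(w, cache_file)
  w
}

# synthetic separable tensors for classifier sanity checks: class means at
# +/- mu on every cell, unit noise
synthetic_tensors <- function(n, mu, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    v <- matrix(stats::rnorm(11 * 105, mean = mu), 11, 105,
                dimnames = list(default_row_order(), NULL))
    structure(v, class = "feature_tensor", row_order = default_row_order(),
              norms_provenance = "synthetic-separable", n_imputed = 0L,
              flags = matrix(FALSE, 11, 105))
  }))
}
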