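#' Simulation configuration
#'
#' Describes the world training and testing data are generated from: a
#' piecewise-constant demography, mutation and recombination rates, locus
#' geometry, sample size, and the distributions sweep parameters are drawn
#' from. Defaults are the conditions the method is described under: a 1.2-Mb
#' locus, 100 sampled chromosomes, equilibrium Ne = 10,000, sweep ages up to
#' `0.125 * 4 * Ne` generations, selection coefficients log-uniform on
#' `[0.001, 0.1]`, starting allele frequencies up to 10% and ending allele
#' frequencies of at least 20%.
#'
#' @param demography `"equilibrium"`, `"decline"`, `"expansion"`,
#'   `"bottleneck"`, or a data frame with columns `time` (generations ago)
#'   and `size` (Ne from that time backwards).
#' @param ne present-day effective population size.
#' @param mu,rho per-bp per-generation mutation and recombination rates.
#' @param locus_length locus length in bp.
#' @param n_haplotypes sampled chromosomes per replicate (even: coalescent
#'   samples are diploid individuals).
#' @param label class label attached to generated matrices.
#' @param tau_range,s_range,saf_range,eaf_range sweep-parameter draw ranges:
#'   sweep age (generations since selection ended; uniform), selection
#'   coefficient (log-uniform), starting and ending allele frequency
#'   (uniform). Point masses (min = max) are allowed.
#' @param demog_factor fold change for the named decline/expansion scenarios.
#' @param demog_time time of the size change, generations ago.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(demography = "equilibrium", ne = 10000,
                       mu = 1.25e-8, rho = 1.25e-8,
                       locus_length = 1200000, n_haplotypes = 100,
                       label = c("neutral", "sweep"),
                       tau_range = c(0, 0.125 * 4 * ne),
                       s_range = c(0.001, 0.1),
                       saf_range = c(0, 0.10),
                       eaf_range = c(0.2, 1.0),
                       demog_factor = 5, demog_time = 0.05 * 4 * ne) {
  label <- match.arg(label)
  if (locus_length <= 0) stop("`locus_length` must be > 0", call. = FALSE)
  if (mu <= 0 || rho < 0) stop("rates must be positive", call. = FALSE)
  steps <- if (is.data.frame(demography)) {
    demography
  } else {
    switch(demography,
      equilibrium = data.frame(time = numeric(0), size = numeric(0)),
      decline = data.frame(time = demog_time, size = ne * demog_factor),
      expansion = data.frame(time = demog_time, size = ne / demog_factor),
      bottleneck = data.frame(time = c(0.02 * 4 * ne, 0.05 * 4 * ne),
                              size = c(ne / 10, ne)),
      stop("unknown demography '", demography, "'", call. = FALSE))
  }
  structure(list(demography = steps, ne = ne, mu = mu, rho = rho,
                 locus_length = locus_length,
                 n_haplotypes = as.integer(n_haplotypes), label = label,
                 tau_range = tau_range, s_range = s_range,
                 saf_range = saf_range, eaf_range = eaf_range),
            class = "sim_config")
}

#' Draw sweep parameters from the configured distributions
#'
#' Sweep age `tau` (generations since selection ended) is uniform on
#' `tau_range`; the selection coefficient `s` is log-uniform on `s_range`;
#' starting (`saf`) and ending (`eaf`) allele frequencies are uniform on
#' their ranges, with draws where `saf >= eaf` rejected and resampled (error
#' after 1,000 attempts). Deterministic under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a list of class `sweep_params` with fields `tau`, `s`, `saf`,
#'   `eaf`, `ne`.
#' @export
draw_sweep_params <- function(config, seed) {
  withr::with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      tau <- stats::runif(1, config$tau_range[1], config$tau_range[2])
      s <- exp(stats::runif(1, log(config$s_range[1]),
                            log(config$s_range[2])))
      saf <- stats::runif(1, config$saf_range[1], config$saf_range[2])
      eaf <- stats::runif(1, config$eaf_range[1], config$eaf_range[2])
      if (saf < eaf) return(sweep_params(tau, s, saf, eaf, config$ne))
    }
    stop("could not draw saf < eaf after 1000 attempts; check ranges",
         call. = FALSE)
  })
}

#' @rdname draw_sweep_params
#' @param tau,s,saf,eaf,ne see [sim_config()].
#' @export
sweep_params <- function(tau, s, saf, eaf, ne) {
  if (!(saf >= 0 && saf < eaf && eaf <= 1))
    stop("need 0 <= saf < eaf <= 1", call. = FALSE)
  if (s <= 0) stop("`s` must be > 0", call. = FALSE)
  if (tau < 0 || tau > 0.25 * 4 * ne)
    stop("`tau` must lie in [0, 0.25*4*Ne] (outer detection bound)",
         call. = FALSE)
  structure(list(tau = tau, s = s, saf = saf, eaf = eaf, ne = ne),
            class = "sweep_params")
}

#' Simulate neutral replicates with a coalescent engine
#'
#' Delegates to msprime (run through the bundled Python helper) under the
#' configured piecewise-constant demography and returns polarized haplotype
#' matrices via the package's ms reader. Deterministic under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param reps number of replicates.
#' @return a list of `hapmat` (or a single `hapmat` when `reps = 1`), each
#'   with `attr(, "label")` set from the config.
#' @export
simulate_neutral <- function(config, seed, reps = 1L) {
  stopifnot(inherits(config, "sim_config"))
  script <- system.file("python", "msprime_neutral.py", package = "sweepnet")
  if (!nzchar(script)) stop("bundled msprime helper not found", call. = FALSE)
  dem <- if (nrow(config$demography))
    paste(sprintf("%g:%g", config$demography$time, config$demography$size),
          collapse = ",") else ""
  args <- c(script,
            "--n", config$n_haplotypes,
            "--length", format(config$locus_length, scientific = FALSE),
            "--ne", config$ne, "--mu", config$mu, "--rho", config$rho,
            "--reps", reps, "--seed", as.integer(seed) %% 2147483646L + 1L)
  if (nzchar(dem)) args <- c(args, "--demography", dem)
  out <- suppressWarnings(system2("python", args, stdout = TRUE,
                                  stderr = FALSE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("msprime helper failed (status ", attr(out, "status"), ")",
         call. = FALSE)
  mats <- read_ms(out, config$locus_length)
  mats <- lapply(mats, `attr<-`, "label", "neutral")
  if (reps == 1L) mats[[1L]] else mats
}

#' Forward Wright-Fisher sweep simulation (fixture scale)
#'
#' A deliberately small forward simulator that stands in for full coalescent
#' sweep machinery at test scale: a haploid Wright-Fisher population with
#' infinite-sites mutation, single-crossover recombination and one selected
#' site at (or nearest) the locus centre. The beneficial allele starts from
#' a standing variant whose frequency is closest to `params$saf` (or a de
#' novo single copy when `saf` rounds below one copy), its trajectory is
#' conditioned on reaching `params$eaf` by rejection sampling (restart cap
#' `max_restarts`), selection is lifted at `eaf`, and the sample is taken
#' `tau` generations later. The founding population defaults to a coalescent
#' draw via [simulate_neutral()] so the standing variation is
#' coalescent-shaped. Population-scaled mutation/recombination rates are
#' preserved by using the config's `4*Ne*mu` with the forward population size
#' `wf_pop_size`.
#'
#' Forward simulation is only allowed at fixture scale
#' (`wf_pop_size <= 2000`, locus <= 200 kb) and requires `s > 10 / (2N)` so
#' selection dominates drift.
#'
#' @param config a [sim_config()]; `config$ne` sets the population-scaled
#'   rates, `wf_pop_size` the simulated chromosome count.
#' @param params a [sweep_params()] (its `tau` is interpreted in generations
#'   of the forward population, so draw params with `ne = wf_pop_size`).
#' @param seed integer seed.
#' @param wf_pop_size forward population size (haploid chromosomes).
#' @param init optional founding `hapmat` with `wf_pop_size` haplotypes.
#' @param max_restarts rejection-sampling restart cap.
#' @return a `hapmat` of `config$n_haplotypes` sampled chromosomes with
#'   attributes `label = "sweep"` and `realized` (focal frequencies,
#'   generations, restarts, the input params).
#' @export
simulate_sweep_wf <- function(config, params, seed, wf_pop_size = 500L,
                              init = NULL, max_restarts = 10000L) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "sweep_params"))
  N <- as.integer(wf_pop_size)
  if (N > 2000L || config$locus_length > 200000)
    stop("forward simulation is fixture-scale only (N <= 2000, ",
         "locus <= 200 kb); import external simulations for full scale",
         call. = FALSE)
  if (params$s <= 10 / (2 * N))
    stop("`s` must exceed 10/(2N) for the forward fixture simulator",
         call. = FALSE)
  if (params$tau > 0.25 * 4 * N)
    stop("`tau` exceeds 0.25*4*N generations of the forward population; ",
         "draw params with ne = wf_pop_size", call. = FALSE)

  if (is.null(init)) {
    init_cfg <- sim_config(demography = config$demography, ne = config$ne,
                           mu = config$mu, rho = config$rho,
                           locus_length = config$locus_length,
                           n_haplotypes = N)
    init <- simulate_neutral(init_cfg, seed = seed)
  }
  if (n_haplotypes(init) != N)
    stop("`init` must have wf_pop_size haplotypes", call. = FALSE)

  # keep the population-scaled rates of the config's world: the forward
  # population is haploid with N chromosomes (pairwise coalescence ~ N
  # generations), so theta = 2*N*mu_wf must equal the coalescent world's
  # 4*Ne*mu
  mu_wf <- 2 * config$mu * config$ne / N
  rho_wf <- 2 * config$rho * config$ne / N
  L <- config$locus_length

  # focal: standing variant nearest saf in frequency (ties: nearest centre),
  # de novo when saf amounts to less than one copy
  focal0 <- -1L
  if (round(params$saf * N) >= 1 && n_sites(init) > 0L) {
    freq <- site_daf(init)
    score <- abs(freq - params$saf) +
      abs(init$positions - L / 2) / L * 1e-3
    focal0 <- which.min(score) - 1L  # 0-based for C++
  }

  res <- withr::with_seed(seed, wf_forward_cpp(
    init$alleles, init$positions, L, focal0, params$s, params$eaf,
    as.integer(round(params$tau)), N * mu_wf * L, rho_wf * L,
    as.integer(max_restarts), config$n_haplotypes, 200000L))

  ord <- order(res$positions)
  pos <- .dedupe_positions(round(res$positions[ord]))
  pos <- pmin(pos, L - 1)
  while (anyDuplicated(pos)) {
    d <- which(duplicated(pos, fromLast = TRUE))
    pos[d] <- pos[d] - 1
  }
  out <- haplotype_matrix(res$alleles[, ord, drop = FALSE], pos, L)
  attr(out, "label") <- "sweep"
  attr(out, "realized") <- list(
    focal_pop_freq = res$focal_pop_freq,
    focal_sample_freq = res$focal_sample_freq,
    generations = res$generations, restarts = res$restarts, params = params)
  out
}

#' Import a directory of ms-format files as a labeled dataset
#'
#' Each file contributes its replicates with the label given for the file;
#' the combined dataset is shuffled (deterministically under `seed`) and a
#' manifest records provenance.
#'
#' @param paths character vector of ms files.
#' @param labels one of "neutral"/"sweep" per file.
#' @param locus_length locus length in bp used to rescale positions.
#' @param seed shuffle seed.
#' @return a list of class `sim_dataset`: `matrices` (list of `hapmat`),
#'   `manifest` (tibble: replicate_id, label, source), `balance` (sweep
#'   fraction).
#' @export
import_dataset <- function(paths, labels, locus_length, seed = 1L) {
  if (length(paths) != length(labels))
    stop("`labels` must have one entry per file", call. = FALSE)
  if (!all(labels %in% c("neutral", "sweep")))
    stop("labels must be 'neutral' or 'sweep'", call. = FALSE)
  mats <- list(); man <- list()
  for (i in seq_along(paths)) {
    reps <- read_ms(paths[i], locus_length)
    ids <- paste0(basename(paths[i]), "#", seq_along(reps))
    for (r in seq_along(reps)) {
      attr(reps[[r]], "label") <- labels[i]
      attr(reps[[r]], "replicate_id") <- ids[r]
    }
    mats <- c(mats, reps)
    man[[i]] <- tibble::tibble(replicate_id = ids, label = labels[i],
                               source = paths[i])
  }
  manifest <- do.call(rbind, man)
  if (anyDuplicated(manifest$replicate_id))
    stop("duplicate replicate IDs in dataset", call. = FALSE)
  ord <- withr::with_seed(seed, sample.int(length(mats)))
  structure(list(matrices = mats[ord], manifest = manifest[ord, ],
                 balance = mean(manifest$label == "sweep")),
            class = "sim_dataset")
}

#' Export a dataset's replicates back to ms files (one per label)
#' @param dataset a [import_dataset()] result.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lab in unique(dataset$manifest$label)) {
    sel <- vapply(dataset$matrices,
                  function(m) identical(attr(m, "label"), lab), TRUE)
    p <- file.path(dir, paste0(lab, ".ms"))
    write_ms(dataset$matrices[sel], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
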