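# Independent brute-force reimplementations of every statistic, written
# directly from the definitions with explicit loops and no shared code with
# the package internals. They are deliberately slow and literal.

oracle_hapdaf <- function(x, focal, fa_max, sum_min, window) {
  al <- x$alleles
  daf <- mean(al[, focal])
  if (daf < 0.25 || daf > 0.95) return(NA_real_)
  der <- which(al[, focal] == 1)
  anc <- which(al[, focal] == 0)
  terms <- c()
  for (j in seq_len(ncol(al))) {
    if (j == focal) next
    if (x$positions[j] < window[1] || x$positions[j] >= window[2]) next
    n_d <- sum(al[der, j] == 1)
    n_a <- sum(al[anc, j] == 1)
    f_d <- n_d / length(der)
    f_a <- n_a / length(anc)
    crit1 <- n_d >= 1 && n_a >= 1
    crit2 <- f_d > f_a
    crit3 <- f_a < fa_max
    crit4 <- (f_d + f_a) > sum_min
    if (crit1 && crit2 && crit3 && crit4) terms <- c(terms, f_d^2 - f_a^2)
  }
  if (length(terms) == 0) return(0)
  sum(terms) / length(terms)
}

oracle_sratio <- function(x, focal, window) {
  al <- x$alleles
  daf <- mean(al[, focal])
  if (daf < 0.25 || daf > 0.95) return(NA_real_)
  der <- which(al[, focal] == 1)
  anc <- which(al[, focal] == 0)
  s_d <- 0; s_a <- 0
  for (j in seq_len(ncol(al))) {
    if (j == focal) next
    if (x$positions[j] < window[1] || x$positions[j] >= window[2]) next
    vd <- al[der, j]; va <- al[anc, j]
    if (length(unique(vd)) > 1) s_d <- s_d + 1
    if (length(unique(va)) > 1) s_a <- s_a + 1
  }
  if (s_d == 0) return(NA_real_)
  s_a / s_d
}

oracle_freq <- function(x, focal, window, high) {
  al <- x$alleles
  daf <- mean(al[, focal])
  if (daf < 0.25 || daf > 0.95) return(NA_real_)
  der <- which(al[, focal] == 1)
  terms <- c()
  for (j in seq_len(ncol(al))) {
    if (j == focal) next
    if (x$positions[j] < window[1] || x$positions[j] >= window[2]) next
    f_dd <- sum(al[der, j] == 1) / length(der)
    if (high) {
      if (f_dd > 0.25) terms <- c(terms, f_dd^2)
    } else {
      if (f_dd > 0 && f_dd < 0.25) terms <- c(terms, (1 - f_dd)^2)
    }
  }
  if (length(terms) == 0) return(0)
  sum(terms) / length(terms)
}

oracle_dind <- function(x, focal, window) {
  al <- x$alleles
  daf <- mean(al[, focal])
  if (daf < 0.25 || daf > 0.95) return(NA_real_)
  der <- which(al[, focal] == 1)
  anc <- which(al[, focal] == 0)
  if (length(der) < 2 || length(anc) < 2) return(NA_real_)
  pairwise_pi <- function(rows) {
    cols <- which(x$positions >= window[1] & x$positions < window[2])
    cols <- setdiff(cols, focal)
    tot <- 0; np <- 0
    for (a in seq_along(rows)) for (b in seq_along(rows)) {
      if (a < b) {
        tot <- tot + sum(al[rows[a], cols] != al[rows[b], cols])
        np <- np + 1
      }
    }
    tot / np
  }
  pd <- pairwise_pi(der)
  if (pd == 0) return(NA_real_)
  pairwise_pi(anc) / pd
}

# EHH at each site outward from focal, by direct pair comparison
oracle_ehh_curve <- function(x, rows, focal, cols_out) {
  al <- x$alleles
  np <- length(rows) * (length(rows) - 1) / 2
  sapply(seq_along(cols_out), function(k) {
    span <- cols_out[1:k]
    same <- 0
    for (a in seq_along(rows)) for (b in seq_along(rows)) {
      if (a < b &&
          all(al[rows[a], span] == al[rows[b], span])) same <- same + 1
    }
    same / np
  })
}

oracle_ihh_side <- function(x, rows, focal, cols_out, dist, cutoff = 0.05) {
  if (length(cols_out) == 0) return(0)
  ehh <- oracle_ehh_curve(x, rows, focal, cols_out)
  xs <- c(0, dist); ys <- c(1, ehh)
  below <- which(ehh < cutoff)
  last <- if (length(below)) below[1] + 1 else length(ys)
  tot <- 0
  for (k in 2:last) tot <- tot + (xs[k] - xs[k - 1]) * (ys[k] + ys[k - 1]) / 2
  tot
}

oracle_ihs <- function(x, focal, window, cutoff = 0.05) {
  al <- x$alleles
  daf <- mean(al[, focal])
  if (daf < 0.25 || daf > 0.95) return(NA_real_)
  der <- which(al[, focal] == 1)
  anc <- which(al[, focal] == 0)
  if (length(der) < 2 || length(anc) < 2) return(NA_real_)
  idx <- which(x$positions >= window[1] & x$positions < window[2])
  left <- rev(idx[idx < focal]); right <- idx[idx > focal]
  fpos <- x$positions[focal]
  one <- function(rows) {
    oracle_ihh_side(x, rows, focal, left, abs(x$positions[left] - fpos),
                    cutoff) +
      oracle_ihh_side(x, rows, focal, right, abs(x$positions[right] - fpos),
                      cutoff)
  }
  ihh_d <- one(der); ihh_a <- one(anc)
  if (ihh_d <= 0 || ihh_a <= 0) return(NA_real_)
  log(ihh_d / ihh_a)
}

oracle_nsl <- function(x, focal, window) {
  al <- x$alleles
  daf <- mean(al[, focal])
  if (daf < 0.25 || daf > 0.95) return(NA_real_)
  der <- which(al[, focal] == 1)
  anc <- which(al[, focal] == 0)
  if (length(der) < 2 || length(anc) < 2) return(NA_real_)
  idx <- which(x$positions >= window[1] & x$positions < window[2])
  left <- rev(idx[idx < focal]); right <- idx[idx > focal]
  sl <- function(rows) {
    tot <- 0; np <- 0
    for (a in seq_along(rows)) for (b in seq_along(rows)) {
      if (a >= b) next
      np <- np + 1
      len <- 1  # the focal site itself
      for (j in left) {
        if (al[rows[a], j] == al[rows[b], j]) len <- len + 1 else break
      }
      for (j in right) {
        if (al[rows[a], j] == al[rows[b], j]) len <- len + 1 else break
      }
      tot <- tot + len
    }
    tot / np
  }
  log(sl(der) / sl(anc))
}

oracle_haf_top <- function(x, window = NULL) {
  al <- x$alleles
  idx <- if (is.null(window)) seq_len(ncol(al))
         else which(x$positions >= window[1] & x$positions < window[2])
  if (length(idx) == 0) return(0)
  counts <- sapply(idx, function(j) sum(al[, j]))
  haf <- sapply(seq_len(nrow(al)), function(h)
    sum(counts[al[h, idx] == 1]))
  k <- ceiling(0.1 * length(haf))
  mean(sort(haf, decreasing = TRUE)[1:k])
}

oracle_safe <- function(x, window = NULL) {
  al <- x$alleles
  idx <- if (is.null(window)) seq_len(ncol(al))
         else which(x$positions >= window[1] & x$positions < window[2])
  A <- al[, idx, drop = FALSE]
  n <- nrow(A)
  counts <- sapply(seq_len(ncol(A)), function(j) sum(A[, j]))
  haf <- sapply(seq_len(n), function(h) sum(counts[A[h, ] == 1]))
  keys <- sapply(seq_len(n), function(h) paste(A[h, ], collapse = ","))
  uniq_keys <- unique(keys)
  sapply(seq_len(ncol(A)), function(j) {
    carriers <- which(A[, j] == 1)
    phi <- sum(haf[carriers]) / sum(haf)
    kappa <- length(unique(keys[carriers])) / length(uniq_keys)
    f <- counts[j] / n
    den <- sqrt(f * (1 - f))
    if (den == 0) 0 else (phi - kappa) / den
  })
}

oracle_h12 <- function(x, window = NULL, identity = 0.8) {
  al <- x$alleles
  idx <- if (is.null(window)) seq_len(ncol(al))
         else which(x$positions >= window[1] & x$positions < window[2])
  if (length(idx) == 0) return(NA_real_)
  A <- al[, idx, drop = FALSE]
  n <- nrow(A)
  keys <- sapply(seq_len(n), function(h) paste(A[h, ], collapse = ","))
  tab <- table(keys)
  firsts <- sapply(names(tab), function(k) min(which(keys == k)))
  ord <- order(-as.integer(tab), names(tab))
  seeds <- list(); sizes <- c()
  for (i in ord) {
    hap <- A[firsts[i], ]
    placed <- FALSE
    for (cl in seq_along(seeds)) {
      if (mean(hap == seeds[[cl]]) >= identity) {
        sizes[cl] <- sizes[cl] + tab[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) { seeds[[length(seeds) + 1]] <- hap; sizes <- c(sizes, tab[i]) }
  }
  p <- sort(as.numeric(sizes) / n, decreasing = TRUE)
  (p[1] + ifelse(length(p) > 1, p[2], 0))^2 +
    ifelse(length(p) > 2, sum(p[3:length(p)]^2), 0)
}

# random binary matrix fixture with valid positions
random_hapmat <- function(n_hap, n_sites, locus = 1000, seed = NULL) {
  gen <- function() {
    repeat {
      al <- matrix(rbinom(n_hap * n_sites, 1,
                          stats::runif(1, 0.2, 0.7)), n_hap, n_sites)
      seg <- apply(al, 2, function(cl) length(unique(cl)) > 1)
      al <- al[, seg, drop = FALSE]
      if (ncol(al) >= 2) break
    }
    pos <- sort(sample(seq(0, locus - 1), ncol(al)))
    haplotype_matrix(al, pos, locus)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
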