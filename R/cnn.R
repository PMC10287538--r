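#' CNN configuration
#'
#' Default architecture: three convolutional blocks whose kernels span
#' multiple statistic rows and adjacent window columns (so filters combine
#' different types of information early), each followed by ReLU, 2x2 max
#' pooling and dropout, then a dense ReLU head and a sigmoid output trained
#' with binary cross-entropy and Adam, early-stopped on validation loss.
#' Every element is configurable.
#'
#' @param input_shape `c(rows, cols)` of the feature tensor.
#' @param blocks list of conv blocks, each `list(filters =, kernel = c(kh, kw))`
#'   (odd kernel dims; kernels never smaller than 3x3 by default).
#' @param pool pooling window `c(ph, pw)`.
#' @param dropout dropout rate after each block and before the output.
#' @param dense_units width of the dense head.
#' @param lr Adam learning rate.
#' @param batch_size,epochs,patience training loop controls; `patience` is
#'   the early-stopping patience on validation loss.
#' @param validation_split fraction of the data held back for in-model
#'   validation (default 20%).
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(11, 105),
                       blocks = list(list(filters = 8, kernel = c(3, 3)),
                                     list(filters = 8, kernel = c(3, 3)),
                                     list(filters = 8, kernel = c(3, 3))),
                       pool = c(2, 2), dropout = 0.25, dense_units = 32,
                       lr = 1e-3, batch_size = 32, epochs = 40,
                       patience = 10, validation_split = 0.2) {
  structure(list(input_shape = input_shape, blocks = blocks, pool = pool,
                 dropout = dropout, dense_units = dense_units, lr = lr,
                 batch_size = batch_size, epochs = epochs,
                 patience = patience, validation_split = validation_split),
            class = "cnn_config")
}

# ---------------------------------------------------------------------------
# minimal deterministic CNN engine (im2col convolutions, Adam)

.conv_fwd <- function(X, K, b) {
  d <- dim(X); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  kd <- dim(K); kh <- kd[1]; kw <- kd[2]; nf <- kd[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Xp <- array(0, c(n, H + 2L * ph, W + 2L * pw, C))
  Xp[, ph + seq_len(H), pw + seq_len(W), ] <- X
  cols <- matrix(0, n * H * W, kh * kw * C)
  m <- 0L
  for (ci in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    m <- m + 1L
    cols[, m] <- Xp[, di:(di + H - 1L), dj:(dj + W - 1L), ci]
  }
  # K is (kh, kw, C, F): column-major flattening (di fastest, then dj, ci)
  # matches the cols fill order above
  Kmat <- matrix(K, kh * kw * C, nf)
  out <- cols %*% Kmat
  out <- sweep(out, 2L, b, "+")
  dim(out) <- c(n, H, W, nf)
  list(out = out, cols = cols, dims = c(n, H, W, C, kh, kw, ph, pw))
}

.conv_bwd <- function(dOut, cache, K) {
  d <- cache$dims
  n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  kh <- d[5]; kw <- d[6]; ph <- d[7]; pw <- d[8]
  nf <- dim(K)[4]
  dOm <- matrix(dOut, n * H * W, nf)
  dK <- crossprod(cache$cols, dOm)
  dim(dK) <- c(kh, kw, C, nf)
  db <- colSums(dOm)
  Kmat <- matrix(K, kh * kw * C, nf)
  dcols <- tcrossprod(dOm, Kmat)
  dXp <- array(0, c(n, H + 2L * ph, W + 2L * pw, C))
  m <- 0L
  for (ci in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    m <- m + 1L
    blk <- dcols[, m]
    dim(blk) <- c(n, H, W)
    dXp[, di:(di + H - 1L), dj:(dj + W - 1L), ci] <-
      dXp[, di:(di + H - 1L), dj:(dj + W - 1L), ci] + blk
  }
  dX <- dXp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
  list(dX = dX, dK = dK, db = db)
}

.pool_fwd <- function(X, ph, pw) {
  d <- dim(X); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- H %/% ph; Wo <- W %/% pw
  cand <- vector("list", ph * pw)
  k <- 0L
  for (dj in seq_len(pw)) for (di in seq_len(ph)) {
    k <- k + 1L
    cand[[k]] <- X[, seq(di, by = ph, length.out = Ho),
                   seq(dj, by = pw, length.out = Wo), , drop = FALSE]
  }
  out <- Reduce(pmax, cand)
  masks <- vector("list", length(cand))
  claimed <- array(FALSE, dim(out))
  for (k in seq_along(cand)) {
    mk <- (cand[[k]] == out) & !claimed
    claimed <- claimed | mk
    masks[[k]] <- mk
  }
  list(out = out, masks = masks, dims = d, ph = ph, pw = pw)
}

.pool_bwd <- function(dOut, cache) {
  d <- cache$dims; ph <- cache$ph; pw <- cache$pw
  Ho <- d[2] %/% ph; Wo <- d[3] %/% pw
  dX <- array(0, d)
  k <- 0L
  for (dj in seq_len(pw)) for (di in seq_len(ph)) {
    k <- k + 1L
    dX[, seq(di, by = ph, length.out = Ho),
       seq(dj, by = pw, length.out = Wo), ] <-
      dOut * cache$masks[[k]]
  }
  dX
}

.init_params <- function(config) {
  p <- list()
  C <- 1L
  H <- config$input_shape[1]; W <- config$input_shape[2]
  for (i in seq_along(config$blocks)) {
    blk <- config$blocks[[i]]
    kh <- blk$kernel[1]; kw <- blk$kernel[2]; nf <- blk$filters
    fan_in <- kh * kw * C
    p[[paste0("K", i)]] <- array(stats::rnorm(kh * kw * C * nf,
                                              sd = sqrt(2 / fan_in)),
                                 c(kh, kw, C, nf))
    p[[paste0("bK", i)]] <- rep(0, nf)
    C <- nf
    H <- H %/% config$pool[1]; W <- W %/% config$pool[2]
    if (H < 1L || W < 1L)
      stop("input shape too small for ", length(config$blocks),
           " pooled conv blocks", call. = FALSE)
  }
  flat <- H * W * C
  p$W1 <- matrix(stats::rnorm(flat * config$dense_units,
                              sd = sqrt(2 / flat)), flat, config$dense_units)
  p$b1 <- rep(0, config$dense_units)
  p$W2 <- matrix(stats::rnorm(config$dense_units, sd = sqrt(1 / config$dense_units)),
                 config$dense_units, 1L)
  p$b2 <- 0
  p
}

.forward <- function(p, X, config, train = FALSE) {
  caches <- list()
  A <- X
  if (length(dim(A)) == 3L) dim(A) <- c(dim(A), 1L)
  keep <- 1 - config$dropout
  for (i in seq_along(config$blocks)) {
    cv <- .conv_fwd(A, p[[paste0("K", i)]], p[[paste0("bK", i)]])
    relu_mask <- cv$out > 0
    A1 <- cv$out * relu_mask
    pl <- .pool_fwd(A1, config$pool[1], config$pool[2])
    A <- pl$out
    drop_mask <- NULL
    if (train && config$dropout > 0) {
      drop_mask <- array(stats::runif(length(A)) < keep, dim(A)) / keep
      A <- A * drop_mask
    }
    caches[[i]] <- list(conv = cv, relu = relu_mask, pool = pl,
                        drop = drop_mask)
  }
  n <- dim(A)[1]
  flat <- matrix(A, n)
  Z1 <- sweep(flat %*% p$W1, 2L, p$b1, "+")
  relu1 <- Z1 > 0
  A1 <- Z1 * relu1
  d1 <- NULL
  if (train && config$dropout > 0) {
    d1 <- matrix(stats::runif(length(A1)) < keep, nrow(A1)) / keep
    A1 <- A1 * d1
  }
  logits <- as.numeric(A1 %*% p$W2 + p$b2)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, caches = caches, flat = flat, flat_dim = dim(A),
       relu1 = relu1, A1 = A1, d1 = d1)
}

.backward <- function(p, fwd, X, y, config) {
  n <- length(y)
  g <- list()
  dlogit <- (fwd$prob - y) / n
  g$W2 <- crossprod(fwd$A1, dlogit)
  g$b2 <- sum(dlogit)
  dA1 <- tcrossprod(matrix(dlogit, ncol = 1L), p$W2)
  dim(dA1) <- dim(fwd$A1)
  if (!is.null(fwd$d1)) dA1 <- dA1 * fwd$d1
  dZ1 <- dA1 * fwd$relu1
  g$W1 <- crossprod(fwd$flat, dZ1)
  g$b1 <- colSums(dZ1)
  dflat <- tcrossprod(dZ1, p$W1)
  dA <- dflat
  dim(dA) <- fwd$flat_dim
  for (i in rev(seq_along(config$blocks))) {
    cache <- fwd$caches[[i]]
    if (!is.null(cache$drop)) dA <- dA * cache$drop
    dA1 <- .pool_bwd(dA, cache$pool)
    dZ <- dA1 * cache$relu
    cb <- .conv_bwd(dZ, cache$conv, p[[paste0("K", i)]])
    g[[paste0("K", i)]] <- cb$dK
    g[[paste0("bK", i)]] <- cb$db
    dA <- cb$dX
  }
  g
}

.adam_step <- function(state, p, g, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(g)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g[[nm]] * 0
      state$v[[nm]] <- g[[nm]] * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, p = p)
}

.bce <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# ---------------------------------------------------------------------------

# bind two (n, H, W) arrays along the first dimension
abind_first <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  attributes(out)[c("row_order", "norms_provenance")] <-
    attributes(a)[c("row_order", "norms_provenance")]
  dim(out) <- c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3])
  out
}

#' Stack feature tensors into a training array
#'
#' @param tensors list of [assemble()] outputs with identical `row_order`
#'   and norms provenance.
#' @return array `(n, rows, cols)` with attributes `row_order` and
#'   `norms_provenance`.
#' @export
stack_tensors <- function(tensors) {
  if (inherits(tensors, "feature_tensor")) tensors <- list(tensors)
  ro <- attr(tensors[[1L]], "row_order")
  pv <- attr(tensors[[1L]], "norms_provenance")
  for (t in tensors) {
    if (!identical(attr(t, "row_order"), ro) ||
        !identical(attr(t, "norms_provenance"), pv))
      stop("tensors mix row orders or norms provenances", call. = FALSE)
  }
  arr <- array(0, c(length(tensors), nrow(tensors[[1L]]),
                    ncol(tensors[[1L]])))
  for (i in seq_along(tensors)) arr[i, , ] <- unclass(tensors[[i]])
  structure(arr, row_order = ro, norms_provenance = pv)
}

#' Train the sweep/neutral CNN
#'
#' Trains on balanced binary labels with a stratified validation split,
#' early stopping on validation loss (best weights restored), and a manifest
#' binding the model to the tensors' statistic row order and norms
#' provenance — a model refuses to predict tensors built differently.
#' Deterministic under `seed` (single-threaded base-R engine).
#'
#' @param x list of feature tensors, or an array `(n, rows, cols)` from
#'   [stack_tensors()].
#' @param labels vector of `"neutral"`/`"sweep"` (or 0/1).
#' @param config a [cnn_config()].
#' @param seed training seed.
#' @param mirror_cols optional column permutation from [mirror_columns()];
#'   when given, the training portion (never the validation split) is
#'   doubled with mirrored copies — locus reversal is an exact symmetry of
#'   the simulated world.
#' @param n_models ensemble size: networks trained from `n_models`
#'   independent initializations (seeds `seed`, `seed + 1`, ...) whose
#'   predicted probabilities are averaged. Small ensembles damp the
#'   optimizer-seed variance of little networks trained on few simulations.
#' @param verbose print per-epoch losses.
#' @return a `sweep_cnn` model object.
#' @export
train_cnn <- function(x, labels, config = cnn_config(), seed = 1L,
                      mirror_cols = NULL, n_models = 1L, verbose = FALSE) {
  if (is.list(x)) x <- stack_tensors(x)
  y0 <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "sweep") else as.integer(labels)
  if (length(unique(y0)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (dim(x)[1] != length(y0))
    stop("labels length does not match tensor count", call. = FALSE)
  config$input_shape <- dim(x)[2:3]

  members <- lapply(seq_len(n_models), function(k)
    .train_one(x, y0, config, seed + k - 1L, mirror_cols, verbose))
  best <- members[[1L]]

  structure(list(
    members = lapply(members, `[[`, "p"),
    config = config,
    manifest = list(row_order = attr(x, "row_order"),
                    norms_provenance = attr(x, "norms_provenance"),
                    seed = seed, n_models = n_models,
                    n_train = best$n_train, n_val = best$n_val,
                    best_epoch = best$epoch,
                    best_val_loss = best$loss),
    history = best$history), class = "sweep_cnn")
}

.train_one <- function(x, y, config, seed, mirror_cols, verbose) {
  withr::with_seed(seed, {
    # stratified validation split
    n0 <- length(y)
    idx0 <- which(y == 0L); idx1 <- which(y == 1L)
    v0 <- sample(idx0, max(1L, round(config$validation_split * length(idx0))))
    v1 <- sample(idx1, max(1L, round(config$validation_split * length(idx1))))
    val <- c(v0, v1)
    tr <- setdiff(seq_along(y), val)
    if (!is.null(mirror_cols)) {
      mirrored <- x[tr, , mirror_cols, drop = FALSE]
      x <- abind_first(x, mirrored)
      y <- c(y, y[tr])
      tr <- c(tr, n0 + seq_along(tr))
    }

    p <- .init_params(config)
    state <- list(m = list(), v = list())
    best <- list(loss = Inf, p = p, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    t_step <- 0L
    patience_left <- config$patience
    Xval <- x[val, , , drop = FALSE]

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr)
      nb <- ceiling(length(ord) / config$batch_size)
      tl <- 0
      for (b in seq_len(nb)) {
        sel <- ord[((b - 1L) * config$batch_size + 1L):
                     min(b * config$batch_size, length(ord))]
        Xb <- x[sel, , , drop = FALSE]
        fwd <- .forward(p, Xb, config, train = TRUE)
        tl <- tl + .bce(fwd$prob, y[sel]) * length(sel)
        g <- .backward(p, fwd, Xb, y[sel], config)
        t_step <- t_step + 1L
        upd <- .adam_step(state, p, g, config$lr, t_step)
        state <- upd$state; p <- upd$p
      }
      vfwd <- .forward(p, Xval, config, train = FALSE)
      vl <- .bce(vfwd$prob, y[val])
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = tl / length(ord),
                                  val_loss = vl))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        tl / length(ord), vl))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, p = p, epoch = epoch)
        patience_left <- config$patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
    list(p = best$p, loss = best$loss, epoch = best$epoch,
         history = history, n_train = length(tr), n_val = length(val))
  })
}

#' @export
print.sweep_cnn <- function(x, ...) {
  cat("<sweep_cnn>", length(x$members), "member(s),",
      x$manifest$n_train, "training tensors (", x$manifest$n_val,
      "validation ), first-member best epoch", x$manifest$best_epoch,
      "val loss", signif(x$manifest$best_val_loss, 4), "\n")
  invisible(x)
}

#' Predict sweep probabilities
#'
#' @param object a [train_cnn()] model.
#' @param tensors a `feature_tensor`, a list of them, or a stacked array.
#' @param check_provenance refuse tensors whose row order or norms
#'   provenance differ from the training manifest (default `TRUE`).
#' @param ... unused.
#' @return numeric vector of sweep probabilities in `[0, 1]`.
#' @export
predict.sweep_cnn <- function(object, tensors, check_provenance = TRUE, ...) {
  if (inherits(tensors, "feature_tensor") || is.list(tensors))
    tensors <- stack_tensors(tensors)
  if (check_provenance && !is.null(attr(tensors, "row_order"))) {
    if (!identical(attr(tensors, "row_order"), object$manifest$row_order))
      stop("tensor row order differs from the model manifest", call. = FALSE)
    if (!identical(attr(tensors, "norms_provenance"),
                   object$manifest$norms_provenance))
      stop("tensor norms provenance differs from the model manifest",
           call. = FALSE)
  }
  n <- dim(tensors)[1]
  out <- numeric(n)
  bs <- 256L
  for (b in seq_len(ceiling(n / bs))) {
    sel <- ((b - 1L) * bs + 1L):min(b * bs, n)
    xb <- tensors[sel, , , drop = FALSE]
    probs <- vapply(object$members, function(p)
      .forward(p, xb, object$config, train = FALSE)$prob,
      numeric(length(sel)))
    out[sel] <- if (length(sel) == 1L) mean(probs) else rowMeans(probs)
  }
  out
}

#' Save / load a trained model as JSON + manifest
#'
#' Plain-text serialization (weights flattened with dimensions) so models
#' survive text-only transport.
#'
#' @param model a `sweep_cnn`.
#' @param path output file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    manifest = model$manifest,
    members = lapply(model$members, function(pp)
      lapply(pp, function(w) list(dim = dim(w), values = as.numeric(w)))),
    history = model$history)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  cf <- ser$config
  config <- cnn_config(
    input_shape = as.integer(unlist(cf$input_shape)),
    blocks = lapply(cf$blocks, function(b)
      list(filters = b$filters, kernel = as.numeric(unlist(b$kernel)))),
    pool = as.numeric(unlist(cf$pool)), dropout = cf$dropout,
    dense_units = cf$dense_units, lr = cf$lr, batch_size = cf$batch_size,
    epochs = cf$epochs, patience = cf$patience,
    validation_split = cf$validation_split)
  members <- lapply(ser$members, function(pp) lapply(pp, function(w) {
    v <- as.numeric(unlist(w$values))
    d <- as.integer(unlist(w$dim))
    if (length(d)) dim(v) <- d
    v
  }))
  manifest <- ser$manifest
  manifest$row_order <- as.character(unlist(manifest$row_order))
  scalars <- intersect(c("norms_provenance", "seed", "n_models", "n_train",
                         "n_val", "best_epoch", "best_val_loss"),
                       names(manifest))
  manifest[scalars] <- lapply(manifest[scalars], function(e)
    if (is.list(e)) e[[1L]] else e)
  structure(list(members = members, config = config, manifest = manifest,
                 history = do.call(rbind, lapply(ser$history, as.data.frame))),
            class = "sweep_cnn")
}
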