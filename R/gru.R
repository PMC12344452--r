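# Gated recurrent unit sequence classifier, implemented natively with
# batched matrix operations and backpropagation through time. Architecture:
# two GRU layers (32 and 16 units) over the per-frame 7-vector input, the
# final recurrent state feeding three ReLU dense layers (16, 8, 4) with a
# single dropout (p = 0.1) after the dense stack, and a 1-unit sigmoid
# output trained with class-weighted binary cross-entropy and Adam.

#' Recurrent model configuration
#'
#' @param gru_dims Hidden sizes of the two GRU layers.
#' @param fc_dims Sizes of the dense stack.
#' @param dropout Dropout rate after the dense stack, in [0, 1).
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without loss improvement
#'   greater than \code{min_delta}).
#' @param min_delta Minimum loss improvement counted by early stopping.
#' @param batch_size Mini-batch size.
#' @param stride Temporal subsampling stride applied to each series (2
#'   halves a 60 fps stream to 30 fps).
#' @param max_len Length cap (frames, after striding) for memory
#'   predictability.
#' @param grad_clip Global gradient-norm clip (stabilizes Adam on the
#'   final-state-only objective).
#' @param class_weights \code{"inverse"} for inverse-frequency weights
#'   normalized to mean one, or a named numeric vector
#'   \code{c(target = , non_target = )} to impose a literal scheme.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return List of class \code{recurrent_config}.
#' @export
recurrent_config <- function(gru_dims = c(32L, 16L), fc_dims = c(16L, 8L, 4L),
                             dropout = 0.1, lr = 3e-3, epochs = 100L,
                             patience = 10L, min_delta = 1e-4,
                             batch_size = 32L, stride = 2L, max_len = 300L,
                             grad_clip = 5, class_weights = "inverse",
                             seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, all(gru_dims > 0), all(fc_dims > 0),
            lr > 0, epochs >= 1, batch_size >= 1, stride >= 1, max_len >= 2)
  structure(list(gru_dims = as.integer(gru_dims),
                 fc_dims = as.integer(fc_dims), dropout = dropout, lr = lr,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 min_delta = min_delta, batch_size = as.integer(batch_size),
                 stride = as.integer(stride), max_len = as.integer(max_len),
                 grad_clip = grad_clip, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "recurrent_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise bias addition (much cheaper than sweep on small matrices).
.addb <- function(M, b) M + rep(b, each = nrow(M))

.unif_mat <- function(nr, nc) {
  k <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

.init_gru_layer <- function(D, H) {
  list(Wz = .unif_mat(D, H), Uz = .unif_mat(H, H), bz = numeric(H),
       Wr = .unif_mat(D, H), Ur = .unif_mat(H, H), br = numeric(H),
       Wc = .unif_mat(D, H), Uc = .unif_mat(H, H), bc = numeric(H))
}

# Dense layers start with a small positive bias so the ReLU stack is
# active at initialization (an all-dead stack receives exactly zero
# gradient and never recovers).
.init_dense <- function(D, H, b0 = 0.1) {
  list(W = .unif_mat(D, H), b = rep(b0, H))
}

.init_params <- function(config, input_dim = 7L) {
  dims <- c(input_dim, config$gru_dims)
  gru <- lapply(seq_along(config$gru_dims),
                function(i) .init_gru_layer(dims[i], dims[i + 1]))
  fdims <- c(config$gru_dims[length(config$gru_dims)], config$fc_dims)
  fc <- lapply(seq_along(config$fc_dims),
               function(i) .init_dense(fdims[i], fdims[i + 1]))
  out <- .init_dense(fdims[length(fdims)], 1L, b0 = 0)
  list(gru = gru, fc = fc, out = out)
}

# Forward pass of one GRU layer over a padded batch.
# X: list over time of (B x D) matrices; mask: T x B matrix in {0, 1}.
# Returns the per-step hidden states and, if keep_cache, the gate caches.
.gru_forward <- function(layer, X, mask, keep_cache = FALSE) {
  Tn <- length(X); B <- nrow(X[[1]]); H <- ncol(layer$Wz)
  h <- matrix(0, B, H)
  Hs <- vector("list", Tn)
  cache <- if (keep_cache) list(z = vector("list", Tn),
                                r = vector("list", Tn),
                                c = vector("list", Tn),
                                hprev = vector("list", Tn))
  for (t in seq_len(Tn)) {
    x <- X[[t]]
    z <- .sigmoid(.addb(x %*% layer$Wz + h %*% layer$Uz, layer$bz))
    r <- .sigmoid(.addb(x %*% layer$Wr + h %*% layer$Ur, layer$br))
    cc <- tanh(.addb(x %*% layer$Wc + (r * h) %*% layer$Uc, layer$bc))
    hnew <- (1 - z) * h + z * cc
    m <- mask[t, ]
    hmasked <- m * hnew + (1 - m) * h
    if (keep_cache) {
      cache$z[[t]] <- z; cache$r[[t]] <- r; cache$c[[t]] <- cc
      cache$hprev[[t]] <- h
    }
    h <- hmasked
    Hs[[t]] <- h
  }
  list(H = Hs, h_last = h, cache = cache)
}

# Backward pass of one GRU layer. dh_last: gradient at the final state;
# dH_seq: optional list of per-step gradients (from the layer above).
.gru_backward <- function(layer, X, mask, fwd, dh_last, dH_seq = NULL) {
  Tn <- length(X); B <- nrow(X[[1]])
  g <- lapply(layer, function(p) array(0, dim = if (is.matrix(p)) dim(p)
                                       else length(p)))
  tUz <- t(layer$Uz); tUr <- t(layer$Ur); tUc <- t(layer$Uc)
  tWz <- t(layer$Wz); tWr <- t(layer$Wr); tWc <- t(layer$Wc)
  dX <- vector("list", Tn)
  dh <- dh_last
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dH_seq) && !is.null(dH_seq[[t]])) dh <- dh + dH_seq[[t]]
    m <- mask[t, ]
    z <- fwd$cache$z[[t]]; r <- fwd$cache$r[[t]]; cc <- fwd$cache$c[[t]]
    hprev <- fwd$cache$hprev[[t]]
    dhn <- dh * m              # gradient into the unmasked update
    dhp <- dh * (1 - m)        # pass-through for padded steps
    dz <- dhn * (cc - hprev) * z * (1 - z)
    dc <- dhn * z * (1 - cc^2)
    dcU <- dc %*% tUc
    dr <- dcU * hprev * r * (1 - r)
    x <- X[[t]]
    g$Wz <- g$Wz + crossprod(x, dz); g$Uz <- g$Uz + crossprod(hprev, dz)
    g$bz <- g$bz + colSums(dz)
    g$Wr <- g$Wr + crossprod(x, dr); g$Ur <- g$Ur + crossprod(hprev, dr)
    g$br <- g$br + colSums(dr)
    g$Wc <- g$Wc + crossprod(x, dc)
    g$Uc <- g$Uc + crossprod(r * hprev, dc)
    g$bc <- g$bc + colSums(dc)
    dX[[t]] <- dz %*% tWz + dr %*% tWr + dc %*% tWc
    dh <- dhn * (1 - z) + dhp + dz %*% tUz + dr %*% tUr + dcU * r
  }
  list(grads = g, dX = dX)
}

# Head forward: dense ReLU stack + dropout + sigmoid output. The dropout
# mask is drawn by the caller so both compute engines share one RNG stream.
.head_forward <- function(params, h, dmask = NULL) {
  acts <- list(); a <- h
  for (i in seq_along(params$fc)) {
    a <- pmax(.addb(a %*% params$fc[[i]]$W, params$fc[[i]]$b), 0)
    acts[[i]] <- a
  }
  if (!is.null(dmask)) a <- a * dmask
  logit <- .addb(a %*% params$out$W, params$out$b)
  list(p = .sigmoid(logit), logit = logit, acts = acts, dmask = dmask,
       dropped = a)
}

.head_backward <- function(params, h, fw, dlogit) {
  gfc <- vector("list", length(params$fc))
  gout <- list(W = crossprod(fw$dropped, dlogit), b = colSums(dlogit))
  da <- dlogit %*% t(params$out$W)
  if (!is.null(fw$dmask)) da <- da * fw$dmask
  for (i in rev(seq_along(params$fc))) {
    a <- fw$acts[[i]]
    da <- da * (a > 0)
    inp <- if (i == 1) h else fw$acts[[i - 1]]
    gfc[[i]] <- list(W = crossprod(inp, da), b = colSums(da))
    da <- da %*% t(params$fc[[i]]$W)
  }
  list(fc = gfc, out = gout, dh = da)
}

# Full forward(+backward) on one padded batch; returns loss, probabilities
# and parameter gradients. `pb` is a padded batch from .pad_batch. The
# compiled Armadillo kernel is the default engine; the pure-R path is the
# reference implementation the kernel is tested against.
.batch_pass <- function(params, pb, y, w, config, train = FALSE,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  B <- length(y)
  dmask <- NULL
  if (train && config$dropout > 0) {
    nd <- nrow(params$out$W)
    dmask <- matrix(stats::rbinom(B * nd, 1, 1 - config$dropout) /
                      (1 - config$dropout), B, nd)
  }
  if (engine == "cpp") {
    res <- .batch_pass_cpp(params, pb$cube, pb$mask, as.numeric(y),
                           as.numeric(w),
                           if (is.null(dmask)) matrix(0, 0, 0) else dmask,
                           train)
    res$p <- as.vector(res$p)
    return(res)
  }
  X <- pb$X
  mask <- pb$mask
  fw1 <- .gru_forward(params$gru[[1]], X, mask, keep_cache = train)
  fw2 <- .gru_forward(params$gru[[2]], fw1$H, mask, keep_cache = train)
  hf <- .head_forward(params, fw2$h_last, dmask)
  p <- pmin(pmax(hf$p, 1e-12), 1 - 1e-12)
  loss <- -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
  if (!train) return(list(loss = loss, p = as.vector(hf$p)))
  dlogit <- matrix(w * (p - y) / B, B, 1)
  hb <- .head_backward(params, fw2$h_last, hf, dlogit)
  bw2 <- .gru_backward(params$gru[[2]], fw1$H, mask, fw2, hb$dh)
  zero <- matrix(0, B, ncol(params$gru[[1]]$Wz))
  bw1 <- .gru_backward(params$gru[[1]], X, mask, fw1, zero, bw2$dX)
  list(loss = loss, p = as.vector(hf$p),
       grads = list(gru = list(bw1$grads, bw2$grads), fc = hb$fc,
                    out = hb$out))
}

# Rescale all gradients so their global L2 norm is at most `clip`.
.clip_grads <- function(grads, clip) {
  sq <- function(g) if (is.list(g)) sum(vapply(g, sq, numeric(1)))
                    else sum(g^2)
  nrm <- sqrt(sq(grads))
  if (!is.finite(nrm) || nrm <= clip) return(grads)
  scale_ <- function(g) if (is.list(g)) lapply(g, scale_) else g * clip / nrm
  scale_(grads)
}

# Adam state/update over the nested parameter structure.
.adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = if (is.matrix(p))
      dim(p) else length(p))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = tt))
}

# Stride, cap and pad a list of series matrices into batches.
.prepare_series <- function(samples, config) {
  lapply(samples, function(s) {
    x <- s$series
    if (config$stride > 1) {
      x <- x[seq(1, nrow(x), by = config$stride), , drop = FALSE]
    }
    if (nrow(x) > config$max_len) x <- x[seq_len(config$max_len), ,
                                         drop = FALSE]
    x
  })
}

.make_batches <- function(series, idx, batch_size) {
  lens <- vapply(series[idx], nrow, integer(1))
  idx <- idx[order(lens)]   # bucket by length to limit padding
  split(idx, ceiling(seq_along(idx) / batch_size))
}

.pad_batch <- function(series_list) {
  B <- length(series_list)
  Tn <- max(vapply(series_list, nrow, integer(1)))
  D <- ncol(series_list[[1]])
  mask <- matrix(0, Tn, B)
  cube <- array(0, dim = c(B, D, Tn))
  for (b in seq_len(B)) {
    s <- series_list[[b]]
    cube[b, , seq_len(nrow(s))] <- t(s)
    mask[seq_len(nrow(s)), b] <- 1
  }
  X <- lapply(seq_len(Tn), function(t) matrix(cube[, , t], B, D))
  list(X = X, mask = mask, cube = cube)
}

# Inverse-frequency class weights normalized so the mean sample weight is 1.
.class_weights <- function(y, scheme) {
  if (is.numeric(scheme)) {
    w <- ifelse(y == 1, scheme[["target"]], scheme[["non_target"]])
    return(w)
  }
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

#' Train the recurrent sequence classifier
#'
#' @param samples List of \code{sequence_sample} (see
#'   [build_sequence_samples()]); both classes must be present.
#' @param config A [recurrent_config()].
#' @param verbose Print per-epoch loss.
#' @return List of class \code{recurrent_model} with fitted parameters,
#'   the config, and the training history.
#' @export
train_recurrent <- function(samples, config = recurrent_config(),
                            verbose = FALSE) {
  y <- vapply(samples, function(s) as.integer(s$label == "target"),
              integer(1))
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  series <- .prepare_series(samples, config)
  w <- .class_weights(y, config$class_weights)
  with_seed(config$seed, {
    params <- .init_params(config, input_dim = ncol(series[[1]]))
    adam <- .adam_init(params)
    history <- numeric(0)
    best <- Inf; wait <- 0L
    # fixed length-bucketed batch composition, padded once; per epoch only
    # the batch order is shuffled
    batches <- .make_batches(series, sample(length(series)),
                             config$batch_size)
    padded <- lapply(batches, function(bidx) .pad_batch(series[bidx]))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(batches))
      ep_loss <- 0
      for (k in ord) {
        bidx <- batches[[k]]
        res <- .batch_pass(params, padded[[k]], y[bidx], w[bidx], config,
                           train = TRUE)
        st <- .adam_step(params, .clip_grads(res$grads, config$grad_clip),
                         adam, config$lr)
        params <- st$params; adam <- st$state
        ep_loss <- ep_loss + res$loss * length(bidx)
      }
      ep_loss <- ep_loss / length(series)
      history <- c(history, ep_loss)
      if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch, ep_loss))
      if (ep_loss < best - config$min_delta) {
        best <- ep_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(params = params, config = config, history = history,
                   final_loss = ep_loss),
              class = "recurrent_model")
  })
}

#' Predict target probabilities with a trained recurrent model
#'
#' @param model A \code{recurrent_model}.
#' @param samples List of \code{sequence_sample}.
#' @return Numeric vector of P(target) per sample.
#' @export
predict_recurrent <- function(model, samples) {
  config <- model$config
  series <- .prepare_series(samples, config)
  p <- numeric(length(series))
  batches <- .make_batches(series, seq_along(series), config$batch_size)
  for (bidx in batches) {
    pb <- .pad_batch(series[bidx])
    res <- .batch_pass(model$params, pb, y = numeric(length(bidx)),
                       w = rep(1, length(bidx)), config, train = FALSE)
    p[bidx] <- res$p
  }
  p
}
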