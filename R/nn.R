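# Minimal deterministic neural-network engine on BLAS matrix products.
#
# Sequence activations are stored as a matrix of shape (B*L) x C with rows
# ordered batch-fastest (row = b + (t-1)*B), carried around as
# list(x, B, L). After flattening, L = 1 and C is the feature width. All
# randomness (initialization, dropout, shuffling) comes from R's global RNG,
# so a single set.seed() makes training bit-reproducible.

sigmoid <- function(z) 1 / (1 + exp(-z))

act <- function(x, B, L) list(x = x, B = B, L = L)

# row indices of time step t..t+K-1 at stride s, batch-fastest layout
time_gather_idx <- function(B, Lout, k, stride, offset = 0L) {
  as.vector(outer(seq_len(B), (seq_len(Lout) - 1L) * stride + (k - 1L + offset), \(b, t) b + t * B))
}

add_bias_rows <- function(Y, b) Y + rep(b, each = nrow(Y))

# column-wise scale / center without sweep() (sweep aperm-copies the matrix)
col_scale <- function(X, v) X * rep(v, each = nrow(X))
col_center <- function(X, v) X - rep(v, each = nrow(X))

## ---- layer constructors (parameters drawn from the global RNG) ----------

nn_conv1d <- function(in_ch, out_ch, kernel = 3L, pad = 0L) {
  W <- matrix(stats::rnorm(kernel * in_ch * out_ch, sd = sqrt(2 / (kernel * in_ch))),
              kernel * in_ch, out_ch)
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = as.integer(kernel),
       pad = as.integer(pad), W = W, b = numeric(out_ch))
}

nn_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", ch = ch, momentum = momentum, eps = eps,
       gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

nn_relu <- function() list(type = "relu")

nn_maxpool <- function(kernel = 3L, stride = 2L) {
  list(type = "maxpool", kernel = as.integer(kernel), stride = as.integer(stride))
}

nn_dropout <- function(p) list(type = "dropout", p = p)

nn_flatten <- function() list(type = "flatten")

nn_dense <- function(in_f, out_f) {
  W <- matrix(stats::rnorm(in_f * out_f, sd = sqrt(2 / in_f)), in_f, out_f)
  list(type = "dense", in_f = in_f, out_f = out_f, W = W, b = numeric(out_f))
}

nn_lstm <- function(in_ch, hidden) {
  k <- 1 / sqrt(hidden)
  Wx <- matrix(stats::runif(in_ch * 4 * hidden, -k, k), in_ch, 4 * hidden)
  Wh <- matrix(stats::runif(hidden * 4 * hidden, -k, k), hidden, 4 * hidden)
  b <- stats::runif(4 * hidden, -k, k)
  b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias: standard stability choice
  list(type = "lstm", in_ch = in_ch, hidden = hidden, Wx = Wx, Wh = Wh, b = b)
}

nn_last_step <- function() list(type = "last_step")

## ---- forward passes ------------------------------------------------------

layer_forward <- function(layer, a, training) {
  switch(layer$type,
    conv1d = {
      # stride-1 convolution as K contiguous-block matmuls: in the
      # batch-fastest layout, kernel offset k touches the contiguous row
      # range [(k-1)*B + 1, (k-1+Lout)*B] of the padded input
      B <- a$B; L <- a$L; p <- layer$pad; K <- layer$kernel; Cin <- layer$in_ch
      Lp <- L + 2L * p
      Lout <- Lp - K + 1L
      if (Lout < 1L) stop(sprintf("architecture error: conv input length %d < kernel %d", L, K),
                          call. = FALSE)
      if (p > 0L) {
        Xp <- matrix(0, B * Lp, Cin)
        Xp[(p * B + 1L):((p + L) * B), ] <- a$x
      } else Xp <- a$x
      Y <- NULL
      for (k in seq_len(K)) {
        rows <- ((k - 1L) * B + 1L):((k - 1L + Lout) * B)
        Wk <- layer$W[((k - 1L) * Cin + 1L):(k * Cin), , drop = FALSE]
        Yk <- Xp[rows, , drop = FALSE] %*% Wk
        Y <- if (is.null(Y)) Yk else Y + Yk
      }
      Y <- add_bias_rows(Y, layer$b)
      list(out = act(Y, B, Lout),
           cache = if (training) list(Xp = Xp, Lp = Lp, Lout = Lout, B = B, L = L))
    },
    batchnorm = {
      X <- a$x
      if (training) {
        mu <- colMeans(X)
        xc <- col_center(X, mu)
        v <- colMeans(xc^2)
        istd <- 1 / sqrt(v + layer$eps)
        xhat <- col_scale(xc, istd)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
        Y <- add_bias_rows(col_scale(xhat, layer$gamma), layer$beta)
        return(list(out = act(Y, a$B, a$L),
                    cache = list(xhat = xhat, istd = istd), layer = layer))
      }
      # inference: one affine map per channel, y = x * s + o
      s <- layer$gamma / sqrt(layer$running_var + layer$eps)
      o <- layer$beta - layer$running_mean * s
      list(out = act(add_bias_rows(col_scale(X, s), o), a$B, a$L), cache = NULL)
    },
    relu = {
      m <- a$x > 0
      list(out = act(a$x * m, a$B, a$L), cache = list(mask = m))
    },
    maxpool = {
      B <- a$B; L <- a$L; K <- layer$kernel; s <- layer$stride
      Lout <- (L - K) %/% s + 1L
      if (Lout < 1L) stop(sprintf("architecture error: pool input length %d < kernel %d", L, K),
                          call. = FALSE)
      idx <- lapply(seq_len(K), function(k) time_gather_idx(B, Lout, k, s))
      slices <- lapply(idx, function(ii) a$x[ii, , drop = FALSE])
      M <- slices[[1]]
      for (k in 2:K) {
        gt <- slices[[k]] > M
        M[gt] <- slices[[k]][gt]
      }
      cache <- NULL
      if (training) {
        # gradient routes to the first occurrence of the maximum
        masks <- vector("list", K)
        claimed <- matrix(FALSE, nrow(M), ncol(M))
        for (k in seq_len(K)) {
          mk <- (slices[[k]] == M) & !claimed
          masks[[k]] <- mk
          claimed <- claimed | mk
        }
        cache <- list(idx = idx, masks = masks, B = B, L = L, C = ncol(M))
      }
      list(out = act(M, B, Lout), cache = cache)
    },
    dropout = {
      if (training && layer$p > 0) {
        m <- matrix((stats::runif(length(a$x)) >= layer$p) / (1 - layer$p),
                    nrow(a$x), ncol(a$x))
        list(out = act(a$x * m, a$B, a$L), cache = list(mask = m))
      } else {
        list(out = a, cache = list(mask = NULL))
      }
    },
    flatten = {
      B <- a$B; L <- a$L; C <- ncol(a$x)
      Y <- matrix(aperm(array(a$x, c(B, L, C)), c(1, 3, 2)), B, L * C)
      list(out = act(Y, B, 1L), cache = list(B = B, L = L, C = C))
    },
    dense = {
      Y <- add_bias_rows(a$x %*% layer$W, layer$b)
      list(out = act(Y, a$B, a$L), cache = if (training) list(X = a$x))
    },
    lstm = {
      B <- a$B; L <- a$L; H <- layer$hidden
      XW <- a$x %*% layer$Wx
      h <- matrix(0, B, H); cs <- matrix(0, B, H)
      Y <- matrix(0, B * L, H)
      steps <- vector("list", L)
      for (t in seq_len(L)) {
        rows <- ((t - 1L) * B + 1L):(t * B)
        Z <- add_bias_rows(XW[rows, , drop = FALSE] + h %*% layer$Wh, layer$b)
        i <- sigmoid(Z[, 1:H, drop = FALSE])
        f <- sigmoid(Z[, H + 1:H, drop = FALSE])
        g <- tanh(Z[, 2 * H + 1:H, drop = FALSE])
        o <- sigmoid(Z[, 3 * H + 1:H, drop = FALSE])
        cn <- f * cs + i * g
        tc <- tanh(cn)
        if (training) {
          steps[[t]] <- list(i = i, f = f, g = g, o = o, cprev = cs, tc = tc, hprev = h)
        }
        cs <- cn
        h <- o * tc
        Y[rows, ] <- h
      }
      list(out = act(Y, B, L),
           cache = if (training) list(steps = steps, X = a$x, B = B, L = L))
    },
    last_step = {
      B <- a$B; L <- a$L
      rows <- ((L - 1L) * B + 1L):(L * B)
      list(out = act(a$x[rows, , drop = FALSE], B, 1L),
           cache = list(B = B, L = L, C = ncol(a$x)))
    },
    stop(sprintf("unknown layer type '%s'", layer$type), call. = FALSE)
  )
}

## ---- backward passes -----------------------------------------------------

layer_backward <- function(layer, cache, d) {
  switch(layer$type,
    conv1d = {
      dY <- d$x
      gb <- colSums(dY)
      Cin <- layer$in_ch; K <- layer$kernel
      B <- cache$B; Lout <- cache$Lout
      gW <- matrix(0, K * Cin, layer$out_ch)
      dXp <- matrix(0, B * cache$Lp, Cin)
      for (k in seq_len(K)) {
        rows <- ((k - 1L) * B + 1L):((k - 1L + Lout) * B)
        kr <- ((k - 1L) * Cin + 1L):(k * Cin)
        gW[kr, ] <- crossprod(cache$Xp[rows, , drop = FALSE], dY)
        dXp[rows, ] <- dXp[rows, ] + dY %*% t(layer$W[kr, , drop = FALSE])
      }
      p <- layer$pad; L <- cache$L
      dX <- if (p > 0L) dXp[(p * B + 1L):((p + L) * B), , drop = FALSE] else dXp
      list(dx = act(dX, B, L), grads = list(W = gW, b = gb))
    },
    batchnorm = {
      dY <- d$x
      N <- nrow(dY)
      dgamma <- colSums(dY * cache$xhat)
      dbeta <- colSums(dY)
      t1 <- col_center(dY, dbeta / N)
      t2 <- col_scale(cache$xhat, dgamma / N)
      dX <- col_scale(t1 - t2, layer$gamma * cache$istd)
      list(dx = act(dX, d$B, d$L), grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = act(d$x * cache$mask, d$B, d$L), grads = NULL),
    maxpool = {
      dX <- matrix(0, cache$B * cache$L, cache$C)
      for (k in seq_along(cache$idx)) {
        ii <- cache$idx[[k]]
        dX[ii, ] <- dX[ii, ] + d$x * cache$masks[[k]]
      }
      list(dx = act(dX, cache$B, cache$L), grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = d, grads = NULL)
      else list(dx = act(d$x * cache$mask, d$B, d$L), grads = NULL)
    },
    flatten = {
      B <- cache$B; L <- cache$L; C <- cache$C
      dX <- matrix(aperm(array(d$x, c(B, C, L)), c(1, 3, 2)), B * L, C)
      list(dx = act(dX, B, L), grads = NULL)
    },
    dense = {
      dY <- d$x
      list(dx = act(dY %*% t(layer$W), d$B, d$L),
           grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
    },
    lstm = {
      B <- cache$B; L <- cache$L; H <- layer$hidden
      dY <- d$x
      dh <- matrix(0, B, H); dc <- matrix(0, B, H)
      dZall <- matrix(0, B * L, 4 * H)
      gWh <- matrix(0, H, 4 * H)
      gb <- numeric(4 * H)
      for (t in rev(seq_len(L))) {
        rows <- ((t - 1L) * B + 1L):(t * B)
        st <- cache$steps[[t]]
        dh <- dh + dY[rows, , drop = FALSE]
        do_ <- dh * st$tc * st$o * (1 - st$o)
        dc <- dc + dh * st$o * (1 - st$tc^2)
        di <- dc * st$g * st$i * (1 - st$i)
        df <- dc * st$cprev * st$f * (1 - st$f)
        dg <- dc * st$i * (1 - st$g^2)
        dZ <- cbind(di, df, dg, do_)
        dZall[rows, ] <- dZ
        gb <- gb + colSums(dZ)
        gWh <- gWh + crossprod(st$hprev, dZ)
        dh <- dZ %*% t(layer$Wh)
        dc <- dc * st$f
      }
      gWx <- crossprod(cache$X, dZall)
      dX <- dZall %*% t(layer$Wx)
      list(dx = act(dX, B, L), grads = list(Wx = gWx, Wh = gWh, b = gb))
    },
    last_step = {
      dX <- matrix(0, cache$B * cache$L, cache$C)
      rows <- ((cache$L - 1L) * cache$B + 1L):(cache$L * cache$B)
      dX[rows, ] <- d$x
      list(dx = act(dX, cache$B, cache$L), grads = NULL)
    }
  )
}

## ---- whole-model forward / backward -------------------------------------

# x: array [B, L, C] (or matrix [L, C] for one instance). Returns logits and,
# in training mode, per-layer caches plus the model with updated batch-norm
# running statistics.
model_forward <- function(model, x, training = FALSE, keep_cache = training) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
  a <- act(matrix(x, B * L, C), B, L)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], a, training)
    a <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (!is.null(r$layer)) model$layers[[i]] <- r$layer
  }
  list(logits = a$x, caches = caches, model = model)
}

# dlogits: gradient of the loss wrt the logits [B x K]
model_backward <- function(model, caches, dlogits, B) {
  d <- act(dlogits, B, 1L)
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], d)
    d <- r$dx
    grads[i] <- list(r$grads)
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class-probability predictions
#'
#' Runs the model in inference mode (batch-norm running statistics, no
#' dropout) over all windows, in batches.
#'
#' @param model A model built by [build_model()].
#' @param x Array `[N, L, C]` of windows, or a single `[L, C]` matrix.
#' @param batch_size Inference batch size.
#' @return Matrix `[N, n_classes]` of softmax probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, x, batch_size = 256L) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  N <- dim(x)[1]
  out <- matrix(0, N, model$config$n_classes)
  for (s in seq.int(1L, N, by = batch_size)) {
    e <- min(s + batch_size - 1L, N)
    fw <- model_forward(model, x[s:e, , , drop = FALSE], training = FALSE,
                        keep_cache = FALSE)
    out[s:e, ] <- softmax_rows(fw$logits)
  }
  out
}

#' Hard-label predictions
#'
#' @inheritParams predict_proba
#' @return Integer vector of class labels in 0..2.
#' @export
predict_labels <- function(model, x, batch_size = 256L) {
  max.col(predict_proba(model, x, batch_size)) - 1L
}

## ---- parameter plumbing (Adam) -------------------------------------------

param_names <- function(layer) {
  switch(layer$type,
    conv1d = c("W", "b"), dense = c("W", "b"),
    batchnorm = c("gamma", "beta"), lstm = c("Wx", "Wh", "b"),
    character(0))
}

#' Number of trainable parameters
#' @param model A built model.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(param_names(l), function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    nms <- param_names(l)
    if (length(nms) == 0L) return(NULL)
    st <- lapply(nms, function(nm) list(m = l[[nm]] * 0, v = l[[nm]] * 0))
    names(st) <- nms
    st
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      s <- state[[i]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g[[nm]]
      s$v <- beta2 * s$v + (1 - beta2) * g[[nm]]^2
      model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      state[[i]][[nm]] <- s
    }
  }
  list(model = model, state = state)
}

# snapshot / restore trainable parameters and batch-norm buffers
model_snapshot <- function(model) {
  lapply(model$layers, function(l) {
    nms <- c(param_names(l), if (l$type == "batchnorm") c("running_mean", "running_var"))
    if (length(nms) == 0L) return(NULL)
    stats::setNames(lapply(nms, function(nm) l[[nm]]), nms)
  })
}

model_restore <- function(model, snap) {
  for (i in seq_along(snap)) {
    if (is.null(snap[[i]])) next
    for (nm in names(snap[[i]])) model$layers[[i]][[nm]] <- snap[[i]][[nm]]
  }
  model
}
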