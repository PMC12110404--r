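# Neural-network primitives.
#
# Activations travel as (C*H*W) x N matrices: one column per sample,
# channel blocks contiguous, spatial positions in column-major (H x W)
# order.  Parameters live in nested lists whose leaves are numeric arrays;
# gradients mirror the structure, and the optimizers walk both trees.

# ---- parameter-tree helpers -------------------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(x[[i]], y[[i]], f)
    out
  } else {
    f(x, y)
  }
}

tree_zeros <- function(x) tree_map(x, function(p) p * 0)

tree_flatten <- function(x) unlist(x, use.names = FALSE)

# ---- optimizers -------------------------------------------------------------

# Integer leaves in a parameter tree are structural metadata (kernel size,
# stride, ...) and are never touched by the optimizers.
is_weight <- function(p) is.double(p)

sgd_init <- function(params) list(vel = tree_zeros(params))

# Momentum SGD with L2 weight decay (decay applied to every weight).
sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  gd <- tree_map2(grads, params, function(g, p) {
    if (is_weight(p)) g + weight_decay * p else g
  })
  state$vel <- tree_map2(state$vel, gd, function(v, g) {
    if (is_weight(v)) momentum * v - lr * g else v
  })
  params <- tree_map2(params, state$vel, function(p, v) {
    if (is_weight(p)) p + v else p
  })
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) {
    if (is_weight(m)) beta1 * m + (1 - beta1) * g else m
  })
  state$v <- tree_map2(state$v, grads, function(v, g) {
    if (is_weight(v)) beta2 * v + (1 - beta2) * g^2 else v
  })
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    if (is_weight(m)) lr * (m / bc1) / (sqrt(v / bc2) + eps) else m
  })
  params <- tree_map2(params, upd, function(p, u) {
    if (is_weight(p)) p - u else p
  })
  list(params = params, state = state)
}

# ---- layer primitives -------------------------------------------------------

conv_fwd <- function(x, p, H, W) {
  conv2d_fwd_cpp(x, p$W, p$b, p$Cin, H, W, p$k, p$stride, p$pad)
}

conv_bwd <- function(x, p, dy, H, W) {
  conv2d_bwd_cpp(x, p$W, dy, p$Cin, H, W, p$k, p$stride, p$pad)
}

conv_init <- function(Cin, Cout, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  fan_in <- Cin * k * k
  list(W = matrix(stats::rnorm(Cout * fan_in, 0, sqrt(2 / fan_in)),
                  Cout, fan_in),
       b = numeric(Cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       Cin = as.integer(Cin), Cout = as.integer(Cout))
}

# Batch normalization over (spatial x batch) per channel.
bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C))
}

bn_buffers_init <- function(C) {
  list(mean = numeric(C), var = rep(1, C))
}

bn_fwd <- function(x, p, buf, HW, train, momentum = 0.1, eps = 1e-5,
                   update = TRUE) {
  C <- length(p$gamma)
  N <- ncol(x)
  if (train) {
    per_cn <- colMeans(matrix(x, HW, C * N))          # mean per (c, n)
    mu <- rowMeans(matrix(per_cn, C, N))
    per_cn2 <- colMeans(matrix(x^2, HW, C * N))
    m2 <- rowMeans(matrix(per_cn2, C, N))
    v <- m2 - mu^2
    if (update) {
      buf$mean <- (1 - momentum) * buf$mean + momentum * mu
      buf$var <- (1 - momentum) * buf$var + momentum * v
    }
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  mu_e <- rep(mu, each = HW)
  is_e <- rep(inv_sd, each = HW)
  xhat <- (x - mu_e) * is_e
  y <- xhat * rep(p$gamma, each = HW) + rep(p$beta, each = HW)
  list(y = y, buf = buf,
       cache = list(xhat = xhat, inv_sd = inv_sd, HW = HW, C = C, N = N,
                    train = train))
}

bn_bwd <- function(dy, p, cache) {
  HW <- cache$HW; C <- cache$C; N <- cache$N
  m <- HW * N
  sum_per_channel <- function(z) {
    rowSums(matrix(colMeans(matrix(z, HW, C * N)) * HW, C, N))
  }
  dgamma <- sum_per_channel(dy * cache$xhat)
  dbeta <- sum_per_channel(dy)
  dxhat <- dy * rep(p$gamma, each = HW)
  if (cache$train) {
    t1 <- rep(sum_per_channel(dxhat) / m, each = HW)
    t2 <- cache$xhat * rep(sum_per_channel(dxhat * cache$xhat) / m, each = HW)
    dx <- (dxhat - t1 - t2) * rep(cache$inv_sd, each = HW)
  } else {
    dx <- dxhat * rep(cache$inv_sd, each = HW)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, y) dy * (y > 0)

linear_init <- function(n_in, n_out, sd = NULL, zero = FALSE) {
  if (zero) {
    W <- matrix(0, n_out, n_in)
  } else {
    if (is.null(sd)) sd <- sqrt(2 / n_in)
    W <- matrix(stats::rnorm(n_out * n_in, 0, sd), n_out, n_in)
  }
  list(W = W, b = numeric(n_out))
}

linear_fwd <- function(x, p) p$W %*% x + p$b
linear_bwd <- function(x, p, dy) {
  list(dx = crossprod(p$W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# ---- self-attention over feature-map tokens --------------------------------

attn_init <- function(C) {
  sd <- 1 / sqrt(C)
  list(WQ = matrix(stats::rnorm(C * C, 0, sd), C, C),
       WK = matrix(stats::rnorm(C * C, 0, sd), C, C),
       WV = matrix(stats::rnorm(C * C, 0, sd), C, C))
}

# Row-wise softmax with the usual max-shift for stability.
row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# One self-attention head over the HW spatial tokens of each sample,
# residual-added: Y = X + softmax(Q K' / sqrt(d_k)) V.
attn_fwd <- function(x, p, HW, C) {
  N <- ncol(x)
  y <- x
  caches <- vector("list", N)
  dk <- sqrt(C)
  for (n in seq_len(N)) {
    Xt <- matrix(x[, n], HW, C)
    Q <- Xt %*% p$WQ
    K <- Xt %*% p$WK
    V <- Xt %*% p$WV
    A <- row_softmax(tcrossprod(Q, K) / dk)
    y[, n] <- as.numeric(Xt + A %*% V)
    caches[[n]] <- list(Xt = Xt, Q = Q, K = K, V = V, A = A)
  }
  list(y = y, cache = list(per_sample = caches, HW = HW, C = C))
}

attn_bwd <- function(dy, p, cache) {
  HW <- cache$HW; C <- cache$C
  N <- length(cache$per_sample)
  dk <- sqrt(C)
  dx <- dy
  dWQ <- matrix(0, C, C); dWK <- matrix(0, C, C); dWV <- matrix(0, C, C)
  for (n in seq_len(N)) {
    cs <- cache$per_sample[[n]]
    dYt <- matrix(dy[, n], HW, C)
    dV <- crossprod(cs$A, dYt)
    dA <- tcrossprod(dYt, cs$V)
    # softmax backward per row
    dS <- cs$A * (dA - rowSums(cs$A * dA))
    dQ <- (dS %*% cs$K) / dk
    dK <- (crossprod(dS, cs$Q)) / dk
    dWQ <- dWQ + crossprod(cs$Xt, dQ)
    dWK <- dWK + crossprod(cs$Xt, dK)
    dWV <- dWV + crossprod(cs$Xt, dV)
    dXt <- dYt +  # residual path
      tcrossprod(dQ, p$WQ) + tcrossprod(dK, p$WK) + tcrossprod(dV, p$WV)
    dx[, n] <- as.numeric(dXt)
  }
  list(dx = dx, dWQ = dWQ, dWK = dWK, dWV = dWV)
}

# ---- pooling and loss -------------------------------------------------------

gap_fwd <- function(x, HW, C) {
  N <- ncol(x)
  matrix(colMeans(matrix(x, HW, C * N)), C, N)
}

gap_bwd <- function(dpooled, HW) {
  C <- nrow(dpooled); N <- ncol(dpooled)
  matrix(rep(dpooled, each = HW), HW * C, N) / HW
}

#' Softmax cross-entropy loss
#'
#' The negative log softmax probability of the true class, averaged over
#' the batch.
#'
#' @param logits numeric matrix (classes x batch) or vector for one sample.
#' @param true_class integer class indices in `0:(K-1)`, recycled over the
#'   batch.
#' @return list with `loss` (scalar), `probs` (classes x batch) and
#'   `dlogits` (gradient of the mean loss).
#' @export
cross_entropy_loss <- function(logits, true_class) {
  if (is.vector(logits)) logits <- matrix(logits, ncol = 1)
  K <- nrow(logits); N <- ncol(logits)
  true_class <- rep_len(as.integer(true_class), N)
  if (any(true_class < 0L | true_class >= K)) {
    stop("true_class index out of range", call. = FALSE)
  }
  shifted <- sweep(logits, 2, apply(logits, 2, max))
  logZ <- log(colSums(exp(shifted)))
  logp <- sweep(shifted, 2, logZ)
  probs <- exp(logp)
  picked <- logp[cbind(true_class + 1L, seq_len(N))]
  onehot <- matrix(0, K, N)
  onehot[cbind(true_class + 1L, seq_len(N))] <- 1
  list(loss = -mean(picked), probs = probs, dlogits = (probs - onehot) / N)
}

#' Self-attention over spatial tokens
#'
#' Applies one attention head to a token matrix: `Q = X WQ`, `K = X WK`,
#' `V = X WV`, `A = softmax(Q K' / sqrt(d_k))` row-wise, and returns the
#' attended tokens added residually to the input.  Each row of `A` sums
#' to 1.
#'
#' @param X token matrix (tokens x channels).
#' @param layer list with square matrices `WQ`, `WK`, `WV` (channels x
#'   channels); `d_k` defaults to the channel count.
#' @return list with `A` (attention weights) and `Y` (tokens after the
#'   residual attention update).
#' @export
self_attention <- function(X, layer) {
  C <- ncol(X)
  if (nrow(layer$WQ) != C || nrow(layer$WK) != C || nrow(layer$WV) != C) {
    stop("attention weight dimension does not match token channels",
         call. = FALSE)
  }
  dk <- layer$d_k %||% C
  Q <- X %*% layer$WQ
  K <- X %*% layer$WK
  V <- X %*% layer$WV
  A <- row_softmax(tcrossprod(Q, K) / sqrt(dk))
  list(A = A, Y = X + A %*% V)
}
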