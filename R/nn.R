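# Self-contained neural-network engine: token embedding, multi-head
# self-attention encoder blocks (post-layer-norm, GELU feed-forward),
# bidirectional LSTM, dense sigmoid head, trained by Adam on binary
# cross-entropy. All activations use the layout X2 = matrix(T*B, d) whose row
# r = t + (b-1)*T holds timestep t of sample b, so linear layers are single
# matrix products and per-sample attention slices are contiguous row blocks.
# Analytic gradients are verified against central finite differences in the
# test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(cfg, vocab_size) {
  d <- cfg$embed_dim
  T_ <- cfg$seq_len
  u <- cfg$lstm_units
  p <- list(emb = list(E = matrix(rnorm(vocab_size * d, sd = 0.02), vocab_size, d)))
  if (cfg$variant == "contextual") {
    p$emb$P <- matrix(rnorm(T_ * d, sd = 0.02), T_, d)
    f <- 4L * d
    p$enc <- lapply(seq_len(cfg$n_layers), function(l) list(
      Wq = glorot(d, d), bq = numeric(d),
      Wk = glorot(d, d), bk = numeric(d),
      Wv = glorot(d, d), bv = numeric(d),
      Wo = glorot(d, d), bo = numeric(d),
      g1 = rep(1, d), be1 = numeric(d),
      W1 = glorot(d, f), b1 = numeric(f),
      W2 = glorot(f, d), b2 = numeric(d),
      g2 = rep(1, d), be2 = numeric(d)
    ))
  }
  lstm_init <- function(nin, u) {
    b <- numeric(4L * u)
    b[(u + 1L):(2L * u)] <- 1  # forget-gate bias starts open
    list(Wx = glorot(nin, 4L * u), Wh = glorot(u, 4L * u), b = b)
  }
  p$lstm_f <- lstm_init(d, u)
  p$lstm_b <- lstm_init(d, u)
  h1 <- cfg$dense_units[1L]
  h2 <- cfg$dense_units[2L]
  p$head <- list(
    Wd1 = glorot(2L * u, h1), bd1 = numeric(h1),
    Wd2 = glorot(h1, h2), bd2 = numeric(h2),
    Wout = glorot(h2, 1L), bout = numeric(1L)
  )
  p
}

n_params <- function(params) {
  sum(unlist(lapply(params, function(x) {
    if (is.list(x)) n_params(x) else length(x)
  })))
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

row_softmax <- function(S) {
  S <- exp(S - apply(S, 1L, max))
  S / rowSums(S)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / s
  list(out = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       xhat = xhat, s = s)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$s
  list(dX = dX, dg = dg, db = db)
}

make_dropout <- function(X, rate) {
  if (rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

drop_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

attention_fwd <- function(X2, lp, cfg, B) {
  T_ <- cfg$seq_len
  H <- cfg$n_heads
  dh <- cfg$embed_dim %/% H
  Q2 <- add_bias(X2 %*% lp$Wq, lp$bq)
  K2 <- add_bias(X2 %*% lp$Wk, lp$bk)
  V2 <- add_bias(X2 %*% lp$Wv, lp$bv)
  O2 <- matrix(0, nrow(X2), cfg$embed_dim)
  A <- array(0, c(T_, T_, H, B))
  sc <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T_ + 1L):(b * T_)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- row_softmax(tcrossprod(Q2[rows, cols, drop = FALSE],
                                   K2[rows, cols, drop = FALSE]) * sc)
      A[, , h, b] <- Ah
      O2[rows, cols] <- Ah %*% V2[rows, cols, drop = FALSE]
    }
  }
  out <- add_bias(O2 %*% lp$Wo, lp$bo)
  list(out = out, Q2 = Q2, K2 = K2, V2 = V2, O2 = O2, A = A)
}

attention_bwd <- function(dOut, cache, X2, lp, cfg, B) {
  T_ <- cfg$seq_len
  H <- cfg$n_heads
  dh <- cfg$embed_dim %/% H
  sc <- 1 / sqrt(dh)
  g <- list(
    Wo = crossprod(cache$O2, dOut), bo = colSums(dOut)
  )
  dO2 <- tcrossprod(dOut, lp$Wo)
  dQ2 <- matrix(0, nrow(X2), cfg$embed_dim)
  dK2 <- dQ2
  dV2 <- dQ2
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T_ + 1L):(b * T_)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- cache$A[, , h, b]
      dOh <- dO2[rows, cols, drop = FALSE]
      Vh <- cache$V2[rows, cols, drop = FALSE]
      dV2[rows, cols] <- crossprod(Ah, dOh)
      dA <- tcrossprod(dOh, Vh)
      dS <- Ah * (dA - rowSums(dA * Ah)) * sc
      dQ2[rows, cols] <- dS %*% cache$K2[rows, cols, drop = FALSE]
      dK2[rows, cols] <- crossprod(dS, cache$Q2[rows, cols, drop = FALSE])
    }
  }
  g$Wq <- crossprod(X2, dQ2); g$bq <- colSums(dQ2)
  g$Wk <- crossprod(X2, dK2); g$bk <- colSums(dK2)
  g$Wv <- crossprod(X2, dV2); g$bv <- colSums(dV2)
  dX <- tcrossprod(dQ2, lp$Wq) + tcrossprod(dK2, lp$Wk) +
    tcrossprod(dV2, lp$Wv)
  list(dX = dX, g = g)
}

lstm_fwd <- function(x_arr, lp, time_order, B, u) {
  H <- matrix(0, B, u)
  C <- matrix(0, B, u)
  steps <- vector("list", length(time_order))
  for (s in seq_along(time_order)) {
    t <- time_order[s]
    xt <- matrix(x_arr[t, , ], nrow = B)
    z <- add_bias(xt %*% lp$Wx + H %*% lp$Wh, lp$b)
    i <- sigmoid(z[, 1:u, drop = FALSE])
    f <- sigmoid(z[, (u + 1L):(2L * u), drop = FALSE])
    o <- sigmoid(z[, (2L * u + 1L):(3L * u), drop = FALSE])
    g <- tanh(z[, (3L * u + 1L):(4L * u), drop = FALSE])
    Cp <- C
    Hp <- H
    C <- f * C + i * g
    H <- o * tanh(C)
    steps[[s]] <- list(t = t, xt = xt, i = i, f = f, o = o, g = g,
                       Cp = Cp, Hp = Hp, C = C)
  }
  list(H = H, steps = steps)
}

lstm_bwd <- function(dH_final, fwd, lp, dX_arr, B, u) {
  gWx <- matrix(0, nrow(lp$Wx), ncol(lp$Wx))
  gWh <- matrix(0, u, 4L * u)
  gb <- numeric(4L * u)
  dH <- dH_final
  dC <- matrix(0, B, u)
  for (s in rev(seq_along(fwd$steps))) {
    st <- fwd$steps[[s]]
    tc <- tanh(st$C)
    do <- dH * tc
    dC <- dC + dH * st$o * (1 - tc^2)
    di <- dC * st$g
    dg <- dC * st$i
    df <- dC * st$Cp
    dz <- cbind(
      di * st$i * (1 - st$i),
      df * st$f * (1 - st$f),
      do * st$o * (1 - st$o),
      dg * (1 - st$g^2)
    )
    gWx <- gWx + crossprod(st$xt, dz)
    gWh <- gWh + crossprod(st$Hp, dz)
    gb <- gb + colSums(dz)
    dX_arr[st$t, , ] <- matrix(dX_arr[st$t, , ], nrow = B) + dz %*% t(lp$Wx)
    dH <- dz %*% t(lp$Wh)
    dC <- dC * st$f
  }
  list(g = list(Wx = gWx, Wh = gWh, b = gb), dX_arr = dX_arr)
}

# full forward pass; train = TRUE draws dropout masks from the R RNG
nn_forward <- function(params, tokens, cfg, train = FALSE) {
  B <- nrow(tokens)
  T_ <- cfg$seq_len
  d <- cfg$embed_dim
  v <- as.vector(t(tokens)) + 1L
  X2 <- params$emb$E[v, , drop = FALSE]
  if (cfg$variant == "contextual") {
    X2 <- X2 + params$emb$P[rep(seq_len(T_), B), , drop = FALSE]
  }
  rate <- if (train) cfg$dropout else 0
  cache <- list(v = v, B = B)
  dr <- make_dropout(X2, rate)
  X2 <- dr$out
  cache$emb_mask <- dr$mask
  if (cfg$variant == "contextual") {
    cache$enc <- vector("list", cfg$n_layers)
    for (l in seq_len(cfg$n_layers)) {
      lp <- params$enc[[l]]
      att <- attention_fwd(X2, lp, cfg, B)
      d1 <- make_dropout(att$out, rate)
      ln1 <- layernorm_fwd(X2 + d1$out, lp$g1, lp$be1)
      Z1 <- ln1$out
      pre <- add_bias(Z1 %*% lp$W1, lp$b1)
      act <- gelu(pre)
      ff <- add_bias(act %*% lp$W2, lp$b2)
      d2 <- make_dropout(ff, rate)
      ln2 <- layernorm_fwd(Z1 + d2$out, lp$g2, lp$be2)
      cache$enc[[l]] <- list(X_in = X2, att = att, d1 = d1$mask, ln1 = ln1,
                             Z1 = Z1, pre = pre, act = act, d2 = d2$mask,
                             ln2 = ln2)
      X2 <- ln2$out
    }
  }
  x_arr <- X2
  dim(x_arr) <- c(T_, B, d)
  u <- cfg$lstm_units
  fw <- lstm_fwd(x_arr, params$lstm_f, seq_len(T_), B, u)
  bw <- lstm_fwd(x_arr, params$lstm_b, rev(seq_len(T_)), B, u)
  Z <- cbind(fw$H, bw$H)
  hp <- params$head
  a1 <- add_bias(Z %*% hp$Wd1, hp$bd1)
  r1 <- pmax(a1, 0)
  dh1 <- make_dropout(r1, rate)
  a2 <- add_bias(dh1$out %*% hp$Wd2, hp$bd2)
  r2 <- pmax(a2, 0)
  dh2 <- make_dropout(r2, rate)
  logit <- dh2$out %*% hp$Wout + hp$bout
  prob <- sigmoid(logit)
  cache <- c(cache, list(
    X_final = X2, fw = fw, bw = bw, Z = Z, a1 = a1, h1m = dh1$mask,
    h1 = dh1$out, a2 = a2, h2m = dh2$mask, h2 = dh2$out, logit = logit
  ))
  list(prob = as.vector(prob), cache = cache)
}

nn_backward <- function(params, tokens, cfg, fwd, dlogit) {
  B <- nrow(tokens)
  T_ <- cfg$seq_len
  d <- cfg$embed_dim
  u <- cfg$lstm_units
  ca <- fwd$cache
  hp <- params$head
  g <- list(head = list())
  dlogit <- matrix(dlogit, ncol = 1L)
  g$head$Wout <- crossprod(ca$h2, dlogit)
  g$head$bout <- sum(dlogit)
  dh2 <- drop_bwd(tcrossprod(dlogit, hp$Wout), ca$h2m)
  da2 <- dh2 * (ca$a2 > 0)
  g$head$Wd2 <- crossprod(ca$h1, da2)
  g$head$bd2 <- colSums(da2)
  dh1 <- drop_bwd(da2 %*% t(hp$Wd2), ca$h1m)
  da1 <- dh1 * (ca$a1 > 0)
  g$head$Wd1 <- crossprod(ca$Z, da1)
  g$head$bd1 <- colSums(da1)
  dZ <- da1 %*% t(hp$Wd1)

  dX_arr <- array(0, c(T_, B, d))
  bf <- lstm_bwd(dZ[, 1:u, drop = FALSE], ca$fw, params$lstm_f, dX_arr, B, u)
  g$lstm_f <- bf$g
  bb <- lstm_bwd(dZ[, (u + 1L):(2L * u), drop = FALSE], ca$bw, params$lstm_b,
                 bf$dX_arr, B, u)
  g$lstm_b <- bb$g
  dX2 <- bb$dX_arr
  dim(dX2) <- c(T_ * B, d)

  if (cfg$variant == "contextual") {
    g$enc <- vector("list", cfg$n_layers)
    for (l in rev(seq_len(cfg$n_layers))) {
      lp <- params$enc[[l]]
      cl <- ca$enc[[l]]
      b2 <- layernorm_bwd(dX2, cl$ln2, lp$g2)
      lg <- list(g2 = b2$dg, be2 = b2$db)
      dff <- drop_bwd(b2$dX, cl$d2)
      lg$W2 <- crossprod(cl$act, dff)
      lg$b2 <- colSums(dff)
      dact <- dff %*% t(lp$W2)
      dpre <- dact * gelu_grad(cl$pre)
      lg$W1 <- crossprod(cl$Z1, dpre)
      lg$b1 <- colSums(dpre)
      dZ1 <- b2$dX + dpre %*% t(lp$W1)
      b1 <- layernorm_bwd(dZ1, cl$ln1, lp$g1)
      lg$g1 <- b1$dg
      lg$be1 <- b1$db
      datt <- drop_bwd(b1$dX, cl$d1)
      ab <- attention_bwd(datt, cl$att, cl$X_in, lp, cfg, B)
      lg <- c(lg, ab$g)
      dX2 <- b1$dX + ab$dX
      g$enc[[l]] <- lg
    }
  }
  dX2 <- drop_bwd(dX2, ca$emb_mask)
  gE <- matrix(0, nrow(params$emb$E), d)
  rs <- rowsum(dX2, ca$v)
  gE[as.integer(rownames(rs)), ] <- rs
  g$emb <- list(E = gE)
  if (cfg$variant == "contextual") {
    g$emb$P <- rowsum(dX2, rep(seq_len(T_), B))
  }
  g
}

# Adam with bias correction, applied over the nested parameter tree
adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

nn_loss_grad <- function(prob, y, pos_weight = 1) {
  eps <- 1e-12
  w <- ifelse(y == 1, pos_weight, 1)
  loss <- -mean(w * (y * log(prob + eps) + (1 - y) * log(1 - prob + eps)))
  dlogit <- w * (prob - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}
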