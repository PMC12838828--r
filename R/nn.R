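# Minimal batched neural-network primitives with hand-written backward
# passes: linear layers, 1-D convolution via im2col, GRU cell, and Adam.
# All forward functions take B x (...) batches and return caches sufficient
# for the exact gradient; everything is plain matrix algebra so the whole
# agent trains on one CPU.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

linear_fwd <- function(x, w, b) {
  y <- x %*% w
  sweep(y, 2L, b, "+")
}

# returns list(dx, dw, db)
linear_bwd <- function(x, w, dy) {
  list(dx = dy %*% t(w), dw = crossprod(x, dy), db = colSums(dy))
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(y, dy) dy * (y > 0)

sigm <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Gradient of log softmax probability of the chosen class w.r.t. logits:
# one-hot(chosen) - probs. Shared by the agent update and the enumeration
# check of the policy-gradient estimator.
softmax_logprob_grad <- function(probs, chosen) {
  g <- -probs
  g[cbind(seq_len(nrow(probs)), chosen)] <-
    g[cbind(seq_len(nrow(probs)), chosen)] + 1
  g
}

# --- 1-D convolution (valid, stride 1) via im2col --------------------------
# x: array (B, Cin, L); w: (Cin * kern) x F; returns y (B, P, F) with
# P = L - kern + 1, plus the im2col matrix for the backward pass.
conv1d_fwd <- function(x, w, b, kern) {
  d <- dim(x)
  bsz <- d[1]; cin <- d[2]; l <- d[3]
  p <- l - kern + 1L
  cols <- array(0, c(bsz, p, cin * kern))
  for (ci in seq_len(cin))
    for (j in seq_len(kern))
      cols[, , (ci - 1L) * kern + j] <- x[, ci, j:(j + p - 1L)]
  mat <- matrix(cols, bsz * p, cin * kern)
  y <- sweep(mat %*% w, 2L, b, "+")
  list(y = array(y, c(bsz, p, ncol(w))), mat = mat,
       dims = c(bsz = bsz, cin = cin, l = l, p = p, kern = kern))
}

conv1d_bwd <- function(cache, w, dy) {
  dm <- cache$dims
  dym <- matrix(dy, dm["bsz"] * dm["p"], dim(dy)[3])
  dw <- crossprod(cache$mat, dym)
  db <- colSums(dym)
  dcols <- array(dym %*% t(w), c(dm["bsz"], dm["p"], dm["cin"] * dm["kern"]))
  dx <- array(0, c(dm["bsz"], dm["cin"], dm["l"]))
  for (ci in seq_len(dm["cin"]))
    for (j in seq_len(dm["kern"])) {
      rng <- j:(j + dm["p"] - 1L)
      dx[, ci, rng] <- dx[, ci, rng] + dcols[, , (ci - 1L) * dm["kern"] + j]
    }
  list(dx = dx, dw = dw, db = db)
}

# Mean pooling over the position axis of a (B, P, F) array -> (B, F).
pool_fwd <- function(x) colSums(aperm(x, c(2, 1, 3))) / dim(x)[2]

pool_bwd <- function(dy, p) {
  bsz <- nrow(dy); f <- ncol(dy)
  dx <- array(0, c(bsz, p, f))
  for (i in seq_len(p)) dx[, i, ] <- dy / p
  dx
}

# --- GRU cell --------------------------------------------------------------
gru_init <- function(in_dim, hidden) {
  list(wz = glorot(in_dim, hidden), uz = glorot(hidden, hidden),
       bz = numeric(hidden),
       wr = glorot(in_dim, hidden), ur = glorot(hidden, hidden),
       br = numeric(hidden),
       wn = glorot(in_dim, hidden), un = glorot(hidden, hidden),
       bn = numeric(hidden), bhn = numeric(hidden))
}

gru_fwd <- function(x, h, p) {
  z <- sigm(sweep(x %*% p$wz + h %*% p$uz, 2L, p$bz, "+"))
  r <- sigm(sweep(x %*% p$wr + h %*% p$ur, 2L, p$br, "+"))
  hun <- sweep(h %*% p$un, 2L, p$bhn, "+")
  nn <- tanh(sweep(x %*% p$wn + r * hun, 2L, p$bn, "+"))
  h_new <- (1 - z) * nn + z * h
  list(h = h_new, cache = list(x = x, h_prev = h, z = z, r = r, nn = nn,
                               hun = hun))
}

gru_bwd <- function(cache, p, dh_new, grads) {
  z <- cache$z; r <- cache$r; nn <- cache$nn
  dz <- dh_new * (cache$h_prev - nn)
  dnn <- dh_new * (1 - z)
  dh <- dh_new * z
  dnn_pre <- dnn * (1 - nn^2)
  dr <- dnn_pre * cache$hun
  dhun <- dnn_pre * r
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  x <- cache$x; hp <- cache$h_prev
  grads$wz <- grads$wz + crossprod(x, dz_pre)
  grads$uz <- grads$uz + crossprod(hp, dz_pre)
  grads$bz <- grads$bz + colSums(dz_pre)
  grads$wr <- grads$wr + crossprod(x, dr_pre)
  grads$ur <- grads$ur + crossprod(hp, dr_pre)
  grads$br <- grads$br + colSums(dr_pre)
  grads$wn <- grads$wn + crossprod(x, dnn_pre)
  grads$un <- grads$un + crossprod(hp, dhun)
  grads$bn <- grads$bn + colSums(dnn_pre)
  grads$bhn <- grads$bhn + colSums(dhun)
  dx <- dz_pre %*% t(p$wz) + dr_pre %*% t(p$wr) + dnn_pre %*% t(p$wn)
  dh <- dh + dz_pre %*% t(p$uz) + dr_pre %*% t(p$ur) + dhun %*% t(p$un)
  list(dx = dx, dh = dh, grads = grads)
}

# --- Adam ------------------------------------------------------------------
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# Gradient-ascent Adam step: `grads` point uphill on the objective.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] + lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
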