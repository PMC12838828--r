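#' Multi-scale glimpse sensor configuration
#'
#' @param n_scales number of concentric windows (>= 1).
#' @param base_length finest window length in samples (>= 4, even).
#' @param scale_factor length multiplier between scales (>= 2).
#' @return A `glimpse_config`.
#' @export
glimpse_config <- function(n_scales = 3L, base_length = 16L,
                           scale_factor = 2L) {
  if (n_scales < 1 || base_length < 4 || scale_factor < 2)
    stop("need n_scales >= 1, base_length >= 4, scale_factor >= 2")
  if (base_length %% 2 != 0) stop("base_length must be even")
  structure(list(n_scales = as.integer(n_scales),
                 base_length = as.integer(base_length),
                 scale_factor = as.integer(scale_factor)),
            class = "glimpse_config")
}

#' Extract a multi-scale glimpse from a sequence
#'
#' Windows of length `base_length * scale_factor^(k-1)` centred at the
#' normalized location `l` in [-1, 1] are extracted (zero-padded outside
#' the sequence) and each is block-averaged down to `base_length` samples,
#' so resolution is finest at the centre scale and coarsens outward.
#'
#' @param x numeric sequence (length >= base_length).
#' @param l location in [-1, 1]; -1 is the first sample, +1 the last.
#' @param cfg a `glimpse_config`.
#' @return `n_scales` x `base_length` matrix, scale 1 (finest) first.
#' @export
glimpse <- function(x, l, cfg = glimpse_config()) {
  n <- length(x)
  if (n < cfg$base_length) stop("sequence shorter than base_length")
  if (l < -1 || l > 1) stop("location must lie in [-1, 1]")
  centre <- floor((l + 1) / 2 * (n - 1)) + 1L
  out <- matrix(0, cfg$n_scales, cfg$base_length)
  for (s in seq_len(cfg$n_scales)) {
    f <- cfg$scale_factor^(s - 1L)
    len <- cfg$base_length * f
    start <- centre - ceiling(len / 2) + 1L
    idx <- start:(start + len - 1L)
    vals <- numeric(len)
    ok <- idx >= 1L & idx <= n
    vals[ok] <- x[idx[ok]]
    out[s, ] <- colMeans(matrix(vals, f, cfg$base_length))
  }
  out
}

#' Training configuration for the glimpse agent
#'
#' Optimization defaults follow the reference protocol: Adam at learning
#' rate 0.001, discount 0.9, batch size 128, 500 epochs, dropout 0.2, and
#' epsilon-greedy exploration decaying from 1.0 to 0.1 over the first 1000
#' episodes. Network sizes (T = 6 glimpses, 3 scales of 16 samples,
#' two 1-D conv layers, GRU hidden size 128) are package defaults, exposed
#' here.
#'
#' @param learning_rate Adam step size.
#' @param gamma reward discount in (0, 1].
#' @param epochs maximum training epochs.
#' @param batch_size Monte-Carlo episodes per update (Eq.-9 sample count).
#' @param epsilon_start,epsilon_end,epsilon_decay_episodes exploration
#'   schedule (linear decay over episodes).
#' @param dropout dropout rate on the glimpse feature layer.
#' @param n_glimpses glimpses (decision steps) per episode.
#' @param train_fraction fraction of the data used for training; the rest
#'   is the held-out evaluation split.
#' @param patience early-stopping patience (epochs without validation
#'   reward improvement).
#' @param sigma_loc SD of the Gaussian location policy (normalized units).
#' @param max_grad_norm global gradient-norm clip applied before the Adam
#'   step (standard stabilizer for recurrent policy gradients; `Inf`
#'   disables).
#' @param hidden recurrent/core state size.
#' @param glimpse_feat glimpse feature dimension.
#' @param conv_channels,kernels channel counts and kernel sizes of the two
#'   conv layers.
#' @param glimpse glimpse sensor configuration.
#' @param seed master seed fanned out to split, init, and sampling.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, gamma = 0.9, epochs = 500L,
                         batch_size = 128L, epsilon_start = 1.0,
                         epsilon_end = 0.1, epsilon_decay_episodes = 1000L,
                         dropout = 0.2, n_glimpses = 6L,
                         train_fraction = 0.75, patience = 20L,
                         sigma_loc = 0.1, max_grad_norm = 5,
                         hidden = 128L, glimpse_feat = 64L,
                         conv_channels = c(8L, 16L), kernels = c(5L, 3L),
                         glimpse = glimpse_config(), seed = 1L) {
  stopifnot(gamma > 0, gamma <= 1, epsilon_start >= 0, epsilon_start <= 1,
            epsilon_end >= 0, epsilon_end <= 1, epochs >= 1,
            batch_size >= 1, n_glimpses >= 1, dropout >= 0, dropout < 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(learning_rate = learning_rate, gamma = gamma,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 epsilon_decay_episodes = as.integer(epsilon_decay_episodes),
                 dropout = dropout, n_glimpses = as.integer(n_glimpses),
                 train_fraction = train_fraction,
                 patience = as.integer(patience), sigma_loc = sigma_loc,
                 max_grad_norm = max_grad_norm,
                 hidden = as.integer(hidden),
                 glimpse_feat = as.integer(glimpse_feat),
                 conv_channels = as.integer(conv_channels),
                 kernels = as.integer(kernels), glimpse = glimpse,
                 seed = as.integer(seed)),
            class = "train_config")
}

epsilon_at <- function(cfg, episodes_seen) {
  frac <- min(1, episodes_seen / cfg$epsilon_decay_episodes)
  cfg$epsilon_start - (cfg$epsilon_start - cfg$epsilon_end) * frac
}

#' Initialize an agent policy
#'
#' Builds the parameter set of the chosen architecture: a glimpse encoder
#' (two 1-D conv layers with mean pooling, or a dense layer for the
#' conv-free variant), a feature combiner that also ingests the glimpse
#' location and any static features, a recurrent GRU core (or a stateless
#' tanh layer for `cnn_rl`), and linear heads for location mean, action
#' distribution, and the scalar value baseline.
#'
#' @param n_class number of action classes (>= 2).
#' @param architecture `"cnn_gru_rl"` (default), `"cnn_rl"` (no
#'   recurrence) or `"gru_rl"` (dense encoder instead of convolutions).
#' @param static_dim length of the static feature vector appended at each
#'   step (0 for none).
#' @param cfg a `train_config` supplying network sizes and the glimpse
#'   sensor configuration.
#' @param seed parameter-initialization seed.
#' @return An `agent_policy`.
#' @export
agent_policy <- function(n_class, architecture = c("cnn_gru_rl", "cnn_rl",
                                                   "gru_rl"),
                         static_dim = 0L, cfg = train_config(), seed = 1L) {
  architecture <- match.arg(architecture)
  if (n_class < 2) stop("need at least 2 classes")
  gc_ <- cfg$glimpse
  f1 <- cfg$conv_channels[1]; f2 <- cfg$conv_channels[2]
  k1 <- cfg$kernels[1]; k2 <- cfg$kernels[2]
  h <- cfg$hidden; g <- cfg$glimpse_feat
  par <- withr::with_seed(seed, {
    p <- list()
    if (architecture %in% c("cnn_gru_rl", "cnn_rl")) {
      p$wc1 <- glorot(gc_$n_scales * k1, f1); p$bc1 <- numeric(f1)
      p$wc2 <- glorot(f1 * k2, f2);          p$bc2 <- numeric(f2)
      feat_dim <- f2
    } else {
      p$wenc <- glorot(gc_$n_scales * gc_$base_length, f2)
      p$benc <- numeric(f2)
      feat_dim <- f2
    }
    p$wg <- glorot(feat_dim + 1L + static_dim, g); p$bg <- numeric(g)
    if (architecture %in% c("cnn_gru_rl", "gru_rl")) {
      p <- c(p, gru_init(g, h))
    } else {
      p$wh <- glorot(g, h); p$bh <- numeric(h)
    }
    p$wl <- glorot(h, 1L); p$bl <- numeric(1L)
    p$wa <- glorot(h, n_class); p$ba <- numeric(n_class)
    p$wb <- glorot(h, 1L); p$bb <- numeric(1L)
    p
  })
  structure(list(par = par, architecture = architecture,
                 n_class = as.integer(n_class),
                 static_dim = as.integer(static_dim),
                 glimpse = gc_, hidden = h, glimpse_feat = g,
                 conv_channels = c(f1, f2), kernels = c(k1, k2),
                 sigma_loc = cfg$sigma_loc, seed = seed,
                 opt = NULL),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  n_par <- sum(vapply(x$par, length, integer(1)))
  cat(sprintf("<agent_policy> %s, %d classes, hidden %d, %d parameters\n",
              x$architecture, x$n_class, x$hidden, n_par))
  invisible(x)
}

recurrent <- function(policy) policy$architecture %in% c("cnn_gru_rl",
                                                         "gru_rl")

# One batched forward step of the agent core. gstack: (B, n_scales, base).
step_fwd <- function(policy, h, gstack, l_prev, static, drop_mask = NULL) {
  p <- policy$par
  cache <- list(gstack = gstack, l_prev = l_prev)
  if (policy$architecture %in% c("cnn_gru_rl", "cnn_rl")) {
    c1 <- conv1d_fwd(gstack, p$wc1, p$bc1, policy$kernels[1])
    a1 <- relu_fwd(c1$y)
    a1p <- aperm(a1, c(1, 3, 2))           # (B, F1, P1) for the next conv
    c2 <- conv1d_fwd(a1p, p$wc2, p$bc2, policy$kernels[2])
    a2 <- relu_fwd(c2$y)
    feat <- pool_fwd(a2)
    cache <- c(cache, list(c1 = c1, a1 = a1, c2 = c2, a2 = a2))
  } else {
    flat <- matrix(gstack, dim(gstack)[1],
                   dim(gstack)[2] * dim(gstack)[3])
    pre <- linear_fwd(flat, p$wenc, p$benc)
    feat <- relu_fwd(pre)
    cache <- c(cache, list(flat = flat, enc = feat))
  }
  inp <- cbind(feat, l_prev, static)
  gf_pre <- linear_fwd(inp, p$wg, p$bg)
  gf <- relu_fwd(gf_pre)
  gfd <- if (is.null(drop_mask)) gf else gf * drop_mask
  if (recurrent(policy)) {
    gr <- gru_fwd(gfd, h, p)
    h_new <- gr$h
    cache$gru <- gr$cache
  } else {
    h_new <- tanh(linear_fwd(gfd, p$wh, p$bh))
    cache$h_core <- h_new
  }
  loc_mean <- tanh(linear_fwd(h_new, p$wl, p$bl))
  logits <- linear_fwd(h_new, p$wa, p$ba)
  probs <- softmax_rows(logits)
  baseline <- as.numeric(linear_fwd(h_new, p$wb, p$bb))
  cache <- c(cache, list(inp = inp, gf = gf, drop_mask = drop_mask,
                         gfd = gfd, h_prev = h, h_new = h_new,
                         loc_mean = loc_mean, probs = probs))
  list(h = h_new, loc_mean = as.numeric(loc_mean), probs = probs,
       baseline = baseline, cache = cache)
}

# Backward through one step. Returns dh_prev and accumulates grads.
step_bwd <- function(policy, cache, dh_new, dlogits, dmu, dbase, grads) {
  p <- policy$par
  h_new <- cache$h_new
  # heads
  la <- linear_bwd(h_new, p$wa, dlogits)
  grads$wa <- grads$wa + la$dw; grads$ba <- grads$ba + la$db
  dh <- dh_new + la$dx
  dmu_pre <- dmu * (1 - cache$loc_mean^2)
  ll <- linear_bwd(h_new, p$wl, dmu_pre)
  grads$wl <- grads$wl + ll$dw; grads$bl <- grads$bl + ll$db
  dh <- dh + ll$dx
  # value head: regressed to returns, detached from the policy path
  lb <- linear_bwd(h_new, p$wb, dbase)
  grads$wb <- grads$wb + lb$dw; grads$bb <- grads$bb + lb$db
  # core
  if (recurrent(policy)) {
    gb <- gru_bwd(cache$gru, p, dh, grads)
    grads <- gb$grads
    dgfd <- gb$dx
    dh_prev <- gb$dh
  } else {
    dpre <- dh * (1 - cache$h_core^2)
    lh <- linear_bwd(cache$gfd, p$wh, dpre)
    grads$wh <- grads$wh + lh$dw; grads$bh <- grads$bh + lh$db
    dgfd <- lh$dx
    dh_prev <- matrix(0, nrow(dh), ncol(dh))
  }
  if (!is.null(cache$drop_mask)) dgfd <- dgfd * cache$drop_mask
  dgf_pre <- relu_bwd(cache$gf, dgfd)
  lg <- linear_bwd(cache$inp, p$wg, dgf_pre)
  grads$wg <- grads$wg + lg$dw; grads$bg <- grads$bg + lg$db
  dfeat <- lg$dx[, seq_len(ncol(lg$dx) - 1L - policy$static_dim),
                 drop = FALSE]
  if (policy$architecture %in% c("cnn_gru_rl", "cnn_rl")) {
    dpool <- pool_bwd(dfeat, dim(cache$a2)[2])
    da2 <- relu_bwd(cache$a2, dpool)
    cb2 <- conv1d_bwd(cache$c2, p$wc2, da2)
    grads$wc2 <- grads$wc2 + cb2$dw; grads$bc2 <- grads$bc2 + cb2$db
    da1 <- aperm(cb2$dx, c(1, 3, 2))
    da1 <- relu_bwd(cache$a1, da1)
    cb1 <- conv1d_bwd(cache$c1, p$wc1, da1)
    grads$wc1 <- grads$wc1 + cb1$dw; grads$bc1 <- grads$bc1 + cb1$db
  } else {
    denc <- relu_bwd(cache$enc, dfeat)
    le <- linear_bwd(cache$flat, p$wenc, denc)
    grads$wenc <- grads$wenc + le$dw; grads$benc <- grads$benc + le$db
  }
  list(dh_prev = dh_prev, grads = grads)
}

# Batched episode roll-out. `forced` replays recorded trajectories (same
# locations/actions/dropout masks) to compute caches and log-probabilities
# at the current parameters.
run_batch <- function(policy, xs, statics, labels, cfg,
                      epsilon = 0, stochastic = TRUE, eval_mode = FALSE,
                      dropout = 0, forced = NULL, keep_caches = FALSE) {
  b <- length(xs)
  tt <- cfg$n_glimpses
  gc_ <- policy$glimpse
  h <- matrix(0, b, policy$hidden)
  l <- rep(0, b)
  locations <- loc_means <- matrix(0, b, tt)
  actions <- matrix(0L, b, tt)
  rewards <- baselines <- matrix(0, b, tt)
  probs <- vector("list", tt)
  caches <- if (keep_caches) vector("list", tt) else NULL
  masks <- vector("list", tt)
  for (t in seq_len(tt)) {
    gstack <- array(0, c(b, gc_$n_scales, gc_$base_length))
    for (i in seq_len(b)) gstack[i, , ] <- glimpse(xs[[i]], l[i], gc_)
    mask <- NULL
    if (!is.null(forced)) {
      mask <- forced$masks[[t]]
    } else if (dropout > 0) {
      mask <- matrix(stats::rbinom(b * policy$glimpse_feat, 1L,
                                   1 - dropout) / (1 - dropout),
                     b, policy$glimpse_feat)
    }
    st <- step_fwd(policy, h, gstack, l, statics, mask)
    h <- st$h
    loc_means[, t] <- st$loc_mean
    baselines[, t] <- st$baseline
    probs[[t]] <- st$probs
    if (!is.null(forced)) {
      l_t <- forced$locations[, t]
      a_t <- forced$actions[, t]
    } else {
      l_t <- if (stochastic)
        pmin(1, pmax(-1, st$loc_mean +
                       stats::rnorm(b, 0, policy$sigma_loc)))
      else st$loc_mean
      if (eval_mode) {
        a_t <- argmax_rows(st$probs)
      } else {
        a_t <- vapply(seq_len(b), function(i)
          sample.int(policy$n_class, 1L, prob = st$probs[i, ]), integer(1))
        if (epsilon > 0) {
          explore <- stats::runif(b) < epsilon
          if (any(explore))
            a_t[explore] <- sample.int(policy$n_class, sum(explore),
                                       replace = TRUE)
        }
      }
    }
    locations[, t] <- l_t
    actions[, t] <- a_t
    rewards[, t] <- as.numeric(a_t == labels)
    masks[t] <- list(mask)   # keep NULL entries (no dropout) in place
    if (keep_caches) caches[[t]] <- st$cache
    l <- l_t
  }
  # discounted returns-to-go
  g <- matrix(0, b, tt)
  g[, tt] <- rewards[, tt]
  if (tt > 1)
    for (t in (tt - 1):1) g[, t] <- rewards[, t] + cfg$gamma * g[, t + 1]
  list(locations = locations, loc_means = loc_means, actions = actions,
       rewards = rewards, returns = g, R = g[, 1], probs = probs,
       baselines = baselines, caches = caches, masks = masks,
       predictions = actions[, tt])
}

statics_matrix <- function(policy, statics, b) {
  if (policy$static_dim == 0L) return(matrix(0, b, 0L))
  m <- do.call(rbind, statics)
  if (ncol(m) != policy$static_dim)
    stop("static feature dimension mismatch")
  m
}

#' One deterministic core update (Eq.-5 style step)
#'
#' Encodes a glimpse stack and performs one recurrent update of the hidden
#' state; pure function of its inputs.
#'
#' @param policy an `agent_policy`.
#' @param h_prev hidden state vector (length `policy$hidden`).
#' @param g glimpse stack (n_scales x base_length matrix).
#' @param l_prev location the glimpse was taken at (default 0).
#' @param static optional static feature vector.
#' @return New hidden state vector.
#' @export
core_step <- function(policy, h_prev, g, l_prev = 0, static = NULL) {
  if (length(h_prev) != policy$hidden) stop("h_prev has wrong length")
  gd <- dim(g)
  if (is.null(gd) || gd[1] != policy$glimpse$n_scales ||
      gd[2] != policy$glimpse$base_length)
    stop("glimpse stack must be n_scales x base_length")
  gstack <- array(0, c(1L, gd[1], gd[2]))
  gstack[1, , ] <- g
  static_m <- if (policy$static_dim > 0L)
    matrix(static, 1L, policy$static_dim) else matrix(0, 1L, 0L)
  st <- step_fwd(policy, matrix(h_prev, 1L), gstack, l_prev, static_m)
  as.numeric(st$h)
}

#' Sample (or read off) the next glimpse location
#'
#' @param policy an `agent_policy`.
#' @param h_t hidden state vector.
#' @param stochastic add Gaussian noise `sigma_loc` and clip to [-1, 1];
#'   when `FALSE`, return the location-head mean.
#' @param seed optional seed for the draw.
#' @return Location in [-1, 1].
#' @export
sample_location <- function(policy, h_t, stochastic = TRUE, seed = NULL) {
  mu <- as.numeric(tanh(linear_fwd(matrix(h_t, 1L), policy$par$wl,
                                   policy$par$bl)))
  if (!stochastic) return(mu)
  draw <- function() mu + stats::rnorm(1, 0, policy$sigma_loc)
  val <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  min(1, max(-1, val))
}

#' Choose a class action
#'
#' With probability `1 - epsilon` the action is drawn from the policy's
#' softmax distribution (or its argmax in eval mode); with probability
#' `epsilon` it is uniform over classes.
#'
#' @param policy an `agent_policy`.
#' @param h_t hidden state vector.
#' @param epsilon exploration rate in [0, 1].
#' @param seed optional seed.
#' @param eval_mode take the argmax instead of sampling.
#' @return List with `action` (class index) and `probs`.
#' @export
act <- function(policy, h_t, epsilon = 0, seed = NULL, eval_mode = FALSE) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  logits <- linear_fwd(matrix(h_t, 1L), policy$par$wa, policy$par$ba)
  probs <- as.numeric(softmax_rows(logits))
  pick <- function() {
    if (eval_mode && epsilon == 0) return(which.max(probs))
    if (stats::runif(1) < epsilon) sample.int(policy$n_class, 1L)
    else sample.int(policy$n_class, 1L, prob = probs)
  }
  action <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  list(action = action, probs = probs)
}

#' Run one classification episode
#'
#' T glimpse/update/act steps; the reward is 1 whenever the step's action
#' matches the true label, the episode return is `R = sum_t gamma^(t-1)
#' r_t`, and the final step's action is the episode's prediction.
#'
#' @param policy an `agent_policy`.
#' @param x observation sequence (e.g. a GFP amplitude series).
#' @param true_label integer class of `x`.
#' @param cfg a `train_config` (supplies T, gamma, sigma_loc).
#' @param seed seed for the stochastic draws.
#' @param epsilon exploration rate.
#' @param stochastic sample locations/actions (`FALSE` for the
#'   deterministic greedy roll-out).
#' @param static optional static feature vector.
#' @return An `rl_episode` with locations, actions, rewards, returns-to-go,
#'   total return `R`, and the step probabilities.
#' @export
run_episode <- function(policy, x, true_label, cfg = train_config(),
                        seed = 1L, epsilon = 0, stochastic = TRUE,
                        static = NULL) {
  statics <- statics_matrix(policy,
                            if (is.null(static)) NULL else list(static), 1L)
  out <- withr::with_seed(seed,
    run_batch(policy, list(x), statics, true_label, cfg,
              epsilon = epsilon, stochastic = stochastic,
              eval_mode = !stochastic))
  structure(list(x = x, static = static, label = true_label,
                 locations = out$locations[1, ], actions = out$actions[1, ],
                 rewards = out$rewards[1, ], returns = out$returns[1, ],
                 R = out$R[1], gamma = cfg$gamma,
                 probs = do.call(rbind, lapply(out$probs, function(p) p[1, ])),
                 baselines = out$baselines[1, ],
                 masks = lapply(out$masks, function(m)
                   if (is.null(m)) NULL else m[1, , drop = FALSE]),
                 prediction = out$predictions[1]),
            class = "rl_episode")
}

#' @export
print.rl_episode <- function(x, ...) {
  cat(sprintf("<rl_episode> T = %d, R = %.3f, prediction = %d (true %d)\n",
              length(x$actions), x$R, x$prediction, x$label))
  invisible(x)
}

#' REINFORCE-with-baseline update
#'
#' Replays a batch of recorded episodes at the current parameters and takes
#' one Adam ascent step on the Monte-Carlo policy gradient
#' `(1/M) sum_i sum_t grad log pi(u_t | s_1:t) * (G_t - b(s_t))`, where
#' `u_t` is the (location, action) pair (log-probabilities add), `G_t` the
#' discounted return-to-go, and `b` the learned value baseline. The value
#' head is regressed to `G_t` by squared error; its gradient is confined
#' to the head (the advantage is treated as a constant elsewhere).
#'
#' @param policy an `agent_policy`.
#' @param episodes non-empty list of `rl_episode` objects of equal length
#'   and compatible inputs.
#' @param cfg a `train_config`.
#' @return List with the updated `policy` and `diagnostics` (mean return,
#'   mean advantage, gradient norm).
#' @export
reinforce_update <- function(policy, episodes, cfg = train_config()) {
  if (length(episodes) == 0) stop("empty episode batch")
  b <- length(episodes)
  xs <- lapply(episodes, `[[`, "x")
  labels <- vapply(episodes, function(e) as.numeric(e$label), numeric(1))
  statics <- statics_matrix(policy, lapply(episodes, `[[`, "static"), b)
  tt <- length(episodes[[1]]$actions)
  if (tt != cfg$n_glimpses)
    stop("episodes were generated with a different glimpse count")
  forced <- list(
    locations = do.call(rbind, lapply(episodes, `[[`, "locations")),
    actions = do.call(rbind, lapply(episodes, `[[`, "actions")),
    masks = lapply(seq_len(tt), function(t) {
      ms <- lapply(episodes, function(e) e$masks[[t]])
      if (all(vapply(ms, is.null, logical(1)))) NULL
      else do.call(rbind, ms)
    })
  )
  fwd <- run_batch(policy, xs, statics, labels, cfg, forced = forced,
                   keep_caches = TRUE)
  grads <- zeros_like(policy$par)
  dh <- matrix(0, b, policy$hidden)
  sig2 <- policy$sigma_loc^2
  adv_all <- fwd$returns - fwd$baselines
  for (t in seq(tt, 1L)) {
    adv <- adv_all[, t]
    dlogits <- softmax_logprob_grad(fwd$probs[[t]], fwd$actions[, t]) *
      (adv / b)
    dmu <- matrix((fwd$locations[, t] - fwd$loc_means[, t]) / sig2 *
                    adv / b, b, 1L)
    dbase <- matrix((fwd$returns[, t] - fwd$baselines[, t]) / b, b, 1L)
    sb <- step_bwd(policy, fwd$caches[[t]], dh, dlogits, dmu, dbase, grads)
    grads <- sb$grads
    dh <- sb$dh_prev
  }
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  clip <- cfg$max_grad_norm %||% Inf
  if (is.finite(clip) && gnorm > clip)
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  if (is.null(policy$opt)) policy$opt <- adam_init(policy$par)
  upd <- adam_step(policy$par, grads, policy$opt, cfg$learning_rate)
  policy$par <- upd$params
  policy$opt <- upd$state
  list(policy = policy,
       diagnostics = list(mean_return = mean(fwd$R),
                          mean_advantage = mean(adv_all),
                          grad_norm = gnorm))
}
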