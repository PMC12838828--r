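test_that("glimpse sensor honours identity, boundary, and decimation", {
  x <- sin(seq(0, 6, length.out = 128))
  cfg1 <- glimpse_config(n_scales = 1, base_length = 128)
  expect_equal(glimpse(x, 0, cfg1)[1, ], x)

  # right edge: second half of the coarsest window is zero padding
  cfg3 <- glimpse_config(n_scales = 3, base_length = 16, scale_factor = 2)
  g_edge <- glimpse(x, 1, cfg3)
  coarse <- g_edge[3, ]
  expect_true(all(coarse[9:16] == 0))
  expect_true(any(coarse[1:8] != 0))

  # block-mean decimation of a ramp equals the analytic block averages
  ramp <- as.numeric(1:64)
  cfg2 <- glimpse_config(n_scales = 2, base_length = 32)
  g <- glimpse(ramp, 0, cfg2)
  expect_equal(g[2, ], colMeans(matrix(1:64, 2, 32)))
  expect_error(glimpse(x, 1.5, cfg3), "\\[-1, 1\\]")
})

test_that("core step is deterministic with bounded hidden state", {
  cfg <- train_config(hidden = 24, glimpse_feat = 16)
  pol <- agent_policy(3, "cnn_gru_rl", cfg = cfg, seed = 5)
  g <- matrix(rnorm(3 * 16), 3, 16)
  h0 <- rep(0, 24)
  h1 <- core_step(pol, h0, g, l_prev = 0.2)
  h2 <- core_step(pol, h0, g, l_prev = 0.2)
  expect_identical(h1, h2)
  expect_true(all(abs(h1) < 1))

  hz <- core_step(pol, h0, matrix(0, 3, 16), l_prev = 0)
  expect_identical(hz, core_step(pol, h0, matrix(0, 3, 16), l_prev = 0))
  expect_error(core_step(pol, rep(0, 5), g), "wrong length")
  expect_error(core_step(pol, h0, matrix(0, 2, 16)), "n_scales")
})

test_that("location sampling is Gaussian around the head mean", {
  cfg <- train_config(hidden = 16, glimpse_feat = 8, sigma_loc = 0.1)
  pol <- agent_policy(2, "gru_rl", cfg = cfg, seed = 6)
  h <- tanh(rnorm(16, 0, 0.3))
  mu <- sample_location(pol, h, stochastic = FALSE)
  expect_identical(mu, sample_location(pol, h, stochastic = FALSE))
  expect_gte(mu, -1); expect_lte(mu, 1)

  draws <- withr::with_seed(7,
    replicate(10000, sample_location(pol, h)))
  expect_true(all(draws >= -1 & draws <= 1))
  expect_lt(abs(mean(draws) - mu), 3 * 0.1 / sqrt(10000) + 1e-3)
})

test_that("action selection mixes the policy with uniform exploration", {
  cfg <- train_config(hidden = 16, glimpse_feat = 8)
  pol <- agent_policy(4, "cnn_gru_rl", cfg = cfg, seed = 8)
  h <- tanh(rnorm(16, 0, 0.3))
  a <- act(pol, h)
  expect_equal(sum(a$probs), 1, tolerance = 1e-6)

  freq <- withr::with_seed(9, {
    draws <- replicate(10000, act(pol, h, epsilon = 1)$action)
    tabulate(draws, 4) / 10000
  })
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se + 1e-3))

  pol$par$ba <- c(10, -10, -10, -10)  # one-hot-dominant distribution
  a_eval <- act(pol, h, epsilon = 0, eval_mode = TRUE)
  expect_equal(a_eval$action, 1L)
})

test_that("episode returns satisfy the discount identity", {
  cfg <- train_config(hidden = 16, glimpse_feat = 8, n_glimpses = 3,
                      gamma = 0.9)
  pol <- agent_policy(2, "cnn_gru_rl", cfg = cfg, seed = 10)
  x <- rnorm(64)

  # bias the action head so every step picks class 1
  pol$par$ba <- c(100, -100)
  ep_right <- run_episode(pol, x, 1L, cfg, seed = 1, stochastic = FALSE)
  expect_equal(ep_right$R, 1 + 0.9 + 0.81)
  ep_wrong <- run_episode(pol, x, 2L, cfg, seed = 1, stochastic = FALSE)
  expect_equal(ep_wrong$R, 0)

  cfg1 <- cfg; cfg1$gamma <- 1
  ep_undisc <- run_episode(pol, x, 1L, cfg1, seed = 1, stochastic = FALSE)
  expect_equal(ep_undisc$R, sum(ep_undisc$rewards))

  set.seed(2)
  ep <- run_episode(pol, x, 2L, cfg, seed = 3, epsilon = 0.5)
  expect_equal(ep$R, sum(cfg$gamma^(seq_along(ep$rewards) - 1) *
                           ep$rewards),
               tolerance = 1e-12)
  expect_true(all(ep$rewards %in% c(0, 1)))
})

test_that("REINFORCE update is zero-advantage-safe and deterministic", {
  cfg <- train_config(hidden = 16, glimpse_feat = 8, n_glimpses = 1,
                      gamma = 1)
  pol <- agent_policy(2, "cnn_gru_rl", cfg = cfg, seed = 11)
  pol$par$ba <- c(100, -100)      # always class 1, reward always 1
  pol$par$wb <- pol$par$wb * 0    # baseline head outputs exactly 1
  pol$par$bb <- 1
  eps <- lapply(1:4, function(i)
    run_episode(pol, rnorm(64), 1L, cfg, seed = i, stochastic = FALSE))
  upd <- reinforce_update(pol, eps, cfg)
  # G_t == baseline everywhere: no parameter moves
  for (nm in names(pol$par))
    expect_equal(upd$policy$par[[nm]], pol$par[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE, label = nm)

  # determinism: identical batches give identical updates
  pol2 <- agent_policy(2, "cnn_gru_rl", cfg = cfg, seed = 11)
  eps2 <- lapply(1:4, function(i)
    run_episode(pol2, rnorm(64), 1L, cfg, seed = i))
  u1 <- reinforce_update(pol2, eps2, cfg)
  u2 <- reinforce_update(pol2, eps2, cfg)
  for (nm in names(pol2$par))
    expect_identical(u1$policy$par[[nm]], u2$policy$par[[nm]])
  expect_error(reinforce_update(pol, list(), cfg), "empty")
})

test_that("policy-gradient estimator equals the finite-difference gradient", {
  expect_lt(pg_gradient_check(n_settings = 3, seed = 1), 1e-4)
})

test_that("numerical gradient of the full network matches backprop", {
  # finite-difference check of the complete BPTT path through conv, GRU,
  # and heads, using the policy-gradient objective on a fixed batch
  cfg <- train_config(hidden = 6, glimpse_feat = 5,
                      conv_channels = c(3L, 4L), kernels = c(3L, 3L),
                      n_glimpses = 2, gamma = 0.9, sigma_loc = 0.2,
                      glimpse = glimpse_config(2, 8, 2))
  set.seed(19)
  pol <- agent_policy(2, "cnn_gru_rl", cfg = cfg, seed = 12)
  episodes <- lapply(1:3, function(i)
    run_episode(pol, rnorm(32), sample(1:2, 1), cfg, seed = 20 + i,
                epsilon = 0.3))
  # advantages at the unperturbed policy (the update treats them as
  # constants, so the finite-difference objective must hold them fixed)
  adv0 <- lapply(episodes, function(e) e$returns - e$baselines)

  # The update ascends the policy-gradient term with the advantage held
  # constant and regresses the value head with its error confined to the
  # head, so core/encoder parameters are checked against the pg-only
  # objective and the value head against the squared-error term alone.
  objective <- function(policy, part = c("pg", "mse")) {
    part <- match.arg(part)
    total <- 0
    for (k in seq_along(episodes)) {
      e <- episodes[[k]]
      fwd <- somnirl:::run_batch(policy, list(e$x),
                                 matrix(0, 1, 0), e$label, cfg,
                                 forced = list(
                                   locations = matrix(e$locations, 1),
                                   actions = matrix(e$actions, 1),
                                   masks = e$masks),
                                 keep_caches = FALSE)
      for (t in seq_len(cfg$n_glimpses)) {
        if (part == "pg") {
          lp_a <- log(fwd$probs[[t]][1, e$actions[t]])
          lp_l <- -(e$locations[t] - fwd$loc_means[1, t])^2 /
            (2 * cfg$sigma_loc^2)
          total <- total + (lp_a + lp_l) * adv0[[k]][t]
        } else {
          total <- total - 0.5 * (fwd$baselines[1, t] -
                                    fwd$returns[1, t])^2
        }
      }
    }
    total / length(episodes)
  }

  # analytic gradient from the update path (recovered via Adam's first step:
  # with zeroed state, step = lr * g / (|g| + eps) only gives the sign, so
  # instead recompute grads directly through the internal machinery)
  grads <- local({
    b <- length(episodes)
    forced <- list(
      locations = do.call(rbind, lapply(episodes, `[[`, "locations")),
      actions = do.call(rbind, lapply(episodes, `[[`, "actions")),
      masks = lapply(seq_len(cfg$n_glimpses), function(t) NULL))
    fwd <- somnirl:::run_batch(pol, lapply(episodes, `[[`, "x"),
                               matrix(0, b, 0),
                               vapply(episodes, `[[`, numeric(1), "label"),
                               cfg, forced = forced, keep_caches = TRUE)
    g <- somnirl:::zeros_like(pol$par)
    dh <- matrix(0, b, pol$hidden)
    for (t in seq(cfg$n_glimpses, 1)) {
      adv <- fwd$returns[, t] - fwd$baselines[, t]
      dlogits <- somnirl:::softmax_logprob_grad(fwd$probs[[t]],
                                                fwd$actions[, t]) * (adv / b)
      dmu <- matrix((fwd$locations[, t] - fwd$loc_means[, t]) /
                      pol$sigma_loc^2 * adv / b, b, 1)
      dbase <- matrix((fwd$returns[, t] - fwd$baselines[, t]) / b, b, 1)
      sb <- somnirl:::step_bwd(pol, fwd$caches[[t]], dh, dlogits, dmu,
                               dbase, g)
      g <- sb$grads
      dh <- sb$dh_prev
    }
    g
  })

  h <- 1e-5
  for (nm in c("wc1", "wn", "uz", "wg", "wl", "wa", "wb", "bb")) {
    part <- if (nm %in% c("wb", "bb")) "mse" else "pg"
    m <- pol$par[[nm]]
    idx <- cbind(sample(nrow(as.matrix(m)), 2, replace = TRUE),
                 sample(ncol(as.matrix(m)), 2, replace = TRUE))
    for (r in 1:2) {
      pp <- pol; pm <- pol
      if (is.matrix(m)) {
        pp$par[[nm]][idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + h
        pm$par[[nm]][idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] - h
        g_ana <- grads[[nm]][idx[r, 1], idx[r, 2]]
      } else {
        pp$par[[nm]][idx[r, 2]] <- m[idx[r, 2]] + h
        pm$par[[nm]][idx[r, 2]] <- m[idx[r, 2]] - h
        g_ana <- grads[[nm]][idx[r, 2]]
      }
      g_num <- (objective(pp, part) - objective(pm, part)) / (2 * h)
      expect_equal(unname(g_ana), unname(g_num), tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("evaluation is deterministic and reports per-class metrics", {
  m <- classification_metrics(9, 1, 8, 2)
  expect_equal(m$acc, 0.85)
  expect_equal(m$ppv, 0.90)
  expect_equal(m$npv, 0.80)
  perfect <- classification_metrics(10, 0, 10, 0)
  expect_equal(c(perfect$acc, perfect$ppv, perfect$npv), c(1, 1, 1))
  expect_true(is.na(classification_metrics(0, 0, 10, 5)$ppv))

  cfg <- train_config(hidden = 16, glimpse_feat = 8, n_glimpses = 2)
  pol <- agent_policy(2, "cnn_gru_rl", cfg = cfg, seed = 13)
  ds <- synthetic_burst_dataset(10, len = 64, seed = 14)
  r1 <- evaluate(pol, ds, cfg)
  r2 <- evaluate(pol, ds, cfg)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(sum(r1$confusion), 20)

  # degenerate all-one-class predictor on a balanced two-class set
  pol$par$ba <- c(100, -100)
  r3 <- evaluate(pol, ds, cfg)
  expect_equal(r3$accuracy, 0.5)
  expect_true(is.na(r3$per_class$ppv[2]))
  expect_error(evaluate(pol, ds, cfg, idx = integer(0)), "empty")
})

test_that("experiment grids delegate to the plain pipeline", {
  synth <- synth_config(duration_s = 10)
  sim <- make_dataset(2, synth, seed = 41)
  cfg <- train_config(epochs = 3, batch_size = 16, hidden = 16,
                      glimpse_feat = 12, n_glimpses = 3, patience = 3,
                      seed = 42)
  res <- channel_subset_experiment(
    sim$recordings, subsets = list(ch19 = montage_10_20(),
                                   ch2 = c("C3", "C4")),
    cfg = cfg, k = 4, n_init = 2, max_iter = 30)
  expect_equal(res$grid$n_channels, c(19, 2))
  expect_true(all(res$grid$accuracy >= 0 & res$grid$accuracy <= 1))
  expect_error(channel_subset_experiment(
    sim$recordings, subsets = list(bad = c("C3", "XX")), cfg = cfg),
    "unknown channel")

  resw <- window_length_experiment(sim$recordings, lengths_s = c(1, 2),
                                   cfg = cfg, k = 4, n_init = 2,
                                   max_iter = 30)
  expect_equal(resw$grid$length_s, c(1, 2))
  expect_equal(resw$grid$n_epochs, c(80, 40))
  expect_error(window_length_experiment(sim$recordings, lengths_s = 60,
                                        cfg = cfg), "exceed")
  expect_equal(vapply(default_channel_subsets(), length, integer(1)),
               c(ch19 = 19L, ch13 = 13L, ch12 = 12L, ch10 = 10L,
                 ch7 = 7L, ch2 = 2L))
})
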