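test_that("analytic signal keeps the input as its real part", {
  set.seed(1)
  x <- rnorm(256)
  z <- analytic_signal(x)
  expect_identical(Re(z), x)
  expect_true(all(Mod(z) >= abs(x) - 1e-9))

  tone <- cos(2 * pi * 10 * (0:499) / 250)
  amp <- Mod(analytic_signal(tone))
  mid <- amp[125:375]
  expect_lt(max(abs(mid - 1)), 0.02)

  expect_warning(analytic_signal(rep(1, 16)), "constant")
  expect_error(analytic_signal(c(1, 2)), "at least 4")
})

test_that("median binarization follows the strict-threshold rule", {
  expect_equal(binarize_median(c(1, 2, 3, 4))$bits, c(0L, 0L, 1L, 1L))
  expect_true(all(binarize_median(rep(5, 10))$bits == 0L))
  set.seed(2)
  x <- rnorm(101)
  expect_length(binarize_median(x)$bits, 101L)
})

test_that("LZ76 count matches the exhaustive-history oracle", {
  expect_equal(lzc("0001101001000101"), 6L)
  expect_equal(lzc("0"), 1L)
  expect_equal(lzc("00000000"), 2L)
  set.seed(3)
  for (i in 1:300) {
    n <- sample(1:64, 1)
    bits <- sample(0:1, n, replace = TRUE)
    expect_equal(lzc(bits), lz76_naive(bits),
                 label = paste(bits, collapse = ""))
    # alphabet symmetry
    expect_equal(lzc(1L - bits), lzc(bits))
  }
})

test_that("normalized LZC behaves asymptotically", {
  set.seed(4)
  vals <- replicate(20, lzc_normalized(sample(0:1, 10000, replace = TRUE)))
  expect_gt(mean(vals), 0.85)
  expect_lt(mean(vals), 1.15)

  zeros <- vapply(c(100, 1000, 10000), function(n)
    lzc_normalized(rep(0L, n)), numeric(1))
  expect_true(all(diff(zeros) < 0))

  expect_gt(lzc_normalized(c(0L, 1L)), 0)
})

test_that("per-channel epoch complexity separates tone from noise", {
  set.seed(5)
  tone <- sin(2 * pi * 10 * (0:499) / 250)
  noise <- rnorm(500)
  out <- epoch_lzc(rbind(tone, noise, noise), fs = 250)
  expect_lt(out[1], out[2])
  expect_identical(unname(out[2]), unname(out[3]))  # duplicated channel
})

test_that("binarized analytic amplitude is scale-invariant", {
  set.seed(6)
  x <- rnorm(300)
  b1 <- binarize_median(Mod(analytic_signal(x)))
  b2 <- binarize_median(Mod(analytic_signal(7.3 * x)))
  expect_identical(b1$bits, b2$bits)
})

test_that("complexity knob monotonically drives broadband LZC", {
  topo <- make_topographies(2, paste0("ch", 1:6), 0.5, seed = 31)
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  knobs <- c(0.05, 0.15, 0.25, 0.35, 0.5)
  n_seeds <- 20
  lz <- matrix(0, n_seeds, length(knobs))
  for (s in seq_len(n_seeds)) {
    for (ki in seq_along(knobs)) {
      sp <- state_spec("x", c(delta = 0.3, theta = 0.3, alpha = 1,
                              beta = 0.3, gamma = 0.1),
                       c(90, 20), tm, noise_sd = 0,
                       complexity_knob = knobs[ki])
      # matched seed per level set: identical noise realization, only the
      # broadband mixing fraction differs
      rec <- simulate_recording(topo, sp, 4, 250, seed = 100 * s)
      lz[s, ki] <- mean(epoch_lzc(rec$data[, 1:500], fs = 250))
    }
  }
  pooled <- colMeans(lz)
  expect_true(all(diff(pooled) > 0))
  # sign test per adjacent level pair at alpha 0.05
  for (ki in seq_len(length(knobs) - 1)) {
    wins <- sum(lz[, ki + 1] > lz[, ki])
    p <- stats::binom.test(wins, n_seeds, alternative = "greater")$p.value
    expect_lt(p, 0.05)
  }
  # REM-with-stimuli style epochs are more complex than eyes-closed style
  specs <- default_state_specs()
  rec_hi <- simulate_recording(topo_hi <- make_topographies(
    4, montage_10_20(), 0.5, seed = 32), specs[["REM_stim"]], 4, 250,
    seed = 33)
  rec_lo <- simulate_recording(topo_hi, specs[["EC"]], 4, 250, seed = 33)
  expect_gt(mean(epoch_lzc(rec_hi$data[, 1:500], fs = 250)),
            mean(epoch_lzc(rec_lo$data[, 1:500], fs = 250)))
})

test_that("feature assembly follows the documented schema", {
  feats <- suppressMessages(temporal_parameters(
    c(1, 1, 2, 2, 2, 1, 3, 3, 4, 4), runif(10), fs = 100, k = 4))
  lz <- stats::setNames(runif(19), montage_10_20())
  fv <- build_features(feats, lz, "mean_gfp+lzc")
  expect_length(fv, 4 + 19)
  expect_equal(names(fv)[1:4], paste0("mean_gfp_state", 1:4))
  expect_true(all(grepl("^lzc_", names(fv)[5:23])))

  fv2 <- build_features(feats, set_id = "duration")
  expect_length(fv2, 4)
  expect_identical(as.numeric(fv2), feats$per_state$duration_ms)
  # pure function
  expect_identical(build_features(feats, lz, "coverage+lzc"),
                   build_features(feats, lz, "coverage+lzc"))
  # epoch identity enforcement
  attr(feats, "epoch_id") <- "e1"
  attr(lz, "epoch_id") <- "e2"
  expect_error(build_features(feats, lz, "mean_gfp+lzc"), "mismatch")
  expect_error(build_features(feats, set_id = "mean_gfp+lzc"),
               "requires lzc_values")
})
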