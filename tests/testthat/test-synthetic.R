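test_that("topography sampling is deterministic and satisfies invariants", {
  t1 <- make_topographies(4, montage_10_20(), 0.5, seed = 7)
  t2 <- make_topographies(4, montage_10_20(), 0.5, seed = 7)
  expect_identical(t1$maps, t2$maps)
  expect_lt(max(abs(rowMeans(t1$maps))), 1e-9)
  expect_lt(max(abs(rowSums(t1$maps^2) - 1)), 1e-9)
  cors <- t1$maps %*% t(t1$maps)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.5 + 1e-12)

  t3 <- make_topographies(2, paste0("ch", 1:4), 0.99, seed = 1)
  expect_lte(abs(sum(t3$maps[1, ] * t3$maps[2, ])), 0.99)
})

test_that("impossible correlation caps fail with an informative error", {
  expect_error(make_topographies(10, paste0("ch", 1:4), 0.01, seed = 1),
               "corr_cap")
  expect_error(make_topographies(1, montage_10_20()), "between 2 and 10")
  expect_error(make_topographies(4, paste0("ch", 1:3)), "4 channels")
})

test_that("label sequences follow the dwell and transition specification", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  sp <- state_spec("EO",
                   c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0),
                   c(100, 0), tm)
  lab <- simulate_label_sequence(sp, 1000, 250, seed = 3)
  r <- rle(lab)
  # zero jitter: every full segment is exactly round(0.1 * fs) samples
  expect_true(all(r$lengths[-length(r$lengths)] == 25L))
  # off-diagonal transitions forbid repeated adjacent labels
  expect_true(all(diff(r$values) != 0))

  sp2 <- state_spec("EC",
                    c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0),
                    c(100, 20), tm)
  lab2 <- simulate_label_sequence(sp2, 10000, 250, seed = 5)
  lens <- rle(lab2)$lengths
  lens <- lens[-length(lens)]
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.1 * 250), 3 * se + 1e-9)
})

test_that("state specifications validate their invariants", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  gains <- c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0)
  expect_error(state_spec("x", gains, c(10, 0), tm), "\\[20, 500\\]")
  expect_error(state_spec("x", gains, c(100, 0), tm * 2), "sum to 1")
  expect_error(state_spec("x", gains * -1, c(100, 0), tm), ">= 0")
  expect_error(state_spec("x", gains, c(100, 0), tm,
                          complexity_knob = 1.5), "\\[0, 1\\]")
})

test_that("recordings mix labeled sources and are seed-reproducible", {
  topo <- make_topographies(2, paste0("ch", 1:6), 0.5, seed = 2)
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  sp <- state_spec("EO",
                   c(delta = 0, theta = 0, alpha = 1, beta = 0, gamma = 0),
                   c(100, 10), tm, noise_sd = 0, complexity_knob = 0)
  r1 <- simulate_recording(topo, sp, 4, 250, seed = 9)
  r2 <- simulate_recording(topo, sp, 4, 250, seed = 9)
  expect_identical(r1$data, r2$data)

  # noiseless: every column is proportional to its labeled topography
  for (i in seq(1, 1000, by = 37)) {
    col <- r1$data[, i]
    map <- topo$maps[r1$true_label_sequence[i], ]
    expect_gt(abs(sum(col * map)) / sqrt(sum(col^2)), 1 - 1e-9)
  }
})

test_that("label recoverability: nearest topography reproduces truth", {
  topo <- make_topographies(4, montage_10_20(), 0.5, seed = 3)
  sp <- default_state_specs()[["EC"]]
  sp$noise_sd <- 0
  rec <- simulate_recording(topo, sp, 4, 250, seed = 11)
  corr <- abs(t(rec$data) %*% t(topo$maps))
  recovered <- max.col(corr, ties.method = "first")
  expect_identical(recovered, rec$true_label_sequence)
})

test_that("dominant band gain yields dominant Welch band power", {
  topo <- make_topographies(4, montage_10_20(), 0.5, seed = 3)
  for (nm in names(default_state_specs())) {
    sp <- default_state_specs()[[nm]]
    sp$noise_sd <- 0
    rec <- simulate_recording(topo, sp, 8, 250, seed = 13)
    psd <- welch_psd(rec$data, rec$fs, spectral_config(500))
    bp <- vapply(default_bands(), function(b)
      mean(band_power(psd, b)), numeric(1))
    expect_identical(names(which.max(bp)),
                     names(which.max(sp$band_gains)),
                     label = paste("state", nm))
  }
})

test_that("datasets are balanced, labeled, and reproducible", {
  cfg <- synth_config(duration_s = 2.5, fs = 100)
  d1 <- make_dataset(2, cfg, seed = 5)
  d2 <- make_dataset(2, cfg, seed = 5)
  expect_length(d1$recordings, 8L)
  states <- vapply(d1$recordings, function(r) r$state_label, character(1))
  expect_equal(unname(table(states)), rep(2L, 4), ignore_attr = TRUE)
  expect_setequal(unique(states), c("EO", "EC", "REM_stim", "REM_nostim"))
  expect_identical(d1$recordings[[3]]$data, d2$recordings[[3]]$data)
  expect_setequal(names(default_state_specs()),
                  c("EO", "EC", "REM_stim", "REM_nostim"))
})
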