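test_that("GFP matches hand evaluation and is homogeneous", {
  expect_equal(gfp(matrix(c(1, -1), 2, 1))$values, 1)
  expect_equal(gfp(matrix(c(3, 3, 3), 3, 1))$values, 0)
  set.seed(1)
  x <- matrix(rnorm(40), 4, 10)
  expect_equal(gfp(-2.5 * x)$values, 2.5 * gfp(x)$values)
  expect_error(gfp(matrix(1, 1, 10)), "2 channels")
})

test_that("GFP peaks are strict local maxima with greedy thinning", {
  expect_length(gfp_peaks(seq_len(10), fs = 100), 0)
  expect_equal(gfp_peaks(c(0, 1, 0, 1, 0), fs = 100), c(2L, 4L))

  # two peaks 5 ms apart at 1000 Hz; only the larger survives 10 ms thinning
  v <- rep(0, 30); v[10] <- 1; v[15] <- 2
  expect_equal(gfp_peaks(v, min_separation_ms = 10, fs = 1000), 15L)
  expect_equal(gfp_peaks(v, min_separation_ms = 0, fs = 1000), c(10L, 15L))
})

test_that("modified k-means recovers orthogonal prototypes exactly", {
  protos <- orthogonal_prototypes(4, 12, seed = 5)
  set.seed(2)
  lab <- sample(1:4, 200, replace = TRUE)
  amp <- rnorm(200, 0, 2)
  maps <- protos[lab, ] * amp
  m <- fit_microstates(maps, 4, n_init = 5, max_iter = 100, seed = 3)
  expect_equal(m$gev, 1, tolerance = 1e-9)
  cors <- abs(m$prototypes %*% t(protos))
  expect_true(all(apply(cors, 2, max) > 0.999))

  # polarity invariance: flipping every map gives the identical model
  m_flip <- fit_microstates(-maps, 4, n_init = 5, max_iter = 100, seed = 3)
  expect_equal(m_flip$prototypes, m$prototypes, tolerance = 1e-9)
  expect_equal(m_flip$gev, m$gev, tolerance = 1e-12)

  # K = P: one map per cluster explains everything
  m_kp <- fit_microstates(maps[1:4, ], 4, n_init = 3, max_iter = 50,
                          seed = 1)
  expect_equal(m_kp$gev, 1, tolerance = 1e-9)
})

test_that("GEV agrees with a brute-force evaluation and hits its bounds", {
  protos <- orthogonal_prototypes(3, 8, seed = 7)
  set.seed(4)
  for (rep_i in 1:5) {
    maps <- matrix(rnorm(10 * 8), 10, 8)
    g_at <- runif(10, 0.5, 2)
    model <- fit_microstates(maps, 3, n_init = 3, max_iter = 50,
                             seed = rep_i)
    expect_equal(gev(model, maps, g_at), gev_brute(model$prototypes, maps,
                                                   g_at),
                 tolerance = 1e-9)
    expect_gte(gev(model, maps, g_at), 0)
    expect_lte(gev(model, maps, g_at), 1)
  }
  # maps drawn from the prototypes: GEV = 1
  lab <- sample(1:3, 30, replace = TRUE)
  maps1 <- protos[lab, ] * rnorm(30)
  model <- fit_microstates(maps1, 3, n_init = 3, max_iter = 50, seed = 1)
  expect_equal(gev(model, maps1, rep(1, 30)), 1, tolerance = 1e-9)
  # maps orthogonal to every prototype: GEV = 0
  ortho6 <- orthogonal_prototypes(6, 8, seed = 7)  # extends the same basis
  maps0 <- ortho6[rep(4:6, 4), ]
  expect_equal(gev(model, maps0, rep(1, 12)), 0, tolerance = 1e-9)
  expect_error(gev(model, maps0, rep(0, 12)), "zero")
})

test_that("class-count selection maximizes GEV over the range", {
  protos <- orthogonal_prototypes(4, 12, seed = 9)
  set.seed(6)
  lab <- sample(1:4, 300, replace = TRUE)
  maps <- protos[lab, ] * rnorm(300) + matrix(rnorm(300 * 12, 0, 0.01),
                                              300, 12)
  sel <- select_n_states(maps, k_range = 4:6, n_init = 3, max_iter = 100,
                         seed = 2)
  expect_gte(sel$gev_table$gev[sel$gev_table$k == 4], 0.99)
  expect_equal(sel$gev, max(sel$gev_table$gev))

  single <- select_n_states(maps, k_range = 4, n_init = 3, max_iter = 100,
                            seed = 2)
  direct <- fit_microstates(maps, 4, n_init = 3, max_iter = 100, seed = 2)
  expect_equal(single$prototypes, direct$prototypes)
  expect_equal(single$gev, direct$gev)
  # the documented default range
  expect_equal(eval(formals(select_n_states)$k_range), 4:10)
})

test_that("backfitting assigns by correlation and smooths short segments", {
  protos <- orthogonal_prototypes(3, 8, seed = 11)
  model <- structure(list(prototypes = protos, k = 3L, gev = 1),
                     class = "microstate_model")
  # columns equal to +/- prototypes
  x <- t(protos[c(1, 1, 2, 3, 3, 2), ] * c(1, -1, 1, -1, 1, -1))
  lab <- backfit(model, x, min_duration_ms = 0)
  expect_equal(lab$labels, c(1L, 1L, 2L, 3L, 3L, 2L))

  # A(50 ms) B(4 ms) A(50 ms) at 1000 Hz with 10 ms smoothing -> all A
  fs <- 1000
  seq_cols <- cbind(t(protos[rep(1, 50), ]), t(protos[rep(2, 4), ]),
                    t(protos[rep(1, 50), ]))
  lab_s <- backfit(model, seq_cols, min_duration_ms = 10, fs = fs)
  expect_true(all(lab_s$labels == 1L))
  lab_raw <- backfit(model, seq_cols, min_duration_ms = 0, fs = fs)
  expect_equal(sum(lab_raw$labels == 2L), 4L)
})

test_that("temporal parameters reproduce the worked example", {
  f <- suppressMessages(temporal_parameters(c(1, 1, 2, 2, 2, 1),
                                            rep(1, 6), fs = 100, k = 2))
  expect_equal(f$per_state$coverage, c(0.5, 0.5))
  expect_equal(f$per_state$duration_ms, c(15, 30))
  expect_equal(f$per_state$occurrence_per_s, c(2 / 0.06, 1 / 0.06))

  single <- suppressMessages(temporal_parameters(rep(1L, 100), rep(2, 100),
                                                 fs = 100, k = 2))
  expect_equal(single$per_state$coverage, c(1, 0))
  expect_equal(single$per_state$duration_ms[1], 1000)
  expect_equal(single$per_state$occurrence_per_s[1], 1)

  set.seed(8)
  lab <- sample(1:4, 500, replace = TRUE)
  f2 <- suppressMessages(temporal_parameters(lab, runif(500), fs = 250,
                                             k = 4))
  expect_equal(sum(f2$per_state$coverage), 1, tolerance = 1e-9)
})

test_that("transition matrix matches brute-force bigram counting", {
  tm <- transition_matrix(c(1, 2, 1, 2), k = 2)
  expect_equal(tm, matrix(c(0, 1, 1, 0), 2, 2))

  set.seed(9)
  for (i in 1:5) {
    lab <- sample(1:3, 60, replace = TRUE)
    tm <- transition_matrix(lab, k = 3)
    expect_equal(tm, transition_brute(lab, 3), tolerance = 1e-12)
    occupied <- rowSums(tm) > 0
    expect_true(all(abs(rowSums(tm)[occupied] - 1) < 1e-9))
  }
  expect_error(transition_matrix(rep(1L, 10), k = 2), "2 segments")
})

test_that("microstate recovery holds on low-noise synthetic recordings", {
  topo <- make_topographies(4, montage_10_20(), 0.5, seed = 21)
  sp <- default_state_specs()[["EC"]]
  sp$noise_sd <- 0.01
  sp$complexity_knob <- 0
  rec <- simulate_recording(topo, sp, 10, 250, seed = 22)
  g <- gfp(rec)
  peaks <- gfp_peaks(g, 10)
  model <- fit_microstates(t(rec$data[, peaks]), 4, n_init = 5,
                           max_iter = 100, seed = 23,
                           gfp_values = g$values[peaks])
  lab <- backfit(model, rec, min_duration_ms = 20)
  # align fitted prototypes with the generating maps
  perm <- apply(abs(model$prototypes %*% t(topo$maps)), 1, which.max)
  mapped <- perm[lab$labels]
  expect_gte(mean(mapped == rec$true_label_sequence), 0.95)
  feats <- suppressMessages(temporal_parameters(lab, g))
  mean_dur <- mean(feats$per_state$duration_ms)
  expect_lt(abs(mean_dur - sp$ms_duration_ms[1]) / sp$ms_duration_ms[1],
            0.15)
})
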