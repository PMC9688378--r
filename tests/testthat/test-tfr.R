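test_that("morlet config validates its grid", {
  expect_error(morlet_config(freqs = c(0, 5, 10)), "positive")
  expect_error(morlet_config(freqs = c(10, 5)), "increasing")
  expect_error(morlet_config(cycles = 1), "cycle")
})

test_that("zero signal yields all-zero power", {
  t <- epoch_times(256)
  tf <- morlet_transform(numeric(length(t)), config = morlet_config(),
                         times = t, fs = 256)
  expect_true(all(tf$power == 0))
})

test_that("analysis frequencies above fs/4 are rejected", {
  t <- seq(0, 2, by = 1 / 64)
  expect_error(
    morlet_transform(sin(2 * pi * 10 * t), config = morlet_config(),
                     times = t, fs = 64),
    "fs/4"
  )
})

test_that("pure tones localize at the nearest grid frequency", {
  t <- epoch_times(256)
  cfg <- morlet_config()
  for (f0 in c(5, 11, 20, 30)) {
    tf <- morlet_transform(sin(2 * pi * f0 * t), config = cfg, times = t, fs = 256)
    mid <- which.min(abs(tf$times - 0.25))
    expect_equal(tf$freqs[which.max(tf$power[, mid])], f0)
    # >= 90% of mid-epoch power mass within +/- 3 Hz of the tone
    near <- abs(tf$freqs - f0) <= 3
    expect_gte(sum(tf$power[near, mid]) / sum(tf$power[, mid]), 0.9)
  }
})

test_that("raw power is quadratic in signal amplitude", {
  withr::with_seed(11, {
    t <- epoch_times(256)
    x <- rnorm(length(t))
    cfg <- morlet_config()
    tf1 <- morlet_transform(x, config = cfg, times = t, fs = 256)
    tf2 <- morlet_transform(2 * x, config = cfg, times = t, fs = 256)
    mid <- tf1$times > -2 & tf1$times < 2.5   # exclude edge cells
    expect_equal(tf2$power[, mid] / tf1$power[, mid],
                 matrix(4, nrow(tf1$power), sum(mid)), tolerance = 1e-9)
    expect_equal(mean(10 * log10(tf2$power[, mid] / tf1$power[, mid])),
                 20 * log10(2), tolerance = 1e-9)
  })
})

test_that("batched epoch transform equals the per-channel transform", {
  cfg <- neural_config(n_per_group = 1, trials_per_condition = 1)
  ep <- synth_epoch(cfg, list(plan = stats::setNames(rep(-1, 6), electrode_meta()$channel),
                              exec = stats::setNames(rep(-3, 6), electrode_meta()$channel)),
                    seed = 2)
  mc <- morlet_config()
  batched <- betatrack:::morlet_epoch(ep, mc)
  for (ch in c("F3", "C4", "P3")) {
    single <- morlet_transform(ep, ch, mc)
    expect_equal(batched$power[ch, , ], single$power, tolerance = 1e-12)
  }
})

test_that("condition averaging equals the brute-force loop", {
  withr::with_seed(5, {
    g <- default_grid()
    tfrs <- lapply(1:7, function(i) {
      flat_tfr(matrix(rexp(33 * 40), 33, 40), g$freqs, g$times[1:40], scale = "RAW")
    })
    avg <- condition_average(tfrs)
    manual <- tfrs[[1]]$power * 0
    for (tf in tfrs) manual <- manual + tf$power
    manual <- manual / 7
    expect_equal(avg$power, manual, tolerance = 1e-12)
    expect_equal(condition_average(tfrs[1])$power, tfrs[[1]]$power)
    expect_equal(condition_average(list(tfrs[[2]], tfrs[[2]]))$power, tfrs[[2]]$power)
    bad <- tfrs[[1]]
    bad$freqs <- bad$freqs + 1
    expect_error(condition_average(list(tfrs[[1]], bad)), "grid")
  })
})

test_that("dB normalization identities hold", {
  g <- default_grid()
  nt <- length(g$times)
  # matrix equal to its own baseline level at every time point -> 0 dB
  P <- matrix(rep(2^(1:33), nt), 33, nt)
  tf <- flat_tfr(P, g$freqs, g$times, scale = "RAW")
  db <- db_normalize(tf, list(tf))
  expect_equal(db$power, matrix(0, 33, nt))
  expect_equal(db$scale, "DB")
  # P = 10 x baseline -> +10 dB
  tf10 <- flat_tfr(10 * P, g$freqs, g$times, scale = "RAW")
  expect_equal(db_normalize(tf10, list(tf))$power, matrix(10, 33, nt))
  # zero baseline is an explicit error
  tf0 <- flat_tfr(P * 0, g$freqs, g$times, scale = "RAW")
  expect_error(db_normalize(tf, list(tf0)), "positive")
  # window outside the axis is an error
  expect_error(db_normalize(tf, list(tf), window = c(10, 11)), "window")
})

test_that("normalization conserves the baseline-window condition average", {
  withr::with_seed(9, {
    g <- default_grid()
    nt <- length(g$times)
    tfrs <- lapply(1:3, function(i) {
      flat_tfr(matrix(rexp(33 * nt, rate = 1 / (i + 1)), 33, nt),
               g$freqs, g$times, scale = "RAW")
    })
    dbs <- lapply(tfrs, db_normalize, baseline_source = tfrs)
    win <- trial_timeline()$baseline_window
    cols <- g$times >= win[1] & g$times <= win[2]
    # windowed mean of the across-condition average *power ratio* is exactly 1,
    # i.e. its dB is 0 within float tolerance
    ratio <- Reduce(`+`, lapply(dbs, function(d) 10^(d$power[, cols] / 10))) / 3
    expect_equal(10 * log10(rowMeans(ratio)), rep(0, 33), tolerance = 1e-9)
  })
})

test_that("injected stage depths are recovered by the TFR stage", {
  # noise-free pure-tone epochs: mean dB over beta x stage window equals the
  # injected depth within 0.3 dB
  cfg <- neural_config(noise_scale = 0, beta_band = c(20, 20))
  ch <- electrode_meta()$channel
  for (d in c(-2, -6)) {
    ep <- synth_epoch(cfg, list(plan = stats::setNames(rep(d / 2, 6), ch),
                                exec = stats::setNames(rep(d, 6), ch)),
                      seed = 7)
    tf <- morlet_transform(ep, "C3", morlet_config())
    db <- db_normalize(tf, list(tf))
    bb <- db$freqs >= 13 & db$freqs <= 30
    plan_cols <- db$times >= -2 & db$times <= 0
    exec_cols <- db$times >= 1 & db$times <= 3
    expect_lt(abs(mean(db$power[bb, plan_cols]) - d / 2), 0.3)
    expect_lt(abs(mean(db$power[bb, exec_cols]) - d), 0.3)
  }
})
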