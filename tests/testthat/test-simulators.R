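# dominant periodogram frequencies of one process, averaged over trials
peak_freqs <- function(ens, p, n_peaks = 1, fmin = 0) {
  m <- ens$data[, p, ]
  fs <- ens$fs
  n <- ncol(m)
  f <- (0:(n - 1)) * fs / n
  keep <- f > fmin & f <= fs / 2
  pw <- colMeans(t(apply(m, 1, function(x) Mod(fft(x - mean(x)))^2)))
  ord <- order(pw[keep], decreasing = TRUE)
  fk <- f[keep][ord]
  # greedy pick of well-separated peaks
  out <- fk[1]
  for (v in fk[-1]) {
    if (length(out) >= n_peaks) break
    if (all(abs(v - out) > 2)) out <- c(out, v)
  }
  sort(out)
}

test_that("sample budgets match duration x fs x trials for every example", {
  sizes <- list(`1` = c(100, 2, 1250), `2` = c(100, 2, 1250),
                `3` = c(100, 2, 1200), `4` = c(50, 2, 2400),
                `5` = c(50, 3, 2400), `6` = c(50, 2, 2000),
                `7` = c(50, 2, 625), `8` = c(50, 2, 1250),
                `9` = c(50, 2, 2500))
  # verify the full-preset sample budgets by arithmetic, and a cheap
  # subset by generation
  expect_identical(unname(vapply(sizes, function(s) prod(s[c(1, 3)]),
                                 numeric(1))),
                   c(125000, 125000, 120000, 120000, 120000, 100000,
                     31250, 62500, 125000))
  for (ex in c(2, 7)) {
    ens <- sim_system(ex, "full", seed = 1)
    expect_identical(dim(ens$data), as.integer(sizes[[as.character(ex)]]))
  }
  ens <- sim_system(8, "reduced", seed = 1)
  expect_identical(dim(ens$data), c(20L, 2L, 1250L))
})

test_that("generation is bit-reproducible under a fixed seed", {
  for (ex in c(2, 3, 5, 6, 9)) {
    a <- sim_system(ex, "reduced", seed = 5, n_trials = 2L,
                    duration = if (ex == 6) 2 else 1)
    b <- sim_system(ex, "reduced", seed = 5, n_trials = 2L,
                    duration = if (ex == 6) 2 else 1)
    c <- sim_system(ex, "reduced", seed = 6, n_trials = 2L,
                    duration = if (ex == 6) 2 else 1)
    expect_identical(a$data, b$data)
    expect_false(identical(a$data, c$data))
  }
})

test_that("every generator records its ground truth", {
  for (ex in 1:9) {
    ens <- sim_system(ex, "reduced", seed = 2, n_trials = 2L,
                      duration = if (ex == 6) 2 else 1)
    gt <- ens$ground_truth
    expect_false(is.null(gt))
    expect_true(all(c("delay", "source_scale", "target_scale",
                      "source", "target") %in% names(gt)))
  }
  gt2 <- sim_system(2, "reduced", seed = 1, n_trials = 2L,
                    duration = 1)$ground_truth
  expect_identical(gt2$delay, 2L)
  expect_identical(gt2$source_scale, 4L)
  expect_identical(gt2$target_scale, 1L)
})

test_that("the uncoupled system has the stated spectra and no cross-correlation", {
  ens <- sim_system(1, "reduced", seed = 3)
  expect_lt(abs(peak_freqs(ens, 1) - 5), 0.4)
  expect_lt(abs(peak_freqs(ens, 2) - 50), 0.4)
  n <- prod(dim(ens$data)[c(1, 3)])
  for (l in c(0, 1, 2, 5)) {
    cc <- mean(apply(ens$data, 1, function(m) {
      ns <- ncol(m)
      cor(m[1, 1:(ns - l)], m[2, (l + 1):ns])
    }))
    expect_lt(abs(cc), 3 / sqrt(n))
  }
})

test_that("one-to-many and redundant systems place power at the stated peaks", {
  # amplitude modulation by the zero-mean 5 Hz rhythm suppresses the
  # carriers themselves and puts the power into +/- 5 Hz sidebands
  ens8 <- sim_system(8, "reduced", seed = 4)
  pk8 <- peak_freqs(ens8, 2, n_peaks = 3)
  for (p in pk8)
    expect_lt(min(abs(p - c(30, 58, 100))), 5.5)
  ens9 <- sim_system(9, "reduced", seed = 4)
  expect_lt(max(abs(peak_freqs(ens9, 1, n_peaks = 5) - c(5, 9, 18, 40, 80))), 0.5)
})

test_that("AR systems oscillate at their pole frequencies and decouple cleanly", {
  ens <- sim_system(3, "reduced", seed = 5, n_trials = 10L)
  expect_lt(abs(peak_freqs(ens, 1, fmin = 2) - 45), 2)
  expect_lt(abs(peak_freqs(ens, 2, fmin = 2) - 45), 2)
  ens4 <- sim_system(4, "reduced", seed = 5, n_trials = 10L)
  expect_lt(abs(peak_freqs(ens4, 1, fmin = 2) - 5), 2)
  expect_lt(abs(peak_freqs(ens4, 2, fmin = 2) - 45), 2)
  # decoupled limit: no lagged cross-correlation above chance
  ens0 <- sim_system(3, "reduced", seed = 6, n_trials = 10L, c1 = 0)
  cc <- mean(apply(ens0$data, 1, function(m) {
    ns <- ncol(m)
    cor(m[1, 1:(ns - 2)], m[2, 3:ns])
  }))
  expect_lt(abs(cc), 3 / sqrt(10 * 1200))
  # 'preset' named in full so the short argument name cannot partial-match
  expect_error(sim_system(3, preset = "reduced", seed = 1, p = 1.01),
               "stab")
})

test_that("the sigmoid network modulates the target only through the driver", {
  ens <- sim_system(5, "reduced", seed = 7, n_trials = 10L)
  expect_lt(abs(peak_freqs(ens, 1) - 6), 0.3)
  expect_lt(abs(peak_freqs(ens, 2) - 80), 0.3)
  expect_lt(abs(peak_freqs(ens, 3) - 90), 0.3)
  # lambda -> 0 freezes the sigoid at 1/2: target variance shrinks to the
  # unmodulated carrier plus noise
  ens0 <- sim_system(5, "reduced", seed = 7, n_trials = 10L, lambda = 0)
  v0 <- var(as.vector(ens0$data[, 2, ]))
  v3 <- var(as.vector(ens$data[, 2, ]))
  expect_lt(abs(v0 - (0.25 * 0.5 + 0.6^2)), 0.02)
  expect_gt(v3, v0)
})

test_that("the Rossler pair oscillates inside the scale-5 band", {
  ens <- sim_system(6, "reduced", seed = 8, n_trials = 5L)
  band <- scale_band(5, ens$fs)   # 7.8-15.6 Hz at fs = 500
  for (p in 1:2) {
    pk <- peak_freqs(ens, p, fmin = 2)
    expect_gt(pk, band[1])
    expect_lt(pk, band[2])
  }
})
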