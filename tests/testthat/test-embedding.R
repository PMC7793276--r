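test_that("embedding pools exactly the in-bounds time indices", {
  set.seed(21)
  ens <- te_ensemble(array(rnorm(10 * 2 * 100), c(10, 2, 100)), fs = 100)
  link <- link_spec(1, 2, delta = 2, source_lags = c(2, 3),
                    target_max_lag = 8)
  emb <- embed_ensemble(ens, link)
  expect_identical(emb$n_points, 10L * (100L - 8L))
  expect_identical(ncol(emb$x_past), 2L)
  expect_identical(ncol(emb$z_past), 0L)
  # rows never span a trial boundary: every used time index leaves room
  # for the deepest lag within its own trial
  expect_true(all(emb$t > 8))
  # spot-check one embedded value against direct array indexing
  r <- 137L
  expect_identical(emb$y_now[r, 1], ens$data[emb$trial[r], 2, emb$t[r]])
  expect_identical(emb$x_past[r, 2], ens$data[emb$trial[r], 1, emb$t[r] - 3L])
  expect_error(embed_ensemble(ens, link_spec(1, 2, delta = 150)), "lag")
})

test_that("overrides replace exactly the contracted blocks", {
  set.seed(22)
  ens <- te_ensemble(array(rnorm(5 * 2 * 64), c(5, 2, 64)), fs = 32)
  link <- link_spec(1, 2, delta = 1, target_max_lag = 4)
  e0 <- embed_ensemble(ens, link)
  # identity override
  e1 <- embed_ensemble(ens, link,
                       override_present = ens$data[, 2, , drop = TRUE])
  expect_identical(e1$y_now, e0$y_now)
  # a scale surrogate of the source changes x_past only
  smat <- t(apply(ens$data[, 1, ], 1, function(tr)
    local({ set.seed(1); source_surrogate(tr, 2, J0 = 4) })))
  e2 <- embed_ensemble(ens, link, override_source = smat)
  expect_identical(e2$y_now, e0$y_now)
  expect_identical(e2$y_past, e0$y_past)
  expect_identical(e2$z_past, e0$z_past)
  expect_false(identical(e2$x_past, e0$x_past))
})

test_that("dyadic lags cover the history depth with one dim per octave", {
  expect_identical(dyadic_lags(16), c(1L, 2L, 4L, 8L, 16L))
  expect_identical(dyadic_lags(10), c(1L, 2L, 4L, 8L, 10L))
  expect_identical(dyadic_lags(1), 1L)
  expect_identical(target_history_depth(125, 5), 16L)
  expect_identical(target_history_depth(125, 5, f_low = 4), 8L)
})

test_that("KSG estimator matches Gaussian closed forms within 3 SE", {
  n <- 20000
  # empirical SE of the estimator at this n is ~0.004 nats
  tol <- 3 * 0.004
  set.seed(23)
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(ksg_cmi(x, y, k = 4) + 0.5 * log(1 - rho^2)), tol)
  }
})

test_that("conditioning removes shared-driver dependence", {
  set.seed(24)
  n <- 20000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  expect_gt(ksg_cmi(x, y, k = 4), 0.1)          # marginally dependent
  expect_lt(abs(ksg_cmi(x, y, z, k = 4)), 0.02) # conditionally independent
})

test_that("KSG estimate is invariant under monotone rescaling", {
  set.seed(25)
  n <- 8000
  x <- rnorm(n)
  y <- 0.6 * x + 0.8 * rnorm(n)
  v0 <- ksg_cmi(x, y, k = 4)
  v1 <- ksg_cmi(exp(x), y^3, k = 4)
  expect_lt(abs(v0 - v1), 2 * 0.012)            # 2 SE at this n
})

test_that("mTE reproduces the Gaussian transfer-entropy closed form", {
  set.seed(26)
  a <- 0.8
  nt <- 10L; ns <- 2000L
  dat <- array(NA_real_, c(nt, 2, ns))
  for (tr in seq_len(nt)) {
    s <- rnorm(ns)
    dat[tr, 1, ] <- s
    dat[tr, 2, ] <- a * c(0, 0, s[1:(ns - 2)]) + rnorm(ns)
  }
  ens <- te_ensemble(dat, fs = 100)
  link <- link_spec(1, 2, delta = 2, target_lags = 1)
  emb <- embed_ensemble(ens, link)
  v <- mte(emb, k = 4)
  expect_lt(abs(v - 0.5 * log(1 + a^2)), 3 * 0.01)
})

test_that("mTE is near zero for uncoupled processes", {
  set.seed(27)
  dat <- array(rnorm(10 * 2 * 1000), c(10, 2, 1000))
  ens <- te_ensemble(dat, fs = 100)
  emb <- embed_ensemble(ens, link_spec(1, 2, delta = 1, target_lags = 1:2))
  expect_lt(abs(mte(emb, k = 4)), 0.01)
})

test_that("conditioning on an independent noise process barely moves mTE", {
  set.seed(28)
  a <- 0.8
  nt <- 10L; ns <- 1500L
  dat <- array(NA_real_, c(nt, 3, ns))
  for (tr in seq_len(nt)) {
    s <- rnorm(ns)
    dat[tr, 1, ] <- s
    dat[tr, 2, ] <- a * c(0, s[1:(ns - 1)]) + rnorm(ns)
    dat[tr, 3, ] <- rnorm(ns)
  }
  ens <- te_ensemble(dat, fs = 100)
  v1 <- mte(embed_ensemble(ens, link_spec(1, 2, delta = 1,
                                          target_lags = 1)))
  v2 <- mte(embed_ensemble(ens, link_spec(1, 2, conditioning = 3L,
                                          delta = 1, target_lags = 1,
                                          cond_lags = 1:2)))
  expect_lt(abs(v1 - v2), 2 * 0.015)
})
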