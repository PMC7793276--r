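# a small coupled ensemble with a clear band structure, cheap to analyse:
# 6 Hz latent rhythm modulates a 50 Hz carrier two samples later (fs 125)
tiny_coupled <- function(seed = 1, nt = 6L, ns = 375L) {
  set.seed(seed)
  fs <- 125
  dat <- array(NA_real_, c(nt, 2, ns))
  for (tr in seq_len(nt)) {
    tt <- (0:(ns + 1)) / fs
    sig <- cos(2 * pi * 6 * tt + runif(1, 0, 2 * pi))
    car <- cos(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
    S <- sig + rnorm(ns + 2)
    Tt <- car * c(0, 0, sig[1:ns]) + rnorm(ns + 2)
    dat[tr, 1, ] <- S[3:(ns + 2)]
    dat[tr, 2, ] <- Tt[3:(ns + 2)]
  }
  te_ensemble(dat, fs = fs)
}

test_that("count-based p-values follow the permutation formula", {
  surr <- seq_len(199) / 1000
  expect_equal(scale_pvalue(1, surr), 1 / 200)       # above all surrogates
  expect_equal(scale_pvalue(0, surr), 1)             # below all surrogates
  expect_equal(scale_pvalue(median(surr), surr), 101 / 200, tolerance = 0.02)
  expect_error(scale_pvalue(1, numeric(0)), "surrogate")
})

test_that("max-drop ties break toward the smaller scale (higher frequency)", {
  fake <- structure(list(scales = data.frame(scale = 1:5,
                                             drop = rep(0.2, 5))),
                    class = "spectral_mte")
  expect_identical(max_drop(fake), 1L)
  fake$scales$drop <- c(0.1, 0.3, 0.3, 0.2, 0)
  expect_identical(max_drop(fake), 2L)
})

test_that("Algorithm I results satisfy their structural invariants", {
  ens <- tiny_coupled(31)
  link <- link_spec(1, 2, delta = 2)
  res <- suppressWarnings(
    spectral_mte(ens, link, side = "source", J0 = 4, n_perm = 12,
                 seed = 42, n_max = 1200))
  expect_s3_class(res, "spectral_mte")
  expect_identical(dim(res$surrogates), c(12L, 4L))
  expect_equal(res$scales$drop,
               res$mte_tot - apply(res$surrogates, 2, median),
               tolerance = 1e-12)
  expect_true(all(res$scales$p >= 1 / 13 & res$scales$p <= 1))
  expect_identical(res$scales$significant,
                   res$scales$p < res$alpha / res$J0)
  expect_identical(max_drop(res), res$max_drop_scale)
  expect_equal(res$scales$f_lo, 125 / 2^(2:5))
})

test_that("identical seeds reproduce Algorithm I bit-for-bit", {
  ens <- tiny_coupled(32)
  link <- link_spec(1, 2, delta = 2)
  r1 <- suppressWarnings(spectral_mte(ens, link, side = "target", J0 = 3,
                                      n_perm = 6, seed = 9, n_max = 800))
  r2 <- suppressWarnings(spectral_mte(ens, link, side = "target", J0 = 3,
                                      n_perm = 6, seed = 9, n_max = 800))
  r3 <- suppressWarnings(spectral_mte(ens, link, side = "target", J0 = 3,
                                      n_perm = 6, seed = 10, n_max = 800))
  expect_identical(r1$surrogates, r2$surrogates)
  expect_identical(r1$mte_tot, r2$mte_tot)
  expect_false(identical(r1$surrogates, r3$surrogates))
})

test_that("insufficient permutations for the Bonferroni level warn", {
  ens <- tiny_coupled(33, nt = 4L)
  link <- link_spec(1, 2, delta = 2)
  expect_warning(
    spectral_mte(ens, link, side = "source", J0 = 5, n_perm = 10,
                 seed = 1, n_max = 500),
    "cannot attain")
})

test_that("delay scan and significance test recover a strong linear link", {
  set.seed(34)
  a <- 1.2
  nt <- 8L; ns <- 500L
  dat <- array(NA_real_, c(nt, 2, ns))
  for (tr in seq_len(nt)) {
    s <- rnorm(ns)
    dat[tr, 1, ] <- s
    dat[tr, 2, ] <- a * c(0, 0, s[1:(ns - 2)]) + rnorm(ns)
  }
  ens <- te_ensemble(dat, fs = 100)
  sc <- scan_delay(ens, 1, 2, delays = 1:3, target_max_lag = 4, seed = 1)
  expect_identical(sc$delay, 2L)
  expect_identical(nrow(sc$table), 3L)
  link <- link_spec(1, 2, delta = 2, target_max_lag = 4)
  tst <- te_significance(ens, link, n_perm = 39, seed = 1)
  expect_equal(tst$p, 1 / 40)
  # uncoupled control: p should not be at the floor
  set.seed(35)
  ens0 <- te_ensemble(array(rnorm(nt * 2 * ns), c(nt, 2, ns)), fs = 100)
  tst0 <- te_significance(ens0, link, n_perm = 39, seed = 1)
  expect_gt(tst0$p, 0.05)
})

test_that("a lagged copy pins the significance test to its floor", {
  set.seed(36)
  nt <- 6L; ns <- 400L
  dat <- array(NA_real_, c(nt, 2, ns))
  for (tr in seq_len(nt)) {
    s <- rnorm(ns)
    dat[tr, 1, ] <- s
    dat[tr, 2, ] <- c(0, s[1:(ns - 1)])
  }
  ens <- te_ensemble(dat, fs = 100)
  tst <- te_significance(ens, link_spec(1, 2, delta = 1, target_max_lag = 2),
                         n_perm = 19, seed = 2)
  expect_equal(tst$p, 1 / 20)
})

test_that("no-op surrogates collapse the SOSO distribution", {
  ens <- tiny_coupled(37, nt = 4L, ns = 256L)
  link <- link_spec(1, 2, delta = 2, target_max_lag = 4)
  # block_size = trial length makes every shuffle the identity permutation
  res <- suppressWarnings(
    soso(ens, link, source_scale = 3, target_scale = 1, n_outer = 6,
         k_inner = 6, J0 = 4, block_size = 256L, seed = 3, n_max = 600))
  expect_lt(abs(res$delta_S), 0.01)
  expect_lt(max(abs(res$delta_surrogates)), 0.01)
  expect_gt(res$p, 0.1)
})

test_that("SOSO is reproducible and carries its structural invariants", {
  ens <- tiny_coupled(38, nt = 4L, ns = 256L)
  link <- link_spec(1, 2, delta = 2, target_max_lag = 4)
  r1 <- suppressWarnings(soso(ens, link, 3, 1, n_outer = 5, k_inner = 5,
                              J0 = 4, seed = 11, n_max = 500))
  r2 <- suppressWarnings(soso(ens, link, 3, 1, n_outer = 5, k_inner = 5,
                              J0 = 4, seed = 11, n_max = 500))
  expect_identical(r1$delta_surrogates, r2$delta_surrogates)
  expect_length(r1$delta_surrogates, 5L)
  expect_true(r1$p >= 1 / 6 && r1$p <= 1)
  expect_error(soso(ens, link, 9, 1, J0 = 4), "1..J0")
})
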