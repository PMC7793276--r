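# LA16 MODWT scaling filter, frozen from an independent wavelet reference
# implementation (PyWavelets sym8 dec_lo / sqrt(2))
LA16_G <- c(-0.0023917292557499763, -0.00038334544810999615,
             0.022411811521809776,   0.0053793058752399465,
            -0.10132432764281898,   -0.04332680770281957,
             0.3403726735943866,     0.5495533152690045,
             0.2576993351865374,    -0.036731254380379635,
            -0.01924676063166981,    0.03474523295558965,
             0.0026931943768799733, -0.010572843264179893,
            -0.00021419715011999785, 0.0013363966963999866)

test_that("least-asymmetric filters satisfy the MODWT filter identities", {
  for (L in c(8L, 16L)) {
    f <- la_filter(L)
    expect_s3_class(f, "wavelet_filter")
    expect_length(f$g, L)
    expect_length(f$h, L)
    expect_equal(sum(f$g), 1, tolerance = 1e-12)
    expect_lt(abs(sum(f$h)), 1e-10)
    expect_equal(sum(f$g^2), 0.5, tolerance = 1e-12)
    # quadrature-mirror relation h_l = (-1)^l g_{L-1-l}
    expect_equal(f$h, (-1)^(0:(L - 1)) * rev(f$g), tolerance = 1e-12)
  }
  expect_error(la_filter(10), "unsupported")
})

test_that("LA16 coefficients match the published table", {
  expect_equal(la_filter(16)$g, LA16_G, tolerance = 1e-14)
})

test_that("constant and impulse inputs behave as the transform predicts", {
  d <- modwt(rep(5, 64), "la8", J0 = 4)
  for (j in 1:4) expect_lt(max(abs(d$W[[j]])), 1e-10)
  expect_equal(imodwt(d), rep(5, 64), tolerance = 1e-10)
  # scaling filter sums to one, so the smooth stays at the signal level
  expect_equal(d$V, rep(5, 64), tolerance = 1e-10)

  x <- c(1, rep(0, 31))
  d <- modwt(x, "la8", J0 = 3)
  energy <- sum(vapply(d$W, function(w) sum(w^2), numeric(1))) + sum(d$V^2)
  expect_equal(energy, 1, tolerance = 1e-8)
})

test_that("perfect reconstruction, energy identity and shift commutation hold", {
  set.seed(11)
  for (N in c(64L, 257L, 1000L)) {
    x <- rnorm(N)
    for (fname in c("la8", "la16")) {
      for (J0 in unique(c(1L, modwt_max_level(N)))) {
        d <- modwt(x, fname, J0 = J0)
        expect_true(all(vapply(d$W, length, 1L) == N))
        expect_length(d$V, N)
        expect_lt(max(abs(imodwt(d) - x)), 1e-8)
        energy <- sum(vapply(d$W, function(w) sum(w^2), numeric(1))) +
          sum(d$V^2)
        expect_equal(energy, sum(x^2), tolerance = 1e-8)
      }
    }
    # circular shift commutes with the transform
    s <- 17L
    shift <- function(v) v[((seq_along(v) - 1 + s) %% length(v)) + 1]
    d1 <- modwt(shift(x), "la8", J0 = 3)
    d2 <- modwt(x, "la8", J0 = 3)
    for (j in 1:3) expect_lt(max(abs(d1$W[[j]] - shift(d2$W[[j]]))), 1e-8)
    expect_lt(max(abs(d1$V - shift(d2$V))), 1e-8)
  }
})

test_that("a band-centred sinusoid concentrates energy on its scale", {
  N <- 4096
  fs <- 1
  j <- 3
  fr <- mean(scale_band(j, fs))          # centre of the scale-3 band
  x <- cos(2 * pi * fr * (0:(N - 1)))
  d <- modwt(x, "la8", J0 = 5)
  en <- vapply(d$W, function(w) sum(w^2), numeric(1))
  total <- sum(en) + sum(d$V^2)
  expect_gt(en[j] / total, 0.6)
  expect_equal(which.max(en), j)
})

test_that("a cosine at fs/8 lands on scale 2 (or its edge-adjacent scale)", {
  fs <- 64
  x <- cos(2 * pi * (fs / 8) * (0:1023) / fs)
  d <- modwt(x, "la8", J0 = 4)
  v <- vapply(d$W, stats::var, numeric(1))
  expect_true(which.max(v) %in% c(2L, 3L))
})

test_that("nominal bands and maximum level follow the dyadic rules", {
  expect_equal(scale_band(1, 250), c(62.5, 125))
  expect_equal(scale_band(5, 240), c(3.75, 7.5))
  expect_equal(scale_band(1, 2), c(0.5, 1))
  expect_identical(modwt_max_level(1250), 10L)
  expect_identical(modwt_max_level(2), 1L)
  expect_identical(modwt_max_level(125000), 16L)
})

test_that("invalid decompositions are rejected", {
  expect_error(modwt(rnorm(16), "la8", J0 = 5), "J0")
  expect_error(modwt(c(1, NA, 3, 4), "la8", J0 = 1), "finite")
  d <- modwt(rnorm(64), "la8", J0 = 3)
  d$W[[2]] <- d$W[[2]][1:10]
  expect_error(imodwt(d), "length")
})

test_that("batched matrix transforms match the per-trial pyramid exactly", {
  set.seed(77)
  mat <- matrix(rnorm(6 * 128), nrow = 6)
  bd <- spectralTE:::batch_modwt(mat, "la8", 4)
  per <- apply(mat, 1, function(tr) modwt(tr, "la8", 4), simplify = FALSE)
  for (j in 1:4)
    expect_identical(bd$W[[j]], t(vapply(per, function(d) d$W[[j]],
                                         numeric(128))))
  expect_identical(spectralTE:::batch_imodwt(bd),
                   t(vapply(per, imodwt, numeric(128))))
  # per-row shuffling reproduces the per-trial RNG stream
  s1 <- local({ set.seed(5); spectralTE:::shuffle_rows(mat) })
  s2 <- local({ set.seed(5)
                t(vapply(seq_len(nrow(mat)),
                         function(r) block_permute(mat[r, ], 1),
                         numeric(128))) })
  expect_identical(s1, s2)
})
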