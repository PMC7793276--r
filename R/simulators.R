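# Seeded generators for the nine validation systems.  "full" presets are
# the reference study conditions; "reduced" presets trim duration/trial
# counts for desk-scale runs while keeping all dynamical parameters.

sim_presets <- list(
  `1` = list(fs = 125, duration = 10, n_trials = 100,
             reduced = c(duration = 5, n_trials = 20)),
  `2` = list(fs = 125, duration = 10, n_trials = 100,
             reduced = c(duration = 5, n_trials = 20)),
  `3` = list(fs = 120, duration = 10, n_trials = 100,
             reduced = c(duration = 10, n_trials = 20)),
  `4` = list(fs = 120, duration = 20, n_trials = 50,
             reduced = c(duration = 10, n_trials = 20)),
  `5` = list(fs = 240, duration = 10, n_trials = 50,
             reduced = c(duration = 5, n_trials = 20)),
  `6` = list(fs = 500, duration = 4, n_trials = 50,
             reduced = c(duration = 4, n_trials = 20)),
  `7` = list(fs = 125, duration = 5, n_trials = 50,
             reduced = c(duration = 5, n_trials = 20)),
  `8` = list(fs = 250, duration = 5, n_trials = 50,
             reduced = c(duration = 5, n_trials = 20)),
  `9` = list(fs = 250, duration = 10, n_trials = 50,
             reduced = c(duration = 5, n_trials = 20)))

#' Simulate one of the nine validation systems
#'
#' Seeded generators for the validation systems with known ground truth:
#' uncoupled harmonics (1), cross-frequency phase-amplitude coupling (2),
#' linearly coupled AR(2) oscillators (3), a bidirectional AR(2) pair (4),
#' a three-node sigmoid-coupled network with a distractor (5), delay-coupled
#' Rossler oscillators (6), many-to-one (7) and one-to-many (8)
#' phase-amplitude systems, and redundant multi-band routing (9).  The
#' returned ensemble carries \code{ground_truth} (true delay in samples,
#' true source/target scales at the default sampling rate, process roles).
#'
#' @param example integer 1..9.
#' @param preset \code{"full"} (reference study sizes) or \code{"reduced"}
#'   (20 trials at shortened duration, for desk-scale analysis).
#' @param seed RNG seed; identical seeds give bit-identical ensembles.
#' @param ... overrides passed to the underlying generator
#'   (\code{fs}, \code{duration}, \code{n_trials}, and per-system
#'   parameters such as \code{A}, \code{c1}, \code{epsilon}, \code{lambda}).
#' @return a \code{\link{te_ensemble}}.
#' @export
sim_system <- function(example, preset = c("full", "reduced"), seed = 1L,
                       ...) {
  preset <- match.arg(preset)
  example <- as.integer(example)
  if (!example %in% 1:9) stop("example must be 1..9")
  p <- sim_presets[[as.character(example)]]
  args <- list(fs = p$fs, duration = p$duration, n_trials = p$n_trials)
  if (preset == "reduced") {
    args$duration <- unname(p$reduced["duration"])
    args$n_trials <- as.integer(p$reduced["n_trials"])
  }
  dots <- list(...)
  args[names(dots)] <- dots
  set.seed(seed)
  gen <- switch(as.character(example),
                `1` = , `2` = , `7` = , `8` = gen_harmonic,
                `3` = , `4` = gen_ar2,
                `5` = gen_sigmoid_network,
                `6` = gen_rossler,
                `9` = gen_redundant)
  if (example %in% c(1, 2, 7, 8)) args$example <- example
  if (example %in% c(3, 4)) args$bidirectional <- example == 4
  do.call(gen, args)
}

# fresh uniform phase per draw
rphase <- function() stats::runif(1, 0, 2 * pi)

#' Harmonic phase-amplitude systems (validation examples 1, 2, 7, 8)
#'
#' Cosine sources with per-trial uniform random phases and i.i.d. Gaussian
#' observation noise; for the coupled variants the source's harmonic
#' component multiplicatively modulates the target carrier at the stated
#' sample delay (the coupling acts on the latent rhythm; \code{w} is
#' observation noise on the recorded signals).
#'
#' @param example 1 (uncoupled), 2 (one source band to one target band,
#'   delay 2), 7 (three source bands to one target band, delay 2) or 8
#'   (one source band to three target bands, delay 1).
#' @param fs,duration,n_trials sampling rate (Hz), trial length (s), trial
#'   count.
#' @param A amplitude (default 1).
#' @return a \code{\link{te_ensemble}} with processes \code{S0}, \code{T1}.
#' @export
gen_harmonic <- function(example, fs, duration, n_trials, A = 1) {
  N <- round(duration * fs)
  cfg <- switch(as.character(example),
    `1` = list(fsrc = 5,  fcar = 50, d = 0L, sd1 = 1,   sd2 = 1,
               gt = list(delay = NA_integer_, source_scale = NA_integer_,
                         target_scale = NA_integer_)),
    `2` = list(fsrc = 6,  fcar = 50, d = 2L, sd1 = 1,   sd2 = 1,
               gt = list(delay = 2L, source_scale = 4L, target_scale = 1L)),
    `7` = list(fsrc = c(12, 6, 3), fcar = 45, d = 2L, sd1 = 1, sd2 = 1,
               gt = list(delay = 2L, source_scale = c(3L, 4L, 5L),
                         target_scale = 1L)),
    `8` = list(fsrc = 5, fcar = c(100, 58, 30), d = 1L, sd1 = 0.4, sd2 = 1,
               gt = list(delay = 1L, source_scale = 5L,
                         target_scale = c(1L, 2L, 3L))),
    stop("gen_harmonic covers examples 1, 2, 7, 8"))
  d <- cfg$d
  dat <- array(NA_real_, c(n_trials, 2L, N))
  for (tr in seq_len(n_trials)) {
    ne <- N + d
    tt <- (0:(ne - 1)) / fs
    Ssig <- rowSums(vapply(cfg$fsrc, function(f)
      A * cos(2 * pi * f * tt + rphase()), numeric(ne)))
    S <- Ssig + stats::rnorm(ne, sd = cfg$sd1)
    car <- rowSums(vapply(cfg$fcar, function(f)
      A * cos(2 * pi * f * tt + rphase()), numeric(ne)))
    Tt <- if (example == 1) {
      car + stats::rnorm(ne, sd = cfg$sd2)
    } else {
      car * c(rep(0, d), Ssig[seq_len(ne - d)]) +
        stats::rnorm(ne, sd = cfg$sd2)
    }
    keep <- (d + 1):ne
    dat[tr, 1, ] <- S[keep]
    dat[tr, 2, ] <- Tt[keep]
  }
  gt <- c(cfg$gt, list(source = 1L, target = 2L, example = example))
  te_ensemble(dat, fs = fs, labels = c("S0", "T1"), ground_truth = gt)
}

#' Coupled AR(2) oscillator systems (validation examples 3 and 4)
#'
#' AR(2) recursions with oscillatory poles at the stated frequencies (pole
#' argument \code{2*pi*f/fs}) and radius \code{p}, linearly coupled, with
#' innovation terms and additive observation noise.  A burn-in of 1000
#' samples is discarded per trial.
#'
#' @param fs,duration,n_trials size parameters.
#' @param bidirectional FALSE for example 3 (unidirectional, delay 2), TRUE
#'   for example 4 (mutual coupling at delay 1).
#' @param f1,f2 pole frequencies (Hz).  Example 3 defaults: both 45 Hz.
#' @param p pole radius (< 1 for stability).
#' @param c1,c2 coupling strengths (example 3 uses \code{c1} only).
#' @param sigma1,sigma2 innovation scales.
#' @param obs_sd observation-noise standard deviation (default 1).
#' @return a \code{\link{te_ensemble}} with processes \code{S0}, \code{T1}
#'   (or \code{y0}, \code{y1}).
#' @export
gen_ar2 <- function(fs, duration, n_trials, bidirectional = FALSE,
                    f1 = if (bidirectional) 5 else 45,
                    f2 = 45, p = 0.98,
                    c1 = if (bidirectional) 0.3 else 0.7,
                    c2 = 0.2,
                    sigma1 = if (bidirectional) 0.6 else 0.3,
                    sigma2 = if (bidirectional) 0.7 else 0.45,
                    obs_sd = 1) {
  if (p >= 1) stop("pole radius p must be < 1 for stability")
  N <- round(duration * fs)
  burn <- 1000L
  a1 <- 2 * p * cos(2 * pi * f1 / fs); a2 <- -p^2
  b1 <- 2 * p * cos(2 * pi * f2 / fs); b2 <- -p^2
  d <- if (bidirectional) 1L else 2L
  dat <- array(NA_real_, c(n_trials, 2L, N))
  for (tr in seq_len(n_trials)) {
    n_tot <- N + burn
    s <- numeric(n_tot); y <- numeric(n_tot)
    e1 <- stats::rnorm(n_tot, sd = sigma1)
    e2 <- stats::rnorm(n_tot, sd = sigma2)
    for (t in 3:n_tot) {
      s[t] <- a1 * s[t - 1] + a2 * s[t - 2] + e1[t] +
        if (bidirectional && t > d) c1 * y[t - d] else 0
      y[t] <- b1 * y[t - 1] + b2 * y[t - 2] + e2[t] +
        if (t > d) (if (bidirectional) c2 else c1) * s[t - d] else 0
    }
    keep <- (burn + 1):n_tot
    dat[tr, 1, ] <- s[keep] + stats::rnorm(N, sd = obs_sd)
    dat[tr, 2, ] <- y[keep] + stats::rnorm(N, sd = obs_sd)
  }
  labs <- if (bidirectional) c("y0", "y1") else c("S0", "T1")
  gt <- if (bidirectional) {
    list(delay = 1L, source_scale = 4L, target_scale = 4L,
         reverse_source_scale = 1L, reverse_target_scale = 1L,
         source = 1L, target = 2L, example = 4L)
  } else {
    list(delay = 2L, source_scale = 1L, target_scale = 1L,
         source = 1L, target = 2L, example = 3L)
  }
  te_ensemble(dat, fs = fs, labels = labs, ground_truth = gt)
}

#' Three-node sigmoid-coupled network (validation example 5)
#'
#' A narrow-band (6 Hz +/- 0.2 Hz) Gaussian-noise driver, unit-variance
#' normalised, modulates the amplitude of an 80 Hz target carrier through a
#' sigmoid with slope \code{lambda} at a 2-sample delay; a 90 Hz distractor
#' node is independent of both.  Band-limiting here is generation-side
#' signal definition, not analysis filtering; a zero-phase (forward-
#' backward) order-4 Butterworth band-pass is used.
#'
#' @param fs,duration,n_trials size parameters.
#' @param f1,f2,f3 driver, target-carrier and distractor frequencies (Hz).
#' @param bw driver bandwidth (Hz).
#' @param lambda sigmoid slope (default 3; 0 gives a constant 1/2, i.e. no
#'   modulation).
#' @param A carrier amplitude.
#' @param noise_sd noise added to (driver, distractor, target).
#' @return a \code{\link{te_ensemble}} with processes \code{S0}, \code{T1},
#'   \code{S2}.
#' @export
gen_sigmoid_network <- function(fs, duration, n_trials, f1 = 6, f2 = 80,
                                f3 = 90, bw = 0.4, lambda = 3, A = 1,
                                noise_sd = c(1.2, 0.8, 0.6)) {
  N <- round(duration * fs)
  d <- 2L
  bf <- signal::butter(4, c(f1 - bw / 2, f1 + bw / 2) / (fs / 2), "pass")
  pad <- 2L * fs  # settle the zero-phase filter away from the kept window
  dat <- array(NA_real_, c(n_trials, 3L, N))
  for (tr in seq_len(n_trials)) {
    ne <- N + d + 2L * pad
    drv <- signal::filtfilt(bf, stats::rnorm(ne))
    drv <- drv / stats::sd(drv)
    tt <- (0:(ne - 1)) / fs
    g <- 1 / (1 + exp(-lambda * c(rep(0, d), drv[seq_len(ne - d)])))
    T1 <- A * sin(2 * pi * f2 * tt + rphase()) * g +
      stats::rnorm(ne, sd = noise_sd[3])
    S2 <- A * sin(2 * pi * f3 * tt + rphase()) +
      stats::rnorm(ne, sd = noise_sd[2])
    S0 <- drv + stats::rnorm(ne, sd = noise_sd[1])
    keep <- (pad + d + 1):(pad + d + N)
    dat[tr, 1, ] <- S0[keep]
    dat[tr, 2, ] <- T1[keep]
    dat[tr, 3, ] <- S2[keep]
  }
  gt <- list(delay = 2L, source_scale = 5L, target_scale = 1L,
             source = 1L, target = 2L, conditioning = 3L, example = 5L)
  te_ensemble(dat, fs = fs, labels = c("S0", "T1", "S2"), ground_truth = gt)
}

# one RK4 step of the coupled Rossler pair; drive = delayed x2 value
rossler_deriv <- function(st, w1, w2, eps, drive) {
  c(-w1 * st[2] - st[3] + eps * drive,
    w1 * st[1] + 0.15 * st[2],
    0.2 + st[3] * (st[1] - 10),
    -w2 * st[5] - st[6],
    w2 * st[4] + 0.15 * st[5],
    0.2 + st[6] * (st[4] - 10))
}

#' Delay-coupled Rossler oscillators (validation example 6)
#'
#' Two Rossler systems with natural frequencies \code{w1}, \code{w2}; the
#' second system's \code{x} drives the first's with strength \code{epsilon}
#' at a delay of \code{tau} samples.  Integrated with fixed-step 4th-order
#' Runge-Kutta; the model-time step per sample is chosen so the attractor's
#' cycling (about \code{w/(2*pi)} cycles per model time unit) appears at
#' \code{f_target} Hz at the given sampling rate.  Trials start from random
#' initial conditions; a transient is discarded; divergent trajectories are
#' regenerated from new initial conditions.
#'
#' Observables: \code{T0 = x1} (process 1, driven), \code{S1 = x2}
#' (process 2, driver).
#'
#' @param fs,duration,n_trials size parameters.
#' @param w1,w2 natural angular frequencies (model units).
#' @param epsilon coupling strength.
#' @param tau delay in samples.
#' @param f_target nominal observed oscillation frequency (Hz).
#' @return a \code{\link{te_ensemble}} with processes \code{T0}, \code{S1}.
#' @export
gen_rossler <- function(fs, duration, n_trials, w1 = 0.8, w2 = 0.9,
                        epsilon = 0.07, tau = 2L, f_target = 8) {
  N <- round(duration * fs)
  # anchor the slower oscillator at f_target so both rhythms sit at or
  # above it (both rhythms are meant to sit at ~8 Hz and upwards)
  h <- 2 * pi * f_target / (min(w1, w2) * fs)
  trans <- 2000L
  n_tot <- N + trans
  dat <- array(NA_real_, c(n_trials, 2L, N))
  for (tr in seq_len(n_trials)) {
    repeat {
      st <- c(stats::runif(2, -5, 5), stats::runif(1, 0, 0.5),
              stats::runif(2, -5, 5), stats::runif(1, 0, 0.5))
      x1h <- numeric(n_tot); x2h <- numeric(n_tot)
      ok <- TRUE
      for (i in seq_len(n_tot)) {
        x1h[i] <- st[1]; x2h[i] <- st[4]
        d0 <- if (i > tau) x2h[i - tau] else x2h[1]
        d1 <- if (i > tau - 1 && i < n_tot) x2h[i - tau + 1] else d0
        dh <- 0.5 * (d0 + d1)
        k1 <- rossler_deriv(st, w1, w2, epsilon, d0)
        k2 <- rossler_deriv(st + h / 2 * k1, w1, w2, epsilon, dh)
        k3 <- rossler_deriv(st + h / 2 * k2, w1, w2, epsilon, dh)
        k4 <- rossler_deriv(st + h * k3, w1, w2, epsilon, d1)
        st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (!all(is.finite(st)) || max(abs(st)) > 1e6) { ok <- FALSE; break }
      }
      if (ok) break
      message("divergent Rossler trajectory; regenerating initial condition")
    }
    dat[tr, 1, ] <- x1h[(trans + 1):n_tot]
    dat[tr, 2, ] <- x2h[(trans + 1):n_tot]
  }
  gt <- list(delay = 2L, source_scale = 5L, target_scale = NA_integer_,
             source = 2L, target = 1L, example = 6L)
  te_ensemble(dat, fs = fs, labels = c("T0", "S1"), ground_truth = gt)
}

#' Redundant multi-band routing system (validation example 9)
#'
#' The source is the sum of a strong 9 Hz component (\code{Astar = 2}) and
#' a unit-amplitude multi-frequency component; the target superposes (i) a
#' multi-frequency carrier modulated by the 9 Hz source component and (ii)
#' a 40 Hz carrier modulated by the multi-frequency source component, both
#' at a 1-sample delay.  The 9 Hz component is the only non-redundant
#' source stream (scale 4 at 250 Hz); the 40 Hz carrier is the receiving
#' band (scale 2); there is no direct scale-4-to-scale-2 transfer.
#'
#' @param fs,duration,n_trials size parameters.
#' @param Astar amplitude of the 9 Hz source component.
#' @param A amplitude of all other components.
#' @return a \code{\link{te_ensemble}} with processes \code{S0}, \code{T1}.
#' @export
gen_redundant <- function(fs, duration, n_trials, Astar = 2, A = 1) {
  N <- round(duration * fs)
  d <- 1L
  fset <- c(80, 40, 18, 9, 5)   # multi-frequency components (scales 1..5)
  g1 <- 40                      # y2 carrier
  dat <- array(NA_real_, c(n_trials, 2L, N))
  for (tr in seq_len(n_trials)) {
    ne <- N + d
    tt <- (0:(ne - 1)) / fs
    x1 <- Astar * cos(2 * pi * 9 * tt + rphase())
    z  <- rowSums(vapply(fset, function(f)
      A * cos(2 * pi * f * tt + rphase()), numeric(ne)))
    x2 <- rowSums(vapply(fset, function(f)
      A * cos(2 * pi * f * tt + rphase()), numeric(ne)))
    lag1 <- function(x) c(0, x[seq_len(ne - 1)])
    y1 <- z * lag1(x1)
    y2 <- A * cos(2 * pi * g1 * tt + rphase()) * lag1(x2)
    S0 <- x1 + x2 + stats::rnorm(ne)
    T1 <- y1 + y2 + stats::rnorm(ne)
    keep <- (d + 1):ne
    dat[tr, 1, ] <- S0[keep]
    dat[tr, 2, ] <- T1[keep]
  }
  gt <- list(delay = 1L, source_scale = 4L, target_scale = 2L,
             soso_direct = FALSE, source = 1L, target = 2L, example = 9L)
  te_ensemble(dat, fs = fs, labels = c("S0", "T1"), ground_truth = gt)
}
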