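#' Least-asymmetric (symlet) wavelet filters for the MODWT
#'
#' Returns the standard least-asymmetric Daubechies scaling and wavelet
#' filter coefficients of length 8 (LA8) or 16 (LA16), rescaled by
#' \code{1/sqrt(2)} as required by the maximal-overlap discrete wavelet
#' transform (MODWT) convention, so that \code{sum(g) == 1} and
#' \code{sum(g^2) == 1/2}.
#' The wavelet filter is derived from the scaling filter by the
#' quadrature-mirror relation \code{h[l] = (-1)^l * g[L - 1 - l]} (zero-based
#' \code{l}).
#'
#' @param length filter length, 8 or 16.
#' @return An object of class \code{"wavelet_filter"} with elements
#'   \code{name}, \code{h} (wavelet filter), \code{g} (scaling filter) and
#'   \code{L} (length).
#' @examples
#' f <- la_filter(8)
#' abs(sum(f$g) - 1) < 1e-10
#' abs(sum(f$h)) < 1e-10
#' @export
la_filter <- function(length = 8) {
  if (!length %in% c(8L, 16L))
    stop("unsupported filter length: ", length, " (use 8 or 16)")
  # unit-norm DWT scaling filters (Daubechies least-asymmetric family)
  g8 <- c(-0.075765714789273330, -0.029635527645998510,
           0.497618667632015450,  0.803738751805916100,
           0.297857795605277360, -0.099219543576847220,
          -0.012603967262037833,  0.032223100604042700)
  g16 <- c(-0.0033824159510061256, -0.0005421323317911481,
            0.0316950878114929800,  0.0076074873249176050,
           -0.1432942383508097000, -0.0612733590676585240,
            0.4813596512583722000,  0.7771857517005235000,
            0.3644418948353314000, -0.0519458381077090400,
           -0.0272190299170560030,  0.0491371796736075060,
            0.0038087520138906150, -0.0149522583370482300,
           -0.0003029205147213668,  0.0018899503327594609)
  g <- if (length == 8L) g8 else g16
  g <- g / sqrt(2)                       # MODWT rescaling
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)         # quadrature mirror
  structure(list(name = paste0("la", L), h = h, g = g, L = L),
            class = "wavelet_filter")
}

resolve_filter <- function(filter) {
  if (inherits(filter, "wavelet_filter")) return(filter)
  if (is.character(filter)) {
    return(switch(tolower(filter),
                  la8 = la_filter(8), la16 = la_filter(16),
                  stop("unknown wavelet filter: ", filter)))
  }
  if (is.numeric(filter) && filter %in% c(8, 16)) return(la_filter(filter))
  stop("cannot interpret 'filter' as a wavelet filter")
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat("Least-asymmetric MODWT filter", toupper(x$name),
      sprintf("(L = %d)\n", x$L))
  invisible(x)
}

#' Maximum MODWT decomposition level
#'
#' @param N number of samples (\code{N >= 2}).
#' @return \code{floor(log2(N))}.
#' @export
modwt_max_level <- function(N) {
  if (N < 2) stop("need at least 2 samples")
  as.integer(floor(log2(N)))
}

#' Nominal frequency band of a wavelet scale
#'
#' MODWT coefficients at scale \code{j} are associated with the nominal band
#' \code{(fs / 2^(j+1), fs / 2^j)}.
#'
#' @param j scale index (>= 1).
#' @param fs sampling rate in Hz.
#' @return numeric vector \code{c(f_lo, f_hi)} in Hz, at full precision.
#' @examples
#' scale_band(1, 250) # 62.5 .. 125 Hz
#' scale_band(5, 240) # 3.75 .. 7.5 Hz
#' @export
scale_band <- function(j, fs) {
  stopifnot(j >= 1, fs > 0)
  c(fs / 2^(j + 1), fs / 2^j)
}

# circular shift used by the pyramid recursions: y[t] = x[(t - s) mod N]
circ_lag <- function(x, s) {
  N <- length(x)
  x[((seq_len(N) - 1 - s) %% N) + 1]
}

#' Maximal-overlap discrete wavelet transform (MODWT)
#'
#' Non-decimated, shift-invariant wavelet transform computed by the pyramid
#' algorithm with circular ("mod N") boundary treatment.  The decomposition
#' of a length-\code{N} series into \code{J0} levels consists of \code{J0}
#' wavelet-coefficient vectors and one scaling-coefficient vector, all of
#' length \code{N}, satisfying the energy identity
#' \code{sum(x^2) == sum_j sum(W[[j]]^2) + sum(V^2)} and exact inversion by
#' \code{\link{imodwt}}.
#'
#' @param x numeric series, all values finite.
#' @param filter a \code{"wavelet_filter"}, or \code{"la8"} / \code{"la16"}.
#' @param J0 number of levels, \code{1 <= J0 <= floor(log2(length(x)))}.
#' @param fs sampling rate in Hz (bookkeeping only; default 1).
#' @return Object of class \code{"modwt"}: list with \code{W} (list of
#'   \code{J0} coefficient vectors), \code{V} (scaling coefficients),
#'   \code{J0}, \code{filter}, \code{N}, \code{fs}.
#' @export
modwt <- function(x, filter = "la8", J0 = NULL, fs = 1) {
  if (!all(is.finite(x))) stop("input contains non-finite samples")
  N <- length(x)
  if (N < 2) stop("need at least 2 samples")
  filter <- resolve_filter(filter)
  if (is.null(J0)) J0 <- min(5L, modwt_max_level(N))
  if (J0 < 1 || J0 > modwt_max_level(N))
    stop("J0 must be between 1 and floor(log2(N)) = ", modwt_max_level(N))
  h <- filter$h; g <- filter$g; L <- filter$L
  W <- vector("list", J0)
  V <- x
  for (j in seq_len(J0)) {
    step <- 2^(j - 1)
    Wj <- numeric(N); Vj <- numeric(N)
    for (l in 0:(L - 1)) {
      s <- circ_lag(V, step * l)
      Wj <- Wj + h[l + 1] * s
      Vj <- Vj + g[l + 1] * s
    }
    W[[j]] <- Wj
    V <- Vj
  }
  structure(list(W = W, V = V, J0 = J0, filter = filter, N = N, fs = fs),
            class = "modwt")
}

#' Inverse MODWT
#'
#' Reconstructs the time series from a (possibly modified) MODWT
#' decomposition.  With unmodified coefficients the reconstruction equals
#' the original series to floating-point accuracy.
#'
#' @param d object of class \code{"modwt"}.
#' @return numeric series of length \code{d$N}.
#' @export
imodwt <- function(d) {
  stopifnot(inherits(d, "modwt"))
  N <- d$N
  if (length(d$V) != N || any(vapply(d$W, length, 1L) != N))
    stop("mismatched coefficient lengths in decomposition")
  h <- d$filter$h; g <- d$filter$g; L <- d$filter$L
  V <- d$V
  for (j in rev(seq_len(d$J0))) {
    step <- 2^(j - 1)
    Vm <- numeric(N)
    for (l in 0:(L - 1)) {
      Vm <- Vm + h[l + 1] * circ_lag(d$W[[j]], -step * l) +
                 g[l + 1] * circ_lag(V, -step * l)
    }
    V <- Vm
  }
  V
}

# Batched MODWT/IMODWT over the rows of a trials x N matrix.  Operation
# order per element matches the per-trial pyramid exactly, so results are
# bitwise identical to looping modwt()/imodwt() over trials.
circ_lag_cols <- function(m, s) {
  N <- ncol(m)
  m[, ((seq_len(N) - 1 - s) %% N) + 1, drop = FALSE]
}

batch_modwt <- function(mat, filter, J0) {
  filter <- resolve_filter(filter)
  h <- filter$h; g <- filter$g; L <- filter$L
  N <- ncol(mat)
  W <- vector("list", J0)
  V <- mat
  for (j in seq_len(J0)) {
    step <- 2^(j - 1)
    Wj <- matrix(0, nrow(mat), N); Vj <- matrix(0, nrow(mat), N)
    for (l in 0:(L - 1)) {
      s <- circ_lag_cols(V, step * l)
      Wj <- Wj + h[l + 1] * s
      Vj <- Vj + g[l + 1] * s
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V, J0 = J0, filter = filter, N = N)
}

batch_imodwt <- function(bd) {
  h <- bd$filter$h; g <- bd$filter$g; L <- bd$filter$L
  V <- bd$V
  for (j in rev(seq_len(bd$J0))) {
    step <- 2^(j - 1)
    Vm <- matrix(0, nrow(V), bd$N)
    for (l in 0:(L - 1)) {
      Vm <- Vm + h[l + 1] * circ_lag_cols(bd$W[[j]], -step * l) +
                 g[l + 1] * circ_lag_cols(V, -step * l)
    }
    V <- Vm
  }
  V
}

# per-row independent permutation of a coefficient matrix; draws one
# sample.int(N) per row in row order (the same RNG stream as calling
# block_permute(row, 1) trial by trial)
shuffle_rows <- function(m) {
  N <- ncol(m)
  ord <- t(vapply(seq_len(nrow(m)), function(r) sample.int(N),
                  integer(N)))
  matrix(m[cbind(rep(seq_len(nrow(m)), N), as.vector(ord))],
         nrow = nrow(m))
}

#' @export
print.modwt <- function(x, ...) {
  cat(sprintf("MODWT: N = %d, J0 = %d, filter = %s, fs = %g Hz\n",
              x$N, x$J0, toupper(x$filter$name), x$fs))
  for (j in seq_len(x$J0)) {
    b <- scale_band(j, x$fs)
    cat(sprintf("  scale %d: band %.4g-%.4g Hz, energy %.4g\n",
                j, b[1], b[2], sum(x$W[[j]]^2)))
  }
  cat(sprintf("  smooth : energy %.4g\n", sum(x$V^2)))
  invisible(x)
}
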