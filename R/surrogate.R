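#' Block permutation of a coefficient sequence
#'
#' Cuts the sequence into \code{ceiling(N / block_size)} contiguous blocks
#' (the last block may be short) and reorders the blocks by a uniform random
#' permutation, preserving the multiset of values exactly.  With
#' \code{block_size = 1} this is a simple random permutation.  Uses the
#' caller's RNG state; seed beforehand for reproducibility.
#'
#' @param x numeric sequence.
#' @param block_size block length in samples, \code{1 <= block_size <= N}.
#' @return permuted sequence of the same length.
#' @export
block_permute <- function(x, block_size = 1L) {
  N <- length(x)
  if (block_size < 1 || block_size > N)
    stop("block_size must be between 1 and length(x)")
  if (block_size == N) return(x)
  if (block_size == 1L) return(x[sample.int(N)])
  starts <- seq(1L, N, by = block_size)
  blocks <- lapply(starts, function(s) x[s:min(s + block_size - 1L, N)])
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

#' Iterative amplitude-adjusted Fourier transform (IAAFT) surrogate
#'
#' Produces a surrogate preserving the amplitude distribution of the input
#' exactly (values are a rank reassignment of the originals) and its power
#' spectrum approximately.  Starting from a full random shuffle (no
#' coefficients are retained), the iteration alternates spectrum matching
#' (impose the original Fourier magnitudes) and amplitude matching (replace
#' values by the sorted originals at the current ranks) until the rank
#' permutation is stable or \code{max_iter} is reached.  Applied to one
#' wavelet scale's coefficients at a time by the surrogate constructors.
#'
#' @param x numeric sequence (length >= 4).
#' @param max_iter iteration cap (default 100).
#' @return surrogate sequence.
#' @export
iaaft <- function(x, max_iter = 100L) {
  N <- length(x)
  if (N < 4) stop("IAAFT needs at least 4 samples")
  amp <- sort(x)
  target_mag <- Mod(stats::fft(x))
  s <- x[sample.int(N)]
  prev_rank <- integer(0)
  for (iter in seq_len(max_iter)) {
    f <- stats::fft(s)
    phase <- f / pmax(Mod(f), .Machine$double.eps)
    r <- Re(stats::fft(target_mag * phase, inverse = TRUE)) / N
    rk <- rank(r, ties.method = "first")
    s <- amp[rk]
    if (identical(rk, prev_rank)) return(s)
    prev_rank <- rk
  }
  warning("IAAFT did not converge within ", max_iter,
          " iterations; returning best iterate")
  s
}

shuffle_scale <- function(w, method, block_size) {
  switch(method,
         block = block_permute(w, block_size),
         iaaft = iaaft(w),
         stop("unknown surrogate method: ", method))
}

#' Frequency-specific source surrogate for one trial
#'
#' Decomposes the trial with the MODWT, destroys the temporal order of the
#' wavelet coefficients at scale \code{j} only (all other scales and the
#' scaling coefficients are left untouched), and reconstructs with the
#' inverse MODWT.  The result differs from the original only through the
#' shuffled scale's content; its power spectrum is approximately preserved.
#' Uses the caller's RNG state.
#'
#' @param x one trial of the series.
#' @param j scale to destroy, \code{1 <= j <= J0}.
#' @param filter wavelet filter (see \code{\link{modwt}}).
#' @param J0 decomposition depth.
#' @param method \code{"block"} or \code{"iaaft"}.
#' @param block_size block length for \code{method = "block"}.
#' @return surrogate trial of the same length.
#' @export
source_surrogate <- function(x, j, filter = "la8", J0 = 5L,
                             method = c("block", "iaaft"), block_size = 1L) {
  method <- match.arg(method)
  if (j < 1 || j > J0) stop("scale j must be in 1..J0")
  d <- modwt(x, filter = filter, J0 = J0)
  d$W[[j]] <- shuffle_scale(d$W[[j]], method, block_size)
  imodwt(d)
}

#' Frequency-specific target surrogate for one trial
#'
#' Identical reconstruction pipeline to \code{\link{source_surrogate}}; the
#' contract that only the target's present value is replaced is enforced
#' downstream by \code{\link{embed_ensemble}}'s \code{override_present}
#' (this surrogate series supplies \code{y_now}; \code{y_past} stays from
#' the original target).
#'
#' @inheritParams source_surrogate
#' @param r target scale to destroy.
#' @return surrogate trial (for present values only).
#' @export
target_surrogate <- function(x, r, filter = "la8", J0 = 5L,
                             method = c("block", "iaaft"), block_size = 1L) {
  source_surrogate(x, r, filter = filter, J0 = J0, method = method,
                   block_size = block_size)
}

# surrogate of one whole process (trials x samples matrix), fresh
# permutation per trial; shared by the spectral algorithms
surrogate_matrix <- function(mat, j, filter, J0, method, block_size) {
  t(apply(mat, 1, function(tr)
    source_surrogate(tr, j, filter = filter, J0 = J0, method = method,
                     block_size = block_size)))
}
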