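#' Multi-trial multichannel ensemble
#'
#' The unit of all analyses: a \code{trials x processes x samples} numeric
#' array with a sampling rate.  All trials must have the same length and the
#' data must be free of non-finite values.
#'
#' @param data 3-d array (trials x processes x samples), or a matrix
#'   (processes x samples) for a single trial.
#' @param fs sampling rate in Hz.
#' @param labels optional per-process identifiers.
#' @param ground_truth optional list describing simulated coupling (used by
#'   the bundled generators: true delay in samples, true source/target
#'   scales).
#' @return Object of class \code{"te_ensemble"}.
#' @export
te_ensemble <- function(data, fs, labels = NULL, ground_truth = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop("data must be a trials x processes x samples array")
  if (!all(is.finite(data))) stop("ensemble contains non-finite values")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  d <- dim(data)
  if (is.null(labels)) labels <- paste0("P", seq_len(d[2]) - 1L)
  if (length(labels) != d[2]) stop("labels must name every process")
  structure(list(data = data, fs = fs, labels = labels,
                 ground_truth = ground_truth),
            class = "te_ensemble")
}

#' @export
print.te_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Ensemble: %d trials x %d processes x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  processes:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$ground_truth))
    cat("  simulated ground truth available (",
        paste(names(x$ground_truth), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

n_trials  <- function(ens) dim(ens$data)[1]
n_samples <- function(ens) dim(ens$data)[3]

# one process as a trials x samples matrix
proc_matrix <- function(ens, p) {
  m <- ens$data[, p, , drop = FALSE]
  dim(m) <- dim(ens$data)[c(1, 3)]
  m
}

#' Default target-history depth
#'
#' The deepest target lag is chosen to cover a quarter cycle of the lowest
#' analysed frequency: with \code{J0} wavelet levels the lowest nominal band
#' starts at \code{fs / 2^(J0+1)}, giving \code{ceiling(2^(J0+1) / 4)} =
#' \code{2^(J0-1)} samples.
#'
#' @param fs sampling rate (Hz).
#' @param J0 number of wavelet levels.
#' @param f_low optional explicit lowest frequency of interest (Hz),
#'   overriding the band rule.
#' @return integer lag depth in samples.
#' @export
target_history_depth <- function(fs, J0, f_low = NULL) {
  if (is.null(f_low)) f_low <- fs / 2^(J0 + 1)
  max(1L, as.integer(ceiling(fs / (4 * f_low))))
}

#' Dyadically spaced embedding lags
#'
#' Lags \code{1, 2, 4, ...} up to and including \code{depth}: one embedding
#' dimension per octave of history, so a quarter-cycle of the lowest
#' analysed band is covered with \code{O(log2(depth))} dimensions.
#'
#' @param depth deepest lag in samples.
#' @return integer vector of lags.
#' @export
dyadic_lags <- function(depth) {
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  as.integer(sort(unique(c(2^(0:floor(log2(depth))), depth))))
}

#' Link specification
#'
#' Identifies a source-target pair with optional conditioning processes and
#' the embedding parameters: coupling delay \code{delta} (samples), source
#' past lags, deepest target-history lag and conditioning lags.
#'
#' @param source,target process indices (1-based), distinct.
#' @param conditioning integer vector of conditioning process indices (may
#'   be empty); must not contain source or target.
#' @param delta coupling delay in samples (>= 1).
#' @param source_lags past-sample offsets for the source (default
#'   \code{delta} only).
#' @param target_max_lag deepest target past lag; defaults at embedding time
#'   to \code{\link{target_history_depth}}.
#' @param target_lags explicit target past lags.  Default: dyadically
#'   spaced lags \code{1, 2, 4, ...} up to \code{target_max_lag}
#'   (\code{\link{dyadic_lags}}), covering the required history depth with
#'   one embedding dimension per octave rather than one per sample, which
#'   keeps the nearest-neighbour estimator usable at moderate sample
#'   counts.
#' @param cond_lags offsets for the conditioning pasts (default \code{1:3}).
#' @return Object of class \code{"link_spec"}.
#' @export
link_spec <- function(source, target, conditioning = integer(0), delta = 1L,
                      source_lags = NULL, target_max_lag = NULL,
                      target_lags = NULL, cond_lags = 1:3) {
  source <- as.integer(source); target <- as.integer(target)
  conditioning <- as.integer(conditioning)
  if (source == target) stop("source and target must differ")
  if (source %in% conditioning || target %in% conditioning)
    stop("conditioning set must not contain the source or the target")
  if (delta < 1) stop("delta must be >= 1 sample")
  if (is.null(source_lags)) source_lags <- as.integer(delta)
  source_lags <- as.integer(source_lags)
  if (any(source_lags < 1) || any(cond_lags < 1))
    stop("all lags must be >= 1")
  if (!is.null(target_max_lag) && target_max_lag < 1)
    stop("target_max_lag must be >= 1")
  if (!is.null(target_lags)) {
    target_lags <- as.integer(target_lags)
    if (any(target_lags < 1)) stop("all lags must be >= 1")
    if (is.null(target_max_lag)) target_max_lag <- max(target_lags)
  }
  structure(list(source = source, target = target,
                 conditioning = conditioning, delta = as.integer(delta),
                 source_lags = source_lags,
                 target_max_lag = if (is.null(target_max_lag)) NULL
                                  else as.integer(target_max_lag),
                 target_lags = target_lags,
                 cond_lags = as.integer(cond_lags)),
            class = "link_spec")
}

#' @export
print.link_spec <- function(x, ...) {
  cat(sprintf("Link: %d -> %d, delta = %d, source lags {%s}\n",
              x$source, x$target, x$delta,
              paste(x$source_lags, collapse = ",")))
  if (length(x$conditioning))
    cat("  conditioning on:", paste(x$conditioning, collapse = ", "),
        "at lags", paste(x$cond_lags, collapse = ","), "\n")
  invisible(x)
}
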