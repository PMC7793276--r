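#' State-space embedding of an ensemble for one link
#'
#' Builds the pooled state vectors used by the transfer-entropy estimator:
#' present target samples \code{y_now}, target history \code{y_past}, source
#' history \code{x_past} and conditioning histories \code{z_past}.  Rows are
#' taken only from time indices where every lag is in bounds within its own
#' trial; no embedding vector spans a trial boundary.
#'
#' The override arguments implement the surrogate contracts: with
#' \code{override_present}, \code{y_now} is read from the override series at
#' the same indices while \code{y_past} remains from the original target
#' (the target-surrogate contract: only the present value is replaced).
#' With \code{override_source}, \code{x_past} is embedded from the override.
#'
#' @param ens a \code{\link{te_ensemble}}.
#' @param link a \code{\link{link_spec}}.  A \code{NULL}
#'   \code{target_max_lag} is resolved with
#'   \code{\link{target_history_depth}} at \code{J0 = 5}.
#' @param override_present,override_source optional trials x samples
#'   matrices replacing the target (present value only) or source series.
#' @return Object of class \code{"te_embedding"}: list with matrices
#'   \code{y_now}, \code{y_past}, \code{x_past}, \code{z_past},
#'   \code{n_points}, and the row index (\code{trial}, \code{t}).
#' @export
embed_ensemble <- function(ens, link, override_present = NULL,
                           override_source = NULL) {
  stopifnot(inherits(ens, "te_ensemble"), inherits(link, "link_spec"))
  ns <- n_samples(ens); nt <- n_trials(ens)
  tml <- link$target_max_lag
  if (is.null(tml)) tml <- target_history_depth(ens$fs, 5L)
  tlags <- link$target_lags
  if (is.null(tlags)) tlags <- dyadic_lags(tml)
  zl <- if (length(link$conditioning)) link$cond_lags else integer(0)
  maxlag <- max(tml, link$source_lags, zl)
  if (maxlag >= ns)
    stop("lag (", maxlag, ") exceeds trial length (", ns, ")")

  tt <- (maxlag + 1L):ns                 # valid time indices in every trial
  trial <- rep(seq_len(nt), each = length(tt))
  tvec <- rep(tt, times = nt)
  n_points <- length(tvec)

  tgt <- proc_matrix(ens, link$target)
  src <- proc_matrix(ens, link$source)
  lin <- function(tshift) trial + (tvec - tshift - 1L) * nt  # linear index

  y_now_src <- if (is.null(override_present)) tgt else override_present
  y_now <- matrix(y_now_src[lin(0L)], ncol = 1)
  y_past <- vapply(tlags, function(l) tgt[lin(l)], numeric(n_points))
  x_src <- if (is.null(override_source)) src else override_source
  x_past <- vapply(link$source_lags, function(l) x_src[lin(l)],
                   numeric(n_points))
  if (length(link$conditioning)) {
    z_past <- do.call(cbind, lapply(link$conditioning, function(p) {
      zm <- proc_matrix(ens, p)
      vapply(link$cond_lags, function(l) zm[lin(l)], numeric(n_points))
    }))
  } else {
    z_past <- matrix(numeric(0), nrow = n_points, ncol = 0)
  }
  structure(list(y_now = y_now, y_past = y_past, x_past = x_past,
                 z_past = z_past, n_points = n_points,
                 trial = trial, t = tvec, fs = ens$fs, link = link,
                 target_max_lag = tml, target_lags = tlags,
                 maxlag = maxlag),
            class = "te_embedding")
}

#' @export
print.te_embedding <- function(x, ...) {
  cat(sprintf(
    "Embedding: %d pooled points; dims y_past=%d, x_past=%d, z_past=%d\n",
    x$n_points, ncol(x$y_past), ncol(x$x_past), ncol(x$z_past)))
  invisible(x)
}
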