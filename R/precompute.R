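#' Coupling-delay scan
#'
#' Computes the multivariate transfer entropy with a single-sample source
#' past at each candidate delay and returns the delay maximising it.  The
#' physical coupling delay of the system shows up as the argmax.
#'
#' @param ens a \code{\link{te_ensemble}}.
#' @param source,target,conditioning process indices.
#' @param delays candidate delays in samples (default \code{1:3}).
#' @param k neighbour count.
#' @param J0 wavelet depth used only to set the default target-history
#'   depth.
#' @param target_max_lag deepest target lag; default
#'   \code{\link{target_history_depth}(fs, J0)}.
#' @param n_max pooled-point cap (seeded subsample shared across delays).
#' @param seed seed for subsampling and estimator jitter.
#' @param n_rep number of independent repetitions (fresh subsample rows and
#'   jitter per repetition; the reported mTE per delay is the mean).
#'   Repetition averaging matters when the pooled sample is much larger
#'   than \code{n_max}: per-evaluation estimator noise is of the order of
#'   the between-delay differences for weakly coupled systems.
#' @return Object of class \code{"delay_scan"}: data.frame \code{table}
#'   (delay, mte) and \code{delay}, the argmax.
#' @export
scan_delay <- function(ens, source, target, conditioning = integer(0),
                       delays = 1:3, k = 4L, J0 = 5L,
                       target_max_lag = NULL, n_max = 12200L, seed = 1L,
                       n_rep = 1L) {
  stopifnot(inherits(ens, "te_ensemble"), length(delays) >= 1)
  if (is.null(target_max_lag))
    target_max_lag <- target_history_depth(ens$fs, J0)
  vals <- matrix(NA_real_, n_rep, length(delays))
  for (r in seq_len(n_rep)) {
    rows <- NULL
    for (di in seq_along(delays)) {
      link <- link_spec(source, target, conditioning, delta = delays[di],
                        target_max_lag = target_max_lag)
      emb <- embed_ensemble(ens, link)
      if (is.null(rows) && emb$n_points > n_max)
        rows <- with_seed(subseed(seed, 999983L, r),
                          sort(sample.int(emb$n_points, n_max)))
      vals[r, di] <- mte(emb, k = k, rows = rows,
                         jitter_seed = subseed(seed, 1L, r))
    }
  }
  mvals <- colMeans(vals)
  structure(list(table = data.frame(delay = delays, mte = mvals),
                 reps = vals, delay = delays[which.max(mvals)]),
            class = "delay_scan")
}

#' @export
print.delay_scan <- function(x, ...) {
  cat("Delay scan (mTE in nats):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("  maximising delay:", x$delay, "samples\n")
  invisible(x)
}

#' Permutation significance of a link's total mTE
#'
#' Builds a null by exchanging the source relative to the target: with five
#' or more trials, whole trials of the source are randomly permuted across
#' the ensemble; with fewer trials the source is circularly rotated within
#' each trial (fallback, reported by message).  The count-based p-value is
#' \code{(1 + #\{mTE_perm >= mTE_tot\}) / (1 + n_perm)}.
#'
#' @param ens a \code{\link{te_ensemble}}.
#' @param link a \code{\link{link_spec}}.
#' @param k neighbour count.
#' @param n_perm number of permutations (>= 19).
#' @param seed master seed.
#' @param n_max pooled-point cap.
#' @return Object of class \code{"te_test"} with \code{mte_tot},
#'   \code{null} values and \code{p}.
#' @export
te_significance <- function(ens, link, k = 4L, n_perm = 100L, seed = 1L,
                            n_max = 12200L) {
  stopifnot(n_perm >= 19)
  if (is.null(link$target_max_lag))
    link$target_max_lag <- target_history_depth(ens$fs, 5L)
  emb <- embed_ensemble(ens, link)
  rows <- NULL
  if (emb$n_points > n_max)
    rows <- with_seed(subseed(seed, 999983L),
                      sort(sample.int(emb$n_points, n_max)))
  mte_tot <- mte(emb, k = k, rows = rows, jitter_seed = subseed(seed, 0L))

  src <- proc_matrix(ens, link$source)
  nt <- nrow(src); ns <- ncol(src)
  use_trials <- nt >= 5
  if (!use_trials)
    message("fewer than 5 trials: falling back to circular rotation of the source")
  null <- vapply(seq_len(n_perm), function(n) {
    smat <- with_seed(subseed(seed, 17L, n), {
      if (use_trials) {
        src[sample.int(nt), , drop = FALSE]
      } else {
        t(apply(src, 1, function(tr) {
          s <- sample(seq(ns %/% 4, 3 * ns %/% 4), 1)
          tr[((seq_len(ns) - 1 + s) %% ns) + 1]
        }))
      }
    })
    emb_s <- embed_ensemble(ens, link, override_source = smat)
    mte(emb_s, k = k, rows = rows, jitter_seed = subseed(seed, 0L))
  }, numeric(1))
  structure(list(mte_tot = mte_tot, null = null,
                 p = scale_pvalue(mte_tot, null), n_perm = n_perm),
            class = "te_test")
}

#' @export
print.te_test <- function(x, ...) {
  cat(sprintf("mTE_tot = %.4f nats; permutation p = %.4g (%d permutations)\n",
              x$mte_tot, x$p, x$n_perm))
  invisible(x)
}
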