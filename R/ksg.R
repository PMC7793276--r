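#' Nearest-neighbour conditional mutual information (KSG estimator 1)
#'
#' Kraskov--Stögbauer--Grassberger estimator of \code{I(X; Y | Z)} in nats,
#' using max-norm distances in the joint space and strictly-within-epsilon
#' neighbour counts in the marginal spaces (Frenzel--Pompe form):
#' \deqn{\psi(k) - \langle \psi(n_{xz}+1) + \psi(n_{yz}+1) - \psi(n_z+1)\rangle.}
#' With an empty \code{z} this reduces to the unconditional KSG mutual
#' information.  Finite-sample estimates may be negative.
#'
#' Exact ties make kNN estimators ill-defined; columns are therefore
#' z-scored and perturbed with seeded uniform jitter of amplitude
#' \code{1e-8} before the neighbour search.
#'
#' @param x,y numeric matrices (or vectors) with one row per observation.
#' @param z optional conditioning matrix; \code{NULL} or zero columns for
#'   unconditional MI.
#' @param k neighbour count (default 4).
#' @param jitter_seed seed for the tie-breaking jitter.
#' @param preprocess marginal preprocessing before the neighbour search:
#'   \code{"rank"} (default) applies a per-column normal-scores transform,
#'   making every marginal exactly standard normal so that changes in
#'   marginal shape (e.g. between original and surrogate series) cannot
#'   shift the estimator's bias; \code{"zscore"} only centres and scales;
#'   \code{"none"} uses the raw values.
#' @param exclude optional integer matrix (n x 2, 1-based row bounds): for
#'   each observation, the contiguous block of rows excluded from its
#'   neighbour searches and counts (a Theiler / dynamic-correlation
#'   exclusion window; the block must contain the observation itself).
#'   Default: each row excludes only itself.
#' @return estimate in nats.
#' @examples
#' set.seed(1)
#' x <- rnorm(2000); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(2000)
#' ksg_cmi(x, y)          # approx -0.5 * log(1 - 0.36) = 0.223 nats
#' @export
ksg_cmi <- function(x, y, z = NULL, k = 4, jitter_seed = 0L,
                    preprocess = c("rank", "zscore", "none"),
                    exclude = NULL) {
  preprocess <- match.arg(preprocess)
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(z)) z <- matrix(numeric(0), nrow = nrow(x), ncol = 0)
  z <- as.matrix(z)
  n <- nrow(x)
  if (n <= k) stop("need more observations than neighbours (n > k)")
  if (preprocess == "rank") {
    x <- rank_gauss_cols(x); y <- rank_gauss_cols(y)
    z <- rank_gauss_cols(z)
  } else if (preprocess == "zscore") {
    x <- standardize_cols(x); y <- standardize_cols(y)
    z <- standardize_cols(z)
  }
  x <- add_jitter(x, subseed(jitter_seed, 1L))
  y <- add_jitter(y, subseed(jitter_seed, 2L))
  z <- add_jitter(z, subseed(jitter_seed, 3L))
  psi_tab <- digamma(seq_len(n))
  if (is.null(exclude)) exclude <- cbind(seq_len(n), seq_len(n))
  .ksg_cmi_cpp(x, y, z, as.integer(k), psi_tab,
               as.integer(exclude[, 1] - 1L), as.integer(exclude[, 2] - 1L))
}

#' Multivariate transfer entropy of an embedded link
#'
#' Computes \code{mTE = I(T_t : S_past | T_past, Z_past)} from an embedding
#' produced by \code{\link{embed_ensemble}} with the \code{\link{ksg_cmi}}
#' estimator.  On an unmodified embedding this is the total multivariate
#' transfer entropy \code{mTE_tot} of the link.
#'
#' @param emb a \code{"te_embedding"}.
#' @param k neighbour count.
#' @param rows optional row subset (used to cap the pooled sample).
#' @param jitter_seed seed forwarded to \code{\link{ksg_cmi}}.
#' @param preprocess marginal preprocessing, see \code{\link{ksg_cmi}}.
#' @param theiler dynamic-correlation (Theiler) exclusion: embedding rows
#'   from the same trial within this many samples of the query row are
#'   excluded from its neighbour searches, so temporally overlapping (and
#'   hence partially duplicated) state vectors cannot masquerade as
#'   recurrences.  Default \code{NULL}: the deepest embedding lag.
#' @return mTE in nats.
#' @export
mte <- function(emb, k = 4, rows = NULL, jitter_seed = 0L,
                preprocess = "rank", theiler = NULL) {
  stopifnot(inherits(emb, "te_embedding"))
  y <- emb$y_now; xp <- emb$x_past
  zc <- cbind(emb$y_past, emb$z_past)
  trial <- emb$trial; tt <- emb$t
  if (!is.null(rows)) {
    y <- y[rows, , drop = FALSE]
    xp <- xp[rows, , drop = FALSE]
    zc <- zc[rows, , drop = FALSE]
    trial <- trial[rows]; tt <- tt[rows]
  }
  if (is.null(theiler)) theiler <- emb$maxlag
  key <- as.double(trial) * (max(tt) + theiler + 2) + tt
  lo <- findInterval(key - theiler - 0.5, key) + 1L
  hi <- findInterval(key + theiler + 0.5, key)
  ksg_cmi(xp, y, zc, k = k, jitter_seed = jitter_seed,
          preprocess = preprocess, exclude = cbind(lo, hi))
}

#' Convert nats to bits
#' @param x value in nats.
#' @return value in bits.
#' @export
nats_to_bits <- function(x) x / log(2)

# Internal fast path for repeated mTE evaluation where only one embedding
# block changes (surrogate loops).  Precomputes the rank-Gaussianised,
# jittered static blocks, the Theiler exclusion bounds and the digamma
# table once; per evaluation only the changing block is re-ranked.
# Numerically identical to mte() with preprocess = "rank".
mte_cache <- function(emb, rows = NULL, k = 4, jitter_seed = 0L,
                      theiler = NULL) {
  y <- emb$y_now; xp <- emb$x_past
  zc <- cbind(emb$y_past, emb$z_past)
  trial <- emb$trial; tt <- emb$t
  if (!is.null(rows)) {
    y <- y[rows, , drop = FALSE]
    xp <- xp[rows, , drop = FALSE]
    zc <- zc[rows, , drop = FALSE]
    trial <- trial[rows]; tt <- tt[rows]
  }
  if (is.null(theiler)) theiler <- emb$maxlag
  key <- as.double(trial) * (max(tt) + theiler + 2) + tt
  lo <- findInterval(key - theiler - 0.5, key) + 1L
  hi <- findInterval(key + theiler + 0.5, key)
  n <- nrow(y)
  jit <- function(m, id) add_jitter(rank_gauss_cols(m),
                                    subseed(jitter_seed, id))
  list(x = jit(xp, 1L), y = jit(y, 2L), z = jit(zc, 3L),
       k = as.integer(k), psi = digamma(seq_len(n)),
       lo = as.integer(lo - 1L), hi = as.integer(hi - 1L),
       jitter_seed = jitter_seed, n = n)
}

# evaluate with the x and/or y block replaced; raw values are rank-
# Gaussianised and jittered exactly as ksg_cmi would
mte_cached_eval <- function(cache, raw_x = NULL, raw_y = NULL) {
  x <- if (is.null(raw_x)) cache$x else
    add_jitter(rank_gauss_cols(as.matrix(raw_x)),
               subseed(cache$jitter_seed, 1L))
  y <- if (is.null(raw_y)) cache$y else
    add_jitter(rank_gauss_cols(as.matrix(raw_y)),
               subseed(cache$jitter_seed, 2L))
  .ksg_cmi_cpp(x, y, cache$z, cache$k, cache$psi, cache$lo, cache$hi)
}
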