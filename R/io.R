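#' Save an ensemble as CSV-per-trial
#'
#' Writes one CSV per trial (\code{trial_001.csv}, ...; samples x processes,
#' header row = process labels) plus a \code{meta.json} with the sampling
#' rate and any ground truth.
#'
#' @param ens a \code{\link{te_ensemble}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "te_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- n_trials(ens)
  for (tr in seq_len(nt)) {
    m <- t(ens$data[tr, , , drop = TRUE])
    if (dim(ens$data)[2] == 1L) m <- matrix(ens$data[tr, 1, ], ncol = 1)
    colnames(m) <- ens$labels
    utils::write.csv(m, file.path(dir, sprintf("trial_%03d.csv", tr)),
                     row.names = FALSE)
  }
  meta <- list(fs = ens$fs, labels = ens$labels, n_trials = nt,
               n_samples = n_samples(ens))
  if (!is.null(ens$ground_truth)) meta$ground_truth <- ens$ground_truth
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load an ensemble from a CSV-per-trial directory
#'
#' Expects the layout written by \code{\link{save_ensemble}}: per-trial CSV
#' files (samples x processes, with a header row supplying the process
#' labels) and optionally a \code{meta.json} carrying \code{fs}.
#'
#' @param dir directory of trial CSVs.
#' @param fs sampling rate; required when no \code{meta.json} is present.
#' @return a \code{\link{te_ensemble}}.
#' @export
load_ensemble <- function(dir, fs = NULL) {
  files <- sort(list.files(dir, pattern = "^trial_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trial_*.csv files found in ", dir)
  meta_path <- file.path(dir, "meta.json")
  gt <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(fs)) fs <- as.numeric(meta$fs)
    gt <- meta$ground_truth
  }
  if (is.null(fs)) stop("sampling rate missing: no meta.json and no fs given")
  trials <- lapply(files, function(f)
    as.matrix(utils::read.csv(f, check.names = FALSE)))
  ns <- vapply(trials, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("ragged trial lengths: ", basename(files[which(ns != ns[1])[1]]),
         " has ", ns[which(ns != ns[1])[1]], " samples, expected ", ns[1])
  np <- ncol(trials[[1]])
  dat <- array(NA_real_, c(length(trials), np, ns[1]))
  for (tr in seq_along(trials)) dat[tr, , ] <- t(trials[[tr]])
  te_ensemble(dat, fs = fs, labels = colnames(trials[[1]]),
              ground_truth = gt)
}

#' Persist an analysis bundle
#'
#' Writes \code{summary.json} (scalars, p-values, scales, bands in Hz),
#' per-side surrogate-distribution CSVs suitable for histogram re-plotting,
#' and a \code{run_log.txt} with all parameters and seeds.
#'
#' @param bundle result of \code{\link{run_analysis}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
save_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (side in c("source", "target")) {
    res <- bundle[[side]]
    if (!is.null(res))
      utils::write.csv(surrogate_table(res),
                       file.path(dir, paste0("surrogates_", side, ".csv")),
                       row.names = FALSE)
  }
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' End-to-end spectral TE analysis run
#'
#' Ties together the precomputation (delay scan and link significance),
#' Algorithm I on both sides, and optional SOSO tests for named scale
#' pairs, from a flat configuration list.  Runs with identical
#' configuration and seed are deterministic.
#'
#' Config keys: either \code{example} (1..9, with optional \code{preset})
#' or \code{input} (a CSV-per-trial directory); \code{source},
#' \code{target}, \code{conditioning} (process indices; defaulted from
#' simulator ground truth when available); \code{J0}, \code{n_perm},
#' \code{method}, \code{block_size}, \code{alpha}, \code{knn},
#' \code{seed}, \code{n_max}, \code{delays}, \code{n_perm_test};
#' \code{soso_pairs} (list of \code{c(source_scale, target_scale)}),
#' \code{soso_n_outer}, \code{soso_k_inner}.
#'
#' @param config named list (or path to a JSON file with one object).
#' @return a result bundle: \code{summary} (list), \code{source},
#'   \code{target} (\code{"spectral_mte"} objects), \code{soso} (list of
#'   \code{"soso"} objects), \code{log} (character).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a named list or a JSON path")
  get_cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  seed <- as.integer(get_cfg("seed", 1L))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (!is.null(config$example)) {
    ens <- sim_system(config$example, preset = get_cfg("preset", "reduced"),
                      seed = seed)
    note("simulated example %s (%s preset, seed %d)", config$example,
         get_cfg("preset", "reduced"), seed)
  } else if (!is.null(config$input)) {
    ens <- load_ensemble(config$input, fs = get_cfg("fs"))
    note("loaded ensemble from %s", config$input)
  } else {
    stop("config error at key 'example'/'input': one of the two is required")
  }
  gt <- ens$ground_truth
  src <- as.integer(get_cfg("source", gt$source))
  tgt <- as.integer(get_cfg("target", gt$target))
  cond <- as.integer(get_cfg("conditioning",
                             if (is.null(gt$conditioning)) integer(0)
                             else gt$conditioning))
  if (!length(src) || !length(tgt))
    stop("config error at key 'source'/'target': required")
  J0 <- as.integer(get_cfg("J0", 5L))
  if (J0 > modwt_max_level(n_samples(ens)))
    stop("config error at key 'J0': exceeds floor(log2(trial length)) = ",
         modwt_max_level(n_samples(ens)))
  n_perm <- as.integer(get_cfg("n_perm", 50L))
  method <- get_cfg("method", "block")
  block_size <- as.integer(get_cfg("block_size", 1L))
  alpha <- as.numeric(get_cfg("alpha", 0.05))
  k <- as.integer(get_cfg("knn", 4L))
  n_max <- as.integer(get_cfg("n_max", 3000L))
  filter <- get_cfg("filter", "la8")
  delays <- as.integer(get_cfg("delays", 1:3))

  scan <- scan_delay(ens, src, tgt, cond, delays = delays, k = k, J0 = J0,
                     n_max = n_max, seed = seed)
  note("delay scan over {%s}: argmax %d samples (%.1f ms)",
       paste(delays, collapse = ","), scan$delay, 1000 * scan$delay / ens$fs)
  link <- link_spec(src, tgt, cond, delta = scan$delay,
                    target_max_lag = target_history_depth(ens$fs, J0))
  test <- te_significance(ens, link, k = k,
                          n_perm = as.integer(get_cfg("n_perm_test", 100L)),
                          seed = seed, n_max = n_max)
  note("link mTE_tot = %.4f nats, permutation p = %.4g", test$mte_tot,
       test$p)

  res_src <- spectral_mte(ens, link, side = "source", J0 = J0,
                          n_perm = n_perm, method = method,
                          block_size = block_size, alpha = alpha, k = k,
                          filter = filter, seed = seed, n_max = n_max)
  res_tgt <- spectral_mte(ens, link, side = "target", J0 = J0,
                          n_perm = n_perm, method = method,
                          block_size = block_size, alpha = alpha, k = k,
                          filter = filter, seed = seed, n_max = n_max)
  band <- function(j) scale_band(j, ens$fs)
  note("source max-drop scale %d (band %.4g-%.4g Hz); target max-drop scale %d (band %.4g-%.4g Hz)",
       res_src$max_drop_scale, band(res_src$max_drop_scale)[1],
       band(res_src$max_drop_scale)[2], res_tgt$max_drop_scale,
       band(res_tgt$max_drop_scale)[1], band(res_tgt$max_drop_scale)[2])

  soso_pairs <- get_cfg("soso_pairs")
  soso_res <- list()
  if (!is.null(soso_pairs)) {
    if (test$p >= alpha)
      stop("SOSO requested but the link's total mTE is not significant (p = ",
           format(test$p, digits = 3), "); refusing")
    if (is.matrix(soso_pairs))
      soso_pairs <- split(soso_pairs, row(soso_pairs))
    for (pair in soso_pairs) {
      s <- soso(ens, link, pair[[1]], pair[[2]],
                n_outer = as.integer(get_cfg("soso_n_outer", 30L)),
                k_inner = as.integer(get_cfg("soso_k_inner", 30L)),
                J0 = J0, method = method, block_size = block_size, k = k,
                filter = filter, seed = seed, n_max = n_max, alpha = alpha)
      note("SOSO %d -> %d: p = %.4g (%s)", s$source_scale, s$target_scale,
           s$p, if (s$significant) "direct" else "not direct")
      soso_res[[paste0(pair[[1]], "_", pair[[2]])]] <- s
    }
  }

  summary <- list(
    fs = ens$fs, J0 = J0, n_perm = n_perm, method = method,
    alpha = alpha, knn = k, seed = seed,
    delay = scan$delay, delay_ms = 1000 * scan$delay / ens$fs,
    mte_tot = test$mte_tot, link_p = test$p,
    source = list(max_drop_scale = res_src$max_drop_scale,
                  band_hz = band(res_src$max_drop_scale),
                  significant_scales = res_src$scales$scale[
                    res_src$scales$significant],
                  p = res_src$scales$p, drop = res_src$scales$drop),
    target = list(max_drop_scale = res_tgt$max_drop_scale,
                  band_hz = band(res_tgt$max_drop_scale),
                  significant_scales = res_tgt$scales$scale[
                    res_tgt$scales$significant],
                  p = res_tgt$scales$p, drop = res_tgt$scales$drop),
    soso = lapply(soso_res, function(s)
      list(source_scale = s$source_scale, target_scale = s$target_scale,
           delta_S = s$delta_S, p = s$p, significant = s$significant)))
  list(summary = summary, source = res_src, target = res_tgt,
       soso = soso_res, scan = scan, test = test, log = log)
}
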