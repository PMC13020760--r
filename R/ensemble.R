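# Instance ensembles at fixed parameters and their landscape-topology
# summary statistics.

#' Model configuration for instance ensembles
#'
#' Bundles everything needed to generate instances: pool size and SME
#' distribution, tuning parameters, the largest `M` analyzed for paths, the
#' ensemble size and the master seed. Two named presets correspond to the
#' calibrated operating points: `"gaussian_calibrated"` (unit-variance
#' Gaussian SMEs, `p = 0.26`, `ET = 2.0`) and `"pareto_calibrated"`
#' (Pareto-cutoff SMEs with `alpha = 0.7`, `xm = 0.1`, cutoff 2,
#' `p = 0.25`, `ET = 1.1`), both with `L = 500`.
#'
#' @param L number of sites (default 500, a typical protein length).
#' @param spec a [dist_spec()].
#' @param p greedy-step probability.
#' @param ET tuning target.
#' @param max_M_paths largest `M` for which the path space is analyzed
#'   (default 14; `2^M` states are enumerated per instance).
#' @param n_instances ensemble size (default 2000).
#' @param seed master seed; instance `i` runs on substream
#'   `substream_seed(seed, i)`.
#' @param preset optional preset name; explicitly supplied arguments
#'   override preset values.
#' @return an object of class `model_config`.
#' @examples
#' model_config(preset = "gaussian_calibrated", n_instances = 100, seed = 1)
#' @export
model_config <- function(L = 500, spec = dist_spec("gaussian"), p = 0.26,
                         ET = 2.0, max_M_paths = 14, n_instances = 2000,
                         seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("gaussian_calibrated", "pareto_calibrated"))
    if (preset == "gaussian_calibrated") {
      if (missing(spec)) spec <- dist_spec("gaussian")
      if (missing(p)) p <- 0.26
      if (missing(ET)) ET <- 2.0
    } else {
      if (missing(spec)) {
        spec <- dist_spec("pareto_cutoff", alpha = 0.7, xm = 0.1, cutoff = 2)
      }
      if (missing(p)) p <- 0.25
      if (missing(ET)) ET <- 1.1
    }
    if (missing(L)) L <- 500
  }
  stopifnot(inherits(spec, "dist_spec"))
  params <- tuning_params(p, ET)        # validates p, ET
  if (n_instances < 1) stop("`n_instances` must be >= 1", call. = FALSE)
  structure(list(L = as.integer(L), spec = spec, p = params$p,
                 ET = params$ET, max_M_paths = as.integer(max_M_paths),
                 n_instances = as.integer(n_instances),
                 seed = as.integer(seed), preset = preset),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "Model config%s: L = %d, p = %g, ET = %g, max_M_paths = %d, n = %d, seed = %d\n",
    if (is.null(x$preset)) "" else paste0(" (", x$preset, ")"),
    x$L, x$p, x$ET, x$max_M_paths, x$n_instances, x$seed))
  print(x$spec)
  invisible(x)
}

#' Generate one model instance
#'
#' Samples a zero-sum SME pool, tunes the blue and red references, and — if
#' `2 <= M <= max_M_paths` — enumerates the subcube and runs the full
#' path-space analysis. Fully reproducible from `(config, instance_seed)`:
#' the pool uses substream counter 1 and the reference pair counter 2.
#'
#' @param config a [model_config()].
#' @param instance_seed integer seed for this instance.
#' @return an object of class `episcape_instance` with fields `pool`,
#'   `pair`, `subcube` (or `NULL`), `result` (a [pathspace_result()], or
#'   `NULL`), `seed`. Signals `episcape_tuning_failure` if a reference
#'   cannot be tuned.
#' @export
generate_instance <- function(config, instance_seed) {
  stopifnot(inherits(config, "model_config"))
  pool <- sample_pool(config$spec, config$L,
                      seed = substream_seed(instance_seed, 1))
  pair <- build_reference_pair(pool, tuning_params(config$p, config$ET),
                               seed = substream_seed(instance_seed, 2))
  sub <- NULL
  res <- NULL
  if (pair$M >= 2L && pair$M <= config$max_M_paths) {
    sub <- enumerate_subcube(pool, pair, max_M = config$max_M_paths)
    res <- pathspace_result(sub)
  }
  structure(list(pool = pool, pair = pair, subcube = sub, result = res,
                 seed = as.integer(instance_seed)),
            class = "episcape_instance")
}

#' @export
print.episcape_instance <- function(x, ...) {
  print(x$pair)
  if (!is.null(x$result)) print(x$result)
  else cat(sprintf("Path space not analyzed (M = %d)\n", x$pair$M))
  invisible(x)
}

instance_row <- function(inst) {
  pair <- inst$pair
  res <- inst$result
  data.frame(
    seed = inst$seed, M = pair$M,
    EBref = pair$blue$Eref, ERref = pair$red$Eref,
    Eminref = pair$Eminref, Emaxref = pair$Emaxref,
    n_greedy_blue = pair$blue$n_greedy, n_greedy_red = pair$red$n_greedy,
    path_analyzed = !is.null(res),
    EC = if (is.null(res)) NA_real_ else res$EC,
    j = if (is.null(res)) NA_integer_ else res$j,
    single_jumper = if (is.null(res)) NA else res$single_jumper,
    proxy_single = if (is.null(res)) NA else res$proxy_single,
    n_paths = if (is.null(res)) NA_real_ else res$n_paths_at_EC,
    log_n_paths = if (is.null(res)) NA_real_ else res$log_n_paths,
    topology = if (is.null(res)) NA_character_ else res$topology,
    stringsAsFactors = FALSE)
}

#' Run an instance ensemble and summarize landscape topology
#'
#' Maps [generate_instance()] over `n_instances` independent substreams of
#' `config$seed`. Tuning failures are counted and the instance is resampled
#' from a fresh substream (counters beyond `n_instances`); a warning is
#' attached if failures exceed 1\% of the ensemble. Path statistics cover
#' instances with `2 <= M <= max_M_paths` only; all instances contribute to
#' the reference-pair statistics.
#'
#' @param config a [model_config()].
#' @return an object of class `ensemble_summary` with fields `config`,
#'   `instances` (one row per instance: `M`, `EBref`, `ERref`, `EC`, `j`,
#'   `n_paths`, flags, ...), `selected_smes` (data frame of the pooled
#'   selected SMEs with their instance index), `n_tuning_failures`, and
#'   `stats` (means, medians and standard errors of the headline
#'   quantities).
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "model_config"))
  n <- config$n_instances
  rows <- vector("list", n)
  smes <- vector("list", n)
  n_fail <- 0L
  for (i in seq_len(n)) {
    s <- substream_seed(config$seed, i)
    inst <- NULL
    repeat {
      inst <- tryCatch(generate_instance(config, s),
                       episcape_tuning_failure = function(e) NULL)
      if (!is.null(inst)) break
      n_fail <- n_fail + 1L
      if (n_fail > max(50L, n)) {
        stop("too many tuning failures; check (p, ET)", call. = FALSE)
      }
      s <- substream_seed(config$seed, n + n_fail)
    }
    rows[[i]] <- instance_row(inst)
    smes[[i]] <- data.frame(instance = i, h = inst$pair$selected_smes)
  }
  instances <- do.call(rbind, rows)
  out <- structure(list(
    config = config,
    instances = instances,
    selected_smes = do.call(rbind, smes),
    n_tuning_failures = n_fail,
    stats = ensemble_stats(instances)),
    class = "ensemble_summary")
  if (n_fail > 0.01 * n) {
    warning(sprintf("%d tuning failures over %d instances (> 1%%)",
                    n_fail, n))
  }
  out
}

se_mean <- function(x) sd(x) / sqrt(length(x))

ensemble_stats <- function(inst) {
  pa <- which(inst$path_analyzed)
  ng <- c(inst$n_greedy_blue, inst$n_greedy_red)
  ECr <- inst$EC[pa] / inst$Emaxref[pa]
  restricted <- pa[inst$proxy_single[pa]]
  ECr_restricted <- inst$EC[restricted] / inst$Emaxref[restricted]
  lognp <- if (length(pa)) {
    ag <- aggregate(log_n_paths ~ M, data = inst[pa, ], FUN = mean)
    setNames(ag$log_n_paths, ag$M)
  } else numeric(0)
  list(
    n_generated = nrow(inst),
    n_path_analyzed = length(pa),
    mean_M = mean(inst$M), se_M = se_mean(inst$M),
    median_M = median(inst$M),
    mean_EBref = mean(inst$EBref), se_EBref = se_mean(inst$EBref),
    mean_n_greedy = mean(ng), median_n_greedy = median(ng),
    mean_EC_over_Emaxref = mean(ECr), se_EC_over_Emaxref = se_mean(ECr),
    median_EC_over_Emaxref = median(ECr),
    mean_EC_over_Emaxref_restricted = mean(ECr_restricted),
    se_EC_over_Emaxref_restricted = se_mean(ECr_restricted),
    frac_proxy_single = mean(inst$proxy_single[pa]),
    frac_EC_below_Eminref = mean(inst$EC[pa] < inst$Eminref[pa]),
    mean_log_n_paths_by_M = lognp)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Ensemble of %d instances (%d path-analyzed, %d tuning failures)\n",
              s$n_generated, s$n_path_analyzed, x$n_tuning_failures))
  cat(sprintf("  mean M                 = %.3f (se %.3f)\n", s$mean_M, s$se_M))
  cat(sprintf("  mean EBref/ET          = %.3f\n",
              s$mean_EBref / x$config$ET))
  cat(sprintf("  mean n_greedy          = %.3f (median %g)\n",
              s$mean_n_greedy, s$median_n_greedy))
  cat(sprintf("  mean EC/Emaxref        = %.3f (restricted %.3f)\n",
              s$mean_EC_over_Emaxref, s$mean_EC_over_Emaxref_restricted))
  cat(sprintf("  P(single-jumper proxy) = %.3f\n", s$frac_proxy_single))
  cat(sprintf("  P(EC < Eminref)        = %.3f\n", s$frac_EC_below_Eminref))
  invisible(x)
}

#' Jumper position profile at fixed M
#'
#' Normalized histogram of the jumper position `j` (mutations from the blue
#' reference) over ensemble instances with the given `M` and a unique
#' jumper. Bins are the integers `1, ..., M - 1`.
#'
#' @param summary an [run_ensemble()] result.
#' @param M_value the stratum `M`.
#' @param min_n minimum number of qualifying instances (default 200);
#'   fewer raise a sample-size error.
#' @return named numeric vector of probabilities over `j = 1, ..., M - 1`,
#'   summing to 1.
#' @export
jumper_position_profile <- function(summary, M_value, min_n = 200) {
  stopifnot(inherits(summary, "ensemble_summary"))
  inst <- summary$instances
  sel <- inst$path_analyzed & inst$M == M_value &
    !is.na(inst$single_jumper) & inst$single_jumper
  j <- inst$j[sel]
  if (length(j) < min_n) {
    stop(errorCondition(
      sprintf("only %d instances at M = %d with a unique jumper (need >= %d)",
              length(j), M_value, min_n),
      class = c("episcape_sample_size_error", "error", "condition")))
  }
  counts <- tabulate(j, nbins = M_value - 1L)
  setNames(counts / sum(counts), seq_len(M_value - 1L))
}
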