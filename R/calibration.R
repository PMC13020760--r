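# Calibration pipeline: for each greedy probability p, find the tuning
# target ET(p) that enforces a mean mutation count <M> ~ 8, fit the linear
# ET(p) relation, scan p recording path-space statistics, and select the
# operating point as the smallest p whose single-jumper probability is
# still very close to one.

#' Configuration of the calibration pipeline
#'
#' @param L number of sites (default 500).
#' @param spec a [dist_spec()].
#' @param target_meanM target mean mutation count between the references
#'   (default 8, chosen to keep `2^M` path enumeration tractable).
#' @param p_grid increasing grid of greedy probabilities in `(0, 1)`.
#' @param n_per_point instances per Monte-Carlo evaluation (default 2000).
#' @param max_M_paths largest `M` analyzed for paths (default 14).
#' @param prob_threshold operating-point rule: smallest grid `p` whose
#'   single-jumper proxy probability is at least this (default 0.99).
#' @param seed master seed.
#' @return an object of class `calibration_config`.
#' @examples
#' calibration_config(spec = dist_spec("gaussian"), n_per_point = 200)
#' @export
calibration_config <- function(L = 500, spec = dist_spec("gaussian"),
                               target_meanM = 8,
                               p_grid = seq(0.05, 0.60, by = 0.05),
                               n_per_point = 2000, max_M_paths = 14,
                               prob_threshold = 0.99, seed = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  if (target_meanM < 2) stop("`target_meanM` must be >= 2", call. = FALSE)
  if (length(p_grid) == 0L || any(p_grid <= 0) || any(p_grid >= 1) ||
      is.unsorted(p_grid, strictly = TRUE)) {
    stop("`p_grid` must be strictly increasing within (0, 1)", call. = FALSE)
  }
  if (n_per_point < 100) stop("`n_per_point` must be >= 100", call. = FALSE)
  structure(list(L = as.integer(L), spec = spec,
                 target_meanM = target_meanM, p_grid = p_grid,
                 n_per_point = as.integer(n_per_point),
                 max_M_paths = as.integer(max_M_paths),
                 prob_threshold = prob_threshold, seed = as.integer(seed)),
            class = "calibration_config")
}

#' Mean mutation count between the tuned references
#'
#' Monte-Carlo estimate of `<M>`: over `config$n_per_point` independent
#' instances (pool resampled each time), the mean Hamming distance between
#' the blue and red references tuned with `(p, ET)`. Instances whose tuning
#' fails are skipped; a calibration warning is raised if they exceed 1\%.
#'
#' @param p greedy-step probability.
#' @param ET tuning target.
#' @param config a [calibration_config()].
#' @param seed master seed for the instance substreams (defaults to
#'   `config$seed`); evaluating different `ET` under the same seed gives
#'   common random numbers.
#' @return the mean `M` (with attribute `n_failures`).
#' @export
mean_M <- function(p, ET, config, seed = config$seed) {
  stopifnot(inherits(config, "calibration_config"))
  params <- tuning_params(p, ET)
  n <- config$n_per_point
  M <- rep(NA_real_, n)
  n_fail <- 0L
  for (i in seq_len(n)) {
    s <- substream_seed(seed, i)
    pair <- tryCatch({
      pool <- sample_pool(config$spec, config$L,
                          seed = substream_seed(s, 1))
      build_reference_pair(pool, params, seed = substream_seed(s, 2))
    }, episcape_tuning_failure = function(e) NULL)
    if (is.null(pair)) n_fail <- n_fail + 1L else M[i] <- pair$M
  }
  if (n_fail > 0.01 * n) {
    warning(sprintf("calibration: %d/%d tuning failures at p = %g, ET = %g",
                    n_fail, n, p, ET))
  }
  structure(mean(M, na.rm = TRUE), n_failures = n_fail)
}

#' Find the tuning target ET enforcing the mean-M constraint at fixed p
#'
#' Bisection on `ET` (after bracketing by doubling) until the Monte-Carlo
#' `<M>` is within `tol_M` of `config$target_meanM`. All evaluations share
#' the same instance seeds (common random numbers), which makes `<M>` a
#' stable, effectively monotone function of `ET` and the search
#' deterministic.
#'
#' @param p greedy-step probability in `(0, 1]`.
#' @param config a [calibration_config()].
#' @param seed seed for the common-random-number batch (defaults to
#'   `config$seed`).
#' @param tol_M stopping tolerance on `|<M> - target|` (default 0.25).
#' @return the calibrated `ET`.
#' @export
calibrate_ET_for_p <- function(p, config, seed = config$seed,
                               tol_M = 0.25) {
  stopifnot(inherits(config, "calibration_config"))
  if (p <= 0 || p > 1) stop("`p` must be in (0, 1]", call. = FALSE)
  target <- config$target_meanM
  f <- function(ET) as.numeric(mean_M(p, ET, config, seed = seed))
  lo <- 1e-3
  if (f(lo) >= target) {
    stop(errorCondition("mean M already exceeds target at tiny ET",
                        class = c("episcape_calibration_error", "error",
                                  "condition")))
  }
  hi <- 0.5
  m_hi <- f(hi)
  while (m_hi < target && hi < 64) {
    hi <- hi * 2
    m_hi <- f(hi)
  }
  if (m_hi < target) {
    stop(errorCondition("no ET in the search bracket reaches the target mean M",
                        class = c("episcape_calibration_error", "error",
                                  "condition")))
  }
  for (iter in seq_len(60)) {
    mid <- (lo + hi) / 2
    m <- f(mid)
    if (abs(m - target) < tol_M) return(mid)
    if (m < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-6) break
  }
  stop(errorCondition("ET bisection did not converge to the target mean M",
                      class = c("episcape_calibration_error", "error",
                                "condition")))
}

#' Ordinary least-squares line through the calibrated (p, ET) points
#'
#' @param points data frame with columns `p` and `ET` (>= 3 rows).
#' @return list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @examples
#' fit_ET_line(data.frame(p = c(0.1, 0.2, 0.3), ET = c(1.2, 1.4, 1.6)))
#' @export
fit_ET_line <- function(points) {
  stopifnot(is.data.frame(points), all(c("p", "ET") %in% names(points)))
  if (nrow(points) < 3) {
    stop("need at least 3 calibrated points for the line fit", call. = FALSE)
  }
  if (length(unique(points$p)) < 2) {
    stop("degenerate fit: all p values are equal", call. = FALSE)
  }
  fit <- lm(ET ~ p, data = points)
  co <- coef(fit)
  list(slope = unname(co["p"]), intercept = unname(co["(Intercept)"]),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Scan the p grid at line-calibrated ET and record path-space statistics
#'
#' For each grid `p`, with `ET` taken from the fitted line, generates
#' `n_per_point` instances and records: the calibrated `ET`; the mean `M`;
#' the mean `EBref/ET`; the mean `EC/Emaxref` restricted to path-analyzed
#' instances (`2 <= M <= max_M_paths`) satisfying the single-jumper proxy
#' `EC < 0.9 Eminref`; and the proxy probability itself (over path-analyzed
#' instances).
#'
#' @param config a [calibration_config()].
#' @param line a [fit_ET_line()] result.
#' @param seed master seed (defaults to `config$seed`).
#' @return a data frame with one row per grid `p`.
#' @export
scan_p <- function(config, line, seed = config$seed) {
  stopifnot(inherits(config, "calibration_config"))
  rows <- lapply(seq_along(config$p_grid), function(k) {
    p <- config$p_grid[k]
    ET <- line$intercept + line$slope * p
    if (ET <= 0) {
      # the linear ET(p) relation leaves no positive tuning target here
      return(data.frame(p = p, ET = ET, mean_M = NA_real_,
                        mean_EBref_over_ET = NA_real_,
                        mean_EC_over_Emaxref_restricted = NA_real_,
                        prob_proxy_single = NA_real_,
                        n_path_analyzed = NA_integer_))
    }
    mc <- model_config(L = config$L, spec = config$spec, p = p, ET = ET,
                       max_M_paths = config$max_M_paths,
                       n_instances = config$n_per_point,
                       seed = substream_seed(seed, 1000 + k))
    ens <- run_ensemble(mc)
    s <- ens$stats
    data.frame(p = p, ET = ET, mean_M = s$mean_M,
               mean_EBref_over_ET = s$mean_EBref / ET,
               mean_EC_over_Emaxref_restricted =
                 s$mean_EC_over_Emaxref_restricted,
               prob_proxy_single = s$frac_proxy_single,
               n_path_analyzed = s$n_path_analyzed)
  })
  do.call(rbind, rows)
}

#' Select the operating point from a calibration scan
#'
#' The smallest grid `p` whose single-jumper proxy probability reaches
#' `prob_threshold`, with its line-evaluated `ET`.
#'
#' @param per_p the [scan_p()] table (columns `p`, `ET`,
#'   `prob_proxy_single`).
#' @param prob_threshold required proxy probability (default 0.99).
#' @return list with `chosen_p` and `chosen_ET`.
#' @examples
#' tab <- data.frame(p = c(0.1, 0.2, 0.25, 0.4), ET = 1:4,
#'                   prob_proxy_single = c(0.6, 0.95, 0.995, 1.0))
#' select_p(tab)$chosen_p
#' @export
select_p <- function(per_p, prob_threshold = 0.99) {
  stopifnot(is.data.frame(per_p), nrow(per_p) >= 1)
  ok <- which(per_p$prob_proxy_single >= prob_threshold)
  if (length(ok) == 0L) {
    stop(errorCondition(
      "no grid point reaches the single-jumper probability threshold; widen the p grid",
      class = c("episcape_selection_error", "error", "condition")))
  }
  k <- min(ok)
  list(chosen_p = per_p$p[k], chosen_ET = per_p$ET[k])
}

#' Run the full calibration pipeline
#'
#' Calibrates `ET(p)` on the grid by bisection, fits the linear `ET(p)`
#' relation, scans the grid at line-evaluated `ET` recording path-space
#' statistics, and selects the operating point. Deterministic given
#' `(config, config$seed)`.
#'
#' At very small `p` the mean-`M` constraint can be infeasible: even as
#' `ET` approaches 0 a tuning trace still takes several steps (a
#' symmetric random walk needs a heavy-tailed number of steps for its
#' first passage above 0), so the mean `M` never drops to the target.
#' Such grid points are recorded with `ET_calibrated = NA`, excluded from
#' the line fit, and still scanned at the line-evaluated `ET`.
#'
#' @param config a [calibration_config()].
#' @return an object of class `calibration_result` with fields `per_p`
#'   (the scan table, plus the bisection `ET_calibrated` per `p`), `line`
#'   (`slope`, `intercept`, `r_squared`), `chosen_p`, `chosen_ET`,
#'   `config`.
#' @export
run_calibration <- function(config) {
  stopifnot(inherits(config, "calibration_config"))
  ET_cal <- vapply(seq_along(config$p_grid), function(k) {
    tryCatch(
      calibrate_ET_for_p(config$p_grid[k], config,
                         seed = substream_seed(config$seed, 500 + k)),
      episcape_calibration_error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(ET_cal)
  pts <- data.frame(p = config$p_grid[ok], ET = ET_cal[ok])
  line <- fit_ET_line(pts)
  per_p <- scan_p(config, line, seed = config$seed)
  per_p$ET_calibrated <- ET_cal
  sel <- select_p(per_p, config$prob_threshold)
  structure(list(per_p = per_p,
                 line = line[c("slope", "intercept", "r_squared")],
                 chosen_p = sel$chosen_p, chosen_ET = sel$chosen_ET,
                 config = config),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration: ET(p) = %.3f + %.3f p (R^2 = %.3f); chosen p = %g, ET = %.3f\n",
    x$line$intercept, x$line$slope, x$line$r_squared,
    x$chosen_p, x$chosen_ET))
  print(x$per_p, digits = 3)
  invisible(x)
}
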