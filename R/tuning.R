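# Construction of the red and blue reference variants from the all-zero
# ancestor by stochastic greedy/random mutation accumulation.

#' Parameters of the reference-variant tuning procedure
#'
#' @param p probability of a greedy step at each iteration (in `[0, 1]`).
#' @param ET tuning target on the trait (> 0): tuning stops the first time
#'   `E > ET` (blue) or `E < -ET` (red).
#' @return an object of class `tuning_params`.
#' @examples
#' tuning_params(p = 0.26, ET = 2)
#' @export
tuning_params <- function(p, ET) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(ET) || length(ET) != 1L || !is.finite(ET) || ET <= 0) {
    stop("`ET` must be > 0", call. = FALSE)
  }
  structure(list(p = p, ET = ET), class = "tuning_params")
}

#' Site chosen by a greedy tuning step
#'
#' The greedy step picks, among unoccupied sites, the one with maximum
#' impact towards the target: the largest `h` for blue, the smallest
#' (most negative) for red. Ties are broken by the lowest site index.
#'
#' @param pool an [sme_pool()][sample_pool].
#' @param occupied integer vector of already-mutated site indices.
#' @param color `"blue"` or `"red"`.
#' @return the chosen site index.
#' @examples
#' pool <- sample_pool(dist_spec("gaussian"), L = 5, seed = 1)
#' greedy_site(pool, occupied = integer(0), color = "blue")
#' @export
greedy_site <- function(pool, occupied, color = c("blue", "red")) {
  color <- match.arg(color)
  stopifnot(inherits(pool, "sme_pool"))
  occ <- logical(pool$L)
  occ[as.integer(occupied)] <- TRUE
  free <- which(!occ)
  if (length(free) == 0L) {
    stop(errorCondition("all sites are occupied",
                        class = c("episcape_exhaustion_error", "error",
                                  "condition")))
  }
  if (color == "blue") free[which.max(pool$h[free])]
  else                 free[which.min(pool$h[free])]
}

tuning_failure <- function(color) {
  stop(errorCondition(
    sprintf("tuning failed: all sites mutated without crossing the %s target",
            color),
    class = c("episcape_tuning_failure", "error", "condition")))
}

#' Tune one reference variant by greedy/random mutation accumulation
#'
#' Starting from the all-zero ancestor, each step is greedy (see
#' [greedy_site()]) with probability `p`, otherwise a uniformly random
#' unoccupied site is mutated (a random step may well oppose the target).
#' Tuning stops the first time the trait crosses the color's target
#' (`E > ET` for blue, `E < -ET` for red). If all `L` sites are mutated
#' without crossing, a `episcape_tuning_failure` condition is signalled.
#'
#' @param pool an [sme_pool()][sample_pool].
#' @param color `"blue"` or `"red"`.
#' @param params a [tuning_params()].
#' @param seed optional integer seed for this trace; if `NULL` the current
#'   RNG stream is consumed.
#' @return an object of class `reference_trace` with fields `genotype`
#'   (0/1 vector), `color`, `Eref` (trait of the tuned variant), `steps`
#'   (data frame of `site`, `kind`), `n_greedy`.
#' @examples
#' pool <- sample_pool(dist_spec("gaussian"), L = 50, seed = 1)
#' tr <- tune_reference(pool, "blue", tuning_params(p = 1, ET = 1))
#' tr$Eref > 1
#' @export
tune_reference <- function(pool, color = c("blue", "red"), params,
                           seed = NULL) {
  color <- match.arg(color)
  stopifnot(inherits(pool, "sme_pool"), inherits(params, "tuning_params"))
  if (!is.null(seed)) {
    return(with_seed(seed, tune_reference(pool, color, params, seed = NULL)))
  }
  h <- pool$h
  L <- pool$L
  sgn <- if (color == "blue") 1 else -1
  occ <- logical(L)
  E <- 0
  sites <- integer(L)
  kinds <- character(L)
  nstep <- 0L
  crossed <- FALSE
  while (nstep < L) {
    free <- which(!occ)
    is_greedy <- runif(1L) < params$p
    site <- if (is_greedy) {
      if (sgn > 0) free[which.max(h[free])] else free[which.min(h[free])]
    } else {
      free[sample.int(length(free), 1L)]
    }
    occ[site] <- TRUE
    E <- E + h[site]
    nstep <- nstep + 1L
    sites[nstep] <- site
    kinds[nstep] <- if (is_greedy) "greedy" else "random"
    if (sgn * E > params$ET) {
      crossed <- TRUE
      break
    }
  }
  if (!crossed) tuning_failure(color)
  steps <- data.frame(site = sites[seq_len(nstep)],
                      kind = kinds[seq_len(nstep)],
                      stringsAsFactors = FALSE)
  structure(list(genotype = as.integer(occ), color = color, Eref = E,
                 steps = steps, n_greedy = sum(steps$kind == "greedy")),
            class = "reference_trace")
}

#' @export
print.reference_trace <- function(x, ...) {
  cat(sprintf("Reference trace (%s): Eref = %.4g, %d steps (%d greedy)\n",
              x$color, x$Eref, nrow(x$steps), x$n_greedy))
  invisible(x)
}

#' Build the blue/red reference pair for one model instance
#'
#' Runs [tune_reference()] independently for the two colors (from two RNG
#' substreams derived from `seed` with counters 1 and 2) and records the
#' `M` sites where the two tuned genotypes differ, together with the pool
#' effects at those sites (the SMEs "selected by evolution").
#'
#' @param pool an [sme_pool()][sample_pool].
#' @param params a [tuning_params()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   consumed sequentially (blue first).
#' @return an object of class `reference_pair` with fields `blue`, `red`
#'   (the two [tune_reference()] traces), `M`, `diff_sites`,
#'   `selected_smes` (the `M` values `h_i` at the differing sites),
#'   `smes_by_reference` (the effects at each reference's own mutated
#'   sites, an alternative accounting that also includes sites mutated in
#'   both references), `Eminref = min(EBref, |ERref|)` and
#'   `Emaxref = max(EBref, |ERref|)`.
#' @examples
#' pool <- sample_pool(dist_spec("gaussian"), L = 100, seed = 1)
#' pair <- build_reference_pair(pool, tuning_params(p = 0.5, ET = 1), seed = 1)
#' pair$M
#' @export
build_reference_pair <- function(pool, params, seed = NULL) {
  if (!is.null(seed)) {
    blue <- tune_reference(pool, "blue", params,
                           seed = substream_seed(seed, 1))
    red <- tune_reference(pool, "red", params,
                          seed = substream_seed(seed, 2))
  } else {
    blue <- tune_reference(pool, "blue", params)
    red <- tune_reference(pool, "red", params)
  }
  diff_sites <- which(blue$genotype != red$genotype)
  structure(list(
    blue = blue, red = red,
    M = length(diff_sites),
    diff_sites = diff_sites,
    selected_smes = pool$h[diff_sites],
    smes_by_reference = list(blue = pool$h[blue$genotype == 1L],
                             red = pool$h[red$genotype == 1L]),
    Eminref = min(blue$Eref, abs(red$Eref)),
    Emaxref = max(blue$Eref, abs(red$Eref))),
    class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf(
    "Reference pair: M = %d, EBref = %.4g, ERref = %.4g (Eminref = %.4g)\n",
    x$M, x$blue$Eref, x$red$Eref, x$Eminref))
  invisible(x)
}

#' Serialize a reference pair to JSON
#'
#' Bitstring genotypes, reference traits and full step traces, for
#' per-instance dumps.
#'
#' @param pair a [build_reference_pair()] result.
#' @return a JSON string.
#' @export
pair_to_json <- function(pair) {
  stopifnot(inherits(pair, "reference_pair"))
  enc <- function(tr) list(
    genotype = genotype_to_string(tr$genotype),
    color = tr$color, Eref = tr$Eref, n_greedy = tr$n_greedy,
    steps = tr$steps)
  jsonlite::toJSON(list(
    blue = enc(pair$blue), red = enc(pair$red), M = pair$M,
    diff_sites = pair$diff_sites, selected_smes = pair$selected_smes,
    Eminref = pair$Eminref, Emaxref = pair$Emaxref),
    auto_unbox = TRUE, digits = NA)
}
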