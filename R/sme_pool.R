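# A-priori distributions of single-mutation effects (SMEs) and zero-sum
# pools h_1, ..., h_L drawn from them.

#' Specify an a-priori distribution of single-mutation effects
#'
#' Two symmetric families are supported. `"gaussian"` is a zero-mean normal
#' with scale `sigma` (default 1; the overall scale of the SMEs can be
#' absorbed into the fitness threshold and sharpness, so unit variance loses
#' no generality). `"pareto_cutoff"` is flat on `|h| < xm`, decays as
#' `(xm/|h|)^(alpha + 1)` on `xm < |h| < cutoff`, and is zero beyond the
#' hard cutoff; the normalization constant is computed in closed form.
#'
#' @param kind `"gaussian"` or `"pareto_cutoff"`.
#' @param alpha Pareto tail exponent (> 0).
#' @param xm Pareto shoulder: the density is flat below this magnitude.
#' @param cutoff hard truncation; the density vanishes for `|h| > cutoff`.
#' @param sigma Gaussian scale (> 0).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("gaussian")
#' dist_spec("pareto_cutoff", alpha = 0.7, xm = 0.1, cutoff = 2)
#' @export
dist_spec <- function(kind = c("gaussian", "pareto_cutoff"),
                      alpha = 0.7, xm = 0.1, cutoff = 2, sigma = 1) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma <= 0) {
      stop("`sigma` must be a positive finite number", call. = FALSE)
    }
    spec <- list(kind = kind, sigma = sigma)
  } else {
    ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
    if (!ok(alpha)) stop("`alpha` must be a positive finite number", call. = FALSE)
    if (!ok(xm) || !ok(cutoff) || xm >= cutoff) {
      stop("need 0 < xm < cutoff", call. = FALSE)
    }
    spec <- list(kind = kind, alpha = alpha, xm = xm, cutoff = cutoff)
  }
  structure(spec, class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$kind == "gaussian") {
    cat(sprintf("SME distribution: gaussian (sigma = %g)\n", x$sigma))
  } else {
    cat(sprintf(
      "SME distribution: pareto_cutoff (alpha = %g, xm = %g, cutoff = %g)\n",
      x$alpha, x$xm, x$cutoff))
  }
  invisible(x)
}

# Closed-form normalization constant A of the pareto_cutoff density:
# 2 A xm [1 + (1 - (xm/cutoff)^alpha)/alpha] = 1.
pareto_norm_const <- function(spec) {
  r <- spec$xm / spec$cutoff
  1 / (2 * spec$xm * (1 + (1 - r^spec$alpha) / spec$alpha))
}

#' Density of an SME distribution
#'
#' Normalized, symmetric density `P(h)`. For the `pareto_cutoff` family it
#' equals `A` on `|x| < xm`, `A (xm/|x|)^(alpha+1)` on `xm <= |x| <= cutoff`,
#' and 0 beyond the cutoff.
#'
#' @param spec a [dist_spec()].
#' @param x numeric vector of evaluation points.
#' @return numeric vector of density values.
#' @examples
#' sp <- dist_spec("pareto_cutoff", alpha = 0.7, xm = 0.1, cutoff = 2)
#' sme_density(sp, c(-3, 0, 0.5, 3))
#' @export
sme_density <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$kind == "gaussian") return(dnorm(x, mean = 0, sd = spec$sigma))
  A <- pareto_norm_const(spec)
  ax <- abs(x)
  out <- numeric(length(x))
  flat <- ax < spec$xm
  tail <- !flat & ax <= spec$cutoff
  out[flat] <- A
  out[tail] <- A * (spec$xm / ax[tail])^(spec$alpha + 1)
  out
}

# Inverse-CDF sampler for the pareto_cutoff magnitude; `u` uniform in (0,1).
pareto_cutoff_quantile <- function(spec, u) {
  A <- pareto_norm_const(spec)
  w0 <- 2 * A * spec$xm            # mass of the flat shoulder
  mag <- numeric(length(u))
  lo <- u <= w0
  mag[lo] <- u[lo] / (2 * A)
  uu <- u[!lo]
  mag[!lo] <- spec$xm *
    (1 - spec$alpha * (uu - w0) / (2 * A * spec$xm))^(-1 / spec$alpha)
  mag
}

# Draw n i.i.d. values from the spec (raw, before any zero-sum shift).
sample_raw <- function(spec, n) {
  if (spec$kind == "gaussian") return(rnorm(n, mean = 0, sd = spec$sigma))
  sgn <- ifelse(runif(n) < 0.5, -1, 1)
  sgn * pareto_cutoff_quantile(spec, runif(n))
}

#' Sample a zero-sum pool of single-mutation effects
#'
#' Draws `L` i.i.d. effects from `spec`, then shifts them once by their
#' empirical mean so the pool sums to zero (the all-mutated genotype then
#' has the same trait as the ancestor). The shift is applied after all
#' draws and never re-applied when subsetting.
#'
#' @param spec a [dist_spec()].
#' @param L number of sites (>= 2).
#' @param seed integer seed; identical `(spec, L, seed)` yield identical
#'   pools.
#' @return an object of class `sme_pool` with fields `h` (length-`L`
#'   zero-sum effects), `L`, `spec`, `seed`.
#' @examples
#' pool <- sample_pool(dist_spec("gaussian"), L = 10, seed = 1)
#' sum(pool$h)
#' @export
sample_pool <- function(spec, L, seed) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!is.numeric(L) || length(L) != 1L || L < 2 || L != round(L)) {
    stop("`L` must be an integer >= 2", call. = FALSE)
  }
  L <- as.integer(L)
  h <- with_seed(seed, sample_raw(spec, L))
  h <- h - mean(h)
  structure(list(h = h, L = L, spec = spec, seed = as.integer(seed)),
            class = "sme_pool")
}

#' @export
print.sme_pool <- function(x, ...) {
  cat(sprintf("SME pool: L = %d, seed = %d, sum(h) = %.3g\n",
              x$L, x$seed, sum(x$h)))
  print(x$spec)
  invisible(x)
}

#' Serialize / deserialize a distribution spec to JSON
#'
#' @param spec a [dist_spec()].
#' @param json a JSON string such as
#'   `'{"kind":"pareto_cutoff","alpha":0.7,"xm":0.1,"cutoff":2.0}'`.
#' @return `spec_to_json()` returns a JSON string; `spec_from_json()`
#'   returns a [dist_spec()].
#' @examples
#' spec_from_json(spec_to_json(dist_spec("gaussian")))
#' @export
spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (identical(x$kind, "gaussian")) {
    dist_spec("gaussian", sigma = if (is.null(x$sigma)) 1 else x$sigma)
  } else if (identical(x$kind, "pareto_cutoff")) {
    dist_spec("pareto_cutoff", alpha = x$alpha, xm = x$xm, cutoff = x$cutoff)
  } else {
    stop("unknown distribution kind: ", x$kind, call. = FALSE)
  }
}
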