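# Genotypes, the additive underlying trait, the two-color nonlinear fitness
# functions and phenotype classification.

check_genotype <- function(a, L = NULL) {
  if (!is.numeric(a) && !is.integer(a) && !is.logical(a)) {
    stop("genotype must be a 0/1 vector", call. = FALSE)
  }
  a <- as.integer(a)
  if (any(is.na(a)) || any(a != 0L & a != 1L)) {
    stop("genotype entries must be 0 or 1", call. = FALSE)
  }
  if (!is.null(L) && length(a) != L) {
    stop(sprintf("genotype length %d does not match pool length %d",
                 length(a), L), call. = FALSE)
  }
  a
}

#' Convert genotypes between 0/1 vectors and bitstrings
#'
#' Genotypes render as bitstrings (`"0110..."`) in files and reports; the
#' character at position `i` is site `i` of the pool.
#'
#' @param a a 0/1 genotype vector.
#' @param s a bitstring such as `"0110"`.
#' @return `genotype_to_string()` a character scalar;
#'   `genotype_from_string()` an integer 0/1 vector.
#' @examples
#' genotype_to_string(c(0, 1, 1, 0))
#' genotype_from_string("0110")
#' @export
genotype_to_string <- function(a) {
  paste(check_genotype(a), collapse = "")
}

#' @rdname genotype_to_string
#' @export
genotype_from_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  bits <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(bits %in% c("0", "1"))) {
    stop("bitstring may contain only 0 and 1", call. = FALSE)
  }
  as.integer(bits)
}

#' Additive underlying trait of a genotype
#'
#' `E(a) = sum_i h_i a_i`: the dot product of the genotype with the pool's
#' single-mutation effects. All epistasis in the model enters later, through
#' the nonlinear fitness map; the trait itself is perfectly additive.
#'
#' @param a a 0/1 genotype vector of length `pool$L`.
#' @param pool an [sme_pool()][sample_pool].
#' @return the trait value `E(a)`.
#' @examples
#' pool <- sample_pool(dist_spec("gaussian"), L = 5, seed = 1)
#' trait(c(1, 0, 0, 0, 0), pool) == pool$h[1]
#' @export
trait <- function(a, pool) {
  stopifnot(inherits(pool, "sme_pool"))
  a <- check_genotype(a, pool$L)
  sum(pool$h[a == 1L])
}

#' Parameters of the two-color fitness functions
#'
#' @param phi0 fitness plateau (> 0, default 1; the overall fitness scale is
#'   irrelevant to the path analysis).
#' @param beta sharpness of the sigmoidal transition (default 50; the model
#'   operates in the sharp-threshold regime `beta >> 1`).
#' @param Eth functionality threshold on the trait (>= 0).
#' @return an object of class `fitness_params`.
#' @examples
#' fitness_params(Eth = 1)
#' @export
fitness_params <- function(phi0 = 1, beta = 50, Eth = 1) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok(phi0) || phi0 <= 0) stop("`phi0` must be > 0", call. = FALSE)
  if (!ok(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (!ok(Eth) || Eth < 0) stop("`Eth` must be >= 0", call. = FALSE)
  structure(list(phi0 = phi0, beta = beta, Eth = Eth),
            class = "fitness_params")
}

#' Two-color sigmoidal fitness of a trait value
#'
#' Blue fitness rises with the trait, red fitness falls:
#' `F_B(E) = phi0 / (1 + exp(beta (Eth - E)))` and
#' `F_R(E) = phi0 / (1 + exp(beta (Eth + E)))`. The exponential saturates
#' gracefully (overflow yields exactly 0 or `phi0`). Negating `E` and
#' swapping colors leaves the value unchanged.
#'
#' @param E numeric vector of trait values.
#' @param color `"blue"` or `"red"`.
#' @param params a [fitness_params()].
#' @return fitness values in `(0, phi0)` (up to floating point saturation).
#' @examples
#' fp <- fitness_params(beta = 50, Eth = 1)
#' fitness(1, "blue", fp)   # sigmoid midpoint: phi0/2
#' @export
fitness <- function(E, color = c("blue", "red"), params) {
  color <- match.arg(color)
  stopifnot(inherits(params, "fitness_params"))
  z <- if (color == "blue") params$beta * (params$Eth - E)
       else                 params$beta * (params$Eth + E)
  params$phi0 / (1 + exp(z))
}

#' Classify a trait value into phenotypes
#'
#' In the sharp-threshold limit the phenotype is decided by the trait alone:
#' blue iff `E > Eth`, red iff `E < -Eth`, nonfunctional otherwise. The
#' inequalities are strict, so boundary values (including `E = Eth` exactly)
#' are nonfunctional.
#'
#' @param E numeric vector of trait values.
#' @param Eth functionality threshold (>= 0).
#' @return character vector in `{"blue", "red", "nonfunctional"}`.
#' @examples
#' phenotype_class(c(-2, 0, 2), Eth = 1)
#' @export
phenotype_class <- function(E, Eth) {
  stopifnot(is.numeric(Eth), length(Eth) == 1L, Eth >= 0)
  out <- rep("nonfunctional", length(E))
  out[E > Eth] <- "blue"
  out[E < -Eth] <- "red"
  out
}
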