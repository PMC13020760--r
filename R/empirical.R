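# Analysis of a measured two-phenotype combinatorial landscape: reading and
# validating the 2^K genotype table, fitness normalization, trait
# deconvolution, the single-mutation-effect spectrum, Pareto tail fits and
# bottleneck topology; plus a synthetic fixture generator that emulates the
# structure of such data (two exclusive fluorescence phenotypes over a
# complete 2^K hypercube with a fat-tailed SME spectrum).

bitstring_to_mask <- function(g, K) {
  bits <- matrix(as.integer(unlist(strsplit(g, "", fixed = TRUE))),
                 ncol = K, byrow = TRUE)
  as.integer(bits %*% 2^(seq_len(K) - 1))
}

mask_to_bitstring <- function(mask, K) {
  vapply(mask, function(m) {
    paste(bitwAnd(bitwShiftR(as.integer(m), seq_len(K) - 1L), 1L),
          collapse = "")
  }, character(1))
}

new_measured_landscape <- function(table, K, normalized = FALSE) {
  structure(list(table = table, K = as.integer(K), normalized = normalized),
            class = "measured_landscape")
}

#' Read a complete combinatorial landscape table
#'
#' Delimited text (TSV or CSV, auto-detected) with header columns
#' `genotype` (a `K`-character bitstring; all-zeros is the blue reference,
#' all-ones the red reference), `F_blue` and `F_red` (non-negative fitness
#' values). The table must contain every genotype of the `2^K` hypercube
#' exactly once; `K` is inferred from the bitstring length.
#'
#' @param path file path.
#' @return an object of class `measured_landscape` with fields `table`
#'   (data frame with `genotype`, `mask`, `F_blue`, `F_red`, sorted by
#'   mask), `K`, `normalized`.
#' @export
read_landscape_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep,
                   colClasses = c(genotype = "character"),
                   stringsAsFactors = FALSE)
  need <- c("genotype", "F_blue", "F_red")
  if (!all(need %in% names(df))) {
    stop("table must have columns genotype, F_blue, F_red", call. = FALSE)
  }
  g <- df$genotype
  lens <- nchar(g)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged bitstrings: lengths %s",
                 paste(sort(unique(lens)), collapse = ", ")), call. = FALSE)
  }
  K <- lens[1]
  if (!all(grepl("^[01]+$", g))) {
    bad <- head(g[!grepl("^[01]+$", g)], 5)
    stop("non-binary genotypes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mask <- bitstring_to_mask(g, K)
  if (anyDuplicated(mask)) {
    dup <- unique(g[duplicated(mask)])
    stop("duplicated genotypes: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(seq_len(2^K) - 1L, mask)
  if (length(missing) > 0L) {
    stop(sprintf("incomplete hypercube: %d of %d genotypes missing (e.g. %s)",
                 length(missing), 2^K,
                 paste(mask_to_bitstring(head(missing, 5), K),
                       collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(df$F_blue)) || any(!is.finite(df$F_red)) ||
      any(df$F_blue < 0) || any(df$F_red < 0)) {
    bad <- g[!is.finite(df$F_blue) | !is.finite(df$F_red) |
               df$F_blue < 0 | df$F_red < 0]
    stop("negative or non-finite fitness at: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(genotype = g, mask = mask, F_blue = df$F_blue,
                    F_red = df$F_red, stringsAsFactors = FALSE)
  tab <- tab[order(tab$mask), , drop = FALSE]
  rownames(tab) <- NULL
  new_measured_landscape(tab, K)
}

#' @export
print.measured_landscape <- function(x, ...) {
  cat(sprintf("Measured landscape: K = %d (%d genotypes), %s%s\n",
              x$K, nrow(x$table),
              if (x$normalized) "normalized" else "raw",
              if ("E" %in% names(x$table)) ", trait derived" else ""))
  invisible(x)
}

#' Normalize fitness to the reference variants
#'
#' Divides the blue fitness by its value at the blue reference (all-zeros)
#' and the red fitness by its value at the red reference (all-ones), so
#' each reference serves as the baseline functional state of its own
#' phenotype: `F_B(a_B) = F_R(a_R) = 1`. Idempotent.
#'
#' @param land a [read_landscape_table()] result.
#' @return the landscape, normalized.
#' @export
normalize_fitness <- function(land) {
  stopifnot(inherits(land, "measured_landscape"))
  tab <- land$table
  n <- nrow(tab)
  fb0 <- tab$F_blue[tab$mask == 0L]
  fr1 <- tab$F_red[tab$mask == n - 1L]
  if (fb0 <= 0 || fr1 <= 0) {
    stop("reference fitness is zero; cannot normalize", call. = FALSE)
  }
  tab$F_blue <- tab$F_blue / fb0
  tab$F_red <- tab$F_red / fr1
  out <- land
  out$table <- tab
  out$normalized <- TRUE
  out
}

#' Deconvolve the underlying trait from normalized fitness
#'
#' Inverts the global nonlinearity with the power-law form
#' `phi^-1(x) = x^exponent` (default exponent 0.44) for both phenotypes:
#' `EB = F_blue^exponent`, `ER = F_red^exponent`, and combines the two
#' exclusive phenotypes into a single signed trait `E = EB - ER` (positive
#' for blue, negative for red). Also records the reference traits
#' `EBref = E(a_B)` and `ERref = E(a_R)`.
#'
#' @param land a normalized [measured_landscape][read_landscape_table].
#' @param exponent positive deconvolution exponent (default 0.44).
#' @return the landscape with derived columns `EB`, `ER`, `E` and
#'   attributes `EBref`, `ERref` stored as fields.
#' @export
deconvolve_trait <- function(land, exponent = 0.44) {
  stopifnot(inherits(land, "measured_landscape"))
  if (!land$normalized) {
    stop("normalize the landscape before deconvolving", call. = FALSE)
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0) {
    stop("`exponent` must be > 0", call. = FALSE)
  }
  tab <- land$table
  tab$EB <- tab$F_blue^exponent
  tab$ER <- tab$F_red^exponent
  tab$E <- tab$EB - tab$ER
  out <- land
  out$table <- tab
  out$exponent <- exponent
  out$EBref <- tab$E[tab$mask == 0L]
  out$ERref <- tab$E[tab$mask == nrow(tab) - 1L]
  out
}

#' Spectrum of single-mutation effects of a measured landscape
#'
#' For every background genotype `a` and every site `i`, the signed trait
#' change `DeltaE_i(a) = E(a with site i flipped) - E(a)`: `K * 2^K` values
#' in total. Each mutation appears with its reverse, so the multiset is
#' symmetric about 0 by construction.
#'
#' @param land a trait-derived landscape (see [deconvolve_trait()]).
#' @return numeric vector of length `K * 2^K`.
#' @export
sme_spectrum <- function(land) {
  stopifnot(inherits(land, "measured_landscape"))
  if (!("E" %in% names(land$table))) {
    stop("derive the trait first (deconvolve_trait)", call. = FALSE)
  }
  K <- land$K
  E <- land$table$E            # table is sorted by mask
  masks <- land$table$mask
  out <- vector("list", K)
  for (i in seq_len(K)) {
    bit <- bitwShiftL(1L, i - 1L)
    partner <- bitwXor(masks, bit)
    out[[i]] <- E[partner + 1L] - E
  }
  unlist(out, use.names = FALSE)
}

#' Fit a truncated Pareto tail to SME magnitudes
#'
#' Maximum-likelihood fit of the power-law tail exponent `alpha` to the
#' magnitudes exceeding the shoulder `xm`, conditional on exceedance, with
#' an optional hard cutoff: the tail density is proportional to
#' `x^-(alpha + 1)` on `(xm, cutoff]`. The standard error comes from the
#' observed information.
#'
#' @param values numeric vector of SME magnitudes `|DeltaE|` (absolute
#'   values are taken).
#' @param xm tail threshold (> 0).
#' @param cutoff hard upper truncation (default `Inf` for an untruncated
#'   tail); values above it are dropped with a warning.
#' @return an object of class `pareto_fit` with `alpha_hat`, `stderr_alpha`,
#'   `xm`, `cutoff`, `n_tail`, `loglik`.
#' @export
fit_pareto_tail <- function(values, xm, cutoff = Inf) {
  stopifnot(is.numeric(values), xm > 0, cutoff > xm)
  x <- abs(values)
  over <- x > cutoff
  if (any(over)) {
    warning(sprintf("%d values above the cutoff dropped", sum(over)))
    x <- x[!over]
  }
  x <- x[x > xm]
  n <- length(x)
  if (n < 30) {
    stop(errorCondition(
      sprintf("only %d tail values above xm = %g (need >= 30)", n, xm),
      class = c("episcape_sample_size_error", "error", "condition")))
  }
  S <- mean(log(x / xm))
  r <- if (is.finite(cutoff)) xm / cutoff else 0
  score <- function(a) {
    1 / a - S + if (r > 0) r^a * log(r) / (1 - r^a) else 0
  }
  alpha <- uniroot(score, c(1e-8, 1e4), tol = 1e-12)$root
  # observed information per the full sample: -l''(alpha) = -n * score'(alpha)
  eps <- 1e-5 * alpha
  dscore <- (score(alpha + eps) - score(alpha - eps)) / (2 * eps)
  se <- 1 / sqrt(-n * dscore)
  ll <- n * (log(alpha) + alpha * log(xm)) - (alpha + 1) * sum(log(x)) -
    if (r > 0) n * log(1 - r^alpha) else 0
  structure(list(alpha_hat = alpha, stderr_alpha = se, xm = xm,
                 cutoff = cutoff, n_tail = n, loglik = ll),
            class = "pareto_fit")
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat(sprintf(
    "Pareto tail fit: alpha = %.4f (se %.4f), xm = %g, cutoff = %g, n_tail = %d\n",
    x$alpha_hat, x$stderr_alpha, x$xm, x$cutoff, x$n_tail))
  invisible(x)
}

#' View a trait-derived landscape as a subcube
#'
#' Re-expresses the measured `2^K` hypercube in the representation used by
#' the path-space module, with the all-zeros corner (blue reference) at
#' mask 0 and the all-ones corner (red reference) at the full mask.
#'
#' @param land a trait-derived landscape (see [deconvolve_trait()]).
#' @return a `subcube_landscape`.
#' @export
as_subcube <- function(land) {
  stopifnot(inherits(land, "measured_landscape"))
  if (!("E" %in% names(land$table))) {
    stop("derive the trait first (deconvolve_trait)", call. = FALSE)
  }
  E <- land$table$E
  new_subcube(E, EBref = E[1], ERref = E[length(E)], M = land$K)
}

#' Bottleneck topology of a measured landscape
#'
#' Runs the full path-space analysis ([pathspace_result()]) on the measured
#' hypercube, with the all-zeros and all-ones corners as endpoints: the
#' connectivity threshold `EC`, jumper set and position, surviving-path
#' count and topology class.
#'
#' @param land a trait-derived landscape (see [deconvolve_trait()]).
#' @param max_M_paths largest `K` analyzed (default 14).
#' @return a [pathspace_result()].
#' @export
empirical_bottleneck <- function(land, max_M_paths = 14) {
  stopifnot(inherits(land, "measured_landscape"))
  if (land$K > max_M_paths) {
    stop(errorCondition(
      sprintf("K = %d exceeds max_M_paths = %d", land$K, max_M_paths),
      class = c("episcape_size_error", "error", "condition")))
  }
  sub <- as_subcube(land)
  if (sub$EBref <= 0 || sub$ERref >= 0) {
    warning(paste("expected a blue (E > 0) all-zeros reference and a red",
                  "(E < 0) all-ones reference; results may be meaningless"))
  }
  pathspace_result(sub)
}

#' Generate a synthetic measured-landscape fixture
#'
#' Emulates the structure of a measured two-phenotype combinatorial
#' landscape without any external data: calibrated-model instances are
#' drawn until one has exactly `M = K` differing sites; the subcube traits
#' are mapped to blue/red fitness through the two-color sigmoid with a
#' finite sharpness `beta` and threshold `Eth = config$ET`, and multiplied
#' by lognormal measurement noise with coefficient of variation
#' `noise_cv`. The blue reference is relabelled to the all-zeros bitstring.
#' The generating instance's traits are attached as field `generator_E`
#' for round-trip checks.
#'
#' @param K hypercube dimension (<= `config$max_M_paths`).
#' @param config a [model_config()] (default the calibrated Gaussian
#'   preset).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise (>= 0; 0 means noiseless).
#' @param seed integer seed.
#' @param beta fitness sharpness used for the forward map (default 10,
#'   finite so the map is invertible in practice).
#' @param file optional path; when given, the table is written as TSV.
#' @param max_tries how many instances to draw while searching for
#'   `M = K` (default 5000).
#' @return a `measured_landscape` (raw, not normalized), with fields
#'   `generator_E` (trait per mask) and `generator_seed`.
#' @export
make_fixture <- function(K, config = model_config(preset = "gaussian_calibrated"),
                         noise_cv = 0.1, seed = 1, beta = 10, file = NULL,
                         max_tries = 5000) {
  stopifnot(inherits(config, "model_config"))
  if (K > config$max_M_paths) {
    stop("`K` must be <= config$max_M_paths", call. = FALSE)
  }
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  found <- NULL
  for (t in seq_len(max_tries)) {
    s <- substream_seed(seed, t)
    inst <- tryCatch({
      pool <- sample_pool(config$spec, config$L,
                          seed = substream_seed(s, 1))
      pair <- build_reference_pair(pool,
                                   tuning_params(config$p, config$ET),
                                   seed = substream_seed(s, 2))
      list(pool = pool, pair = pair)
    }, episcape_tuning_failure = function(e) NULL)
    if (!is.null(inst) && inst$pair$M == K) {
      found <- inst
      found$seed <- s
      break
    }
  }
  if (is.null(found)) {
    stop(errorCondition(
      sprintf("no instance with M = %d found in %d tries", K, max_tries),
      class = c("episcape_fixture_error", "error", "condition")))
  }
  sub <- enumerate_subcube(found$pool, found$pair, max_M = K)
  fp <- fitness_params(phi0 = 1, beta = beta, Eth = config$ET)
  FB <- fitness(sub$E, "blue", fp)
  FR <- fitness(sub$E, "red", fp)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    noise <- with_seed(substream_seed(found$seed, 3), {
      rlnorm(2 * length(FB), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    FB <- FB * noise[seq_along(FB)]
    FR <- FR * noise[length(FB) + seq_along(FR)]
  }
  tab <- data.frame(genotype = mask_to_bitstring(seq_along(FB) - 1L, K),
                    mask = seq_along(FB) - 1L,
                    F_blue = FB, F_red = FR, stringsAsFactors = FALSE)
  land <- new_measured_landscape(tab, K)
  land$generator_E <- sub$E
  land$generator_seed <- found$seed
  if (!is.null(file)) {
    write.table(tab[, c("genotype", "F_blue", "F_red")], file = file,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  land
}
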