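# Shared fixtures and independent oracles for the test suite.

# All permutations of a vector (used only at M <= 6 for factorial oracles).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Factorial brute-force oracle for the connectivity threshold: enumerate
# every directed order, take each order's minimum intermediate |E|, maximize
# over orders, cap at Eminref.
brute_force_EC <- function(E, M) {
  Eminref <- min(E[1], abs(E[2^M]))
  if (M == 1L) return(Eminref)
  best <- -Inf
  for (ord in all_perms(seq_len(M))) {
    mask <- 0
    mn <- Inf
    for (k in seq_len(M - 1L)) {
      mask <- mask + 2^(ord[k] - 1L)
      mn <- min(mn, abs(E[mask + 1L]))
    }
    best <- max(best, mn)
  }
  min(best, Eminref)
}

# Factorial brute-force oracle for surviving-path counts (closed condition
# |E| >= threshold on the M - 1 intermediates).
brute_force_count <- function(E, M, threshold) {
  n <- 0L
  for (ord in all_perms(seq_len(M))) {
    mask <- 0
    ok <- TRUE
    for (k in seq_len(M - 1L)) {
      mask <- mask + 2^(ord[k] - 1L)
      if (abs(E[mask + 1L]) < threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) n <- n + 1L
  }
  n
}

# A subcube with prescribed trait values (endpoints first/last).
toy_subcube <- function(E, M) {
  episcape:::new_subcube(E, EBref = E[1], ERref = E[2^M], M = M)
}

# Random subcube with functional endpoints, for property tests.
random_subcube <- function(M) {
  E <- rnorm(2^M)
  E[1] <- abs(E[1]) + 0.5
  E[2^M] <- -abs(E[2^M]) - 0.5
  toy_subcube(E, M)
}

# Complete K = 3 toy landscape table written to a temp file.
write_toy_table <- function(path, drop = NULL, duplicate = NULL,
                            sep = "\t") {
  g <- vapply(0:7, function(m) {
    paste(bitwAnd(bitwShiftR(m, 0:2), 1L), collapse = "")
  }, character(1))
  df <- data.frame(genotype = g,
                   F_blue = c(4, 2, 1.5, 1, 0.5, 0.4, 0.2, 0.1),
                   F_red = c(0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3))
  if (!is.null(drop)) df <- df[df$genotype != drop, ]
  if (!is.null(duplicate)) df <- rbind(df, df[df$genotype == duplicate, ])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Ensembles reused across test files (helpers are sourced once per run, so
# this environment acts as a per-run cache).
.ens_cache <- new.env(parent = emptyenv())

cached_ensemble <- function(preset, n, seed) {
  key <- paste(preset, n, seed, sep = "_")
  if (is.null(.ens_cache[[key]])) {
    cfg <- model_config(preset = preset, n_instances = n, seed = seed)
    .ens_cache[[key]] <- run_ensemble(cfg)
  }
  .ens_cache[[key]]
}

# Draw extra instances beyond an ensemble until `n_needed` path-analyzed
# instances with the given M and a unique jumper are available; returns
# their jumper positions j.
jumper_positions_at_M <- function(ens, M_value, n_needed,
                                  max_extra = 20000) {
  inst <- ens$instances
  sel <- inst$path_analyzed & inst$M == M_value &
    !is.na(inst$single_jumper) & inst$single_jumper
  j <- inst$j[which(sel)]
  cfg <- ens$config
  extra <- 0L
  while (length(j) < n_needed && extra < max_extra) {
    extra <- extra + 1L
    s <- substream_seed(cfg$seed, 10 * cfg$n_instances + extra)
    one <- tryCatch(generate_instance(cfg, s),
                    episcape_tuning_failure = function(e) NULL)
    if (is.null(one) || is.null(one$result)) next
    if (one$pair$M == M_value && one$result$single_jumper) {
      j <- c(j, one$result$j)
    }
  }
  j
}
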