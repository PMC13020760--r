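# Path-space analysis on the subcube of intermediates between the two
# reference variants: the connectivity threshold EC (a maximin over the M!
# directed paths), jumper genotypes, and surviving-path counts. All
# computations are dynamic programs over the subset lattice (O(M 2^M)),
# never a brute force over M! orders.
#
# Subset states are encoded as integer bitmasks over the differing sites
# (bit b = site diff_sites[b + 1] flipped from its blue-reference value to
# its red-reference value); mask 0 is the blue reference, the full mask the
# red reference. Vectors are indexed by mask + 1.

new_subcube <- function(E, EBref, ERref, M, diff_sites = NULL,
                        delta = NULL) {
  n <- length(E)
  stopifnot(n == 2^M)
  # popcount by subset doubling: appending bit b adds 1
  pc <- 0L
  for (b in seq_len(M)) pc <- c(pc, pc + 1L)
  structure(list(M = as.integer(M), diff_sites = diff_sites, delta = delta,
                 E = E, popcount = pc, EBref = EBref, ERref = ERref),
            class = "subcube_landscape")
}

#' Enumerate the subcube of intermediates between the two references
#'
#' Computes the trait `E` for all `2^M` combinations of the `M` differing
#' sites, incrementally: flipping site `b` from its blue-reference value to
#' its red-reference value changes the trait by `delta_b = ±h_b`, and the
#' subset sums are accumulated by doubling over bits. Mask 0 is the blue
#' reference (`E = EBref`), the full mask the red reference (`E = ERref`).
#'
#' @param pool an [sme_pool()][sample_pool].
#' @param pair a [build_reference_pair()] result.
#' @param max_M largest `M` analyzed (default 14); larger instances raise a
#'   size error so callers can skip them with a logged reason.
#' @return an object of class `subcube_landscape` with fields `M`,
#'   `diff_sites`, `delta`, `E` (length `2^M`, indexed by mask + 1),
#'   `popcount`, `EBref`, `ERref`.
#' @examples
#' pool <- sample_pool(dist_spec("gaussian"), L = 50, seed = 1)
#' pair <- build_reference_pair(pool, tuning_params(p = 1, ET = 1), seed = 1)
#' sub <- enumerate_subcube(pool, pair)
#' length(sub$E) == 2^pair$M
#' @export
enumerate_subcube <- function(pool, pair, max_M = 14) {
  stopifnot(inherits(pool, "sme_pool"), inherits(pair, "reference_pair"))
  M <- pair$M
  if (M > max_M) {
    stop(errorCondition(
      sprintf("M = %d exceeds max_M = %d; instance skipped", M, max_M),
      class = c("episcape_size_error", "error", "condition")))
  }
  aB <- pair$blue$genotype[pair$diff_sites]
  aR <- pair$red$genotype[pair$diff_sites]
  delta <- pool$h[pair$diff_sites] * (aR - aB)
  E <- pair$blue$Eref
  for (b in seq_len(M)) E <- c(E, E + delta[b])
  new_subcube(E, EBref = pair$blue$Eref, ERref = pair$red$Eref, M = M,
              diff_sites = pair$diff_sites, delta = delta)
}

#' @export
print.subcube_landscape <- function(x, ...) {
  cat(sprintf(
    "Subcube landscape: M = %d (%d states), EBref = %.4g, ERref = %.4g\n",
    x$M, length(x$E), x$EBref, x$ERref))
  invisible(x)
}

# Masks grouped by popcount layer 0..M, each as an integer vector.
masks_by_layer <- function(sub) {
  split(seq_along(sub$E) - 1L, sub$popcount)
}

subcube_Eminref <- function(sub) min(sub$EBref, abs(sub$ERref))
subcube_Emaxref <- function(sub) max(sub$EBref, abs(sub$ERref))

#' Connectivity threshold EC of a subcube
#'
#' Over all `M!` directed paths (each differing mutation introduced exactly
#' once, no back-mutations) from the blue to the red reference, each path's
#' bottleneck is the minimum of `|E|` over its `M - 1` intermediate states
#' (endpoints excluded). `EC` is the maximum bottleneck over paths — the
#' widest-path value — capped at `Eminref = min(EBref, |ERref|)`, since
#' raising the functionality threshold beyond the weaker reference is not
#' meaningful. For `M = 1` (no intermediates) `EC = Eminref`.
#'
#' Computed by a maximin dynamic program over the subset lattice in
#' increasing layer order:
#' `best(s) = max over predecessors of min(best(pred), |E(s)|)`.
#'
#' @param sub a [enumerate_subcube()] result.
#' @return the scalar `EC`.
#' @export
compute_EC <- function(sub) {
  stopifnot(inherits(sub, "subcube_landscape"))
  M <- sub$M
  Eminref <- subcube_Eminref(sub)
  if (M == 1L) return(Eminref)
  absE <- abs(sub$E)
  n <- length(absE)
  best <- rep(-Inf, n)
  best[1L] <- Inf                      # blue endpoint: no constraint yet
  layers <- masks_by_layer(sub)
  for (k in seq_len(M)) {
    ms <- layers[[k + 1L]]
    for (b in seq_len(M) - 1L) {
      bit <- bitwShiftL(1L, b)
      sel <- bitwAnd(ms, bit) > 0L
      if (!any(sel)) next
      m2 <- ms[sel]
      pred <- m2 - bit
      cand <- best[pred + 1L]
      if (k < M) cand <- pmin(cand, absE[m2 + 1L])  # endpoints excluded
      best[m2 + 1L] <- pmax(best[m2 + 1L], cand)
    }
  }
  min(best[n], Eminref)
}

# Number of viable directed chains from mask 0 to every mask, where a chain
# is viable if all its states except mask 0 and the full mask satisfy
# `viable`. Counts are exact in double arithmetic (M <= 14 keeps them below
# 14! < 2^53).
forward_counts <- function(viable, M, layers) {
  n <- 2L^M
  viable[1L] <- TRUE
  viable[n] <- TRUE
  cnt <- numeric(n)
  cnt[1L] <- 1
  for (k in seq_len(M)) {
    ms <- layers[[k + 1L]]
    ms <- ms[viable[ms + 1L]]
    if (length(ms) == 0L) next
    for (b in seq_len(M) - 1L) {
      bit <- bitwShiftL(1L, b)
      sel <- bitwAnd(ms, bit) > 0L
      if (!any(sel)) next
      m2 <- ms[sel]
      cnt[m2 + 1L] <- cnt[m2 + 1L] + cnt[m2 - bit + 1L]
    }
  }
  cnt
}

#' Count directed paths surviving a functionality threshold
#'
#' Number of directed blue-to-red paths whose `M - 1` intermediates all
#' satisfy `|E| >= threshold` (closed condition; endpoints always viable).
#' Computed by a path-count dynamic program over the subset lattice; counts
#' are exact (they stay below `14! < 2^53`). `count_paths(sub, -Inf)`
#' equals `M!`.
#'
#' @param sub a [enumerate_subcube()] result.
#' @param threshold functionality threshold on `|E|`.
#' @return the number of surviving paths (numeric, exact integer value).
#' @export
count_paths <- function(sub, threshold) {
  stopifnot(inherits(sub, "subcube_landscape"))
  viable <- abs(sub$E) >= threshold
  cnt <- forward_counts(viable, sub$M, masks_by_layer(sub))
  cnt[length(cnt)]
}

# Backward chain counts: number of viable chains from every mask to the
# full mask, by mirroring the forward DP on the complemented subcube.
backward_counts <- function(viable, M, layers) {
  n <- 2L^M
  full <- n - 1L
  idx_rev <- bitwXor(seq_len(n) - 1L, full) + 1L
  cnt_rev <- forward_counts(viable[idx_rev], M, layers)
  cnt_rev[idx_rev]
}

#' Single-jumper proxy
#'
#' Numerical proxy for "a single jumper genotype": `EC < 0.9 * Eminref`
#' (strict; equality returns `FALSE`).
#'
#' @param EC connectivity threshold from [compute_EC()].
#' @param Eminref the weaker reference trait magnitude (> 0).
#' @return logical.
#' @examples
#' single_jumper_proxy(0.5, 1)
#' @export
single_jumper_proxy <- function(EC, Eminref) {
  stopifnot(Eminref > 0)
  EC < 0.9 * Eminref
}

#' Locate jumper genotypes at the connectivity threshold
#'
#' Jumpers are intermediate states with `|E|` equal to `EC` (relative
#' tolerance 1e-12) lying on at least one surviving path at the closed
#' threshold `|E| >= EC`. When the cap `EC = Eminref` is active there is no
#' jumper and the topology is `"capped_no_jumper"`; otherwise the topology
#' records whether the (first) jumper connects by single mutations to one or
#' several surviving states of the opposite phenotype sign.
#'
#' @param sub a [enumerate_subcube()] result.
#' @param EC the threshold from [compute_EC()].
#' @return a list with `jumpers` (integer masks), `j` (mutations from the
#'   blue reference of the first jumper; the minimum layer if several),
#'   `single_jumper` (logical), `topology` (one of
#'   `"single_jump_single_landing"`, `"single_jump_multi_landing"`,
#'   `"capped_no_jumper"`).
#' @export
find_jumpers <- function(sub, EC) {
  stopifnot(inherits(sub, "subcube_landscape"))
  M <- sub$M
  n <- length(sub$E)
  Eminref <- subcube_Eminref(sub)
  if (M == 1L || EC >= Eminref) {
    return(list(jumpers = integer(0), j = NA_integer_,
                single_jumper = FALSE, topology = "capped_no_jumper"))
  }
  absE <- abs(sub$E)
  layers <- masks_by_layer(sub)
  viable <- absE >= EC
  cf <- forward_counts(viable, M, layers)
  cb <- backward_counts(viable, M, layers)
  on_path <- cf > 0 & cb > 0
  tol <- 1e-12 * max(EC, 1)
  is_jumper <- abs(absE - EC) <= tol & on_path
  is_jumper[c(1L, n)] <- FALSE
  jumpers <- which(is_jumper) - 1L
  if (length(jumpers) == 0L) {
    # numerically degenerate (should not occur for continuous P(h))
    return(list(jumpers = integer(0), j = NA_integer_,
                single_jumper = FALSE, topology = "capped_no_jumper"))
  }
  jl <- sub$popcount[jumpers + 1L]
  j <- min(jl)
  jmask <- jumpers[which.min(jl)]
  # landings: surviving single-mutation neighbors with opposite trait sign
  sgn <- sign(sub$E[jmask + 1L])
  bits <- bitwShiftL(1L, seq_len(M) - 1L)
  nb <- bitwXor(jmask, bits)
  land <- on_path[nb + 1L] & (sign(sub$E[nb + 1L]) == -sgn) & sgn != 0
  topology <- if (sum(land) <= 1L) "single_jump_single_landing"
              else "single_jump_multi_landing"
  list(jumpers = jumpers, j = as.integer(j),
       single_jumper = length(jumpers) == 1L, topology = topology)
}

#' Full path-space analysis of a subcube
#'
#' Convenience wrapper: [compute_EC()], [find_jumpers()], surviving-path
#' count at `EC` and the single-jumper proxy, assembled into one result.
#'
#' @param sub a [enumerate_subcube()] result.
#' @return an object of class `pathspace_result` with fields `M`, `EC`,
#'   `Eminref`, `Emaxref`, `jumpers`, `j`, `single_jumper`, `proxy_single`,
#'   `n_paths_at_EC`, `log_n_paths`, `topology`.
#' @export
pathspace_result <- function(sub) {
  EC <- compute_EC(sub)
  jm <- find_jumpers(sub, EC)
  npaths <- count_paths(sub, EC)
  structure(list(
    M = sub$M, EC = EC,
    Eminref = subcube_Eminref(sub), Emaxref = subcube_Emaxref(sub),
    jumpers = jm$jumpers, j = jm$j, single_jumper = jm$single_jumper,
    proxy_single = single_jumper_proxy(EC, subcube_Eminref(sub)),
    n_paths_at_EC = npaths, log_n_paths = log(npaths),
    topology = jm$topology),
    class = "pathspace_result")
}

#' @export
print.pathspace_result <- function(x, ...) {
  cat(sprintf(
    paste0("Path-space result: M = %d, EC = %.4g (Eminref = %.4g), ",
           "j = %s, %d jumper(s), %g path(s) at EC, topology = %s\n"),
    x$M, x$EC, x$Eminref, ifelse(is.na(x$j), "NA", x$j),
    length(x$jumpers), x$n_paths_at_EC, x$topology))
  invisible(x)
}

#' Export the surviving-path graph
#'
#' Builds the graph of states with `|E| >= threshold` (endpoints always
#' included) connected by single mutations, with node attributes `E`,
#' `layer` (mutations from the blue reference), and `phenotype` (sign of
#' `E`), and writes it in GraphML or DOT format.
#'
#' @param sub a [enumerate_subcube()] result.
#' @param threshold functionality threshold (typically `EC`).
#' @param file output path; if `NULL` the igraph object is returned without
#'   writing.
#' @param format `"graphml"` or `"dot"`.
#' @return the igraph object, invisibly when written to file.
#' @export
export_path_graph <- function(sub, threshold, file = NULL,
                              format = c("graphml", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(sub, "subcube_landscape"))
  M <- sub$M
  n <- length(sub$E)
  viable <- abs(sub$E) >= threshold
  viable[c(1L, n)] <- TRUE
  masks <- which(viable) - 1L
  id <- match(seq_len(n) - 1L, masks)          # mask -> node index
  edges <- NULL
  bits <- bitwShiftL(1L, seq_len(M) - 1L)
  for (b in bits) {
    lower <- masks[bitwAnd(masks, b) == 0L]
    upper <- lower + b
    keep <- viable[upper + 1L]
    if (any(keep)) {
      edges <- rbind(edges, cbind(id[lower[keep] + 1L], id[upper[keep] + 1L]))
    }
  }
  g <- igraph::make_empty_graph(n = length(masks), directed = TRUE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- vapply(masks, function(m) {
    paste(bitwAnd(bitwShiftR(m, seq_len(M) - 1L), 1L), collapse = "")
  }, character(1))
  igraph::V(g)$E <- sub$E[masks + 1L]
  igraph::V(g)$layer <- sub$popcount[masks + 1L]
  igraph::V(g)$phenotype <- c("red", "nonfunctional",
                              "blue")[sign(sub$E[masks + 1L]) + 2]
  if (is.null(file)) return(g)
  igraph::write_graph(g, file, format = format)
  invisible(g)
}
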