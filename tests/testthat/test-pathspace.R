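test_that("subcube enumeration is incremental and matches direct traits", {
  pool <- sample_pool(dist_spec("gaussian"), L = 100, seed = 17)
  params <- tuning_params(p = 0.3, ET = 1.2)
  pair <- NULL
  for (seed in 1:50) {                    # find a pair with usable M
    cand <- build_reference_pair(pool, params, seed = seed)
    if (cand$M >= 4 && cand$M <= 10) {
      pair <- cand
      break
    }
  }
  expect_false(is.null(pair))
  sub <- enumerate_subcube(pool, pair)
  M <- pair$M
  expect_length(sub$E, 2^M)
  expect_equal(sub$E[1], pair$blue$Eref)
  expect_equal(sub$E[2^M], pair$red$Eref, tolerance = 1e-10)
  # direct-evaluation oracle on every state
  for (mask in seq_len(2^M) - 1L) {
    a <- pair$blue$genotype
    flip <- pair$diff_sites[bitwAnd(bitwShiftR(mask, seq_len(M) - 1L), 1L) == 1L]
    a[flip] <- 1L - a[flip]
    expect_equal(sub$E[mask + 1L], trait(a, pool), tolerance = 1e-10)
  }
  # size guard
  expect_error(enumerate_subcube(pool, pair, max_M = M - 1),
               class = "episcape_size_error")
})

test_that("EC on hand-built two-site subcubes matches the hand enumeration", {
  # intermediates |E| = 0.3 and 0.7: two monotone paths, maximin 0.7
  sub <- toy_subcube(c(1.0, 0.3, 0.7, -1.2), M = 2)
  expect_equal(compute_EC(sub), 0.7)
  jm <- find_jumpers(sub, 0.7)
  expect_identical(jm$jumpers, 2L)        # the |E| = 0.7 state is mask 2
  expect_identical(jm$j, 1L)
  expect_true(jm$single_jumper)
  # both intermediates dead: EC = 0
  expect_equal(compute_EC(toy_subcube(c(1, 0, 0, -1.2), 2)), 0)
  # all intermediates above both references: cap at Eminref
  sub_cap <- toy_subcube(c(1.0, 1.5, -1.6, -1.2), 2)
  expect_equal(compute_EC(sub_cap), 1.0)
  expect_identical(find_jumpers(sub_cap, 1.0)$topology, "capped_no_jumper")
  # M = 1 has no intermediates: EC = Eminref by convention
  expect_equal(compute_EC(toy_subcube(c(0.8, -1.1), 1)), 0.8)
})

test_that("DP agrees with the factorial brute force on random subcubes", {
  set.seed(42)
  for (rep in 1:200) {
    M <- sample(2:6, 1)
    sub <- random_subcube(M)
    expect_equal(compute_EC(sub), brute_force_EC(sub$E, M))
    thr <- runif(1, 0, 1.2)
    expect_identical(count_paths(sub, thr),
                     as.numeric(brute_force_count(sub$E, M, thr)))
  }
})

test_that("path counts behave at the threshold extremes and by hand", {
  set.seed(1)
  for (M in 2:7) {
    sub <- random_subcube(M)
    expect_identical(count_paths(sub, -Inf), factorial(M))
    # counts are non-increasing in the threshold
    thr <- sort(runif(5, 0, 1.5))
    cnt <- vapply(thr, function(t) count_paths(sub, t), numeric(1))
    expect_true(all(diff(cnt) <= 0))
    # at EC at least one path survives; above EC none (when uncapped)
    EC <- compute_EC(sub)
    expect_gte(count_paths(sub, EC), 1)
    if (EC < min(sub$E[1], abs(sub$E[2^M]))) {
      expect_identical(count_paths(sub, EC + 1e-9), 0)
    }
  }
  # M = 3, one blocked intermediate (mask 1): orders starting with
  # mutation 1 are the blocked ones, leaving 4 of the 6
  E <- c(1, 0.05, 0.8, 0.6, 0.9, 0.7, 0.5, -1)
  sub <- toy_subcube(E, 3)
  expect_identical(count_paths(sub, 0.4), 4)
  # single viable chain
  E2 <- c(1, 0.9, 0.01, 0.8, 0.02, 0.03, 0.04, -1)
  expect_identical(count_paths(toy_subcube(E2, 3), 0.5), 1)
})

test_that("raising an intermediate's |E| never decreases EC", {
  set.seed(7)
  for (rep in 1:50) {
    M <- sample(2:5, 1)
    sub <- random_subcube(M)
    EC0 <- compute_EC(sub)
    i <- sample(2:(2^M - 1), 1)
    sub2 <- sub
    sub2$E[i] <- sign(sub$E[i]) * (abs(sub$E[i]) + runif(1, 0, 2))
    expect_gte(compute_EC(sub2), EC0 - 1e-12)
  }
})

test_that("color swap preserves EC, counts and jumpers, mirroring j", {
  set.seed(19)
  for (rep in 1:50) {
    M <- sample(2:6, 1)
    sub <- random_subcube(M)
    full <- 2^M - 1L
    flipped <- toy_subcube(-sub$E[bitwXor(seq_len(2^M) - 1L, full) + 1L], M)
    EC <- compute_EC(sub)
    expect_equal(compute_EC(flipped), EC)
    thr <- runif(1, 0, 1)
    expect_identical(count_paths(sub, thr), count_paths(flipped, thr))
    jm <- find_jumpers(sub, EC)
    jf <- find_jumpers(flipped, EC)
    expect_identical(length(jm$jumpers), length(jf$jumpers))
    if (!is.na(jm$j) && length(jm$jumpers) == 1L) {
      expect_identical(jf$j, M - jm$j)
    }
  }
})

test_that("single-jumper proxy uses the strict 0.9 rule", {
  expect_true(single_jumper_proxy(0.5, 1.0))
  expect_false(single_jumper_proxy(0.95, 1.0))
  expect_false(single_jumper_proxy(0.9, 1.0))   # boundary is strict
})

test_that("pathspace_result assembles consistent fields", {
  set.seed(3)
  for (rep in 1:20) {
    sub <- random_subcube(sample(3:7, 1))
    res <- pathspace_result(sub)
    expect_gte(res$EC, 0)
    expect_lte(res$EC, res$Eminref)
    expect_gte(res$n_paths_at_EC, 1)
    expect_equal(res$log_n_paths, log(res$n_paths_at_EC))
    if (res$topology == "capped_no_jumper") {
      expect_length(res$jumpers, 0)
    } else {
      expect_gte(res$j, 1L)
      expect_lte(res$j, res$M - 1L)
      # every reported jumper sits exactly at EC
      expect_true(all(abs(abs(sub$E[res$jumpers + 1L]) - res$EC) <=
                        1e-12 * max(1, res$EC)))
    }
  }
})

test_that("surviving-path graph export has the right structure", {
  sub <- toy_subcube(c(1.0, 0.3, 0.7, -1.2), M = 2)
  g <- export_path_graph(sub, threshold = 0.7)
  expect_equal(igraph::vcount(g), 3)      # endpoints + one survivor
  expect_equal(igraph::ecount(g), 2)
  f <- tempfile(fileext = ".graphml")
  export_path_graph(sub, 0.7, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  f2 <- tempfile(fileext = ".dot")
  export_path_graph(sub, 0.7, file = f2, format = "dot")
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
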