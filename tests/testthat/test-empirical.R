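test_that("landscape tables load and validate the complete hypercube", {
  f <- write_toy_table(tempfile(fileext = ".tsv"))
  land <- read_landscape_table(f)
  expect_identical(land$K, 3L)
  expect_identical(nrow(land$table), 8L)
  expect_false(land$normalized)
  # CSV variant of the same table
  fc <- write_toy_table(tempfile(fileext = ".csv"), sep = ",")
  expect_equal(read_landscape_table(fc)$table, land$table)
  # missing genotype named in the error
  fm <- write_toy_table(tempfile(), drop = "111")
  expect_error(read_landscape_table(fm), "111")
  # duplicate named in the error
  fd <- write_toy_table(tempfile(), duplicate = "010")
  expect_error(read_landscape_table(fd), "010")
})

test_that("normalization rescales to the references and is idempotent", {
  f <- write_toy_table(tempfile())
  land <- normalize_fitness(read_landscape_table(f))
  tab <- land$table
  expect_equal(tab$F_blue[tab$mask == 0], 1)      # FB(a_B) was 4
  expect_equal(tab$F_blue, c(4, 2, 1.5, 1, 0.5, 0.4, 0.2, 0.1) / 4)
  expect_equal(tab$F_red[tab$mask == 7], 1)
  expect_equal(normalize_fitness(land)$table, tab) # idempotent
  # zero reference fitness is an error
  bad <- read_landscape_table(f)
  bad$table$F_blue[bad$table$mask == 0] <- 0
  expect_error(normalize_fitness(bad), "zero")
})

test_that("trait deconvolution applies the power law and the color combination", {
  f <- write_toy_table(tempfile())
  land <- deconvolve_trait(normalize_fitness(read_landscape_table(f)))
  tab <- land$table
  expect_equal(tab$EB, tab$F_blue^0.44)
  expect_equal(tab$EB[tab$mask == 0], 1)
  expect_equal(tab$E, tab$EB - tab$ER)
  expect_equal(land$EBref, tab$E[tab$mask == 0])
  expect_equal(0.5^0.44, 0.7371346, tolerance = 1e-6)
  expect_error(deconvolve_trait(read_landscape_table(f)), "normalize")
  expect_error(deconvolve_trait(land, exponent = -1), "> 0")
})

test_that("the SME spectrum is complete, symmetric and background-free when additive", {
  # additive toy landscape built from a known h
  K <- 6
  h <- c(0.9, -0.4, 0.2, -0.7, 0.05, -0.05)
  masks <- 0:(2^K - 1)
  bits <- sapply(seq_len(K), function(i) bitwAnd(bitwShiftR(masks, i - 1L), 1L))
  E <- as.vector(bits %*% h) + 1          # offset so the corners differ
  land <- episcape:::new_measured_landscape(
    data.frame(genotype = episcape:::mask_to_bitstring(masks, K),
               mask = masks, F_blue = 1, F_red = 1), K, normalized = TRUE)
  land$table$E <- E
  sp <- sme_spectrum(land)
  expect_length(sp, K * 2^K)
  # every value appears with its negative equally often
  expect_equal(sort(sp), sort(-sp))
  # background independence: each site's effects are exactly +/- h_i
  spm <- matrix(sp, ncol = K)
  for (i in seq_len(K)) {
    expect_lt(max(abs(abs(spm[, i]) - abs(h[i]))), 1e-10)
  }
})

test_that("Pareto tail MLE recovers the exponent and cross-checks Hill", {
  sp <- dist_spec("pareto_cutoff", alpha = 0.7, xm = 0.1, cutoff = 2)
  x <- abs(episcape:::with_seed(4, episcape:::sample_raw(sp, 1e5)))
  fit <- fit_pareto_tail(x, xm = 0.1, cutoff = 2)
  expect_lt(abs(fit$alpha_hat - 0.7), 3 * fit$stderr_alpha)
  expect_gt(fit$n_tail, 30)
  # untruncated synthetic tail: MLE equals the Hill estimator analytically,
  # so compare both to the truth
  xm <- 0.1
  u <- episcape:::with_seed(9, runif(2e4))
  y <- xm * u^(-1 / 0.7)                   # pure Pareto(0.7) above xm
  fit2 <- fit_pareto_tail(y, xm = xm)
  hill <- 1 / mean(log(y / xm))
  expect_equal(fit2$alpha_hat, hill, tolerance = 1e-6)
  expect_lt(abs(fit2$alpha_hat - 0.7), 2 * fit2$stderr_alpha)
  # guards
  expect_error(fit_pareto_tail(runif(100, 0, 0.05), xm = 0.1),
               class = "episcape_sample_size_error")
})

test_that("Pareto recovery bias is small at large tail samples", {
  xm <- 0.1
  est <- vapply(1:100, function(r) {
    u <- episcape:::with_seed(1000 + r, runif(10000))
    y <- xm * u^(-1 / 0.7)
    fit_pareto_tail(y, xm = xm)$alpha_hat
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.02)
})

test_that("bottleneck analysis of a measured hypercube matches construction", {
  # additive landscape with one high pass and otherwise deep valleys:
  # EC must equal the constructed pass bottleneck
  K <- 4
  masks <- 0:(2^K - 1)
  E <- rep(0.05, 2^K)
  E[1] <- 1
  E[2^K] <- -1.1
  chain <- c(1, 3, 7)                      # masks of one monotone path
  E[chain + 1] <- c(0.8, 0.6, -0.7)
  land <- episcape:::new_measured_landscape(
    data.frame(genotype = episcape:::mask_to_bitstring(masks, K),
               mask = masks, F_blue = 1, F_red = 1), K, normalized = TRUE)
  land$table$E <- E
  res <- empirical_bottleneck(land)
  expect_equal(res$EC, 0.6)
  expect_identical(res$topology, "single_jump_single_landing")
  # all intermediates above both references: capped, no jumper
  land2 <- land
  land2$table$E <- c(1, rep(1.5, 2^K - 2), -1.1) * rep(1, 2^K)
  res2 <- empirical_bottleneck(land2)
  expect_equal(res2$EC, 1)
  expect_identical(res2$topology, "capped_no_jumper")
  # factorial oracle agreement on random measured hypercubes
  set.seed(23)
  for (rep in 1:20) {
    Kr <- sample(3:5, 1)
    Er <- rnorm(2^Kr)
    Er[1] <- abs(Er[1]) + 0.5
    Er[2^Kr] <- -abs(Er[2^Kr]) - 0.5
    lr <- episcape:::new_measured_landscape(
      data.frame(genotype = episcape:::mask_to_bitstring(0:(2^Kr - 1), Kr),
                 mask = 0:(2^Kr - 1), F_blue = 1, F_red = 1), Kr,
      normalized = TRUE)
    lr$table$E <- Er
    expect_equal(empirical_bottleneck(lr)$EC, brute_force_EC(Er, Kr))
  }
  expect_error(empirical_bottleneck(land, max_M_paths = 3),
               class = "episcape_size_error")
})

test_that("synthetic fixtures validate, round-trip and preserve the bottleneck", {
  cfg <- model_config(preset = "gaussian_calibrated", n_instances = 1,
                      seed = 1)
  f <- tempfile(fileext = ".tsv")
  land <- make_fixture(K = 6, config = cfg, noise_cv = 0, seed = 42,
                       file = f)
  expect_identical(land$K, 6L)
  # the written file passes the reader's validation
  reread <- read_landscape_table(f)
  expect_identical(reread$K, 6L)
  expect_equal(reread$table$F_blue, land$table$F_blue, tolerance = 1e-6)
  # noiseless round trip: deconvolution recovers the generating trait order
  dec <- deconvolve_trait(normalize_fitness(land))
  expect_equal(cor(dec$table$E, land$generator_E, method = "spearman"), 1)
  # and the recovered landscape shows a bottleneck at a sensible EC
  res <- empirical_bottleneck(dec)
  expect_gt(res$EC, 0)
  expect_lte(res$EC, res$Eminref)
  # noisy fixture still validates and keeps non-negative fitness
  noisy <- make_fixture(K = 5, config = cfg, noise_cv = 0.1, seed = 7)
  expect_true(all(noisy$table$F_blue >= 0))
  expect_identical(nrow(noisy$table), 32L)
  # determinism
  again <- make_fixture(K = 5, config = cfg, noise_cv = 0.1, seed = 7)
  expect_equal(noisy$table, again$table)
})
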