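test_that("size factors match closed forms and a brute-force oracle", {
  # proportional columns force ratio 1:2 with geometric mean 1
  m <- matrix(c(2L, 6L, 4L, 12L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))

  # identical samples
  m2 <- matrix(rep(c(5L, 9L, 2L), 4), 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))

  # independent median-of-ratios oracle on a random 200 x 8 matrix
  set.seed(11)
  m3 <- matrix(rnbinom(1600, mu = 50, size = 10), 200,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  geo <- exp(rowMeans(log(m3)))
  keep <- is.finite(log(geo)) & geo > 0
  oracle <- apply(m3[keep, ] / geo[keep], 2, median)
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(size_factors(m3)), unname(oracle), tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  samples <- tiny_samples(3L)
  counts <- tiny_counts(samples, n_genes = 150L, seed = 12L)
  ours <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # same convention up to the geometric-mean-1 rescaling; DESeq2 takes the
  # median on the log scale, which can differ in the last digits when the
  # middle ratios are averaged
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("size factors demand a usable reference or explicit fallback", {
  m <- matrix(c(0L, 3L, 5L, 0L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m), "pseudo-reference",
               class = "mntox_data_error")
  s <- size_factors(m, pseudo_reference = TRUE)
  expect_true(all(s > 0))
  expect_equal(exp(mean(log(s))), 1)
})

test_that("BH adjustment matches the analytic step-up and an oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1), 1)
  set.seed(13)
  p <- runif(1000)
  expect_equal(adjust_bh(p), bh_oracle(p))
  # NA excluded from the number of tests
  p2 <- c(0.01, NA, 0.02)
  expect_equal(adjust_bh(p2), c(0.02, NA, 0.02))
  expect_error(adjust_bh(c(0.1, 1.2)), class = "mntox_data_error")
  # monotone and never below the raw p
  padj <- adjust_bh(p)
  expect_true(all(padj >= p))
  o <- order(p)
  expect_true(all(diff(padj[o]) >= -1e-15))
})

test_that("noiseless counts identify the genotype coefficient exactly", {
  samples <- tiny_samples(3L)
  g <- as.integer(samples$analysis_group == "mutant")
  counts <- rbind(gA = as.integer(2^(5 + g)))
  colnames(counts) <- samples$sample_id
  fit <- fit_nb_glm(counts, setNames(rep(1, nrow(samples)),
                                     samples$sample_id),
                    1e-8, samples)
  expect_equal(unname(fit$beta[1, "betaG"]), 1, tolerance = 1e-6)
  expect_equal(unname(fit$beta[1, "betaT"]), 0, tolerance = 1e-6)
})

test_that("per-gene fits equal direct likelihood maximisation", {
  samples <- tiny_samples(2L)
  set.seed(14)
  counts <- tiny_counts(samples, n_genes = 5L, mu = 60, seed = 14L)
  counts[2, samples$treatment == "exposed"] <-
    counts[2, samples$treatment == "exposed"] * 3L
  sf <- size_factors(counts)
  alpha <- 0.08
  fit <- fit_nb_glm(counts, sf, alpha, samples)
  X <- design_matrix(samples)
  for (i in seq_len(nrow(counts))) {
    nll <- function(beta_log2) {
      mu <- sf * 2^(as.numeric(X %*% beta_log2))
      -sum(dnbinom(counts[i, ], mu = mu, size = 1 / alpha, log = TRUE))
    }
    direct <- optim(c(6, 0, 0, 0), nll, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
    expect_equal(unname(fit$beta[i, ]), direct$par, tolerance = 1e-4)
  }
})

test_that("coefficients are invariant to sample order and to offset scale", {
  samples <- tiny_samples(3L)
  counts <- tiny_counts(samples, seed = 15L)
  sf <- size_factors(counts)
  fit <- fit_nb_glm(counts, sf, 0.05, samples)
  perm <- rev(seq_len(nrow(samples)))
  fit_p <- fit_nb_glm(counts[, perm], sf[perm], 0.05, samples[perm, ])
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-9)

  # scaling every size factor by a constant shifts only the intercept
  fit_s <- fit_nb_glm(counts, sf * 2, 0.05, samples)
  expect_equal(fit_s$beta[, "beta0"], fit$beta[, "beta0"] - 1,
               tolerance = 1e-8)
  expect_equal(fit_s$beta[, -1], fit$beta[, -1], tolerance = 1e-8)
})

test_that("dispersion estimates recover a constant truth and flag zeros", {
  cfg <- sim_config(n_genes = 2000L, n_per_condition = 8L, seed = 16L,
                    class_fractions = c(null = 1),
                    dispersion_meanlog = log(0.1), dispersion_sdlog = 1e-12)
  sim <- simulate_counts(cfg)
  counts <- sim$counts
  counts[1, ] <- 0L                      # plant an all-zero gene
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf, sim$samples)
  expect_true(disp$flagged[1])
  expect_true(is.na(disp$alpha_final[1]))
  expect_gt(median(disp$alpha_final, na.rm = TRUE), 0.05)
  expect_lt(median(disp$alpha_final, na.rm = TRUE), 0.2)

  # dispersion is a function of fitted means only: rescaling the offsets
  # leaves every estimate unchanged
  disp2 <- estimate_dispersions(counts, sf * 3, sim$samples)
  expect_equal(disp2$alpha_raw, disp$alpha_raw, tolerance = 1e-6)

  # flagged gene carries NA statistics and leaves the BH denominator
  fit <- fit_nb_glm(counts, sf, disp, sim$samples)
  res <- wald_contrast(fit, c(0, 0, 1, 0), "toxicity")
  expect_true(is.na(res$pvalue[1]) && is.na(res$padj[1]))
  expect_false(any(is.na(res$padj[-1])))
})

test_that("Wald machinery is internally consistent and validates contrasts", {
  samples <- tiny_samples(3L)
  counts <- tiny_counts(samples, seed = 17L)
  de <- run_de(counts, samples)
  res <- de$results$mutant
  expect_equal(res$stat, res$lfc / res$se)
  expect_equal(res$pvalue, 2 * pnorm(-abs(res$stat)))
  # closed-form normal tail: z = 2 gives p ~ 0.0455
  expect_equal(2 * pnorm(-2), 0.04550026, tolerance = 1e-7)
  expect_true(all(res$se > 0, na.rm = TRUE))
  expect_error(wald_contrast(de$fit, c(0, 0, 0, 0)),
               class = "mntox_contract_error")
  expect_error(wald_contrast(de$fit, c(0, 1)),
               class = "mntox_contract_error")
})

test_that("single-sample rescaling moves its size factor, not the LFCs", {
  samples <- tiny_samples(3L)
  counts <- tiny_counts(samples, n_genes = 100L, seed = 18L)
  de <- run_de(counts, samples)
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 4L
  de2 <- run_de(counts2, samples)
  expect_equal(unname(de2$size_factors[3] / de$size_factors[3] /
                        (de2$size_factors[1] / de$size_factors[1])), 4,
               tolerance = 1e-9)
  # LFC estimates are essentially unchanged; they are not bit-identical
  # because the NB score weights every sample by its fitted mean, so a
  # rescaled sample re-weights its condition slightly
  keep <- de$fit$converged & de2$fit$converged
  expect_lt(max(abs(de2$fit$beta[keep, "betaT"] -
                      de$fit$beta[keep, "betaT"])), 0.05)
})
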