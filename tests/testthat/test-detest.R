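test_that("TMM factors: symmetry, scaling absorption and unit geometric mean", {
  set.seed(10)
  y <- matrix(rnbinom(4000, mu = 50, size = 10), 2000, 2)
  colnames(y) <- c("s1", "s2")
  same <- cbind(s1 = y[, 1], s2 = y[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  doubled <- cbind(s1 = y[, 1], s2 = 2L * y[, 1])
  f <- tmm_factors(doubled)
  expect_equal(unname(f[1] / f[2]), 1, tolerance = 1e-10)
  set.seed(2)
  y4 <- matrix(rnbinom(8000, mu = 80, size = 5), 2000, 4)
  colnames(y4) <- paste0("s", 1:4)
  expect_equal(exp(mean(log(tmm_factors(y4)))), 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("TMM factors track the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  mu <- rexp(3000, 1 / 60)
  y <- cbind(s1 = rnbinom(3000, mu = mu, size = 10),
             s2 = rnbinom(3000, mu = 3 * mu, size = 10),
             s3 = rnbinom(3000, mu = mu * c(rep(4, 600), rep(1, 2400)), size = 10))
  ours <- tmm_factors(y)
  ref <- edgeR::calcNormFactors(y, method = "TMM")
  ref <- ref / exp(mean(log(ref)))
  expect_lt(max(abs(log2(ours) - log2(ref))), 0.1)
})

test_that("common dispersion is recovered across its range", {
  set.seed(7)
  grp <- factor(rep(1:2, each = 3))
  y <- matrix(rnbinom(2000 * 6, mu = 100, size = 1 / 0.1), 2000, 6)
  phi <- estimate_common_dispersion(y, grp)
  expect_gt(phi, 0.08); expect_lt(phi, 0.12)
  yp <- matrix(rpois(2000 * 6, 100), 2000, 6)
  expect_lte(estimate_common_dispersion(yp, grp), 0.01)
  # identical replicate columns: no overdispersion signal at all
  y0 <- matrix(rep(rpois(500, 80), 6), 500, 6)
  expect_lte(estimate_common_dispersion(y0, grp), 1e-5)
  expect_warning(estimate_common_dispersion(y[, c(1, 4)], factor(1:2)),
                 "no group with >= 2 replicates")
})

test_that("dispersion estimate agrees with the reference qCML estimate", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  grp <- factor(rep(1:2, each = 3))
  y <- matrix(rnbinom(3000 * 6, mu = 150, size = 1 / 0.07), 3000, 6)
  ours <- estimate_common_dispersion(y, grp)
  d <- edgeR::estimateCommonDisp(edgeR::DGEList(counts = y, group = grp))
  expect_lt(abs(ours - d$common.dispersion), 0.01)
})

test_that("exact test reduces to the binomial law at zero dispersion", {
  # S = 4 split 3|1 across 1 vs 1 replicate: Binomial(4, 1/2)
  expect_equal(nb_exact_test(3, 1, dispersion = 0), 10 / 16)
  # direct binomial oracle on a few asymmetric designs
  for (cse in list(list(s = c(7, 2), n = c(1, 2)), list(s = c(0, 9), n = c(2, 1)),
                   list(s = c(12, 12), n = c(3, 3)))) {
    S <- sum(cse$s)
    pr <- cse$n[1] / sum(cse$n)
    pmf <- dbinom(0:S, S, pr)
    want <- sum(pmf[pmf <= pmf[cse$s[1] + 1] * (1 + 1e-10)])
    got <- nb_exact_test(rep(cse$s[1] / cse$n[1], cse$n[1]),
                         rep(cse$s[2] / cse$n[2], cse$n[2]), dispersion = 0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("exact test matches brute-force conditional enumeration", {
  for (phi in c(0, 0.05, 0.5)) {
    for (design in list(c(1, 1), c(2, 3), c(3, 3))) {
      for (S in c(1, 7, 30, 120)) {
        for (s1 in unique(round(c(0, S * 0.25, S * 0.5, S * 0.9, S)))) {
          got <- nb_exact_test(c(s1, rep(0, design[1] - 1)),
                               c(S - s1, rep(0, design[2] - 1)), phi)
          want <- oracle_nb_exact(s1, S - s1, design[1], design[2], phi)
          expect_equal(got, want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("exact test handles edge cases per contract", {
  expect_equal(nb_exact_test(5, 5, dispersion = 0.3), 1)  # observed is the mode
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.1), 1)
  expect_error(nb_exact_test(c(-1, 2), c(1, 1), 0.1), "negative")
  p <- nb_exact_test(c(100, 90, 110), c(10, 12, 9), 0.05)
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("BH adjustment follows the step-up closed form", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(5)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # raising p-values never creates discoveries
  p2 <- pmin(1, p * 1.5)
  expect_lte(sum(bh_fdr(p2) < 0.05), sum(q < 0.05))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_fdr(c(0.01, NA, 0.5))[2], NA_real_)
})

test_that("contrast validation rejects malformed group specs", {
  cfg <- sim_config(n_genes = 60, seed = 14)
  gc <- generate_counts(generate_truth(cfg), cfg)
  uc <- unit_counts(gc$counts, gc$meta, cfg$polyploids)
  expect_error(run_contrast(uc, "Maxxa_A_1", "Maxxa_A_1"), "disjoint")
  expect_error(run_contrast(uc, character(0), "Maxxa_A_1"), "empty")
  expect_error(run_contrast(uc, "Maxxa_A_1", "nope_1"), "unknown units")
})

test_that("low-count genes are excluded from testing as NA", {
  cfg <- sim_config(n_genes = 300, frac_silent = 0.4, silent_leak = 0.0005,
                    seed = 15)
  tr <- generate_truth(cfg)
  gc <- generate_counts(tr, cfg)
  uc <- unit_counts(gc$counts, gc$meta, cfg$polyploids)
  de <- run_contrast(uc, paste0("Tx_D_", 1:3), paste0("Tx_A_", 1:3))
  low <- rowSums(uc$counts[, c(paste0("Tx_D_", 1:3), paste0("Tx_A_", 1:3))]) < 5
  expect_true(all(is.na(de$p[low])))
  expect_true(all(!is.na(de$p[!low])))
  expect_true(all(de$call == (!is.na(de$q) & de$q < 0.05)))
})

test_that("p-values are valid under the null at several alpha levels", {
  cfg <- sim_config(n_genes = 4000, depth = 120, phi = 0.05, frac_biased = 0,
                    frac_silent = 0, depth_sd_log2 = 0,
                    eld_fractions = stats::setNames(numeric(0), character(0)),
                    seed = 16)
  gc <- generate_counts(generate_truth(cfg), cfg)
  uc <- unit_counts(gc$counts, gc$meta, cfg$polyploids)
  de <- run_contrast(uc, paste0("Tom_D_", 1:3), paste0("Tom_A_", 1:3))
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(de$p <= alpha, na.rm = TRUE), alpha + 0.02)
  }
})
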