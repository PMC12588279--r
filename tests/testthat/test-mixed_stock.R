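test_that("containers validate their invariants", {
  expect_error(baseline_matrix(matrix(1, 2, 2)), "rownames")
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
              dimnames = list(c("A", "B"), c("X", "Y")))
  expect_error(baseline_matrix(m), "empty baseline: B")
  expect_error(mixture_counts(c(3, -1)), "named")
  expect_error(mixture_counts(c(X = -1)), "nonnegative")
  expect_equal(attr(mixture_counts(c(X = 2, Y = 3)), "total"), 5L)
})

test_that("single-source posterior is the degenerate simplex", {
  bl <- baseline_matrix(matrix(c(5L, 5L), 1, 2,
                               dimnames = list("only", c("X", "Y"))))
  post <- msa_gibbs(bl, mixture_counts(c(X = 3, Y = 4)), n_iter = 200,
                    burn_in = 100, n_chains = 2, seed = 1)
  expect_equal(unname(post$point), 1)
  expect_equal(unname(post$ci95[, "lo"]), 1)
  expect_equal(unname(post$ci95[, "hi"]), 1)
  expect_equal(unname(post$psrf), 1)  # degenerate but converged
})

test_that("Gibbs matches the analytic Dirichlet posterior on diagnostic markers", {
  bl <- diagnostic_baseline(2000L)  # concentrated q: haplotypes effectively diagnostic
  mix <- mixture_counts(c(X = 30, Y = 70))
  post <- msa_gibbs(bl, mix, n_iter = 20000, burn_in = 10000, n_chains = 4,
                    seed = 101)
  # theta | z ~ Dirichlet(1/2 + 30, 1/2 + 70): mean 30.5/101
  analytic <- c(30.5, 70.5) / 101
  flat <- matrix(aperm(post$draws, c(2, 1, 3)), ncol = 2)
  ess_floor <- 500  # conservative: draws are autocorrelated
  mc_se <- apply(flat, 2, stats::sd) / sqrt(ess_floor)
  expect_lt(abs(post$point[["A"]] - analytic[1]), 3 * mc_se[1])
  expect_lt(abs(post$point[["B"]] - analytic[2]), 3 * mc_se[2])
  # Gibbs vs EM agreement on the same problem
  em <- msa_em(bl, mix)
  expect_lt(abs(post$point[["A"]] - em$theta[["A"]]), 3 * mc_se[1] + 0.5 / 101)
})

test_that("every retained draw lies on the simplex and label order permutes outputs", {
  bl <- gen_baseline(default_source_specs(), 50, seed = 21)
  mix <- gen_mixture(bl$truth, 80, seed = 22)
  post <- msa_gibbs(bl$counts, mix, n_iter = 600, burn_in = 300, n_chains = 2,
                    seed = 23)
  sums <- apply(post$draws, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(post$draws >= 0))
  # permuting source rows permutes the posterior identically
  perm <- c(3, 1, 2, 5, 4, 9, 8, 7, 6)
  bl_p <- baseline_matrix(unclass(bl$counts)[perm, ])
  post_p <- msa_gibbs(bl_p, mix, n_iter = 600, burn_in = 300, n_chains = 2,
                      seed = 23)
  expect_equal(post_p$point, post$point[perm])
  expect_equal(post_p$psrf, post$psrf[perm])
})

test_that("mixture haplotypes absent from the baseline are excluded with a logged count", {
  bl <- diagnostic_baseline(10L)
  mix <- mixture_counts(c(X = 5, Y = 5, GHOST = 3))
  expect_message(post <- msa_gibbs(bl, mix, n_iter = 200, burn_in = 100,
                                   n_chains = 2, seed = 1),
                 "excluding 3")
  expect_equal(post$n_excluded, 3L)
  expect_error(suppressMessages(
    msa_gibbs(bl, mixture_counts(c(GHOST = 3)), n_iter = 100, burn_in = 50,
              n_chains = 2, seed = 1)), "no usable")
})

test_that("EM conditional MLE: closed form, grid oracle, boundary, monotone ascent", {
  # diagnostic 30/70: MLE is exactly the haplotype proportions
  em <- msa_em(diagnostic_baseline(10L), mixture_counts(c(X = 30, Y = 70)))
  expect_equal(unname(em$theta), c(0.3, 0.7), tolerance = 1e-7)
  expect_true(em$converged)
  expect_true(all(diff(em$trace) >= -1e-9))  # monotone nondecreasing

  # shared-haplotype problem vs brute-force likelihood grid at step 1e-4
  bl <- shared_baseline()
  for (mix in list(c(X = 40, Y = 25, Z = 35), c(X = 10, Y = 70, Z = 20))) {
    m <- mixture_counts(mix)
    em2 <- msa_em(bl, m, tol = 1e-10)
    grid <- grid_mle_2source(bl, m)
    expect_lt(abs(em2$theta[["A"]] - grid), 1e-3)
  }

  # mixture exactly proportional to source A's frequency row: boundary MLE
  blb <- baseline_matrix(matrix(c(60L, 40L, 20L, 80L), 2, 2, byrow = TRUE,
                                dimnames = list(c("A", "B"), c("X", "Y"))))
  emb <- msa_em(blb, mixture_counts(c(X = 60, Y = 40)), tol = 1e-12,
                max_iter = 100000)
  expect_equal(unname(emb$theta), c(1, 0), tolerance = 1e-3)
})

test_that("gelman_rubin reproduces the hand-evaluated formula and edge cases", {
  # chains {1,2,3}, {2,3,4}: W = 1, B/n = var(c(2,3)) = 0.5,
  # vhat = (2/3)*1 + 0.5; Rhat = sqrt(7/6)
  r <- gelman_rubin(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(unname(r), sqrt((2 / 3 * 1 + 0.5) / 1), tolerance = 1e-12)
  # two iid chains from the same distribution: Rhat near 1
  set.seed(5)
  r2 <- gelman_rubin(list(rnorm(5000), rnorm(5000)))
  expect_gte(unname(r2), 1 - 1e-8)
  expect_lt(unname(r2), 1.05)
  # degenerate chains: equal means converge, differing means diverge
  expect_equal(unname(gelman_rubin(list(rep(2, 10), rep(2, 10)))), 1)
  expect_equal(unname(gelman_rubin(list(rep(0, 10), rep(10, 10)))), Inf)
  expect_error(gelman_rubin(list(1:3)), ">= 2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal lengths")
})

test_that("summarize_contributions partitions detected sources by reporting", {
  bl <- diagnostic_baseline(100L)
  post <- msa_gibbs(bl, mixture_counts(c(X = 50, Y = 50)), n_iter = 2000,
                    burn_in = 1000, n_chains = 2, seed = 3)
  rep_all <- summarize_contributions(post, reporting_sources = c("A", "B"))
  expect_length(rep_all$detected_unreported, 0)
  rep_none <- summarize_contributions(post, reporting_sources = character())
  expect_setequal(rep_none$detected_unreported, c("A", "B"))
  expect_error(summarize_contributions(post, "Zz"), "subset")
})

test_that("a six-source truth with three reporting regions yields three unreported detections", {
  # recovery at sufficient sample size: n = 2000 market fins against a
  # 1000-per-source baseline (small-n baselines let the mixture reshape q,
  # see the methods vignette), flat contribution prior so that lower
  # credible bounds do not collapse to zero for minor contributors,
  # detection floor 1% of the market
  theta <- c(SWA = 0.06, Car = 0, Ant = 0, NWA = 0, EAt = 0.07, IOc = 0.22,
             WPa = 0.30, CPa = 0.10, EPa = 0.25)
  bl <- gen_baseline(default_source_specs(), 1000, seed = 31, theta = theta)
  mix <- gen_mixture(bl$truth, 2000, seed = 32)
  post <- msa_gibbs(bl$counts, mix, n_iter = 8000, burn_in = 4000,
                    n_chains = 2, seed = 33, alpha_theta = 1)
  rep <- summarize_contributions(post, reporting_sources = c("WPa", "IOc", "EPa"),
                                 detection_floor = 0.01)
  expect_setequal(rep$detected_reported, c("WPa", "IOc", "EPa"))
  expect_setequal(rep$detected_unreported, c("SWA", "EAt", "CPa"))
})
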