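make_events <- function(year_hits, labels_per_event = 20L) {
  # year_hits: named list year -> logical vector, one entry per vendor visit
  ev <- list()
  for (yr in names(year_hits)) {
    hits <- year_hits[[yr]]
    for (i in seq_along(hits)) {
      labels <- rep("other", labels_per_event)
      if (hits[i]) labels[1] <- "focal"
      ev[[length(ev) + 1L]] <- list(vendor_id = sprintf("%s-v%d", yr, i),
                                    year = as.integer(yr),
                                    species_labels = labels)
    }
  }
  ev
}

test_that("incidence counts vendor visits with at least one focal trimming", {
  ev <- make_events(list(`2016` = c(TRUE, TRUE, TRUE, rep(FALSE, 7))))
  s <- compute_incidence(ev, "focal")
  expect_equal(s$trials, 10L)
  expect_equal(s$successes, 3L)
  expect_equal(s$incidence, 0.3)
  # absent species: zero successes everywhere
  s0 <- compute_incidence(ev, "ghost")
  expect_equal(s0$successes, 0L)
  # duplicate labels beyond the first and trimming order do not matter
  ev2 <- ev
  ev2[[1]]$species_labels <- rev(c(rep("focal", 7), rep("other", 13)))
  expect_equal(compute_incidence(ev2, "focal")$successes, 3L)
  # malformed event rejected with its id
  ev3 <- ev
  ev3[[2]]$species_labels <- rep("other", 19)
  expect_error(compute_incidence(ev3, "focal"), "2016-v2")
})

test_that("incidence matches the closed-form complement rule at p = 0.02", {
  # P(at least one of 20) = 1 - (1 - 0.02)^20
  probs <- matrix(c(0.02, 0.98), 1, 2,
                  dimnames = list("2016", c("focal", "other")))
  sv <- gen_survey(2016, survey_design(vendors_per_event = 500L), probs, seed = 8)
  s <- compute_incidence(sv, "focal")
  expected <- 1 - (1 - 0.02)^20
  n_ev <- sum(s$trials)
  expect_gte(n_ev, 5000)
  se <- sqrt(expected * (1 - expected) / n_ev)
  expect_lt(abs(sum(s$successes) / n_ev - expected), 3 * se)
})

test_that("fit_trend: flat data, saturated 2-year fit, window, separation", {
  flat <- data.frame(year = 2015:2021, trials = 100L, successes = 25L)
  f <- fit_trend(flat)
  expect_lt(abs(f$beta1), 1e-8)
  expect_false(f$significant)
  expect_equal(f$fitted$p_hat, rep(0.25, 7), tolerance = 1e-8)

  two <- data.frame(year = c(2016, 2017), trials = c(50L, 80L),
                    successes = c(10L, 40L))
  f2 <- fit_trend(two)
  expect_equal(f2$fitted$p_hat, c(10 / 50, 40 / 80), tolerance = 1e-9)

  span <- data.frame(year = 2014:2021, trials = 100L,
                     successes = c(90L, rep(25L, 7)))
  fw <- fit_trend(span, window = c(2015, 2021))
  expect_equal(fw$fitted$year, 2015:2021)

  sep <- data.frame(year = 2015:2020, trials = 50L,
                    successes = c(0L, 0L, 0L, 50L, 50L, 50L))
  expect_warning(fs <- fit_trend(sep), "separation")
  expect_true(fs$separation)

  expect_error(fit_trend(flat[1, ]), "2 distinct years")
  expect_error(fit_trend(data.frame(year = 2015:2016, trials = 10L,
                                    successes = 0L)), "all-zero")
})

test_that("fit_trend agrees with an independent likelihood grid search", {
  df <- data.frame(year = 2015:2021, trials = c(120, 110, 100, 115, 90, 80, 95),
                   successes = c(20, 25, 19, 30, 28, 30, 40))
  f <- fit_trend(df)
  # brute-force profile over (beta0, beta1) on a fine grid around the MLE
  yc <- df$year - mean(df$year)
  nll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * yc)
    -sum(stats::dbinom(df$successes, df$trials, p, log = TRUE))
  }
  b0g <- seq(f$beta0 - 0.05, f$beta0 + 0.05, by = 1e-4)
  b1g <- seq(f$beta1 - 0.05, f$beta1 + 0.05, by = 1e-4)
  grid <- outer(b0g, b1g, Vectorize(nll))
  best <- which(grid == min(grid), arr.ind = TRUE)[1, ]
  expect_lt(abs(f$beta0 - b0g[best[1]]), 1e-3)
  expect_lt(abs(f$beta1 - b1g[best[2]]), 1e-3)
})

test_that("Wald test holds the nominal type-I error under a flat null", {
  set.seed(77)
  rej <- vapply(1:1000, function(r) {
    k <- rep(10L, 7)
    y <- rbinom(7, k, 0.3)
    if (all(y == 0) || all(y == k)) return(NA)
    f <- suppressWarnings(
      fit_trend(data.frame(year = 2015:2021, trials = k, successes = y)))
    f$p_wald < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.02)
})

test_that("a stable synthetic market shows no significant trend at design power", {
  probs <- matrix(c(0.05, 0.95), 1, 2,
                  dimnames = list("x", c("focal", "other")))
  probs <- probs[rep(1, 7), ]
  rownames(probs) <- as.character(2015:2021)
  sv <- gen_survey(2015:2021, survey_design(), probs, seed = 14)
  f <- fit_trend(compute_incidence(sv, "focal"))
  expect_false(f$significant)
  # and the model passes the randomized-quantile residual uniformity check
  qr <- quantile_residual_check(f, seed = 15)
  expect_gt(qr$ks_p, 0.01)
})

test_that("proportional contributions match hand tallies and conserve totals", {
  # hand-counted toy: 50 trimmings over 4 species in one year
  labels <- c(rep("a", 20), rep("b", 15), rep("c", 10), rep("d", 5))
  ev <- lapply(1:5, function(i) list(vendor_id = paste0("v", i), year = 2018L,
                                     species_labels = labels[(i - 1) * 10 + 1:10]))
  pc <- proportional_contribution(ev, c("a", "b", "c", "d"))
  expect_equal(pc$n_identified, 50L)
  expect_equal(pc$frac_a, 0.4)
  expect_equal(pc$frac_b, 0.3)
  expect_equal(pc$frac_c + pc$frac_d, 0.3)
  # all-one-species closure
  ev1 <- list(list(vendor_id = "v", year = 2019L,
                   species_labels = rep("a", 20)))
  pc1 <- proportional_contribution(ev1, c("a", "b"))
  expect_equal(pc1$frac_a, 1)
  expect_equal(pc1$frac_b, 0)
  # unidentified-only year: fractions undefined
  evu <- list(list(vendor_id = "v", year = 2020L,
                   species_labels = rep("unidentified", 20)))
  pcu <- proportional_contribution(evu, "a")
  expect_true(is.na(pcu$frac_a))
})

test_that("a study-sized survey runs and conserves counts", {
  # 16,222 barcoded trimmings over 2014-2021 is the real survey's scale;
  # the design maximum (2014 biweekly + 7 monthly years) is 40,800 -
  # partial stocking brings the realized count near the study's
  probs <- matrix(c(0.05, 0.95), 1, 2, dimnames = list("x", c("focal", "other")))
  probs <- probs[rep(1, 8), ]
  rownames(probs) <- as.character(2014:2021)
  sv <- gen_survey(2014:2021, survey_design(stocking_prob = 0.4), probs, seed = 6)
  expect_equal(nrow(sv) %% 20, 0)
  pc <- proportional_contribution(sv, "focal")
  expect_equal(sum(pc$n_identified), nrow(sv))
  s <- compute_incidence(sv, "focal")
  expect_equal(sum(s$trials) * 20L, nrow(sv))
})
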