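test_that("gen_baseline conserves row sums, honors exclusivity, reproduces under seed", {
  specs <- default_source_specs()
  bl <- gen_baseline(specs, n_per_source = 50, seed = 1)
  expect_equal(dim(bl$counts), c(9L, 34L))
  expect_equal(unname(rowSums(bl$counts)), rep(50, 9))
  expect_equal(unname(rowSums(bl$truth$q_true)), rep(1, 9), tolerance = 1e-12)
  expect_equal(sum(bl$truth$theta_true), 1, tolerance = 1e-12)
  # exclusive haplotypes are zero (counts and true frequency) in all other sources
  for (i in seq_along(specs)) {
    excl <- specs[[i]]$exclusive_haplotypes
    other <- setdiff(seq_along(specs), i)
    expect_true(all(bl$counts[other, excl] == 0L))
    expect_true(all(bl$truth$q_true[other, excl] == 0))
  }
  expect_identical(gen_baseline(specs, 50, seed = 1), bl)
  expect_false(identical(gen_baseline(specs, 50, seed = 2)$counts, bl$counts))
})

test_that("gen_baseline degenerate and error cases", {
  one <- source_pop_spec("only", 1, exclusive_haplotypes = "h1")
  bl <- gen_baseline(list(one), n_per_source = 7, seed = 3)
  expect_equal(unname(unclass(bl$counts)), matrix(7L, 1, 1))
  overlapping <- list(source_pop_spec("a", 2, "h1"), source_pop_spec("b", 2, "h1"))
  expect_error(gen_baseline(overlapping, 10, seed = 1), "overlap.*h1")
  expect_error(source_pop_spec("a", 1, c("h1", "h2")), "n_haplotypes")
})

test_that("gen_mixture totals, closure and large-n frequency recovery", {
  truth <- synthetic_truth(c(1, 0),
                           rbind(c(0.5, 0.5, 0), c(0, 0, 1)))
  m <- gen_mixture(truth, 100, seed = 5)
  expect_equal(sum(m), 100L)
  expect_equal(unname(m[3]), 0L)  # source 2 never sampled
  m92 <- gen_mixture(synthetic_truth(c(0.4, 0.6), rbind(c(1, 0), c(0, 1))),
                     92, seed = 1)
  expect_equal(attr(m92, "total"), 92L)
  expect_error(gen_mixture(truth, 0, seed = 1), "n")

  # law of large numbers with fully diagnostic baselines: haplotype
  # proportions approach theta within 3 binomial standard errors
  truth2 <- synthetic_truth(c(0.3, 0.7), rbind(c(1, 0), c(0, 1)))
  n <- 10000
  mx <- gen_mixture(truth2, n, seed = 11)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mx[1] / n - 0.3), 3 * se)
})

test_that("amplicon generator: derived overlap, determinism, zero-overlap concatenation", {
  haps <- gen_haplotype_sequences(3, length = 535, seed = 2)
  # 388 + 168 - 535 = 21 bp overlap forced by the printed fragment lengths
  frags <- gen_amplicon_reads(haps, c(388, 168), overlap = 21, error_rate = 0)
  expect_equal(unname(nchar(frags$frag_a)), rep(388L, 3))
  expect_equal(unname(nchar(frags$frag_b)), rep(168L, 3))
  # overlap region: template positions 368..388 appear at the end of the 5'
  # fragment and the start of the 3' fragment
  expect_identical(substr(haps, 368, 388), substr(frags$frag_b, 1, 21))
  expect_identical(substr(frags$frag_a, 368, 388), substr(frags$frag_b, 1, 21))
  expect_identical(gen_amplicon_reads(haps, c(388, 168), 21, 0.02, seed = 9),
                   gen_amplicon_reads(haps, c(388, 168), 21, 0.02, seed = 9))
  toy <- c(t1 = "ACGTA")
  z <- gen_amplicon_reads(toy, c(3, 2), overlap = 0)
  expect_equal(unname(paste0(z$frag_a, z$frag_b)), "ACGTA")
  expect_error(gen_amplicon_reads(toy, c(6, 2), overlap = 3), "longer than")
  expect_error(gen_amplicon_reads(toy, c(3, 3), overlap = 0), "inconsistent")
})

test_that("survey generator matches the vendor-visit design", {
  probs <- matrix(c(0.1, 0.9), 1, 2,
                  dimnames = list("2014", c("sp1", "other")))
  sv14 <- gen_survey(2014, survey_design(), probs, seed = 1)
  jan <- sv14[sv14$month == 1, ]
  expect_equal(length(unique(jan$vendor_id)), 20L)  # biweekly: 2 x 10 visits
  expect_true(all(table(jan$vendor_id) == 20L))     # 2 bags x 10 trimmings
  probs16 <- `rownames<-`(probs, "2016")
  sv16 <- gen_survey(2016, survey_design(), probs16, seed = 1)
  expect_equal(length(unique(sv16$vendor_id[sv16$month == 1])), 10L)  # monthly
  # zero-probability closure
  probs0 <- matrix(c(0, 1), 1, 2, dimnames = list("2016", c("ghost", "other")))
  sv0 <- gen_survey(2016, survey_design(), probs0, seed = 2)
  expect_false("ghost" %in% sv0$species)
  expect_error(gen_survey(2016, survey_design(),
                          `dimnames<-`(matrix(c(-0.1, 1.1), 1, 2),
                                       list("2016", c("a", "b"))), seed = 1),
               "negative")
})

test_that("trade ledger generator: flag closure, mismatch injection, determinism", {
  nations <- data.frame(
    nation = c("Repland", "Silentia"),
    mean_annual_kg = c(1000, 2000),
    range_state_count = c(3L, 4L),
    fao_rfmo_catch = c(TRUE, FALSE),
    seizure_implicated = c(FALSE, TRUE),
    cites_reporting = c(TRUE, FALSE))
  led <- gen_trade_ledgers(nations, 2015:2018, seed = 4, mismatch_rate = 1)
  expect_false("Silentia" %in% led$trade$exporter)
  expect_true(all(led$customs$kg > 0))
  expect_equal(nrow(led$customs), 2L * 4L)
  # mismatch injection: well-formed records appear on both sides with differing kg
  ok <- led$trade[led$trade$unit == "kg" & led$trade$source_code == "W" &
                    led$trade$purpose_code == "T", ]
  both <- tapply(ok$reported_by, paste(ok$year, ok$taxon), function(x) length(unique(x)))
  expect_true(any(both == 2))
  expect_identical(gen_trade_ledgers(nations, 2015:2018, seed = 4, mismatch_rate = 1), led)
  expect_error(gen_trade_ledgers(nations, integer(0), seed = 1), "empty year")
})
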