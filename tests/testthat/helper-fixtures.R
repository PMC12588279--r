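# Shared fixtures built in code.

# Tiny fully diagnostic 2-source baseline; large counts so that baseline
# frequency uncertainty is negligible and closed-form posteriors apply.
diagnostic_baseline <- function(n = 2000L) {
  baseline_matrix(matrix(c(n, 0L, 0L, n), 2, 2,
                         dimnames = list(c("A", "B"), c("X", "Y"))))
}

# Two-source baseline with a shared haplotype, for grid-search oracles.
shared_baseline <- function() {
  baseline_matrix(matrix(c(60L, 10L, 30L,
                           10L, 60L, 30L),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), c("X", "Y", "Z"))))
}

# Independent brute-force oracle for the 2-source mixture MLE: profile the
# mixture log-likelihood over theta in [0, 1] on a fixed grid.
grid_mle_2source <- function(baseline, mixture, step = 1e-4) {
  q <- unclass(baseline) / rowSums(baseline)
  x <- stats::setNames(integer(ncol(baseline)), colnames(baseline))
  x[names(mixture)] <- as.integer(mixture)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(t1) {
    p <- t1 * q[1, ] + (1 - t1) * q[2, ]
    keep <- x > 0
    sum(x[keep] * log(p[keep]))
  }, 0)
  grid[which.max(ll)]
}

# Independent direct-sum AMOVA oracle: explicit loops over all sequence
# pairs, no matrix shortcuts.
phi_oracle <- function(pop_a, pop_b) {
  seqs <- c(pop_a, pop_b)
  grp <- c(rep(1L, length(pop_a)), rep(2L, length(pop_b)))
  N <- length(seqs)
  d <- function(s1, s2) {
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    sum(a != b & a != "N" & b != "N")
  }
  tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) tot <- tot + d(seqs[i], seqs[j])
  ssd_total <- tot / N
  ssd_within <- 0
  for (g in 1:2) {
    idx <- which(grp == g)
    w <- 0
    if (length(idx) > 1) {
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx)) {
        w <- w + d(seqs[idx[ii]], seqs[idx[jj]])
      }
    }
    ssd_within <- ssd_within + w / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - 2)
  n_prime <- (N - (sum(grp == 1)^2 + sum(grp == 2)^2) / N) / 1
  sigma_a <- (ssd_among / 1 - sigma_w) / n_prime
  sigma_a / (sigma_a + sigma_w)
}

# Random equal-length sequences for structure tests.
random_seqs <- function(n, len = 30L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# Minimal well-formed trade record.
trade_record <- function(exporter = "Spain", year = 2018L,
                         taxon = "Sphyrna lewini", quantity = 100,
                         unit = "kg", source_code = "W", purpose_code = "T",
                         term = "fins", reported_by = "importer",
                         importer = "Hong Kong") {
  data.frame(exporter = exporter, importer = importer, year = year,
             taxon = taxon, term = term, unit = unit, quantity = quantity,
             source_code = source_code, purpose_code = purpose_code,
             reported_by = reported_by, stringsAsFactors = FALSE)
}
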