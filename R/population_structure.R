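#' Pairwise nucleotide-difference matrix
#'
#' Number of differing sites for every pair of equal-length sequences.
#' Positions where either base is `N` are skipped (wildcard).
#'
#' @param seqs Character vector of equal-length sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
pairwise_diff_matrix <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n && length(unique(nchar(seqs))) > 1L) {
    stop("sequences must have equal length", call. = FALSE)
  }
  D <- matrix(0L, n, n)
  if (n < 2L) return(D)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (i in seq_len(n - 1L)) {
    a <- chars[i, ]
    for (j in (i + 1L):n) {
      b <- chars[j, ]
      d <- sum(a != b & a != "N" & b != "N")
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Two-level AMOVA variance components from a (squared) distance matrix and
# a two-group assignment, following the sum-of-squared-deviations
# decomposition: SSD(total) = sum_{i<j} d2[i,j] / N and SSD(within) =
# sum over groups of within-group pair sums / group size.
amova_phi <- function(D, in_a) {
  N <- nrow(D)
  na <- sum(in_a); nb <- N - na
  tot <- sum(D) / 2
  wa <- sum(D[in_a, in_a]) / 2
  wb <- sum(D[!in_a, !in_a]) / 2
  ssd_total <- tot / N
  ssd_within <- wa / na + wb / nb
  ssd_among <- ssd_total - ssd_within
  if (ssd_total <= 0) {
    return(list(phi = NA_real_, ssd_among = 0, ssd_within = 0,
                sigma_among = NA_real_, sigma_within = NA_real_))
  }
  df_among <- 1L
  df_within <- N - 2L
  sigma_w <- ssd_within / df_within
  n_prime <- (N - (na^2 + nb^2) / N) / df_among
  sigma_a <- (ssd_among / df_among - sigma_w) / n_prime
  phi <- sigma_a / (sigma_a + sigma_w)
  list(phi = phi, ssd_among = ssd_among, ssd_within = ssd_within,
       sigma_among = sigma_a, sigma_within = sigma_w)
}

#' Pairwise Phi-ST between two populations
#'
#' AMOVA-style fixation index from the two-level variance decomposition
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`, with
#' inter-sequence distances taken as raw pairwise nucleotide differences
#' (no substitution-model correction). The variance components use the
#' standard unbiased moment estimators, so `Phi_ST` can be slightly
#' negative when there is no among-group variance; when the pooled sample
#' has zero total variance the index is undefined and reported as `NA`.
#'
#' @param pop_a,pop_b Character vectors (>= 2 sequences each, equal
#'   lengths across both).
#' @param names Optional length-2 character vector of population names.
#' @return Object of class `structure_test` with `phi_st`, the variance
#'   components, and (when produced by [permutation_test()]) `p_value` and
#'   `n_permutations`.
#' @export
pairwise_phi_st <- function(pop_a, pop_b, names = c("A", "B")) {
  if (length(pop_a) < 2L || length(pop_b) < 2L) {
    stop("each population needs >= 2 sequences", call. = FALSE)
  }
  D <- pairwise_diff_matrix(c(pop_a, pop_b))
  in_a <- c(rep(TRUE, length(pop_a)), rep(FALSE, length(pop_b)))
  comp <- amova_phi(D, in_a)
  structure(list(phi_st = comp$phi,
                 sigma_among = comp$sigma_among,
                 sigma_within = comp$sigma_within,
                 p_value = NA_real_, n_permutations = 0L,
                 pair = names,
                 n = c(length(pop_a), length(pop_b))),
            class = "structure_test")
}

#' @export
print.structure_test <- function(x, ...) {
  cat(sprintf("Phi_ST(%s, %s) = %s  [n = %d + %d]\n",
              x$pair[1], x$pair[2],
              ifelse(is.na(x$phi_st), "undefined (zero total variance)",
                     sprintf("%.4f", x$phi_st)),
              x$n[1], x$n[2]))
  if (x$n_permutations > 0L) {
    cat(sprintf("permutation p = %.5g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Permutation test of population differentiation
#'
#' Permutes individuals across the two groups (group sizes fixed) and
#' recomputes `Phi_ST`; the p-value is
#' `(#\{permuted Phi >= observed\} + 1) / (n_permutations + 1)`.
#'
#' @inheritParams pairwise_phi_st
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return A `structure_test` with `p_value` and `n_permutations` filled.
#' @export
permutation_test <- function(pop_a, pop_b, n_permutations = 10000L,
                             seed = NULL, names = c("A", "B")) {
  stopifnot_scalar_count(n_permutations, "n_permutations")
  res <- pairwise_phi_st(pop_a, pop_b, names = names)
  N <- sum(res$n); na <- res$n[1]
  D <- pairwise_diff_matrix(c(pop_a, pop_b))
  obs <- res$phi_st
  if (is.na(obs)) {
    res$p_value <- NA_real_
    res$n_permutations <- n_permutations
    return(res)
  }
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_permutations)) {
      in_a <- logical(N)
      in_a[sample.int(N, na)] <- TRUE
      if (amova_phi(D, in_a)$phi >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  res$p_value <- (exceed + 1) / (n_permutations + 1)
  res$n_permutations <- as.integer(n_permutations)
  res
}

#' Decide whether a candidate sample is a distinct population
#'
#' The candidate is tested against every baseline population with
#' [permutation_test()]. It is declared `distinct` only when every
#' pairwise comparison remains significant after the multiple-testing
#' correction; otherwise it is merged into the baseline population with
#' the smallest nonsignificant `Phi_ST` (the natural generalization of
#' folding new samples into the population whose common haplotypes they
#' share).
#'
#' @param candidate Character vector of sequences (>= 2).
#' @param baseline_pops Named list of sequence vectors, one per baseline
#'   population (nonempty).
#' @param alpha Significance level after correction (default 0.05).
#' @param n_permutations Permutations per pairwise test (default 999).
#' @param correction Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @param seed Integer seed.
#' @return List of class `delimit_result`: `decision` (`"distinct"` or
#'   `"merged"`), `merged_with` (population name or `NA`), and `tests`
#'   (per-population data frame).
#' @export
delimit_population <- function(candidate, baseline_pops, alpha = 0.05,
                               n_permutations = 999L,
                               correction = "bonferroni", seed = NULL) {
  if (length(baseline_pops) == 0L) stop("empty baseline map", call. = FALSE)
  if (is.null(names(baseline_pops)) || any(!nzchar(names(baseline_pops)))) {
    stop("`baseline_pops` must be a named list", call. = FALSE)
  }
  if (length(candidate) < 2L) stop("candidate needs >= 2 sequences", call. = FALSE)
  tests <- with_seed(seed, {
    lapply(names(baseline_pops), function(nm) {
      permutation_test(candidate, baseline_pops[[nm]],
                       n_permutations = n_permutations,
                       names = c("candidate", nm))
    })
  })
  df <- data.frame(
    population = names(baseline_pops),
    phi_st = vapply(tests, function(t) t$phi_st, 0),
    p_value = vapply(tests, function(t) t$p_value, 0),
    stringsAsFactors = FALSE)
  df$p_adjusted <- stats::p.adjust(df$p_value, method = correction)
  df$significant <- !is.na(df$p_adjusted) & df$p_adjusted < alpha
  nonsig <- df[!df$significant, , drop = FALSE]
  if (nrow(nonsig) == 0L) {
    decision <- "distinct"; merged_with <- NA_character_
  } else {
    decision <- "merged"
    # an undefined Phi (zero total variance) means the candidate is
    # indistinguishable from that population: most mergeable of all
    rank_phi <- ifelse(is.na(nonsig$phi_st), -Inf, nonsig$phi_st)
    merged_with <- nonsig$population[which.min(rank_phi)]
  }
  structure(list(decision = decision, merged_with = merged_with, tests = df,
                 alpha = alpha, correction = correction),
            class = "delimit_result")
}

#' @export
print.delimit_result <- function(x, ...) {
  print(x$tests, ...)
  if (x$decision == "distinct") {
    cat(sprintf("-> distinct population (all pairwise tests significant at alpha = %g, %s)\n",
                x$alpha, x$correction))
  } else {
    cat(sprintf("-> merged into '%s' (smallest nonsignificant Phi_ST)\n",
                x$merged_with))
  }
  invisible(x)
}
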