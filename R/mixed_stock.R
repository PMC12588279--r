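#' Source-by-haplotype baseline counts
#'
#' The "global baseline": observed haplotype counts per source population.
#' Every source row must have a positive total. Columns that are all zero
#' are permitted: the haplotype catalogue comes from the literature, not
#' from this particular baseline sample, and an unsampled haplotype is
#' identified only through the prior.
#'
#' @param counts Nonnegative integer matrix, sources in rows (rownames),
#'   haplotypes in columns (colnames).
#' @return Validated matrix of class `baseline_matrix`.
#' @export
baseline_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("baseline needs source rownames and haplotype colnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("baseline counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) <= 0)) {
    bad <- rownames(counts)[rowSums(counts) <= 0]
    stop("source(s) with empty baseline: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("baseline_matrix", "matrix"))
}

#' Haplotype counts observed in a market mixture
#'
#' @param x Named nonnegative integer vector of haplotype counts.
#' @return Vector of class `mixture_counts`; `attr(, "total")` is the
#'   sample size.
#' @export
mixture_counts <- function(x) {
  if (is.null(names(x))) stop("mixture counts must be named by haplotype", call. = FALSE)
  if (any(x < 0) || any(x != floor(x))) {
    stop("mixture counts must be nonnegative integers", call. = FALSE)
  }
  x <- stats::setNames(as.integer(x), names(x))
  structure(x, total = sum(x), class = "mixture_counts")
}

# Align a mixture onto the baseline's haplotype columns. Haplotypes absent
# from the baseline catalogue cannot be modeled; they are dropped with a
# message (mirroring the attrition bookkeeping of real market samples) and
# the dropped total is recorded.
align_mixture <- function(baseline, mixture, on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  x <- stats::setNames(integer(ncol(baseline)), colnames(baseline))
  known <- names(mixture) %in% colnames(baseline)
  if (any(!known & mixture > 0L)) {
    n_bad <- sum(mixture[!known])
    if (on_unknown == "error") {
      stop("mixture haplotype(s) absent from baseline: ",
           paste(names(mixture)[!known & mixture > 0L], collapse = ", "),
           call. = FALSE)
    }
    message(sprintf("excluding %d mixture record(s) with haplotypes absent from the baseline", n_bad))
  }
  keep <- mixture[known]
  x[names(keep)] <- x[names(keep)] + as.integer(keep)
  attr(x, "n_excluded") <- sum(mixture[!known])
  x
}

#' Bayesian mixed-stock analysis by Gibbs sampling
#'
#' Estimates the proportional contribution `theta[s]` of each baseline
#' source population to a mixed market sample from haplotype counts, under
#' the standard many-to-one Dirichlet-multinomial mixture model. The Gibbs
#' cycle augments each mixture individual with a latent source label `z`:
#' \enumerate{
#'   \item `z[i] | theta, q` proportional to `theta[s] * q[s, h(i)]`;
#'   \item `theta | z ~ Dirichlet(alpha_theta + tally(z))`;
#'   \item `q[s, ] | data ~ Dirichlet(alpha_q + baseline[s, ] + tally of
#'     mixture individuals assigned to s)`,
#' }
#' so baseline sampling uncertainty propagates into the contribution
#' estimates. Convergence is assessed with the Gelman-Rubin potential
#' scale reduction factor across chains (threshold 1.2 by default).
#'
#' @param baseline A [baseline_matrix()].
#' @param mixture A [mixture_counts()]; haplotypes must exist in the
#'   baseline catalogue (others are excluded with a logged count).
#' @param n_iter Iterations per chain (default 100000).
#' @param burn_in Burn-in iterations discarded per chain (default 50000).
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param seed Integer seed for the whole run.
#' @param alpha_theta Dirichlet prior concentration on contributions;
#'   default `1/S` (one prior pseudo-individual spread over sources).
#' @param alpha_q Dirichlet prior concentration per baseline cell
#'   (default 1).
#' @param psrf_threshold Convergence threshold on max R-hat (default 1.2).
#' @return Object of class `msa_posterior`: `draws` (chains x kept x S
#'   array), `point` (posterior means), `ci95`, `psrf`, `converged`,
#'   `n_excluded`, plus the settings used.
#' @seealso [msa_em()] for the conditional-MLE cross-check,
#'   [gelman_rubin()], [summarize_contributions()].
#' @export
msa_gibbs <- function(baseline, mixture, n_iter = 100000L, burn_in = 50000L,
                      n_chains = 4L, seed = NULL, alpha_theta = NULL,
                      alpha_q = 1, psrf_threshold = 1.2) {
  stopifnot(inherits(baseline, "baseline_matrix"))
  stopifnot_scalar_count(n_iter, "n_iter")
  stopifnot_scalar_count(burn_in, "burn_in", min = 0L)
  if (burn_in >= n_iter) stop("`burn_in` must be < `n_iter`", call. = FALSE)
  stopifnot_scalar_count(n_chains, "n_chains")
  # canonical internal ordering makes the sampler exactly equivariant to
  # row/column permutations of the inputs (RNG consumption would otherwise
  # depend on the order sources are stored in)
  in_order <- rownames(baseline)
  baseline <- baseline_matrix(unclass(baseline)[order(rownames(baseline)),
                                                order(colnames(baseline)),
                                                drop = FALSE])
  S <- nrow(baseline); H <- ncol(baseline)
  sources <- rownames(baseline)
  alpha_theta <- alpha_theta %||% (1 / S)
  x <- align_mixture(baseline, mixture)
  n_excluded <- attr(x, "n_excluded")
  hx <- which(x > 0L)
  if (!length(hx)) stop("mixture has no usable records", call. = FALSE)
  xh <- as.integer(x[hx])
  A_q <- alpha_q + unclass(baseline)
  kept <- n_iter - burn_in
  draws <- array(NA_real_, dim = c(n_chains, kept, S),
                 dimnames = list(NULL, NULL, sources))
  rhat_ok <- n_chains >= 2L
  if (!rhat_ok) {
    warning("n_chains < 2: Gelman-Rubin diagnostic unavailable", call. = FALSE)
  }

  with_seed(seed, {
    for (ch in seq_len(n_chains)) {
      # overdispersed start: theta from a flat Dirichlet, q from its prior
      theta <- rdirichlet(rep(1, S))
      q <- rdirichlet(A_q)
      m_hx <- matrix(0L, S, length(hx))
      for (it in seq_len(n_iter)) {
        W <- theta * q[, hx, drop = FALSE]
        for (j in seq_along(hx)) {
          m_hx[, j] <- stats::rmultinom(1L, xh[j], W[, j])
        }
        theta <- rdirichlet(alpha_theta + rowSums(m_hx))
        Aq <- A_q
        Aq[, hx] <- Aq[, hx] + m_hx
        q <- rdirichlet(Aq)
        if (it > burn_in) draws[ch, it - burn_in, ] <- theta
      }
    }
  })

  flat <- matrix(aperm(draws, c(2, 1, 3)), ncol = S,
                 dimnames = list(NULL, sources))
  point <- colMeans(flat)
  ci95 <- t(apply(flat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci95) <- c("lo", "hi")
  psrf <- if (rhat_ok) {
    gelman_rubin(lapply(seq_len(n_chains),
                        function(ch) matrix(draws[ch, , ], ncol = S)))
  } else {
    rep(NA_real_, S)
  }
  psrf <- stats::setNames(as.numeric(psrf), sources)
  # restore the caller's source order
  back <- match(in_order, sources)
  draws <- draws[, , back, drop = FALSE]
  point <- point[back]
  ci95 <- ci95[back, , drop = FALSE]
  psrf <- psrf[back]
  structure(list(
    draws = draws, point = point, ci95 = ci95, psrf = psrf,
    converged = if (rhat_ok) all(psrf < psrf_threshold) else NA,
    n_excluded = n_excluded,
    settings = list(n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                    seed = seed, alpha_theta = alpha_theta, alpha_q = alpha_q,
                    psrf_threshold = psrf_threshold)),
    class = "msa_posterior")
}

#' @export
print.msa_posterior <- function(x, ...) {
  cat(sprintf("Mixed-stock posterior: %d sources, %d chains x %d kept draws\n",
              length(x$point), dim(x$draws)[1], dim(x$draws)[2]))
  df <- data.frame(mean = round(x$point, 4),
                   lo95 = round(x$ci95[, "lo"], 4),
                   hi95 = round(x$ci95[, "hi"], 4),
                   Rhat = round(x$psrf, 3))
  print(df, ...)
  cat(sprintf("max R-hat = %.4f; converged (< %.2f): %s; excluded records: %d\n",
              max(x$psrf), x$settings$psrf_threshold, x$converged, x$n_excluded))
  invisible(x)
}

#' Conditional maximum-likelihood mixture estimate (EM)
#'
#' Independent frequentist cross-check for [msa_gibbs()]: baseline
#' frequencies are fixed at their row MLEs `q[s,h] = n[s,h] / n[s,.]` and
#' the mixture log-likelihood `sum_h x[h] log(sum_s theta[s] q[s,h])` is
#' maximized over the contribution simplex by EM. The log-likelihood is
#' checked to be nondecreasing at every step.
#'
#' @param baseline A [baseline_matrix()].
#' @param mixture A [mixture_counts()].
#' @param tol Stop when the max absolute change in `theta` falls below this.
#' @param max_iter Iteration cap.
#' @return List of class `msa_em`: `theta` (named MLE), `loglik` (final),
#'   `trace` (log-likelihood per iteration), `iterations`, `converged`,
#'   `n_excluded`.
#' @export
msa_em <- function(baseline, mixture, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(baseline, "baseline_matrix"))
  S <- nrow(baseline)
  x <- align_mixture(baseline, mixture)
  n_excluded <- attr(x, "n_excluded")
  q <- unclass(baseline) / rowSums(baseline)
  # a haplotype never observed in any baseline row has q[, h] = 0: its
  # mixture records carry no information under fixed-q and are excluded
  zero_col <- colSums(q) == 0 & x > 0L
  if (any(zero_col)) {
    message(sprintf("excluding %d record(s) whose haplotype has zero baseline frequency", sum(x[zero_col])))
    n_excluded <- n_excluded + sum(x[zero_col])
    x[zero_col] <- 0L
  }
  hx <- which(x > 0L)
  if (!length(hx)) stop("mixture has no usable records", call. = FALSE)
  xh <- x[hx]; M <- sum(xh)
  qh <- q[, hx, drop = FALSE]
  theta <- rep(1 / S, S)
  ll <- function(th) sum(xh * log(colSums(th * qh)))
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- colSums(theta * qh)                    # mixture haplotype probs
    r <- (theta * qh) / rep(p, each = S)        # responsibilities r[s,h]
    theta_new <- as.numeric(r %*% xh) / M
    cur <- ll(theta_new)
    if (cur < prev - 1e-9) {
      stop(sprintf("EM log-likelihood decreased at iteration %d (%.10g -> %.10g)",
                   it, prev, cur), call. = FALSE)
    }
    trace <- c(trace, cur)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    prev <- cur
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(theta = stats::setNames(theta, rownames(baseline)),
                 loglik = prev, trace = trace, iterations = length(trace),
                 converged = converged, n_excluded = n_excluded),
            class = "msa_em")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF per parameter:
#' `R-hat = sqrt(((n - 1) / n * W + B / n) / W)` where `W` is the mean
#' within-chain variance and `B / n` the between-chain variance of the
#' chain means. Chains with zero within-chain variance yield 1 when their
#' means agree (degenerate but converged) and `Inf` when they differ.
#'
#' @param chains List (length >= 2) of equal-sized numeric vectors or
#'   matrices (iterations x parameters), one per chain.
#' @return Named numeric vector of per-parameter R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need a list of >= 2 chains", call. = FALSE)
  }
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1L) else as.matrix(ch)
  })
  n <- unique(vapply(chains, nrow, 0L))
  p <- unique(vapply(chains, ncol, 0L))
  if (length(n) != 1L || length(p) != 1L) {
    stop("chains must have equal lengths and parameter counts", call. = FALSE)
  }
  if (n < 2L) stop("chains must have >= 2 draws", call. = FALSE)
  means <- vapply(chains, colMeans, numeric(p))             # p x m
  vars <- vapply(chains, function(ch) apply(ch, 2, stats::var), numeric(p))
  if (p == 1L) { means <- matrix(means, nrow = 1L); vars <- matrix(vars, nrow = 1L) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)
  vhat <- (n - 1) / n * W + B_over_n
  rhat <- ifelse(W > 0, sqrt(vhat / W), ifelse(B_over_n > 0, Inf, 1))
  nm <- colnames(chains[[1]]) %||% paste0("param", seq_len(p))
  stats::setNames(as.numeric(rhat), nm)
}

#' Summarize posterior contributions against reported trade origins
#'
#' Flags each source as "detected" when the lower bound of its 95%
#' credible interval exceeds `detection_floor`, then partitions detected
#' sources into those from regions with reported trade and those without —
#' the discrepancy pattern that indicates unreported (illegal) trade.
#'
#' @param post An `msa_posterior` from [msa_gibbs()].
#' @param reporting_sources Character vector of source names with reported
#'   trade (subset of the baseline sources).
#' @param detection_floor Detection threshold on the 2.5% quantile
#'   (default 0).
#' @return List of class `msa_report`: `table` (per-source summary),
#'   `detected_reported`, `detected_unreported`.
#' @export
summarize_contributions <- function(post, reporting_sources = character(),
                                    detection_floor = 0) {
  stopifnot(inherits(post, "msa_posterior"))
  sources <- names(post$point)
  if (!all(reporting_sources %in% sources)) {
    stop("`reporting_sources` must be a subset of the baseline sources", call. = FALSE)
  }
  tab <- data.frame(
    source = sources,
    mean = as.numeric(post$point),
    lo95 = post$ci95[, "lo"],
    hi95 = post$ci95[, "hi"],
    detected = post$ci95[, "lo"] > detection_floor,
    reporting = sources %in% reporting_sources,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    detected_reported = tab$source[tab$detected & tab$reporting],
    detected_unreported = tab$source[tab$detected & !tab$reporting]),
    class = "msa_report")
}

#' @export
print.msa_report <- function(x, ...) {
  print(x$table, ...)
  cat("detected, trade reported:  ",
      paste(x$detected_reported, collapse = ", "), "\n")
  cat("detected, no reported trade:",
      paste(x$detected_unreported, collapse = ", "), "\n")
  invisible(x)
}
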