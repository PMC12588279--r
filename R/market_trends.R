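# Normalize survey input into a list of events, each a list with
# `vendor_id`, `year`, `species_labels`. Accepts the survey_trimmings
# data.frame (one row per trimming) or an already-built event list.
as_survey_events <- function(events) {
  if (is.data.frame(events)) {
    if (!all(c("vendor_id", "species") %in% names(events))) {
      stop("survey data needs `vendor_id` and `species` columns", call. = FALSE)
    }
    yr <- if ("year" %in% names(events)) {
      events$year
    } else if ("date" %in% names(events)) {
      as.integer(substr(as.character(events$date), 1, 4))
    } else {
      stop("survey data needs a `year` or `date` column", call. = FALSE)
    }
    split_idx <- split(seq_len(nrow(events)), events$vendor_id)
    lapply(split_idx, function(ix) {
      list(vendor_id = events$vendor_id[ix[1]],
           year = yr[ix[1]],
           species_labels = as.character(events$species[ix]))
    })
  } else if (is.list(events)) {
    events
  } else {
    stop("`events` must be a data frame or a list of events", call. = FALSE)
  }
}

#' Annual incidence of a species across vendor-visit trials
#'
#' A trial is one vendor visit (two bags, 20 genotyped trimmings); the
#' trial is a success when at least one of its 20 trimmings is the focal
#' species. Incidence for a year is successes / trials. Duplicate labels
#' beyond the first within a visit do not change the statistic, nor does
#' trimming order.
#'
#' @param events Survey data: a `survey_trimmings` data frame (one row per
#'   trimming) or a list of events with `vendor_id`, `year`,
#'   `species_labels`.
#' @param species Focal species label.
#' @param labels_per_event Required number of labels per event (default
#'   20); an event with any other count is rejected, naming the vendor.
#' @return `data.frame` of class `incidence_series` with columns `year`,
#'   `trials`, `successes`, `incidence`; the species is kept as an
#'   attribute.
#' @export
compute_incidence <- function(events, species, labels_per_event = 20L) {
  ev <- as_survey_events(events)
  if (!length(ev)) stop("no survey events supplied", call. = FALSE)
  nlab <- vapply(ev, function(e) length(e$species_labels), 0L)
  if (any(nlab != labels_per_event)) {
    bad <- vapply(ev[nlab != labels_per_event], function(e) as.character(e$vendor_id), "")
    stop(sprintf("event(s) with != %d trimmings: %s", labels_per_event,
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  year <- vapply(ev, function(e) as.integer(e$year), 0L)
  hit <- vapply(ev, function(e) species %in% e$species_labels, TRUE)
  years <- sort(unique(year))
  out <- data.frame(
    year = years,
    trials = vapply(years, function(y) sum(year == y), 0L),
    successes = vapply(years, function(y) sum(hit[year == y]), 0L))
  out$incidence <- out$successes / out$trials
  attr(out, "species") <- species
  class(out) <- c("incidence_series", "data.frame")
  out
}

#' Binomial-logit trend in annual incidence
#'
#' Fits `logit(p_t) = beta0 + beta1 * (year - mean(year))` by IRLS
#' ([stats::glm()] with a binomial family), with one Bernoulli trial per
#' vendor visit aggregated per year. The year predictor is centered for
#' numerical stability (this changes only the intercept). Significance of
#' the year slope is judged by its Wald test; the 95% confidence band is
#' the delta-method interval on the linear predictor mapped through the
#' inverse logit. Complete separation is flagged rather than allowed to
#' diverge silently.
#'
#' @param series An [compute_incidence()] result (or data frame with
#'   `year`, `trials`, `successes`).
#' @param alpha Significance level for the trend classification.
#' @param window Optional length-2 year range to restrict the fit (e.g.
#'   `c(2015, 2021)`).
#' @return Object of class `trend_fit`: `beta0`, `beta1`, `se_beta1`,
#'   `p_wald`, `significant`, `fitted` (per-year probabilities with CI),
#'   `separation`, and the underlying `glm` object.
#' @export
fit_trend <- function(series, alpha = 0.05, window = NULL) {
  df <- as.data.frame(series)
  if (!all(c("year", "trials", "successes") %in% names(df))) {
    stop("`series` needs year/trials/successes columns", call. = FALSE)
  }
  if (!is.null(window)) {
    df <- df[df$year >= window[1] & df$year <= window[2], , drop = FALSE]
  }
  if (length(unique(df$year)) < 2L) {
    stop("need >= 2 distinct years to fit a trend", call. = FALSE)
  }
  if (all(df$successes == 0L) || all(df$successes == df$trials)) {
    stop("all-zero or all-maximal incidence: trend undefined", call. = FALSE)
  }
  df$year_c <- df$year - mean(df$year)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(successes, trials - successes) ~ year_c,
               family = stats::binomial(link = "logit"), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  separation <- sep_warned || abs(co["year_c", "Estimate"]) > 15
  if (separation) {
    warning("possible complete separation: slope estimate unreliable", call. = FALSE)
  }
  pr <- stats::predict(fit, newdata = df, type = "link", se.fit = TRUE)
  fitted <- data.frame(
    year = df$year,
    observed = df$successes / df$trials,
    p_hat = stats::plogis(pr$fit),
    lo95 = stats::plogis(pr$fit - 1.96 * pr$se.fit),
    hi95 = stats::plogis(pr$fit + 1.96 * pr$se.fit))
  p_wald <- co["year_c", "Pr(>|z|)"]
  structure(list(beta0 = unname(co["(Intercept)", "Estimate"]),
                 beta1 = unname(co["year_c", "Estimate"]),
                 se_beta1 = unname(co["year_c", "Std. Error"]),
                 p_wald = unname(p_wald),
                 significant = unname(p_wald < alpha),
                 alpha = alpha,
                 fitted = fitted,
                 separation = separation,
                 model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("logit(p) = %.4f %+.4f * (year - mean)   [Wald p = %.4g, %s at alpha = %g]\n",
              x$beta0, x$beta1, x$p_wald,
              if (x$significant) "significant" else "nonsignificant", x$alpha))
  if (x$separation) cat("warning: possible complete separation\n")
  print(x$fitted, ...)
  invisible(x)
}

#' Randomized-quantile residual uniformity check
#'
#' Simple goodness-of-fit diagnostic for a [fit_trend()] model: for each
#' year a randomized quantile residual is drawn uniformly between the
#' fitted binomial CDF at `successes - 1` and at `successes`; under a
#' correct model these are i.i.d. uniform, which is assessed with a
#' Kolmogorov-Smirnov test.
#'
#' @param fit A `trend_fit`.
#' @param seed Integer seed for the randomization.
#' @return List with `residuals` (uniform scale) and `ks_p`.
#' @export
quantile_residual_check <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  df <- fit$model$data
  p_hat <- stats::fitted(fit$model)
  with_seed(seed, {
    lo <- stats::pbinom(df$successes - 1, df$trials, p_hat)
    hi <- stats::pbinom(df$successes, df$trials, p_hat)
    u <- stats::runif(length(p_hat), lo, hi)
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    list(residuals = u, ks_p = ks$p.value)
  })
}

#' Proportional contribution of species to annual sampled trimmings
#'
#' For each year, the number of trimmings identified as each species in
#' `species_set` divided by all identified trimmings that year. Labels in
#' `unidentified_labels` are excluded from the denominator; a year with
#' zero identified trimmings yields `NA` fractions.
#'
#' @param events Survey data as in [compute_incidence()].
#' @param species_set Character vector of focal species.
#' @param unidentified_labels Labels treated as identification failures.
#' @return `data.frame` with one row per year: `year`, `n_identified`, and
#'   one `frac_*` column per species.
#' @export
proportional_contribution <- function(events, species_set,
                                      unidentified_labels = c("unidentified", "unknown")) {
  ev <- as_survey_events(events)
  if (!length(ev)) stop("no survey events supplied", call. = FALSE)
  year <- unlist(lapply(ev, function(e) rep(as.integer(e$year),
                                            length(e$species_labels))))
  lab <- unlist(lapply(ev, `[[`, "species_labels"))
  ok <- !(lab %in% unidentified_labels)
  years <- sort(unique(year))
  out <- data.frame(year = years,
                    n_identified = vapply(years, function(y) sum(ok & year == y), 0L))
  for (sp in species_set) {
    cnt <- vapply(years, function(y) sum(ok & year == y & lab == sp), 0L)
    out[[paste0("frac_", gsub("[^A-Za-z0-9]+", "_", sp))]] <-
      ifelse(out$n_identified > 0L, cnt / out$n_identified, NA_real_)
  }
  out
}
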