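#' CoP16-listed shark species
#'
#' The five shark species added to CITES Appendix II at the 16th Conference
#' of the Parties: three hammerheads, the oceanic whitetip and the porbeagle.
#'
#' @format Character vector of five binomials.
#' @export
cop16_species <- function() {
  c("Sphyrna lewini", "Sphyrna zygaena", "Sphyrna mokarran",
    "Carcharhinus longimanus", "Lamna nasus")
}

#' Describe one source population for baseline simulation
#'
#' A source population is characterized by the set of mitochondrial
#' control-region haplotypes that can occur in it. Haplotypes listed in
#' `exclusive_haplotypes` occur in this source and nowhere else; the
#' remainder of its `n_haplotypes` are filled from a shared pool common to
#' all sources. Exclusive haplotype groups are what make the mixed-stock
#' analysis identifiable.
#'
#' @param name Short population code, e.g. `"WPa"`.
#' @param n_haplotypes Total number of haplotypes segregating in the source.
#' @param exclusive_haplotypes Character vector of haplotype IDs private to
#'   this source (may be empty).
#' @param concentration Symmetric Dirichlet concentration used when drawing
#'   the source's true haplotype frequencies.
#' @return An object of class `source_pop_spec`.
#' @seealso [default_source_specs()], [gen_baseline()]
#' @export
source_pop_spec <- function(name, n_haplotypes,
                            exclusive_haplotypes = character(),
                            concentration = 1) {
  stopifnot_scalar_count(n_haplotypes, "n_haplotypes")
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  exclusive_haplotypes <- as.character(exclusive_haplotypes)
  if (anyDuplicated(exclusive_haplotypes)) {
    stop("duplicated IDs in `exclusive_haplotypes`", call. = FALSE)
  }
  if (n_haplotypes < length(exclusive_haplotypes)) {
    stop(sprintf("source '%s': n_haplotypes (%d) < number of exclusive haplotypes (%d)",
                 name, n_haplotypes, length(exclusive_haplotypes)), call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1L || concentration <= 0) {
    stop("`concentration` must be a positive scalar", call. = FALSE)
  }
  structure(list(name = name,
                 n_haplotypes = as.integer(n_haplotypes),
                 exclusive_haplotypes = exclusive_haplotypes,
                 concentration = concentration),
            class = "source_pop_spec")
}

#' Default nine-source global baseline preset
#'
#' Emulates the structure of the published global scalloped hammerhead
#' baseline: nine populations (SWA, Car, Ant, NWA, EAt, IOc, WPa, CPa, EPa)
#' jointly segregating 34 mtCR haplotypes, each population carrying a group
#' of exclusive (private) haplotypes on top of a shared backbone. Each
#' source here receives two private haplotypes (18 in total) plus the same
#' 16 shared haplotypes, so every source has 18 haplotypes. The published
#' frequencies themselves are not reproduced (they are not printed); only
#' the identifiability regime is.
#'
#' @param concentration Dirichlet concentration passed to every source.
#' @return List of nine [source_pop_spec()] objects.
#' @export
default_source_specs <- function(concentration = 1) {
  pops <- c("SWA", "Car", "Ant", "NWA", "EAt", "IOc", "WPa", "CPa", "EPa")
  n_excl <- 2L
  n_shared <- 16L
  lapply(seq_along(pops), function(i) {
    excl <- paste0("H", (n_excl * (i - 1L) + 1L):(n_excl * i))
    source_pop_spec(pops[i], n_haplotypes = n_excl + n_shared,
                    exclusive_haplotypes = excl,
                    concentration = concentration)
  })
}

#' Simulate a source-by-haplotype baseline
#'
#' Draws true haplotype frequencies for every source from a symmetric
#' Dirichlet restricted to that source's allowed haplotypes, then draws
#' observed baseline counts as one multinomial sample of size
#' `n_per_source` per source. The haplotype catalogue (column set) is fixed
#' by the specs, so a haplotype that happens not to be sampled in the
#' baseline keeps its (all-zero) column: the catalogue is knowledge
#' external to this particular sample, exactly as a literature-derived
#' baseline would be.
#'
#' @param specs List of [source_pop_spec()] objects with pairwise-disjoint
#'   exclusive haplotype sets.
#' @param n_per_source Baseline sample size per source.
#' @param seed Integer seed; identical seeds give identical output.
#' @param theta True mixture contribution vector (recycled into the
#'   returned truth object for downstream [gen_mixture()] calls). Defaults
#'   to equal contributions.
#' @param shared_pool Optional character vector naming the shared haplotype
#'   pool; autogenerated (`"S1"`, `"S2"`, ...) when `NULL`.
#' @return List with class `baseline_sim`: `$counts` (a [baseline_matrix()]),
#'   `$truth` (a `synthetic_truth`: `theta_true`, `q_true`, `seed`).
#' @export
gen_baseline <- function(specs, n_per_source, seed, theta = NULL,
                         shared_pool = NULL) {
  if (inherits(specs, "source_pop_spec")) specs <- list(specs)
  if (length(specs) < 1L) stop("need at least one source spec", call. = FALSE)
  stopifnot_scalar_count(n_per_source, "n_per_source")
  excl_sets <- lapply(specs, `[[`, "exclusive_haplotypes")
  all_excl <- unlist(excl_sets)
  if (anyDuplicated(all_excl)) {
    dup <- unique(all_excl[duplicated(all_excl)])
    stop("exclusive haplotype sets overlap across sources: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  n_needed <- max(vapply(specs, function(s) s$n_haplotypes - length(s$exclusive_haplotypes), 0L))
  if (is.null(shared_pool)) {
    shared_pool <- if (n_needed > 0L) paste0("S", seq_len(n_needed)) else character()
  } else if (length(shared_pool) < n_needed) {
    stop("`shared_pool` too small for the requested n_haplotypes", call. = FALSE)
  }
  if (any(shared_pool %in% all_excl)) {
    stop("`shared_pool` overlaps an exclusive haplotype set", call. = FALSE)
  }
  sources <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(sources)) stop("duplicated source names", call. = FALSE)
  haps <- c(all_excl, shared_pool)
  S <- length(specs); H <- length(haps)

  q_true <- matrix(0, S, H, dimnames = list(sources, haps))
  counts <- matrix(0L, S, H, dimnames = list(sources, haps))
  with_seed(seed, {
    for (i in seq_len(S)) {
      sp <- specs[[i]]
      n_sh <- sp$n_haplotypes - length(sp$exclusive_haplotypes)
      allowed <- c(sp$exclusive_haplotypes, shared_pool[seq_len(n_sh)])
      q_true[i, allowed] <- rdirichlet(rep(sp$concentration, length(allowed)))
      counts[i, ] <- as.integer(stats::rmultinom(1, n_per_source, q_true[i, ]))
    }
  })
  theta <- theta %||% rep(1 / S, S)
  truth <- synthetic_truth(theta, q_true, seed)
  structure(list(counts = baseline_matrix(counts), truth = truth),
            class = "baseline_sim")
}

#' Ground truth for a simulated scenario
#'
#' @param theta_true Source contribution vector (sums to 1).
#' @param q_true Source-by-haplotype frequency matrix (rows sum to 1).
#' @param seed Seed used by the generator that produced this truth.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(theta_true, q_true, seed = NULL) {
  theta_true <- as.numeric(theta_true)
  if (any(theta_true < 0) || abs(sum(theta_true) - 1) > 1e-12) {
    stop("theta_true must be nonnegative and sum to 1 (tol 1e-12)", call. = FALSE)
  }
  q_true <- as.matrix(q_true)
  if (is.null(colnames(q_true))) colnames(q_true) <- paste0("H", seq_len(ncol(q_true)))
  if (is.null(rownames(q_true))) rownames(q_true) <- paste0("src", seq_len(nrow(q_true)))
  if (length(theta_true) != nrow(q_true)) {
    stop("length(theta_true) must equal nrow(q_true)", call. = FALSE)
  }
  if (any(q_true < 0) || any(abs(rowSums(q_true) - 1) > 1e-12)) {
    stop("rows of q_true must be nonnegative and sum to 1 (tol 1e-12)", call. = FALSE)
  }
  structure(list(theta_true = theta_true, q_true = q_true, seed = seed),
            class = "synthetic_truth")
}

#' Simulate a market mixture sample
#'
#' Each of `n` individuals is assigned a source population with
#' probabilities `theta_true`, then a haplotype from that source's true
#' frequency row. This is exactly the data-generating process the
#' mixed-stock model assumes.
#'
#' @param truth A `synthetic_truth` (see [gen_baseline()]).
#' @param n Number of individuals in the mixture.
#' @param seed Integer seed.
#' @return A [mixture_counts()] whose counts sum to `n`.
#' @export
gen_mixture <- function(truth, n, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  stopifnot_scalar_count(n, "n")
  q <- truth$q_true
  x <- with_seed(seed, {
    per_source <- as.integer(stats::rmultinom(1, n, truth$theta_true))
    xx <- integer(ncol(q))
    for (s in seq_len(nrow(q))) {
      if (per_source[s] > 0L) {
        xx <- xx + as.integer(stats::rmultinom(1, per_source[s], q[s, ]))
      }
    }
    xx
  })
  names(x) <- colnames(q)
  mixture_counts(x)
}

#' Generate distinct random haplotype sequences
#'
#' @param n Number of distinct sequences.
#' @param length Sequence length in bp (default 535, the informative mtCR
#'   section used by the market assay).
#' @param seed Integer seed.
#' @return Named character vector (`H1`, `H2`, ...), all pairwise distinct.
#' @export
gen_haplotype_sequences <- function(n, length = 535L, seed = NULL) {
  stopifnot_scalar_count(n, "n")
  stopifnot_scalar_count(length, "length")
  with_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n) {
      need <- n - length(seqs)
      new <- vapply(seq_len(need), function(i) {
        paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
      }, "")
      seqs <- unique(c(seqs, new))
    }
    names(seqs) <- paste0("H", seq_len(n))
    seqs
  })
}

#' Split haplotypes into two overlapping amplicons
#'
#' Emulates the two-fragment amplification strategy used for degraded
#' market DNA: a 5' fragment and a 3' fragment whose concatenation (after
#' removing the duplicated overlap) restores the full-length sequence.
#' With the default lengths 388 and 168 bp on a 535 bp template the
#' implied overlap is 388 + 168 - 535 = 21 bp.
#'
#' @param haplotypes Named character vector of full-length sequences.
#' @param frag_lengths Integer pair: lengths of the 5' and 3' fragments.
#' @param overlap Expected overlap in bp; must satisfy
#'   `sum(frag_lengths) - overlap == nchar(haplotype)` for every input.
#' @param error_rate Per-base substitution probability applied
#'   independently to each fragment (0 = faithful fragments).
#' @param seed Integer seed (only used when `error_rate > 0`).
#' @return List with named character vectors `frag_a` and `frag_b`.
#' @export
gen_amplicon_reads <- function(haplotypes, frag_lengths = c(388L, 168L),
                               overlap = 21L, error_rate = 0, seed = NULL) {
  if (is.null(names(haplotypes)) || !is.character(haplotypes)) {
    stop("`haplotypes` must be a named character vector", call. = FALSE)
  }
  la <- as.integer(frag_lengths[1]); lb <- as.integer(frag_lengths[2])
  overlap <- as.integer(overlap)
  if (overlap < 0L) stop("`overlap` must be >= 0", call. = FALSE)
  lens <- nchar(haplotypes)
  if (any(la > lens) || any(lb > lens)) {
    stop("fragment longer than source sequence", call. = FALSE)
  }
  if (any(la + lb - overlap != lens)) {
    bad <- names(haplotypes)[la + lb - overlap != lens]
    stop("fragment lengths/overlap inconsistent with sequence length for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1) stop("`error_rate` must be in [0, 1)", call. = FALSE)
  frag_a <- substr(haplotypes, 1L, la)
  frag_b <- substr(haplotypes, lens - lb + 1L, lens)
  if (error_rate > 0) {
    mutate <- function(seqs) {
      vapply(seqs, function(s) {
        ch <- seq_chars(s)
        hit <- which(stats::runif(length(ch)) < error_rate)
        for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
        paste(ch, collapse = "")
      }, "", USE.NAMES = TRUE)
    }
    with_seed(seed, {
      frag_a <- mutate(frag_a)
      frag_b <- mutate(frag_b)
    })
  }
  names(frag_a) <- names(frag_b) <- names(haplotypes)
  list(frag_a = frag_a, frag_b = frag_b)
}

#' Survey design parameters
#'
#' Encodes the vendor/bag/trimming design of the Hong Kong retail survey:
#' 10 stocked vendors per sampling event, two bags of trimmings per vendor,
#' 10 trimmings genotyped per bag (20 per vendor visit). Sampling events
#' happen twice a month in `biweekly_years` (up to 20 vendor-visit trials
#' per month) and once a month otherwise (up to 10).
#'
#' @param biweekly_years Years sampled every two weeks (default 2014).
#' @param vendors_per_event Stocked vendors visited per sampling event.
#' @param bags_per_vendor Bags purchased per vendor.
#' @param trimmings_per_bag Trimmings genotyped per bag.
#' @param stocking_prob Probability a planned vendor visit yields stock
#'   (1 = every planned visit happens, giving the design maximum).
#' @return Object of class `survey_design`.
#' @export
survey_design <- function(biweekly_years = 2014L, vendors_per_event = 10L,
                          bags_per_vendor = 2L, trimmings_per_bag = 10L,
                          stocking_prob = 1) {
  stopifnot(stocking_prob >= 0, stocking_prob <= 1)
  structure(list(biweekly_years = as.integer(biweekly_years),
                 vendors_per_event = as.integer(vendors_per_event),
                 bags_per_vendor = as.integer(bags_per_vendor),
                 trimmings_per_bag = as.integer(trimmings_per_bag),
                 stocking_prob = stocking_prob),
            class = "survey_design")
}

#' Simulate a multi-year market survey
#'
#' Generates one row per genotyped trimming. Species labels are drawn
#' independently per trimming from the focal year's composition row, which
#' emulates well-mixed vendor stock; real bags are likely over-dispersed
#' (see the methods vignette).
#'
#' @param years Integer vector of survey years.
#' @param design A [survey_design()].
#' @param species_probs Matrix of per-trimming species probabilities with
#'   one row per year (rownames = year, colnames = species); rows must be
#'   nonnegative and sum to 1.
#' @param seed Integer seed.
#' @return `data.frame` of class `survey_trimmings` with columns `date`,
#'   `year`, `month`, `event_id`, `vendor_id`, `bag_id`, `species`.
#' @export
gen_survey <- function(years, design = survey_design(), species_probs, seed) {
  stopifnot(inherits(design, "survey_design"))
  species_probs <- as.matrix(species_probs)
  if (is.null(rownames(species_probs))) {
    if (nrow(species_probs) != length(years)) {
      stop("`species_probs` needs rownames or one row per year", call. = FALSE)
    }
    rownames(species_probs) <- as.character(years)
  }
  if (any(species_probs < 0)) stop("negative species probabilities", call. = FALSE)
  if (any(abs(rowSums(species_probs) - 1) > 1e-8)) {
    stop("rows of `species_probs` must sum to 1", call. = FALSE)
  }
  missing_years <- setdiff(as.character(years), rownames(species_probs))
  if (length(missing_years)) {
    stop("no composition row for year(s): ", paste(missing_years, collapse = ", "),
         call. = FALSE)
  }
  species <- colnames(species_probs)
  n_trim <- design$bags_per_vendor * design$trimmings_per_bag
  with_seed(seed, {
    out <- vector("list", 0L)
    for (yr in years) {
      p <- species_probs[as.character(yr), ]
      events_pm <- if (yr %in% design$biweekly_years) 2L else 1L
      for (mo in 1:12) {
        for (ev in seq_len(events_pm)) {
          day <- if (events_pm == 2L && ev == 2L) 15L else 1L
          for (v in seq_len(design$vendors_per_event)) {
            if (stats::runif(1) > design$stocking_prob) next
            labels <- sample(species, n_trim, replace = TRUE, prob = p)
            out[[length(out) + 1L]] <- data.frame(
              date = sprintf("%d-%02d-%02d", yr, mo, day),
              year = yr, month = mo,
              event_id = sprintf("%d-%02d-e%d", yr, mo, ev),
              vendor_id = sprintf("%d-%02d-e%d-v%02d", yr, mo, ev, v),
              bag_id = rep(seq_len(design$bags_per_vendor),
                           each = design$trimmings_per_bag),
              species = labels,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    df <- do.call(rbind, out)
    class(df) <- c("survey_trimmings", "data.frame")
    df
  })
}

#' Simulate CITES-style trade records and customs import totals
#'
#' Produces the two ledgers the reconciliation module consumes. Customs
#' totals exist for every nation-year; CITES records are generated only for
#' nations whose profile has `cites_reporting = TRUE`. Deliberately
#' malformed records (unknown quantity, non-wild source, non-commercial
#' purpose) and importer/exporter volume mismatches are injected at the
#' given rates so that filtering and reconciliation logic can be exercised.
#'
#' @param nations `data.frame` of nation profiles (see [table1_profiles()]):
#'   columns `nation`, `mean_annual_kg`, `cites_reporting` are used.
#' @param years Integer vector of ledger years (nonempty).
#' @param seed Integer seed.
#' @param taxa Taxa reported in CITES records.
#' @param mismatch_rate Probability that a record is double-reported with a
#'   discrepant exporter-side volume.
#' @param malformed_rate Probability of attaching one malformed record
#'   (unknown-quantity, source C, or purpose P) per nation-year.
#' @param importer Importing territory (fixed: the trade hub under study).
#' @return List with `trade` (CITES-style records) and `customs`
#'   (`origin_nation`, `year`, `kg`) data frames.
#' @export
gen_trade_ledgers <- function(nations, years, seed, taxa = cop16_species(),
                              mismatch_rate = 0.3, malformed_rate = 0.1,
                              importer = "Hong Kong") {
  if (NROW(nations) == 0L) stop("`nations` must be nonempty", call. = FALSE)
  if (length(years) == 0L) stop("empty year range", call. = FALSE)
  with_seed(seed, {
    customs <- expand.grid(origin_nation = nations$nation, year = years,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- nations$mean_annual_kg[match(customs$origin_nation, nations$nation)]
    customs$kg <- round(mu * stats::rlnorm(nrow(customs), 0, 0.3), 2)
    customs$kg <- pmax(customs$kg, 0.01)

    rec <- list()
    add <- function(exporter, year, taxon, qty, unit = "kg", src = "W",
                    purp = "T", by = "importer", term = "fins") {
      rec[[length(rec) + 1L]] <<- data.frame(
        exporter = exporter, importer = importer, year = year, taxon = taxon,
        term = term, unit = unit, quantity = qty, source_code = src,
        purpose_code = purp, reported_by = by, stringsAsFactors = FALSE)
    }
    reporting <- nations[nations$cites_reporting, , drop = FALSE]
    for (i in seq_len(nrow(reporting))) {
      nat <- reporting$nation[i]
      for (yr in years) {
        k <- sample(length(taxa), 1L)
        for (tx in sample(taxa, k)) {
          qty <- round(stats::rlnorm(1, log(500), 1), 2)
          add(nat, yr, tx, qty)
          if (stats::runif(1) < mismatch_rate) {
            add(nat, yr, tx, round(qty * stats::rlnorm(1, 0, 0.2), 2),
                by = "exporter")
          }
        }
        if (stats::runif(1) < malformed_rate) {
          kind <- sample(c("unknown_quantity", "source_C", "purpose_P"), 1L)
          switch(kind,
            unknown_quantity = add(nat, yr, sample(taxa, 1L),
                                   round(stats::runif(1, 1, 500)), unit = "fins"),
            source_C = add(nat, yr, sample(taxa, 1L),
                           round(stats::rlnorm(1, log(100), 1), 2), src = "C"),
            purpose_P = add(nat, yr, sample(taxa, 1L),
                            round(stats::rlnorm(1, log(100), 1), 2), purp = "P"))
        }
      }
    }
    trade <- if (length(rec)) do.call(rbind, rec) else data.frame(
      exporter = character(), importer = character(), year = integer(),
      taxon = character(), term = character(), unit = character(),
      quantity = numeric(), source_code = character(),
      purpose_code = character(), reported_by = character(),
      stringsAsFactors = FALSE)
    list(trade = trade, customs = customs)
  })
}
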