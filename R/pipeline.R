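#' Default end-to-end scenario configuration
#'
#' The stated world of the default simulation: the nine-source global
#' baseline preset (50 baseline samples per source), two 2019 market
#' strata of 92 fin trimmings and 142 small fins, a market mixture drawn
#' mostly from the Western Pacific, Eastern Pacific and Indian Ocean with
#' smaller Central Pacific, Eastern Atlantic and Southwestern Atlantic
#' contributions (six of nine sources present), the biweekly-2014 /
#' monthly-thereafter survey design with a stable species composition, and
#' 2014-2022 trade ledgers built on the packaged nation table.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param preset `"smoke"` (fast MCMC settings, default) or `"paper"`
#'   (100000 iterations, 50000 burn-in).
#' @return Scenario list consumed by [run_pipeline()].
#' @export
default_scenario <- function(seed = 1L, preset = c("smoke", "paper")) {
  preset <- match.arg(preset)
  msa <- if (preset == "paper") {
    list(n_iter = 100000L, burn_in = 50000L, n_chains = 4L)
  } else {
    list(n_iter = 4000L, burn_in = 2000L, n_chains = 4L)
  }
  list(
    seed = as.integer(seed),
    years = 2014:2021,
    baseline = list(n_per_source = 50L, concentration = 1),
    mixture = list(
      n_trimmings = 92L, n_small_fins = 142L,
      theta = c(SWA = 0.06, Car = 0, Ant = 0, NWA = 0, EAt = 0.07,
                IOc = 0.22, WPa = 0.30, CPa = 0.10, EPa = 0.25)),
    amplicon = list(length = 535L, frag_lengths = c(388L, 168L),
                    overlap = 21L, error_rate = 0),
    survey = list(biweekly_years = 2014L, stocking_prob = 1),
    composition = list(
      "Prionace glauca" = 0.35, "Carcharhinus falciformis" = 0.12,
      "blacktip complex" = 0.08, "Sphyrna lewini" = 0.05,
      "Sphyrna zygaena" = 0.03, "Sphyrna mokarran" = 0.02,
      "Carcharhinus longimanus" = 0.007, "Lamna nasus" = 0.004,
      unidentified = 0.02),
    msa = c(msa, list(alpha_q = 1, detection_floor = 0.01,
                      reporting_sources = c("WPa", "IOc", "EPa"))),
    structure = list(n_permutations = 199L, seqs_per_pop = 20L,
                     alpha = 0.05),
    trend = list(alpha = 0.05, window = NULL),
    trade = list(years = 2014:2022, mismatch_rate = 0.3,
                 malformed_rate = 0.1))
}

# Per-year composition matrix from the scenario's stable composition; the
# remainder is assigned to a pooled "other" category.
scenario_composition <- function(cfg) {
  base <- unlist(cfg$composition)
  if (sum(base) > 1) stop("scenario composition exceeds 1", call. = FALSE)
  probs <- c(base, other = 1 - sum(base))
  m <- matrix(rep(probs, each = length(cfg$years)), nrow = length(cfg$years),
              dimnames = list(as.character(cfg$years), names(probs)))
  m
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full surveillance pipeline on a scenario
#'
#' Executes simulate, haplotype, structure, msa, trends and reconcile in
#' order, writing per-stage outputs and a `manifest.json` (settings echo,
#' seeds, per-stage row counts and exclusion tallies) into `out_dir`.
#' Reruns with the same scenario are reproducible: all randomness derives
#' from `config$seed`.
#'
#' @param config Scenario list from [default_scenario()] or
#'   [read_scenario()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (in pipeline order).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_scenario(), out_dir,
                         stages = c("simulate", "haplotype", "structure",
                                    "msa", "trends", "reconcile")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package = "finmix",
                   version = as.character(utils::packageVersion("finmix")),
                   r_version = R.version.string,
                   seed = seed, config = config, stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- c(list(status = "completed"), list(...))
  }
  p <- function(...) file.path(out_dir, ...)
  env <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) run_stage("simulate", {
    specs <- default_source_specs(config$baseline$concentration)
    env$bl <- gen_baseline(specs, config$baseline$n_per_source, seed,
                           theta = config$mixture$theta)
    env$mix_trim <- gen_mixture(env$bl$truth, config$mixture$n_trimmings, seed + 1L)
    env$mix_fins <- gen_mixture(env$bl$truth, config$mixture$n_small_fins, seed + 2L)
    env$haps <- gen_haplotype_sequences(ncol(env$bl$counts),
                                        config$amplicon$length, seed + 3L)
    names(env$haps) <- colnames(env$bl$counts)
    env$amps <- gen_amplicon_reads(env$haps, config$amplicon$frag_lengths,
                                   config$amplicon$overlap,
                                   config$amplicon$error_rate, seed + 6L)
    env$survey <- gen_survey(config$years,
                             survey_design(biweekly_years = config$survey$biweekly_years,
                                           stocking_prob = config$survey$stocking_prob),
                             scenario_composition(config), seed + 4L)
    env$profiles <- table1_profiles()
    env$ledgers <- gen_trade_ledgers(env$profiles, config$trade$years, seed + 5L,
                                     mismatch_rate = config$trade$mismatch_rate,
                                     malformed_rate = config$trade$malformed_rate)
    write_baseline_csv(env$bl$counts, p("baseline.csv"))
    write_mixture_csv(env$mix_trim, p("mixture_trimmings.csv"))
    write_mixture_csv(env$mix_fins, p("mixture_smallfins.csv"))
    write_fasta_seqs(env$haps, p("haplotypes.fasta"))
    write_fasta_seqs(env$amps$frag_a, p("frag_a.fasta"))
    write_fasta_seqs(env$amps$frag_b, p("frag_b.fasta"))
    utils::write.csv(env$survey, p("survey.csv"), row.names = FALSE)
    utils::write.csv(env$ledgers$trade, p("cites_trade.csv"), row.names = FALSE)
    utils::write.csv(env$ledgers$customs, p("customs.csv"), row.names = FALSE)
    note("simulate",
         n_baseline = sum(env$bl$counts),
         n_trimmings = sum(env$mix_trim), n_small_fins = sum(env$mix_fins),
         n_survey_trimmings = nrow(env$survey),
         n_trade_records = nrow(env$ledgers$trade),
         n_customs_records = nrow(env$ledgers$customs))
  })

  if ("haplotype" %in% stages) run_stage("haplotype", {
    merged <- vapply(names(env$haps), function(id) {
      merge_amplicons(env$amps$frag_a[[id]], env$amps$frag_b[[id]],
                      config$amplicon$length)
    }, "")
    baseline_tab <- define_haplotypes(merged)
    baseline_tab$haplotype_id <- names(env$haps)  # catalogue IDs
    # push every mixture record through assignment against the catalogue
    recs <- rep(names(env$mix_trim), as.integer(env$mix_trim))
    calls <- vapply(recs, function(h) {
      assign_to_baseline(merged[[h]], stats::setNames(baseline_tab$sequence,
                                                      baseline_tab$haplotype_id))
    }, "", USE.NAMES = FALSE)
    env$assigned <- calls
    utils::write.csv(baseline_tab, p("haplotype_table.csv"), row.names = FALSE)
    note("haplotype",
         n_records = length(calls),
         n_assigned = sum(!calls %in% c("NOVEL", "unresolvable")),
         n_novel = sum(calls == "NOVEL"),
         n_unresolvable = sum(calls == "unresolvable"),
         recovery_rate = mean(calls == recs))
  })

  if ("structure" %in% stages) run_stage("structure", {
    q <- env$bl$truth$q_true
    draw_pop <- function(src, n, s) {
      with_seed(s, {
        ids <- sample(colnames(q), n, replace = TRUE, prob = q[src, ])
        unname(env$haps[ids])
      })
    }
    npp <- config$structure$seqs_per_pop
    pops <- rownames(q)[1:3]
    baseline_pops <- stats::setNames(
      lapply(seq_along(pops), function(i) draw_pop(pops[i], npp, seed + 10L + i)),
      pops)
    candidate <- draw_pop(pops[1], npp, seed + 20L)
    env$delimit <- delimit_population(candidate, baseline_pops,
                                      alpha = config$structure$alpha,
                                      n_permutations = config$structure$n_permutations,
                                      seed = seed + 21L)
    utils::write.csv(env$delimit$tests, p("structure_tests.csv"), row.names = FALSE)
    note("structure", decision = env$delimit$decision,
         merged_with = env$delimit$merged_with,
         n_tests = nrow(env$delimit$tests))
  })

  if ("msa" %in% stages) run_stage("msa", {
    run_one <- function(mix, s) {
      msa_gibbs(env$bl$counts, mix, n_iter = config$msa$n_iter,
                burn_in = config$msa$burn_in, n_chains = config$msa$n_chains,
                seed = s, alpha_q = config$msa$alpha_q)
    }
    env$msa_trim <- run_one(env$mix_trim, seed + 30L)
    env$msa_fins <- run_one(env$mix_fins, seed + 31L)
    summ <- function(post) {
      rep_tab <- summarize_contributions(post, config$msa$reporting_sources,
                                         detection_floor = config$msa$detection_floor %||% 0)
      cbind(rep_tab$table, rhat = as.numeric(post$psrf))
    }
    utils::write.csv(summ(env$msa_trim), p("msa_trimmings.csv"), row.names = FALSE)
    utils::write.csv(summ(env$msa_fins), p("msa_smallfins.csv"), row.names = FALSE)
    note("msa",
         max_rhat_trimmings = max(env$msa_trim$psrf),
         max_rhat_smallfins = max(env$msa_fins$psrf),
         converged = isTRUE(env$msa_trim$converged) && isTRUE(env$msa_fins$converged),
         n_excluded = env$msa_trim$n_excluded + env$msa_fins$n_excluded)
  })

  if ("trends" %in% stages) run_stage("trends", {
    fits <- list()
    for (sp in cop16_species()) {
      series <- compute_incidence(env$survey, sp)
      fit <- tryCatch(fit_trend(series, alpha = config$trend$alpha,
                                window = config$trend$window),
                      error = function(e) NULL)
      fits[[sp]] <- if (is.null(fit)) {
        data.frame(species = sp, beta1 = NA, se_beta1 = NA, p_wald = NA,
                   significant = NA, note = "trend undefined")
      } else {
        data.frame(species = sp, beta1 = fit$beta1, se_beta1 = fit$se_beta1,
                   p_wald = fit$p_wald, significant = fit$significant,
                   note = if (fit$separation) "separation" else "")
      }
    }
    trends <- do.call(rbind, fits)
    rownames(trends) <- NULL
    contrib <- proportional_contribution(env$survey, cop16_species())
    utils::write.csv(trends, p("trends.csv"), row.names = FALSE)
    utils::write.csv(contrib, p("contributions.csv"), row.names = FALSE)
    env$trends <- trends
    note("trends", n_species = nrow(trends),
         n_significant = sum(trends$significant, na.rm = TRUE))
  })

  if ("reconcile" %in% stages) run_stage("reconcile", {
    filt <- filter_records(env$ledgers$trade)
    recon <- reconcile_partner_reports(filt$kept)
    shares <- legal_share(recon, env$ledgers$customs)
    flags <- flag_nations(env$profiles)
    utils::write.csv(shares, p("legal_share.csv"), row.names = FALSE)
    utils::write.csv(flags$profiles, p("nation_flags.csv"), row.names = FALSE)
    jsonlite::write_json(flags$summary, p("nation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("reconcile", n_input = nrow(env$ledgers$trade),
         n_kept = nrow(filt$kept), n_excluded = nrow(filt$excluded),
         n_reconciled = nrow(recon), n_years = nrow(shares),
         n_flagged = flags$summary$n_flagged)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

# --- command-line interface -------------------------------------------------

parse_cli_opts <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_int <- function(x, default) if (is.null(x)) default else as.integer(x)
cli_num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line entry point
#'
#' Dispatches the `finmix` subcommands (`run`, `simulate`, `haplotype`,
#' `structure`, `msa`, `trends`, `reconcile`). The installed wrapper
#' script `inst/cli/finmix` forwards `commandArgs(trailingOnly = TRUE)`
#' here; tests call this function directly.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
finmix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: finmix <run|simulate|haplotype|structure|msa|trends|reconcile> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  parsed <- parse_cli_opts(args[-1])
  o <- parsed$opts; pos <- parsed$pos
  out <- o$out %||% "finmix_out"
  switch(cmd,
    run = ,
    simulate = {
      cfg <- if (length(pos)) read_scenario(pos[1]) else default_scenario()
      if (!is.null(o$seed)) cfg$seed <- as.integer(o$seed)
      stages <- if (cmd == "simulate") "simulate" else
        c("simulate", "haplotype", "structure", "msa", "trends", "reconcile")
      man <- run_pipeline(cfg, out, stages = stages)
      cat(sprintf("completed %d stage(s) -> %s\n", length(man$stages), out))
    },
    haplotype = {
      fa <- read_fasta_seqs(o$frag_a); fb <- read_fasta_seqs(o$frag_b)
      len <- cli_int(o$expected_length, 535L)
      merged <- vapply(names(fa), function(id) merge_amplicons(fa[[id]], fb[[id]], len), "")
      tab <- define_haplotypes(merged)
      if (!is.null(o$baseline)) {
        base <- utils::read.csv(o$baseline, stringsAsFactors = FALSE)
        tab$assignment <- vapply(tab$sequence, function(s) {
          assign_to_baseline(s, stats::setNames(base$sequence, base$haplotype_id))
        }, "", USE.NAMES = FALSE)
      }
      utils::write.csv(tab, file.path(out), row.names = FALSE)
      cat(sprintf("%d record(s), %d haplotype(s) -> %s\n",
                  attr(tab, "total"), nrow(tab), out))
    },
    structure = {
      cand <- read_fasta_seqs(o$candidate)
      man <- utils::read.csv(o$baseline, stringsAsFactors = FALSE)
      pops <- stats::setNames(lapply(man$fasta, read_fasta_seqs), man$population)
      res <- delimit_population(cand, pops,
                                n_permutations = cli_int(o$perms, 999L),
                                seed = cli_int(o$seed, NULL))
      utils::write.csv(res$tests, out, row.names = FALSE)
      print(res)
    },
    msa = {
      base <- read_baseline_csv(o$baseline)
      mix <- read_mixture_csv(o$mixture)
      post <- msa_gibbs(base, mix,
                        n_iter = cli_int(o$iters, 100000L),
                        burn_in = cli_int(o$burnin, 50000L),
                        n_chains = cli_int(o$chains, 4L),
                        seed = cli_int(o$seed, NULL))
      tab <- data.frame(source = names(post$point), mean = as.numeric(post$point),
                        lo95 = post$ci95[, "lo"], hi95 = post$ci95[, "hi"],
                        rhat = as.numeric(post$psrf))
      utils::write.csv(tab, out, row.names = FALSE)
      print(post)
    },
    trends = {
      events <- utils::read.csv(o$events, stringsAsFactors = FALSE)
      series <- compute_incidence(events, o$species)
      fit <- fit_trend(series, alpha = cli_num(o$alpha, 0.05))
      utils::write.csv(fit$fitted, out, row.names = FALSE)
      print(fit)
    },
    reconcile = {
      trade <- utils::read.csv(o$cites, stringsAsFactors = FALSE)
      customs <- utils::read.csv(o$customs, stringsAsFactors = FALSE)
      profiles <- if (!is.null(o$profiles)) {
        utils::read.csv(o$profiles, stringsAsFactors = FALSE)
      } else table1_profiles()
      filt <- filter_records(trade)
      recon <- reconcile_partner_reports(filt$kept)
      shares <- legal_share(recon, customs)
      flags <- flag_nations(profiles)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(shares, file.path(out, "legal_share.csv"), row.names = FALSE)
      utils::write.csv(flags$profiles, file.path(out, "nation_flags.csv"),
                       row.names = FALSE)
      print(flags)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
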