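#' Filter CITES-style trade records to analyzable fin trade
#'
#' A record is kept only when it is a fin record of known quantity (unit =
#' kg) from wild-caught specimens (source = W) traded commercially
#' (purpose = T). Every excluded record carries a machine-readable reason;
#' filtering never throws and partitions its input exactly.
#'
#' @param records `data.frame` of trade records with columns `term`,
#'   `unit`, `quantity`, `source_code`, `purpose_code` (see
#'   [gen_trade_ledgers()] for the full schema).
#' @return List with `kept` (records) and `excluded` (records plus a
#'   `reason` column; multiple reasons are semicolon-joined).
#' @export
filter_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("term", "unit", "quantity", "source_code", "purpose_code")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  reasons <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    why <- character()
    if (!identical(r$term, "fins")) why <- c(why, "non-fin term")
    if (!identical(r$unit, "kg") || is.na(r$quantity) || r$quantity <= 0) {
      why <- c(why, "unknown quantity")
    }
    if (!identical(r$source_code, "W")) why <- c(why, "non-wild source")
    if (!identical(r$purpose_code, "T")) why <- c(why, "non-commercial purpose")
    paste(why, collapse = ";")
  }, "")
  keep <- !nzchar(reasons)
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reasons[!keep] else excluded$reason <- character(0)
  list(kept = records[keep, , drop = FALSE], excluded = excluded)
}

#' Reconcile importer- and exporter-reported volumes
#'
#' CITES trade is double-reported; partner volumes frequently disagree.
#' Within each (exporter, importer, year, taxon) key the quantities are
#' first summed per reporting side, then the larger side's total is kept
#' (the conservative "highest reported volume by any trade partner" rule).
#' Keys reported by a single side pass through unchanged. The operation is
#' idempotent.
#'
#' @param records Filtered trade records (see [filter_records()]).
#' @return `data.frame` with one record per key; `reported_by` names the
#'   side whose total was kept (`"importer"` on ties).
#' @export
reconcile_partner_reports <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) return(records)
  key <- interaction(records$exporter, records$importer, records$year,
                     records$taxon, drop = TRUE, sep = "\r")
  pieces <- lapply(split(records, key), function(grp) {
    per_side <- tapply(grp$quantity, grp$reported_by, sum)
    win <- names(per_side)[which.max(per_side)]
    if (length(per_side) > 1L && length(unique(per_side)) == 1L &&
        "importer" %in% names(per_side)) {
      win <- "importer"
    }
    out <- grp[1L, , drop = FALSE]
    out$quantity <- unname(max(per_side))
    out$reported_by <- win
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$exporter, out$year, out$taxon), , drop = FALSE]
}

#' Legal share of fin imports per year
#'
#' Reported (and therefore legal) imports of the focal species, as a
#' fraction of the hub's total fin imports from customs records, per year.
#'
#' @param cites Reconciled trade records ([reconcile_partner_reports()]).
#' @param customs `data.frame` of customs totals: `origin_nation`, `year`,
#'   `kg`.
#' @return `data.frame` of class `legal_share_series`: `year`, `v_cites`
#'   (kg), `v_total` (kg), `share` (fraction), `percent`; years with zero
#'   or missing customs volume have `NA` share.
#' @export
legal_share <- function(cites, customs) {
  customs <- as.data.frame(customs)
  cites <- as.data.frame(cites)
  years <- sort(unique(customs$year))
  if (!length(years)) stop("customs ledger is empty", call. = FALSE)
  v_total <- vapply(years, function(y) sum(customs$kg[customs$year == y]), 0)
  v_cites <- vapply(years, function(y) {
    if (nrow(cites)) sum(cites$quantity[cites$year == y]) else 0
  }, 0)
  share <- ifelse(v_total > 0, v_cites / v_total, NA_real_)
  out <- data.frame(year = years, v_cites = v_cites, v_total = v_total,
                    share = share, percent = 100 * share)
  class(out) <- c("legal_share_series", "data.frame")
  out
}

#' Ratio of market presence to reported trade share
#'
#' The headline disparity statistic: how many times larger a species'
#' share of sampled market trimmings is than its share of reported
#' (legal) imports. Both arguments must be on the same scale (both
#' fractions or both percentages).
#'
#' @param market_share Species share of identified market trimmings.
#' @param reported_share Species share of total imports from CITES
#'   records.
#' @return A single ratio (e.g. 0.7% vs 0.01% gives 70).
#' @export
market_disparity_ratio <- function(market_share, reported_share) {
  if (reported_share <= 0) stop("reported share must be positive", call. = FALSE)
  market_share / reported_share
}

#' Load the packaged nation-profile table
#'
#' Transcription of the printed summary of the 90 nations exporting shark
#' fins to Hong Kong 2014-2022: mean annual export volume, CoP16
#' range-state count, FAO/RFMO catch reporting, implication in Hong Kong
#' fin seizures, and whether any CoP16 trade was reported to CITES. The
#' `bolded_in_print` column records the typography of the printed table,
#' which deviates from the stated flagging rule for two nations (see the
#' methods vignette); [flag_nations()] applies the stated rule.
#'
#' @return `data.frame` with 90 rows.
#' @export
table1_profiles <- function() {
  path <- system.file("extdata", "table1_nations.csv", package = "finmix",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Canonicalize nation names
#'
#' Maps common alternative spellings onto the canonical names used by the
#' packaged nation table; matching after canonicalization is exact.
#'
#' @param x Character vector of nation names.
#' @param aliases Optional two-column data frame (`alias`, `canonical`);
#'   defaults to the packaged table.
#' @return Character vector of canonical names.
#' @export
canonicalize_nations <- function(x, aliases = NULL) {
  if (is.null(aliases)) {
    path <- system.file("extdata", "nation_aliases.csv", package = "finmix",
                        mustWork = TRUE)
    aliases <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  i <- match(x, aliases$alias)
  ifelse(is.na(i), x, aliases$canonical[i])
}

#' Flag nations likely involved in unreported fin trade
#'
#' Applies the three-part rule: a nation is flagged when it (1) exports
#' unidentified fins to the hub (true of every profiled nation), (2) is
#' known to catch CoP16 species (FAO/RFMO catch reports) and/or has been
#' implicated through border seizures, and (3) reported no CoP16 trade to
#' CITES. Also returns the headline summary counts.
#'
#' @param profiles `data.frame` of nation profiles with columns `nation`,
#'   `range_state_count`, `fao_rfmo_catch`, `seizure_implicated`,
#'   `cites_reporting` (see [table1_profiles()]).
#' @return List of class `nation_flags`: `profiles` (input plus `flagged`
#'   column) and `summary` with `n_total`, `n_reporting`,
#'   `n_nonreporting`, `pct_nonreporting`,
#'   `n_nonreporting_seizure_implicated`, `n_catch_but_no_export`,
#'   `n_flagged`.
#' @export
flag_nations <- function(profiles) {
  profiles <- as.data.frame(profiles)
  if (!nrow(profiles)) stop("`profiles` must be nonempty", call. = FALSE)
  need <- c("nation", "range_state_count", "fao_rfmo_catch",
            "seizure_implicated", "cites_reporting")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(profiles$nation)) {
    stop("duplicate nation names: ",
         paste(unique(profiles$nation[duplicated(profiles$nation)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(profiles$range_state_count < 0 | profiles$range_state_count > 5)) {
    stop("range_state_count must be in [0, 5]", call. = FALSE)
  }
  profiles$flagged <- (profiles$fao_rfmo_catch | profiles$seizure_implicated) &
    !profiles$cites_reporting
  nonrep <- !profiles$cites_reporting
  summary <- list(
    n_total = nrow(profiles),
    n_reporting = sum(profiles$cites_reporting),
    n_nonreporting = sum(nonrep),
    pct_nonreporting = 100 * mean(nonrep),
    n_nonreporting_seizure_implicated = sum(nonrep & profiles$seizure_implicated),
    n_catch_but_no_export = sum(profiles$fao_rfmo_catch & nonrep),
    n_flagged = sum(profiles$flagged))
  structure(list(profiles = profiles, summary = summary),
            class = "nation_flags")
}

#' @export
print.nation_flags <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d fin-exporting nations: %d reported CoP16 trade, %d (%.1f%%) did not\n",
              s$n_total, s$n_reporting, s$n_nonreporting, s$pct_nonreporting))
  cat(sprintf("non-reporters implicated in seizures: %d; catch reported but no export: %d; flagged by rule: %d\n",
              s$n_nonreporting_seizure_implicated, s$n_catch_but_no_export,
              s$n_flagged))
  invisible(x)
}
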