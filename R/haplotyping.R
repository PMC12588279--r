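# Wildcard-aware base agreement: N is compatible with anything.
bases_agree <- function(a, b) a == b | a == "N" | b == "N"

#' Merge two overlapping amplicons into a full-length sequence
#'
#' The degraded-DNA assay amplifies a 5' and a 3' fragment whose union
#' covers the informative mtCR section; their concatenation minus the
#' duplicated overlap restores the full-length sequence (388 + 168 bp
#' fragments with a 21 bp overlap give 535 bp). The implied overlap
#' `k = nchar(a) + nchar(b) - expected_length` must agree base-for-base
#' between the suffix of `frag_a` and the prefix of `frag_b`; an `N` on one
#' side is resolved toward the concrete base on the other, while two
#' different concrete bases are a chimera error.
#'
#' @param frag_a 5' fragment (character string, or named length-1 vector).
#' @param frag_b 3' fragment.
#' @param expected_length Target merged length in bp.
#' @return Merged sequence string of exactly `expected_length` characters.
#' @examples
#' merge_amplicons("ACGT", "GTTT", 6)  # "ACGTTT"
#' @export
merge_amplicons <- function(frag_a, frag_b, expected_length) {
  a <- toupper(as.character(frag_a)[1]); b <- toupper(as.character(frag_b)[1])
  if (!nzchar(a) || !nzchar(b)) stop("fragments must be non-empty", call. = FALSE)
  la <- nchar(a); lb <- nchar(b)
  k <- la + lb - as.integer(expected_length)
  if (k < 0L) {
    stop(sprintf("fragments too short: |a| + |b| = %d < expected_length %d",
                 la + lb, expected_length), call. = FALSE)
  }
  if (k > min(la, lb)) {
    stop(sprintf("implied overlap %d bp exceeds a fragment length", k), call. = FALSE)
  }
  if (k == 0L) return(paste0(a, b))
  ov_a <- seq_chars(substr(a, la - k + 1L, la))
  ov_b <- seq_chars(substr(b, 1L, k))
  ok <- bases_agree(ov_a, ov_b)
  if (!all(ok)) {
    pos <- (la - k + which(!ok))  # 1-based positions in the merged sequence
    stop(sprintf(
      "overlap disagreement (possible chimera) at merged position(s) %s: %s vs %s",
      paste(pos, collapse = ", "),
      paste(ov_a[!ok], collapse = ""), paste(ov_b[!ok], collapse = "")),
      call. = FALSE)
  }
  consensus <- ifelse(ov_a == "N", ov_b, ov_a)
  paste0(substr(a, 1L, la - k), paste(consensus, collapse = ""),
         substr(b, k + 1L, lb))
}

#' Tabulate haplotypes from equal-length sequences
#'
#' A haplotype is a distinct sequence string; counts partition the input.
#' IDs are assigned in first-occurrence order, so the table is reproducible
#' from the input ordering while haplotype frequencies are
#' order-invariant.
#'
#' @param seqs Character vector of equal-length sequences (names optional).
#' @param prefix ID prefix (default `"H"`).
#' @return `data.frame` of class `haplotype_table` with columns
#'   `haplotype_id`, `sequence`, `count`; attribute `total` holds the input
#'   size.
#' @export
define_haplotypes <- function(seqs, prefix = "H") {
  seqs <- toupper(as.character(seqs))
  if (length(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != stats::median(lens))
      stop("sequences differ in length; offending record(s): ",
           paste(sprintf("#%d (%d bp)", bad, lens[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  uniq <- unique(seqs)
  tab <- data.frame(
    haplotype_id = if (length(uniq)) paste0(prefix, seq_along(uniq)) else character(),
    sequence = uniq,
    count = as.integer(tabulate(match(seqs, uniq), nbins = length(uniq))),
    stringsAsFactors = FALSE)
  attr(tab, "total") <- length(seqs)
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

#' Assign a market sequence to a baseline haplotype
#'
#' Assignment is exact string matching with `N` treated as a wildcard on
#' either side. A sequence matching exactly one baseline haplotype gets
#' that ID; a sequence whose wildcards leave several baseline haplotypes
#' compatible, or one that differs from every baseline haplotype at a
#' resolved position, is returned as `"NOVEL"` (conservative: only
#' unambiguous matches enter the mixed-stock analysis). Sequences with more
#' than `max_ambiguous` `N` bases are `"unresolvable"` and should be
#' excluded downstream with a logged count.
#'
#' @param seq Query sequence (same length as the baseline haplotypes).
#' @param baseline A [define_haplotypes()] table, or a character vector of
#'   sequences named by haplotype ID.
#' @param max_ambiguous Maximum tolerated number of `N` bases in the query.
#' @return A single string: the haplotype ID, `"NOVEL"`, or
#'   `"unresolvable"`.
#' @export
assign_to_baseline <- function(seq, baseline, max_ambiguous = 5L) {
  if (inherits(baseline, "haplotype_table")) {
    refs <- baseline$sequence
    ids <- baseline$haplotype_id
  } else {
    refs <- as.character(baseline)
    ids <- names(baseline) %||% paste0("H", seq_along(refs))
  }
  q <- toupper(as.character(seq)[1])
  if (!length(refs)) return("NOVEL")
  if (nchar(q) != nchar(refs[1])) {
    stop(sprintf("query length %d != baseline length %d (trim first)",
                 nchar(q), nchar(refs[1])), call. = FALSE)
  }
  qc <- seq_chars(q)
  if (sum(qc == "N") > max_ambiguous) return("unresolvable")
  hits <- vapply(refs, function(r) all(bases_agree(qc, seq_chars(r))), TRUE,
                 USE.NAMES = FALSE)
  if (sum(hits) == 1L) ids[hits] else "NOVEL"
}

#' Trim a longer sequence to baseline coordinates
#'
#' Anchored, gap-free alignment of the baseline reference inside a longer
#' query: the offset minimizing the number of resolved-base mismatches is
#' chosen and the corresponding window returned. Ties go to the leftmost
#' offset.
#'
#' @param seq Query sequence, at least as long as `reference`.
#' @param reference Baseline-length reference haplotype.
#' @return Substring of `seq` with `nchar(reference)` characters.
#' @export
trim_to_baseline <- function(seq, reference) {
  q <- toupper(as.character(seq)[1]); r <- toupper(as.character(reference)[1])
  lq <- nchar(q); lr <- nchar(r)
  if (lq < lr) stop("query shorter than reference", call. = FALSE)
  rc <- seq_chars(r)
  best_off <- 0L; best_mm <- lr + 1L
  for (off in 0:(lq - lr)) {
    wc <- seq_chars(substr(q, off + 1L, off + lr))
    mm <- sum(!bases_agree(wc, rc))
    if (mm < best_mm) { best_mm <- mm; best_off <- off }
  }
  substr(q, best_off + 1L, best_off + lr)
}
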