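#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_seqs <- function(path) {
  dna <- ape::read.FASTA(path)
  vapply(as.character(dna), function(ch) toupper(paste(ch, collapse = "")), "")
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  mat <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  ape::write.FASTA(ape::as.DNAbin(mat), path)
  invisible(path)
}

#' Read a baseline counts matrix from CSV
#'
#' Expected layout: first column `source`, remaining columns one per
#' haplotype ID.
#'
#' @param path CSV path.
#' @return A [baseline_matrix()].
#' @export
read_baseline_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  baseline_matrix(m)
}

#' Write a baseline counts matrix to CSV
#' @param baseline A [baseline_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baseline_csv <- function(baseline, path) {
  df <- data.frame(source = rownames(baseline),
                   as.data.frame(unclass(baseline), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read mixture haplotype counts from CSV (`haplotype,count`)
#' @param path CSV path.
#' @return A [mixture_counts()].
#' @export
read_mixture_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mixture_counts(stats::setNames(df$count, df$haplotype))
}

#' Write mixture haplotype counts to CSV
#' @param mixture A [mixture_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_csv <- function(mixture, path) {
  utils::write.csv(data.frame(haplotype = names(mixture),
                              count = as.integer(mixture)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline scenario configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`) by extension.
#'
#' @param path Config file path.
#' @return Scenario list (see [default_scenario()]).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported scenario format: .", ext, call. = FALSE))
  utils::modifyList(default_scenario(), cfg)
}
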