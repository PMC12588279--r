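#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Dirichlet sampler via normalized gammas. Rows of `alpha` (matrix) give
# independent draws; a vector gives a single draw.
rdirichlet <- function(alpha) {
  if (is.matrix(alpha)) {
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
    g / rowSums(g)
  } else {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
}

# Split a sequence string into a character vector of bases.
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

# Local RNG scope: run `expr` under `seed` without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
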