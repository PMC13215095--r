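#' @importFrom rlang .data abort warn inform %||% :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Derive a stage-specific RNG seed from a single root seed so that every
# stochastic stage of a run is independently reseedable and reproducible.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    simulate = 11L, gene_sets = 23L, autofs = 37L, search = 41L,
    gsea = 53L, repeat_run = 67L, permutation = 79L, benchmark = 97L
  )
  off <- offsets[[stage]]
  if (is.null(off)) abort(paste0("unknown seed stage '", stage, "'"))
  as.integer((as.numeric(seed) * 1103L + off * 8191L + index * 131L) %%
               2147483629)
}

# Positive part / finite check helpers used across modules.
is_finite_matrix <- function(x) is.numeric(x) && all(is.finite(x))

# Stable lexicographic ordering independent of the session locale.
lex_order <- function(x) order(x, method = "radix")

vapply_dbl <- function(x, f, ...) vapply(x, f, numeric(1), ...)
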