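# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (all user-facing determinism contracts route through this).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed stream: n distinct seeds < 2^31 derived from `seed`.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Normalized 1-d Gaussian kernel of odd length `size`.
gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  t <- seq_len(size) - (size + 1) / 2
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a matrix with mirrored edges.
gaussian_smooth <- function(x, sigma, size = NULL) {
  if (sigma <= 0) return(x)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  cpp_sepfilter2(x, gaussian_kernel(size, sigma), "same_reflect")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
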