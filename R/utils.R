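# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL consumes the current stream instead.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Dirichlet draws via normalized gammas; rows are samples.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# Row-wise means and unbiased variances over a column subset.
rowGroupStats <- function(m, idx) {
  n <- length(idx)
  x <- m[, idx, drop = FALSE]
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  list(mean = mu, var = v, n = n)
}
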