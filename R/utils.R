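# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards so pipeline stages do not perturb each other.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Two-sample Kolmogorov-Smirnov sup statistics, handling ties.
# Returns c(D = two-sided sup |F1 - F2|, Dplus = sup (F1 - F2)).
ksStatistics <- function(x, y) {
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= nx, 1 / nx, -1 / ny))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)   # evaluate CDF gap at distinct values only
  z <- z[keep]
  c(D = max(abs(z)), Dplus = max(z))
}

# Asymptotic two-sided KS p-value (Kolmogorov distribution tail).
ksPValueAsymptotic <- function(D, nx, ny) {
  neff <- nx * ny / (nx + ny)
  lambda <- sqrt(neff) * D
  if (lambda < 1e-10) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

# One-sided asymptotic p-value for Dplus (Smirnov tail).
ksPValueOneSided <- function(Dplus, nx, ny) {
  neff <- nx * ny / (nx + ny)
  min(1, max(0, exp(-2 * neff * Dplus^2)))
}

# Euclidean k-nearest neighbours with deterministic ascending-index
# tie-breaking. Exact search over the full distance matrix; fine for the
# atlas scales this package targets (thousands of cells).
knnIndices <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  t(vapply(seq_len(n), function(i) {
    order(d[i, ], seq_len(n))[seq_len(k)]   # ties broken by ascending index
  }, integer(k)))
}

# Consistent stop() with a short context tag.
atlasStop <- function(context, ...) {
  stop(sprintf("[%s] %s", context, paste0(...)), call. = FALSE)
}

atlasWarn <- function(context, ...) {
  warning(sprintf("[%s] %s", context, paste0(...)), call. = FALSE)
}
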