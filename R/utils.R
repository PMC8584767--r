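# Internal helpers shared across modules.

# Empirical quantile rule used everywhere a percentile threshold appears
# (calendar-day thresholds, wet-day 99th percentile, quartile deprivation
# cutoffs). Linear interpolation (type 7); a single place to change it.
.ecvi_quantile_type <- 7L

ecvi_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, na.rm = TRUE,
                  type = .ecvi_quantile_type)
}

# Rank-based n-tile assignment with a stable tie-break on a secondary key.
# Returns integer categories 1..n_categories. Invariant under strictly
# monotone transforms of `x` because only ranks are used.
rank_ntile <- function(x, n_categories, tie_key = seq_along(x)) {
  ord <- order(x, tie_key)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  as.integer(ceiling(r * n_categories / length(x)))
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results below .Machine$integer.max and stable across platforms.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483563) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Dirichlet sampler via normalized gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard exact zeros from tiny shapes so log-densities stay finite
  x <- pmax(x, 1e-300)
  x / rowSums(x)
}

ddirichlet_log <- function(g, alpha) {
  # g: matrix with rows on the simplex; alpha: length-K vector
  g <- pmax(g, 1e-12)
  nrow(g) * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum(sweep(log(g), 2L, alpha - 1, `*`))
}

# All permutations of 1..k (k small; used for label alignment).
permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
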