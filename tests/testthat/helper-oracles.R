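# Independent oracles used to check the implementation. These deliberately
# use direct enumeration / naive formulas rather than the package's code
# paths.

# Exact two-sample KS p-value by exhausting every assignment of the pooled
# observations to the two groups (permutation distribution, ties included).
oracle_ks_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  ks_D <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(q) mean(x <= q) - mean(y <= q), numeric(1))))
  }
  D_obs <- ks_D(a, b)
  combos <- utils::combn(na + nb, na)
  Ds <- apply(combos, 2, function(ix) ks_D(pooled[ix], pooled[-ix]))
  list(D = D_obs, p = mean(Ds >= D_obs - 1e-12))
}

# Exact outcome distribution of the sequential replication chain by
# depth-first enumeration of every stopping path.
oracle_replicate_enum <- function(x, N0, K, tol = 1e-14) {
  if (x == 0) return(c(`0` = 1))
  p_rep <- function(n) 1 / (1 + (n / N0)^K)
  out <- new.env()
  recurse <- function(n, prob) {
    if (prob < tol) {
      key <- as.character(n)
      out[[key]] <- (out[[key]] %||% 0) + prob  # dump the residual tail here
      return()
    }
    p <- p_rep(n)
    key <- as.character(n)
    out[[key]] <- (out[[key]] %||% 0) + prob * (1 - p)
    recurse(n + 1, prob * p)
  }
  `%||%` <- function(u, v) if (is.null(u)) v else u
  recurse(x, 1)
  v <- unlist(as.list(out))
  v[order(as.integer(names(v)))]
}

# Naive tilted-binomial weights (no log-space tricks).
oracle_partition_weights <- function(x, a) {
  w <- choose(x, 0:x)^a
  w / sum(w)
}

# One rendered noise-free spot on constant background, for fit oracles.
render_single_spot <- function(shape = c(31, 31), x0 = 16, y0 = 16,
                               total = 1000, sigma = 1.5, bg = 10) {
  xs <- seq_len(shape[2]); ys <- seq_len(shape[1])
  amp <- total / (2 * pi * sigma^2)
  bg + amp * outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
                   exp(-(xs - x0)^2 / (2 * sigma^2)))
}
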