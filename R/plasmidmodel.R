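# Stochastic model of plasmid copy-number distributions: tilted-binomial
# partitioning at division (coefficient a), feedback-limited replication back
# toward the target copy number N0 (sensitivity K), Moran-style population
# turnover, grid fitting to observed distributions, and a two-state
# (telegraph) transcription simulator.

#' Exact partition probabilities
#'
#' Probability mass of the tilted binomial used for plasmid segregation at
#' division: `P(x1 | x) proportional to choose(x, x1)^a`. `a = 1` is the
#' unbiased binomial `Binomial(x, 1/2)`; large `a` concentrates mass at the
#' even split (less plasmid loss); `a -> 0` approaches the uniform
#' distribution on `0..x` (more loss).
#'
#' @param x plasmid count of the dividing cell (>= 0).
#' @param a partitioning coefficient (> 0).
#' @return numeric vector of length `x + 1`: probabilities of `x1 = 0..x`.
#' @export
partition_pmf <- function(x, a) {
  stopifnot(x >= 0, a > 0)
  lw <- a * lchoose(x, 0:x)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Randomly partition plasmids between two daughter cells
#'
#' Draws `x1` from [partition_pmf()] and returns `c(x1, x2)` with
#' `x1 + x2 = x` always.
#'
#' @inheritParams partition_pmf
#' @param seed integer seed (`NULL` uses the ambient RNG).
#' @return integer vector `c(x1, x2)`.
#' @export
partition <- function(x, a, seed = NULL) {
  stopifnot(x >= 0, a > 0)
  x1 <- with_seed(seed, cpp_partition(as.integer(x), a))
  c(x1 = x1, x2 = as.integer(x) - x1)
}

#' Replicate plasmids back toward the target copy number
#'
#' Sequential single-copy replications with Hill-type feedback: at current
#' count `n` the next replication occurs with probability
#' `1 / (1 + (n / N0)^K)`, stopping at the first failure. `x = 0` returns 0
#' (no template). As `K -> Inf` the outcome from `x < N0` concentrates on
#' `{N0, N0 + 1}` ("replicate until N0 is reobtained"); smaller `K` gives
#' broader outcomes and higher copy-number variance.
#'
#' @param x post-division plasmid count (>= 0).
#' @param N0 target mean copy number (>= 1).
#' @param K replication-control sensitivity (> 0).
#' @param seed integer seed (`NULL` uses the ambient RNG).
#' @return integer plasmid count after replication.
#' @export
replicate_plasmids <- function(x, N0, K, seed = NULL) {
  stopifnot(x >= 0, N0 >= 1, K > 0)
  with_seed(seed, cpp_replicate(as.integer(x), N0, K))
}

#' Vectorized draws from the partition and replication kernels
#'
#' @inheritParams partition
#' @param n number of draws.
#' @return integer vector of `x1` values (for `rpartition`) or
#'   post-replication counts (for `rreplicate`).
#' @export
rpartition <- function(n, x, a, seed = NULL) {
  stopifnot(n >= 1, x >= 0, a > 0)
  with_seed(seed, cpp_partition_many(as.integer(x), a, as.integer(n)))
}

#' @rdname rpartition
#' @inheritParams replicate_plasmids
#' @export
rreplicate <- function(n, x, N0, K, seed = NULL) {
  stopifnot(n >= 1, x >= 0, N0 >= 1, K > 0)
  with_seed(seed, cpp_replicate_many(as.integer(x), N0, K, as.integer(n)))
}

#' Exact outcome distribution of the replication kernel
#'
#' Closed-form probabilities of the sequential stopping process in
#' [replicate_plasmids()]: starting from `x`, the final count is `n` with
#' probability `prod(p(j), j = x..n-1) * (1 - p(n))` where
#' `p(n) = 1 / (1 + (n / N0)^K)`. The support is truncated where the
#' remaining mass falls below `tol`.
#'
#' @inheritParams replicate_plasmids
#' @param tol truncation tolerance for the upper tail.
#' @return data.frame (count, prob) with probabilities summing to 1 within
#'   `tol`.
#' @export
replicate_pmf <- function(x, N0, K, tol = 1e-15) {
  stopifnot(x >= 0, N0 >= 1, K > 0)
  if (x == 0) return(data.frame(count = 0L, prob = 1))
  p_rep <- function(n) 1 / (1 + exp(pmin(pmax(K * (log(n) - log(N0)), -700), 700)))
  counts <- integer(); probs <- numeric()
  surv <- 1  # probability the chain reaches the current count
  n <- x
  cap <- 100 * N0 + 1000
  while (surv > tol && n < cap) {
    p <- p_rep(n)
    counts <- c(counts, n)
    probs <- c(probs, surv * (1 - p))
    surv <- surv * p
    n <- n + 1L
  }
  if (surv > 0) { counts <- c(counts, n); probs <- c(probs, surv) }
  data.frame(count = counts, prob = probs)
}

#' Simulate a stationary plasmid copy-number distribution
#'
#' Constant-size population dynamics: repeatedly pick a uniformly random
#' plasmid-bearing cell, partition its plasmids between two daughters
#' ([partition()]), let each daughter replicate back toward `N0`
#' ([replicate_plasmids()]), insert both daughters and remove one uniformly
#' random cell. Plasmid-free cells persist (antibiotic selection keeps them
#' in the population snapshot) but never divide; random turnover sets the
#' stationary loss fraction. The returned snapshot holds post-replication
#' (division-ready) counts after `generations * pop_size` division events
#' following an equally long burn-in.
#'
#' @param N0 target mean copy number.
#' @param a partitioning coefficient.
#' @param K replication-control sensitivity.
#' @param pop_size number of cells (>= 10).
#' @param generations mean divisions per cell in each of the burn-in and
#'   sampling phases.
#' @param init initial counts: `"N0"` (all cells at `N0`, default), `"one"`
#'   (all cells at a single copy), `"high"` (all cells at `4 * N0`), or an
#'   integer vector of length `pop_size`.
#' @param seed integer seed; the run is deterministic given the seed.
#' @return list: `counts` (integer vector, one per cell), `mean`, `var`,
#'   `loss_fraction` (fraction of plasmid-free cells), and the parameters.
#' @export
simulate_plasmid_population <- function(N0, a = 1, K = 5, pop_size = 2000L,
                                        generations = 20, init = "N0",
                                        seed = NULL) {
  stopifnot(N0 >= 1, a > 0, K > 0, pop_size >= 10, generations > 0)
  init_counts <- if (is.numeric(init)) {
    stopifnot(length(init) == pop_size, all(init >= 0))
    as.integer(init)
  } else {
    switch(match.arg(init, c("N0", "one", "high")),
           N0 = rep(as.integer(round(N0)), pop_size),
           one = rep(1L, pop_size),
           high = rep(as.integer(4 * round(N0)), pop_size))
  }
  if (all(init_counts == 0L)) {
    stop_pf("extinction: every cell is plasmid-free", class = "pf_extinction")
  }
  n_events <- 2 * generations * pop_size  # burn-in + sampling phases
  counts <- with_seed(seed,
    cpp_simulate_population(init_counts, N0, a, K, n_events))
  list(counts = counts, mean = mean(counts), var = var(counts),
       loss_fraction = mean(counts == 0),
       N0 = N0, a = a, K = K, pop_size = pop_size,
       generations = generations, seed = seed)
}

# Two-sample KS statistic (no p-value), used as the fit distance.
ks_distance <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(q) mean(a <= q), numeric(1))
  Fb <- vapply(pts, function(q) mean(b <= q), numeric(1))
  max(abs(Fa - Fb))
}

#' Fit partition/replication parameters to an observed distribution
#'
#' Grid search over `(a, K)` minimizing the two-sample Kolmogorov-Smirnov
#' statistic between the observed copy-number distribution and a simulation
#' run at each grid point with a fixed seed (the same seed for every point,
#' so the search is deterministic and self-consistent). `N0` is fixed from
#' the observed mean unless supplied. Ties are broken toward smaller `K`,
#' then smaller `a`.
#'
#' @param observed integer vector of observed per-cell copy numbers.
#' @param N0 target copy number; default `round(mean(observed))`.
#' @param a_grid,K_grid parameter grids (defaults: 13 log-spaced points in
#'   `[0.1, 10]` for `a` and `[0.5, 32]` for `K`).
#' @param pop_size,generations simulation size per grid point.
#' @param seed integer seed used for every grid-point simulation.
#' @return list: `a`, `K`, `N0`, `ks_distance`, and `grid` (data.frame of all
#'   evaluated points with their distances).
#' @export
fit_sim_params <- function(observed, N0 = NULL,
                           a_grid = 10^seq(-1, 1, length.out = 13),
                           K_grid = 2^seq(log2(0.5), log2(32), length.out = 13),
                           pop_size = 2000L, generations = 10, seed = 1L) {
  stopifnot(length(observed) > 0, length(a_grid) > 0, length(K_grid) > 0)
  if (is.null(N0)) N0 <- max(1, round(mean(observed)))
  grid <- expand.grid(a = a_grid, K = K_grid)
  grid$D <- vapply(seq_len(nrow(grid)), function(i) {
    sim <- simulate_plasmid_population(N0 = N0, a = grid$a[i], K = grid$K[i],
                                       pop_size = pop_size,
                                       generations = generations, seed = seed)
    ks_distance(sim$counts, observed)
  }, numeric(1))
  ord <- order(grid$D, grid$K, grid$a)
  best <- grid[ord[1], ]
  list(a = best$a, K = best$K, N0 = N0, ks_distance = best$D, grid = grid)
}

#' Stationary mRNA counts under the two-state (telegraph) promoter model
#'
#' Exact stochastic simulation of a promoter switching between OFF and ON at
#' rates `k_on` and `k_off`, transcribing at rate `k_tx` while ON, with
#' first-order transcript degradation at rate `tau`. Each cell is simulated
#' independently to `t_end` starting from the stationary promoter state and
#' zero transcripts. The stationary mean is
#' `k_on / (k_on + k_off) * k_tx / tau`; slow switching produces
#' super-Poissonian (Fano > 1) distributions, while `k_off = 0` recovers a
#' Poisson distribution with mean `k_tx / tau`.
#'
#' @param k_on,k_off promoter switching rates (1/s); `k_off = 0` allowed.
#' @param k_tx transcription rate in the ON state (1/s).
#' @param tau mRNA degradation rate (1/s).
#' @param n_cells number of independent cells.
#' @param t_end simulated time per cell (seconds); default
#'   `8 * max(1/tau, 1/(k_on + k_off))`, several relaxation times of both the
#'   transcript and the promoter state.
#' @param seed integer seed.
#' @return integer vector of stationary mRNA counts, one per cell.
#' @export
telegraph_mrna <- function(k_on, k_off, k_tx, tau, n_cells, t_end = NULL,
                           seed = NULL) {
  stopifnot(k_on > 0, k_off >= 0, k_tx > 0, tau > 0, n_cells >= 1)
  if (is.null(t_end)) t_end <- 8 * max(1 / tau, 1 / (k_on + k_off))
  with_seed(seed,
    cpp_telegraph(as.integer(n_cells), k_on, k_off, k_tx, tau, t_end))
}
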