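# Plasmid partition/replication model, population dynamics, parameter
# fitting and the telegraph transcript simulator.

test_that("partition pmf matches brute-force tilted-binomial weights", {
  expect_equal(partition_pmf(2, 1), c(0.25, 0.5, 0.25))
  expect_equal(partition_pmf(2, 2), c(1, 4, 1) / 6)
  for (x in 0:6) {
    for (a in c(0.3, 1, 2, 5)) {
      expect_equal(partition_pmf(x, a), oracle_partition_weights(x, a),
                   tolerance = 1e-12)
    }
  }
  # x = 0 divides into (0, 0) with certainty
  expect_equal(partition(0, 1, seed = 1), c(x1 = 0L, x2 = 0L))
})

test_that("partition draws conserve plasmids and match Binomial at a = 1", {
  for (s in 1:20) {
    x <- sample(0:40, 1)
    pr <- partition(x, a = runif(1, 0.2, 5), seed = s)
    expect_equal(sum(pr), x)
  }
  draws <- rpartition(1e5, x = 10, a = 1, seed = 99)
  obs <- tabulate(draws + 1L, nbins = 11)
  expected <- dbinom(0:10, 10, 0.5) * 1e5
  expect_gt(stats::chisq.test(obs, p = expected / 1e5)$p.value, 0.01)
})

test_that("replication outcome distribution equals chain enumeration", {
  expect_equal(replicate_plasmids(0, 4, 5, seed = 1), 0L)
  # near-deterministic control: from 1 copy toward N0 = 4 at huge K the
  # chain stops at 4 or 5 with probability one half each
  pmf <- replicate_pmf(1, 4, 1e6)
  expect_equal(pmf$prob[pmf$count == 4], 0.5, tolerance = 1e-9)
  expect_equal(pmf$prob[pmf$count == 5], 0.5, tolerance = 1e-9)
  # exact match to depth-first enumeration across small N0
  for (N0 in 2:6) {
    for (x in c(1, 2, N0, 2 * N0)) {
      for (K in c(1, 2, 8)) {
        ora <- oracle_replicate_enum(x, N0, K)
        pmf <- replicate_pmf(x, N0, K)
        # compare everywhere except each method's own truncation point
        common <- setdiff(intersect(pmf$count, as.integer(names(ora))),
                          c(max(pmf$count), max(as.integer(names(ora)))))
        expect_equal(pmf$prob[match(common, pmf$count)],
                     unname(ora[as.character(common)]), tolerance = 1e-12)
      }
    }
  }
  # the sampler follows the exact pmf
  draws <- rreplicate(2e4, x = 2, N0 = 4, K = 2, seed = 7)
  pmf <- replicate_pmf(2, 4, 2)
  emp <- vapply(pmf$count, function(k) mean(draws == k), numeric(1))
  expect_lt(max(abs(emp - pmf$prob)), 0.015)
})

test_that("population simulation is stationary, seeded and conserves sense", {
  s1 <- simulate_plasmid_population(4, a = 1, K = 5, pop_size = 2000,
                                    generations = 15, seed = 100)
  expect_identical(s1$counts,
                   simulate_plasmid_population(4, 1, 5, 2000, 15,
                                               seed = 100)$counts)
  expect_gt(s1$mean, 0.8 * 4)
  expect_lt(s1$mean, 1.2 * 4)
  # doubling the run leaves the distribution unchanged (stationarity)
  s2 <- simulate_plasmid_population(4, a = 1, K = 5, pop_size = 2000,
                                    generations = 30, seed = 101)
  expect_lt(ks_pool_test(s1$counts, s2$counts)$D, 0.05)
  # all-plasmid-free population is an explicit extinction signal
  expect_error(simulate_plasmid_population(4, 1, 5, pop_size = 100,
                                           init = rep(0L, 100), seed = 1),
               class = "pf_extinction")
})

test_that("tighter replication control lowers variance; even partitioning lowers loss", {
  vars <- vapply(c(1, 5, 20), function(K) {
    mean(vapply(1:3, function(r)
      simulate_plasmid_population(9, a = 1, K = K, pop_size = 2000,
                                  generations = 15,
                                  seed = 200 + r)$var, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
  loss <- vapply(c(0.25, 1, 4), function(a) {
    mean(vapply(1:3, function(r)
      simulate_plasmid_population(4, a = a, K = 5, pop_size = 2000,
                                  generations = 15,
                                  seed = 300 + r)$loss_fraction, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(loss) <= 0))
})

test_that("stationary distribution forgets the initial condition", {
  lo <- simulate_plasmid_population(9, a = 1, K = 5, pop_size = 2000,
                                    generations = 20, init = "one", seed = 400)
  hi <- simulate_plasmid_population(9, a = 1, K = 5, pop_size = 2000,
                                    generations = 20, init = "high", seed = 401)
  expect_lt(ks_pool_test(lo$counts, hi$counts)$D, 0.05)
})

test_that("telegraph transcription has the analytic mean and Fano behaviour", {
  tau <- 0.01
  # always-ON limit: Poisson with mean k_tx / tau
  m_on <- telegraph_mrna(k_on = 0.01, k_off = 0, k_tx = 0.1, tau = tau,
                         n_cells = 1e4, seed = 500)
  expect_equal(var(m_on) / mean(m_on), 1, tolerance = 0.05)
  expect_equal(mean(m_on), 10, tolerance = 2 * sqrt(10 / 1e4) / 10 * 5)
  # stationary mean matches f_on * k_tx / tau within 2 SE
  m2 <- telegraph_mrna(k_on = 0.02, k_off = 0.01, k_tx = 0.15, tau = tau,
                       n_cells = 1e4, seed = 501)
  closed <- (0.02 / 0.03) * 0.15 / tau
  expect_lt(abs(mean(m2) - closed), 2 * sd(m2) / sqrt(1e4) + 0.02 * closed)
  # slow switching is super-Poissonian
  m3 <- telegraph_mrna(k_on = 0.1 * tau, k_off = 0.1 * tau, k_tx = 0.2,
                       tau = tau, n_cells = 1e4, seed = 502)
  expect_gt(var(m3) / mean(m3), 1.5)
})

test_that("grid fitting recovers generating parameters", {
  a_grid <- 10^seq(-1, 1, length.out = 7)
  K_grid <- 2^seq(log2(0.5), log2(32), length.out = 7)
  obs <- simulate_plasmid_population(9, a = a_grid[4], K = K_grid[5],
                                     pop_size = 1500, generations = 10,
                                     seed = 600)$counts
  fit <- fit_sim_params(obs, N0 = 9, a_grid = a_grid, K_grid = K_grid,
                        pop_size = 1500, generations = 10, seed = 600)
  # same seed protocol: the generating grid point reproduces `obs` exactly
  expect_equal(fit$a, a_grid[4])
  expect_equal(fit$K, K_grid[5])
  expect_equal(fit$ks_distance, 0)
})
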