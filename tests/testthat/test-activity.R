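# Degradation-rate fitting, promoter activity, population statistics, KS
# pooling, Hill fits.

test_that("decay fit reproduces exact half-life data and rejects growth", {
  mu <- 6.8
  f <- decay_fit(c(0, mu, 2 * mu), c(100, 50, 25))
  expect_equal(f$half_life_min, mu, tolerance = 1e-8)
  expect_equal(f$tau, log(2) / (mu * 60), tolerance = 1e-8)
  # exact identity between rate and half-life fields
  expect_equal(f$half_life_min, log(2) / (f$tau * 60))
  expect_error(decay_fit(c(0, 5, 10), c(10, 20, 40)),
               class = "pf_non_decaying")
  expect_error(decay_fit(c(0, 5), c(10, 5)), "3 time points")
})

test_that("decay fit is scale equivariant and recovers simulated rates", {
  ser <- simulate_decay_series(120, 6.8, n_cells = 500, seed = 30)
  f1 <- decay_fit(ser, n_boot = 50, seed = 31)
  expect_equal(f1$half_life_min, 6.8, tolerance = 0.1)
  expect_true(is.finite(f1$se_half_life_min))
  # scaling all counts leaves the rate unchanged
  means <- tapply(ser$count, ser$time_min, mean)
  tt <- as.numeric(names(means))
  f2 <- decay_fit(tt, 13 * as.numeric(means))
  expect_equal(f2$tau, decay_fit(tt, as.numeric(means))$tau, tolerance = 1e-8)
})

test_that("promoter activity follows J = tau * m / N", {
  tau <- log(2) / 408   # half-life 6.8 min in seconds
  expect_equal(promoter_activity(0, 5, tau), 0)
  expect_equal(promoter_activity(100, 9, tau), tau * 100 / 9)
  expect_equal(promoter_activity(100, 9, tau), 0.0189, tolerance = 0.003)
  # homogeneity: doubling N at fixed m halves J
  expect_equal(promoter_activity(40, 10, tau),
               promoter_activity(40, 5, tau) / 2)
  # N = 0 is an excluded-cell signal, not a number
  expect_true(is.na(promoter_activity(3, 0, tau)))
})

test_that("population activity statistics hold exactly", {
  tau <- log(2) / 408
  set.seed(40)
  rec <- data.frame(m = rpois(500, 30), N = rpois(500, 9),
                    replicate = rep(1:3, length.out = 500))
  pop <- population_activity(rec, tau)
  inc <- rec[rec$N >= 1, ]
  # <J> = tau * <m/N> to machine precision
  expect_equal(pop$mean_J, tau * mean(inc$m / inc$N), tolerance = 1e-12)
  expect_equal(pop$mean_J, mean(pop$records$J[rec$N >= 1]), tolerance = 1e-12)
  expect_equal(pop$plasmid_loss_fraction, mean(rec$N == 0))
  expect_true(is.finite(pop$sd_day))

  all0 <- population_activity(data.frame(m = c(0, 0), N = c(2, 3)), tau)
  expect_equal(all0$mean_J, 0)
  expect_equal(all0$zero_activity_fraction, 1)
  expect_error(population_activity(data.frame(m = numeric(), N = numeric()),
                                   tau), "empty")
})

test_that("population activity recovers the generating rate", {
  tab <- simulate_population_table(2000, plasmid_dist = list(kind = "poisson",
                                                             mean = 9),
                                   mrna_per_plasmid = 11.2,
                                   zero_activity_prob = 0.05, seed = 41)
  tau <- log(2) / 408
  pop <- population_activity(tab, tau)
  truth <- tau * 11.2 * 0.95
  se <- pop$sd_population / sqrt(pop$n_included)
  expect_lt(abs(pop$mean_J - truth), 2 * se + 0.02 * truth)
  expect_equal(pop$zero_activity_fraction, 0.05, tolerance = 0.4)
})

test_that("KS pooling test matches edge cases and enumeration", {
  same <- c(1, 2, 3, 4)
  r <- ks_pool_test(same, same)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  sep <- ks_pool_test(1:5, 101:105)
  expect_equal(sep$D, 1)
  # small-sample p equals full enumeration of group assignments
  set.seed(50)
  a <- c(0.1, 0.9, 1.7); b <- c(0.5, 1.1, 2.3)
  ora <- oracle_ks_exact(a, b)
  got <- ks_pool_test(a, b)
  expect_equal(got$D, ora$D, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-9)
  expect_error(ks_pool_test(numeric(), 1:3), "nonempty")
})

test_that("Hill fits round-trip and reduce to the linear regime", {
  hill <- function(x, ymax, x50, h) ymax * x^h / (x50^h + x^h)
  # discrete x levels: every binned mean then sits exactly on the curve and
  # recovery is limited only by optimizer tolerance
  x <- rep(seq(1, 60, length.out = 12), each = 40)
  y <- hill(x, ymax = 8, x50 = 15, h = 1.6)
  fit <- bin_and_fit_hill(x, y, n_bins = 12)
  expect_equal(fit$ymax, 8, tolerance = 1e-6)
  expect_equal(fit$x50, 15, tolerance = 1e-6)
  expect_equal(fit$h, 1.6, tolerance = 1e-6)

  # h = 1, x << x50: response is linear with slope ymax / x50
  x2 <- rep(seq(0.1, 2, length.out = 10), each = 30)
  y2 <- hill(x2, ymax = 10, x50 = 500, h = 1)
  fit2 <- bin_and_fit_hill(x2, y2, n_bins = 8)
  pred_slope <- (fit2$fitted(2) - fit2$fitted(0.1)) / 1.9
  expect_equal(pred_slope, 10 / 500, tolerance = 0.05)

  expect_error(bin_and_fit_hill(x, rep(1, length(x))),
               class = "pf_degenerate")
})
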