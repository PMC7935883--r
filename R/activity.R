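# Promoter activity in absolute units: degradation-rate fitting, per-cell
# RNAP flux J = tau * m / N, population statistics, replicate pooling by the
# two-sample Kolmogorov-Smirnov test, and binned Hill-equation fits.

#' Fit a single-exponential decay to a transcription-arrest time course
#'
#' Fits `m(t) = m0 * exp(-k t)` by least squares to the per-time-point mean
#' transcript counts (t in minutes) and reports the degradation rate
#' `tau = k / 60` (1/s) and the half-life `ln(2) / k` (minutes). When
#' per-cell counts are supplied, the half-life standard error is estimated by
#' bootstrap over cells within each time point.
#'
#' @param time_min time points in minutes. Alternatively a data.frame with
#'   columns `time_min` and `count` (per-cell) may be passed as the first
#'   argument.
#' @param counts per-time-point mean counts (same length as `time_min`), or
#'   omitted when a data.frame is given.
#' @param n_boot bootstrap resamples for the half-life standard error
#'   (requires per-cell data; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @return object of class `decay_fit`: `tau` (1/s), `half_life_min`,
#'   `m0`, `rss`, `se_half_life_min` (NA without per-cell data),
#'   `means` (the fitted per-time-point means).
#' @export
decay_fit <- function(time_min, counts = NULL, n_boot = 200L, seed = NULL) {
  percell <- NULL
  if (is.data.frame(time_min)) {
    percell <- time_min
    stopifnot(all(c("time_min", "count") %in% names(percell)))
    agg <- stats::aggregate(count ~ time_min, percell, mean)
    tt <- agg$time_min; mm <- agg$count
  } else {
    tt <- time_min; mm <- counts
  }
  if (length(tt) < 3) {
    stop_pf("need at least 3 time points", class = "pf_bad_input")
  }
  if (mm[which.min(tt)] <= 0) {
    stop_pf("mean count at the first time point must be positive",
            class = "pf_bad_input")
  }
  fit_means <- function(tt, mm) {
    pos <- mm > 0
    sl <- stats::coef(stats::lm(log(mm[pos]) ~ tt[pos]))
    start <- list(m0 = exp(sl[[1]]), k = max(-sl[[2]], 1e-6))
    f <- minpack.lm::nlsLM(mm ~ m0 * exp(-k * tt), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
    stats::coef(f)
  }
  cf <- fit_means(tt, mm)
  if (cf[["k"]] <= 1e-9) {
    stop_pf("non-decaying data: fitted degradation rate is not positive",
            class = "pf_non_decaying")
  }
  se <- NA_real_
  if (!is.null(percell) && n_boot > 0) {
    hl <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      res <- tryCatch({
        mm_b <- vapply(tt, function(t0) {
          x <- percell$count[percell$time_min == t0]
          mean(x[sample.int(length(x), replace = TRUE)])
        }, numeric(1))
        cb <- fit_means(tt, mm_b)
        if (cb[["k"]] > 0) log(2) / cb[["k"]] else NA_real_
      }, error = function(e) NA_real_)
      res
    }, numeric(1)))
    se <- sd(hl, na.rm = TRUE)
  }
  k_min <- cf[["k"]]                 # 1/min
  structure(list(tau = k_min / 60, half_life_min = log(2) / k_min,
                 m0 = cf[["m0"]],
                 rss = sum((mm - cf[["m0"]] * exp(-k_min * tt))^2),
                 se_half_life_min = se,
                 means = data.frame(time_min = tt, mean_count = mm)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Single-exponential mRNA decay fit\n")
  cat(sprintf("  half-life : %.2f min%s\n", x$half_life_min,
              if (is.finite(x$se_half_life_min))
                sprintf(" (bootstrap SE %.2f)", x$se_half_life_min) else ""))
  cat(sprintf("  tau       : %.3e 1/s\n", x$tau))
  invisible(x)
}

#' Per-cell promoter activity (RNAP flux per DNA copy)
#'
#' `J = tau * m / N` in RNAP/s-DNA: the rate at which RNA polymerases
#' productively exit one promoter copy, inferred from the steady-state
#' balance between transcript production (N promoter copies working at rate
#' J) and first-order degradation at rate `tau`. Cells with `N = 0` carry no
#' per-copy activity and are returned as `NA` (excluded cells).
#'
#' @param m mRNA count(s), >= 0.
#' @param N plasmid copy number(s).
#' @param tau mRNA degradation rate, 1/s.
#' @return numeric vector of J values (RNAP/s-DNA), `NA` where `N = 0`.
#' @export
promoter_activity <- function(m, N, tau) {
  stopifnot(tau > 0, all(m >= 0), all(N >= 0))
  ifelse(N >= 1, tau * m / N, NA_real_)
}

#' Population statistics of promoter activity
#'
#' Computes per-cell activities for plasmid-bearing cells, their mean
#' (identically `tau * mean(m/N)`), the pooled-population SD, the fraction
#' of plasmid-bearing cells with no detected activity (m = 0), the
#' plasmid-loss fraction (N = 0), total activity `N * J = tau * m` per cell,
#' and - when a `replicate` column is present - the day-to-day SD across
#' replicate means.
#'
#' @param records data.frame with columns `m` and `N` (and optionally
#'   `cell_id`, `replicate`).
#' @param tau mRNA degradation rate, 1/s.
#' @return list: `records` (input plus `J`, `J_total`), `mean_J`, `sd_population`,
#'   `sd_day` (NA without replicates), `zero_activity_fraction`,
#'   `plasmid_loss_fraction`, `n_included`.
#' @export
population_activity <- function(records, tau) {
  stopifnot(is.data.frame(records), all(c("m", "N") %in% names(records)))
  if (nrow(records) == 0) {
    stop_pf("empty record set", class = "pf_bad_input")
  }
  records$J <- promoter_activity(records$m, records$N, tau)
  records$J_total <- tau * records$m
  inc <- records[records$N >= 1, , drop = FALSE]
  if (nrow(inc) == 0) {
    stop_pf("no plasmid-bearing cells to analyse", class = "pf_bad_input")
  }
  sd_day <- NA_real_
  if ("replicate" %in% names(inc) && length(unique(inc$replicate)) > 1) {
    day_means <- tapply(inc$J, inc$replicate, mean)
    sd_day <- sd(day_means)
  }
  list(records = records,
       mean_J = mean(inc$J),
       sd_population = sd(inc$J),
       sd_day = sd_day,
       zero_activity_fraction = mean(inc$m == 0),
       plasmid_loss_fraction = mean(records$N == 0),
       n_included = nrow(inc))
}

#' Two-sample Kolmogorov-Smirnov test for replicate pooling
#'
#' Computes the two-sample KS statistic D and its p-value, used to decide
#' whether replicate distributions can be pooled. The p-value is exact
#' (computed from the permutation distribution of D, accounting for ties)
#' when `length(a) * length(b) <= 100`, and asymptotic otherwise.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `D` and `p`.
#' @export
ks_pool_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_pf("both samples must be nonempty", class = "pf_bad_input")
  }
  exact <- length(a) * length(b) <= 100
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = min(kt$p.value, 1))
}

#' Bin single-cell data and fit a Hill equation to the binned means
#'
#' Bins `x` into equal-occupancy bins, computes bin means and SDs of `y`, and
#' fits `y = ymax * x^h / (x50^h + x^h)` to the binned means by
#' Levenberg-Marquardt least squares. Reports the fold change of the fitted
#' response across the observed x range.
#'
#' @param x per-cell covariate (plasmid copy number or cell volume).
#' @param y per-cell response (total activity, per-copy activity,
#'   fluorescence).
#' @param n_bins number of equal-occupancy bins (>= 4 non-empty required).
#' @return list: `bins` (data.frame x_mean, y_mean, y_sd, n), `ymax`, `x50`,
#'   `h`, `fold_change`, `fitted` (function of x).
#' @export
bin_and_fit_hill <- function(x, y, n_bins = 8L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 5) {
    stop_pf("fewer than 4 distinct bins available", class = "pf_bad_input")
  }
  bin <- cut(x, qs, include.lowest = TRUE)
  bins <- data.frame(
    x_mean = as.numeric(tapply(x, bin, mean)),
    y_mean = as.numeric(tapply(y, bin, mean)),
    y_sd = as.numeric(tapply(y, bin, sd)),
    n = as.numeric(table(bin)))
  bins <- bins[bins$n > 0, , drop = FALSE]
  if (nrow(bins) < 4) {
    stop_pf("need at least 4 non-empty bins for a Hill fit",
            class = "pf_bad_input")
  }
  if (sd(bins$y_mean) == 0) {
    stop_pf("degenerate response: binned means are constant",
            class = "pf_degenerate")
  }
  ymax0 <- max(bins$y_mean)
  half <- ymax0 / 2
  i <- which.min(abs(bins$y_mean - half))
  start <- list(ymax = ymax0 * 1.2, x50 = max(bins$x_mean[i], 1e-9), h = 1)
  fit <- minpack.lm::nlsLM(
    y_mean ~ ymax * x_mean^h / (x50^h + x_mean^h), data = bins, start = start,
    lower = c(ymax = 0, x50 = 1e-12, h = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- as.list(stats::coef(fit))
  hill <- function(xx) p$ymax * xx^p$h / (p$x50^p$h + xx^p$h)
  rng <- range(bins$x_mean)
  list(bins = bins, ymax = p$ymax, x50 = p$x50, h = p$h,
       fold_change = hill(rng[2]) / hill(rng[1]), fitted = hill)
}
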