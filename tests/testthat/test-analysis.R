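test_that("binned trajectory statistics match a brute-force group-by", {
  t1 <- data.frame(t = seq(0, 999, 10), x_c = 2)
  t2 <- data.frame(t = seq(0, 999, 10), x_c = 3)
  st <- binned_trajectory_stats(list(t1, t2), bin = 200)
  expect_equal(st$mean, rep(2.5, 5))
  st0 <- binned_trajectory_stats(list(t1, t1), bin = 200)
  expect_equal(st0$sd, rep(0, 5))
  # random data vs direct aggregation oracle
  set.seed(5)
  trs <- lapply(1:3, function(i)
    data.frame(t = seq(0, 499, 7), x_c = runif(72)))
  st <- binned_trajectory_stats(trs, bin = 100)
  tt <- unlist(lapply(trs, `[[`, "t")); xx <- unlist(lapply(trs, `[[`, "x_c"))
  oracle <- tapply(xx, floor(tt / 100), mean)
  expect_equal(unname(st$mean), unname(as.numeric(oracle)))
})

test_that("conditioned profiles report dwell bookkeeping honestly", {
  p <- p_fast(t_min = 60)
  # target the start position: an immobile (dimer-free) cluster dwells forever
  p0 <- pom_update(p, N_total = 0)
  cp <- conditioned_profiles(p0, target_frac = p$L_c / 2 / p$L,
                             t_end = 100, n_runs = 1, seed = 1,
                             record_dt = 10)
  expect_equal(cp$episodes, 1)
  expect_equal(cp$dwell, 100, tolerance = 1)
  expect_true(all(cp$c == 0))  # no dimers anywhere
  # unreachable window: flagged empty, not NaN-filled
  expect_warning(
    cp2 <- conditioned_profiles(p0, target_frac = 0.9, t_end = 50,
                                n_runs = 1, seed = 1, record_dt = 10),
    "never dwelt")
  expect_equal(cp2$dwell, 0)
  expect_null(cp2$c)
})

test_that("conditioned profiles reproduce the stationary flux difference", {
  p <- p_fast()
  cp <- conditioned_profiles(p, target_frac = 0.3, t_end = 1000, n_runs = 5,
                             seed = 77, record_dt = 5)
  expect_gt(cp$dwell, 10)
  jd <- flux_difference_estimator(cp$j)
  jd_rd <- solve_stationary(p, 0.3 * p$L)$j_diff
  expect_gt(jd, 0.3 * jd_rd)
  expect_lt(jd, 2.5 * jd_rd)
})

test_that("flux-difference estimator recovers the edge inflow difference", {
  # antisymmetric profile: zero
  x <- seq(-1, 1, 0.01)
  expect_equal(flux_difference_estimator(sin(pi * x)), 0, tolerance = 1e-12)
  # same-sign degenerate profile warns
  expect_warning(flux_difference_estimator(c(1, 2, 3)), "degenerate")
  # RD-generated profile: estimator within 5% of analytic j_R - j_L
  p <- p_fast()
  prof <- solve_stationary(p, 0.76)
  expect_equal(flux_difference_estimator(prof$j), prof$j_diff,
               tolerance = 0.05)
})

test_that("force-velocity fit recovers an exact linear law", {
  tab <- data.frame(velocity = c(0.001, 0.002, 0.004),
                    F_ext = 3.7 * c(0.001, 0.002, 0.004))
  fit <- suppressWarnings(force_velocity_fit(tab))
  expect_equal(fit$gamma, 3.7, tolerance = 1e-10)
  expect_error(force_velocity_fit(tab[1:2, ]), "at least 3")
  perm <- tab[c(3, 1, 2), ]
  expect_equal(suppressWarnings(force_velocity_fit(perm))$gamma, fit$gamma)
})

test_that("histogram classifier separates central peaks from split peaks", {
  set.seed(6)
  g1 <- rnorm(20000, 2.5, 0.3)
  g2 <- c(rnorm(10000, 1.5, 0.2), rnorm(10000, 3.5, 0.2))
  expect_equal(as.character(position_histogram_classifier(g1, 5)), "monomodal")
  expect_equal(as.character(position_histogram_classifier(g2, 5)), "bimodal")
  # stable under +-50% bin-count changes
  expect_equal(as.character(position_histogram_classifier(g2, 5, bins = 50)),
               "bimodal")
  expect_equal(as.character(position_histogram_classifier(g2, 5, bins = 150)),
               "bimodal")
  # mirror invariance
  expect_equal(as.character(position_histogram_classifier(5 - g2, 5)),
               "bimodal")
  expect_equal(as.character(position_histogram_classifier(5 - g1, 5)),
               "monomodal")
})

test_that("the 2%-of-maximum peak rule is a strict inequality", {
  set.seed(7)
  g2 <- c(rnorm(8000, 1.6, 0.25), rnorm(8000, 3.4, 0.25))
  cl <- position_histogram_classifier(g2, 5)
  expect_equal(as.character(cl), "bimodal")
  # recompute the observed peak difference and set the threshold exactly there
  y <- attr(cl, "histogram")
  n <- length(y)
  is_max <- sapply(2:(n - 1), function(i) y[i] > y[i - 1] && y[i] >= y[i + 1])
  is_min <- sapply(2:(n - 1), function(i) y[i] < y[i - 1] && y[i] <= y[i + 1])
  imax <- which(is_max) + 1; imin <- which(is_min) + 1
  imin <- imin[imin > min(imax) & imin < max(imax)]
  dfrac <- (max(y[imax]) - min(y[imin])) / max(y)
  at_boundary <- position_histogram_classifier(g2, 5, threshold = dfrac)
  expect_equal(as.character(at_boundary), "monomodal")
  below <- position_histogram_classifier(g2, 5, threshold = dfrac * 0.999)
  expect_equal(as.character(below), "bimodal")
})

test_that("FFT detector recovers a sinusoid to one frequency bin", {
  set.seed(8)
  tg <- seq(0, 6000, by = 12)
  f0 <- 2 / 600
  trs <- lapply(1:10, function(i)
    data.frame(t = tg, x_c = 2.5 + 0.5 * sin(2 * pi * f0 * tg + runif(1) * 6.28) +
                 rnorm(length(tg), 0, 0.05)))
  r <- fft_oscillation_detector(trs, L = 5)
  expect_equal(r$classification, "oscillatory")
  df <- 60 / 6000  # one frequency bin in 1/min
  expect_lt(abs(r$frequency - f0 * 60), df + 1e-9)
  expect_gte(r$frequency, r$f_min)
})

test_that("mean-reverting noise is not classified as oscillatory", {
  set.seed(9)
  tg <- seq(0, 6000, by = 12)
  trs <- lapply(1:20, function(i) {
    x <- numeric(length(tg))
    for (j in 2:length(tg)) x[j] <- x[j - 1] * exp(-12 / 300) + rnorm(1, 0, 0.1)
    data.frame(t = tg, x_c = 2.5 + x)
  })
  r <- fft_oscillation_detector(trs, L = 5)
  expect_equal(r$classification, "non-oscillatory")
  expect_true(is.na(r$frequency))
})

test_that("estimators are reproducible given identical inputs", {
  set.seed(10)
  tg <- seq(0, 3000, by = 12)
  trs <- lapply(1:5, function(i)
    data.frame(t = tg, x_c = 2.5 + rnorm(length(tg), 0, 0.2)))
  r1 <- fft_oscillation_detector(trs, L = 5)
  r2 <- fft_oscillation_detector(trs, L = 5)
  expect_identical(r1, r2)
})
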