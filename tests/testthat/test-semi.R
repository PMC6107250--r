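test_that("force-constant estimators are consistent with each other", {
  fake <- data.frame(f_int = rep(0, 50), t_i = rexp(50, 1))
  expect_equal(estimate_C(fake, k_h = 1, n_boot = 50)$C, 0)
  expect_error(estimate_C(fake[0, ], k_h = 1), "empty")

  p <- p_fine()
  rec <- run_one_particle(p, n_interactions = 2500, seed = 13)
  est <- estimate_C(rec, p$k_h, n_boot = 400)
  # the f/k_h and mean-f_int estimators agree within combined bootstrap CIs
  expect_lt(abs(est$C - est$C_int),
            2 * sqrt(est$se_C^2 + est$se_C_int^2) + 1e-12)
  expect_gt(est$C, 0)
  # mean interaction time converges to 1/k_h
  expect_equal(mean(rec$t_i), 1 / p$k_h, tolerance = 0.1)
})

test_that("effective friction follows the tether-drag formula", {
  p <- pom_params()
  expect_equal(effective_friction(0, p), p$gamma_c)
  add1 <- effective_friction(20, p) - p$gamma_c
  p2 <- pom_update(p, D_nuc = 2 * p$D_nuc, D_clu = 2 * p$D_clu)
  add2 <- effective_friction(20, p2) - p$gamma_c
  expect_equal(add2, add1 / 2)
  expect_equal(effective_friction(10, p),
               p$gamma_c + p$kBT * 10 / (p$D_clu + p$D_nuc))
})

test_that("velocity field vanishes at midnucleoid and restores the cluster", {
  p <- p_fast()
  C <- 0.002
  expect_equal(velocity_field(p$L / 2, C, p), 0, tolerance = 1e-10)
  vL <- velocity_field(p$L / 2 - 0.4, C, p)
  vR <- velocity_field(p$L / 2 + 0.4, C, p)
  expect_gt(vL, 0)
  expect_equal(vL, -vR, tolerance = 1e-8)
})

test_that("trajectory integration is monotone with no overshoot", {
  p <- p_fast()
  C <- 0.002
  flat <- integrate_trajectory(p$L / 2, 500, C, p)
  expect_equal(flat$x_c, rep(p$L / 2, nrow(flat)), tolerance = 1e-6)
  xg <- seq(p$L_c / 2, p$L - p$L_c / 2, length.out = 31)
  vf <- stats::approxfun(xg, velocity_field(xg, C, p), rule = 2)
  tr <- integrate_trajectory(p$L_c / 2, 4000, C, p, v_fun = vf)
  expect_true(all(diff(tr$x_c) >= -1e-9))
  expect_true(all(tr$x_c <= p$L / 2 + 1e-6))
})

test_that("halving C rescales the trajectory time axis", {
  p <- p_fast()
  xg <- seq(p$L_c / 2, p$L - p$L_c / 2, length.out = 31)
  v1 <- stats::approxfun(xg, velocity_field(xg, 0.002, p), rule = 2)
  v2 <- stats::approxfun(xg, velocity_field(xg, 0.001, p), rule = 2)
  t1 <- integrate_trajectory(p$L_c / 2, 1000, 0.002, p,
                             times = seq(0, 1000, 50), v_fun = v1)
  t2 <- integrate_trajectory(p$L_c / 2, 2000, 0.001, p,
                             times = seq(0, 2000, 100), v_fun = v2)
  expect_equal(t2$x_c, t1$x_c, tolerance = 1e-6)
})

test_that("time-scale criterion arithmetic and limits", {
  p <- pom_params(D_nuc = 1e-4)
  tc <- timescale_criterion(p, C = 0.006)
  expect_equal(tc$t_PomZ, 2.5e5)
  # very fast nucleoid diffusion is always stable
  pf <- pom_params(D_nuc = 50)
  expect_true(timescale_criterion(pf, C = 0.006)$stable)
  expect_equal(tc$margin, tc$t_PomZ / tc$t_cluster)
})
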