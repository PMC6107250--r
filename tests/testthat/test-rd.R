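test_that("midnucleoid solution is symmetric with vanishing flux difference", {
  p <- p_fast()
  prof <- solve_stationary(p, p$L / 2)
  expect_lt(abs(prof$j_diff), 1e-10)
  expect_equal(prof$c, rev(prof$c), tolerance = 1e-9)
  expect_equal(prof$c_b, rev(prof$c_b), tolerance = 1e-9)
})

test_that("stationary profile satisfies its defining identities", {
  p <- p_fast()
  for (xc in c(0.4, 0.76, 1.1)) {
    prof <- solve_stationary(p, xc)
    rp <- prof$params
    # no-flux outer boundaries
    expect_lt(abs(prof$cp_fun(0)), 1e-10 * max(prof$c))
    expect_lt(abs(prof$cp_fun(p$L)), 1e-10 * max(prof$c))
    # continuity of density and flux at the cluster edges
    h <- 1e-9
    for (e in c(xc - p$L_c / 2, xc + p$L_c / 2)) {
      expect_equal(prof$c_fun(e - h), prof$c_fun(e + h), tolerance = 1e-6)
      expect_equal(prof$cp_fun(e - h), prof$cp_fun(e + h), tolerance = 1e-5)
    }
    # no-flux cluster edges for the doubly-bound density (one-sided interior
    # difference; c_b is zero outside the footprint)
    d <- 1e-6
    eL <- xc - p$L_c / 2; eR <- xc + p$L_c / 2
    slopeL <- (prof$cb_fun(eL + 2 * d) - prof$cb_fun(eL + d)) / d
    slopeR <- (prof$cb_fun(eR - d) - prof$cb_fun(eR - 2 * d)) / d
    expect_lt(abs(slopeL), 1e-4 * max(prof$c_b) / p$L_c)
    expect_lt(abs(slopeR), 1e-4 * max(prof$c_b) / p$L_c)
    # total particle number and global turnover balance
    tot <- prof$N_cyto + sum(prof$c) * p$a + sum(prof$c_b) * p$a
    expect_equal(tot, p$N_total, tolerance = 1e-4)
    lhs <- rp$k_on * prof$N_cyto * (p$L - p$L_c) / p$L
    expect_equal(lhs, rp$k_h * prof$N, tolerance = 1e-8)
    # interior equation residual (central differences on the closed form)
    xs <- seq(xc - p$L_c / 2 + 0.02, xc + p$L_c / 2 - 0.02, length.out = 7)
    hh <- 1e-4
    res <- rp$D_nuc * (prof$c_fun(xs + hh) - 2 * prof$c_fun(xs) +
                         prof$c_fun(xs - hh)) / hh^2 -
      rp$k_a_total * prof$c_fun(xs)
    expect_lt(max(abs(res)) / (rp$k_a_total * max(prof$c)), 1e-4)
  }
})

test_that("closed-form solution matches the time-marched FD oracle", {
  # gentle absorption and a grid-aligned cluster so the FD discretisation
  # error stays below the comparison tolerance
  # nx = 500 puts the cluster edges exactly on cell faces, so the FD
  # discretisation resolves the same footprint as the closed form
  p <- p_fast(ka0 = 2)
  rd <- solve_stationary(p, 0.76)
  tm <- rd_time_march(p, 0.76, t_final = 5e4, nx = 500)
  expect_lt(max(abs(tm$c - rd$c_fun(tm$x))) / max(rd$c), 1e-4)
  expect_lt(max(abs(tm$c_b - rd$cb_fun(tm$x))) / max(rd$c_b), 1e-4)
  expect_equal(tm$N_cyto, rd$N_cyto, tolerance = 1e-5)
})

test_that("flux difference is antisymmetric and points toward midnucleoid", {
  p <- p_fast()
  for (d in c(0.2, 0.5, 0.8)) {
    jp <- flux_difference(p, p$L / 2 - d)
    jm <- flux_difference(p, p$L / 2 + d)
    expect_equal(jp, -jm, tolerance = 1e-8)
    expect_gt(jp, 0)
  }
})

test_that("flux difference dips for clusters very close to the pole", {
  # particle-number conservation weakens the source when the cluster pins a
  # large bound population near the pole; visible at fast cytosol recycling
  p <- p_fast(k_on = 1)
  fr <- c(0.074, 0.09, 0.12, 0.2)
  jd <- flux_difference(p, fr * p$L)
  expect_lt(jd[1], max(jd))          # non-monotone: pole value below the max
  expect_gt(which.max(jd), 1)
  expect_gt(jd[2], jd[4])            # still decreasing toward midnucleoid
})

test_that("bound count obeys the binding-hydrolysis balance", {
  p <- p_fast()
  expect_equal(bound_count(pom_update(p, ka0 = 0), 0.76), 0)
  prof <- solve_stationary(p, 0.76)
  rp <- prof$params
  int_c_inside <- stats::integrate(prof$c_fun, 0.76 - p$L_c / 2,
                                   0.76 + p$L_c / 2, rel.tol = 1e-10)$value
  expect_equal(rp$k_a_total * int_c_inside, rp$k_h * prof$N,
               tolerance = 1e-6)
})

test_that("degenerate parameter combinations are diagnosed or solved exactly", {
  p <- p_fast()
  expect_error(solve_stationary(pom_update(p, k_h = 0), 0.76), "no steady state")
  expect_error(solve_stationary(p, 0.05), "x_c")
  # no binding and no detachment: the exact free-diffusion limit is a
  # uniform fluxless nucleoid density holding every dimer
  u <- solve_stationary(pom_update(p, ka0 = 0, k_off = 0), 0.76)
  expect_equal(u$c, rep(p$N_total / p$L, length(u$c)))
  expect_equal(u$N, 0)
  expect_equal(u$N_cyto, 0)
  expect_equal(u$j_diff, 0)
})

test_that("nucleoid detachment flattens the flux-difference profile", {
  p <- p_fast()
  kos <- c(0, 0.02, 0.1, 0.5)
  jd <- sapply(kos, function(ko)
    flux_difference(pom_update(p, k_off = ko), 0.2 * p$L))
  expect_true(all(diff(jd) < 0))
})

test_that("RD bound count matches the stochastic stationary mean", {
  p <- p_fast()
  rd <- solve_stationary(p, 0.76)
  nb <- sapply(1:6, function(r)
    run_stationary(p, 0.76, t_end = 600, seed = 40 + r, burn_in = 250)$n_bound)
  se <- stats::sd(nb) / sqrt(length(nb))
  expect_lt(abs(mean(nb) - rd$N), 4 * se + 0.02 * rd$N)
})
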