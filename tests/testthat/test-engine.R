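test_that("particle number is conserved after every recorded event", {
  p <- p_fast()
  tr <- suppressWarnings(run_dynamic(p, t_end = 300, seed = 1, record_dt = 2))
  expect_true(all(tr$n_bound + tr$n_nucleoid + tr$n_cyto == p$N_total))
  expect_true(all(diff(tr$t) > 0))
})

test_that("a system without dimers leaves the cluster immobile", {
  p <- p_fast(N_total = 0, t_min = 10)
  tr <- run_dynamic(p, t_end = 50, seed = 1, record_dt = 5)
  expect_true(all(tr$x_c == tr$x_c[1]))
})

test_that("waiting times obey the exponential law (PIT over the event log)", {
  p <- p_fast(t_min = 0)
  st <- run_stationary(p, 1.26, t_end = 100, seed = 10, burn_in = 0,
                       n_log = 50000)
  u <- exp(-st$event_log$alpha * st$event_log$dt)
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("cytosolic dimers land uniformly outside the cluster footprint", {
  # frozen-landing oracle: no hopping, no unbinding, so the final nucleoid
  # sites are exactly the i.i.d. attachment draws
  p <- pom_params(L = 2.5, L_c = 0.36, a = 0.02, D_nuc = 0, D_clu = 0,
                  ka0 = 0, k_h = 0, k_on = 1, N_total = 20000, t_min = 0,
                  lambda_null = 50)
  x_c <- 0.76
  st <- run_stationary(p, x_c, t_end = 15, seed = 5, burn_in = 0)
  xs <- st$final_xn_free
  expect_equal(length(xs), p$N_total)
  expect_equal(sum(xs > x_c - p$L_c / 2 & xs < x_c + p$L_c / 2), 0)
  sites <- pomsim:::nucleoid_sites(p)
  elig <- sites < x_c - p$L_c / 2 | sites > x_c + p$L_c / 2
  counts <- table(factor(round(xs / p$a - 0.5),
                         levels = round(sites[elig] / p$a - 0.5)))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("interaction durations are exponential with the hydrolysis rate", {
  p <- p_fast(k_h = 0.1, t_min = 0)
  rec <- run_one_particle(p, n_interactions = 2000, seed = 4)
  expect_true(all(rec$t_i > 0))
  expect_true(all(is.finite(rec$f_int)))
  expect_equal(rec$f_i * rec$t_i, rec$f_int, tolerance = 1e-12)
  # rate recovered within 5%
  expect_equal(1 / mean(rec$t_i), 0.1, tolerance = 0.05)
  expect_gt(stats::ks.test(rec$t_i, "pexp", rate = 0.1)$p.value, 0.01)
})

test_that("with all removal rates zero the bound count never decreases", {
  p <- p_fast(k_h = 0, k_off = 0, t_min = 0, N_total = 30)
  tr <- suppressWarnings(run_dynamic(p, t_end = 150, seed = 6, record_dt = 1))
  nucleoid_or_bound <- tr$n_bound + tr$n_nucleoid
  expect_true(all(diff(nucleoid_or_bound) >= 0))
  expect_true(all(diff(tr$n_bound) >= 0))
})

test_that("k_off turnover balances attachment in steady state", {
  p <- p_fast(ka0 = 0, k_off = 0.2, t_min = 0)
  st <- run_stationary(p, 1.26, t_end = 2000, seed = 8, burn_in = 200)
  # global balance: k_on <N_cyto> (L-L_c)/L = k_off <N_free>
  ncy <- p$N_total - st$n_free
  lhs <- p$k_on * ncy * (p$L - p$L_c) / p$L
  expect_equal(lhs, p$k_off * st$n_free, tolerance = 0.1)
  # mean nucleoid residence = 1/k_off from the event counters
  expect_equal(st$T * st$n_free / st$events$k_off, 1 / p$k_off,
               tolerance = 0.1)
})

test_that("a null-event rate leaves the summary statistics unchanged", {
  p0 <- p_fast(t_min = 0)
  get_stats <- function(lam, seed) {
    p <- pom_update(p0, lambda_null = lam)
    st <- run_stationary(p, 0.76, t_end = 600, seed = seed, burn_in = 150)
    c(st$n_bound, st$n_free)
  }
  s0 <- rowMeans(sapply(1:4, function(s) get_stats(0, s)))
  s1 <- rowMeans(sapply(1:4, function(s) get_stats(5000, 100 + s)))
  expect_equal(s1[1], s0[1], tolerance = 0.15)
  expect_equal(s1[2], s0[2], tolerance = 0.15)
})

test_that("mirrored initial conditions give mirrored ensemble trajectories", {
  p <- p_fast(t_min = 120)
  n <- 10
  m1 <- rowMeans(sapply(1:n, function(r)
    suppressWarnings(run_dynamic(p, 400, seed = 20 + r, record_dt = 20,
                                 x_c0 = p$L_c / 2))$x_c))
  m2 <- rowMeans(sapply(1:n, function(r)
    suppressWarnings(run_dynamic(p, 400, seed = 50 + r, record_dt = 20,
                                 x_c0 = p$L - p$L_c / 2))$x_c))
  # the mirror of the right-start ensemble should match the left-start one
  expect_lt(max(abs(m1 - (p$L - m2))), 0.25)
})

test_that("one-particle records show attachment stretched toward the cluster", {
  p <- p_fine()
  rec <- run_one_particle(p, n_interactions = 1500, seed = 9)
  est <- estimate_C(rec, p$k_h, n_boot = 200)
  # right-side arrivals bind reaching over toward the cluster on average
  expect_gt(est$dx0, 0)
  # and impart a net force toward their arrival side
  expect_gt(est$C, 0)
})

test_that("friction assay with no tethers recovers the bare cytosolic drag", {
  p <- p_fast(t_min = 0)
  fv <- run_friction_assay(p, N_bound = 0, F_ext_list = c(0.005, 0.01, 0.02),
                           n_runs = 2, seed = 1, t_end = 40, burn_in = 5)
  expect_equal(fv$velocity, fv$F_ext / p$gamma_c, tolerance = 1e-10)
  fit <- suppressWarnings(force_velocity_fit(fv))
  expect_equal(fit$gamma, p$gamma_c, tolerance = 1e-8)
})
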