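test_that("cluster binding rate is the spring-Boltzmann-weighted scale", {
  p <- pom_params()
  expect_equal(cluster_binding_rate(1, 1, p), p$ka0)
  d <- sqrt(2 * p$kBT / p$k)
  expect_equal(cluster_binding_rate(0, d, p), p$ka0 * exp(-1))
  expect_equal(cluster_binding_rate(0, d, p), cluster_binding_rate(0, -d, p))
  # far dimer: total rate over all cluster sites is a Gaussian tail
  xc <- p$L / 2
  sites <- pomsim:::cluster_sites(p, xc)
  far <- xc + p$L_c / 2 + 12 * sqrt(p$kBT / p$k)
  expect_lt(sum(cluster_binding_rate(far, sites, p)), 1e-6 * p$ka0)
})

test_that("hopping satisfies detailed balance exactly", {
  p <- pom_params()
  eps_n <- p$D_nuc / p$a^2
  expect_equal(hop_rate(0.03, 0.03, "nucleoid", p), eps_n)
  expect_equal(hop_rate(NA, NA, "free", p), eps_n)
  set.seed(1)
  for (i in 1:50) {
    s1 <- runif(1, -0.1, 0.1); s2 <- s1 + sample(c(-1, 1), 1) * p$a
    ch <- sample(c("nucleoid", "cluster"), 1)
    fw <- hop_rate(s1, s2, ch, p); bw <- hop_rate(s2, s1, ch, p)
    eps0 <- switch(ch, nucleoid = p$D_nuc, cluster = p$D_clu) / p$a^2
    expect_equal(fw * bw, eps0^2, tolerance = 1e-12)
    dE <- p$k * (s2^2 - s1^2) / 2
    expect_equal(fw / bw, exp(-dE / p$kBT), tolerance = 1e-12)
  }
})

test_that("nucleoid attachment propensity matches the accessible fraction", {
  p <- pom_params()
  expect_equal(attachment_propensity(0, p), 0)
  expect_equal(attachment_propensity(10, p), 10 * p$k_on * (p$L - p$L_c) / p$L)
  tiny <- pom_params(L = 5, L_c = 0.01, a = 0.01)
  expect_equal(attachment_propensity(1, tiny) / tiny$k_on, 1, tolerance = 0.01)
  expect_error(attachment_propensity(1, pom_params(L = 5, L_c = 5)),
               "no eligible")
})

test_that("closed-form cluster advance matches its analytic limits", {
  p <- pom_params()
  expect_equal(advance_cluster(2.5, 1, numeric(0), numeric(0), p), 2.5)
  # one bound dimer: stretch decays exponentially
  s0 <- 0.05
  dt <- 0.05
  x1 <- advance_cluster(2.5, dt, offsets = 0, x_nuc = 2.5 - s0, p)
  s1 <- (x1 + 0) - (2.5 - s0)
  expect_equal(s1, s0 * exp(-p$k * dt / p$gamma_c), tolerance = 1e-9)
  # external force on a free cluster: uniform drift
  pf <- pom_params(F_ext = 0.02)
  expect_equal(advance_cluster(1, 2, numeric(0), numeric(0), pf),
               1 + 0.02 * 2 / pf$gamma_c)
})

test_that("closed-form advance agrees with fine-step Euler integration", {
  p <- pom_params()
  set.seed(2)
  for (rep in 1:8) {
    n <- sample(1:4, 1)
    off <- runif(n, -p$L_c / 2, p$L_c / 2)
    xn <- runif(n, 2, 3)
    x0 <- runif(1, 2, 3)
    dt <- runif(1, 0.01, 0.3)
    Fx <- sample(c(0, 0.01), 1)
    pp <- pom_update(p, F_ext = Fx)
    exact <- advance_cluster(x0, dt, off, xn, pp)
    # fine-step Euler oracle
    nsub <- 1e5
    x <- x0; h <- dt / nsub
    cBo <- sum(off) - sum(xn)
    for (i in seq_len(nsub))
      x <- x + h * (-pp$k * (n * x + cBo) + Fx) / pp$gamma_c
    expect_equal(exact, x, tolerance = 1e-6)
  }
})

test_that("gillespie waiting time follows the exponential law", {
  expect_equal(gillespie_waiting_time(10, xi = 1), 0)
  expect_error(gillespie_waiting_time(0), "absorbing")
  set.seed(3)
  dts <- replicate(1e5, gillespie_waiting_time(4))
  expect_equal(mean(dts), 1 / 4, tolerance = 0.01)
})
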