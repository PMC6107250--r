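#' Single-dimer force constant from one-particle interaction records
#'
#' The net force on the cluster is proportional to the PomZ flux
#' difference, `F = C * j_diff`, where `C = f / k_h` converts an arrival
#' rate into a force. `f` is the ensemble average of the time-averaged
#' force a single dimer exerts during one cluster interaction, weighting
#' each interaction by its duration: `f = sum(f_int_i) / sum(t_i)`.
#' Equivalently `C` is the mean time-integrated force per interaction,
#' `C ~ mean(f_int_i)`, because the mean interaction time converges to
#' `1/k_h`. Both estimators are returned with nonparametric bootstrap
#' standard errors.
#'
#' @param records data frame from [run_one_particle()] with columns
#'   `f_int` (pN s) and `t_i` (s).
#' @param k_h hydrolysis rate used in the runs (1/s).
#' @param n_boot bootstrap resamples for the standard errors.
#' @return A list: `C` (pN s, the `f/k_h` estimator), `C_int` (pN s, the
#'   mean-`f_int` estimator), `f` (pN), `f_int` (pN s, identical to
#'   `C_int`), `dx0` (mean attachment stretch oriented toward the cluster,
#'   `mean(x_nuc - x_clu)` at binding, um: positive when right-side
#'   arrivals bind reaching over towards the cluster; requires a
#'   `dx_attach` column), `se_C`, `se_C_int`, `n`.
#' @export
estimate_C <- function(records, k_h, n_boot = 1000) {
  stopifnot(is.data.frame(records), all(c("f_int", "t_i") %in% names(records)))
  n <- nrow(records)
  if (n == 0) stop("empty interaction record set", call. = FALSE)
  stopifnot(all(records$t_i > 0))
  f <- sum(records$f_int) / sum(records$t_i)
  C_int <- mean(records$f_int)
  boots <- replicate(n_boot, {
    i <- sample.int(n, n, replace = TRUE)
    c(sum(records$f_int[i]) / sum(records$t_i[i]) / k_h,
      mean(records$f_int[i]))
  })
  list(C = f / k_h, C_int = C_int, f = f, f_int = C_int,
       dx0 = if ("dx_attach" %in% names(records)) -mean(records$dx_attach)
             else NA_real_,
       se_C = stats::sd(boots[1, ]), se_C_int = stats::sd(boots[2, ]),
       n = n)
}

#' Effective friction coefficient of the tethered cluster
#'
#' The cluster's cytosolic drag plus the drag contributed by `N` elastic
#' PomZ tethers: `gamma = gamma_c + kBT * N / (D_clu + D_nuc)`. The more
#' tethers, and the less mobile they are, the more the cluster's movement
#' is restricted.
#'
#' @param N number of cluster-bound dimers (may be fractional: a
#'   steady-state mean). Vectorised.
#' @param params a [pom_params()] object.
#' @return Friction coefficient (pN s/um).
#' @examples
#' effective_friction(0, pom_params()) # == gamma_c
#' @export
effective_friction <- function(N, params) {
  stopifnot(all(N >= 0))
  params$gamma_c + params$kBT * N / (params$D_clu + params$D_nuc)
}

#' Predicted mean cluster velocity field
#'
#' The central relation of the semi-analytic theory:
#' `v(x_c) = C * j_diff(x_c) / gamma(x_c)`, with the flux difference and
#' the cluster-bound number `N(x_c)` taken from the stationary RD solution
#' and the friction from [effective_friction()]. Valid in the adiabatic
#' regime where PomZ redistribution is fast compared to cluster motion.
#'
#' @param x_c cluster position(s) (um).
#' @param C force constant (pN s), from [estimate_C()].
#' @param params a [pom_params()] object.
#' @return Velocity (um/s). Vectorised over `x_c`.
#' @export
velocity_field <- function(x_c, C, params) {
  vapply(x_c, function(xc) {
    prof <- solve_stationary(params, xc)
    C * prof$j_diff / effective_friction(prof$N, params)
  }, numeric(1))
}

#' Deterministic approximation of the average cluster trajectory
#'
#' Integrates `dx_c/dt = v(x_c)` with the velocity field of the
#' semi-analytic theory, starting from `x0`. In the adiabatic regime the
#' trajectory approaches midnucleoid monotonically (the velocity vanishes
#' only there in the interior).
#'
#' @param x0 initial cluster position (um).
#' @param t_end integration horizon (s).
#' @param C force constant (pN s).
#' @param params a [pom_params()] object.
#' @param times output times (s); default 200 points over `[0, t_end]`.
#' @param v_fun optional velocity function `v(x_c)` overriding the default
#'   RD-based field (e.g. an interpolant, for speed).
#' @return A data frame with columns `t` and `x_c`.
#' @export
integrate_trajectory <- function(x0, t_end, C, params, times = NULL,
                                 v_fun = NULL) {
  if (is.null(times)) times <- seq(0, t_end, length.out = 200)
  if (is.null(v_fun)) v_fun <- function(x) velocity_field(x, C, params)
  lo <- params$L_c / 2; hi <- params$L - params$L_c / 2
  rhs <- function(t, y, parms) {
    x <- min(max(y[1], lo), hi)
    list(v_fun(x))
  }
  out <- deSolve::ode(c(x = x0), times, rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  data.frame(t = out[, 1], x_c = out[, 2])
}

#' Time-scale criterion for stable midnucleoid positioning
#'
#' Compares the time a PomZ dimer needs to explore the nucleoid,
#' `t_PomZ = L^2 / D_nuc`, with the time the cluster would need to cross
#' it under a fully one-sided inflow,
#' `t_cluster = L * gamma(L/2) / (C * j_right(L/2))`. Stable positioning
#' requires `t_PomZ << t_cluster`; the package operationalises this as
#' `t_PomZ < rho * t_cluster` with a configurable ratio (default 0.1) and
#' reports the dimensionless margin `t_PomZ / t_cluster`, not only the
#' verdict. When the margin is large the PomZ gradient lags the cluster
#' and the cluster overshoots and oscillates around midnucleoid.
#'
#' @param params a [pom_params()] object.
#' @param C force constant (pN s).
#' @param rho stability threshold for the ratio `t_PomZ / t_cluster`.
#' @return A list: `t_PomZ` (s), `t_cluster` (s), `margin`
#'   (`= t_PomZ / t_cluster`), `stable` (logical), `rho`.
#' @examples
#' # slow nucleoid diffusion: t_PomZ = 2.5e5 s for L = 5 um, D = 1e-4
#' timescale_criterion(pom_params(D_nuc = 1e-4), C = 0.006)$t_PomZ
#' @export
timescale_criterion <- function(params, C, rho = 0.1) {
  stopifnot(rho > 0)
  t_PomZ <- params$L^2 / params$D_nuc
  prof <- solve_stationary(params, params$L / 2)
  gam <- effective_friction(prof$N, params)
  j_right <- prof$j_R
  t_cluster <- if (C * j_right > 0) params$L * gam / (C * j_right) else Inf
  margin <- t_PomZ / t_cluster
  list(t_PomZ = t_PomZ, t_cluster = t_cluster, margin = margin,
       stable = margin < rho, rho = rho)
}
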