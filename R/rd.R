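#' Reaction-diffusion parameters derived from the stochastic model
#'
#' The stationary reaction-diffusion (RD) description replaces the elastic
#' binding kinetics by a uniform aggregate binding rate inside the cluster
#' footprint `I_c = [x_c - L_c/2, x_c + L_c/2]`:
#' `k_a_total = (ka0 / a) * sqrt(2 pi kBT / k)`, the continuum limit of the
#' lattice sum of spring-weighted per-site binding rates, so that the RD
#' and stochastic modules describe the same physics. Doubly-bound dimers
#' diffuse with `D_b = 0.5 * D_nuc`.
#'
#' @param params a [pom_params()] object.
#' @return The parameter list with `D_b` and `k_a_total` added, classed
#'   `pom_rd_params`.
#' @export
rd_params <- function(params) {
  stopifnot(inherits(params, "pom_params"))
  p <- unclass(params)
  p$D_b <- 0.5 * p$D_nuc
  p$k_a_total <- if (p$k > 0) p$ka0 / p$a * sqrt(2 * pi * p$kBT / p$k) else Inf
  class(p) <- c("pom_rd_params", "pom_params")
  p
}

as_rd <- function(params) {
  if (inherits(params, "pom_rd_params")) params else rd_params(params)
}

#' Stationary reaction-diffusion profile for a fixed cluster position
#'
#' Solves the time-independent RD system for the nucleoid-only density
#' `c(x)` and the doubly-bound density `c_b(x)`: outside the cluster
#' footprint, diffusion with a uniform cytosolic attachment source (and
#' optional detachment `k_off`); inside, diffusion with aggregate cluster
#' binding `k_a_total`; `c_b` diffuses with `D_b`, gains `k_a_total c` and
#' loses `k_h c_b`. Boundary conditions: no flux at the nucleoid ends for
#' `c` and at the cluster edges for `c_b`; `c` and its flux are continuous
#' at the cluster edges. The cytosolic pool is closed self-consistently by
#' total particle number conservation. The solution is an exact piecewise
#' closed form (cosh/sinh inside, quadratic or cosh outside) obtained from
#' a 4x4 linear matching system; [rd_time_march()] provides an independent
#' finite-difference cross-check.
#'
#' @param params a [pom_params()] or [rd_params()] object.
#' @param x_c cluster position (um), in `[L_c/2, L - L_c/2]`.
#' @return A `pom_rd_profile` list: grid `x` (lattice cell centres), `c`,
#'   `c_b` (1/um), `j = -D_nuc dc/dx` on the same grid (1/s), `N_cyto`,
#'   `N` (cluster-bound number), one-sided edge inflows `j_R`, `j_L` (both
#'   >= 0 in normal regimes) and `j_diff = j_R - j_L`, plus closures
#'   `c_fun`, `cp_fun`, `cb_fun` for pointwise evaluation.
#' @examples
#' prof <- solve_stationary(pom_params(), x_c = 1)
#' prof$j_diff
#' @export
solve_stationary <- function(params, x_c) {
  p <- as_rd(params)
  h <- p$L_c / 2
  if (!(x_c >= h - 1e-9 && x_c <= p$L - h + 1e-9))
    stop("x_c must lie in [L_c/2, L - L_c/2]", call. = FALSE)
  D <- p$D_nuc
  ka <- p$k_a_total
  if (ka > 0 && p$k_h <= 0)
    stop(paste("singular stationary system: k_h = 0 with k_a_total > 0",
               "admits no steady state with finite bound number"),
         call. = FALSE)
  if (D <= 0) stop("D_nuc must be > 0 for the RD solution", call. = FALSE)
  if (ka == 0 && p$k_off == 0) {
    # free-diffusion limit: every dimer ends on the nucleoid, the density is
    # uniform and fluxless, and nothing binds the cluster
    xg <- nucleoid_sites(p)
    c0 <- if (p$k_on > 0) p$N_total / p$L else 0
    N_cyto <- if (p$k_on > 0) 0 else p$N_total
    return(structure(list(
      x = xg, c = rep(c0, length(xg)), c_b = rep(0, length(xg)),
      j = rep(0, length(xg)), N_cyto = N_cyto, N = 0,
      j_R = 0, j_L = 0, j_diff = 0, x_c = x_c, params = p,
      c_fun = function(x) rep(c0, length(x)),
      cp_fun = function(x) rep(0, length(x)),
      cb_fun = function(x) rep(0, length(x))),
      class = "pom_rd_profile"))
  }

  xl <- x_c - h; xr <- x_c + h
  s0 <- p$k_on / p$L              # source density per unit N_cyto
  q2 <- (ka + p$k_off) / D
  q <- sqrt(q2)
  # unknowns: (AL, AR, P, Q) with
  #  left:  c = base_L(x) + AL * phiL(x)
  #  right: c = base_R(x) + AR * phiR(x)
  #  inside: c = P cosh(q(x - x_c)) + Q sinh(q(x - x_c))  (or P + Q u if q=0)
  # basis functions are normalised to 1 at the matching edges so the linear
  # system stays well conditioned for strong absorption (large q L_c) and
  # fast detachment (large mu L)
  if (p$k_off > 0) {
    mu <- sqrt(p$k_off / D)
    base_L <- function(x) rep(s0 / p$k_off, length(x))
    base_Lp <- function(x) rep(0, length(x))
    phiL <- function(x) exp(mu * (x - xl)) * (1 + exp(-2 * mu * x)) /
      (1 + exp(-2 * mu * xl))                      # cosh(mu x)/cosh(mu xl)
    phiLp <- function(x) mu * phiL(x) * tanh(mu * x)
    base_R <- base_L; base_Rp <- base_Lp
    phiR <- function(x) exp(mu * (xr - x)) * (1 + exp(-2 * mu * (p$L - x))) /
      (1 + exp(-2 * mu * (p$L - xr)))
    phiRp <- function(x) -mu * phiR(x) * tanh(mu * (p$L - x))
  } else {
    base_L <- function(x) -s0 * x^2 / (2 * D)
    base_Lp <- function(x) -s0 * x / D
    phiL <- function(x) rep(1, length(x))
    phiLp <- function(x) rep(0, length(x))
    base_R <- function(x) -s0 * (p$L - x)^2 / (2 * D)
    base_Rp <- function(x) s0 * (p$L - x) / D
    phiR <- function(x) rep(1, length(x))
    phiRp <- function(x) rep(0, length(x))
  }
  if (q > 0) {
    # b1 = cosh(qu)/cosh(qh), b2 = sinh(qu)/sinh(qh); both in [-1, 1] on I_c
    b1 <- function(u) exp(q * (abs(u) - h)) * (1 + exp(-2 * q * abs(u))) /
      (1 + exp(-2 * q * h))
    b2 <- function(u) sign(u) * exp(q * (abs(u) - h)) *
      (1 - exp(-2 * q * abs(u))) / (1 - exp(-2 * q * h))
    T_q <- tanh(q * h); K_q <- 1 / T_q
    fI <- function(u) cbind(b1(u), b2(u))
    # b1' = q tanh(qh) b2, b2' = q coth(qh) b1
    fIp <- function(u) cbind(q * T_q * b2(u), q * K_q * b1(u))
  } else {
    fI <- function(u) cbind(rep(1, length(u)), u)
    fIp <- function(u) cbind(rep(0, length(u)), rep(1, length(u)))
  }
  # matching: continuity of c and c' at xl and xr
  A <- matrix(0, 4, 4); b <- numeric(4)
  Il <- fI(-h); Ilp <- fIp(-h); Ir <- fI(h); Irp <- fIp(h)
  A[1, ] <- c(phiL(xl), 0, -Il[1], -Il[2]);  b[1] <- -base_L(xl)
  A[2, ] <- c(phiLp(xl), 0, -Ilp[1], -Ilp[2]); b[2] <- -base_Lp(xl)
  A[3, ] <- c(0, phiR(xr), -Ir[1], -Ir[2]);  b[3] <- -base_R(xr)
  A[4, ] <- c(0, phiRp(xr), -Irp[1], -Irp[2]); b[4] <- -base_Rp(xr)
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("singular matching system for the stationary RD profile: ",
         conditionMessage(e), call. = FALSE))
  AL <- sol[1]; AR <- sol[2]; P <- sol[3]; Q <- sol[4]

  piecewise <- function(x, fl, fm, fr) {
    out <- numeric(length(x))
    iL <- x < xl; iR <- x > xr; iM <- !iL & !iR
    if (any(iL)) out[iL] <- fl(x[iL])
    if (any(iM)) out[iM] <- fm(x[iM])
    if (any(iR)) out[iR] <- fr(x[iR])
    out
  }
  c_hat <- function(x) piecewise(x,
    function(z) base_L(z) + AL * phiL(z),
    function(z) as.numeric(fI(z - x_c) %*% c(P, Q)),
    function(z) base_R(z) + AR * phiR(z))
  cp_hat <- function(x) piecewise(x,
    function(z) base_Lp(z) + AL * phiLp(z),
    function(z) as.numeric(fIp(z - x_c) %*% c(P, Q)),
    function(z) base_Rp(z) + AR * phiRp(z))

  # doubly-bound density inside I_c (per unit N_cyto)
  m2 <- if (p$D_b > 0) p$k_h / p$D_b else Inf
  if (ka > 0) {
    if (!is.finite(m2))
      stop("D_b = 0 with k_a_total > 0: c_b has no diffusive profile",
           call. = FALSE)
    m <- sqrt(m2)
    dq <- m2 - q2
    if (abs(dq) < 1e-10 * max(m2, q2)) dq <- sign(dq + 1e-300) * 1e-10 * max(m2, q2)
    alpha <- ka / (p$D_b * dq)
    # homogeneous basis normalised at the edges, like b1/b2
    g1 <- function(u) exp(m * (abs(u) - h)) * (1 + exp(-2 * m * abs(u))) /
      (1 + exp(-2 * m * h))
    g2 <- function(u) sign(u) * exp(m * (abs(u) - h)) *
      (1 - exp(-2 * m * abs(u))) / (1 - exp(-2 * m * h))
    T_m <- tanh(m * h); K_m <- 1 / T_m
    Rh <- -alpha * q * P * T_q / (m * T_m)
    Sh <- -alpha * q * Q * K_q / (m * K_m)
    cb_hat <- function(x) {
      u <- x - x_c
      out <- numeric(length(x))
      i <- abs(u) <= h + 1e-12
      if (any(i))
        out[i] <- alpha * (P * b1(u[i]) + Q * b2(u[i])) +
          Rh * g1(u[i]) + Sh * g2(u[i])
      out
    }
    int_cb <- 2 * alpha * P * T_q / q + 2 * Rh * T_m / m
  } else {
    cb_hat <- function(x) rep(0, length(x))
    int_cb <- 0
  }

  # closure by total particle number; closed-form integrals of each piece
  if (p$k_off > 0) {
    int_left <- s0 / p$k_off * xl + AL * tanh(mu * xl) / mu
    int_right <- s0 / p$k_off * (p$L - xr) + AR * tanh(mu * (p$L - xr)) / mu
  } else {
    int_left <- AL * xl - s0 * xl^3 / (6 * D)
    int_right <- AR * (p$L - xr) - s0 * (p$L - xr)^3 / (6 * D)
  }
  int_inside <- if (q > 0) 2 * P * T_q / q else 2 * P * h
  int_c <- int_left + int_inside + int_right
  N_cyto <- p$N_total / (1 + int_c + int_cb)

  xg <- nucleoid_sites(p)
  c_g <- as.numeric(c_hat(xg)) * N_cyto
  cb_g <- as.numeric(cb_hat(xg)) * N_cyto
  j_g <- -D * as.numeric(cp_hat(xg)) * N_cyto
  j_R <- D * as.numeric(cp_hat(xr)) * N_cyto
  j_L <- -D * as.numeric(cp_hat(xl)) * N_cyto
  structure(list(
    x = xg, c = c_g, c_b = cb_g, j = j_g,
    N_cyto = N_cyto, N = int_cb * N_cyto,
    j_R = j_R, j_L = j_L, j_diff = j_R - j_L,
    x_c = x_c, params = p,
    c_fun = function(x) as.numeric(c_hat(x)) * N_cyto,
    cp_fun = function(x) as.numeric(cp_hat(x)) * N_cyto,
    cb_fun = function(x) as.numeric(cb_hat(x)) * N_cyto),
    class = "pom_rd_profile")
}

#' @export
print.pom_rd_profile <- function(x, ...) {
  cat("Stationary RD profile\n")
  cat(sprintf("  x_c = %g um; N_cyto = %.4g; cluster-bound N = %.4g\n",
              x$x_c, x$N_cyto, x$N))
  cat(sprintf("  edge inflows j_R = %.4g, j_L = %.4g 1/s; j_diff = %.4g 1/s\n",
              x$j_R, x$j_L, x$j_diff))
  invisible(x)
}

#' PomZ flux difference into the cluster
#'
#' The difference between the one-sided diffusive inflows of nucleoid-bound
#' PomZ at the two cluster edges, `j_diff = j_R - j_L`, evaluated from the
#' stationary RD solution. Positive when the cluster sits left of
#' midnucleoid (larger inflow from the longer right side); antisymmetric
#' about midnucleoid.
#'
#' @inheritParams solve_stationary
#' @return `j_diff` (1/s). Vectorised over `x_c`.
#' @export
flux_difference <- function(params, x_c) {
  vapply(x_c, function(xc) solve_stationary(params, xc)$j_diff, numeric(1))
}

#' Cluster-bound dimer number from the RD steady state
#'
#' Integral of the doubly-bound density over the cluster footprint; the
#' steady state satisfies `k_a_total * int(c) = k_h * N(x_c)` over the
#' footprint.
#'
#' @inheritParams solve_stationary
#' @return `N(x_c)`. Vectorised over `x_c`.
#' @export
bound_count <- function(params, x_c) {
  vapply(x_c, function(xc) solve_stationary(params, xc)$N, numeric(1))
}

#' Time-marched finite-difference solution of the RD system
#'
#' Independent numerical route to the stationary profile: method-of-lines
#' discretisation of the full time-dependent RD system (cell-centred grid,
#' no-flux boundaries, conservative fluxes) integrated to a long time with
#' a stiff ODE solver. Used to validate [solve_stationary()].
#'
#' @inheritParams solve_stationary
#' @param t_final integration time (s); should exceed the slowest
#'   relaxation time, roughly `L^2/D_nuc` and `1/k_on`.
#' @param nx number of grid cells (default: the lattice resolution).
#' @return A list with `x`, `c`, `c_b`, `N_cyto`, `N`.
#' @export
rd_time_march <- function(params, x_c, t_final = NULL, nx = NULL) {
  p <- as_rd(params)
  h <- p$L_c / 2
  if (is.null(nx)) nx <- round(p$L / p$a)
  dx <- p$L / nx
  x <- dx * (seq_len(nx) - 0.5)
  inside <- x > x_c - h & x < x_c + h
  outside <- !inside
  # footprint measure as resolved by the grid; keeps the source and the
  # cytosol sink exactly consistent (conservative) even when the cluster
  # edges do not fall on cell faces
  Lc_eff <- sum(inside) * dx
  if (is.null(t_final))
    t_final <- 20 * max(p$L^2 / p$D_nuc,
                        1 / max(p$k_on, 1e-6),
                        1 / max(p$k_h, 1e-6))
  lap <- function(u, D) {
    # conservative no-flux Laplacian on the cell-centred grid
    flux <- D * diff(u) / dx           # at interior faces
    (c(flux, 0) - c(0, flux)) / dx
  }
  inside_idx <- which(inside)
  rhs <- function(t, y, parms) {
    cc <- y[seq_len(nx)]
    cb <- y[nx + seq_len(nx)]
    Nc <- y[2 * nx + 1]
    dc <- lap(cc, p$D_nuc)
    dc[outside] <- dc[outside] + p$k_on * Nc / p$L
    dc <- dc - p$k_off * cc
    dc[inside] <- dc[inside] - p$k_a_total * cc[inside]
    dcb <- numeric(nx)
    if (length(inside_idx) > 1) {
      ui <- cb[inside_idx]
      fi <- p$D_b * diff(ui) / dx
      dcb[inside_idx] <- (c(fi, 0) - c(0, fi)) / dx
    }
    dcb[inside] <- dcb[inside] + p$k_a_total * cc[inside] - p$k_h * cb[inside]
    dNc <- p$k_h * sum(cb) * dx + p$k_off * sum(cc) * dx -
      p$k_on * Nc * (p$L - Lc_eff) / p$L
    list(c(dc, dcb, dNc))
  }
  y0 <- c(rep(0, 2 * nx), p$N_total)
  out <- deSolve::ode(y0, times = c(0, t_final), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  yf <- unname(out[nrow(out), -1])
  list(x = x, c = yf[seq_len(nx)], c_b = yf[nx + seq_len(nx)],
       N_cyto = yf[2 * nx + 1],
       N = sum(yf[nx + seq_len(nx)]) * dx)
}
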