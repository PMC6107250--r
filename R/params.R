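#' Model parameters for the flux-based positioning model
#'
#' Collects all physical rates, geometry and constants shared by the
#' stochastic engine, the reaction-diffusion solver and the semi-analytical
#' theory. All lengths are in micrometres, times in seconds, forces in
#' piconewtons.
#'
#' The defaults are the package baseline. Anchored values: lattice spacing
#' `a = 0.01` um, cluster length `L_c = 0.7` um, nucleoid length `L = 5` um,
#' `N_total = 100` PomZ dimers, equilibration time `t_min = 600` s, and a
#' hydrolysis rate `k_h = 1` 1/s (the combined ATP-hydrolysis/release rate of
#' cluster-bound dimers, which together with the single-dimer force sets the
#' force constant of the mechanism). See the methods vignette for how the
#' remaining rates were fixed.
#'
#' @param L nucleoid length (um).
#' @param L_c PomXY cluster length (um); must not exceed `L` unless
#'   `infinite_lattice = TRUE`.
#' @param a lattice spacing (um). Must divide both `L` and `L_c` to within
#'   one part in 1e6.
#' @param k spring stiffness of a PomZ tether (pN/um). Models the combined
#'   elasticity of the chromosome and the dimer.
#' @param kBT thermal energy (pN um); default 4.1e-3 (298 K).
#' @param k_on attachment rate scale of a cytosolic dimer to the nucleoid
#'   (1/s). The realised per-dimer rate is `k_on * (L - L_c)/L` because the
#'   nucleoid under the cluster footprint is not available for attachment.
#' @param ka0 per-cluster-site binding rate scale of a nucleoid-bound dimer
#'   (1/s); the realised rate per site carries the spring Boltzmann factor.
#' @param k_h hydrolysis/detachment rate of cluster-bound dimers (1/s).
#' @param k_off optional detachment rate of nucleoid-only dimers (1/s,
#'   default 0: in the core model dimers leave the nucleoid only via the
#'   cluster).
#' @param D_nuc diffusion coefficient of PomZ on the nucleoid (um^2/s).
#' @param D_clu diffusion coefficient of cluster-bound PomZ along the
#'   cluster (um^2/s).
#' @param gamma_c cytosolic friction coefficient of the cluster (pN s/um);
#'   the cluster's cytosolic diffusivity is `kBT/gamma_c`.
#' @param N_total total number of PomZ dimers.
#' @param t_min equilibration time with the cluster frozen (s).
#' @param infinite_lattice if `TRUE`, both lattices are unbounded (friction
#'   assay geometry); positional boundary checks are skipped.
#' @param F_ext constant external force on the cluster (pN, default 0).
#' @param lambda_null optional null-event rate (1/s) added to the total
#'   propensity; the null event does nothing but shortens Gillespie steps,
#'   bounding the error of freezing position-dependent rates between events.
#'
#' @return An object of class `pom_params` (a validated named list).
#' @examples
#' p <- pom_params()
#' p$k_h
#' @export
pom_params <- function(L = 5, L_c = 0.7, a = 0.01,
                       k = 25, kBT = 4.1e-3,
                       k_on = 0.01, ka0 = 50, k_h = 1, k_off = 0,
                       D_nuc = 0.3, D_clu = 0.3,
                       gamma_c = 1.0,
                       N_total = 100, t_min = 600,
                       infinite_lattice = FALSE, F_ext = 0,
                       lambda_null = 0) {
  p <- list(L = L, L_c = L_c, a = a, k = k, kBT = kBT,
            k_on = k_on, ka0 = ka0, k_h = k_h, k_off = k_off,
            D_nuc = D_nuc, D_clu = D_clu, gamma_c = gamma_c,
            N_total = N_total, t_min = t_min,
            infinite_lattice = isTRUE(infinite_lattice), F_ext = F_ext,
            lambda_null = lambda_null)
  validate_pom_params(p)
}

validate_pom_params <- function(p) {
  num_fields <- c("L", "L_c", "a", "k", "kBT", "k_on", "ka0", "k_h", "k_off",
                  "D_nuc", "D_clu", "gamma_c", "N_total", "t_min", "F_ext",
                  "lambda_null")
  errs <- character()
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      errs <- c(errs, sprintf("'%s' must be a single finite number", f))
  }
  if (length(errs) == 0L) {
    nonneg <- setdiff(num_fields, "F_ext")
    for (f in nonneg) if (p[[f]] < 0)
      errs <- c(errs, sprintf("'%s' must be >= 0 (all rates and lengths are non-negative)", f))
    if (p$a <= 0) errs <- c(errs, "'a' must be > 0")
    if (p$kBT <= 0) errs <- c(errs, "'kBT' must be > 0")
    if (p$gamma_c <= 0) errs <- c(errs, "'gamma_c' must be > 0")
    if (!p$infinite_lattice) {
      if (p$L_c > p$L)
        errs <- c(errs, "'L_c' must not exceed 'L' on a finite nucleoid")
      if (!divides_within(p$L, p$a))
        errs <- c(errs, "'a' must divide 'L' to within one part in 1e6")
    }
    if (!divides_within(p$L_c, p$a))
      errs <- c(errs, "'a' must divide 'L_c' to within one part in 1e6")
    if (abs(p$N_total - round(p$N_total)) > 1e-9)
      errs <- c(errs, "'N_total' must be an integer count")
  }
  if (length(errs))
    stop("invalid model parameters:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  p$N_total <- as.integer(round(p$N_total))
  class(p) <- "pom_params"
  p
}

divides_within <- function(len, a, tol = 1e-6) {
  n <- len / a
  abs(n - round(n)) <= tol * max(1, abs(n))
}

#' @export
print.pom_params <- function(x, ...) {
  cat("Flux-based positioning model parameters\n")
  cat(sprintf("  nucleoid L = %g um, cluster L_c = %g um, lattice a = %g um%s\n",
              x$L, x$L_c, x$a,
              if (x$infinite_lattice) " (infinite-lattice mode)" else ""))
  cat(sprintf("  spring k = %g pN/um, kBT = %g pN um\n", x$k, x$kBT))
  cat(sprintf("  rates: k_on = %g, ka0 = %g, k_h = %g, k_off = %g [1/s]\n",
              x$k_on, x$ka0, x$k_h, x$k_off))
  cat(sprintf("  diffusion: D_nuc = %g, D_clu = %g um^2/s; gamma_c = %g pN s/um\n",
              x$D_nuc, x$D_clu, x$gamma_c))
  cat(sprintf("  N_total = %d, t_min = %g s, F_ext = %g pN\n",
              x$N_total, x$t_min, x$F_ext))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params a [pom_params()] object.
#' @param ... named fields to override.
#' @return A new `pom_params` object.
#' @examples
#' p <- pom_update(pom_params(), k_h = 0.1)
#' @export
pom_update <- function(params, ...) {
  stopifnot(inherits(params, "pom_params"))
  mods <- list(...)
  if (length(mods)) {
    bad <- setdiff(names(mods), names(unclass(params)))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  }
  validate_pom_params(unclass(params))
}

# Nucleoid lattice site centres: a*(i + 1/2), i = 0..L/a-1.
nucleoid_sites <- function(params) {
  n <- round(params$L / params$a)
  params$a * (seq_len(n) - 0.5)
}

# Cluster lattice site centres for a cluster at x_c.
cluster_sites <- function(params, x_c) {
  n <- round(params$L_c / params$a)
  x_c - params$L_c / 2 + params$a * (seq_len(n) - 0.5)
}
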