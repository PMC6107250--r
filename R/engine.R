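#' Dynamic-cluster simulation
#'
#' Runs the full coupled stochastic dynamics: PomZ dimers attach to the
#' nucleoid, diffuse, bind the cluster through their elastic tether,
#' hydrolyse ATP and recycle through the cytosol, while the cluster moves
#' overdamped under the summed tether forces. All dimers start cytosolic;
#' the cluster is held at its initial position for `t_min` seconds so the
#' PomZ distribution can equilibrate, then released. By default the cluster
#' starts with its left edge at the left nucleoid edge (`x_c = L_c/2`).
#'
#' @param params a [pom_params()] object.
#' @param t_end simulated time after release (s).
#' @param seed integer RNG seed; recorded in the result.
#' @param record_dt sampling interval of the trajectory (s).
#' @param x_c0 initial cluster position (um); default `L_c/2`.
#' @param condition optional position window for conditioned profile
#'   accumulation: a list with `target`, `enter_tol`, `exit_tol` (um); see
#'   [conditioned_profiles()] which drives this.
#' @param n_log number of initial events to log (`t`, `dt`, `alpha`) for
#'   diagnostics of the waiting-time law; 0 disables.
#' @return A `pom_trajectory`: a data frame with columns `t` (s, 0 at
#'   release; negative during equilibration), `x_c` (um), `n_bound`,
#'   `n_nucleoid`, `n_cyto`, with the parameters, seed and excursion time
#'   (time spent with the cluster centre outside `[L_c/2, L - L_c/2]`,
#'   which is logged rather than clamped) as attributes.
#' @examples
#' \donttest{
#' p <- pom_params(L = 2.5, L_c = 0.35, a = 0.02, t_min = 60)
#' tr <- run_dynamic(p, t_end = 120, seed = 1)
#' tail(tr)
#' }
#' @export
run_dynamic <- function(params, t_end, seed, record_dt = 1,
                        x_c0 = NULL, condition = NULL, n_log = 0L) {
  stopifnot(inherits(params, "pom_params"), t_end > 0, record_dt > 0)
  if (is.null(x_c0)) x_c0 <- params$L_c / 2
  set.seed(as.integer(seed))
  res <- cpp_run_dynamic(unclass(params), t_end, record_dt, x_c0,
                         condition, as.integer(n_log))
  traj <- data.frame(t = res$t - params$t_min, x_c = res$x_c,
                     n_bound = res$n_bound, n_nucleoid = res$n_nucleoid,
                     n_cyto = res$n_cyto)
  if (res$excursion_time > 0)
    warning(sprintf("cluster centre outside [L_c/2, L - L_c/2] for %.3g s",
                    res$excursion_time))
  structure(traj,
            params = params, seed = as.integer(seed),
            excursion_time = res$excursion_time,
            profiles = res$profiles, event_log = res$event_log,
            class = c("pom_trajectory", "data.frame"))
}

#' Stationary-cluster simulation
#'
#' The cluster is held fixed at `x_c` and only the PomZ dynamics is
#' simulated. After a burn-in, the run accumulates the time-averaged PomZ
#' occupancy per lattice site (nucleoid binding site for nucleoid-only
#' dimers, cluster binding site for cluster-bound dimers), the net hop flux
#' of nucleoid-only dimers across every interior lattice edge, and the
#' time-averaged total spring force on the cluster.
#'
#' @param params a [pom_params()] object.
#' @param x_c fixed cluster position (um).
#' @param t_end accumulation time (s).
#' @param seed integer RNG seed.
#' @param burn_in equilibration time before accumulation (s); defaults to
#'   `params$t_min`.
#' @param n_log,sample_dt,init_bound diagnostics: event log length, stretch
#'   sampling interval (s; samples the tether stretch of the first bound
#'   dimer), and number of dimers to start doubly bound at the cluster
#'   centre (used by equilibrium checks).
#' @return A `pom_stationary` list: `x` (site centres, um), `c` and `c_b`
#'   (number densities, 1/um), `x_edge` and `j` (net rightward flux of
#'   nucleoid-only dimers at interior edges, 1/s), `force` (time-averaged
#'   spring force on the cluster, pN), `n_bound`, `n_free` (time-averaged
#'   counts), `T` (averaging time), plus any requested diagnostics.
#' @export
run_stationary <- function(params, x_c, t_end, seed, burn_in = NULL,
                           n_log = 0L, sample_dt = 0, init_bound = 0L) {
  stopifnot(inherits(params, "pom_params"), t_end > 0)
  if (!params$infinite_lattice)
    stopifnot(x_c >= params$L_c / 2, x_c <= params$L - params$L_c / 2)
  if (is.null(burn_in)) burn_in <- params$t_min
  set.seed(as.integer(seed))
  res <- cpp_run_stationary(unclass(params), x_c, t_end, burn_in,
                            as.integer(n_log), sample_dt,
                            as.integer(init_bound))
  a <- params$a
  x <- nucleoid_sites(params)
  n <- length(x)
  out <- list(
    x = x,
    c = res$dens_free[seq_len(n)] / (res$T * a),
    c_b = res$dens_bound[seq_len(n)] / (res$T * a),
    x_edge = a * seq_len(n - 1),
    j = res$flux_net[2:n] / res$T,
    force = res$mean_force,
    n_bound = res$mean_bound,
    n_free = res$mean_free,
    T = res$T,
    x_c = x_c, params = params, seed = as.integer(seed),
    events = res$events, final_xn_free = res$final_xn_free)
  if (n_log > 0) out$event_log <- res$event_log
  if (sample_dt > 0) out$stretch_samples <- res$stretch_samples
  class(out) <- "pom_stationary"
  out
}

#' One-particle force simulations
#'
#' A single PomZ dimer interacts repeatedly with a cluster held at
#' midnucleoid. The dimer is injected on the right side of the cluster,
#' just beyond the elastic binding reach, diffuses, binds the cluster,
#' exerts its tether force and is released by hydrolysis, after which it is
#' re-injected. Each cluster interaction yields one record.
#'
#' @param params a [pom_params()] object; `N_total` is forced to 1.
#' @param n_interactions number of complete dimer-cluster interactions to
#'   record.
#' @param seed integer RNG seed.
#' @param inject_gap distance between the right cluster edge and the
#'   injection site (um); defaults to just beyond the binding reach, so the
#'   injected dimer cannot interact with the cluster immediately.
#' @return A data frame of interaction records: `t_attach`, `t_detach`,
#'   `t_i` (interaction duration, s), `f_int` (time-integrated tether force
#'   on the cluster, pN s), `f_i = f_int/t_i` (time-averaged force, pN) and
#'   `dx_attach` (tether stretch at the moment of binding, um).
#' @export
run_one_particle <- function(params, n_interactions, seed,
                             inject_gap = NULL) {
  stopifnot(inherits(params, "pom_params"), n_interactions >= 1)
  params <- pom_update(params, N_total = 1, k_on = 0)
  reach <- if (params$k > 0) sqrt(2 * params$kBT * 27.631021 / params$k)
           else stop("one-particle protocol requires k > 0")
  if (is.null(inject_gap)) inject_gap <- reach + 2 * params$a
  x_c <- params$L / 2
  x_inject <- x_c + params$L_c / 2 + inject_gap
  if (x_inject >= params$L)
    stop("injection site beyond the nucleoid; increase L or reduce inject_gap")
  site <- round(x_inject / params$a - 0.5)
  set.seed(as.integer(seed))
  res <- cpp_run_one_particle(unclass(params), x_c, site,
                              as.integer(n_interactions), Inf)
  t_i <- res$t_detach - res$t_attach
  data.frame(t_attach = res$t_attach, t_detach = res$t_detach,
             t_i = t_i, f_int = res$f_int, f_i = res$f_int / t_i,
             dx_attach = res$dx_attach)
}

#' Friction (force-velocity) assay
#'
#' Measures the effective friction coefficient of the cluster: on
#' infinitely extended nucleoid and cluster lattices, a fixed number of
#' dimers is permanently bound (`k_h = 0`), a constant external force is
#' applied, and the mean steady-state velocity is recorded for each force.
#'
#' @param params a [pom_params()] object; `infinite_lattice`, `k_h = 0`,
#'   `k_on = 0` are forced.
#' @param N_bound number of permanently bound tethering dimers.
#' @param F_ext_list external forces to probe (pN).
#' @param n_runs replicate trajectories per force.
#' @param seed integer base seed; replicate r at force f uses
#'   `seed + 1000*f_index + r`.
#' @param t_end measurement time per trajectory (s).
#' @param burn_in equilibration time before measurement (s).
#' @return A data frame with one row per force: `F_ext`, `velocity` (mean
#'   over runs of the end-to-end velocity, um/s), `se` (standard error over
#'   runs), `n_runs`.
#' @export
run_friction_assay <- function(params, N_bound, F_ext_list, n_runs, seed,
                               t_end = 200, burn_in = 20) {
  stopifnot(inherits(params, "pom_params"), N_bound >= 0, n_runs >= 1)
  rows <- lapply(seq_along(F_ext_list), function(fi) {
    f <- F_ext_list[[fi]]
    p <- pom_update(params, infinite_lattice = TRUE, k_h = 0, k_on = 0,
                    k_off = 0, F_ext = f)
    v <- vapply(seq_len(n_runs), function(r) {
      set.seed(as.integer(seed) + 1000L * fi + r)
      tr <- cpp_run_friction(unclass(p), as.integer(N_bound), t_end,
                             burn_in, t_end, FALSE, 0)
      (tr$x_c[length(tr$x_c)] - tr$x_c[1]) / (tr$t[length(tr$t)] - tr$t[1])
    }, numeric(1))
    data.frame(F_ext = f, velocity = mean(v),
               se = stats::sd(v) / sqrt(n_runs), n_runs = n_runs)
  })
  do.call(rbind, rows)
}

#' Ensemble of dynamic-cluster trajectories
#'
#' Convenience driver: runs `n_runs` replicates of [run_dynamic()] with
#' seeds `seed + (1:n_runs)` and returns them as a list.
#'
#' @inheritParams run_dynamic
#' @param n_runs number of replicate trajectories.
#' @return A list of `pom_trajectory` objects.
#' @export
run_ensemble <- function(params, t_end, n_runs, seed, record_dt = 1,
                         x_c0 = NULL) {
  lapply(seq_len(n_runs), function(r)
    suppressWarnings(run_dynamic(params, t_end, seed = as.integer(seed) + r,
                                 record_dt = record_dt, x_c0 = x_c0)))
}
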