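#' Spring-weighted cluster binding rate
#'
#' Rate with which a nucleoid-bound PomZ dimer at `x_nuc` binds a given
#' cluster lattice site: the bare rate scale `ka0` multiplied by the
#' Boltzmann factor of the spring energy of the resulting tether,
#' `ka0 * exp(-k (x_clu_site - x_nuc)^2 / (2 kBT))`. Symmetric in the sign
#' of the offset; dimers well outside the thermal reach
#' `sqrt(kBT/k)` contribute a Gaussian-tail rate only.
#'
#' @param x_nuc nucleoid binding-site position (um). Vectorised.
#' @param x_clu_site cluster binding-site position (um). Vectorised.
#' @param params a [pom_params()] object.
#' @return Binding rate(s) (1/s).
#' @examples
#' p <- pom_params()
#' cluster_binding_rate(0, 0, p) # == ka0
#' @export
cluster_binding_rate <- function(x_nuc, x_clu_site, params) {
  d <- x_clu_site - x_nuc
  params$ka0 * exp(-params$k * d^2 / (2 * params$kBT))
}

#' Spring-weighted hopping rate
#'
#' Rate of a one-lattice-site hop of either binding site of a dimer. The
#' bare rate is `D/a^2` for the selected channel; for a doubly-bound dimer
#' it is weighted by `exp(-k (s_to^2 - s_from^2) / (4 kBT))` where `s` is
#' the tether stretch `x_clu - x_nuc` before/after the hop. The factor 1/2
#' relative to the full energy difference makes forward and backward rates
#' satisfy detailed balance: their ratio is `exp(-dE/kBT)` with
#' `dE = k (s_to^2 - s_from^2)/2`, and their product is the squared bare
#' rate. For a dimer bound only to the nucleoid no spring energy is defined
#' and the rate is the bare `D_nuc/a^2`.
#'
#' @param stretch_from,stretch_to tether stretch before/after the hop (um);
#'   ignored (may be `NA`) when `channel = "free"`.
#' @param channel `"nucleoid"` or `"cluster"` for the two binding sites of a
#'   doubly-bound dimer, or `"free"` for a nucleoid-only dimer.
#' @param params a [pom_params()] object.
#' @return Hop rate (1/s).
#' @export
hop_rate <- function(stretch_from, stretch_to,
                     channel = c("nucleoid", "cluster", "free"), params) {
  channel <- match.arg(channel)
  a2 <- params$a^2
  if (channel == "free") return(params$D_nuc / a2)
  eps0 <- switch(channel, nucleoid = params$D_nuc, cluster = params$D_clu) / a2
  eps0 * exp(-params$k * (stretch_to^2 - stretch_from^2) / (4 * params$kBT))
}

#' Total nucleoid attachment propensity
#'
#' Aggregate rate with which cytosolic dimers attach anywhere on the
#' nucleoid outside the cluster footprint:
#' `k_on * N_cyto * (L - L_c)/L`. The landing site is uniform over the
#' nucleoid lattice sites outside `[x_c - L_c/2, x_c + L_c/2]` (dimers may
#' subsequently hop into the region beneath the cluster).
#'
#' @param n_cyto number of cytosolic dimers.
#' @param params a [pom_params()] object.
#' @return Attachment propensity (1/s).
#' @export
attachment_propensity <- function(n_cyto, params) {
  if (!params$infinite_lattice && params$L_c >= params$L)
    stop("no eligible attachment site: cluster covers the whole nucleoid",
         call. = FALSE)
  params$k_on * n_cyto * (params$L - params$L_c) / params$L
}

#' Closed-form overdamped cluster advance
#'
#' Between Gillespie events the binding-site assignments are frozen and the
#' cluster obeys `gamma_c dx_c/dt = -k * S + F_ext` with total stretch
#' `S = sum(x_clu_i - x_nuc_i)`. Cluster-bound sites translate rigidly with
#' the cluster, so `S = N x_c + B` with
#' `B = sum(offsets) - sum(x_nuc_i)` constant, and the update is the exact
#' exponential relaxation towards `x_eq = (F_ext/k - B)/N`; the stretch sum
#' relaxes as `S(t) = (S0 - F_ext/k) exp(-N k t / gamma_c) + F_ext/k`.
#' With no bound dimer the motion is uniform drift `F_ext/gamma_c`. No
#' thermal (Langevin) noise acts on the cluster.
#'
#' @param x_c cluster position (um).
#' @param dt time interval (s).
#' @param offsets cluster binding-site offsets `x_clu_i - x_c` of the bound
#'   dimers (um); may be empty.
#' @param x_nuc nucleoid binding-site positions of the same dimers (um).
#' @param params a [pom_params()] object.
#' @return New cluster position (um).
#' @examples
#' p <- pom_params()
#' advance_cluster(2.5, 1, numeric(0), numeric(0), p) # unchanged
#' @export
advance_cluster <- function(x_c, dt, offsets, x_nuc, params) {
  stopifnot(length(offsets) == length(x_nuc), dt >= 0)
  n <- length(offsets)
  if (n == 0L) return(x_c + params$F_ext * dt / params$gamma_c)
  B <- sum(offsets) - sum(x_nuc)
  x_eq <- (params$F_ext / params$k - B) / n
  x_eq + (x_c - x_eq) * exp(-n * params$k * dt / params$gamma_c)
}

#' Gillespie waiting time
#'
#' Draws (or transforms a supplied uniform variate into) the waiting time to
#' the next event, `dt = -log(xi)/alpha`, for total propensity `alpha`.
#'
#' @param alpha total propensity (1/s); must be > 0.
#' @param xi optional uniform(0,1] variate; drawn internally if `NULL`.
#' @return Waiting time (s).
#' @export
gillespie_waiting_time <- function(alpha, xi = NULL) {
  if (alpha <= 0)
    stop("absorbing state: total propensity is zero", call. = FALSE)
  if (is.null(xi)) xi <- stats::runif(1)
  -log(xi) / alpha
}
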