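#' Ensemble statistics of binned cluster trajectories
#'
#' Groups the sampled cluster positions of an ensemble of runs into time
#' bins and returns the per-bin ensemble mean and standard deviation.
#' Default bin width 3.33 min.
#'
#' @param trajectories a list of trajectory data frames with columns `t`
#'   (s) and `x_c` (um); rows with `t < 0` (equilibration) are dropped.
#' @param bin bin width (s).
#' @return A data frame with `t` (bin centre, s), `mean`, `sd`, `n`.
#' @export
binned_trajectory_stats <- function(trajectories, bin = 3.33 * 60) {
  stopifnot(length(trajectories) >= 1, bin > 0)
  tt <- unlist(lapply(trajectories, function(tr) tr$t))
  xx <- unlist(lapply(trajectories, function(tr) tr$x_c))
  keep <- tt >= 0
  tt <- tt[keep]; xx <- xx[keep]
  b <- floor(tt / bin)
  agg <- tapply(xx, b, function(v) c(mean(v), stats::sd(v), length(v)))
  m <- do.call(rbind, agg)
  data.frame(t = (as.numeric(names(agg)) + 0.5) * bin,
             mean = m[, 1], sd = m[, 2], n = m[, 3], row.names = NULL)
}

#' Position-conditioned density and flux profiles
#'
#' Reproduces the recording protocol for profiles at a given cluster
#' position in a moving-cluster simulation: accumulation starts when the
#' cluster enters `target +/- enter_tol` and stops when it leaves
#' `target +/- exit_tol` (defaults 0.2% and 1% of nucleoid length);
#' profiles are averaged over all dwell episodes, weighted by the time
#' spent in the window. Returned in both absolute and cluster-relative
#' coordinates.
#'
#' @param params a [pom_params()] object.
#' @param target_frac target cluster position as a fraction of `L`.
#' @param t_end,n_runs,seed,record_dt simulation settings for the
#'   underlying [run_dynamic()] ensemble.
#' @param enter_tol,exit_tol window half-widths as fractions of `L`.
#' @param x_c0 initial cluster position (um); default `L_c/2`.
#' @return A list: `x`, `c`, `c_b`, `x_edge`, `j` (absolute coordinates);
#'   `x_rel`, `c_rel`, `c_b_rel`, `j_rel` (cluster-relative, 0 = cluster
#'   centre); `dwell` (total conditioning time, s), `episodes`,
#'   `n_bound` (dwell-averaged cluster-bound number). If the window is
#'   never entered, `dwell = 0` and the profiles are `NULL` (flagged, not
#'   NaN-filled).
#' @export
conditioned_profiles <- function(params, target_frac, t_end, n_runs, seed,
                                 record_dt = 1,
                                 enter_tol = 0.002, exit_tol = 0.01,
                                 x_c0 = NULL) {
  stopifnot(inherits(params, "pom_params"),
            exit_tol >= enter_tol, enter_tol > 0)
  cond <- list(target = target_frac * params$L,
               enter_tol = enter_tol * params$L,
               exit_tol = exit_tol * params$L)
  a <- params$a
  n <- round(params$L / a)
  acc <- list(free = numeric(n), bound = numeric(n), flux = numeric(n + 1),
              rfree = numeric(n), rbound = numeric(n), rflux = numeric(n + 1))
  dwell <- 0; episodes <- 0; nb_dwell <- 0
  for (r in seq_len(n_runs)) {
    tr <- suppressWarnings(
      run_dynamic(params, t_end, seed = as.integer(seed) + r,
                  record_dt = record_dt, x_c0 = x_c0, condition = cond))
    pr <- attr(tr, "profiles")
    if (is.null(pr) || pr$dwell <= 0) next
    acc$free <- acc$free + pr$dens_free
    acc$bound <- acc$bound + pr$dens_bound
    acc$flux <- acc$flux + pr$flux_net
    acc$rfree <- acc$rfree + pr$rel_free
    acc$rbound <- acc$rbound + pr$rel_bound
    acc$rflux <- acc$rflux + pr$rel_flux
    episodes <- episodes + pr$episodes
    if (is.finite(pr$mean_bound)) nb_dwell <- nb_dwell + pr$mean_bound * pr$dwell
    dwell <- dwell + pr$dwell
  }
  if (dwell <= 0) {
    warning("cluster never dwelt in the conditioning window; empty result")
    return(list(dwell = 0, episodes = episodes, x = NULL, c = NULL,
                c_b = NULL, j = NULL, x_rel = NULL, c_rel = NULL,
                c_b_rel = NULL, j_rel = NULL, n_bound = NA_real_))
  }
  x <- a * (seq_len(n) - 0.5)
  list(x = x,
       c = acc$free / (dwell * a), c_b = acc$bound / (dwell * a),
       x_edge = a * seq_len(n - 1), j = acc$flux[2:n] / dwell,
       x_rel = x - params$L / 2,
       c_rel = acc$rfree / (dwell * a), c_b_rel = acc$rbound / (dwell * a),
       j_rel = acc$rflux[2:n] / dwell,
       dwell = dwell, episodes = episodes, n_bound = nb_dwell / dwell)
}

#' Flux-difference estimator from an averaged flux profile
#'
#' Follows the recording recipe: in the averaged flux profile of
#' nucleoid-only dimers, locate the maximal and the minimal value (they
#' typically sit a short distance outside the cluster edges, because
#' dimers can bind the cluster in a stretched configuration) and add the
#' two extreme values of opposite sign. The result is reported in the
#' orientation of the flux difference *into* the cluster, `j_R - j_L`
#' (positive when the dominant inflow arrives from the right): with the
#' package's rightward-positive flux profiles the right-side inflow is the
#' profile minimum, so the signed sum of extremes is negated.
#'
#' @param j flux profile values, rightward-positive (1/s).
#' @return The estimated flux difference `j_R - j_L` (1/s), with attribute
#'   `degenerate = TRUE` and a warning if the two extremes have the same
#'   sign.
#' @export
flux_difference_estimator <- function(j) {
  stopifnot(is.numeric(j), length(j) >= 2)
  jmax <- max(j); jmin <- min(j)
  est <- -(jmax + jmin)
  if (jmax * jmin > 0) {
    warning("degenerate flux profile: both extreme values have the same sign")
    attr(est, "degenerate") <- TRUE
  }
  est
}

#' Friction coefficient from a force-velocity table
#'
#' Ordinary least-squares fit of force against velocity; the effective
#' friction coefficient is the slope, with its confidence interval from
#' the fit.
#'
#' @param table data frame with columns `F_ext` (pN) and `velocity`
#'   (um/s), one row per probed force (at least 3).
#' @param level confidence level.
#' @return A list: `gamma` (pN s/um), `ci` (length-2), `fit` (the `lm`
#'   object).
#' @export
force_velocity_fit <- function(table, level = 0.95) {
  stopifnot(is.data.frame(table),
            all(c("F_ext", "velocity") %in% names(table)))
  if (nrow(table) < 3)
    stop("at least 3 force-velocity points are required", call. = FALSE)
  fit <- stats::lm(F_ext ~ velocity, data = table)
  ci <- stats::confint(fit, "velocity", level = level)
  list(gamma = unname(stats::coef(fit)["velocity"]),
       ci = as.numeric(ci), fit = fit)
}

# Gaussian-weighted moving average with reflecting ends
gaussian_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(y)
  ypad <- c(rev(y[seq_len(min(half, n))]), y,
            rev(y[seq.int(max(1, n - half + 1), n)]))
  sm <- stats::filter(ypad, w / sum(w), sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Monomodal/bimodal classification of the cluster position histogram
#'
#' Histograms the pooled cluster positions, smooths the counts with a
#' Gaussian-weighted moving average and locates local maxima and minima.
#' The distribution is classified bimodal iff a local minimum exists, the
#' difference between the maximal and the minimal peak exceeds 2% of the
#' maximal count (strict inequality), and the maximum lies farther from
#' midnucleoid than the minimum; otherwise monomodal.
#'
#' @param positions pooled cluster positions (um).
#' @param L nucleoid length (um).
#' @param bins number of histogram bins over `[0, L]`.
#' @param sigma_bins Gaussian smoothing width in bins.
#' @param threshold peak-difference threshold as a fraction of the maximal
#'   count.
#' @return `"monomodal"` or `"bimodal"`, with the smoothed histogram and
#'   settings attached as attributes.
#' @export
position_histogram_classifier <- function(positions, L, bins = 100,
                                          sigma_bins = 2, threshold = 0.02) {
  stopifnot(length(positions) > 0, L > 0)
  br <- seq(0, L, length.out = bins + 1)
  h <- graphics::hist(pmin(pmax(positions, 0), L), breaks = br, plot = FALSE)
  y <- gaussian_smooth(h$counts, sigma_bins)
  mid <- (h$mids - L / 2)
  n <- length(y)
  is_max <- is_min <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) is_max[i] <- TRUE
    if (y[i] < y[i - 1] && y[i] <= y[i + 1]) is_min[i] <- TRUE
  }
  cls <- "monomodal"
  # only dips between peaks qualify as the separating minimum
  if (any(is_max)) {
    rng <- range(which(is_max))
    is_min[seq_len(n) < rng[1] | seq_len(n) > rng[2]] <- FALSE
  }
  if (any(is_min) && any(is_max)) {
    ymax <- max(y[is_max]); imax <- which(is_max)[which.max(y[is_max])]
    ymin <- min(y[is_min]); imin <- which(is_min)[which.min(y[is_min])]
    if ((ymax - ymin) > threshold * max(y) &&
        abs(mid[imax]) > abs(mid[imin]))
      cls <- "bimodal"
  }
  structure(cls, histogram = y, mids = h$mids,
            settings = list(bins = bins, sigma_bins = sigma_bins,
                            threshold = threshold))
}

#' FFT-based oscillation detector
#'
#' Per run, subtracts the temporal mean of the cluster position and
#' Fourier-transforms the (uniformly resampled) trajectory; the moduli are
#' summed over runs and smoothed with a Gaussian-weighted moving average.
#' The ensemble is classified oscillatory iff the largest interior peak of
#' the smoothed spectrum exceeds 1.2 times the smoothed value at the
#' lowest resolvable frequency `f_min = 1/T_max`; the peak frequency is
#' then reported.
#'
#' @param trajectories list of data frames with `t` (s) and `x_c` (um);
#'   only `t >= 0` is used. Runs are resampled to a common uniform grid by
#'   previous-value interpolation (default 0.2 min) before the FFT.
#' @param T_max signal duration to analyse (s); default the shortest run.
#' @param resample_dt resampling interval (s).
#' @param sigma_bins spectrum smoothing width in frequency bins.
#' @param peak_factor required peak height relative to the spectrum at
#'   `f_min`.
#' @param positions optional pooled positions for the histogram-shape
#'   field; defaults to the pooled resampled trajectories.
#' @param L nucleoid length for the histogram classifier; taken from the
#'   first trajectory's `params` attribute when present.
#' @return An `OscillationReport` list: `classification`
#'   (`"oscillatory"`/`"non-oscillatory"`), `frequency` (1/min, `NA` when
#'   non-oscillatory), `f_min` (1/min), `histogram_shape`, `spectrum`
#'   (data frame `f_per_min`, `power`, `smoothed`) and `settings`.
#' @export
fft_oscillation_detector <- function(trajectories, T_max = NULL,
                                     resample_dt = 12,
                                     sigma_bins = 2, peak_factor = 1.2,
                                     positions = NULL, L = NULL) {
  stopifnot(length(trajectories) >= 1)
  if (is.null(L)) {
    pp <- attr(trajectories[[1]], "params")
    L <- if (!is.null(pp)) pp$L else NA_real_
  }
  ends <- vapply(trajectories, function(tr) max(tr$t), numeric(1))
  if (is.null(T_max)) T_max <- min(ends)
  grid <- seq(0, T_max, by = resample_dt)
  n <- length(grid)
  if (n < 8) stop("trajectories too short for spectral analysis", call. = FALSE)
  resampled <- lapply(trajectories, function(tr) {
    tr <- tr[tr$t >= 0, , drop = FALSE]
    stats::approx(tr$t, tr$x_c, xout = grid, method = "constant",
                  rule = 2)$y
  })
  spec <- Reduce(`+`, lapply(resampled, function(x) Mod(stats::fft(x - mean(x)))))
  nf <- floor(n / 2)
  power <- spec[2:(nf + 1)]            # drop the zero-frequency bin
  freq <- (seq_len(nf)) / (n * resample_dt)   # 1/s
  sm <- gaussian_smooth(power, sigma_bins)
  f_min <- 1 / T_max
  base <- sm[1]                         # smoothed value at the lowest frequency
  # interior local maxima of the smoothed spectrum
  idx <- which(diff(sign(diff(sm))) < 0) + 1
  idx <- idx[sm[idx] > peak_factor * base]
  if (length(idx) > 0) {
    ipk <- idx[which.max(sm[idx])]
    classification <- "oscillatory"
    frequency <- freq[ipk] * 60
  } else {
    classification <- "non-oscillatory"
    frequency <- NA_real_
  }
  if (is.null(positions)) positions <- unlist(resampled)
  shape <- if (is.finite(L))
    as.character(position_histogram_classifier(positions, L))
  else NA_character_
  list(classification = classification,
       frequency = frequency,
       f_min = f_min * 60,
       histogram_shape = shape,
       spectrum = data.frame(f_per_min = freq * 60, power = power,
                             smoothed = sm),
       settings = list(resample_dt = resample_dt, sigma_bins = sigma_bins,
                       peak_factor = peak_factor, T_max = T_max))
}
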