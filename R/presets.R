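#' Experiment presets
#'
#' Named, fully reproducible experiment recipes mirroring the study's
#' figure-level protocols: baseline positioning ensembles, parameter
#' sweeps, stationary-profile comparisons, the friction assay and the
#' oscillation scan. Each preset declares its full-scale replicate counts
#' and horizons; `scale` < 1 reduces both proportionally (recorded in the
#' manifest), which is how desk-scale runs are produced.
#'
#' @return `list_presets()` returns a data frame of preset names and
#'   descriptions.
#' @export
list_presets <- function() {
  data.frame(
    name = names(preset_table()),
    description = vapply(preset_table(), function(p) p$description, ""),
    row.names = NULL)
}

preset_table <- function() {
  base <- pom_params()
  list(
    positioning_baseline = list(
      description = "ensemble of dynamic-cluster trajectories, baseline parameters (>= 100 at full scale)",
      type = "dynamic", params = base, n_runs = 100, t_end = 3600,
      sweep = NULL),
    sweep_kh = list(
      description = "dynamic ensembles over a hydrolysis-rate sweep",
      type = "dynamic", params = base, n_runs = 100, t_end = 3600,
      sweep = list(field = "k_h", values = c(0.01, 0.1, 1, 10))),
    sweep_dclu = list(
      description = "dynamic ensembles over a cluster-diffusivity sweep",
      type = "dynamic", params = base, n_runs = 100, t_end = 3600,
      sweep = list(field = "D_clu", values = c(0.3, 0.03, 0.003))),
    oscillation_lowD = list(
      description = "midnucleoid start, reduced PomZ diffusivity; trajectories for oscillation analysis (10000 min at full scale)",
      type = "oscillation", params = pom_update(base, D_nuc = 0.003,
                                                D_clu = 0.003),
      n_runs = 100, t_end = 600000, sweep = NULL),
    stationary_profiles = list(
      description = "stationary-cluster density/flux profiles at 10/30/50% nucleoid length",
      type = "stationary", params = base, n_runs = 10, t_end = 2000,
      sweep = list(field = "x_c_frac", values = c(0.1, 0.3, 0.5))),
    friction_assay = list(
      description = "force-velocity assay, 20 bound dimers, forces 0.005/0.01/0.02 pN, 100 runs each at full scale",
      type = "friction", params = base, n_runs = 100, t_end = 300,
      sweep = list(field = "F_ext", values = c(0.005, 0.01, 0.02))))
}

#' Run an experiment preset
#'
#' Executes a preset's simulations and analysis chain and writes
#' trajectories/profiles plus a JSON manifest (parameters, seeds, scale,
#' wall-clock) to `out_dir`. The seed policy is `base_seed + replicate`;
#' together with the preset name and scale this fully determines the
#' outputs.
#'
#' @param name preset name; see [list_presets()].
#' @param base_seed integer base seed.
#' @param scale factor in (0, 1] applied to replicate counts and horizons.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_preset <- function(name, base_seed, scale = 1, out_dir) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; see list_presets()", call. = FALSE)
  stopifnot(scale > 0, scale <= 1)
  pre <- tab[[name]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_runs <- max(2L, as.integer(ceiling(pre$n_runs * scale)))
  t_end <- pre$t_end * max(scale, 0.01)
  started <- Sys.time()
  files <- character()
  incomplete <- character()
  sweep_vals <- if (is.null(pre$sweep)) list(NULL) else as.list(pre$sweep$values)
  for (si in seq_along(sweep_vals)) {
    sv <- sweep_vals[[si]]
    tag <- if (is.null(sv)) "base" else sprintf("%s_%g", pre$sweep$field, sv)
    p <- pre$params
    if (!is.null(sv) && pre$sweep$field %in% names(unclass(p)))
      p <- do.call(pom_update, stats::setNames(list(p, sv), c("params", pre$sweep$field)))
    res <- tryCatch({
      if (pre$type %in% c("dynamic", "oscillation")) {
        x0 <- if (pre$type == "oscillation") p$L / 2 else NULL
        trs <- run_ensemble(p, t_end, n_runs,
                            seed = base_seed + 10000L * si, x_c0 = x0)
        for (r in seq_along(trs)) {
          f <- file.path(out_dir, sprintf("%s_%s_run%03d.tsv", name, tag, r))
          write_trajectory(trs[[r]], f)
          files <- c(files, f)
        }
        st <- binned_trajectory_stats(trs, bin = 200)
        f <- file.path(out_dir, sprintf("%s_%s_binned.tsv", name, tag))
        utils::write.table(st, f, sep = "\t", row.names = FALSE, quote = FALSE)
        files <- c(files, f)
        if (pre$type == "oscillation") {
          rep_osc <- fft_oscillation_detector(trs, L = p$L)
          f <- file.path(out_dir, sprintf("%s_%s_oscillation.json", name, tag))
          jsonlite::write_json(rep_osc[c("classification", "frequency",
                                         "f_min", "histogram_shape",
                                         "settings")],
                               f, auto_unbox = TRUE, digits = NA)
          files <- c(files, f)
        }
        TRUE
      } else if (pre$type == "stationary") {
        xc <- sv * p$L
        st <- run_stationary(p, xc, t_end, seed = base_seed + 10000L * si)
        rd <- solve_stationary(p, xc)
        f1 <- file.path(out_dir, sprintf("%s_%s_stoch.tsv", name, tag))
        f2 <- file.path(out_dir, sprintf("%s_%s_rd.tsv", name, tag))
        write_profile(st, f1); write_profile(rd, f2)
        files <- c(files, f1, f2)
        TRUE
      } else if (pre$type == "friction") {
        tab_fv <- run_friction_assay(p, N_bound = 20,
                                     F_ext_list = pre$sweep$values,
                                     n_runs = n_runs,
                                     seed = base_seed + 10000L * si,
                                     t_end = t_end)
        f <- file.path(out_dir, sprintf("%s_forcevelocity.tsv", name))
        utils::write.table(tab_fv, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        files <- c(files, f)
        TRUE
      } else FALSE
    }, error = function(e) {
      incomplete <<- c(incomplete, sprintf("%s: %s", tag, conditionMessage(e)))
      FALSE
    })
    if (!isTRUE(res) && !length(incomplete)) incomplete <- c(incomplete, tag)
    if (pre$type == "friction") break  # sweep handled inside the assay
  }
  manifest <- list(
    preset = name, base_seed = base_seed, scale = scale,
    n_runs = n_runs, t_end = t_end,
    params = unclass(pre$params)[names(formals(pom_params))],
    files = basename(files), incomplete = incomplete,
    wall_clock_s = as.numeric(difftime(Sys.time(), started, units = "secs")),
    pomsim_version = as.character(utils::packageVersion("pomsim")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
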