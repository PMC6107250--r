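#' Read a validated experiment configuration
#'
#' Reads a YAML configuration with up to three tables: `model` (fields of
#' [pom_params()]), `run` (`t_end`, `record_dt`, `n_runs`, `seed`,
#' `x_c0`), and `output` (`dir`, `prefix`). Unknown keys anywhere are
#' rejected, and all schema violations are reported together, not
#' first-error-only.
#'
#' @param path path to a YAML file.
#' @return A list with elements `model` (a `pom_params` object), `run`,
#'   `output`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  errs <- character()
  known_top <- c("model", "run", "output")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    errs <- c(errs, sprintf("unknown top-level key '%s'", bad))
  model_fields <- names(formals(pom_params))
  run_fields <- c("t_end", "record_dt", "n_runs", "seed", "x_c0")
  out_fields <- c("dir", "prefix")
  if (!is.null(raw$model)) {
    bad <- setdiff(names(raw$model), model_fields)
    if (length(bad))
      errs <- c(errs, sprintf("unknown [model] key '%s'", bad))
  }
  if (!is.null(raw$run)) {
    bad <- setdiff(names(raw$run), run_fields)
    if (length(bad))
      errs <- c(errs, sprintf("unknown [run] key '%s'", bad))
  }
  if (!is.null(raw$output)) {
    bad <- setdiff(names(raw$output), out_fields)
    if (length(bad))
      errs <- c(errs, sprintf("unknown [output] key '%s'", bad))
  }
  if (length(errs))
    stop("invalid configuration '", path, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  model <- tryCatch(
    do.call(pom_params, raw$model %||% list()),
    error = function(e)
      stop("invalid configuration '", path, "': ", conditionMessage(e),
           call. = FALSE))
  list(model = model, run = raw$run %||% list(),
       output = raw$output %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment configuration
#'
#' Inverse of [read_config()]: serialises a parameter set (and optional
#' run/output tables) to YAML so that `read_config(write_config(...))`
#' round-trips.
#'
#' @param params a [pom_params()] object.
#' @param path output path.
#' @param run,output optional named lists for the `run`/`output` tables.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, run = NULL, output = NULL) {
  stopifnot(inherits(params, "pom_params"))
  cfg <- list(model = unclass(params)[names(formals(pom_params))])
  if (!is.null(run)) cfg$run <- run
  if (!is.null(output)) cfg$output <- output
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a trajectory as a self-describing TSV
#'
#' Tab-separated columns `t_s`, `x_c_um`, `n_cluster_bound`,
#' `n_nucleoid_only`, `n_cyto`, preceded by `#`-prefixed header lines
#' carrying the full parameter set and the RNG seed, so every output file
#' reconstructs its provenance.
#'
#' @param traj a `pom_trajectory` from [run_dynamic()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  p <- attr(traj, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pomsim trajectory; seed=%d", attr(traj, "seed")), con)
  kv <- unclass(p)[names(formals(pom_params))]
  writeLines(sprintf("# params: %s",
                     paste(sprintf("%s=%g", names(kv), as.numeric(unlist(kv))),
                           collapse = " ")), con)
  writeLines("t_s\tx_c_um\tn_cluster_bound\tn_nucleoid_only\tn_cyto", con)
  utils::write.table(
    data.frame(traj$t, traj$x_c, traj$n_bound, traj$n_nucleoid, traj$n_cyto),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory()]
#'
#' @param path input path.
#' @return A data frame with columns `t`, `x_c`, `n_bound`, `n_nucleoid`,
#'   `n_cyto`; the seed and the parameter header line are attached as
#'   attributes.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 3)
  hdr <- grep("^#", lines, value = TRUE)
  seed <- NA_integer_
  m <- regmatches(hdr[1], regexec("seed=([0-9]+)", hdr[1]))[[1]]
  if (length(m) == 2) seed <- as.integer(m[2])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  names(df) <- c("t", "x_c", "n_bound", "n_nucleoid", "n_cyto")
  attr(df, "seed") <- seed
  attr(df, "header") <- hdr
  df
}

#' Write a stationary or RD profile as TSV
#'
#' Tab-separated columns `x_um`, `c`, `c_b`, `j` with a header carrying
#' the cluster position and summary quantities.
#'
#' @param profile a `pom_stationary` or `pom_rd_profile` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(profile, "pom_rd_profile")) {
    writeLines(sprintf(
      "# pomsim RD profile; x_c=%g N_cyto=%.6g N=%.6g j_R=%.6g j_L=%.6g j_diff=%.6g",
      profile$x_c, profile$N_cyto, profile$N, profile$j_R, profile$j_L,
      profile$j_diff), con)
    j <- profile$j
  } else {
    writeLines(sprintf(
      "# pomsim stationary-cluster profile; x_c=%g seed=%d force=%.6g n_bound=%.6g",
      profile$x_c, profile$seed, profile$force, profile$n_bound), con)
    j <- c(profile$j, NA)  # edge fluxes padded to the site grid
  }
  writeLines("x_um\tc\tc_b\tj", con)
  utils::write.table(data.frame(profile$x, profile$c, profile$c_b, j),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
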