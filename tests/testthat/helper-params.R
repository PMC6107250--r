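# Shared reduced-scale parameter sets for the test suite.
#
# Ensemble work uses a half-length nucleoid (L = 2.5 um) with a coarser
# lattice (a = 0.02 um) and a proportionally shorter cluster; one-particle
# force runs keep the fine lattice a = 0.01 um. These are the package's
# reduced study conditions (see the methods vignette).

p_fast <- function(...) {
  args <- list(L = 2.5, L_c = 0.36, a = 0.02, t_min = 300)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(pom_params, args)
}

p_fine <- function(...) {
  args <- list(L = 2.5, L_c = 0.35, a = 0.01, t_min = 0)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(pom_params, args)
}

# lattice-commensurate stationary cluster positions (a moving cluster
# averages over lattice phases, but a frozen one must not be pinned at a
# fractional phase offset; see the methods vignette)
snap_lattice <- function(x, a) round(x / a) * a
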