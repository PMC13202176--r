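#' Calibrate the DNA bending constant against a target persistence length
#'
#' Simulates a naked DNA chain at each candidate bending stiffness and
#' interpolates the stiffness that reproduces the target persistence length
#' at the given salt (50 nm at physiological 150 mM for the shipped
#' default). The discrete wormlike-chain relation
#' \eqn{l_p \approx 2 K_\theta b / k_B T} provides the initial bracket; the
#' simulation includes the Debye-Hueckel self-repulsion of the chain, which
#' stiffens it further at low salt.
#'
#' @param target_lp_nm Target persistence length, nm.
#' @param k_grid Candidate bending constants, kcal/mol/rad^2.
#' @param dna_bp Chain length in bp.
#' @param salt_mM Salt concentration.
#' @param n_steps Sampling steps per candidate.
#' @param seed Integer seed.
#' @return List with `k_bend` (interpolated optimum) and the scan tibble.
#' @export
calibrate_bending <- function(target_lp_nm = 50,
                              k_grid = c(3.2, 4.0, 4.8),
                              dna_bp = 1050, salt_mM = 150, n_steps = 4e5,
                              seed = 1) {
  scan <- dplyr::bind_rows(lapply(k_grid, function(k) {
    ff <- default_forcefield(salt_mM = salt_mM, k_bend = k)
    sys <- build_fiber(fiber_spec("dna", dna_bp), ff)
    topo <- build_topology(sys)
    cfg <- sim_config(salt_mM = salt_mM, n_steps = n_steps,
                      dump_interval = 500, seed = seed)
    tr <- run_langevin(sys, topo, cfg)
    lp <- persistence_length(tr, burn_in = floor(n_frames(tr) * 0.25))
    tibble(k_bend = k, lp_nm = lp$lp_nm)
  }))
  fit <- stats::lm(lp_nm ~ k_bend, data = scan)
  k_opt <- (target_lp_nm - stats::coef(fit)[1]) / stats::coef(fit)[2]
  list(k_bend = unname(k_opt), scan = scan)
}

#' Calibrate the Morse well depth against a target unwrapping constant
#'
#' Runs the canonical dinucleosome (63-bp linker) at each candidate well
#' depth, measures the unwrapping equilibrium constant, and interpolates
#' log K against De (the relation is exponential to good accuracy). The same
#' routine with `acetyl = TRUE` calibrates the acetyl well-depth scaling
#' against the three-fold increased unwrapping of acetylated nucleosomes.
#'
#' @param target_keq Target equilibrium constant.
#' @param de_grid Candidate well depths, kcal/mol.
#' @param acetyl Calibrate on an acetylated dinucleosome.
#' @param n_steps Sampling steps per candidate (convergence needs several
#'   hundred breathing transitions).
#' @param seed Integer seed.
#' @return List with `morse_de` and the scan tibble.
#' @export
calibrate_morse <- function(target_keq = 0.10, de_grid = c(2.8, 3.1, 3.4),
                            acetyl = FALSE, n_steps = 1e7, seed = 1) {
  scan <- dplyr::bind_rows(lapply(de_grid, function(de) {
    ff <- default_forcefield(morse_de = de, morse_acetyl_scale = 1)
    sys <- build_fiber(regular_fiber(2, 210, label = "dinucleosome",
                                     acetylated = acetyl), ff)
    topo <- build_topology(sys)
    cfg <- sim_config(n_steps = n_steps, dump_interval = 500, seed = seed)
    tr <- run_langevin(sys, topo, cfg)
    kq <- unwrapping_keq(tr, burn_in = floor(n_frames(tr) * 0.1))
    tibble(de = de, k_eq = kq$k_eq, se = kq$se)
  }))
  fit <- stats::lm(log(k_eq) ~ de, data = scan)
  de_opt <- (log(target_keq) - stats::coef(fit)[1]) / stats::coef(fit)[2]
  list(morse_de = unname(de_opt), scan = scan)
}
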