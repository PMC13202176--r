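#' Simulation configuration
#'
#' Langevin-dynamics run parameters. The internal unit system is Angstrom /
#' kcal/mol / unit mass, so one internal time unit is
#' \eqn{t^* = \sqrt{m\,\mathrm{\AA}^2 / (\mathrm{kcal/mol})}}. `time_scale`
#' (ns of physical time per timestep, default 1.4, from matching simulated and
#' experimental nucleosome diffusion) is pure metadata: it labels trajectory
#' times and converts the 140-ns damping factor into timesteps, but never
#' alters the integrated equations.
#'
#' @param temperature Kelvin.
#' @param salt_mM Monovalent salt, mM.
#' @param timestep Integration timestep in internal time units.
#' @param damping_ns Langevin damping factor in mapped ns (140 ns
#'   corresponds to a low-viscosity regime of 100 timesteps).
#' @param n_steps Number of timesteps.
#' @param dump_interval Save coordinates every this many timesteps.
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param time_scale ns of physical time per timestep (metadata).
#' @param colvar_interval Record the restraint collective variable every this
#'   many steps (0 = off).
#' @param force_max Abort threshold on any bead force (kcal/mol/A).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(temperature = 300, salt_mM = 150, timestep = 0.02,
                       damping_ns = 140, n_steps = 1e5, dump_interval = 1e5,
                       seed = 1, time_scale = 1.4, colvar_interval = 0,
                       force_max = 1e5) {
  stopifnot(temperature > 0, salt_mM > 0, timestep > 0, damping_ns > 0,
            n_steps > 0, dump_interval > 0, time_scale > 0)
  structure(list(
    temperature = temperature, salt_mM = salt_mM, timestep = timestep,
    damping_ns = damping_ns, n_steps = n_steps,
    dump_interval = dump_interval, seed = seed, time_scale = time_scale,
    colvar_interval = colvar_interval, force_max = force_max),
    class = "sim_config")
}

# assemble the model list consumed by the C++ engine
.engine_model <- function(system, topology, config,
                          softcore = FALSE, restraint = NULL,
                          orientation = NULL) {
  ff <- topology$forcefield
  ld <- debye_length(config$salt_mM, config$temperature, ff$dielectric)
  b <- system$boundary
  btype <- switch(b$type, none = 0L, sphere = 1L, slab = 2L)
  list(
    class_id = as.integer(system$beads$class_id),
    charge = as.numeric(system$beads$charge),
    eps_matrix = unclass(topology$eps_matrix),
    sigma = ff$sigma,
    rc_lj = ff$lj_cutoff,
    rc_dh = ff$dh_cutoff_debye * ld,
    kappa = 1 / ld,
    coul_pref = .coulomb_const / ff$dielectric,
    softcore = softcore,
    rcap = ff$relax_rcap,
    boundary = btype,
    wall_radius = if (btype == 1L) b$radius else 0,
    wall_eps = ff$wall_eps,
    box = if (btype == 2L) as.numeric(b$box) else c(0, 0, 0),
    restrain = !is.null(restraint),
    restraint_center = if (is.null(restraint)) 0 else restraint$center,
    restraint_k = if (is.null(restraint)) 0 else restraint$k,
    group1 = if (is.null(restraint)) integer(0) else as.integer(restraint$group1),
    group2 = if (is.null(restraint)) integer(0) else as.integer(restraint$group2),
    orient = !is.null(orientation),
    orient_k = if (is.null(orientation)) 0 else orientation$k,
    coax = !is.null(orientation) && !is.null(orientation$coax_k) &&
      orientation$coax_k > 0,
    coax_k = if (is.null(orientation) || is.null(orientation$coax_k)) 0 else
      orientation$coax_k,
    a_top = if (is.null(orientation)) integer(0) else as.integer(orientation$a_top),
    a_bot = if (is.null(orientation)) integer(0) else as.integer(orientation$a_bot),
    b_top = if (is.null(orientation)) integer(0) else as.integer(orientation$b_top),
    b_bot = if (is.null(orientation)) integer(0) else as.integer(orientation$b_bot),
    bonds = as.matrix(topology$bonds[, c("i", "j", "r0", "k")]),
    morse = as.matrix(topology$morse[, c("i", "j", "de", "a", "r0")]),
    angles = as.matrix(topology$angles[, c("i", "j", "k", "theta0", "k_theta")]),
    exclusions = matrix(as.integer(as.matrix(topology$exclusions)), ncol = 2))
}

.run_params <- function(config, velocities = NULL, quench = FALSE) {
  damp_internal <- config$damping_ns / config$time_scale * config$timestep
  list(dt = config$timestep, damp = damp_internal,
       kBT = kBT(config$temperature),
       n_steps = config$n_steps, dump_every = config$dump_interval,
       colvar_every = config$colvar_interval, seed = config$seed,
       force_max = config$force_max, quench = quench,
       velocities = if (is.null(velocities)) matrix(0, 0, 3) else velocities)
}

.as_trajectory <- function(raw, system, topology, config) {
  n <- n_beads(system)
  nf <- nrow(raw$frames)
  frames <- lapply(seq_len(nf), function(k) {
    matrix(raw$frames[k, ], n, 3, byrow = TRUE)
  })
  structure(list(
    frames = frames,
    frame_step = raw$frame_step,
    times_ns = raw$frame_step * config$time_scale,
    potential = raw$potential,
    kinetic = raw$kinetic,
    colvar = raw$colvar,
    final_positions = raw$final_positions,
    final_velocities = raw$final_velocities,
    beads = system$beads,
    boundary = system$boundary,
    topology = topology,
    config = config), class = "chromatin_trajectory")
}

#' @export
print.chromatin_trajectory <- function(x, ...) {
  cat(sprintf("<chromatin_trajectory> %d frames x %d beads, %.3g ns total (%.3g ns/frame)\n",
              length(x$frames), nrow(x$beads),
              if (length(x$times_ns)) max(x$times_ns) else 0,
              x$config$dump_interval * x$config$time_scale))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `chromatin_trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Integrate Langevin dynamics
#'
#' BAOAB-split Langevin integration at the configured temperature, with the
#' class-matrix Lennard-Jones plus Debye-Hueckel nonbonded interactions, the
#' harmonic/Morse/angle bonded terms of the topology, a purely repulsive
#' spherical wall (sphere boundary) or periodic images (slab boundary). Unit
#' mass per bead. Deterministic for a given seed: every bead draws from its
#' own counter-based random substream.
#'
#' @param system A `chromatin_system` (ideally relaxed, see
#'   [soft_core_relax()]).
#' @param topology Interaction topology from [build_topology()].
#' @param config A [sim_config()].
#' @param velocities Optional initial velocity matrix (defaults to a
#'   Maxwell-Boltzmann draw).
#' @param restraint Optional list `(group1, group2, center, k)` adding a
#'   harmonic restraint on the centroid-centroid distance of two bead groups.
#' @return A `chromatin_trajectory`.
#' @export
run_langevin <- function(system, topology, config, velocities = NULL,
                         restraint = NULL) {
  raw <- .cg_run(system$positions,
                 .engine_model(system, topology, config, restraint = restraint),
                 .run_params(config, velocities))
  .as_trajectory(raw, system, topology, config)
}

#' Single-point potential energy
#'
#' Evaluates the full potential (and per-term breakdown) of a configuration
#' under a topology, using the same functional forms as the integrator.
#'
#' @param system A `chromatin_system`.
#' @param topology From [build_topology()].
#' @param config A [sim_config()] (supplies temperature/salt for the
#'   electrostatics).
#' @param positions Optional coordinate matrix overriding the system's.
#' @return A list with `total` and per-term energies (kcal/mol) and `forces`.
#' @export
potential_energy <- function(system, topology, config = sim_config(),
                             positions = NULL) {
  pos <- if (is.null(positions)) system$positions else positions
  .cg_energy(pos, .engine_model(system, topology, config))
}

#' Soft-core relaxation of an initial structure
#'
#' Freshly grown structures may contain steric clashes. Relaxation proceeds
#' in two stages: (i) Langevin dynamics with a soft-core (force-capped below
#' 0.8 sigma) pair potential, which lets overlapping beads slide past each
#' other, then (ii) a zero-temperature damped quench under the full
#' potential. The bonded topology is untouched. Fails with the offending pair
#' if a clash below 0.8 sigma survives the step budget.
#'
#' @param system A `chromatin_system`.
#' @param topology From [build_topology()].
#' @param config A [sim_config()]; `n_steps` is used for the soft-core stage.
#' @param quench_steps Steps for the full-potential quench stage.
#' @return The system with relaxed positions (field `positions` replaced).
#' @export
soft_core_relax <- function(system, topology, config = sim_config(n_steps = 4000,
                                                                  dump_interval = 4000),
                            quench_steps = 2000) {
  model_full <- .engine_model(system, topology, config, softcore = FALSE)
  model_soft <- .engine_model(system, topology, config, softcore = TRUE)
  rcap <- topology$forcefield$relax_rcap
  pre <- .cg_min_nonbonded(system$positions, model_full)
  start_pos <- system$positions
  # overdamped descent with a reduced timestep: initial structures can carry
  # very steep gradients
  quench_params <- function(n) {
    cfgq <- config
    cfgq$timestep <- config$timestep / 5
    cfgq$damping_ns <- config$damping_ns / 10
    cfgq$n_steps <- n
    cfgq$dump_interval <- n
    .run_params(cfgq, quench = TRUE)
  }
  pos <- start_pos
  for (cycle in 1:4) {
    if (is.finite(pre$min_dist) && pre$min_dist < rcap) {
      # capped-force stages, only needed when clashes exist: first a damped
      # descent, then thermal soft-core dynamics
      raw0 <- .cg_run(pos, model_soft, quench_params(2000))
      cfg1 <- config
      cfg1$dump_interval <- config$n_steps
      cfg1$seed <- config$seed + cycle
      raw1 <- .cg_run(raw0$final_positions, model_soft, .run_params(cfg1))
      pos <- raw1$final_positions
    }
    raw2 <- .cg_run(pos, model_full, quench_params(quench_steps))
    pos <- raw2$final_positions
    chk <- .cg_min_nonbonded(pos, model_full)
    # 0.5 percent numerical tolerance: dense quenched minima can sit right
    # at the clash threshold
    if (!is.finite(chk$min_dist) || chk$min_dist >= 0.995 * rcap) break
    pre <- chk  # clashes remain: run another thermal + quench cycle
    if (cycle == 4) {
      stop(sprintf(paste0("soft-core relaxation could not resolve the clash ",
                          "between beads %d and %d (%.2f A < %.2f A)"),
                   chk$i, chk$j, chk$min_dist, 0.995 * rcap))
    }
  }
  out <- system
  out$positions <- pos
  out
}

#' Bead indices of one nucleosome
#'
#' @param system A `chromatin_system`.
#' @param fiber_id Fiber index (1-based).
#' @param nucleosome Nucleosome index within the fiber.
#' @param core_only If `TRUE`, only DNA + histone beads (H1 excluded).
#' @return Integer bead indices.
#' @export
nucleosome_beads <- function(system, fiber_id, nucleosome, core_only = TRUE) {
  b <- system$beads
  sel <- b$fiber_id == fiber_id & !is.na(b$nucleosome) & b$nucleosome == nucleosome
  if (core_only) sel <- sel & !(b$role %in% c("H1_GLOB", "H1_TAIL"))
  b$bead[sel]
}

#' Umbrella sampling along an inter-nucleosome distance
#'
#' Runs one restrained Langevin simulation per window on the centroid
#' distance between two tagged nucleosomes, each started from the final
#' configuration of the previous window (first window starts from the input
#' system). Warns when adjacent windows' sample histograms overlap by less
#' than 5 percent.
#'
#' @param system A `chromatin_system` containing the two nucleosomes.
#' @param topology From [build_topology()].
#' @param windows A data frame with columns `center` (A) and `k`
#'   (kcal/mol/A^2).
#' @param config A [sim_config()]; `n_steps` is the per-window sampling
#'   length and `colvar_interval` the collective-variable stride.
#' @param nucleosomes List of two `c(fiber_id, nucleosome)` pairs (defaults
#'   to the first nucleosome of fibers 1 and 2).
#' @param equil_steps Per-window equilibration steps discarded before
#'   sampling.
#' @param orientation_k Strength (kcal/mol) of an optional nematic restraint
#'   keeping the two nucleosomes' superhelix axes aligned,
#'   \eqn{U = k_o (1 - \cos^2\theta)} on the angle between the axes
#'   (estimated from the histone-bead halves). 0 disables it. The restraint
#'   is identical in every window, so it defines the sampled (stacked)
#'   ensemble without entering the WHAM bias.
#' @return A list of class `umbrella_set`: `samples` (tibble with `window`,
#'   `center`, `k`, `r`), `windows`, `config`.
#' @export
run_umbrella <- function(system, topology, windows, config,
                         nucleosomes = list(c(1, 1), c(2, 1)),
                         equil_steps = 2e4, orientation_k = 0,
                         coaxial_k = orientation_k) {
  stopifnot(all(c("center", "k") %in% names(windows)))
  if (config$colvar_interval <= 0) config$colvar_interval <- 50
  g1 <- nucleosome_beads(system, nucleosomes[[1]][1], nucleosomes[[1]][2])
  g2 <- nucleosome_beads(system, nucleosomes[[2]][1], nucleosomes[[2]][2])
  orientation <- NULL
  if (orientation_k > 0) {
    hist_of <- function(fid, nuc) {
      b <- system$beads
      b$bead[b$fiber_id == fid & !is.na(b$nucleosome) & b$nucleosome == nuc &
               b$role == "HIST"]
    }
    h1_ <- hist_of(nucleosomes[[1]][1], nucleosomes[[1]][2])
    h2_ <- hist_of(nucleosomes[[2]][1], nucleosomes[[2]][2])
    orientation <- list(k = orientation_k, coax_k = coaxial_k,
                        a_top = h1_[5:8], a_bot = h1_[1:4],
                        b_top = h2_[5:8], b_bot = h2_[1:4])
  }
  pos <- system$positions
  out <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    restraint <- list(group1 = g1, group2 = g2,
                      center = windows$center[w], k = windows$k[w])
    cfg <- config
    cfg$seed <- config$seed + w
    cfg$n_steps <- config$n_steps + equil_steps
    cfg$dump_interval <- cfg$n_steps
    model <- .engine_model(system, topology, cfg, restraint = restraint,
                           orientation = orientation)
    raw <- .cg_run(pos, model, .run_params(cfg))
    pos <- raw$final_positions
    nskip <- floor(equil_steps / cfg$colvar_interval)
    r <- raw$colvar[-seq_len(nskip)]
    out[[w]] <- tibble(window = w, center = windows$center[w],
                       k = windows$k[w], r = r)
  }
  samples <- dplyr::bind_rows(out)
  # adjacent-window overlap diagnostic
  for (w in seq_len(nrow(windows) - 1)) {
    a <- out[[w]]$r; b <- out[[w + 1]]$r
    lo <- max(min(a), min(b)); hi <- min(max(a), max(b))
    ov <- mean(a >= lo & a <= hi)
    ov2 <- mean(b >= lo & b <= hi)
    if (hi <= lo || min(ov, ov2) < 0.05) {
      warning(sprintf("umbrella windows %d and %d overlap poorly (%.1f%%/%.1f%%)",
                      w, w + 1, 100 * max(ov, 0), 100 * max(ov2, 0)))
    }
  }
  structure(list(samples = samples, windows = as_tibble(windows),
                 config = config,
                 temperature = config$temperature), class = "umbrella_set")
}

#' @export
print.umbrella_set <- function(x, ...) {
  cat(sprintf("<umbrella_set> %d windows, %d samples, centers %.1f-%.1f A\n",
              nrow(x$windows), nrow(x$samples), min(x$windows$center),
              max(x$windows$center)))
  invisible(x)
}
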