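# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

ff_default <- function() fixture("ff", function() default_forcefield())

dinucleosome_system <- function() fixture("dinuc", function() {
  sys <- build_fiber(regular_fiber(2, 210, label = "dinucleosome"), ff_default())
  list(system = sys, topology = build_topology(sys))
})

# short dinucleosome trajectory shared by several analysis tests
dinucleosome_trajectory <- function() fixture("dinuc_traj", function() {
  d <- dinucleosome_system()
  cfg <- sim_config(n_steps = 2e5, dump_interval = 500, seed = 101)
  run_langevin(d$system, d$topology, cfg)
})

# hand-made single-bead-per-nucleosome trajectory for analysis-oracle tests:
# `frames` is a list of (n_nuc x 3) center matrices
make_toy_trajectory <- function(frames, states = NULL, dyads = NULL,
                                boundary = list(type = "none",
                                                box = c(0, 0, 0)),
                                dump_interval = 1, time_scale = 1.4) {
  n <- nrow(frames[[1]])
  if (is.null(states)) states <- rep("CANONICAL", n)
  if (is.null(dyads)) dyads <- (seq_len(n) - 0.5) * 195
  beads <- tibble::tibble(
    bead = seq_len(n), role = "NUC_DNA", nucleosome = seq_len(n),
    state = states, dyad = dyads, type = "NUC_DNA", type_id = 2L,
    class = "CANONICAL_NUC", class_id = 2L, charge = 0, fiber = "toy",
    fiber_id = 1L)
  structure(list(
    frames = frames,
    frame_step = seq_along(frames) * dump_interval,
    times_ns = seq_along(frames) * dump_interval * time_scale,
    beads = beads, boundary = boundary,
    config = list(dump_interval = dump_interval, time_scale = time_scale,
                  temperature = 300)),
    class = "chromatin_trajectory")
}

# minimal two-bead system bound by a Morse bond plus a soft harmonic tether,
# for the analytic two-state unwrapping oracle
morse_toy <- function(de = 1.2, a = 0.2, r0 = 22, k_tether = 0.05,
                      r_tether = 30) {
  ff <- default_forcefield()
  beads <- tibble::tibble(
    bead = 1:2, role = c("NUC_DNA", "HIST"), nucleosome = 1L,
    state = "CANONICAL", dyad = 73.5, type = c("NUC_DNA", "H3"),
    type_id = c(2L, 6L), class = "CANONICAL_NUC", class_id = 2L, charge = 0,
    fiber = "toy", fiber_id = 1L)
  system <- structure(list(
    positions = rbind(c(0, 0, 0), c(r0, 0, 0)), beads = beads,
    fibers = list(), offsets = 0L,
    boundary = list(type = "none", box = c(0, 0, 0)),
    forcefield = ff), class = "chromatin_system")
  topology <- structure(list(
    bonds = tibble::tibble(i = 1, j = 2, r0 = r_tether, k = k_tether),
    morse = tibble::tibble(i = 1, j = 2, de = de, a = a, r0 = r0),
    angles = tibble::tibble(i = numeric(0), j = numeric(0), k = numeric(0),
                            theta0 = numeric(0), k_theta = numeric(0)),
    exclusions = tibble::tibble(i = numeric(0), j = numeric(0)),
    morse_meta = tibble::tibble(nucleosome = 1L, terminus = 1L,
                                entry_bead = 1, partner_bead = 2,
                                r0 = r0, a = a, de = de, fiber_id = 1L),
    eps_matrix = ff$pair_matrix, forcefield = ff),
    class = "chromatin_topology")
  list(system = system, topology = topology)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

perp_unit <- function(v) {
  p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3(v, p)
  w / sqrt(sum(w^2))
}

# a dilute gas of independent free beads (one-bead fibers on a wide grid),
# for clean free-diffusion statistics
free_bead_gas <- function(n = 27, spacing = 600) {
  ff <- ff_default()
  specs <- lapply(seq_len(n), function(i) fiber_spec(paste0("b", i), 10.5))
  refs <- lapply(specs, nucfold:::.fiber_reference, ff = ff)
  g <- ceiling(n^(1 / 3))
  pos <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- i - 1
    spacing * c(k %% g, (k %/% g) %% g, k %/% (g * g))
  }))
  nucfold:::.new_system(specs, refs, pos,
                        list(type = "none", box = c(0, 0, 0)), ff)
}
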