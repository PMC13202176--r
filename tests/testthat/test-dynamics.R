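test_that("trajectories are bit-reproducible for a fixed seed", {
  d <- dinucleosome_system()
  cfg <- sim_config(n_steps = 5e3, dump_interval = 500, seed = 9)
  t1 <- run_langevin(d$system, d$topology, cfg)
  t2 <- run_langevin(d$system, d$topology, cfg)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_langevin(d$system, d$topology,
                     sim_config(n_steps = 5e3, dump_interval = 500, seed = 10))
  expect_false(identical(t1$frames[[10]], t3$frames[[10]]))
})

test_that("frame times follow the dump interval and the ns-per-step mapping", {
  tr <- dinucleosome_trajectory()
  expect_equal(diff(tr$frame_step), rep(500, n_frames(tr) - 1))
  expect_equal(tr$times_ns, tr$frame_step * 1.4)
})

test_that("kinetic energy satisfies equipartition within 2 percent", {
  tr <- dinucleosome_trajectory()
  dof <- 3 * nrow(tr$beads)
  kbt_est <- mean(tr$kinetic[-(1:40)]) / dof * 2
  expect_lt(abs(kbt_est - kBT(300)) / kBT(300), 0.02)
})

test_that("free beads diffuse with MSD slope 6 kBT damp/m", {
  sys <- free_bead_gas(27)
  topo <- build_topology(sys)
  cfg <- sim_config(n_steps = 6e5, dump_interval = 50, seed = 12)
  tr <- run_langevin(sys, topo, cfg)
  lags <- c(20, 40, 80, 160)
  msd <- vapply(lags, function(L) {
    mean(vapply(seq_len(n_frames(tr) - L), function(t0) {
      mean(rowSums((tr$frames[[t0 + L]] - tr$frames[[t0]])^2))
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(msd ~ I(lags * 50 * cfg$timestep))
  damp_internal <- cfg$damping_ns / cfg$time_scale * cfg$timestep
  expected_slope <- 6 * kBT(300) * damp_internal
  expect_lt(abs(stats::coef(fit)[2] - expected_slope) / expected_slope, 0.05)
})

test_that("a harmonic dimer samples the Boltzmann bond-length distribution", {
  ff <- default_forcefield(k_bond = 2)
  sys <- build_fiber(fiber_spec("dimer", 21), ff)
  topo <- build_topology(sys)
  cfg <- sim_config(n_steps = 1.2e6, dump_interval = 300, seed = 13)
  tr <- run_langevin(sys, topo, cfg)
  r <- vapply(tr$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
              numeric(1))[-(1:200)]
  # analytic radial Boltzmann CDF for U = k (r - r0)^2
  beta <- 1 / kBT(300)
  dens <- function(x) x^2 * exp(-beta * 2 * (x - 35)^2)
  zz <- stats::integrate(dens, 0, 80)$value
  cdf <- Vectorize(function(x) stats::integrate(dens, 0, x)$value / zz)
  ks <- suppressWarnings(stats::ks.test(r, cdf))
  expect_gt(ks$p.value, 0.01)
  # thermostat independence: equilibrium statistics insensitive to damping
  cfg2 <- sim_config(n_steps = 1.2e6, dump_interval = 300, seed = 14,
                     damping_ns = 35)
  r2 <- vapply(run_langevin(sys, topo, cfg2)$frames,
               function(f) sqrt(sum((f[1, ] - f[2, ])^2)), numeric(1))[-(1:200)]
  expect_lt(abs(mean(r) - mean(r2)), 3 * sqrt(stats::var(r) / length(r) +
                                                stats::var(r2) / length(r2)) + 0.05)
})

test_that("the spherical wall contains all beads", {
  ff <- ff_default()
  spec <- regular_fiber(3, 195, label = "t")
  refs <- list(nucfold:::.fiber_reference(spec, ff))
  sys <- nucfold:::.new_system(list(spec), refs, refs[[1]]$xyz,
                               list(type = "sphere", radius = 450,
                                    box = c(0, 0, 0)), ff)
  # recentre the straight fiber inside the sphere
  sys$positions <- sweep(sys$positions, 2, colMeans(sys$positions))
  topo <- build_topology(sys)
  sys <- soft_core_relax(sys, topo)
  tr <- run_langevin(sys, topo, sim_config(n_steps = 3e4, dump_interval = 1000,
                                           seed = 3))
  maxr <- max(vapply(tr$frames, function(f) max(sqrt(rowSums(f^2))),
                     numeric(1)))
  expect_lte(maxr, 450 + ff$sigma)
})

test_that("soft-core relaxation resolves clashes and preserves the topology", {
  ff <- ff_default()
  d <- dinucleosome_system()
  sys <- d$system
  # create hard clashes: rigidly slide the second nucleosome into partial
  # overlap with the first (growth never produces worse than this)
  nuc2 <- which(!is.na(sys$beads$nucleosome) & sys$beads$nucleosome == 2)
  shift <- sys$positions[5, ] + c(46, 18, 12) - sys$positions[nuc2[5], ]
  sys$positions[nuc2, ] <- sweep(sys$positions[nuc2, ], 2, shift, "+")
  chk0 <- nucfold:::.cg_min_nonbonded(
    sys$positions, nucfold:::.engine_model(sys, d$topology, sim_config()))
  expect_lt(chk0$min_dist, 0.5 * ff$sigma)  # genuinely clashed before relaxation
  rel <- soft_core_relax(sys, d$topology,
                         config = sim_config(n_steps = 2e4,
                                             dump_interval = 2e4))
  chk <- nucfold:::.cg_min_nonbonded(
    rel$positions, nucfold:::.engine_model(rel, d$topology, sim_config()))
  expect_gte(chk$min_dist, 0.99 * 0.8 * ff$sigma)
  expect_equal(nrow(rel$positions), nrow(sys$positions))
  # a second relaxation of an already-relaxed system barely moves it
  rel2 <- soft_core_relax(rel, d$topology)
  rms <- sqrt(mean(rowSums((rel2$positions - rel$positions)^2)))
  expect_lt(rms, 0.1 * ff$sigma)

  # two coincident (nonbonded) beads separate beyond 0.8 sigma
  gas <- free_bead_gas(2)
  gas$positions[2, ] <- gas$positions[1, ] + c(0.01, 0, 0)
  relt <- soft_core_relax(gas, build_topology(gas))
  sep <- sqrt(sum((relt$positions[1, ] - relt$positions[2, ])^2))
  expect_gte(sep, 0.8 * ff$sigma)
})

test_that("umbrella restraints pin the collective variable at stiff spring", {
  ff <- ff_default()
  sys <- stacked_pair_system(70, ff = ff)
  topo <- build_topology(sys)
  cfg <- sim_config(n_steps = 2e4, dump_interval = 2e4, seed = 5,
                    colvar_interval = 20)
  um <- run_umbrella(sys, topo, data.frame(center = 80, k = 50), cfg,
                     equil_steps = 5e3)
  expect_lt(abs(mean(um$samples$r) - 80), 1.0)
  # per-seed determinism of window trajectories
  um2 <- run_umbrella(sys, topo, data.frame(center = 80, k = 50), cfg,
                      equil_steps = 5e3)
  expect_identical(um$samples$r, um2$samples$r)
})
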