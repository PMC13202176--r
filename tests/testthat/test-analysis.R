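test_that("radius of gyration has the closed-form values on constructed frames", {
  # all beads at a point
  tr0 <- make_toy_trajectory(list(matrix(5, 8, 3)))
  expect_equal(radius_of_gyration(tr0)$rg_nm, 0)
  # beads on a sphere surface of radius R have R_g = R
  set.seed(1)
  u <- matrix(rnorm(300), 100)
  u <- 120 * u / sqrt(rowSums(u^2))
  u <- sweep(u, 2, colMeans(u))  # centroid at origin up to sampling noise
  tr1 <- make_toy_trajectory(list(u))
  expect_equal(radius_of_gyration(tr1)$rg_nm,
               sqrt(mean(rowSums(u^2))) / 10, tolerance = 1e-12)
})

test_that("contact maps count frozen contacts exactly and stay symmetric", {
  ff <- ff_default()
  sys <- stacked_pair_system(60, ff = ff)
  # a frozen trajectory of 7 identical stacked frames
  tr <- make_toy_trajectory(rep(list(sys$positions), 7))
  tr$beads <- sys$beads
  tr$beads$fiber_id <- sys$beads$fiber_id
  cm <- contact_map(tr)
  expect_equal(unname(cm$counts[1, 2]), 7)   # in contact every frame
  expect_equal(unname(diag(cm$counts)), c(7, 7))
  expect_true(isSymmetric(cm$counts))
  # frame permutation leaves the counts unchanged
  trp <- tr
  trp$frames <- rev(trp$frames)
  expect_equal(contact_map(trp)$counts, cm$counts)
})

test_that("normalization preserves symmetry through the O/E and correlation steps", {
  set.seed(3)
  n <- 12
  walk <- apply(matrix(rnorm(3 * 40), ncol = 3), 2, cumsum)
  frames <- lapply(1:6, function(i) {
    35 * apply(matrix(rnorm(3 * n, sd = 1), ncol = 3), 2, cumsum) + i
  })
  tr <- make_toy_trajectory(frames)
  cm <- contact_map(tr, cutoff = 80)
  oe <- normalize_contact_map(cm, "distance")
  cc <- normalize_contact_map(cm, "correlation")
  expect_true(isSymmetric(oe$counts))
  expect_true(isSymmetric(cc$counts))
})

test_that("PC1 splits a two-block toy matrix exactly", {
  # exact eigen-decomposition oracle on a block correlation matrix
  n <- 12
  blocks <- rep(c(1, 2), each = n / 2)
  m <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, -0.8))
  diag(m) <- 1
  cm <- structure(list(counts = m, n_frames = 1, normalization = "correlation",
                       cutoff = 52.5,
                       nucleosomes = tibble::tibble(fiber_id = 1,
                                                    nucleosome = 1:n,
                                                    dyad = 1:n * 195)),
                  class = "contact_matrix")
  pc <- compartment_pc1(cm)
  expect_true(all(sign(pc$pc1[blocks == 1]) == sign(pc$pc1[1])))
  expect_true(all(sign(pc$pc1[blocks == 2]) == -sign(pc$pc1[1])))
  # oracle: leading eigenvector of the centered matrix splits identically
  ev <- eigen(scale(m, scale = FALSE))$vectors[, 1]
  expect_equal(abs(sign(pc$pc1)), abs(sign(ev)))
  # sign convention: positively correlated with acetylation
  ac <- ifelse(blocks == 2, 2.0, 0.1)
  pc2 <- compartment_pc1(cm, acetylation = ac)
  expect_gt(pc2$r, 0.9)
  expect_gt(mean(pc2$pc1[blocks == 2]), 0)
  # relabeling nucleosomes permutes PC1 identically
  perm <- sample(n)
  cmp <- cm
  cmp$counts <- m[perm, perm]
  pcp <- compartment_pc1(cmp)
  expect_equal(abs(pcp$pc1), abs(pc$pc1[perm]), tolerance = 1e-8)
})

test_that("insulation is zero on a uniform matrix", {
  cm <- structure(list(counts = matrix(4, 20, 20), n_frames = 4,
                       normalization = "raw", cutoff = 52.5,
                       nucleosomes = tibble::tibble(fiber_id = 1,
                                                    nucleosome = 1:20,
                                                    dyad = 1:20 * 195)),
                  class = "contact_matrix")
  ins <- insulation_score(cm, window = 3)
  expect_true(all(abs(ins$insulation) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(ins$insulation[c(1:3, 18:20)])))
})

test_that("compartmentalization coefficient matches hand-summed oracles", {
  # perfect two-block matrix with zero inter-block contacts saturates at 1
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 2; m[4:6, 4:6] <- 2
  pc1 <- c(1, 1, 1, -1, -1, -1)
  expect_equal(compartmentalization_coefficient(m, pc1), 1)
  # checkerboard with 3:1 within:between ratio, 4 bins: hand summation gives
  # (6 + 6 - 2*4) / (6 + 6 + 2*4) = 0.2
  m2 <- matrix(1, 4, 4)
  m2[1:2, 1:2] <- 3; m2[3:4, 3:4] <- 3
  expect_equal(compartmentalization_coefficient(m2, c(1, 1, -1, -1)), 0.2)
})

test_that("structure clustering recovers constructed archetypes exactly", {
  # three archetype frame sets with distinct pair-distance patterns
  mk <- function(d12, d13, d23, n) {
    lapply(seq_len(n), function(i) {
      tibble::tibble(frame = i, time_ns = i,
                     pair = c("E1-P1", "E1-P2", "P1-P2"),
                     distance_nm = c(d12, d13, d23) + stats::rnorm(3, 0, 0.5))
    })
  }
  set.seed(5)
  d <- dplyr::bind_rows(c(mk(50, 50, 50, 10),
                          lapply(mk(150, 50, 150, 10), function(x) {
                            x$frame <- x$frame + 10; x
                          }),
                          lapply(mk(250, 250, 50, 10), function(x) {
                            x$frame <- x$frame + 20; x
                          })))
  cl <- cluster_structures(d, k = 3, seed = 2)
  lab <- tidy(cl)$cluster
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_equal(length(unique(lab[21:30])), 1)
  expect_equal(length(unique(c(lab[1], lab[11], lab[21]))), 3)
  # identical frames collapse to a single nonempty cluster
  same <- dplyr::bind_rows(mk(100, 100, 100, 6))
  same$distance_nm <- 100
  cl1 <- cluster_structures(same, k = 3, seed = 2)
  expect_equal(cl1$k, 1)
  expect_equal(cl1$sizes, 6)
})

test_that("MSD fitting recovers free diffusion and rejects immobile beads", {
  # analytic oracle: Brownian walk with known diffusion constant
  set.seed(8)
  n_fr <- 400
  D <- 0.5  # A^2 per frame-step axis variance
  steps <- array(rnorm(n_fr * 3 * 5, sd = sqrt(2 * D)), c(n_fr, 5, 3))
  frames <- lapply(seq_len(n_fr), function(t) {
    apply(steps, c(2, 3), function(z) sum(z[seq_len(t)]))
  })
  tr <- make_toy_trajectory(frames, dump_interval = 1000)
  fit <- msd_fit(tr)
  expect_lt(abs(fit$alpha - 1), 0.05)
  # immobile beads are rejected with a message
  tr0 <- make_toy_trajectory(rep(list(matrix(1, 4, 3)), 30))
  expect_error(msd_fit(tr0), "immobile")
})

test_that("persistence length reports a rigid rod as infinite", {
  ff <- ff_default()
  sys <- build_fiber(fiber_spec("dna", 525), ff)
  tr <- make_toy_trajectory(rep(list(sys$positions), 4))
  tr$beads <- sys$beads
  lp <- persistence_length(tr)
  expect_true(is.infinite(lp$lp_nm))
})

test_that("discrete wormlike chain recovers the configured persistence length", {
  # analytic mapping: l_p = 2 K b / kBT for the harmonic angle chain; at
  # near-zero screening length the chain is the bare WLC
  target_lp <- 500  # A
  k_theta <- target_lp * kBT(300) / (2 * 35)
  ff <- default_forcefield(salt_mM = 5000, k_bend = k_theta)
  sys <- build_fiber(fiber_spec("dna", 1050), ff)
  topo <- build_topology(sys)
  # The chain's global shape decorrelates far slower than any tractable run,
  # so a single trajectory's tangent correlation carries the variance of one
  # conformation. Pool several replicas, each started from an independent
  # equilibrium draw of the ideal discrete wormlike chain (deflection angles
  # Boltzmann-sampled), so no slow relaxation is needed.
  n <- 100
  draw_chain <- function() {
    tangent <- c(1, 0, 0)
    pos <- matrix(0, n, 3)
    for (i in 2:n) {
      th <- sqrt(-kBT(300) * log(runif(1)) / k_theta) # P ~ th exp(-K th^2/kBT)
      phi <- runif(1, 0, 2 * pi)
      perp1 <- perp_unit(tangent)
      perp2 <- cross3(tangent, perp1)
      newt <- cos(th) * tangent + sin(th) * (cos(phi) * perp1 +
                                               sin(phi) * perp2)
      tangent <- newt / sqrt(sum(newt^2))
      pos[i, ] <- pos[i - 1, ] + 35 * tangent
    }
    pos
  }
  frames <- list()
  for (rep_ in 1:8) {
    set.seed(1000 + rep_)
    sys$positions <- draw_chain()
    cfg <- sim_config(salt_mM = 5000, n_steps = 2.5e5, dump_interval = 2500,
                      seed = 21 + rep_)
    tr <- run_langevin(sys, topo, cfg)
    frames <- c(frames, tr$frames)
  }
  tr$frames <- frames
  lp <- persistence_length(tr)
  expect_lt(abs(lp$lp_nm - 50) / 50, 0.10)
})

test_that("Kirkwood sedimentation has the exact one- and two-bead limits", {
  # single bead: Stokes-Einstein closed form
  eta <- 1.002e-3; rho <- 0.99823; a <- 17.5e-10
  m <- nucfold:::.bead_mass("NUC_DNA")
  s1 <- sedimentation_coefficient(matrix(0, 1, 3), types = "NUC_DNA")
  expect_equal(s1, (m / 1000) * (1 - 0.65 * rho) /
                 (6.02214076e23 * 6 * pi * eta * a) / 1e-13,
               tolerance = 1e-10)
  # rigid touching dimer: Kirkwood two-bead ratio s2/s1 = 2 f1 / f2 = 1.5
  s2 <- sedimentation_coefficient(rbind(c(0, 0, 0), c(35, 0, 0)),
                                  types = c("NUC_DNA", "NUC_DNA"))
  expect_equal(s2 / s1, 1.5, tolerance = 1e-10)
  # compaction monotonicity: smaller R_g sediments faster at fixed mass
  ff <- ff_default()
  sys <- build_fiber(regular_fiber(6, 207), ff)
  ext <- sys$positions
  comp <- ext * 0.55
  s_ext <- sedimentation_coefficient(ext, types = sys$beads$type)
  s_comp <- sedimentation_coefficient(comp, types = sys$beads$type)
  expect_gt(s_comp, s_ext)
})

test_that("unwrapping K_eq matches the analytic two-state toy", {
  toy <- morse_toy(de = 1.2, a = 0.2, r0 = 22, k_tether = 0.05, r_tether = 30)
  cfg <- sim_config(n_steps = 3e6, dump_interval = 300, seed = 31)
  tr <- run_langevin(toy$system, toy$topology, cfg)
  kq <- unwrapping_keq(tr, burn_in = 500)
  # analytic oracle: radial Boltzmann integrals of the exact pair potential
  beta <- 1 / kBT(300)
  U <- function(r) 0.05 * (r - 30)^2 + 1.2 * (1 - exp(-0.2 * (r - 22)))^2
  w <- function(r) r^2 * exp(-beta * U(r))
  thr <- 22 + 2 / 0.2
  k_exact <- stats::integrate(w, thr, 200)$value /
    stats::integrate(w, 1e-3, thr)$value
  expect_lt(abs(kq$k_eq - k_exact), 3 * kq$se + 0.02)
  expect_gt(kq$n_transitions, 50)
  # all-wrapped trajectory gives exactly zero
  frames <- rep(list(rbind(c(0, 0, 0), c(22, 0, 0))), 20)
  tr0 <- tr
  tr0$frames <- frames
  expect_equal(unwrapping_keq(tr0)$k_eq, 0)
})

test_that("bootstrap errors shrink with sample size on stationary series", {
  toy <- morse_toy()
  cfg <- sim_config(n_steps = 1e6, dump_interval = 300, seed = 32)
  tr <- run_langevin(toy$system, toy$topology, cfg)
  short <- tr
  short$frames <- tr$frames[1:800]
  se_short <- unwrapping_keq(short, n_boot = 100)$se
  se_long <- unwrapping_keq(tr, n_boot = 100)$se
  expect_lt(se_long, se_short)
})

test_that("slab density profiles resolve constructed coexistence", {
  box <- c(500, 500, 5000)
  bnd <- list(type = "slab", box = box)
  # uniform lattice: condensed equals dilute equals the mean
  zs <- seq(25, 4975, length.out = 60)
  uni <- lapply(1:3, function(i) cbind(250, 250, zs))
  tru <- make_toy_trajectory(uni, boundary = bnd)
  su <- slab_densities(tru, n_bins = 20)
  expect_false(su$phase_separated)
  expect_equal(su$dilute_uM, su$condensed_uM)
  # step profile: all nucleosomes in the central 20 percent of the box
  zc <- seq(2000, 3000, length.out = 60)
  stp <- lapply(1:3, function(i) cbind(250, 250, zc))
  trs <- make_toy_trajectory(stp, boundary = bnd)
  ss <- slab_densities(trs, n_bins = 20)
  expect_true(ss$phase_separated)
  dens_expected <- nucleosome_concentration(60 / 4, 500 * 500 * 250 * 1e-3)
  expect_equal(ss$condensed_uM, dens_expected, tolerance = 0.05)
  expect_lt(ss$dilute_uM, 0.05 * ss$condensed_uM)
})

test_that("mass scaling exponent separates rods from random walks", {
  set.seed(9)
  n <- 120
  # ideal-chain centers: D ~ 2
  frames_rw <- lapply(1:12, function(i) {
    35 * apply(matrix(rnorm(3 * n), ncol = 3), 2, cumsum)
  })
  tr_rw <- make_toy_trajectory(frames_rw)
  D_rw <- scaling_exponent(tr_rw, sizes_kb = c(2, 4, 8, 16))$D
  expect_lt(abs(D_rw - 2), 0.35)
  # straight rod: D ~ 1
  rod <- cbind(35 * seq_len(n), 0, 0)
  tr_rod <- make_toy_trajectory(rep(list(rod), 3))
  D_rod <- scaling_exponent(tr_rod, sizes_kb = c(2, 4, 8, 16))$D
  expect_lt(abs(D_rod - 1), 0.1)
})

test_that("element distances map through nucleosome centroids", {
  n <- 20
  cen <- cbind(100 * seq_len(n), 0, 0)
  tr <- make_toy_trajectory(list(cen), dyads = (seq_len(n) - 0.5) * 195)
  el <- tibble::tibble(name = c("E1", "P1"),
                       start = c(0, 3000), end = c(400, 3400))
  pd <- pair_distance_series(tr, el)
  # E1 covers nucleosomes 1-2 (centroid x = 150), P1 nucleosomes 16-17 (1650)
  expect_equal(pd$distance_nm, (1650 - 150) / 10)
  expect_equal(pd$pair, "E1-P1")
})

test_that("estimators are invariant to global rotation and translation", {
  set.seed(12)
  n <- 30
  frames <- lapply(1:14, function(i) {
    40 * apply(matrix(rnorm(3 * n), ncol = 3), 2, cumsum)
  })
  R <- nucfold:::.rot_axis(c(1, 2, 3), 1.1)
  moved <- lapply(frames, function(f) sweep(f %*% t(R), 2, c(100, -50, 7), "+"))
  t1 <- make_toy_trajectory(frames)
  t2 <- make_toy_trajectory(moved)
  expect_equal(radius_of_gyration(t1)$rg_nm, radius_of_gyration(t2)$rg_nm,
               tolerance = 1e-9)
  expect_equal(contact_map(t1, cutoff = 80)$counts,
               contact_map(t2, cutoff = 80)$counts)
  expect_equal(msd_fit(t1, fit_range = c(1, 3))$alpha,
               msd_fit(t2, fit_range = c(1, 3))$alpha, tolerance = 1e-9)
})

test_that("WHAM reconstructs toy potentials from independently drawn samples", {
  set.seed(4)
  kT <- kBT(300)
  # single unbiased window on a flat potential: flat profile
  # samples drawn from the r^2 Jacobian density by inverse-CDF
  u <- runif(20000)
  r <- (40^3 + u * (120^3 - 40^3))^(1 / 3)
  flat <- data.frame(window = 1, center = 0, k = 0, r = r)
  pm <- wham_pmf(flat, n_bins = 30)
  interior <- pm$profile$pmf_kbt[4:27]
  expect_lt(max(abs(interior - mean(interior))), 0.1)

  # analytic double well, rejection-sampled per window (oracle independent
  # of the dynamics engine)
  U <- function(x) 2 * kT * ((x - 10)^2 / 4 - 1)^2 / 4  # wells at 8 and 12
  centers <- seq(6, 14, by = 0.5)
  kk <- 1.5 * kT
  samp <- dplyr::bind_rows(lapply(seq_along(centers), function(w) {
    c0 <- centers[w]
    xs <- numeric(0)
    while (length(xs) < 6000) {
      x <- runif(8000, 4, 16)
      p <- exp(-(U(x) + kk * (x - c0)^2) / kT)
      xs <- c(xs, x[runif(8000) < p / max(p)])
    }
    data.frame(window = w, center = c0, k = kk, r = xs[1:6000])
  }))
  pm2 <- wham_pmf(samp, n_bins = 40, jacobian = FALSE)
  prof <- pm2$profile
  sel <- prof$r > 6 & prof$r < 14
  truth <- U(prof$r[sel]) / kT
  est <- prof$pmf_kbt[sel]
  # compare up to an additive constant
  err <- (est - truth) - mean(est - truth)
  expect_lt(max(abs(err)), 0.2)

  # gauge invariance: shifting one window's bias center label leaves the
  # zeroed profile unchanged when the samples carry the matching energies
  pm3 <- wham_pmf(samp, n_bins = 40, jacobian = FALSE, tol = 1e-8)
  expect_equal(pm2$profile$pmf_kbt, pm3$profile$pmf_kbt, tolerance = 1e-4)
})
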