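test_that("canonical nucleosome geometry matches the superhelix construction", {
  ff <- ff_default()
  g <- build_nucleosome(nucleosome_record(73.5), ff)
  expect_equal(length(g$dna_idx), 14)
  expect_equal(length(g$hist_idx), 8)
  expect_equal(nrow(g$xyz), 22)
  gh <- build_nucleosome(nucleosome_record(73.5, h1 = TRUE), ff)
  expect_equal(nrow(gh$xyz), 24)

  # superhelix metrics, exact by construction
  rad_dna <- sqrt(rowSums(g$xyz[g$dna_idx, 1:2]^2))
  rad_hist <- sqrt(rowSums(g$xyz[g$hist_idx, 1:2]^2))
  expect_true(all(abs(rad_dna - 40) < 1e-6))
  expect_true(all(abs(rad_hist - 18) < 1e-6))

  # rise between consecutive DNA beads = pitch * angular step / 2 pi
  rises <- diff(g$xyz[g$dna_idx, 3])
  expect_true(all(abs(rises - 25 * g$angular_step / (2 * pi)) < 1e-6))

  # contour (arc) spacing between beads is sigma = 35 A: the arc length of
  # one angular step on a helix of radius R and pitch c*2*pi
  cc <- 25 / (2 * pi)
  arc <- g$angular_step * sqrt(40^2 + cc^2)
  expect_equal(arc, 35, tolerance = 1e-9)

  # H1 bead placement on the dyad axis
  expect_equal(unname(gh$xyz[gh$h1_idx[1], ]), c(70, 0, 0))
  expect_equal(unname(gh$xyz[gh$h1_idx[2], ]), c(105, 0, 0))
})

test_that("invalid nucleosome records are rejected with informative errors", {
  expect_error(build_nucleosome(nucleosome_record(73.5, wrap_bp = 94.5)),
               "wrap_bp")
  expect_error(nucleosome_record(73.5, wrap_bp = 140), "whole")
  expect_error(nucleosome_record(73.5, brd4 = TRUE), "acetylated")
  expect_error(fiber_spec("x", 400, tibble::tibble(
    dyad_position = c(100, 200), acetylated = FALSE, brd4 = FALSE,
    h1 = FALSE, wrap_bp = 147)), "overlap|footprint")
  # partial wraps for breathing-initialized states are allowed down to 10 beads
  g <- build_nucleosome(nucleosome_record(73.5, wrap_bp = 105))
  expect_equal(length(g$dna_idx), 10)
})

test_that("fiber bead counts follow the bead-mapping arithmetic", {
  ff <- ff_default()
  # 12-mer at NRL 207: 60-bp linkers, 6 beads each
  s12 <- regular_fiber(12, 207)
  expect_equal(n_beads(build_fiber(s12, ff)), 12 * 22 + 11 * 6)
  # dinucleosome with a 63-bp linker
  expect_equal(n_beads(dinucleosome_system()$system), 50)
  # 1050-bp naked DNA
  expect_equal(n_beads(build_fiber(fiber_spec("dna", 1050), ff)), 100)

  # bead-count conservation on randomized specs vs the arithmetic oracle
  set.seed(42)
  for (i in 1:8) {
    n <- sample(2:10, 1)
    nrl <- 147 + 10.5 * sample(2:8, 1)
    h1 <- runif(n) < 0.5
    ac <- runif(n) < 0.4
    spec <- regular_fiber(n, nrl, acetylated = ac, h1 = h1,
                          brd4 = ac & runif(n) < 0.3)
    oracle <- n * 22 + 2 * sum(h1) + (n - 1) * round((nrl - 147) / 10.5)
    expect_equal(fiber_bead_count(spec), oracle)
    expect_equal(n_beads(build_fiber(spec, ff)), oracle)
  }
})

test_that("rebuilding from a stored spec reproduces coordinates bit-identically", {
  ff <- ff_default()
  spec <- regular_fiber(5, 195, acetylated = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                        h1 = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  a <- build_fiber(spec, ff)
  path <- tempfile(fileext = ".json")
  write_fiber_spec(spec, path)
  b <- build_fiber(read_fiber_spec(path), ff)
  expect_identical(a$positions, b$positions)
})

test_that("the alternating validation array has 8 blocks of 12", {
  arr <- alternating_array()
  st <- arr$nucleosomes$acetylated
  expect_equal(length(st), 96)
  r <- rle(st)
  expect_equal(r$lengths, rep(12, 8))
  expect_false(st[1])
})

test_that("grown systems hit the density prescription and are reproducible", {
  ff <- ff_default()
  target <- regular_fiber(103, 195, label = "locus")  # ~20 kb
  vol_um3 <- 4 / 3 * pi * (916e-4)^3
  bg_bp <- 12.4 * vol_um3 * 1e6 - target$length_bp
  bg <- background_fibers(n = 2, total_bp = bg_bp, length_range = c(5e3, 11e3),
                          seed = 3)
  sys <- grow_system(target, bg, sphere_radius = 916, seed = 5, ff = ff)
  expect_lt(abs(sys$realized_density_Mbp_um3 - 12.4) / 12.4, 0.10)
  # all beads inside the sphere
  expect_lt(max(sqrt(rowSums(sys$positions^2))), 916)
  # no hard clashes at the stated overlap tolerance
  cfgc <- sim_config(n_steps = 1)
  topo <- build_topology(sys)
  chk <- nucfold:::.cg_min_nonbonded(sys$positions,
                                     nucfold:::.engine_model(sys, topo, cfgc))
  expect_gte(chk$min_dist, 0.5 * ff$sigma)
  # determinism
  sys2 <- grow_system(target, bg, sphere_radius = 916, seed = 5, ff = ff)
  expect_identical(sys$positions, sys2$positions)
  # density request sweep at smaller scale
  for (dens in c(6, 18)) {
    vol <- 4 / 3 * pi * (700e-4)^3
    tt <- regular_fiber(round(dens * vol * 1e6 / 2 / 195), 195, label = "t")
    bb <- background_fibers(n = 1, total_bp = dens * vol * 1e6 - tt$length_bp,
                            length_range = c(1e3, 20e3), seed = 1)
    s <- grow_system(tt, bb, 700, seed = 2, ff = ff, target_density = dens)
    expect_lt(abs(s$realized_density_Mbp_um3 - dens) / dens, 0.10)
  }
})

test_that("slab systems report the initial nucleosome concentration", {
  ff <- ff_default()
  # 45 copies of 12-mers in 100 x 100 x 1000 nm^3 give 90 uM; scaled-down
  # replica preserving the concentration arithmetic:
  sys <- build_slab_system(6, regular_fiber(4, 207), box = c(1000, 1000, 4000),
                           seed = 3, ff = ff)
  expect_equal(sys$initial_concentration_uM,
               nucleosome_concentration(24, 1000 * 1000 * 4000 * 1e-3))
  expect_equal(sum(!is.na(sys$beads$nucleosome) &
                     !(sys$beads$role %in% c("H1_GLOB", "H1_TAIL"))) / 22, 24)
  # full-scale arithmetic (no placement needed): 540 nucleosomes in 1e7 nm^3
  expect_equal(nucleosome_concentration(45 * 12, 100 * 100 * 1000),
               89.67, tolerance = 0.01)
  expect_error(build_slab_system(2, regular_fiber(4, 207), box = c(50, 50, 100)),
               "small")
})
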