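test_that("pair matrix is symmetric with the model strength ordering", {
  pm <- pair_matrix()
  expect_true(isSymmetric(unclass(pm)))
  e0 <- pm["CANONICAL_NUC", "CANONICAL_NUC"]
  eac <- pm["ACETYL_NUC", "ACETYL_NUC"]
  eh <- pm["CANONICAL_NUC", "ACETYL_NUC"]
  eb <- pm["ACETYL_NUC", "ACETYL_BRD4_NUC"]
  expect_true(eac < eh && eh < e0 && e0 < eb)
  expect_equal(eh, sqrt(e0 * eac))  # geometric-mean mixing
  expect_true(all(pm > 0))
  # ordering holds across random valid configurations
  set.seed(7)
  for (i in 1:10) {
    e0i <- runif(1, 0.05, 0.3)
    eaci <- runif(1, 0.01, e0i * 0.9)
    pmi <- pair_matrix(eps0 = e0i, eps_ac = eaci, eps_b = e0i * runif(1, 1.1, 3))
    expect_true(isSymmetric(unclass(pmi)))
    expect_true(pmi["ACETYL_NUC", "ACETYL_NUC"] <
                  pmi["CANONICAL_NUC", "ACETYL_NUC"])
  }
})

test_that("the 20 bead types map onto 5 classes with the model charges", {
  tt <- bead_type_table()
  expect_equal(nrow(tt), 20)
  expect_equal(length(unique(tt$class)), 5)
  expect_true(all(tt$diameter == 35))
  expect_equal(tt$charge[tt$type == "LINKER_DNA"], -7.35)
  expect_equal(tt$charge[tt$class == "LINKER_HISTONE"], c(5, 5))
  expect_true(all(tt$charge[grepl("NUC", tt$class)] == 0))
})

test_that("BRD4 enhancement applies only between acetylated nucleosomes", {
  pm <- pair_matrix()
  expect_equal(brd4_rule("ACETYL_BRD4", "ACETYL", pm),
               pm["ACETYL_NUC", "ACETYL_BRD4_NUC"])
  expect_equal(brd4_rule("ACETYL_BRD4", "ACETYL_BRD4", pm),
               pm["ACETYL_NUC", "ACETYL_BRD4_NUC"])
  expect_equal(brd4_rule("ACETYL_BRD4", "CANONICAL", pm),
               pm["CANONICAL_NUC", "ACETYL_NUC"])  # no enhancement
  expect_equal(brd4_rule("CANONICAL", "CANONICAL", pm), 0.115)
  expect_equal(brd4_rule("ACETYL", "ACETYL", pm), 0.06)
  expect_error(brd4_rule("NONSENSE", "ACETYL"), "unknown")
})

test_that("pair energies reproduce the Lennard-Jones minima and limits", {
  ff <- default_forcefield()
  rmin <- 2^(1 / 6) * 35
  # the truncation shift at 3 sigma raises the minimum by 4 eps (3^-12 - 3^-6),
  # about half a percent of eps
  u_cc <- pair_energy("CANONICAL_NUC", "CANONICAL_NUC", rmin, ff)
  expect_equal(u_cc, -0.115, tolerance = 0.01)
  expect_equal(u_cc, -0.115 - 4 * 0.115 * (3^-12 - 3^-6), tolerance = 1e-9)
  u_mix <- pair_energy("CANONICAL_NUC", "ACETYL_NUC", rmin, ff)
  expect_equal(u_mix, -sqrt(0.115 * 0.06), tolerance = 0.01)
  # uncharged pair vanishes beyond the cutoff
  expect_equal(pair_energy("CANONICAL_NUC", "ACETYL_NUC", 1e4, ff), 0)
  # continuity at the cutoff
  eps_ <- 1e-7
  for (cl in list(c("CANONICAL_NUC", "CANONICAL_NUC"),
                  c("LINKER_DNA", "LINKER_DNA"),
                  c("LINKER_DNA", "LINKER_HISTONE"))) {
    below <- pair_energy(cl[1], cl[2], ff$lj_cutoff - eps_, ff)
    above <- pair_energy(cl[1], cl[2], ff$lj_cutoff + eps_, ff)
    expect_lt(abs(below - above), 1e-10)
  }
})

test_that("Debye screening length matches the closed-form electrolyte theory", {
  # independent oracle: kappa^-1 = sqrt(eps0 epsr kB T / (2 NA e^2 I))
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23; e <- 1.602176634e-19
  NAv <- 6.02214076e23
  oracle <- function(I_molar, T, epsr) {
    sqrt(eps0 * epsr * kB * T / (2 * NAv * e^2 * I_molar * 1000)) * 1e10
  }
  expect_equal(debye_length(150, 300, 78), oracle(0.15, 300, 78),
               tolerance = 1e-6)
  expect_equal(debye_length(150, 300, 78), 7.85, tolerance = 0.02)
  expect_equal(debye_length(10, 300, 78), oracle(0.01, 300, 78),
               tolerance = 1e-6)
})

test_that("harmonic-bond sets equal the brute-force sub-38 A reference scan", {
  ff <- ff_default()
  wraps <- c(147, 126, 115.5)
  for (w in wraps) {
    spec <- fiber_spec("n", w, tibble::tibble(
      dyad_position = w / 2, acetylated = FALSE, brd4 = FALSE, h1 = w == 147,
      wrap_bp = w))
    geom <- build_nucleosome(spec$nucleosomes, ff)
    oracle <- scan_reference_bonds(geom, ff$bond_cut)
    topo <- build_topology(build_fiber(spec, ff), ff)
    got <- as.matrix(topo$bonds[, c("i", "j")])
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(unname(got), oracle$harmonic * 1.0)
    gm <- as.matrix(topo$morse[, c("i", "j")])
    gm <- t(apply(gm, 1, sort))
    expect_equal(unname(gm[order(gm[, 1]), , drop = FALSE]),
                 oracle$morse[order(oracle$morse[, 1]), , drop = FALSE] * 1.0)
  }
})

test_that("chain topologies carry the expected bond, angle and Morse counts", {
  ff <- ff_default()
  naked <- build_topology(build_fiber(fiber_spec("dna", 1050), ff))
  expect_equal(nrow(naked$bonds), 99)
  expect_equal(nrow(naked$angles), 98)
  expect_equal(nrow(naked$morse), 0)
  di <- dinucleosome_system()$topology
  expect_equal(nrow(di$morse), 4)  # one per entry/exit DNA bead
  # a single free bead carries no bonds and is still a valid system
  free <- build_fiber(fiber_spec("bead", 10.5), ff)
  expect_equal(nrow(build_topology(free)$bonds), 0)
})

test_that("the Morse well curvature matches its harmonic-equivalent stiffness", {
  ff <- ff_default()
  de <- ff$morse_de; a <- ff$morse_a; r0 <- 22
  morse <- function(r) de * (1 - exp(-a * (r - r0)))^2
  h <- 1e-4
  curv <- (morse(r0 + h) - 2 * morse(r0) + morse(r0 - h)) / h^2
  expect_equal(curv, 2 * de * a^2, tolerance = 1e-2)
})

test_that("in-silico mutations modify only the intended interactions", {
  ff <- ff_default()
  target <- regular_fiber(6, 195, label = "target",
                          acetylated = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                          brd4 = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                          h1 = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  bg <- regular_fiber(4, 195, label = "bg", h1 = TRUE)
  sys <- build_fiber(target, ff)
  sys2 <- build_fiber(bg, ff)
  # assemble a two-fiber system by concatenation through the grow machinery:
  specs <- list(target, bg)
  refs <- lapply(specs, nucfold:::.fiber_reference, ff = ff)
  pos <- rbind(refs[[1]]$xyz,
               sweep(refs[[2]]$xyz, 2, c(0, 500, 0), "+"))
  two <- nucfold:::.new_system(specs, refs, pos,
                               list(type = "none", box = c(0, 0, 0)), ff)

  m1 <- apply_mutation(two, "delta_brd4")
  tb <- m1$system$beads
  expect_equal(sum(tb$state == "ACETYL_BRD4" & tb$fiber_id == 1, na.rm = TRUE), 0)
  expect_equal(sum(m1$system$fibers[[1]]$nucleosomes$acetylated), 3)

  m2 <- apply_mutation(two, "delta_h1")
  expect_equal(sum(m2$system$beads$role %in% c("H1_GLOB", "H1_TAIL") &
                     m2$system$beads$fiber_id == 1), 0)
  # background H1 untouched
  expect_equal(sum(m2$system$beads$role == "H1_GLOB" &
                     m2$system$beads$fiber_id == 2), 4)

  m3 <- apply_mutation(two, "short_linker")
  old_nrl <- mean(diff(two$fibers[[1]]$nucleosomes$dyad_position))
  new_nrl <- mean(diff(m3$system$fibers[[1]]$nucleosomes$dyad_position))
  expect_equal(old_nrl - new_nrl, 10.5)
  # background spacing unchanged
  expect_equal(mean(diff(m3$system$fibers[[2]]$nucleosomes$dyad_position)), 195)

  m4 <- apply_mutation(two, "delta_interaction")
  pm <- m4$forcefield$pair_matrix
  expect_equal(unname(pm["CANONICAL_NUC", "CANONICAL_NUC"]), 0.06)
  expect_equal(unname(pm["CANONICAL_NUC", "ACETYL_BRD4_NUC"]), 0.06)
  # acetyl-BRD4 enhancement itself is untouched
  expect_equal(unname(pm["ACETYL_NUC", "ACETYL_BRD4_NUC"]), 0.23)
})
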