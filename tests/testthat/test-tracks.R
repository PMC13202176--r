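test_that("peak calling recovers a regular nucleosome lattice", {
  tk <- synth_tracks(50e3, seed = 2)
  dy <- call_nucleosome_positions(tk$positions)
  expect_equal(length(dy), nrow(tk$positions))   # every peak recovered
  expect_equal(mean(diff(dy)), 195, tolerance = 0.02)
})

test_that("the exclusion zone keeps only the stronger of two close peaks", {
  tr <- genomic_track("c", c(1000, 1100), c(1010, 1110), c(1.0, 2.0))
  dy <- call_nucleosome_positions(tr, min_spacing = 147)
  expect_equal(dy, 1105)
  # uniform zero signal: no calls, with a warning
  z <- genomic_track("c", c(0, 500), c(100, 600), c(0, 0))
  expect_warning(dy0 <- call_nucleosome_positions(z), "empty")
  expect_length(dy0, 0)
})

test_that("peak calling is invariant to positive rescaling of the track", {
  tk <- synth_tracks(30e3, seed = 9)
  a <- call_nucleosome_positions(tk$positions)
  scaled <- tk$positions
  scaled$value <- scaled$value * 137.5
  expect_identical(a, call_nucleosome_positions(scaled))
})

test_that("state assignment hits the target fractions for flat signals", {
  n <- 1000
  dyads <- (seq_len(n) - 0.5) * 195
  flat <- genomic_track("c", 0, n * 195, 1)
  st <- assign_states(dyads, flat, flat, flat,
                      target_fractions = c(0.20, 0.31, 0.167), seed = 11)
  ci <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(st$acetylated) - 0.20), ci(0.20))
  expect_lt(abs(mean(st$h1) - 0.31), ci(0.31))
  n_ac <- sum(st$acetylated)
  expect_lt(abs(mean(st$brd4[st$acetylated]) - 0.167),
            3 * sqrt(0.167 * (1 - 0.167) / n_ac))
  # BRD4 implies acetylated
  expect_true(all(st$acetylated[st$brd4]))
  # reproducibility
  st2 <- assign_states(dyads, flat, flat, flat, seed = 11)
  expect_identical(st$acetylated, st2$acetylated)
  # zero BRD4 signal means zero BRD4 flags
  zero <- genomic_track("c", 0, n * 195, 0)
  st3 <- assign_states(dyads, flat, flat, zero, seed = 11)
  expect_equal(sum(st3$brd4), 0)
})

test_that("synthetic tracks carry the configured statistical structure", {
  tk <- synth_tracks(50e3, block_scale = 12.5e3, seed = 4)
  # acetylation block scale within 20 percent of the configured 12.5 kb
  expect_lt(abs(track_block_scale(tk$ac) - 12.5e3) / 12.5e3, 0.20)
  # H1 anti-correlates with acetylation
  expect_lt(stats::cor(tk$ac$value, tk$h1$value), 0)
  # BRD4 peaks are nested inside acetylated blocks
  b_mid <- (tk$brd4$start + tk$brd4$end) / 2
  ac_at_brd4 <- nucfold:::.track_signal(tk$ac, b_mid - 50, b_mid + 50)
  expect_gt(min(ac_at_brd4), stats::median(tk$ac$value))
})

test_that("bedGraph round trip preserves intervals and values", {
  tk <- synth_tracks(20e3, seed = 6)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tk$ac, path)
  back <- read_track(path)
  expect_equal(as.data.frame(tk$ac), as.data.frame(back),
               ignore_attr = TRUE)
})

test_that("track-to-fiber mapping produces a valid stochastic single cell", {
  tk <- synth_tracks(50e3, seed = 3)
  fib <- fiber_from_tracks(tk$positions, tk$ac, tk$h1, tk$brd4, c(0, 50e3),
                           seed = 8)
  expect_s3_class(fib, "fiber_spec")
  nuc <- fib$nucleosomes
  expect_true(all(diff(nuc$dyad_position) >= 147))
  expect_true(all(nuc$acetylated[nuc$brd4]))
  # acetylated nucleosomes concentrate in high-signal blocks
  sig <- nucfold:::.track_signal(tk$ac, nuc$dyad_position - 73,
                                 nuc$dyad_position + 73)
  expect_gt(mean(sig[nuc$acetylated]), mean(sig[!nuc$acetylated]))
})

test_that("the packaged regulatory-element fixtures parse as BED", {
  bed <- read_bed(system.file("extdata", "pou5f1_elements.bed",
                              package = "nucfold"))
  expect_equal(bed$name, c("E1", "E2", "P1", "P2"))
  expect_true(all(bed$end > bed$start))
  # locus-relative sanity: P1 sits 21.4 kb into the 50-kb locus
  expect_equal((bed$start[3] + bed$end[3]) / 2 - 35484600, 21400)
})
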