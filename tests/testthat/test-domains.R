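test_that("two well-separated compact balls resolve as exactly two domains", {
  set.seed(2)
  ball <- function(center, n) {
    sweep(matrix(rnorm(3 * n, sd = 30), ncol = 3), 2, center, "+")
  }
  cen <- rbind(ball(c(0, 0, 0), 20), ball(c(2000, 0, 0), 20))
  tr <- make_toy_trajectory(list(cen))
  part <- infomap_domains(tr, frame = 1, cutoff = 120)
  expect_equal(length(unique(part$domain)), 2)
  expect_equal(length(unique(part$domain[1:20])), 1)
  expect_equal(length(unique(part$domain[21:40])), 1)
  # partition covers every nucleosome exactly once
  expect_equal(sort(part$id), 1:40)
  expect_false(any(is.na(part$domain)))
})

test_that("a fully connected clique is one domain; an empty graph is singletons", {
  cen <- matrix(rnorm(3 * 8, sd = 10), ncol = 3)
  tr <- make_toy_trajectory(list(cen))
  p1 <- infomap_domains(tr, frame = 1, cutoff = 500)
  expect_equal(length(unique(p1$domain)), 1)
  p0 <- infomap_domains(tr, frame = 1, cutoff = 1e-3)
  expect_equal(length(unique(p0$domain)), 8)
})

test_that("infomap partitions are map-equation optimal on small graphs", {
  # two 4-cliques joined by a single bridge edge: enumerate all Bell(8)=4140
  # partitions and compare code lengths
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(4, 5))
  parts <- enumerate_partitions(8)
  scores <- vapply(parts, function(p) map_equation(g, p), numeric(1))
  best <- min(scores)
  set.seed(1)
  cl <- igraph::cluster_infomap(g, nb.trials = 10)
  got <- map_equation(g, as.integer(igraph::membership(cl)))
  expect_lte(got, best + 1e-9)
  # two disconnected 5-cliques: the optimal partition is the split
  g2 <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  split <- rep(1:2, each = 5)
  merged <- rep(1, 10)
  expect_lt(map_equation(g2, split), map_equation(g2, merged))
  set.seed(1)
  cl2 <- igraph::cluster_infomap(g2, nb.trials = 10)
  expect_equal(map_equation(g2, as.integer(igraph::membership(cl2))),
               map_equation(g2, split))
})

test_that("domain tracking emits exactly the constructed events", {
  mk_part <- function(domains) {
    n <- length(domains)
    tibble::tibble(id = 1:n, fiber_id = 1L, nucleosome = 1:n,
                   state = "CANONICAL", dyad = (1:n) * 195,
                   domain = domains)
  }
  # static sequence: no events
  static <- lapply(1:5, function(i) mk_part(rep(1:2, each = 20)))
  expect_equal(nrow(track_domains(static)), 0)
  # one 40-member domain splitting into two 20-member domains
  seq2 <- list(mk_part(rep(1L, 40)), mk_part(rep(1:2, each = 20)))
  ev <- track_domains(seq2)
  expect_equal(nrow(ev[ev$type == "split", ]), 1)
  expect_equal(nrow(ev[ev$type == "merge", ]), 0)
  # the converse is one merge
  ev2 <- track_domains(rev(seq2))
  expect_equal(nrow(ev2[ev2$type == "merge", ]), 1)
  # stride-doubling on a slowly varying sequence preserves the event list
  slow <- list(mk_part(rep(1L, 40)), mk_part(rep(1L, 40)),
               mk_part(rep(1:2, each = 20)), mk_part(rep(1:2, each = 20)))
  ev_all <- track_domains(slow)
  ev_strided <- track_domains(slow[c(1, 3)])
  expect_equal(ev_all[, c("type", "domain")], ev_strided[, c("type", "domain")])
})

test_that("clutch detection segments collapsed regions against hand-built frames", {
  # nucleosomes 1-6 collapsed to ~12 A spacing, 7-12 extended at 300 A
  collapsed <- cbind(12 * (1:6), 0, 0)
  extended <- cbind(72 + 300 * (1:6), 0, 0)
  cen <- rbind(collapsed, extended)
  tr <- make_toy_trajectory(list(cen))
  cl <- clutch_detect(tr, frame = 1, window = 4)
  expect_equal(nrow(cl$clutches), 1)
  expect_equal(cl$clutches$start, 1)
  expect_gte(cl$clutches$end, 6)
  expect_gte(cl$clutches$size, 4)
  # clutches and intervals tile the fiber exactly
  segs <- dplyr::arrange(dplyr::bind_rows(cl$clutches, cl$intervals), start)
  expect_equal(segs$start[1], 1)
  expect_equal(segs$end[nrow(segs)], 12)
  expect_true(all(diff(segs$start) == segs$size[-nrow(segs)]))
  # windows exactly at the threshold are not clutches (strictly-below rule)
  uni <- cbind(100 * (1:12), 0, 0)
  tru <- make_toy_trajectory(list(uni))
  cl0 <- clutch_detect(tru, frame = 1, window = 4)
  expect_equal(nrow(cl0$clutches), 0)
})

test_that("stacking classification implements the distance and angle cutoffs", {
  ff <- ff_default()
  g <- build_nucleosome(nucleosome_record(73.5), ff)
  place <- function(dist, angle_deg) {
    R <- nucfold:::.rot_axis(c(1, 0, 0), angle_deg * pi / 180)
    sweep(g$xyz %*% t(R), 2, c(0, 0, dist), "+")
  }
  expect_equal(as.character(stacking_classify(g$xyz, place(60, 0))), "stacked")
  expect_equal(as.character(stacking_classify(g$xyz, place(80, 0))),
               "contact-unstacked")
  expect_equal(as.character(stacking_classify(g$xyz, place(70, 45))),
               "contact-unstacked")
  expect_equal(as.character(stacking_classify(g$xyz, place(400, 0))),
               "no-contact")
  # axes are undirected: a flipped partner still stacks
  flipped <- sweep(g$xyz %*% diag(c(1, -1, -1)), 2, c(0, 0, 60), "+")
  expect_equal(as.character(stacking_classify(g$xyz, flipped)), "stacked")
  # stacked pairs are a subset of contact pairs
  cls <- stacking_classify(g$xyz, place(60, 10))
  expect_true(attr(cls, "distance") < 75)
})

test_that("same-domain frequency is exact on frozen partitions", {
  mk_part <- function(domains, states) {
    n <- length(domains)
    tibble::tibble(id = 1:n, fiber_id = 1L, nucleosome = 1:n,
                   state = states, dyad = (1:n) * 195, domain = domains)
  }
  states <- rep("CANONICAL", 30)
  # single-domain system: frequency 1 everywhere
  parts <- lapply(1:4, function(i) mk_part(rep(1L, 30), states))
  f <- same_domain_frequency(parts, bin_bp = 400, max_bp = 4000)
  expect_true(all(f$frequency == 1))
  # frozen two-block fixture: step function at the boundary distance
  blocks <- rep(1:2, each = 15)
  parts2 <- lapply(1:4, function(i) mk_part(blocks, states))
  f2 <- same_domain_frequency(parts2, bin_bp = 195, max_bp = 195 * 29)
  # pairs 195 bp apart: 28 within-block of 29 total
  first <- f2[f2$distance_bp == min(f2$distance_bp), ]
  expect_equal(first$frequency, 28 / 29)
  far <- f2[f2$distance_bp == max(f2$distance_bp), ]
  expect_equal(far$frequency, 0)
})
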