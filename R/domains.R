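#' Per-frame spatial domains by map-equation community detection
#'
#' Builds the spatial-proximity graph of one frame (nodes = all nucleosomes,
#' target and background; unweighted edges between nucleosome pairs whose
#' minimum inter-bead distance is below the contact cutoff) and partitions it
#' with the Infomap algorithm (two-level map equation, 10 seeded outer
#' trials). An empty graph leaves every nucleosome in its own domain.
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param frame Frame index.
#' @param cutoff Contact cutoff, Angstrom (same definition as
#'   [contact_map()]).
#' @param seed Seed for the stochastic search.
#' @param trials Infomap outer trials.
#' @return A `domain_partition`: tibble with `id` (nucleosome), `fiber_id`,
#'   `nucleosome`, `state`, `domain`, plus attributes `frame` and the
#'   per-domain summary (`members`, `size`, `rg_nm`).
#' @export
infomap_domains <- function(trajectory, frame = 1, cutoff = 52.5, seed = 1,
                            trials = 10) {
  nt <- .nucleosome_table(trajectory$beads)
  stopifnot(nrow(nt) >= 2)
  pos <- trajectory$frames[[frame]]
  group <- integer(nrow(trajectory$beads))
  for (k in seq_len(nrow(nt))) group[nt$beads[[k]]] <- nt$id[k]
  box <- if (trajectory$boundary$type == "slab") {
    as.numeric(trajectory$boundary$box)
  } else {
    c(0, 0, 0)
  }
  ed <- .cg_contact_pairs(pos, group, nrow(nt), cutoff, box)
  g <- igraph::make_empty_graph(n = nrow(nt), directed = FALSE)
  if (nrow(ed) > 0) g <- igraph::add_edges(g, t(ed))
  memb <- if (igraph::ecount(g) == 0) {
    seq_len(nrow(nt))
  } else {
    set.seed(seed %% .Machine$integer.max)
    cl <- igraph::cluster_infomap(g, nb.trials = trials)
    igraph::membership(cl)
  }
  part <- tibble(id = nt$id, fiber_id = nt$fiber_id,
                 nucleosome = nt$nucleosome, state = nt$state,
                 dyad = nt$dyad, domain = as.integer(memb))
  centers <- nucleosome_centers(pos, nt)
  dsum <- dplyr::group_by(part, .data$domain)
  dsum <- dplyr::summarise(
    dsum, size = dplyr::n(),
    rg_nm = {
      x <- centers[.data$id, , drop = FALSE]
      sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2))) / 10
    }, .groups = "drop")
  attr(part, "frame") <- frame
  attr(part, "domains") <- dsum
  class(part) <- c("domain_partition", class(part))
  part
}

#' Two-level map equation of a partition
#'
#' Code length (bits) of the two-level map equation for an undirected,
#' unweighted graph under a given node-to-module assignment. Used as the
#' exhaustive-search oracle for community detection on small graphs: on
#' graphs of a dozen nodes every partition can be enumerated
#' ([enumerate_partitions()]) and the returned minimum compared against the
#' Infomap result.
#'
#' @param graph An igraph object (undirected, unweighted).
#' @param membership Integer module id per node.
#' @return Code length in bits.
#' @export
map_equation <- function(graph, membership) {
  E <- igraph::ecount(graph)
  stopifnot(E > 0)
  deg <- igraph::degree(graph)
  p <- deg / (2 * E)                      # node visit rates
  el <- igraph::as_edgelist(graph, names = FALSE)
  mods <- sort(unique(membership))
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  q <- vapply(mods, function(m) {
    cut <- sum(xor(membership[el[, 1]] == m, membership[el[, 2]] == m) &
                 (membership[el[, 1]] == m | membership[el[, 2]] == m))
    cut / (2 * E)
  }, numeric(1))
  qt <- sum(q)
  idx_term <- plogp(qt) - sum(plogp(q))
  mod_term <- sum(vapply(seq_along(mods), function(k) {
    m <- mods[k]
    pm <- sum(p[membership == m])
    tot <- q[k] + pm
    plogp(tot) - plogp(q[k]) - sum(plogp(p[membership == m]))
  }, numeric(1)))
  idx_term + mod_term
}

#' Enumerate all set partitions of n items
#'
#' Restricted-growth-string enumeration; practical for n of about a dozen.
#'
#' @param n Number of items.
#' @return List of integer membership vectors.
#' @export
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, kmax) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(kmax + 1)) {
      rec(c(prefix, v), max(kmax, v))
    }
  }
  rec(integer(0), 0L)
  out
}

#' Track domains over time: splits, merges, births, deaths
#'
#' Matches the domains of consecutive partitions by maximal member overlap.
#' A parent splitting into several substantial children (each receiving at
#' least `min_share` of its members) is a split event; the converse a merge;
#' domains without any overlapping partner are births/deaths.
#'
#' @param partitions List of `domain_partition`s on the same node set, in
#'   time order.
#' @param min_share Minimal member share for a substantial child/parent.
#' @return Tibble of events: `frame`, `type`
#'   (`"split"|"merge"|"birth"|"death"`), `domain`, `partners`.
#' @export
track_domains <- function(partitions, min_share = 0.2) {
  ev <- list()
  for (t in seq_len(length(partitions) - 1)) {
    a <- partitions[[t]]$domain
    b <- partitions[[t + 1]]$domain
    tab <- table(a, b)
    an <- rownames(tab); bn <- colnames(tab)
    asz <- rowSums(tab); bsz <- colSums(tab)
    # splits: one domain at t feeding >= 2 substantial domains at t+1
    for (i in seq_along(an)) {
      kids <- which(tab[i, ] >= pmax(1, min_share * asz[i]) & tab[i, ] > 0)
      # only count children dominated by this parent
      kids <- kids[vapply(kids, function(j) which.max(tab[, j]) == i, logical(1))]
      if (length(kids) >= 2) {
        ev[[length(ev) + 1]] <- tibble(frame = t + 1, type = "split",
                                       domain = an[i],
                                       partners = paste(bn[kids], collapse = "+"))
      }
      if (all(tab[i, ] == 0)) {
        ev[[length(ev) + 1]] <- tibble(frame = t + 1, type = "death",
                                       domain = an[i], partners = "")
      }
    }
    for (j in seq_along(bn)) {
      parents <- which(tab[, j] >= pmax(1, min_share * bsz[j]) & tab[, j] > 0)
      parents <- parents[vapply(parents, function(i) which.max(tab[i, ]) == j,
                                logical(1))]
      if (length(parents) >= 2) {
        ev[[length(ev) + 1]] <- tibble(frame = t + 1, type = "merge",
                                       domain = bn[j],
                                       partners = paste(an[parents], collapse = "+"))
      }
      if (all(tab[, j] == 0)) {
        ev[[length(ev) + 1]] <- tibble(frame = t + 1, type = "birth",
                                       domain = bn[j], partners = "")
      }
    }
  }
  if (!length(ev)) {
    return(tibble(frame = integer(0), type = character(0),
                  domain = character(0), partners = character(0)))
  }
  dplyr::bind_rows(ev)
}

#' Nucleosome clutches along a fiber
#'
#' Sliding-window radius of gyration over `window` consecutive nucleosome
#' centers; the threshold is the trajectory-average window R_g. A maximal
#' run of nucleosomes covered by strictly-below-threshold windows is one
#' clutch; the complementary runs are intervals. Clutches and intervals tile
#' the fiber exactly.
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param frame Frame to segment (`NULL` segments every frame after
#'   `burn_in`).
#' @param window Window size in nucleosomes.
#' @param fiber_id Target fiber.
#' @param burn_in Frames discarded from the threshold average.
#' @param threshold Override the trajectory-average threshold (Angstrom).
#' @return List with `clutches` (tibble `frame`, `start`, `end`, `size`),
#'   `intervals` (same form), `threshold` and the per-frame window R_g
#'   matrix.
#' @export
clutch_detect <- function(trajectory, frame = NULL, window = 4, fiber_id = 1,
                          burn_in = 0, threshold = NULL) {
  nt <- .nucleosome_table(trajectory$beads)
  nt <- nt[nt$fiber_id == fiber_id, ]
  n_nuc <- nrow(nt)
  stopifnot(n_nuc >= window)
  idx <- (burn_in + 1):n_frames(trajectory)
  nw <- n_nuc - window + 1
  wrg <- matrix(NA_real_, length(idx), nw)
  for (kk in seq_along(idx)) {
    cen <- nucleosome_centers(trajectory$frames[[idx[kk]]], nt)
    for (s in seq_len(nw)) {
      x <- cen[s:(s + window - 1), , drop = FALSE]
      wrg[kk, s] <- sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
    }
  }
  thr <- if (is.null(threshold)) mean(wrg) else threshold
  frames_to_do <- if (is.null(frame)) seq_along(idx) else match(frame, idx)
  cl <- list(); iv <- list()
  for (kk in frames_to_do) {
    below <- wrg[kk, ] < thr
    covered <- rep(FALSE, n_nuc)
    for (s in which(below)) covered[s:(s + window - 1)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in seq_along(r$values)) {
      row <- tibble(frame = idx[kk], start = starts[seg], end = ends[seg],
                    size = r$lengths[seg])
      if (r$values[seg]) cl[[length(cl) + 1]] <- row else
        iv[[length(iv) + 1]] <- row
    }
  }
  empty <- tibble(frame = integer(0), start = integer(0), end = integer(0),
                  size = integer(0))
  list(clutches = if (length(cl)) dplyr::bind_rows(cl) else empty,
       intervals = if (length(iv)) dplyr::bind_rows(iv) else empty,
       threshold = thr, window_rg = wrg)
}

# nucleosome symmetry axis from the ordered histone beads: sum of cross
# products of consecutive chords (robust where a total-least-squares line fit
# is near-degenerate, since the helix's axial and lateral extents are close)
.nucleosome_axis <- function(hist_xyz) {
  ch <- diff(hist_xyz)
  cr <- vapply(seq_len(nrow(ch) - 1), function(i) {
    c(ch[i, 2] * ch[i + 1, 3] - ch[i, 3] * ch[i + 1, 2],
      ch[i, 3] * ch[i + 1, 1] - ch[i, 1] * ch[i + 1, 3],
      ch[i, 1] * ch[i + 1, 2] - ch[i, 2] * ch[i + 1, 1])
  }, numeric(3))
  .normalize(rowSums(cr))
}

#' Classify the geometry of a nucleosome pair
#'
#' Face-to-face stacking requires a center-center distance below 7.5 nm and
#' an angle between the two superhelix axes below 30 degrees (axes are
#' undirected: the angle is folded to 0-90 degrees). Pairs in spatial
#' contact (minimum bead distance below the contact cutoff) without the
#' stacking geometry are `"contact-unstacked"`; the rest `"no-contact"`.
#'
#' @param xyz_i,xyz_j Bead coordinates of the two nucleosomes (DNA + histone,
#'   in build order: DNA beads first, then the 8 histone beads).
#' @param dist_cutoff Stacking center-center cutoff, Angstrom.
#' @param angle_cutoff Stacking axis-angle cutoff, degrees.
#' @param contact_cutoff Minimum-bead-distance contact cutoff, Angstrom.
#' @return One of `"stacked"`, `"contact-unstacked"`, `"no-contact"`, plus
#'   attributes `distance` (A) and `angle` (degrees).
#' @export
stacking_classify <- function(xyz_i, xyz_j, dist_cutoff = 75,
                              angle_cutoff = 30, contact_cutoff = 52.5) {
  ni <- nrow(xyz_i); nj <- nrow(xyz_j)
  ax_i <- .nucleosome_axis(xyz_i[(ni - 7):ni, , drop = FALSE])
  ax_j <- .nucleosome_axis(xyz_j[(nj - 7):nj, , drop = FALSE])
  d <- sqrt(sum((colMeans(xyz_i) - colMeans(xyz_j))^2))
  ang <- acos(min(abs(sum(ax_i * ax_j)), 1)) * 180 / pi
  mind <- min(vapply(seq_len(ni), function(a) {
    min(sqrt(rowSums(sweep(xyz_j, 2, xyz_i[a, ])^2)))
  }, numeric(1)))
  out <- if (d < dist_cutoff && ang < angle_cutoff) {
    "stacked"
  } else if (mind < contact_cutoff) {
    "contact-unstacked"
  } else {
    "no-contact"
  }
  attr(out, "distance") <- d
  attr(out, "angle") <- ang
  out
}

#' Nearest-neighbor stacking statistics of a frame
#'
#' For every nucleosome, its minimum-center-distance contact partner is
#' classified with [stacking_classify()]; reports the stacked fraction per
#' state-pair class and the fraction of stacked pairs that are long-range
#' (>= 10 nucleosomes apart along the genome).
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param frame Frame index.
#' @param contact_cutoff Contact cutoff, Angstrom.
#' @return Tibble with one row per nucleosome: partner, distance, angle,
#'   class, pair state class, genomic separation.
#' @export
stacking_stats <- function(trajectory, frame = 1, contact_cutoff = 52.5) {
  nt <- .nucleosome_table(trajectory$beads)
  pos <- trajectory$frames[[frame]]
  cen <- nucleosome_centers(pos, nt)
  n <- nrow(nt)
  out <- lapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(cen, 2, cen[i, ])^2))
    d[i] <- Inf
    j <- which.min(d)
    cls <- stacking_classify(pos[nt$beads[[i]], ], pos[nt$beads[[j]], ],
                             contact_cutoff = contact_cutoff)
    sep <- if (nt$fiber_id[i] == nt$fiber_id[j]) {
      abs(nt$nucleosome[i] - nt$nucleosome[j])
    } else {
      NA_integer_
    }
    st <- sort(c(nt$state[i], nt$state[j]))
    tibble(id = i, partner = j, distance = attr(cls, "distance"),
           angle = attr(cls, "angle"), class = as.character(cls),
           pair_class = paste(substr(st[1], 1, 3), substr(st[2], 1, 3),
                              sep = "-"),
           genomic_sep = sep)
  })
  dplyr::bind_rows(out)
}

#' Same-domain frequency versus genomic distance
#'
#' For every intra-fiber nucleosome pair, the fraction of partitions in
#' which the pair shares a spatial domain, binned by genomic distance and
#' split by the pair's epigenetic state class (can-can, can-ac, ac-ac;
#' BRD4-associated counts as acetylated).
#'
#' @param partitions List of `domain_partition`s.
#' @param fiber_id Target fiber.
#' @param bin_bp Genomic distance bin width.
#' @param max_bp Largest genomic distance reported.
#' @return Tibble with `distance_bp`, `pair_class`, `frequency`, `n_pairs`.
#' @export
same_domain_frequency <- function(partitions, fiber_id = 1, bin_bp = 1000,
                                  max_bp = 10000) {
  p1 <- partitions[[1]]
  sel <- p1$fiber_id == fiber_id
  ids <- p1$id[sel]
  dyad <- p1$dyad[sel]
  state <- ifelse(p1$state[sel] == "CANONICAL", "can", "ac")
  n <- length(ids)
  prs <- utils::combn(n, 2)
  gsep <- abs(dyad[prs[1, ]] - dyad[prs[2, ]])
  keep <- gsep <= max_bp
  prs <- prs[, keep, drop = FALSE]
  gsep <- gsep[keep]
  same <- rowMeans(vapply(partitions, function(p) {
    dm <- p$domain[match(ids, p$id)]
    dm[prs[1, ]] == dm[prs[2, ]]
  }, logical(ncol(prs))))
  cls <- paste(pmin(state[prs[1, ]], state[prs[2, ]]),
               pmax(state[prs[1, ]], state[prs[2, ]]), sep = "-")
  df <- tibble(distance_bp = (floor(gsep / bin_bp) + 0.5) * bin_bp,
               pair_class = cls, same = same)
  out <- dplyr::group_by(df, .data$distance_bp, .data$pair_class)
  dplyr::summarise(out, frequency = mean(same), n_pairs = dplyr::n(),
                   se = stats::sd(same) / sqrt(dplyr::n()), .groups = "drop")
}
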