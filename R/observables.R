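#' Radius of gyration
#'
#' Mass-uniform radius of gyration of a bead subset, per frame, reported in
#' nm.
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param beads Bead indices (default: all beads).
#' @return Tibble with `frame`, `time_ns`, `rg_nm`.
#' @export
radius_of_gyration <- function(trajectory, beads = NULL) {
  stopifnot(n_frames(trajectory) >= 1)
  if (is.null(beads)) beads <- seq_len(nrow(trajectory$beads))
  rg <- vapply(trajectory$frames, function(f) {
    x <- f[beads, , drop = FALSE]
    sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  }, numeric(1))
  tibble(frame = seq_along(rg), time_ns = trajectory$times_ns, rg_nm = rg / 10)
}

#' Mean squared displacement and anomalous-exponent fit
#'
#' Time- and particle-averaged MSD of nucleosome centers versus lag time,
#' with a log-log least-squares fit of the subdiffusive power law
#' \eqn{MSD = K_\alpha \tau^\alpha} over the pre-plateau lags. Lag times are
#' reported in mapped ns.
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param beads Bead indices to track; default: nucleosome centers of all
#'   fibers.
#' @param fit_range Lag index range (in frames) used in the fit; default the
#'   first decade up to a third of the trajectory.
#' @param burn_in Initial frames discarded.
#' @return Object of class `msd_fit`: `msd` tibble (`lag_ns`, `msd_nm2`),
#'   `alpha`, `K_alpha` (nm^2/ns^alpha), `fit_range`.
#' @export
msd_fit <- function(trajectory, beads = NULL, fit_range = NULL, burn_in = 0) {
  nt <- .nucleosome_table(trajectory$beads)
  frames <- trajectory$frames[(burn_in + 1):n_frames(trajectory)]
  pos <- if (is.null(beads) && nrow(nt) > 0) {
    lapply(frames, nucleosome_centers, nuc_table = nt)
  } else {
    if (is.null(beads)) beads <- seq_len(nrow(trajectory$beads))
    lapply(frames, function(f) f[beads, , drop = FALSE])
  }
  nf <- length(pos)
  stopifnot(nf >= 11)
  lags <- unique(round(exp(seq(0, log(nf - 1), length.out = 40))))
  msd <- vapply(lags, function(L) {
    origins <- seq(1, nf - L, by = max(1, floor(L / 4)))
    mean(vapply(origins, function(t0) {
      mean(rowSums((pos[[t0 + L]] - pos[[t0]])^2))
    }, numeric(1)))
  }, numeric(1))
  dt_ns <- trajectory$config$dump_interval * trajectory$config$time_scale
  if (all(msd < 1e-12)) stop("MSD is identically zero (immobile beads); fit rejected")
  if (is.null(fit_range)) fit_range <- c(1, max(10, floor((nf - 1) / 3)))
  sel <- lags >= fit_range[1] & lags <= fit_range[2] & msd > 0
  if (sum(sel) < 3) stop("fewer than 3 lags in the fit range")
  fit <- stats::lm(log(msd[sel]) ~ log(lags[sel] * dt_ns))
  alpha <- unname(stats::coef(fit)[2])
  k_alpha <- exp(unname(stats::coef(fit)[1])) / 100 # A^2 -> nm^2
  structure(list(
    msd = tibble(lag_frames = lags, lag_ns = lags * dt_ns, msd_nm2 = msd / 100),
    alpha = alpha, K_alpha = k_alpha, fit_range = fit_range,
    r_squared = summary(fit)$r.squared), class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> alpha = %.3f, K_alpha = %.4g nm^2/ns^alpha (R^2 = %.3f)\n",
              x$alpha, x$K_alpha, x$r_squared))
  invisible(x)
}

#' DNA persistence length from tangent correlations
#'
#' Fits \eqn{\langle t(s) \cdot t(s+\Delta) \rangle = e^{-\Delta / l_p}} over
#' the first decay decade (correlations in `[0.1, 1]`) of a linear DNA chain.
#' A rigid rod (no measurable decay) returns `Inf`.
#'
#' @param trajectory A `chromatin_trajectory` of a naked DNA chain.
#' @param burn_in Initial frames discarded.
#' @return List with `lp_nm`, the correlation tibble, and the mean bond
#'   length.
#' @export
persistence_length <- function(trajectory, burn_in = 0) {
  chain <- trajectory$beads$bead[trajectory$beads$role == "LINKER"]
  stopifnot(length(chain) >= 10)
  frames <- trajectory$frames[(burn_in + 1):n_frames(trajectory)]
  nb <- length(chain) - 1
  corr <- matrix(0, length(frames), nb - 1)
  bl <- 0
  for (k in seq_along(frames)) {
    x <- frames[[k]][chain, ]
    tv <- diff(x)
    len <- sqrt(rowSums(tv^2))
    bl <- bl + mean(len)
    tv <- tv / len
    for (dd in seq_len(nb - 1)) {
      corr[k, dd] <- mean(rowSums(tv[1:(nb - dd), , drop = FALSE] *
                                    tv[(1 + dd):nb, , drop = FALSE]))
    }
  }
  bl <- bl / length(frames)
  cbar <- colMeans(corr)
  dd <- seq_len(nb - 1)
  # fit the first decay length only: short-wavelength bending modes
  # equilibrate far faster than the chain's end-to-end relaxation
  lim <- which(cbar < exp(-1))[1]
  if (is.na(lim)) lim <- length(cbar)
  sel <- cbar > exp(-1) & cbar < 1 & dd <= lim
  if (sum(sel) < 2 || all(cbar[sel] > 0.999)) {
    return(list(lp_nm = Inf, correlation = tibble(sep = dd, corr = cbar),
                bond_length = bl))
  }
  fit <- stats::lm(log(cbar[sel]) ~ 0 + dd[sel])
  lp <- -bl / unname(stats::coef(fit)[1])
  list(lp_nm = lp / 10, correlation = tibble(sep = dd, corr = cbar),
       bond_length = bl)
}

# per-type bead masses (g/mol): one DNA turn, individual histones, H1 halves
.bead_mass <- function(type) {
  base <- c(LINKER_DNA = 6825, NUC_DNA = 6825, ENTRY_DNA = 6825,
            H2A = 14000, H2B = 13900, H3 = 15300, H4 = 11400,
            H1_GLOB = 10700, H1_TAIL = 10700)
  key <- sub("_(AC|B)$", "", type)
  unname(base[key])
}

#' Sedimentation coefficient (s20,w) by the Kirkwood bead model
#'
#' Kirkwood double-sum approximation for the friction of a rigid bead
#' assembly, averaged over frames: hydrodynamic radius sigma/2 per bead,
#' partial specific volume 0.65 mL/g (chromatin), solvent water at 20 C.
#' Bead masses: 6825 g/mol per DNA turn, histone masses per protein, 21.4 kDa
#' split over the two H1 beads. For a single bead this reduces exactly to the
#' Stokes-Einstein closed form.
#'
#' @param frames List of coordinate matrices (or a `chromatin_trajectory`).
#' @param types Per-bead type labels (taken from the trajectory if one is
#'   supplied).
#' @param bead_radius Hydrodynamic radius per bead, Angstrom.
#' @param vbar Partial specific volume, mL/g.
#' @param burn_in Initial frames discarded (trajectory input).
#' @return Mean s20,w in Svedberg.
#' @export
sedimentation_coefficient <- function(frames, types = NULL,
                                      bead_radius = 17.5, vbar = 0.65,
                                      burn_in = 0) {
  if (inherits(frames, "chromatin_trajectory")) {
    types <- frames$beads$type
    frames <- frames$frames[(burn_in + 1):n_frames(frames)]
  }
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(!is.null(types))
  mass <- sum(.bead_mass(types))            # g/mol
  eta <- 1.002e-3                           # Pa s, water 20 C
  rho <- 0.99823                            # g/mL
  a <- bead_radius * 1e-10                  # m
  NA_ <- 6.02214076e23
  s_frames <- vapply(frames, function(x) {
    n <- nrow(x)
    f1 <- 6 * pi * eta * a
    if (n > 1) {
      inv <- 1 / stats::dist(x)             # 1/A
      ssum <- 2 * sum(inv) * 1e10           # 1/m, both orderings
      # Kirkwood: f = N f1 / (1 + (a/N) * sum_{i != j} <1/r_ij>)
      f <- f1 * n / (1 + (a / n) * ssum)
    } else {
      f <- f1
    }
    (mass / 1000) * (1 - vbar * rho) / (NA_ * f) # kg/mol -> s
  }, numeric(1))
  mean(s_frames) / 1e-13                    # Svedberg
}

#' Nucleosome unwrapping equilibrium constant
#'
#' A nucleosome terminus counts as unwrapped in a frame when its entry/exit
#' DNA bead is further than `r0 + 2/a` (the Morse width scale) from its
#' Morse-bonded histone partner. K_eq is the ratio of pooled unwrapped to
#' wrapped time fractions over all termini; the uncertainty is a moving-block
#' bootstrap over frames.
#'
#' @param trajectory A `chromatin_trajectory` (its topology carries the
#'   Morse bookkeeping).
#' @param burn_in Initial frames discarded.
#' @param threshold Optional override of the unwrapping distance threshold
#'   (Angstrom).
#' @param n_boot Bootstrap replicates.
#' @param n_blocks Number of blocks for the bootstrap.
#' @return List with `k_eq`, `se`, `fraction_unwrapped`, `n_transitions`,
#'   and the per-terminus tibble.
#' @export
unwrapping_keq <- function(trajectory, burn_in = 0, threshold = NULL,
                           n_boot = 200, n_blocks = 20) {
  mm <- trajectory$topology$morse_meta
  if (nrow(mm) == 0) stop("no Morse bonds in this topology")
  idx <- (burn_in + 1):n_frames(trajectory)
  thr <- if (is.null(threshold)) mm$r0 + 2 / mm$a else rep(threshold, nrow(mm))
  un <- vapply(seq_len(nrow(mm)), function(k) {
    vapply(trajectory$frames[idx], function(f) {
      sqrt(sum((f[mm$entry_bead[k], ] - f[mm$partner_bead[k], ])^2)) > thr[k]
    }, logical(1))
  }, logical(length(idx)))
  F <- mean(un)
  k_eq <- F / (1 - F)
  per <- tibble(nucleosome = mm$nucleosome, terminus = mm$terminus,
                fraction_unwrapped = colMeans(un))
  ntrans <- sum(apply(un, 2, function(z) sum(abs(diff(z)))))
  # moving-block bootstrap over the frame axis
  nfr <- nrow(un)
  bl <- max(2, floor(nfr / n_blocks))
  starts_all <- seq_len(nfr - bl + 1)
  ks <- vapply(seq_len(n_boot), function(b) {
    st <- sample(starts_all, ceiling(nfr / bl), replace = TRUE)
    rows <- as.vector(vapply(st, function(s) s:(s + bl - 1), numeric(bl)))
    Fb <- mean(un[rows[rows <= nfr], ])
    Fb / (1 - Fb)
  }, numeric(1))
  list(k_eq = k_eq, se = stats::sd(ks), fraction_unwrapped = F,
       n_transitions = ntrans, per_terminus = per)
}

#' Coexistence densities from a slab trajectory
#'
#' Nucleosome-center density profile along the long (z) axis of the periodic
#' slab, cyclically re-centred on the densest region per frame. The condensed
#' density is the mean over plateau bins (above half the plateau level), the
#' dilute density the mean over bins below 10 percent of the plateau
#' (interfacial bins are discarded). The system is flagged phase-separated
#' when condensed/dilute exceeds `ratio_threshold`.
#'
#' @param trajectory A `chromatin_trajectory` with slab boundary.
#' @param burn_in Initial frames discarded.
#' @param n_bins Number of z bins.
#' @param ratio_threshold Condensed/dilute ratio defining phase separation.
#' @return List with `dilute_uM`, `condensed_uM`, `phase_separated`, and the
#'   mean `profile` tibble.
#' @export
slab_densities <- function(trajectory, burn_in = 0, n_bins = 50,
                           ratio_threshold = 5) {
  stopifnot(trajectory$boundary$type == "slab")
  box <- trajectory$boundary$box
  nt <- .nucleosome_table(trajectory$beads)
  idx <- (burn_in + 1):n_frames(trajectory)
  edges <- seq(0, box[3], length.out = n_bins + 1)
  binw <- diff(edges)[1]
  vol_nm3 <- box[1] * box[2] * binw * 1e-3    # A^3 -> nm^3
  prof <- rep(0, n_bins)
  for (k in idx) {
    z <- nucleosome_centers(trajectory$frames[[k]], nt)[, 3] %% box[3]
    h <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
    # cyclic re-centering on the densest window (1/5 of the box)
    w <- max(3, floor(n_bins / 5))
    run <- vapply(seq_len(n_bins), function(i) {
      sum(h[((i - 1 + 0:(w - 1)) %% n_bins) + 1])
    }, numeric(1))
    shift <- which.max(run) + floor(w / 2) - 1
    h <- h[((seq_len(n_bins) - 1 + shift - floor(n_bins / 2)) %% n_bins) + 1]
    prof <- prof + h
  }
  prof <- prof / length(idx)
  dens <- vapply(prof, nucleosome_concentration, numeric(1),
                 volume_nm3 = vol_nm3)
  plateau <- stats::quantile(dens, 0.95)
  if (plateau <= 0 || stats::sd(dens) < 0.05 * mean(dens) + 1e-12) {
    mu <- mean(dens)
    return(list(dilute_uM = mu, condensed_uM = mu, phase_separated = FALSE,
                profile = tibble(z_nm = (edges[-1] - binw / 2) / 10,
                                 density_uM = dens)))
  }
  cond <- mean(dens[dens >= 0.5 * plateau])
  dil_bins <- dens <= 0.1 * plateau
  dil <- if (any(dil_bins)) mean(dens[dil_bins]) else min(dens)
  list(dilute_uM = dil, condensed_uM = cond,
       phase_separated = is.finite(cond / max(dil, 1e-12)) &&
         cond / max(dil, 1e-9) > ratio_threshold,
       profile = tibble(z_nm = (edges[-1] - binw / 2) / 10, density_uM = dens))
}

#' Mass-scaling exponent of intra-locus regions
#'
#' Fits \eqn{R_g(N) \propto N^{1/D}} over sliding continuous sub-regions of
#' the target fiber: for each region size N (kb) the mean radius of gyration
#' over windows and frames is computed, and D is the inverse slope of
#' log R_g versus log N.
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param fiber_id Target fiber.
#' @param sizes_kb Region sizes to probe (>= 3 values).
#' @param burn_in Initial frames discarded.
#' @return List with `D`, and the `scaling` tibble (`N_kb`, `rg_nm`).
#' @export
scaling_exponent <- function(trajectory, fiber_id = 1,
                             sizes_kb = c(5, 10, 20, 40), burn_in = 0) {
  stopifnot(length(sizes_kb) >= 3)
  nt <- .nucleosome_table(trajectory$beads)
  nt <- nt[nt$fiber_id == fiber_id, ]
  frames <- trajectory$frames[(burn_in + 1):n_frames(trajectory)]
  n_nuc <- nrow(nt)
  nrl_kb <- if (n_nuc > 1) mean(diff(nt$dyad)) / 1000 else 0.195
  rg_of <- function(sub_beads) {
    mean(vapply(frames, function(f) {
      x <- f[sub_beads, , drop = FALSE]
      sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
    }, numeric(1)))
  }
  total_kb <- n_nuc * nrl_kb
  out <- lapply(sizes_kb[sizes_kb < total_kb], function(N) {
    span <- max(2, round(N / nrl_kb))
    starts <- unique(round(seq(1, n_nuc - span + 1,
                               length.out = min(8, n_nuc - span + 1))))
    rg <- mean(vapply(starts, function(s) {
      rg_of(unlist(nt$beads[s:(s + span - 1)]))
    }, numeric(1)))
    tibble(N_kb = span * nrl_kb, rg_nm = rg / 10)
  })
  sc <- dplyr::bind_rows(out)
  fit <- stats::lm(log(rg_nm) ~ log(N_kb), data = sc)
  list(D = 1 / unname(stats::coef(fit)[2]), scaling = sc)
}

#' Distances between regulatory elements over time
#'
#' Maps BED-style elements to the nucleosomes whose dyads fall inside them
#' (coordinates relative to the fiber), takes the element position as the
#' centroid of those nucleosomes, and reports all pairwise element distances
#' per frame.
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param elements Tibble with `name`, `start`, `end` (bp, fiber-relative).
#' @param fiber_id Target fiber.
#' @return Tibble with `frame`, `time_ns`, `pair`, `distance_nm`.
#' @export
pair_distance_series <- function(trajectory, elements, fiber_id = 1) {
  nt <- .nucleosome_table(trajectory$beads)
  nt <- nt[nt$fiber_id == fiber_id, ]
  el_beads <- lapply(seq_len(nrow(elements)), function(k) {
    sel <- which(nt$dyad >= elements$start[k] & nt$dyad <= elements$end[k])
    if (!length(sel)) {
      # fall back to the nearest nucleosome to the element midpoint
      sel <- which.min(abs(nt$dyad - (elements$start[k] + elements$end[k]) / 2))
    }
    unlist(nt$beads[sel])
  })
  prs <- utils::combn(nrow(elements), 2)
  out <- list()
  for (f in seq_len(n_frames(trajectory))) {
    fr <- trajectory$frames[[f]]
    cent <- lapply(el_beads, function(ix) colMeans(fr[ix, , drop = FALSE]))
    for (c_ in seq_len(ncol(prs))) {
      i <- prs[1, c_]; j <- prs[2, c_]
      out[[length(out) + 1]] <- tibble(
        frame = f, time_ns = trajectory$times_ns[f],
        pair = paste0(elements$name[i], "-", elements$name[j]),
        distance_nm = sqrt(sum((cent[[i]] - cent[[j]])^2)) / 10)
    }
  }
  dplyr::bind_rows(out)
}

#' K-means clustering of structures by regulatory-element distances
#'
#' Standardizes the per-frame pair-distance matrix and clusters frames with
#' seeded k-means (50 restarts). Three clusters reproduce the canonical
#' all-interacting / partially-interacting archetypes analysis.
#'
#' @param distances Output of [pair_distance_series()] (long form).
#' @param k Number of clusters.
#' @param seed Seed for the k-means restarts.
#' @param nstart Random restarts.
#' @return Object of class `structure_clusters`: `cluster` per frame,
#'   `centers` (original units, nm), `sizes`, and the k-means fit.
#' @export
cluster_structures <- function(distances, k = 3, seed = 1, nstart = 50) {
  wide <- tidyr::pivot_wider(distances, id_cols = "frame",
                             names_from = "pair",
                             values_from = "distance_nm")
  m <- as.matrix(wide[, -1])
  keep_cols <- apply(m, 2, function(z) stats::sd(z) > 0)
  ms <- scale(m[, keep_cols, drop = FALSE])
  set.seed(seed %% .Machine$integer.max)
  if (all(!keep_cols) || nrow(unique(m)) < k) {
    # degenerate: identical frames collapse into a single nonempty cluster
    cl <- rep(1L, nrow(m))
    return(structure(list(cluster = cl,
                          centers = matrix(colMeans(m), 1,
                                           dimnames = list(NULL, colnames(m))),
                          sizes = nrow(m), fit = NULL, k = 1L),
                     class = "structure_clusters"))
  }
  km <- stats::kmeans(ms, centers = k, nstart = nstart, iter.max = 100)
  centers <- vapply(seq_len(k), function(c_) colMeans(m[km$cluster == c_, ,
                                                        drop = FALSE]),
                    numeric(ncol(m)))
  structure(list(cluster = km$cluster, centers = t(centers),
                 sizes = km$size, fit = km, k = k),
            class = "structure_clusters")
}

#' @export
print.structure_clusters <- function(x, ...) {
  cat(sprintf("<structure_clusters> k = %d, sizes: %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}
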