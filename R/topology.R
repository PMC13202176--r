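#' Build the complete interaction topology of a system
#'
#' Derives every bonded term from the reference (as-built) geometry of each
#' fiber, independently of the system's current coordinates:
#' \itemize{
#' \item a harmonic bond (stiffness `k_bond`, rest length = reference
#'   distance) for every intra-nucleosome bead pair closer than 38 Angstrom
#'   in the reference geometry, and between consecutive DNA-chain beads at
#'   35 Angstrom;
#' \item one Morse bond per entry/exit DNA bead to its nearest histone-core
#'   bead (nucleosome breathing); the terminus' remaining sub-38-Angstrom
#'   reference pairs are excluded from all interactions so it can detach.
#'   Acetylated (and BRD4-associated) nucleosomes use a well depth scaled by
#'   `morse_acetyl_scale`, which raises their unwrapping equilibrium
#'   constant about three-fold;
#' \item DNA bending angles (equilibrium 180 degrees, stiffness `k_bend`) on
#'   every consecutive DNA-chain triplet centred on a linker or entry/exit
#'   bead;
#' \item H1 anchoring: harmonic bonds from the globular H1 bead to the dyad
#'   DNA beads within 38 Angstrom plus angle terms keeping the tail radial.
#' }
#' Directly bonded (1-2) pairs are excluded from nonbonded interactions;
#' angle (1-3) pairs are not.
#'
#' @param system A `chromatin_system`.
#' @param ff Force field; defaults to the one stored in the system.
#' @return A list of class `chromatin_topology` with tibbles `bonds`
#'   (`i, j, r0, k`), `morse` (`i, j, de, a, r0`), `angles`
#'   (`i, j, k, theta0, k_theta`), `exclusions`, `morse_meta` (per-terminus
#'   bookkeeping for breathing analysis), the `eps_matrix` and the force
#'   field.
#' @export
build_topology <- function(system, ff = system$forcefield) {
  refs <- lapply(system$fibers, .fiber_reference, ff = ff)
  off <- system$offsets
  shift <- function(m, cols, k) { m[, cols] <- m[, cols] + k; m }
  bonds <- list(); morse <- list(); angles <- list(); excl <- list(); meta <- list()
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    if (nrow(r$bonds)) bonds[[i]] <- shift(r$bonds, 1:2, off[i])
    if (nrow(r$morse)) morse[[i]] <- shift(r$morse, 1:2, off[i])
    if (nrow(r$angles)) angles[[i]] <- shift(r$angles, 1:3, off[i])
    if (nrow(r$exclusions)) excl[[i]] <- r$exclusions + off[i]
    mm <- r$morse_meta
    if (nrow(mm)) {
      mm$entry_bead <- mm$entry_bead + off[i]
      mm$partner_bead <- mm$partner_bead + off[i]
      mm$fiber_id <- i
      meta[[i]] <- mm
    }
  }
  bmat <- function(lst, nm) {
    m <- if (length(lst)) do.call(rbind, lst) else matrix(0, 0, length(nm))
    colnames(m) <- nm
    as_tibble(m)
  }
  topo <- structure(list(
    bonds = bmat(bonds, c("i", "j", "r0", "k")),
    morse = bmat(morse, c("i", "j", "de", "a", "r0")),
    angles = bmat(angles, c("i", "j", "k", "theta0", "k_theta")),
    exclusions = bmat(excl, c("i", "j")),
    morse_meta = if (length(meta)) dplyr::bind_rows(meta) else
      refs[[1]]$morse_meta[0, ],
    eps_matrix = ff$pair_matrix,
    forcefield = ff), class = "chromatin_topology")
  # dangling beads are a build error: every bead of a multi-bead fiber must
  # carry at least one bond (single-bead fibers are legitimately free)
  n <- n_beads(system)
  multi <- unlist(lapply(seq_along(system$fibers), function(i) {
    cnt <- fiber_bead_count(system$fibers[[i]])
    if (cnt > 1) system$offsets[i] + seq_len(cnt)
  }))
  if (length(multi)) {
    seen <- unique(c(topo$bonds$i, topo$bonds$j, topo$morse$i, topo$morse$j))
    dangling <- setdiff(multi, seen)
    if (length(dangling)) {
      stop("dangling bead(s) with no bonds: ",
           paste(utils::head(dangling, 5), collapse = ", "))
    }
  }
  topo
}

#' @export
print.chromatin_topology <- function(x, ...) {
  cat(sprintf("<chromatin_topology> %d harmonic bonds, %d Morse bonds, %d angles, %d extra exclusions\n",
              nrow(x$bonds), nrow(x$morse), nrow(x$angles), nrow(x$exclusions)))
  invisible(x)
}

#' Brute-force reference bond oracle for one nucleosome
#'
#' Independent O(n^2) distance scan over a built nucleosome's reference
#' geometry, applying the same bonding rule as the topology builder: all
#' sub-38-Angstrom pairs bond harmonically except those involving the two
#' entry/exit beads, which keep only their DNA chain bond and one Morse bond
#' to the nearest histone bead. Used to cross-check [build_topology()].
#'
#' @param geom A `nucleosome_geometry` from [build_nucleosome()].
#' @param bond_cut Distance rule, Angstrom.
#' @return A list with sorted two-column matrices `harmonic` and `morse`.
#' @export
scan_reference_bonds <- function(geom, bond_cut = 38) {
  xyz <- geom$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d < bond_cut, arr.ind = TRUE)
  entry <- geom$entry_idx
  n_dna <- length(geom$dna_idx)
  keep <- apply(pairs, 1, function(p) {
    inv <- p[1] %in% entry || p[2] %in% entry
    chain <- p[2] == p[1] + 1 && p[2] <= n_dna
    !inv || chain
  })
  harmonic <- pairs[keep, , drop = FALSE]
  morse <- t(vapply(entry, function(e) {
    hd <- d[e, geom$hist_idx]
    sort(c(e, geom$hist_idx[which.min(hd)]))
  }, numeric(2)))
  ord <- order(harmonic[, 1], harmonic[, 2])
  list(harmonic = unname(harmonic[ord, , drop = FALSE]), morse = unname(morse))
}

#' In-silico mutation of a system
#'
#' Reproduces the perturbation protocols used to probe the role of each
#' regulatory factor. `delta_interaction` lowers every Lennard-Jones strength
#' involving canonical nucleosomes to 0.06 kcal/mol (widespread-acetylation
#' mimic; BRD4 enhancement still does not apply to these nucleosomes).
#' `delta_brd4` demotes BRD4-associated nucleosomes of the target fiber to
#' plain acetylated. `delta_h1` removes linker histone H1 from the target
#' fiber. `short_linker` removes one DNA bead (10.5 bp) from every linker of
#' the target fiber, reducing its NRL. Background fibers are never modified.
#' Mutations changing bead counts rebuild the target fiber geometry in place
#' (grown systems should be re-grown from the mutated specs for production
#' use).
#'
#' @param system A `chromatin_system`.
#' @param mode One of `"delta_interaction"`, `"delta_brd4"`, `"delta_h1"`,
#'   `"short_linker"`.
#' @param target_fiber Index of the target fiber (default 1).
#' @param ff Force field (used when the pair matrix must change).
#' @return A list with the modified `system` and `forcefield`.
#' @export
apply_mutation <- function(system, mode = c("delta_interaction", "delta_brd4",
                                            "delta_h1", "short_linker"),
                           target_fiber = 1, ff = system$forcefield) {
  mode <- match.arg(mode)
  if (mode == "delta_interaction") {
    pm <- ff$pair_matrix
    can <- "CANONICAL_NUC"
    pm[can, ] <- pmin(pm[can, ], 0.06)
    pm[, can] <- pmin(pm[, can], 0.06)
    # keep the weak baseline for non-nucleosome partners untouched
    pm[can, can] <- 0.06
    ff2 <- ff
    ff2$pair_matrix <- pm
    sys <- system
    sys$forcefield <- ff2
    return(list(system = sys, forcefield = ff2))
  }
  spec <- system$fibers[[target_fiber]]
  nuc <- spec$nucleosomes
  if (mode == "delta_brd4") {
    nuc$brd4 <- FALSE
  } else if (mode == "delta_h1") {
    nuc$h1 <- FALSE
  } else if (mode == "short_linker") {
    # shrink every internal linker by one bead: shift dyads cumulatively
    if (nrow(nuc) > 1) {
      linkers <- diff(nuc$dyad_position) -
        (nuc$wrap_bp[-nrow(nuc)] + nuc$wrap_bp[-1]) / 2
      newlink <- pmax(linkers - .bp_per_bead, 0)
      if (any(linkers < .bp_per_bead)) {
        warning("some linkers shorter than 10.5 bp were clamped at 0")
      }
      removed <- sum(linkers - newlink)
      nuc$dyad_position <- nuc$dyad_position[1] +
        c(0, cumsum(newlink + (nuc$wrap_bp[-nrow(nuc)] + nuc$wrap_bp[-1]) / 2))
      spec$length_bp <- spec$length_bp - removed
    }
  }
  newspec <- fiber_spec(spec$label, spec$length_bp, nuc)
  specs <- system$fibers
  specs[[target_fiber]] <- newspec
  refs <- lapply(specs, .fiber_reference, ff = ff)
  # keep untouched fibers' coordinates; rebuild the target fiber straight at
  # its previous first-bead position
  counts <- vapply(refs, function(r) nrow(r$xyz), integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  pos <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    old_range <- (system$offsets[i] + 1):(system$offsets[i] +
                                            fiber_bead_count(system$fibers[[i]]))
    if (i != target_fiber) {
      pos[[i]] <- system$positions[old_range, , drop = FALSE]
    } else {
      origin <- system$positions[old_range[1], ]
      pos[[i]] <- sweep(refs[[i]]$xyz, 2, refs[[i]]$xyz[1, ] - origin, "-")
    }
  }
  sys <- .new_system(specs, refs, do.call(rbind, pos), system$boundary, ff)
  list(system = sys, forcefield = ff)
}

#' Two free nucleosomes in a stacked configuration
#'
#' Builds two single-nucleosome fibers (no linker DNA beyond the wrap) placed
#' coaxially at a given center-center separation, the starting point for
#' stacking potential-of-mean-force calculations.
#'
#' @param separation Center-center distance along the shared axis, Angstrom.
#' @param acetylated Logical; both nucleosomes acetylated.
#' @param ff Force field.
#' @return A `chromatin_system` with two fibers.
#' @export
stacked_pair_system <- function(separation = 60, acetylated = FALSE,
                                ff = default_forcefield()) {
  mk <- function(lab) fiber_spec(lab, 147, nucleosome_record(
    dyad_position = 73.5, acetylated = acetylated))
  s1 <- mk("nucA"); s2 <- mk("nucB")
  g <- build_nucleosome(s1$nucleosomes, ff)
  refs <- list(.fiber_reference(s1, ff), .fiber_reference(s2, ff))
  pos <- rbind(g$xyz, sweep(g$xyz, 2, c(0, 0, separation), "+"))
  .new_system(list(s1, s2), refs, pos,
              list(type = "none", box = c(0, 0, 0), radius = 0), ff)
}
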