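#' @importFrom stats runif rnorm
NULL

# --- small linear-algebra helpers -------------------------------------------

.normalize <- function(v) v / sqrt(sum(v^2))

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
.rot_align <- function(a, b) {
  a <- .normalize(a); b <- .normalize(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .normalize(p - sum(p * a) * a)
    return(.rot_axis(ax, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

.rot_axis <- function(axis, angle) {
  axis <- .normalize(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    c_ + x^2 * (1 - c_), x * y * (1 - c_) + z * s_, x * z * (1 - c_) - y * s_,
    x * y * (1 - c_) - z * s_, c_ + y^2 * (1 - c_), y * z * (1 - c_) + x * s_,
    x * z * (1 - c_) + y * s_, y * z * (1 - c_) - x * s_, c_ + z^2 * (1 - c_)),
    3, 3)
}

# --- single nucleosome -------------------------------------------------------

#' Build the local bead geometry of one nucleosome / chromatosome
#'
#' Arranges the wrapped DNA (one bead per 10.5 bp; 14 beads for the canonical
#' 147 bp) along a superhelix of radius 40 Angstrom and pitch 25 Angstrom with
#' a fixed 35 Angstrom contour spacing between consecutive beads, and the 8
#' histone beads along a coaxial superhelix of radius 18 Angstrom with the
#' same pitch, evenly spaced over the same angular span. When `h1` is set, the
#' two linker-histone beads sit on the dyad axis at 70 and 105 Angstrom from
#' the nucleosome center. The local frame has the superhelix axis along +z and
#' the nucleosome center (axis midpoint) at the origin; the dyad axis is +x.
#'
#' @param record A one-row nucleosome record (see [nucleosome_record()]).
#' @param ff Force field (geometry constants are read from it).
#' @return A list of class `nucleosome_geometry` with `xyz` (beads x 3,
#'   Angstrom), `role`, `dna_idx`, `hist_idx`, `h1_idx`, `entry_idx` (the two
#'   entry/exit DNA beads), `axis`, `center` and `record`.
#' @export
build_nucleosome <- function(record, ff = default_forcefield()) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1)
  validate_nucleosomes(record)
  wrap <- record$wrap_bp
  if (wrap < 104.5 - 1e-9 || wrap > 147 + 1e-9) {
    stop("wrap_bp must lie in [104.5, 147] bp")
  }
  n_dna <- .bp_to_beads(wrap)
  Rd <- ff$superhelix_radius_dna
  Rh <- ff$superhelix_radius_histone
  cc <- ff$superhelix_pitch / (2 * pi)
  dphi <- ff$sigma / sqrt(Rd^2 + cc^2)
  phi <- ((seq_len(n_dna) - 1) - (n_dna - 1) / 2) * dphi
  dna <- cbind(Rd * cos(phi), Rd * sin(phi), cc * phi)
  phih <- seq(phi[1], phi[n_dna], length.out = 8)
  hist <- cbind(Rh * cos(phih), Rh * sin(phih), cc * phih)
  xyz <- rbind(dna, hist)
  role <- c(rep("NUC_DNA", n_dna), rep("HIST", 8))
  role[c(1, n_dna)] <- "ENTRY_DNA"
  h1_idx <- integer(0)
  if (isTRUE(record$h1)) {
    xyz <- rbind(xyz, c(ff$h1_distance, 0, 0), c(ff$h1_distance + ff$sigma, 0, 0))
    role <- c(role, "H1_GLOB", "H1_TAIL")
    h1_idx <- n_dna + 8 + 1:2
  }
  structure(list(
    xyz = xyz, role = role, dna_idx = seq_len(n_dna),
    hist_idx = n_dna + 1:8, h1_idx = h1_idx, entry_idx = c(1L, n_dna),
    axis = c(0, 0, 1), center = c(0, 0, 0), angular_step = dphi,
    record = record), class = "nucleosome_geometry")
}

#' @export
print.nucleosome_geometry <- function(x, ...) {
  cat(sprintf("<nucleosome_geometry> %d beads (%d DNA + 8 histone%s)\n",
              nrow(x$xyz), length(x$dna_idx),
              if (length(x$h1_idx)) " + 2 H1" else ""))
  invisible(x)
}

# reference bonded topology of one nucleosome (local indices)
# Harmonic bonds join every bead pair closer than ff$bond_cut in the reference
# geometry, except pairs involving the two entry/exit DNA beads: each terminus
# keeps (i) its harmonic chain bond to the adjacent DNA bead and (ii) one
# Morse bond to its nearest histone-core bead; all its other sub-cutoff
# reference pairs are excluded from both bonding and nonbonded interactions so
# the terminus can detach (nucleosome breathing).
.nucleosome_topology <- function(geom, ff, acetylated = FALSE) {
  xyz <- geom$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  entry <- geom$entry_idx
  n_dna <- length(geom$dna_idx)
  bonds <- list(); excl <- list(); morse <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] >= ff$bond_cut) next
      chain <- (j == i + 1) && (j <= n_dna)  # consecutive DNA beads
      inv_entry <- (i %in% entry) || (j %in% entry)
      if (!inv_entry || chain) {
        bonds[[length(bonds) + 1]] <- c(i, j, d[i, j], ff$k_bond)
      } else {
        excl[[length(excl) + 1]] <- c(i, j)
      }
    }
  }
  de <- ff$morse_de * if (acetylated) ff$morse_acetyl_scale else 1
  for (e in entry) {
    hd <- d[e, geom$hist_idx]
    partner <- geom$hist_idx[which.min(hd)]
    morse[[length(morse) + 1]] <- c(e, partner, de, ff$morse_a, min(hd))
    # the Morse pair must not appear in the exclusion list twice; it is
    # excluded from nonbonded automatically as a bonded pair
    excl <- Filter(function(p) !setequal(p, c(e, partner)), excl)
  }
  angles <- list()
  if (length(geom$h1_idx)) {
    g <- geom$h1_idx[1]; t <- geom$h1_idx[2]
    for (b in seq_len(n_dna)) {
      if (d[g, b] < ff$bond_cut) {
        v1 <- xyz[b, ] - xyz[g, ]; v2 <- xyz[t, ] - xyz[g, ]
        th0 <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
        angles[[length(angles) + 1]] <- c(b, g, t, th0, ff$k_h1)
      }
    }
  }
  list(
    bonds = do.call(rbind, bonds),
    morse = do.call(rbind, morse),
    angles = do.call(rbind, angles),
    exclusions = do.call(rbind, excl))
}

# --- straight fiber assembly -------------------------------------------------

.state_of <- function(rec) {
  if (isTRUE(rec$brd4)) "ACETYL_BRD4" else if (isTRUE(rec$acetylated)) "ACETYL" else "CANONICAL"
}

.histone_roles <- c("H3", "H4", "H2A", "H2B", "H2B", "H2A", "H4", "H3")

.type_for <- function(role, state, hist_role = NA) {
  switch(role,
    LINKER = "LINKER_DNA",
    NUC_DNA = switch(state, CANONICAL = "NUC_DNA", ACETYL = "NUC_DNA_AC",
                     ACETYL_BRD4 = "NUC_DNA_B"),
    # entry/exit beads of BRD4-associated nucleosomes reuse the acetylated
    # entry/exit type: breathing is acetylation-level, BRD4 enhancement is a
    # core nonbonded effect
    ENTRY_DNA = switch(state, CANONICAL = "ENTRY_DNA", ACETYL = "ENTRY_DNA_AC",
                       ACETYL_BRD4 = "ENTRY_DNA_AC"),
    HIST = {
      base <- hist_role
      switch(state, CANONICAL = base, ACETYL = paste0(base, "_AC"),
             ACETYL_BRD4 = paste0(base, "_B"))
    },
    H1_GLOB = "H1_GLOB",
    H1_TAIL = "H1_TAIL")
}

# Straight reference assembly of one fiber. Returns coordinates, the per-bead
# table, and the complete fiber-local topology. Consecutive nucleosomes are
# rolled by 180 degrees about the fiber axis (deterministic convention,
# recorded in system metadata); initial inter-nucleosome orientation is
# relaxed away before production dynamics.
.fiber_reference <- function(spec, ff) {
  sg <- ff$sigma
  nuc <- spec$nucleosomes
  n_nuc <- nrow(nuc)
  linker_beads <- .bp_to_beads(spec$linker_lengths)

  pos <- list(); role <- character(0); nuc_id <- integer(0)
  hist_role <- character(0); state <- character(0)
  chain <- integer(0)   # bead indices forming the DNA chain, in order
  bonds <- list(); morse <- list(); angles <- list(); excl <- list()
  morse_meta <- list()
  nuc_axis <- list(); nuc_center <- list()

  cursor <- c(0, 0, 0)
  have_prev <- FALSE
  add_beads <- function(xyz, roles, nid, hroles, st) {
    k <- length(role)
    pos[[length(pos) + 1]] <<- xyz
    role <<- c(role, roles)
    nuc_id <<- c(nuc_id, rep(nid, length(roles)))
    hist_role <<- c(hist_role, hroles)
    state <<- c(state, rep(st, length(roles)))
    k + seq_len(length(roles))
  }
  add_linker_run <- function(nb) {
    if (nb == 0) return(invisible(NULL))
    for (b in seq_len(nb)) {
      at <- if (have_prev) cursor + c(sg, 0, 0) else cursor
      idx <- add_beads(matrix(at, 1), "LINKER", NA_integer_, NA_character_, NA_character_)
      if (have_prev) {
        prev_chain <- chain[length(chain)]
        bonds[[length(bonds) + 1]] <<- c(prev_chain, idx, sg, ff$k_bond)
      }
      chain <<- c(chain, idx)
      cursor <<- at
      have_prev <<- TRUE
    }
  }

  # leading linker
  add_linker_run(linker_beads[1])

  for (j in seq_len(n_nuc)) {
    rec <- nuc[j, ]
    geom <- build_nucleosome(rec, ff)
    topo <- .nucleosome_topology(geom, ff, acetylated = rec$acetylated || rec$brd4)
    e1 <- geom$entry_idx[1]; e2 <- geom$entry_idx[2]
    thru <- geom$xyz[e2, ] - geom$xyz[e1, ]
    Ra <- .rot_align(.normalize(thru), c(1, 0, 0))
    Rr <- .rot_axis(c(1, 0, 0), pi * (j - 1))
    Rm <- Rr %*% Ra
    local <- t(Rm %*% t(sweep(geom$xyz, 2, geom$xyz[e1, ])))
    at <- if (have_prev) cursor + c(sg, 0, 0) else cursor
    xyz <- sweep(local, 2, at, "+")
    st <- .state_of(rec)
    hr <- rep(NA_character_, nrow(xyz))
    hr[geom$hist_idx] <- .histone_roles
    idx <- add_beads(xyz, geom$role, j, hr, st)
    off <- idx[1] - 1
    prev_chain <- if (length(chain)) chain[length(chain)] else NA_integer_
    # connect previous chain bead to the entry bead
    if (have_prev && !is.na(prev_chain)) {
      bonds[[length(bonds) + 1]] <- c(prev_chain, off + e1, sg, ff$k_bond)
    }
    if (!is.null(topo$bonds)) {
      b <- topo$bonds; b[, 1:2] <- b[, 1:2] + off
      bonds <- c(bonds, split(b, row(b)[, 1]))
    }
    if (!is.null(topo$morse)) {
      m <- topo$morse; m[, 1:2] <- m[, 1:2] + off
      morse <- c(morse, split(m, row(m)[, 1]))
      for (r in seq_len(nrow(m))) {
        morse_meta[[length(morse_meta) + 1]] <-
          tibble(nucleosome = j, terminus = r,
                 entry_bead = m[r, 1], partner_bead = m[r, 2],
                 r0 = m[r, 5], a = m[r, 4], de = m[r, 3])
      }
    }
    if (!is.null(topo$angles)) {
      a <- topo$angles; a[, 1:3] <- a[, 1:3] + off
      angles <- c(angles, split(a, row(a)[, 1]))
    }
    if (!is.null(topo$exclusions)) {
      x <- topo$exclusions + off
      excl <- c(excl, split(x, row(x)[, 1]))
    }
    chain <- c(chain, off + geom$dna_idx)
    nuc_axis[[j]] <- as.numeric(Rm %*% geom$axis)
    nuc_center[[j]] <- as.numeric(Rm %*% (geom$center - geom$xyz[e1, ])) + at
    cursor <- xyz[e2, ]
    have_prev <- TRUE
    add_linker_run(linker_beads[j + 1])
  }
  if (n_nuc == 0) add_linker_run(0) # nothing further; naked DNA handled above

  xyz <- do.call(rbind, pos)
  n <- nrow(xyz)
  # DNA bending angles: every consecutive chain triplet whose center bead is
  # linker or entry/exit DNA (interior wrapped DNA is held by the bond net)
  if (length(chain) >= 3) {
    for (m in 2:(length(chain) - 1)) {
      cb <- chain[m]
      if (role[cb] %in% c("LINKER", "ENTRY_DNA")) {
        angles[[length(angles) + 1]] <- c(chain[m - 1], cb, chain[m + 1],
                                          pi, ff$k_bend)
      }
    }
  }

  tt <- bead_type_table(ff$sigma)
  type <- vapply(seq_len(n), function(i)
    .type_for(role[i], state[i], hist_role[i]), character(1))
  ti <- match(type, tt$type)
  dyad <- ifelse(is.na(nuc_id), NA_real_, nuc$dyad_position[nuc_id])
  beads <- tibble(
    bead = seq_len(n), role = role, nucleosome = nuc_id, state = state,
    dyad = dyad,
    type = type, type_id = tt$type_id[ti], class = tt$class[ti],
    class_id = match(tt$class[ti], .classes), charge = tt$charge[ti])

  list(xyz = xyz, beads = beads,
       bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 4),
       morse = if (length(morse)) do.call(rbind, morse) else matrix(0, 0, 5),
       angles = if (length(angles)) do.call(rbind, angles) else matrix(0, 0, 5),
       exclusions = if (length(excl)) do.call(rbind, excl) else matrix(0, 0, 2),
       morse_meta = if (length(morse_meta)) dplyr::bind_rows(morse_meta) else
         tibble(nucleosome = integer(0), terminus = integer(0),
                entry_bead = numeric(0), partner_bead = numeric(0),
                r0 = numeric(0), a = numeric(0), de = numeric(0)),
       chain = chain,
       nuc_axis = nuc_axis, nuc_center = nuc_center)
}

# --- chromatin systems -------------------------------------------------------

.new_system <- function(fibers, refs, positions, boundary, ff) {
  counts <- vapply(refs, function(r) nrow(r$xyz), integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  beads <- dplyr::bind_rows(lapply(seq_along(refs), function(i) {
    b <- refs[[i]]$beads
    b$bead <- b$bead + offsets[i]
    b$fiber <- fibers[[i]]$label
    b$fiber_id <- i
    b
  }))
  structure(list(
    positions = positions, beads = beads, fibers = fibers,
    offsets = offsets, boundary = boundary,
    forcefield = ff,
    orientation_convention = "entry-exit axis along path; alternating 180-degree roll (straight assembly) or seeded random roll (grown systems)"),
    class = "chromatin_system")
}

#' Number of beads in a system
#' @param system A `chromatin_system`.
#' @export
n_beads <- function(system) nrow(system$positions)

#' @export
print.chromatin_system <- function(x, ...) {
  nn <- sum(!is.na(x$beads$nucleosome))
  n_nuc <- nrow(dplyr::distinct(x$beads[!is.na(x$beads$nucleosome), ],
                                fiber_id, nucleosome))
  cat(sprintf("<chromatin_system> %d beads, %d fibers, %d nucleosomes; boundary: %s\n",
              n_beads(x), length(x$fibers), n_nuc, x$boundary$type))
  invisible(x)
}

#' Build a straight single-fiber system
#'
#' Lays the fiber along a straight path: linker DNA beads at 35 Angstrom
#' spacing along the fiber axis, nucleosomes inserted rigidly at their dyads
#' with the entry/exit axis along the path.
#'
#' @param spec A [fiber_spec()].
#' @param ff Force field.
#' @return A `chromatin_system` with no boundary.
#' @export
build_fiber <- function(spec, ff = default_forcefield()) {
  ref <- .fiber_reference(spec, ff)
  .new_system(list(spec), list(ref), ref$xyz,
              list(type = "none", box = c(0, 0, 0), radius = 0), ff)
}

# --- random growth -----------------------------------------------------------

# occupancy grid for clash checks, cell size = sigma
.grid_new <- function(cell) {
  list(env = new.env(parent = emptyenv()), cell = cell)
}
.grid_key <- function(g, p) {
  paste(floor(p[1] / g$cell), floor(p[2] / g$cell), floor(p[3] / g$cell))
}
.grid_add <- function(g, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  for (i in seq_len(nrow(xyz))) {
    k <- .grid_key(g, xyz[i, ])
    g$env[[k]] <- rbind(g$env[[k]], xyz[i, ])
  }
}
.grid_near <- function(g, p, rad) {
  cx <- floor(p[1] / g$cell); cy <- floor(p[2] / g$cell); cz <- floor(p[3] / g$cell)
  span <- ceiling(rad / g$cell)
  out <- list()
  for (ix in (cx - span):(cx + span))
    for (iy in (cy - span):(cy + span))
      for (iz in (cz - span):(cz + span)) {
        m <- g$env[[paste(ix, iy, iz)]]
        if (!is.null(m)) out[[length(out) + 1]] <- m
      }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
.grid_clash <- function(g, xyz, tol) {
  xyz <- matrix(xyz, ncol = 3)
  for (i in seq_len(nrow(xyz))) {
    near <- .grid_near(g, xyz[i, ], tol)
    if (!is.null(near)) {
      d2 <- (near[, 1] - xyz[i, 1])^2 + (near[, 2] - xyz[i, 2])^2 +
        (near[, 3] - xyz[i, 3])^2
      if (any(d2 < tol^2)) return(TRUE)
    }
  }
  FALSE
}

.rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# grow one fiber along a self-avoiding random reference backbone inside a
# region. `inside` is a list of two predicates: `bead` (the full region) and
# `walk` (the region shrunk by the nucleosome reach, so a nucleosome unit
# always fits wherever the backbone goes). Bead order matches
# .fiber_reference.
.grow_fiber_positions <- function(ref, ff, inside, start, grid, tol,
                                  max_attempts = 80) {
  sg <- ff$sigma
  beads <- ref$beads
  n <- nrow(beads)
  xyz <- matrix(NA_real_, n, 3)
  # nucleosome blocks: local coordinates relative to their entry bead,
  # entry->exit axis along +x (as assembled)
  dirp <- .rand_unit()
  cursor <- start
  placed_any <- FALSE
  i <- 1
  while (i <= n) {
    if (beads$role[i] == "LINKER") {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        dir <- if (att <= 30) .normalize(dirp + 0.8 * .rand_unit()) else
          .rand_unit()
        cand <- if (placed_any) cursor + sg * dir else cursor
        if (inside$walk(cand) && !.grid_clash(grid, cand, tol)) {
          xyz[i, ] <- cand
          .grid_add(grid, cand)
          cursor <- cand
          dirp <- dir
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
      placed_any <- TRUE
      i <- i + 1
    } else {
      # whole nucleosome block: contiguous beads with this nucleosome id
      nid <- beads$nucleosome[i]
      fib_rows <- which(beads$nucleosome == nid & !is.na(beads$nucleosome))
      block <- ref$xyz[fib_rows, , drop = FALSE]
      entry_local <- block[1, ]   # first bead of the block is the entry bead
      rel <- sweep(block, 2, entry_local)
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        dir <- if (att <= 30) .normalize(dirp + 0.8 * .rand_unit()) else
          .rand_unit()
        at <- if (placed_any) cursor + sg * dir else cursor
        if (!inside$walk(at)) next
        Rm <- .rot_axis(dir, runif(1, 0, 2 * pi)) %*% .rot_align(c(1, 0, 0), dir)
        cand <- sweep(rel %*% t(Rm), 2, at, "+")
        # the exit bead continues the walk, so it must stay in the walk region
        eidx <- which(beads$role[fib_rows] == "ENTRY_DNA")
        if (!inside$walk(cand[eidx[length(eidx)], ])) next
        if (all(apply(cand, 1, inside$bead)) && !.grid_clash(grid, cand, tol)) {
          xyz[fib_rows, ] <- cand
          .grid_add(grid, cand)
          cursor <- cand[eidx[length(eidx)], ]
          dirp <- dir
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
      placed_any <- TRUE
      i <- max(fib_rows) + 1
    }
  }
  xyz
}

.grow_fibers <- function(specs, ff, inside, sample_start, seed, tol,
                         max_restarts = 40) {
  refs <- lapply(specs, .fiber_reference, ff = ff)
  grid <- .grid_new(ff$sigma)
  all_pos <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    done <- FALSE
    for (r in seq_len(max_restarts)) {
      # snapshot the grid by rebuilding on failure: cheaper to track additions
      saved <- as.list(grid$env)
      xyz <- .grow_fiber_positions(refs[[i]], ff, inside, sample_start(), grid, tol)
      if (!is.null(xyz)) { all_pos[[i]] <- xyz; done <- TRUE; break }
      rm(list = ls(grid$env), envir = grid$env)
      for (k in names(saved)) grid$env[[k]] <- saved[[k]]
    }
    if (!done) {
      placed <- sum(vapply(all_pos[!vapply(all_pos, is.null, logical(1))],
                           nrow, integer(1)))
      stop(sprintf(paste0("could not place fiber '%s' after %d restarts ",
                          "(%d beads already placed; overlap tolerance %.1f A). ",
                          "The confining volume is likely too small for the ",
                          "requested chromatin content."),
                   specs[[i]]$label, max_restarts, placed, tol))
    }
  }
  list(refs = refs, positions = do.call(rbind, all_pos))
}

#' Grow a multi-fiber system inside a spherical volume
#'
#' Generates an initial structure by growing each chromatin fiber along a
#' self-avoiding random reference backbone confined to a sphere, emulating an
#' isotropic nuclear environment: the target locus plus short background
#' fibers at nuclear DNA density. The realized DNA concentration must be
#' within 10 percent of `target_density` (12.4 Mbp/um^3 reproduces the
#' average density of a mouse nucleus and gives roughly 100 uM nucleosomes).
#'
#' @param target Target-locus [fiber_spec()].
#' @param background List of background [fiber_spec()]s (see
#'   [background_fibers()]).
#' @param sphere_radius Confining sphere radius in Angstrom.
#' @param seed Integer seed; growth is deterministic given the seed.
#' @param ff Force field.
#' @param target_density Requested DNA density, Mbp/um^3.
#' @param overlap_tol Pre-relaxation overlap tolerance in Angstrom (hard
#'   clashes only; soft-core relaxation removes the rest).
#' @return A `chromatin_system` with a spherical boundary.
#' @export
grow_system <- function(target, background, sphere_radius, seed = 1,
                        ff = default_forcefield(), target_density = 12.4,
                        overlap_tol = 0.5 * ff$sigma) {
  specs <- c(list(target), background)
  total_bp <- sum(vapply(specs, function(s) s$length_bp, numeric(1)))
  vol_um3 <- 4 / 3 * pi * (sphere_radius * 1e-4)^3
  dens <- total_bp / 1e6 / vol_um3
  if (abs(dens - target_density) / target_density > 0.10) {
    stop(sprintf(paste0("total chromatin (%.3f Mbp) gives %.2f Mbp/um^3, more ",
                        "than 10%% away from the requested %.2f Mbp/um^3"),
                 total_bp / 1e6, dens, target_density))
  }
  r_eff <- sphere_radius - ff$sigma / 2
  r_walk <- r_eff - 170  # keep the backbone where a chromatosome always fits
  if (r_walk < 5 * ff$sigma) stop("sphere too small for nucleosome placement")
  inside <- list(bead = function(p) sum(p^2) < r_eff^2,
                 walk = function(p) sum(p^2) < r_walk^2)
  set.seed(seed %% .Machine$integer.max)
  sample_start <- function() {
    repeat {
      p <- runif(3, -0.9 * r_walk, 0.9 * r_walk)
      if (sum(p^2) < (0.9 * r_walk)^2) return(p)
    }
  }
  g <- .grow_fibers(specs, ff, inside, sample_start, seed, overlap_tol)
  sys <- .new_system(specs, g$refs, g$positions,
                     list(type = "sphere", radius = sphere_radius,
                          box = c(0, 0, 0)), ff)
  sys$realized_density_Mbp_um3 <- dens
  nuc <- sum(vapply(specs, function(s) nrow(s$nucleosomes), integer(1)))
  sys$nucleosome_concentration_uM <-
    nucleosome_concentration(nuc, vol_um3 * 1e9)
  sys
}

#' Background chromatin fibers at nuclear composition
#'
#' Short nonspecific fibers filling the simulation volume around a target
#' locus. Lengths are drawn within `length_range` and rescaled so the total
#' chromatin content meets the requested density exactly; epigenetic states
#' are assigned by flat-probability draws at the stated genome-average
#' fractions (20 percent acetylated, 31 percent H1-bound, 16.7 percent of
#' acetylated nucleosomes BRD4-bound).
#'
#' @param n Number of background fibers.
#' @param total_bp Total background DNA to distribute, bp.
#' @param length_range Admissible per-fiber length range, bp.
#' @param nrl Nucleosome repeat length used for the background fibers, bp.
#' @param fractions Target fractions `c(acetylated, h1, brd4_of_acetylated)`.
#' @param seed Integer seed.
#' @return List of [fiber_spec()]s.
#' @export
background_fibers <- function(n = 5, total_bp = 50e3,
                              length_range = c(10e3, 16e3), nrl = 195,
                              fractions = c(0.20, 0.31, 0.167), seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  len <- runif(n, length_range[1], length_range[2])
  len <- len * total_bp / sum(len)
  lapply(seq_len(n), function(i) {
    nn <- floor((len[i] - 147) / nrl) + 1
    ac <- runif(nn) < fractions[1]
    h1 <- runif(nn) < fractions[2]
    b4 <- ac & (runif(nn) < fractions[3])
    regular_fiber(nn, nrl = nrl, label = sprintf("background_%d", i),
                  acetylated = ac, brd4 = b4, h1 = h1)
  })
}

#' Build a periodic slab system
#'
#' Places `copies` of a fiber inside an elongated periodic box, initially
#' confined to the central region along the long (z) axis, the standard
#' geometry for measuring liquid-liquid phase-separation coexistence
#' densities. 45 copies of a 12-nucleosome fiber in a 100 x 100 x 1000 nm^3
#' box give an initial nucleosome concentration of 90 uM.
#'
#' @param copies Number of fiber copies (>= 1).
#' @param fiber A [fiber_spec()] to replicate.
#' @param box Box dimensions `c(Lx, Ly, Lz)` in Angstrom.
#' @param seed Integer seed.
#' @param ff Force field.
#' @param central_fraction Fraction of the z extent used for initial
#'   placement.
#' @param overlap_tol Pre-relaxation overlap tolerance, Angstrom.
#' @return A `chromatin_system` with periodic slab boundary; the initial
#'   nucleosome concentration (uM) is stored in the field
#'   `initial_concentration_uM`.
#' @export
build_slab_system <- function(copies, fiber, box, seed = 1,
                              ff = default_forcefield(),
                              central_fraction = 0.2,
                              overlap_tol = 0.5 * ff$sigma) {
  stopifnot(copies >= 1, length(box) == 3, all(box > 0))
  if (any(box < 4 * ff$sigma)) stop("box too small for the bead diameter")
  specs <- lapply(seq_len(copies), function(i) {
    s <- fiber; s$label <- sprintf("%s_copy%d", fiber$label, i); s
  })
  zc <- box[3] / 2
  zhw <- central_fraction * box[3] / 2
  margin <- ff$sigma / 2
  reach <- 170
  wm <- pmin(margin + reach, box[1:2] / 3)
  zw <- max(zhw - reach, box[3] * 0.02)
  inside <- list(
    bead = function(p) {
      all(p[1:2] > margin) && all(p[1:2] < box[1:2] - margin) &&
        p[3] > zc - zhw && p[3] < zc + zhw
    },
    walk = function(p) {
      all(p[1:2] > wm) && all(p[1:2] < box[1:2] - wm) &&
        p[3] > zc - zw && p[3] < zc + zw
    })
  set.seed(seed %% .Machine$integer.max)
  sample_start <- function() c(runif(1, wm[1], box[1] - wm[1]),
                               runif(1, wm[2], box[2] - wm[2]),
                               runif(1, zc - zw, zc + zw))
  g <- .grow_fibers(specs, ff, inside, sample_start, seed, overlap_tol)
  sys <- .new_system(specs, g$refs, g$positions,
                     list(type = "slab", box = box, radius = 0), ff)
  n_nuc <- copies * nrow(fiber$nucleosomes)
  sys$initial_concentration_uM <-
    nucleosome_concentration(n_nuc, prod(box) * 1e-3) # A^3 -> nm^3
  sys
}

# --- structure export --------------------------------------------------------

#' Export coordinates as XYZ
#'
#' @param system A `chromatin_system` (or a trajectory; all frames written).
#' @param path Output path.
#' @export
export_xyz <- function(system, path) {
  frames <- if (inherits(system, "chromatin_trajectory")) {
    system$frames
  } else {
    list(system$positions)
  }
  beads <- if (inherits(system, "chromatin_trajectory")) system$beads else system$beads
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(as.character(nrow(f)), con)
    writeLines("nucfold export", con)
    writeLines(sprintf("%s %.4f %.4f %.4f", substr(beads$role, 1, 2),
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Export a structure as a multi-model PDB-like file
#'
#' One HETATM record per bead; chain per fiber (cycled A-Z), residue number =
#' nucleosome index, B-factor encodes the interaction class id. Trajectories
#' are written as successive MODEL blocks.
#'
#' @param system A `chromatin_system` or `chromatin_trajectory`.
#' @param path Output path.
#' @export
export_pdb <- function(system, path) {
  frames <- if (inherits(system, "chromatin_trajectory")) {
    system$frames
  } else {
    list(system$positions)
  }
  beads <- system$beads
  chains <- LETTERS[(beads$fiber_id - 1) %% 26 + 1]
  resno <- ifelse(is.na(beads$nucleosome), 0L, beads$nucleosome)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    f <- frames[[m]]
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f",
      (beads$bead - 1) %% 99999 + 1, substr(beads$type, 1, 4),
      substr(beads$role, 1, 3), chains, resno %% 9999,
      f[, 1], f[, 2], f[, 3], beads$class_id), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
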