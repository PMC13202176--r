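#' Export a system as runnable LAMMPS inputs
#'
#' Writes a self-contained LAMMPS data file (atom style `full`, hybrid
#' harmonic/Morse/zero bond styles, harmonic angles, all coefficient tables
#' embedded) and a companion input script encoding the Langevin run: 300 K,
#' the 140-ns damping factor, `lj/cut/coul/debye` pair interactions with the
#' model cutoffs, and coordinate dumps every 10^5 timesteps. Entry/exit-bead
#' exclusion pairs are emitted as zero-style bonds so that `special_bonds`
#' removes them from the nonbonded neighbor lists, exactly as the internal
#' engine does.
#'
#' @param system A `chromatin_system`.
#' @param topology From [build_topology()].
#' @param config A [sim_config()].
#' @param data_path,input_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
export_lammps <- function(system, topology, config = sim_config(),
                          data_path = "system.data",
                          input_path = "system.in") {
  ff <- topology$forcefield
  if (!system$boundary$type %in% c("none", "sphere", "slab")) {
    stop("unsupported boundary type: ", system$boundary$type)
  }
  beads <- system$beads
  pos <- system$positions
  n <- nrow(pos)
  tt <- bead_type_table(ff$sigma)

  # bond types: harmonic by (k, r0), morse by (de, a, r0), zero for exclusions
  hb <- topology$bonds
  mb <- topology$morse
  xb <- topology$exclusions
  hkey <- sprintf("h_%.17g_%.17g", hb$k, hb$r0)
  mkey <- sprintf("m_%.17g_%.17g_%.17g", mb$de, mb$a, mb$r0)
  keys <- c(unique(hkey), unique(mkey), if (nrow(xb)) "zero")
  btype_of_h <- match(hkey, keys)
  btype_of_m <- match(mkey, keys)
  ztype <- match("zero", keys)
  ab <- topology$angles
  akey <- sprintf("a_%.17g_%.17g", ab$k_theta, ab$theta0)
  akeys <- unique(akey)
  atype_of <- match(akey, akeys)

  b <- system$boundary
  if (b$type == "slab") {
    lo <- c(0, 0, 0); hi <- as.numeric(b$box)
  } else {
    pad <- 4 * ff$sigma
    lo <- apply(pos, 2, min) - pad
    hi <- apply(pos, 2, max) + pad
    if (b$type == "sphere") {
      lo <- pmin(lo, -b$radius - pad); hi <- pmax(hi, b$radius + pad)
    }
  }
  ld <- debye_length(config$salt_mM, config$temperature, ff$dielectric)

  con <- file(data_path, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file generated by nucfold # pair lj/cut/coul/debye kappa=%.17g rc_lj=%.17g rc_dh=%.17g dielectric=%.17g sigma=%.17g",
    1 / ld, ff$lj_cutoff, ff$dh_cutoff_debye * ld, ff$dielectric, ff$sigma)
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(hb) + nrow(mb) + nrow(xb))
  w("%d angles", nrow(ab))
  w("%d atom types", nrow(tt))
  w("%d bond types", length(keys))
  w("%d angle types", max(length(akeys), 1L))
  w("")
  w("%.6f %.6f xlo xhi", lo[1], hi[1])
  w("%.6f %.6f ylo yhi", lo[2], hi[2])
  w("%.6f %.6f zlo zhi", lo[3], hi[3])
  w("")
  w("Masses")
  w("")
  for (t in seq_len(nrow(tt))) w("%d 1.0 # %s", t, tt$type[t])
  w("")
  w("Bond Coeffs # hybrid")
  w("")
  for (k in seq_along(keys)) {
    if (startsWith(keys[k], "h_")) {
      pr <- as.numeric(strsplit(keys[k], "_")[[1]][2:3])
      w("%d harmonic %.17g %.17g", k, pr[1], pr[2])
    } else if (startsWith(keys[k], "m_")) {
      pr <- as.numeric(strsplit(keys[k], "_")[[1]][2:4])
      w("%d morse %.17g %.17g %.17g", k, pr[1], pr[2], pr[3])
    } else {
      w("%d zero", k)
    }
  }
  if (nrow(ab)) {
    w("")
    w("Angle Coeffs # harmonic, theta0 in degrees")
    w("")
    for (k in seq_along(akeys)) {
      pr <- as.numeric(strsplit(akeys[k], "_")[[1]][2:3])
      w("%d %.17g %.17g", k, pr[1], pr[2] * 180 / pi)
    }
  }
  w("")
  w("Atoms # full")
  w("")
  mol <- beads$fiber_id
  for (i in seq_len(n)) {
    w("%d %d %d %.6g %.8f %.8f %.8f", i, mol[i], beads$type_id[i],
      beads$charge[i], pos[i, 1], pos[i, 2], pos[i, 3])
  }
  w("")
  w("Bonds")
  w("")
  bid <- 0
  for (r in seq_len(nrow(hb))) {
    bid <- bid + 1
    w("%d %d %d %d", bid, btype_of_h[r], hb$i[r], hb$j[r])
  }
  for (r in seq_len(nrow(mb))) {
    bid <- bid + 1
    w("%d %d %d %d", bid, btype_of_m[r], mb$i[r], mb$j[r])
  }
  if (nrow(xb)) {
    for (r in seq_len(nrow(xb))) {
      bid <- bid + 1
      w("%d %d %d %d", bid, ztype, xb$i[r], xb$j[r])
    }
  }
  if (nrow(ab)) {
    w("")
    w("Angles")
    w("")
    for (r in seq_len(nrow(ab))) {
      w("%d %d %d %d %d", r, atype_of[r], ab$i[r], ab$j[r], ab$k[r])
    }
  }
  close(con)

  # input script
  cls_id <- match(tt$class, .classes)
  pm <- unclass(ff$pair_matrix)
  con <- file(input_path, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("# nucfold coarse-grained chromatin run")
  w("units real")
  w("atom_style full")
  w("boundary %s", if (b$type == "slab") "p p p" else "f f f")
  w("special_bonds lj/coul 0.0 1.0 1.0")
  w("bond_style hybrid harmonic morse%s", if (nrow(xb)) " zero" else "")
  if (nrow(ab)) w("angle_style harmonic")
  w("pair_style lj/cut/coul/debye %.8g %.8g %.8g", 1 / ld, ff$lj_cutoff,
    ff$dh_cutoff_debye * ld)
  w("dielectric %.8g", ff$dielectric)
  w("read_data %s", basename(data_path))
  for (a in seq_len(nrow(tt))) {
    for (bb in a:nrow(tt)) {
      w("pair_coeff %d %d %.8g %.8g", a, bb, pm[cls_id[a], cls_id[bb]],
        ff$sigma)
    }
  }
  w("pair_modify shift yes")
  if (b$type == "sphere") {
    w("region confine sphere 0 0 0 %.6f side in", b$radius)
    w("fix wall all wall/region confine lj126 %.6g %.6g %.6g", ff$wall_eps,
      ff$sigma, ff$sigma * 2^(1 / 6))
  }
  w("velocity all create %.1f %d", config$temperature, config$seed)
  w("fix lang all langevin %.1f %.1f %.8g %d", config$temperature,
    config$temperature, config$damping_ns / config$time_scale, config$seed)
  w("fix nve all nve")
  w("timestep 1.0 # one internal timestep; %.3g ns of physical time", config$time_scale)
  w("dump traj all custom %d traj.lammpstrj id type x y z", config$dump_interval)
  w("thermo 10000")
  w("run %d", as.integer(config$n_steps))
  close(con)
  invisible(c(data = data_path, input = input_path))
}

#' Parse a nucfold-generated LAMMPS data file
#'
#' Reads back the atom, bond, angle and coefficient tables (including the
#' embedded pair metadata header), sufficient to reconstruct the full
#' interaction topology and recompute energies independently of the engine.
#'
#' @param path Data file path.
#' @return List with `atoms`, `bonds`, `angles`, `bond_coeffs`,
#'   `angle_coeffs`, `box`, `meta`.
#' @export
read_lammps_data <- function(path) {
  ln <- readLines(path)
  meta <- list()
  m <- regmatches(ln[1], gregexpr("[a-z_]+=[0-9.eE+-]+", ln[1]))[[1]]
  for (kv in m) {
    p <- strsplit(kv, "=")[[1]]
    meta[[p[1]]] <- as.numeric(p[2])
  }
  counts <- function(what) {
    r <- grep(paste0("^\\s*\\d+\\s+", what, "\\s*$"), ln, value = TRUE)
    if (!length(r)) return(0L)
    as.integer(strsplit(trimws(r[1]), "\\s+")[[1]][1])
  }
  n_at <- counts("atoms"); n_b <- counts("bonds"); n_an <- counts("angles")
  section <- function(name, nrows, ncols = NULL) {
    if (nrows == 0) return(NULL)
    st <- grep(paste0("^", name, "\\b"), ln)
    if (!length(st)) return(NULL)
    block <- ln[(st[1] + 2):(st[1] + 1 + nrows)]
    block <- sub("#.*", "", block)
    if (is.null(ncols)) {
      utils::read.table(text = block, fill = TRUE, stringsAsFactors = FALSE)
    } else {
      utils::read.table(text = block, fill = TRUE, stringsAsFactors = FALSE,
                        col.names = paste0("V", seq_len(ncols)))
    }
  }
  at <- section("Atoms", n_at)
  atoms <- tibble(id = at[[1]], mol = at[[2]], type = at[[3]], q = at[[4]],
                  x = at[[5]], y = at[[6]], z = at[[7]])
  atoms <- dplyr::arrange(atoms, .data$id)
  bd <- section("Bonds", n_b)
  bonds <- if (is.null(bd)) NULL else
    tibble(id = bd[[1]], type = bd[[2]], i = bd[[3]], j = bd[[4]])
  an <- section("Angles", n_an)
  angles <- if (is.null(an)) NULL else
    tibble(id = an[[1]], type = an[[2]], i = an[[3]], j = an[[4]], k = an[[5]])
  nbt <- counts("bond types"); nat2 <- counts("angle types")
  bc_raw <- section("Bond Coeffs", nbt, ncols = 5)
  bond_coeffs <- if (is.null(bc_raw)) NULL else
    tibble(type = bc_raw[[1]], style = bc_raw[[2]],
           p1 = suppressWarnings(as.numeric(bc_raw[[3]])),
           p2 = suppressWarnings(as.numeric(bc_raw[[4]])),
           p3 = suppressWarnings(as.numeric(bc_raw[[5]])))
  ac_raw <- section("Angle Coeffs", nat2)
  angle_coeffs <- if (is.null(ac_raw) || n_an == 0) NULL else
    tibble(type = ac_raw[[1]], k = as.numeric(ac_raw[[2]]),
           theta0_deg = as.numeric(ac_raw[[3]]))
  bx <- function(tag) {
    r <- grep(tag, ln, value = TRUE)[1]
    as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:2])
  }
  list(atoms = atoms, bonds = bonds, angles = angles,
       bond_coeffs = bond_coeffs, angle_coeffs = angle_coeffs,
       box = rbind(bx("xlo"), bx("ylo"), bx("zlo")), meta = meta)
}

#' Recompute the potential energy from exported LAMMPS definitions
#'
#' Independent R-side evaluator over the parsed data file: truncated-shifted
#' Lennard-Jones with per-type-pair strengths, Debye-Hueckel electrostatics
#' for charged pairs, hybrid harmonic/Morse bonds and harmonic angles, with
#' 1-2 bonded pairs (including zero-style exclusion bonds) removed from the
#' nonbonded sum. Used to verify that the engine and the exported model
#' define the same energy surface.
#'
#' @param parsed Output of [read_lammps_data()].
#' @param pair_eps Matrix of per-atom-type LJ strengths (from the force
#'   field's class matrix; see [bead_type_table()]).
#' @param positions Optional coordinate matrix overriding the file's.
#' @return Total potential energy in kcal/mol.
#' @export
lammps_reference_energy <- function(parsed, pair_eps, positions = NULL) {
  at <- parsed$atoms
  pos <- if (is.null(positions)) as.matrix(at[, c("x", "y", "z")]) else positions
  n <- nrow(pos)
  meta <- parsed$meta
  sg <- meta$sigma
  rc <- meta$rc_lj; rcd <- meta$rc_dh; kap <- meta$kappa
  excl <- matrix(FALSE, n, n)
  if (!is.null(parsed$bonds)) {
    excl[cbind(parsed$bonds$i, parsed$bonds$j)] <- TRUE
    excl[cbind(parsed$bonds$j, parsed$bonds$i)] <- TRUE
  }
  dm <- as.matrix(stats::dist(pos))
  e <- 0
  ljs <- function(eps, r) {
    s6 <- (sg / r)^6
    s6c <- (sg / rc)^6
    4 * eps * (s6^2 - s6) - 4 * eps * (s6c^2 - s6c)
  }
  dhs <- function(qq, r) {
    pref <- .coulomb_const / meta$dielectric * qq
    pref * exp(-kap * r) / r - pref * exp(-kap * rcd) / rcd
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (excl[i, j]) next
      r <- dm[i, j]
      if (r < rc) e <- e + ljs(pair_eps[at$type[i], at$type[j]], r)
      qq <- at$q[i] * at$q[j]
      if (qq != 0 && r < rcd) e <- e + dhs(qq, r)
    }
  }
  if (!is.null(parsed$bonds)) {
    bc <- parsed$bond_coeffs
    for (r in seq_len(nrow(parsed$bonds))) {
      b <- parsed$bonds[r, ]
      cf <- bc[bc$type == b$type, ]
      d <- dm[b$i, b$j]
      e <- e + switch(cf$style,
        harmonic = cf$p1 * (d - cf$p2)^2,
        morse = cf$p1 * (1 - exp(-cf$p2 * (d - cf$p3)))^2,
        zero = 0)
    }
  }
  if (!is.null(parsed$angles)) {
    ac <- parsed$angle_coeffs
    for (r in seq_len(nrow(parsed$angles))) {
      a <- parsed$angles[r, ]
      cf <- ac[ac$type == a$type, ]
      v1 <- pos[a$i, ] - pos[a$j, ]
      v2 <- pos[a$k, ] - pos[a$j, ]
      th <- acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2)))))
      e <- e + cf$k * (th - cf$theta0_deg * pi / 180)^2
    }
  }
  e
}

#' Per-atom-type LJ strength matrix for the exported model
#'
#' Expands the 5-class pair matrix to the full 20-type pair table used by
#' the LAMMPS export.
#'
#' @param ff Force field.
#' @return 20 x 20 numeric matrix.
#' @export
type_pair_matrix <- function(ff = default_forcefield()) {
  tt <- bead_type_table(ff$sigma)
  cls <- match(tt$class, .classes)
  m <- unclass(ff$pair_matrix)[cls, cls]
  dimnames(m) <- list(tt$type, tt$type)
  m
}
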