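#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# interaction classes, in fixed order
.classes <- c("LINKER_DNA", "CANONICAL_NUC", "ACETYL_NUC", "ACETYL_BRD4_NUC",
              "LINKER_HISTONE")

#' Bead type table
#'
#' The model uses 20 bead types grouped into 5 interaction classes: linker
#' DNA, canonical nucleosome, acetylated nucleosome, acetylated nucleosome
#' associated with BRD4, and linker histone H1. All beads share the same
#' diameter sigma = 35 Angstrom (one DNA helical turn). Linker-DNA beads carry
#' -7.35e, each of the two H1 beads carries +5e, nucleosome-core beads are
#' neutral. Only the class-level behaviour is contractual; the per-type
#' enumeration (histone roles, nucleosomal vs entry/exit DNA) is internal.
#'
#' @param sigma Bead diameter in Angstrom.
#' @return A tibble with columns `type_id`, `type`, `class`, `charge`,
#'   `diameter`.
#' @export
bead_type_table <- function(sigma = 35) {
  can <- c("NUC_DNA", "ENTRY_DNA", "H2A", "H2B", "H3", "H4")
  types <- c(
    "LINKER_DNA",
    can,
    paste0(can, "_AC"),
    paste0(c("NUC_DNA", "H2A", "H2B", "H3", "H4"), "_B"),
    "H1_GLOB", "H1_TAIL")
  cls <- c(
    "LINKER_DNA",
    rep("CANONICAL_NUC", 6),
    rep("ACETYL_NUC", 6),
    rep("ACETYL_BRD4_NUC", 5),
    rep("LINKER_HISTONE", 2))
  charge <- ifelse(types == "LINKER_DNA", -7.35,
                   ifelse(cls == "LINKER_HISTONE", 5, 0))
  tibble(type_id = seq_along(types), type = types, class = cls,
         charge = charge, diameter = sigma)
}

#' Nonbonded Lennard-Jones pair matrix between interaction classes
#'
#' Encodes the epigenetic interaction rules: canonical-canonical pairs attract
#' with `eps0`; acetylation weakens the attraction to `eps_ac`; mixed
#' canonical-acetylated pairs use the geometric-mean strength `eps_h`; pairs
#' where at least one partner is an acetylated nucleosome associated with BRD4
#' and the other is acetylated (with or without BRD4) are enhanced to `eps_b`;
#' H1 beads bind linker DNA with `eps_h1`. All remaining class pairs use the
#' weak near-excluded-volume strength `eps_weak`. Charged pairs (linker DNA
#' and H1) additionally interact through Debye-Hueckel electrostatics.
#'
#' @param eps0 Canonical-canonical strength, kcal/mol.
#' @param eps_ac Acetyl-acetyl strength, kcal/mol.
#' @param eps_h Canonical-acetyl strength; default geometric mean of `eps0`
#'   and `eps_ac`.
#' @param eps_b BRD4-enhanced acetyl strength, kcal/mol.
#' @param eps_h1 H1 to linker-DNA strength, kcal/mol.
#' @param eps_weak Baseline strength for all remaining class pairs, kcal/mol.
#' @return A symmetric 5 x 5 matrix with class names, class "pair_matrix".
#' @export
pair_matrix <- function(eps0 = 0.115, eps_ac = 0.06,
                        eps_h = sqrt(eps0 * eps_ac),
                        eps_b = 0.23, eps_h1 = 0.50, eps_weak = 0.03) {
  stopifnot(eps_ac < eps_h, eps_h < eps0, eps_b > eps_ac,
            eps0 > 0, eps_ac > 0, eps_h1 > 0, eps_weak > 0)
  m <- matrix(eps_weak, 5, 5, dimnames = list(.classes, .classes))
  m["CANONICAL_NUC", "CANONICAL_NUC"] <- eps0
  m["ACETYL_NUC", "ACETYL_NUC"] <- eps_ac
  m["CANONICAL_NUC", "ACETYL_NUC"] <- eps_h
  m["CANONICAL_NUC", "ACETYL_BRD4_NUC"] <- eps_h
  m["ACETYL_NUC", "ACETYL_BRD4_NUC"] <- eps_b
  m["ACETYL_BRD4_NUC", "ACETYL_BRD4_NUC"] <- eps_b
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  class(m) <- c("pair_matrix", class(m))
  m
}

#' Effective Lennard-Jones strength for a nucleosome pair
#'
#' BRD4 bridging is acetyl-specific: the enhanced strength applies when at
#' least one partner is an acetylated nucleosome associated with BRD4 and the
#' other is acetylated (with or without BRD4). A BRD4-associated nucleosome
#' facing a canonical one falls back to the hybrid canonical-acetyl strength.
#'
#' @param state_i,state_j Nucleosome states, one of `"CANONICAL"`, `"ACETYL"`,
#'   `"ACETYL_BRD4"`.
#' @param pm Pair matrix from [pair_matrix()].
#' @return Effective epsilon in kcal/mol.
#' @export
brd4_rule <- function(state_i, state_j, pm = pair_matrix()) {
  valid <- c("CANONICAL", "ACETYL", "ACETYL_BRD4")
  if (!(state_i %in% valid) || !(state_j %in% valid)) {
    stop("unknown nucleosome state: ", state_i, " / ", state_j)
  }
  cls <- function(s) switch(s, CANONICAL = "CANONICAL_NUC",
                            ACETYL = "ACETYL_NUC",
                            ACETYL_BRD4 = "ACETYL_BRD4_NUC")
  unname(pm[cls(state_i), cls(state_j)])
}

#' Default force field
#'
#' All constants of the model in one list: the pair matrix, charges and
#' geometry via [bead_type_table()], bonded constants, Morse (nucleosome
#' breathing) parameters, electrostatics and cutoffs. Bonded constants and the
#' Morse well were calibrated in-package: the DNA bending constant against the
#' salt-dependent DNA persistence length, the Morse well depth against a
#' spontaneous unwrapping equilibrium constant of 0.10 for canonical
#' nucleosomes, and the acetyl Morse scaling against the three-fold increased
#' unwrapping of acetylated nucleosomes (see the methods vignette for the
#' calibration protocol).
#'
#' @param temperature Kelvin.
#' @param salt_mM Monovalent salt, mM.
#' @param pm Pair matrix, from [pair_matrix()].
#' @param ... Overrides for any scalar constant listed below.
#' @return A list of class `nucfold_forcefield`.
#' @export
default_forcefield <- function(temperature = 300, salt_mM = 150,
                               pm = pair_matrix(), ...) {
  ff <- list(
    version = "nucfold-ff-1",
    sigma = 35,                 # bead diameter, A
    pair_matrix = pm,
    temperature = temperature,
    salt_mM = salt_mM,
    dielectric = 78,
    lj_cutoff = 3 * 35,         # 3 sigma
    dh_cutoff_debye = 5,        # Debye-Hueckel cutoff, in Debye lengths
    k_bond = 10,                # intra-nucleosome + chain harmonic, kcal/mol/A^2
    k_bend = 4.4,               # DNA angle constant, kcal/mol/rad^2 (calibrated)
    k_h1 = 10,                  # H1 anchoring angle constant, kcal/mol/rad^2
    bond_cut = 38,              # harmonic-bond reference-distance rule, A
    morse_de = 3.05,             # Morse well depth, kcal/mol (calibrated)
    morse_a = 0.2,              # Morse width, 1/A
    morse_acetyl_scale = 0.777,  # well-depth scaling for acetylated entry/exit (calibrated)
    superhelix_radius_dna = 40,
    superhelix_radius_histone = 18,
    superhelix_pitch = 25,
    h1_distance = 70,           # first H1 bead to nucleosome center, A
    wall_eps = 1.0,             # spherical wall repulsion strength, kcal/mol
    relax_rcap = 0.8 * 35       # soft-core force-capping radius, A
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(ff))
  if (length(bad)) stop("unknown force-field constants: ", paste(bad, collapse = ", "))
  ff[names(dots)] <- dots
  ff$dh_cutoff <- ff$dh_cutoff_debye *
    debye_length(ff$salt_mM, ff$temperature, ff$dielectric)
  class(ff) <- "nucfold_forcefield"
  ff
}

#' @export
print.nucfold_forcefield <- function(x, ...) {
  cat("<nucfold_forcefield>", x$version, "\n")
  cat(sprintf("  T = %g K, salt = %g mM, sigma = %g A\n",
              x$temperature, x$salt_mM, x$sigma))
  cat(sprintf("  eps0 = %g, eps_ac = %g, eps_h = %.4f, eps_B = %g, eps_H1 = %g kcal/mol\n",
              x$pair_matrix["CANONICAL_NUC", "CANONICAL_NUC"],
              x$pair_matrix["ACETYL_NUC", "ACETYL_NUC"],
              x$pair_matrix["CANONICAL_NUC", "ACETYL_NUC"],
              x$pair_matrix["ACETYL_NUC", "ACETYL_BRD4_NUC"],
              x$pair_matrix["LINKER_DNA", "LINKER_HISTONE"]))
  cat(sprintf("  Morse: De = %g kcal/mol, a = %g 1/A, acetyl scale = %g\n",
              x$morse_de, x$morse_a, x$morse_acetyl_scale))
  invisible(x)
}

#' Write a force field to a YAML parameter file
#'
#' @param ff Force field from [default_forcefield()].
#' @param path Output file path.
#' @export
write_forcefield_yaml <- function(ff, path) {
  out <- unclass(ff)
  out$pair_matrix <- apply(unclass(ff$pair_matrix), 1, as.list, simplify = FALSE)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Pairwise nonbonded energy between two interaction classes
#'
#' Lennard-Jones with the class-pair strength, truncated and shifted to zero
#' at the cutoff, plus a Debye-Hueckel term for charged class pairs (linker
#' DNA and H1 beads), similarly shifted.
#'
#' @param class_i,class_j Interaction class names (see [bead_type_table()]).
#' @param r Separation in Angstrom (vectorized).
#' @param ff Force field.
#' @param salt_mM Salt concentration override, mM.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(class_i, class_j, r, ff = default_forcefield(),
                        salt_mM = ff$salt_mM) {
  stopifnot(all(r > 0))
  if (!(class_i %in% .classes) || !(class_j %in% .classes)) {
    stop("unknown interaction class pair: ", class_i, " / ", class_j)
  }
  eps <- ff$pair_matrix[class_i, class_j]
  sg <- ff$sigma
  ljs <- function(rr) {
    s6 <- (sg / rr)^6
    4 * eps * (s6^2 - s6)
  }
  u <- ifelse(r < ff$lj_cutoff, ljs(r) - ljs(ff$lj_cutoff), 0)
  q <- c(LINKER_DNA = -7.35, CANONICAL_NUC = 0, ACETYL_NUC = 0,
         ACETYL_BRD4_NUC = 0, LINKER_HISTONE = 5)
  qq <- q[[class_i]] * q[[class_j]]
  if (qq != 0) {
    ld <- debye_length(salt_mM, ff$temperature, ff$dielectric)
    rc <- ff$dh_cutoff_debye * ld
    dh <- function(rr) .coulomb_const / ff$dielectric * qq * exp(-rr / ld) / rr
    u <- u + ifelse(r < rc, dh(r) - dh(rc), 0)
  }
  unname(u)
}
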