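#' Nucleosome records and fiber specifications
#'
#' A nucleosome record is the genomic-level description of one nucleosome:
#' the dyad position (bp), the wrapped length (147 bp canonical; one bead per
#' 10.5 bp), and the epigenetic state flags (acetylated, BRD4-associated,
#' H1-bound). BRD4 association implies acetylation.
#'
#' @param dyad_position Genomic dyad coordinate, bp (0-based).
#' @param acetylated,brd4,h1 Logical state flags.
#' @param wrap_bp Wrapped DNA, bp; must map to a whole number of beads.
#' @return A one-row tibble.
#' @export
nucleosome_record <- function(dyad_position, acetylated = FALSE, brd4 = FALSE,
                              h1 = FALSE, wrap_bp = 147) {
  rec <- tibble(dyad_position = as.numeric(dyad_position),
                acetylated = acetylated, brd4 = brd4, h1 = h1,
                wrap_bp = as.numeric(wrap_bp))
  validate_nucleosomes(rec)
  rec
}

validate_nucleosomes <- function(nuc) {
  if (nrow(nuc) == 0) return(invisible(nuc))
  beads <- nuc$wrap_bp / .bp_per_bead
  off <- abs(beads - round(beads)) > 1e-6
  if (any(off)) {
    stop("wrap_bp not representable as whole 10.5-bp beads at dyad(s) ",
         paste(nuc$dyad_position[off], collapse = ", "))
  }
  if (any(nuc$brd4 & !nuc$acetylated)) {
    stop("BRD4 can only be associated with acetylated nucleosomes")
  }
  if (nrow(nuc) > 1) {
    sp <- diff(nuc$dyad_position)
    need <- (nuc$wrap_bp[-nrow(nuc)] + nuc$wrap_bp[-1]) / 2
    if (any(sp <= 0)) stop("dyad positions must be strictly increasing")
    bad <- sp < need
    if (any(bad)) {
      stop("overlapping nucleosome footprints at dyads ",
           paste(sprintf("%g/%g", nuc$dyad_position[which(bad)],
                         nuc$dyad_position[which(bad) + 1]), collapse = ", "))
    }
  }
  invisible(nuc)
}

#' Fiber specification
#'
#' The genomic-coordinate description of a chromatin fiber: an ordered set of
#' nucleosome records within `[0, length_bp)`, with linker DNA in between.
#' Linkers are discretized to `round(linker_bp / 10.5)` beads; the rounding
#' remainder is absorbed into the adjacent linker so total bead count is a
#' deterministic function of the spec.
#'
#' @param label Fiber name.
#' @param length_bp Total fiber length in bp.
#' @param nucleosomes Tibble of nucleosome records (see [nucleosome_record()]),
#'   ordered by dyad.
#' @return A list of class `fiber_spec` with fields `label`, `length_bp`,
#'   `nucleosomes` and the derived `linker_lengths` (bp; includes the leading
#'   and trailing naked DNA segments, so it has `n_nucleosomes + 1` entries).
#' @export
fiber_spec <- function(label, length_bp, nucleosomes = nucleosome_record(numeric(0))[0, ]) {
  nucleosomes <- as_tibble(nucleosomes)
  validate_nucleosomes(nucleosomes)
  n <- nrow(nucleosomes)
  if (n > 0) {
    starts <- nucleosomes$dyad_position - nucleosomes$wrap_bp / 2
    ends <- nucleosomes$dyad_position + nucleosomes$wrap_bp / 2
    if (starts[1] < -1e-9 || ends[n] > length_bp + 1e-9) {
      stop("nucleosome footprints extend beyond the fiber [0, length_bp)")
    }
    linkers <- c(starts[1], if (n > 1) starts[-1] - ends[-n] else numeric(0),
                 length_bp - ends[n])
  } else {
    linkers <- length_bp
  }
  if (any(linkers < -1e-9)) stop("negative linker length")
  structure(list(label = label, length_bp = length_bp,
                 nucleosomes = nucleosomes, linker_lengths = pmax(linkers, 0)),
            class = "fiber_spec")
}

#' Regularly spaced fiber
#'
#' Convenience constructor for validation arrays: `n` nucleosomes at a fixed
#' nucleosome repeat length (NRL = wrap + linker), with optional uniform or
#' per-nucleosome epigenetic states and no naked flanks.
#'
#' @param n Number of nucleosomes.
#' @param nrl Nucleosome repeat length, bp (e.g. 207 gives 60-bp linkers).
#' @param label Fiber label.
#' @param acetylated,brd4,h1 Logical, length 1 or `n`.
#' @param wrap_bp Wrapped length per nucleosome.
#' @return A [fiber_spec()].
#' @export
regular_fiber <- function(n, nrl = 207, label = "fiber", acetylated = FALSE,
                          brd4 = FALSE, h1 = FALSE, wrap_bp = 147) {
  stopifnot(n >= 1, nrl >= wrap_bp)
  dyads <- wrap_bp / 2 + (seq_len(n) - 1) * nrl
  nuc <- tibble(dyad_position = dyads,
                acetylated = rep(acetylated, length.out = n),
                brd4 = rep(brd4, length.out = n),
                h1 = rep(h1, length.out = n),
                wrap_bp = wrap_bp)
  len <- n * wrap_bp + (n - 1) * (nrl - wrap_bp)
  fiber_spec(label, len, nuc)
}

#' Alternating canonical/acetylated validation array
#'
#' Builds the 96-nucleosome array alternating between canonical and
#' acetylated blocks of 12 used for contact-map validation (or any other
#' block pattern).
#'
#' @param n_total Total nucleosomes (default 96).
#' @param block Nucleosomes per block (default 12).
#' @param nrl Repeat length in bp.
#' @param label Fiber label.
#' @return A [fiber_spec()] whose state vector alternates in blocks,
#'   starting canonical.
#' @export
alternating_array <- function(n_total = 96, block = 12, nrl = 207,
                              label = "alt96") {
  ac <- ((seq_len(n_total) - 1) %/% block) %% 2 == 1
  regular_fiber(n_total, nrl = nrl, label = label, acetylated = ac)
}

#' @export
print.fiber_spec <- function(x, ...) {
  n <- nrow(x$nucleosomes)
  cat(sprintf("<fiber_spec> %s: %g bp, %d nucleosomes", x$label, x$length_bp, n))
  if (n > 0) {
    cat(sprintf(" (%d ac, %d BRD4, %d H1)", sum(x$nucleosomes$acetylated),
                sum(x$nucleosomes$brd4), sum(x$nucleosomes$h1)))
  }
  cat("\n")
  invisible(x)
}

#' Expected bead count of a fiber spec
#'
#' Exact arithmetic from the bead-mapping rule: `round(wrap/10.5)` DNA beads
#' plus 8 histone beads (plus 2 H1 beads when bound) per nucleosome, and
#' `round(linker/10.5)` beads per linker segment.
#'
#' @param spec A [fiber_spec()].
#' @return Integer bead count.
#' @export
fiber_bead_count <- function(spec) {
  n <- nrow(spec$nucleosomes)
  nuc_beads <- if (n) sum(.bp_to_beads(spec$nucleosomes$wrap_bp) + 8L +
                            2L * spec$nucleosomes$h1) else 0L
  as.integer(nuc_beads + sum(.bp_to_beads(spec$linker_lengths)))
}

#' Serialize / restore fiber specifications as JSON
#'
#' @param spec A [fiber_spec()] (or list of them for `write_fiber_spec`).
#' @param path File path.
#' @return `read_fiber_spec` returns a `fiber_spec` (or list of them).
#' @export
write_fiber_spec <- function(spec, path) {
  specs <- if (inherits(spec, "fiber_spec")) list(spec) else spec
  out <- lapply(specs, function(s) {
    list(label = s$label, length_bp = s$length_bp,
         nucleosomes = as.data.frame(s$nucleosomes))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiber_spec
#' @export
read_fiber_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(length(raw$label)), function(i) {
    nuc <- raw$nucleosomes[[i]]
    nuc <- if (is.null(nuc) || length(nuc) == 0) {
      nucleosome_record(numeric(0))[0, ]
    } else {
      as_tibble(nuc)
    }
    fiber_spec(raw$label[[i]], raw$length_bp[[i]], nuc)
  })
  if (length(specs) == 1) specs[[1]] else specs
}
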