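#' @importFrom rlang .data
NULL

# per-nucleosome bookkeeping: one row per nucleosome over all fibers, with its
# bead indices, dyad, state
.nucleosome_table <- function(beads) {
  nb <- beads[!is.na(beads$nucleosome) &
                !(beads$role %in% c("H1_GLOB", "H1_TAIL")), ]
  grp <- dplyr::group_by(nb, .data$fiber_id, .data$nucleosome)
  out <- dplyr::summarise(grp, beads = list(.data$bead),
                          state = .data$state[1], dyad = .data$dyad[1],
                          .groups = "drop")
  out <- dplyr::arrange(out, .data$fiber_id, .data$nucleosome)
  out$id <- seq_len(nrow(out))
  out
}

# centroid coordinates of every nucleosome in one frame
nucleosome_centers <- function(frame, nuc_table) {
  t(vapply(nuc_table$beads, function(ix) colMeans(frame[ix, , drop = FALSE]),
           numeric(3)))
}

.frames_matrix <- function(trajectory, frames_idx) {
  n <- nrow(trajectory$beads)
  m <- matrix(0, length(frames_idx), 3 * n)
  for (k in seq_along(frames_idx)) {
    m[k, ] <- t(trajectory$frames[[frames_idx[k]]])
  }
  m
}

#' Nucleosome contact map from a trajectory
#'
#' Two nucleosomes are in contact in a frame when the minimum distance
#' between any of their beads (DNA + histone core) is below `cutoff`
#' (default 1.5 sigma = 52.5 Angstrom). Counts accumulate over frames after
#' the burn-in; the diagonal is defined as the frame count (self-contact).
#'
#' @param trajectory A `chromatin_trajectory`.
#' @param cutoff Contact cutoff, Angstrom.
#' @param burn_in Number of initial frames discarded.
#' @param fibers Restrict to these fiber ids (default: all).
#' @return A `contact_matrix`: list with `counts`, `n_frames`,
#'   `normalization` (`"raw"`), `cutoff` and the `nucleosomes` table.
#' @export
contact_map <- function(trajectory, cutoff = 52.5, burn_in = 0, fibers = NULL) {
  stopifnot(cutoff > 0, burn_in < n_frames(trajectory))
  nt <- .nucleosome_table(trajectory$beads)
  if (!is.null(fibers)) nt <- nt[nt$fiber_id %in% fibers, ]
  nt$id <- seq_len(nrow(nt))
  group <- integer(nrow(trajectory$beads))
  for (k in seq_len(nrow(nt))) group[nt$beads[[k]]] <- nt$id[k]
  idx <- (burn_in + 1):n_frames(trajectory)
  box <- if (trajectory$boundary$type == "slab") {
    as.numeric(trajectory$boundary$box)
  } else {
    c(0, 0, 0)
  }
  fm <- .frames_matrix(trajectory, idx)
  counts <- .cg_contact_counts(fm, group, nrow(nt), cutoff, box)
  diag(counts) <- length(idx)
  structure(list(counts = counts, n_frames = length(idx),
                 normalization = "raw", cutoff = cutoff, nucleosomes = nt),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d nucleosomes, %d frames, %s, cutoff %.1f A\n",
              nrow(x$counts), ncol(x$counts), x$n_frames, x$normalization,
              x$cutoff))
  invisible(x)
}

#' Normalize a contact map
#'
#' `"distance"` produces an observed/expected matrix (each entry divided by
#' the mean contact at its genomic separation, computed within fibers);
#' `"correlation"` additionally replaces the O/E matrix by its column
#' correlation matrix, the standard input for compartment PCA.
#'
#' @param cm A `contact_matrix` (raw).
#' @param mode `"distance"` or `"correlation"`.
#' @return A `contact_matrix` with updated `counts` and `normalization`.
#' @export
normalize_contact_map <- function(cm, mode = c("distance", "correlation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$counts
  nt <- cm$nucleosomes
  n <- nrow(m)
  sep <- abs(outer(nt$nucleosome, nt$nucleosome, "-"))
  same <- outer(nt$fiber_id, nt$fiber_id, "==")
  oe <- m
  for (s in sort(unique(sep[same]))) {
    sel <- same & sep == s
    mu <- mean(m[sel])
    oe[sel] <- if (mu > 0) m[sel] / mu else 0
  }
  oe[!same] <- {
    mu <- mean(m[!same])
    if (isTRUE(mu > 0)) m[!same] / mu else 0
  }
  out <- cm
  if (mode == "distance") {
    out$counts <- oe
    out$normalization <- "distance-normalized"
  } else {
    cc <- suppressWarnings(stats::cor(oe))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    out$counts <- cc
    out$normalization <- "correlation"
  }
  out
}

#' Compartment signal (PC1) of a normalized contact map
#'
#' First principal component of the distance-normalized, correlation-
#' transformed contact map. When an acetylation signal is supplied, the PC1
#' sign is fixed so it correlates positively with acetylation, and the
#' Pearson correlation against the log-normalized acetylation
#' (log of per-bin signal over its mean) is reported.
#'
#' @param cm A `contact_matrix` with `normalization == "correlation"` (a raw
#'   map is normalized automatically).
#' @param acetylation Optional per-nucleosome acetylation signal (or logical
#'   flags).
#' @return List with `pc1`, `explained` (variance fraction), and, when
#'   acetylation is given, `r` and `p_value`.
#' @export
compartment_pc1 <- function(cm, acetylation = NULL) {
  if (cm$normalization == "raw") {
    cm <- normalize_contact_map(cm, "correlation")
  } else if (cm$normalization == "distance-normalized") {
    cc <- suppressWarnings(stats::cor(cm$counts))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    cm$counts <- cc
    cm$normalization <- "correlation"
  }
  pc <- stats::prcomp(cm$counts, center = TRUE, scale. = FALSE)
  pc1 <- pc$rotation[, 1] * sqrt(max(pc$sdev[1], 1e-300))
  explained <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out <- list(pc1 = unname(pc1), explained = explained)
  if (!is.null(acetylation)) {
    a <- as.numeric(acetylation)
    a_log <- log(pmax(a, 1e-3 * max(a, 1e-12)) / mean(pmax(a, 0) + 1e-12))
    if (stats::sd(a_log) > 0) {
      ct <- suppressWarnings(stats::cor.test(out$pc1, a_log))
      if (!is.na(ct$estimate) && ct$estimate < 0) {
        out$pc1 <- -out$pc1
        ct <- suppressWarnings(stats::cor.test(out$pc1, a_log))
      }
      out$r <- unname(ct$estimate)
      out$p_value <- ct$p.value
    }
  }
  out
}

#' Insulation score
#'
#' Diamond-window contact depletion: for each bin, the mean contact count in
#' the `window` x `window` diamond spanning the bin, log2-scaled relative to
#' the genome-wide expected (mean over all bins). Boundaries between
#' self-interacting domains appear as strong negative minima; a uniform
#' matrix scores 0 everywhere.
#'
#' @param cm A `contact_matrix` (raw or O/E).
#' @param window Window half-size in bins (>= 2).
#' @return Tibble with `bin` and `insulation` (NA where the window does not
#'   fit).
#' @export
insulation_score <- function(cm, window = 10) {
  stopifnot(window >= 2)
  m <- cm$counts
  n <- nrow(m)
  v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- (i - window):(i - 1)
    hi <- (i + 1):(i + window)
    if (min(lo) < 1 || max(hi) > n) next
    v[i] <- mean(m[lo, hi])
  }
  expd <- mean(v, na.rm = TRUE)
  tibble(bin = seq_len(n),
         insulation = ifelse(is.na(v), NA, log2(pmax(v, 1e-12) / expd)))
}

#' Compartmentalization coefficient
#'
#' Scalar strength of A/B-style compartment segregation:
#' \deqn{COMP = (S_{AA} + S_{BB} - 2 S_{AB}) / (S_{AA} + S_{BB} + 2 S_{AB})}
#' where the sums run over the off-diagonal entries of the supplied
#' (observed/expected) matrix split by the sign of PC1. 1 means perfect
#' segregation (no AB contacts), 0 none.
#'
#' @param cm A `contact_matrix` (use the distance-normalized form) or a plain
#'   matrix.
#' @param pc1 Per-bin compartment signal; A = `pc1 >= 0`.
#' @return Scalar in `[-1, 1]`.
#' @export
compartmentalization_coefficient <- function(cm, pc1) {
  m <- if (inherits(cm, "contact_matrix")) cm$counts else cm
  stopifnot(length(pc1) == nrow(m))
  A <- pc1 >= 0
  off <- !diag(nrow(m))
  saa <- sum(m[A, A][off[A, A]])
  sbb <- sum(m[!A, !A][off[!A, !A]])
  sab <- sum(m[A, !A])
  (saa + sbb - 2 * sab) / (saa + sbb + 2 * sab)
}
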