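#' Genomic signal track
#'
#' A bedGraph-semantics signal track: non-overlapping, sorted, 0-based
#' half-open intervals with finite non-negative values. Conversions to 1-based
#' kb labels happen only at report boundaries.
#'
#' @param chrom Chromosome name (recycled).
#' @param start,end Interval bounds, 0-based half-open.
#' @param value Signal value, finite and >= 0.
#' @return A tibble of class `genomic_track`.
#' @export
genomic_track <- function(chrom, start, end, value) {
  tr <- tibble(chrom = chrom, start = as.numeric(start),
               end = as.numeric(end), value = as.numeric(value))
  tr <- dplyr::arrange(tr, chrom, start)
  if (any(!is.finite(tr$value)) || any(tr$value < 0)) {
    stop("track values must be finite and non-negative")
  }
  if (any(tr$end <= tr$start)) stop("empty or inverted interval")
  ov <- dplyr::group_by(tr, chrom)
  ov <- dplyr::summarise(ov, bad = any(start[-1] < end[-dplyr::n()] &
                                         dplyr::n() > 1))
  if (any(ov$bad, na.rm = TRUE)) stop("overlapping intervals")
  class(tr) <- c("genomic_track", class(tr))
  tr
}

#' Read / write bedGraph tracks
#'
#' Uses rtracklayer when installed (which also enables bigWig input);
#' otherwise falls back to plain whitespace-delimited reading. Track
#' definition lines are ignored.
#'
#' @param path File path (`.bedGraph`/`.bg`, or `.bw`/`.bigWig` with
#'   rtracklayer).
#' @return A [genomic_track()].
#' @export
read_track <- function(path) {
  is_bw <- grepl("\\.(bw|bigwig)$", tolower(path))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path,
                              format = if (is_bw) "BigWig" else "bedGraph")
    return(genomic_track(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L,
                         GenomicRanges::end(gr),
                         gr$score))
  }
  if (is_bw) stop("bigWig input needs the rtracklayer package")
  ln <- readLines(path)
  ln <- ln[!grepl("^(track|browser|#)", ln)]
  f <- utils::read.table(text = ln, col.names = c("chrom", "start", "end", "value"))
  genomic_track(f$chrom, f$start, f$end, f$value)
}

#' @rdname read_track
#' @param track A [genomic_track()].
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.6g", track$chrom, as.integer(track$start),
                     as.integer(track$end), track$value), path)
  invisible(path)
}

#' Read a BED interval file
#'
#' @param path BED file (3+ columns; optional 4th column is the name).
#' @return Tibble with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^(track|browser|#)", ln) & nzchar(ln)]
  f <- utils::read.table(text = ln, fill = TRUE, stringsAsFactors = FALSE)
  tibble(chrom = f[[1]], start = as.numeric(f[[2]]), end = as.numeric(f[[3]]),
         name = if (ncol(f) >= 4) as.character(f[[4]]) else
           paste0("elem", seq_len(nrow(f))))
}

# mean signal over a window, length-weighted across overlapping intervals
.track_signal <- function(track, lo, hi) {
  vapply(seq_along(lo), function(k) {
    sel <- track$end > lo[k] & track$start < hi[k]
    if (!any(sel)) return(0)
    tt <- track[sel, ]
    w <- pmin(tt$end, hi[k]) - pmax(tt$start, lo[k])
    sum(w * tt$value) / (hi[k] - lo[k])
  }, numeric(1))
}

#' Call nucleosome dyad positions from a chemical-mapping-style track
#'
#' Greedy descending-score peak selection: candidate peaks (interval
#' midpoints) are accepted in order of decreasing score, each accepted dyad
#' suppressing all candidates within `min_spacing`. Scale-invariant by
#' construction: multiplying the track by a positive constant changes no
#' calls.
#'
#' @param track A [genomic_track()] of per-position nucleosome scores.
#' @param locus `c(start, end)` of the region to call (0-based half-open).
#' @param min_spacing Exclusion zone, bp (default one nucleosome footprint).
#' @return Sorted numeric vector of dyad positions (bp).
#' @export
call_nucleosome_positions <- function(track, locus = NULL, min_spacing = 147) {
  if (!is.null(locus)) {
    track <- track[track$start >= locus[1] & track$end <= locus[2], ]
  }
  track <- track[track$value > 0, ]
  if (nrow(track) == 0) {
    warning("empty track: no nucleosomes called")
    return(numeric(0))
  }
  cand <- (track$start + track$end) / 2
  score <- track$value
  ord <- order(-score, cand)
  taken <- numeric(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - cand[i]) >= min_spacing)) {
      taken <- c(taken, cand[i])
    }
  }
  sort(taken)
}

#' Stochastic single-cell state assignment from epigenetic tracks
#'
#' ChIP-seq profiles are population averages; a single simulated fiber is one
#' stochastic realization. Each nucleosome draws its acetylation and H1 flags
#' from Bernoulli probabilities proportional to the local signal (mean over
#' dyad +/- 73 bp), rescaled so the expected fractions match
#' `target_fractions`; BRD4 is then drawn among acetylated nucleosomes only,
#' proportional to the BRD4 signal. Probabilities are capped at 1 after
#' rescaling.
#'
#' @param dyads Dyad positions (bp).
#' @param ac_track,h1_track,brd4_track [genomic_track()]s.
#' @param target_fractions `c(acetylated, h1, brd4_among_acetylated)`.
#' @param seed Integer seed (assignment reproducible from tracks + seed).
#' @param footprint Half-window around the dyad for signal averaging, bp.
#' @return Tibble with per-nucleosome flags and the probabilities used;
#'   attributes `seed`, `target_fractions`.
#' @export
assign_states <- function(dyads, ac_track, h1_track, brd4_track,
                          target_fractions = c(0.20, 0.31, 0.167), seed = 1,
                          footprint = 73) {
  n <- length(dyads)
  sig <- function(track) .track_signal(track, dyads - footprint, dyads + footprint)
  rescale <- function(s, f, who = "signal") {
    if (f <= 0) return(rep(0, length(s)))
    if (all(s == 0)) stop("all-zero ", who, " cannot satisfy target fraction ", f)
    g <- function(lam) mean(pmin(lam * s, 1)) - f
    if (g(1e9) < 0) {
      warning("target fraction ", f, " not reachable for ", who,
              " (signal covers only ", signif(mean(s > 0), 3),
              " of nucleosomes); saturating")
      return(as.numeric(s > 0))
    }
    lam <- stats::uniroot(g, c(0, 1e9), tol = 1e-12)$root
    pmin(lam * s, 1)
  }
  p_ac <- rescale(sig(ac_track), target_fractions[1], "acetylation signal")
  p_h1 <- rescale(sig(h1_track), target_fractions[2], "H1 signal")
  set.seed(seed %% .Machine$integer.max)
  ac <- runif(n) < p_ac
  h1 <- runif(n) < p_h1
  b_sig <- sig(brd4_track)
  brd4 <- rep(FALSE, n)
  p_b <- rep(0, n)
  if (any(ac) && target_fractions[3] > 0) {
    if (all(b_sig[ac] == 0)) {
      if (any(b_sig > 0)) {
        # BRD4 peaks exist but none under acetylated nucleosomes of this draw
        p_b[ac] <- 0
      }
    } else {
      p_b[ac] <- rescale(b_sig[ac], target_fractions[3], "BRD4 signal")
    }
    brd4[ac] <- runif(sum(ac)) < p_b[ac]
  }
  out <- tibble(dyad_position = dyads, acetylated = ac, h1 = h1, brd4 = brd4,
                p_acetylated = p_ac, p_h1 = p_h1, p_brd4 = p_b)
  attr(out, "seed") <- seed
  attr(out, "target_fractions") <- target_fractions
  out
}

#' Build a fiber spec from genomic tracks
#'
#' End-to-end mapping: call dyads from the nucleosome-position track, assign
#' epigenetic states stochastically, and package the result as a
#' [fiber_spec()] in locus-relative coordinates.
#'
#' @param position_track Nucleosome chemical-mapping-style score track.
#' @param ac_track,h1_track,brd4_track Epigenetic signal tracks.
#' @param locus `c(start, end)` genomic interval (0-based half-open).
#' @param label Fiber label.
#' @param target_fractions,seed,min_spacing See [assign_states()] and
#'   [call_nucleosome_positions()].
#' @return A [fiber_spec()].
#' @export
fiber_from_tracks <- function(position_track, ac_track, h1_track, brd4_track,
                              locus, label = "locus",
                              target_fractions = c(0.20, 0.31, 0.167),
                              seed = 1, min_spacing = 147) {
  dyads <- call_nucleosome_positions(position_track, locus, min_spacing)
  # keep full footprints inside the locus
  dyads <- dyads[dyads - 73.5 >= locus[1] & dyads + 73.5 <= locus[2]]
  st <- assign_states(dyads, ac_track, h1_track, brd4_track,
                      target_fractions, seed)
  nuc <- tibble(dyad_position = dyads - locus[1], acetylated = st$acetylated,
                brd4 = st$brd4, h1 = st$h1, wrap_bp = 147)
  fiber_spec(label, locus[2] - locus[1], nuc)
}

#' Generate synthetic epigenomic tracks
#'
#' Stand-in generator emulating the statistical structure of the experimental
#' inputs so the whole pipeline runs without downloads: a nucleosome-position
#' track with peaks at the experimental mean repeat length (195 bp); a peaky
#' acetylation signal organized in alternating high/low blocks at the
#' sub-TAD compartment interval scale (~12.5 kb); a broad H1 signal
#' anti-correlated with acetylation; and narrow BRD4 peaks nested inside
#' acetylation peaks. The realized acetylation block scale (mean run length
#' of the above-median binarized signal) matches `block_scale` by
#' construction.
#'
#' @param locus_length Length of the synthetic locus, bp.
#' @param nrl Mean nucleosome repeat length for the position track, bp.
#' @param block_scale Acetylation block interval scale, bp.
#' @param bin Signal bin width, bp.
#' @param seed Integer seed.
#' @param chrom Chromosome label for the tracks.
#' @return Named list of four [genomic_track()]s: `positions`, `ac`, `h1`,
#'   `brd4`.
#' @export
synth_tracks <- function(locus_length = 50e3, nrl = 195, block_scale = 12.5e3,
                         bin = 100, seed = 1, chrom = "synth") {
  set.seed(seed %% .Machine$integer.max)
  # nucleosome positions: jittered lattice at the target NRL
  dyads <- seq(nrl / 2, locus_length - nrl / 2, by = nrl)
  jit <- pmin(pmax(rnorm(length(dyads), 0, 12), -20), 20)
  dyads <- round(dyads + jit)
  dyads <- dyads[dyads > 75 & dyads < locus_length - 75]
  pos_track <- genomic_track(chrom, dyads - 5, dyads + 5,
                             round(runif(length(dyads), 0.5, 1.5), 4))
  # acetylation blocks
  starts <- seq(0, locus_length, by = bin)
  starts <- starts[starts < locus_length]
  ends <- pmin(starts + bin, locus_length)
  mid <- (starts + ends) / 2
  block_id <- floor(mid / block_scale)
  high <- block_id %% 2 == 1
  ac_val <- ifelse(high, runif(length(mid), 0.7, 1.3),
                   runif(length(mid), 0, 0.08))
  ac_track <- genomic_track(chrom, starts, ends, round(ac_val, 4))
  # H1: broad, anti-correlated with acetylation
  sm <- stats::filter(ac_val, rep(1 / 21, 21), sides = 2)
  sm[is.na(sm)] <- mean(ac_val)
  h1_val <- pmax(0.9 - 0.7 * as.numeric(sm) + rnorm(length(mid), 0, 0.05), 0)
  h1_track <- genomic_track(chrom, starts, ends, round(h1_val, 4))
  # BRD4: narrow peaks nested at the center of acetylated blocks
  b_val <- rep(0, length(mid))
  for (b in unique(block_id[high])) {
    sel <- which(block_id == b & high)
    if (length(sel) < 7) next
    ctr <- sel[ceiling(length(sel) / 2)]
    pk <- ctr + (-12:12)
    pk <- pk[pk >= 1 & pk <= length(mid)]
    b_val[pk] <- round(ac_val[pk] * runif(length(pk), 0.8, 1.2), 4)
  }
  keep <- b_val > 0
  brd4_track <- if (any(keep)) {
    genomic_track(chrom, starts[keep], ends[keep], b_val[keep])
  } else {
    genomic_track(character(0), numeric(0), numeric(0), numeric(0))
  }
  list(positions = pos_track, ac = ac_track, h1 = h1_track, brd4 = brd4_track)
}

#' Acetylation block scale of a track
#'
#' Mean run length (in bp) of the above-median binarized signal, the
#' estimator paired with the block structure of [synth_tracks()].
#'
#' @param track A [genomic_track()].
#' @return Scale in bp.
#' @export
track_block_scale <- function(track) {
  v <- track$value > stats::median(track$value)
  r <- rle(v)
  w <- track$end - track$start
  mean(r$lengths) * stats::median(w)
}
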