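#' Weighted-histogram (WHAM) reconstruction of a potential of mean force
#'
#' Standard self-consistent WHAM over umbrella windows with harmonic biases
#' \eqn{u_k(r) = k_k (r - c_k)^2}. For a distance collective variable between
#' two free bodies the entropic Jacobian \eqn{2 k_B T \ln r} is removed so an
#' ideal (non-interacting) pair gives a flat profile; the PMF is zeroed on
#' the unbound plateau (outermost 15 percent of the sampled range) and the
#' well depth reported as plateau minus minimum. Free energies are
#' gauge-invariant: adding a constant to any window's bias changes nothing
#' after zeroing.
#'
#' @param umbrella An `umbrella_set` from [run_umbrella()], or a data frame
#'   with columns `window`, `center`, `k`, `r`.
#' @param n_bins Histogram bins over the sampled range.
#' @param tol Self-consistency tolerance on the window free energies
#'   (kcal/mol).
#' @param max_iter Iteration cap.
#' @param temperature Kelvin (taken from the umbrella set when available).
#' @param jacobian Remove the 2 kBT ln r term (set `FALSE` for collective
#'   variables that are not a free pair distance).
#' @return Object of class `wham_pmf`: `profile` tibble (`r`, `pmf_kbt`),
#'   `well_depth_kbt`, `f_window` (window free energies), `converged`,
#'   `iterations`.
#' @export
wham_pmf <- function(umbrella, n_bins = 60, tol = 1e-6, max_iter = 10000,
                     temperature = NULL, jacobian = TRUE) {
  samples <- if (inherits(umbrella, "umbrella_set")) umbrella$samples else
    as_tibble(umbrella)
  if (is.null(temperature)) {
    temperature <- if (inherits(umbrella, "umbrella_set")) {
      umbrella$temperature
    } else {
      300
    }
  }
  kT <- kBT(temperature)
  wins <- dplyr::distinct(samples[, c("window", "center", "k")])
  nw <- nrow(wins)
  lo <- min(samples$r); hi <- max(samples$r)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  H <- matrix(0, nw, n_bins)
  N <- numeric(nw)
  for (w in seq_len(nw)) {
    r <- samples$r[samples$window == wins$window[w]]
    cut_ix <- pmin(pmax(findInterval(r, edges, all.inside = TRUE), 1), n_bins)
    H[w, ] <- tabulate(cut_ix, n_bins)
    N[w] <- length(r)
  }
  # bias energy of window w at bin b
  U <- outer(seq_len(nw), seq_len(n_bins),
             function(w, b) wins$k[w] * (mids[b] - wins$center[w])^2)
  f <- numeric(nw)
  nb_tot <- colSums(H)
  for (it in seq_len(max_iter)) {
    denom <- vapply(seq_len(n_bins), function(b) {
      sum(N * exp((f - U[, b]) / kT))
    }, numeric(1))
    p <- ifelse(denom > 0, nb_tot / denom, 0)
    fnew <- vapply(seq_len(nw), function(w) {
      -kT * log(sum(p * exp(-U[w, ] / kT)))
    }, numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  converged <- delta < tol
  denom <- vapply(seq_len(n_bins), function(b) {
    sum(N * exp((f - U[, b]) / kT))
  }, numeric(1))
  p <- ifelse(denom > 0, nb_tot / denom, NA_real_)
  pmf <- -log(p)                       # in kBT
  if (jacobian) pmf <- pmf + 2 * log(mids)
  ok <- is.finite(pmf)
  plateau_sel <- ok & mids >= lo + 0.85 * (hi - lo)
  plateau <- mean(pmf[plateau_sel])
  pmf <- pmf - plateau
  depth <- -min(pmf[ok])
  structure(list(
    profile = tibble(r = mids, pmf_kbt = pmf),
    well_depth_kbt = depth, f_window = f, converged = converged,
    iterations = it, temperature = temperature), class = "wham_pmf")
}

#' @export
print.wham_pmf <- function(x, ...) {
  cat(sprintf("<wham_pmf> well depth %.2f kBT (%s after %d iterations)\n",
              x$well_depth_kbt,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
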