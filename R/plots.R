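#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_point geom_hline
#'   scale_fill_viridis_c labs theme_minimal autoplot scale_x_log10
#'   scale_y_log10 facet_wrap geom_tile
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Plot a contact map
#'
#' @param cm A `contact_matrix`.
#' @param log_scale Log10-scale the fill (raw counts).
#' @return A ggplot.
#' @export
plot_contact_map <- function(cm, log_scale = cm$normalization == "raw") {
  m <- cm$counts
  df <- tibble(
    i = rep(seq_len(nrow(m)), times = ncol(m)),
    j = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  if (log_scale) df$value <- log10(df$value + 1)
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = if (log_scale) "log10(1+n)" else
      cm$normalization) +
    labs(x = "nucleosome", y = "nucleosome",
         title = sprintf("Contact map (%s, %d frames)", cm$normalization,
                         cm$n_frames)) +
    theme_minimal()
}

#' @export
autoplot.contact_matrix <- function(object, ...) plot_contact_map(object, ...)

#' @export
autoplot.wham_pmf <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$r / 10, y = .data$pmf_kbt)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "separation (nm)", y = "PMF (kBT)",
         title = sprintf("Well depth %.2f kBT", object$well_depth_kbt)) +
    theme_minimal()
}

#' @export
autoplot.msd_fit <- function(object, ...) {
  ggplot(object$msd, aes(x = .data$lag_ns, y = .data$msd_nm2)) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "lag (ns)", y = expression(MSD ~ (nm^2)),
         title = sprintf("alpha = %.2f", object$alpha)) +
    theme_minimal()
}

#' Plot the domain timeline of a partition sequence
#'
#' Frame-by-nucleosome raster colored by domain id, the standard visual for
#' domain splitting/merging dynamics.
#'
#' @param partitions List of `domain_partition`s.
#' @param fiber_id Restrict to one fiber (`NULL` keeps all).
#' @return A ggplot.
#' @export
plot_domain_timeline <- function(partitions, fiber_id = 1) {
  df <- dplyr::bind_rows(lapply(seq_along(partitions), function(t) {
    p <- partitions[[t]]
    if (!is.null(fiber_id)) p <- p[p$fiber_id == fiber_id, ]
    tibble(frame = t, nucleosome = p$nucleosome,
           domain = factor(p$domain))
  }))
  ggplot(df, aes(x = .data$frame, y = .data$nucleosome,
                 fill = .data$domain)) +
    geom_tile(show.legend = FALSE) +
    labs(x = "frame", y = "nucleosome") +
    theme_minimal()
}

# --- broom-style methods -----------------------------------------------------

#' @export
tidy.msd_fit <- function(x, ...) x$msd

#' @export
glance.msd_fit <- function(x, ...) {
  tibble(alpha = x$alpha, K_alpha = x$K_alpha, r_squared = x$r_squared)
}

#' @export
tidy.wham_pmf <- function(x, ...) x$profile

#' @export
glance.wham_pmf <- function(x, ...) {
  tibble(well_depth_kbt = x$well_depth_kbt, converged = x$converged,
         iterations = x$iterations, temperature = x$temperature)
}

#' @export
tidy.structure_clusters <- function(x, ...) {
  tibble(frame = seq_along(x$cluster), cluster = x$cluster)
}

#' @export
glance.structure_clusters <- function(x, ...) {
  tibble(k = x$k, n = length(x$cluster),
         tot_withinss = if (is.null(x$fit)) 0 else x$fit$tot.withinss)
}
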