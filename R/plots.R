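# ggplot2 visualizations: mirror plots of spectrum matches, exposure
# heatmaps, mass-offset frequency bars, and cluster summaries.

#' Mirror plot of two MS/MS spectra
#'
#' Draws the query spectrum upward and the target spectrum downward,
#' coloring matched peaks (direct and precursor-shifted) from the modified
#' cosine pairing.
#'
#' @param a,b Spectra (one-row spectra tibbles or lists).
#' @param frag_tol Fragment tolerance used for pairing, Da.
#' @return A ggplot object.
#' @export
plot_spectrum_mirror <- function(a, b, frag_tol = 0.02) {
  sa <- .as_spec(a); sb <- .as_spec(b)
  shift <- sb$precursor_mz - sa$precursor_mz
  el <- .eligible_pairs(sa$peaks, sb$peaks, shift, frag_tol, "sqrt")
  kept <- if (is.null(el$pairs)) NULL else .greedy_assign(el$pairs)
  lab <- function(pk, idx_col) {
    status <- rep("unmatched", nrow(pk))
    if (!is.null(kept) && nrow(kept)) {
      status[kept[[idx_col]][!kept$shifted]] <- "matched"
      status[kept[[idx_col]][kept$shifted]] <- "shifted"
    }
    status
  }
  df <- dplyr::bind_rows(
    tibble::tibble(mz = sa$peaks$mz,
                   intensity = sa$peaks$intensity / max(sa$peaks$intensity),
                   which = "query", status = lab(sa$peaks, "i")),
    tibble::tibble(mz = sb$peaks$mz,
                   intensity = -sb$peaks$intensity / max(sb$peaks$intensity),
                   which = "target", status = lab(sb$peaks, "j")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity,
                                   color = .data$status)) +
    ggplot2::geom_segment(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(matched = "#1b7837",
                                           shifted = "#762a83",
                                           unmatched = "grey60")) +
    ggplot2::labs(x = "m/z", y = "relative intensity",
                  title = sprintf("mass offset %+0.4f Da", shift)) +
    ggplot2::theme_minimal()
}

#' Heatmap of an exposure table
#'
#' Samples by parent drugs, shaded by log(1 + summed area); undetected
#' cells are blank.
#'
#' @param object An `exposure_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exposure_table
#' @export
autoplot.exposure_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$log_area <- log1p(df$summed_area)
  ggplot2::ggplot(df[df$detected, ],
                  ggplot2::aes(x = .data$sample_id, y = .data$parent_drug,
                               fill = .data$log_area)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log(1 + area)") +
    ggplot2::labs(x = "sample", y = "parent drug") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Frequency of mass offsets among analog matches
#'
#' Bars of analog counts per unit-mass offset bin, split into gains and
#' losses and colored by the matched offset category.
#'
#' @param matches Analog match tibble with `mass_offset`.
#' @param offsets Mass-offset table for category labels.
#' @param tol Matching tolerance, Da.
#' @return A ggplot object.
#' @export
plot_mass_offset_frequency <- function(matches,
                                       offsets = default_mass_offsets(),
                                       tol = 0.01) {
  df <- tibble::as_tibble(matches)
  df$category <- vapply(df$mass_offset, function(d) {
    i <- which(abs(d - offsets$delta_mass) <= tol)
    if (length(i)) offsets$category[i[1]] else "unexplained"
  }, character(1))
  df$unit_offset <- round(df$mass_offset)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$unit_offset),
                                   fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "mass offset (unit mass, Da)", y = "analog spectra") +
    ggplot2::theme_minimal()
}

#' Cluster sizes of an exposure stratification
#'
#' @param object A `cluster_assignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_assignment
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "exposure cluster", y = "samples",
                  title = sprintf("%s linkage, %s distance",
                                  attr(object, "method"),
                                  attr(object, "metric"))) +
    ggplot2::theme_minimal()
}
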