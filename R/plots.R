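#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage track
#'
#' Per-base depth along the reference, the standard view in which
#' amplification bias shows up as isolated spikes over a near-empty
#' baseline while unamplified libraries give an even band.
#'
#' @param object A [coverage_track()].
#' @param bin Bin width in bp for display (mean depth per bin).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_track <- function(object, bin = 100, ...) {
  d <- object$depth
  n_bins <- ceiling(length(d) / bin)
  idx <- rep(seq_len(n_bins), each = bin, length.out = length(d))
  df <- tibble::tibble(position = (seq_len(n_bins) - 0.5) * bin,
                       depth = as.numeric(tapply(d, idx, mean)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::labs(x = sprintf("position on %s (bp)", object$ref_id),
                  y = sprintf("mean depth / %d bp", bin)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted qPCR standard curve
#'
#' @param object A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_molecules,
                                   y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "log10 molecules", y = "Cq",
                  subtitle = sprintf("efficiency %.2f, r-squared %.4f",
                                     object$efficiency, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot correspondence-analysis coordinates
#'
#' Row (profile) principal coordinates on the first two dimensions.
#'
#' @param object A [correspondence_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_result <- function(object, ...) {
  df <- object$row_coords
  ydim <- if (object$dims >= 2) "dim2" else "dim1"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data[[ydim]],
                                   label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("dim 1 (inertia %.3g)", object$inertias[1]),
                  y = if (object$dims >= 2) {
                    sprintf("dim 2 (inertia %.3g)", object$inertias[2])
                  } else "dim 1") +
    ggplot2::theme_minimal()
}

#' Plot a cluster-count stringency sweep
#'
#' Cluster count against identity threshold, per method; amplified read
#' sets collapse steeply as the threshold is relaxed.
#'
#' @param curve A [cluster_curve()] tibble, optionally with a `method`
#'   column.
#' @return A ggplot object.
#' @export
plot_cluster_curve <- function(curve) {
  aes <- if ("method" %in% names(curve)) {
    ggplot2::aes(x = .data$threshold, y = .data$n_clusters,
                 colour = .data$method)
  } else {
    ggplot2::aes(x = .data$threshold, y = .data$n_clusters)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "identity threshold", y = "clusters") +
    ggplot2::theme_minimal()
}

#' Plot the subsampled coverage-comparison p-values
#'
#' @param object A [subsample_compare()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subsample_comparison <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0, fill = "grey35") +
    ggplot2::geom_vline(xintercept = attr(object, "median_p"),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "per-replicate CvM p-value", y = "replicates") +
    ggplot2::theme_minimal()
}
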