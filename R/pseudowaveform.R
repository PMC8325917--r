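# Lidar pseudo-waveforms: per-crown vertical profiles built by binning
# discrete-return point heights. Height anomalies (below-ground returns from
# timing errors, spuriously high returns e.g. bird strikes) are removed
# per point-cloud file by a percentile filter before crowns are clipped.

#' Filter height anomalies from a point cloud
#'
#' Keeps points whose height lies within `[P_lower, P_upper]` (inclusive),
#' the percentiles being computed over the whole input cloud with linear
#' interpolation between order statistics.
#'
#' @param points data.frame with columns `x`, `y`, `h`.
#' @param lower_percentile,upper_percentile percentile bounds in
#'   `[0, 100]`, defaults 1 and 99.
#' @return The filtered data.frame.
#' @export
filter_height_anomalies <- function(points, lower_percentile = 1,
                                    upper_percentile = 99) {
  assert_that(nrow(points) > 0, "point cloud is empty")
  assert_that(lower_percentile >= 0 && upper_percentile <= 100 &&
                lower_percentile < upper_percentile,
              "percentile bounds must satisfy 0 <= lower < upper <= 100")
  q <- stats::quantile(points$h, c(lower_percentile, upper_percentile) / 100,
                       type = 7, names = FALSE)
  points[points$h >= q[1] & points$h <= q[2], , drop = FALSE]
}

#' Compute a crown's pseudo-waveform
#'
#' Points are clipped to the crown footprint (half-open `[lo, hi)` in x and
#' y, matching the raster cell convention) and each point is assigned to
#' exactly one of `n_bins` equal-width height bins spanning
#' `[0, max_height]`; bin edges are half-open with the final bin closed.
#' Heights above `max_height` are clamped into the top bin and heights below
#' zero into the bottom bin (with a message), so no clipped point is lost.
#' Empty bins have proportion zero, and a crown containing no points yields
#' the all-zero waveform.
#'
#' @param points data.frame with columns `x`, `y`, `h` (already
#'   anomaly-filtered).
#' @param polygon crown bounding box; `NULL` skips spatial clipping.
#' @param n_bins number of height bins (default 39).
#' @param max_height top of the binned range in meters (default 40);
#'   bin width is `max_height / n_bins`.
#' @return A `pseudo_waveform`: list with `proportions` (length `n_bins`),
#'   `total_points`, and `bin_edges` (length `n_bins + 1`).
#' @export
compute_pseudowaveform <- function(points, polygon = NULL, n_bins = 39L,
                                   max_height = 40) {
  assert_that(n_bins >= 1, "n_bins must be at least 1")
  assert_that(max_height > 0, "max_height must be positive")
  if (!is.null(polygon)) {
    bb <- as_bbox(polygon)
    keep <- points$x >= bb[["xmin"]] & points$x < bb[["xmax"]] &
      points$y >= bb[["ymin"]] & points$y < bb[["ymax"]]
    points <- points[keep, , drop = FALSE]
  }
  edges <- seq(0, max_height, length.out = n_bins + 1)
  n <- nrow(points)
  if (n == 0L) {
    return(structure(list(proportions = rep(0, n_bins), total_points = 0L,
                          bin_edges = edges), class = "pseudo_waveform"))
  }
  h <- points$h
  n_out <- sum(h > max_height) + sum(h < 0)
  if (n_out > 0) {
    message(sprintf("%d point(s) outside [0, %g] m clamped into the edge bins",
                    n_out, max_height))
  }
  idx <- findInterval(h, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(proportions = counts / n, total_points = n, bin_edges = edges),
            class = "pseudo_waveform")
}

#' @export
print.pseudo_waveform <- function(x, ...) {
  cat(sprintf("pseudo_waveform: %d bins over [%g, %g] m, %d points\n",
              length(x$proportions), min(x$bin_edges), max(x$bin_edges),
              x$total_points))
  invisible(x)
}

#' Flatten a pseudo-waveform into the lidar feature block
#'
#' The per-bin proportions followed by the total point count, giving
#' `n_bins + 1` features (40 under the default configuration).
#'
#' @param waveform a `pseudo_waveform`.
#' @return numeric vector of length `n_bins + 1`.
#' @export
waveform_features <- function(waveform) {
  c(waveform$proportions, waveform$total_points)
}
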