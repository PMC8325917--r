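#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois quantile sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Normalize any accepted polygon representation to a bounding box
# c(xmin, ymin, xmax, ymax). Accepts a length-4 numeric (already a bbox),
# a two-column coordinate matrix, or a list with $xmin etc. Non-rectangular
# coordinate rings are replaced by their bounding box with a warning.
as_bbox <- function(polygon) {
  if (is.numeric(polygon) && length(polygon) == 4L && is.null(dim(polygon))) {
    bb <- as.numeric(polygon)
  } else if (is.matrix(polygon) && ncol(polygon) == 2L) {
    xs <- polygon[, 1]; ys <- polygon[, 2]
    ux <- sort(unique(xs)); uy <- sort(unique(ys))
    if (length(ux) > 2L || length(uy) > 2L) {
      warning("non-rectangular polygon replaced by its bounding box")
    }
    bb <- c(min(xs), min(ys), max(xs), max(ys))
  } else if (is.list(polygon) && all(c("xmin", "ymin", "xmax", "ymax") %in% names(polygon))) {
    bb <- c(polygon$xmin, polygon$ymin, polygon$xmax, polygon$ymax)
  } else {
    stop("unsupported polygon representation")
  }
  if (bb[3] <= bb[1] || bb[4] <= bb[2]) stop("polygon has non-positive area")
  names(bb) <- c("xmin", "ymin", "xmax", "ymax")
  bb
}

bbox_centroid <- function(bbox) {
  c(x = (bbox[["xmin"]] + bbox[["xmax"]]) / 2,
    y = (bbox[["ymin"]] + bbox[["ymax"]]) / 2)
}

# stopifnot with a custom message
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
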