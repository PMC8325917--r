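# Geospatial containers and readers/writers.
#
# Rasters are kept in memory as a `raster_tile`: a [rows, cols, channels]
# array plus the map coordinates of the north-west corner and a square cell
# size in meters. Indexing is row-major from the north-west corner and cell
# membership uses half-open intervals [lo, hi) along both axes (measuring the
# y axis as distance south of the tile's top edge), matching the convention
# of common geospatial raster readers.

#' Construct a raster tile
#'
#' @param values numeric array `[rows, cols, channels]` (a matrix is promoted
#'   to a single-channel array).
#' @param origin map coordinates `c(x, y)` of the north-west corner.
#' @param res cell size in meters (square cells).
#' @return A `raster_tile` object.
#' @export
raster_tile <- function(values, origin = c(0, dim(values)[1] * res), res = 1) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  assert_that(length(dim(values)) == 3L, "values must be a [rows, cols, channels] array")
  assert_that(res > 0, "resolution must be positive")
  assert_that(all(dim(values)[1:2] >= 1L), "grid must be nonempty")
  structure(list(values = values, origin = as.numeric(origin), res = res),
            class = "raster_tile")
}

#' @export
print.raster_tile <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_tile: %d x %d cells, %d channel(s), %.3g m cells, NW corner (%.6g, %.6g)\n",
              d[1], d[2], d[3], x$res, x$origin[1], x$origin[2]))
  invisible(x)
}

tile_extent <- function(tile) {
  d <- dim(tile$values)
  c(xmin = tile$origin[1], ymin = tile$origin[2] - d[1] * tile$res,
    xmax = tile$origin[1] + d[2] * tile$res, ymax = tile$origin[2])
}

#' Clip a raster tile to a crown bounding box
#'
#' Returns the sub-grid covering exactly the cells whose centers fall inside
#' the polygon's bounding box, under the half-open `[lo, hi)` convention on
#' both axes.
#'
#' @param tile a [raster_tile()].
#' @param polygon a bounding box `c(xmin, ymin, xmax, ymax)` or coordinate
#'   matrix (non-rectangular rings collapse to their bounding box).
#' @return A `raster_tile` covering the clipped cells, origin adjusted.
#' @export
clip_raster <- function(tile, polygon) {
  bb <- as_bbox(polygon)
  d <- dim(tile$values)
  ext <- tile_extent(tile)
  cx <- ext[["xmin"]] + (seq_len(d[2]) - 0.5) * tile$res
  # distance of each row center south of the top edge
  dy <- (seq_len(d[1]) - 0.5) * tile$res
  d_lo <- ext[["ymax"]] - bb[["ymax"]]
  d_hi <- ext[["ymax"]] - bb[["ymin"]]
  cols <- which(cx >= bb[["xmin"]] & cx < bb[["xmax"]])
  rows <- which(dy >= d_lo & dy < d_hi)
  if (!length(rows) || !length(cols)) {
    stop("polygon does not cover any cell center of the tile")
  }
  raster_tile(tile$values[rows, cols, , drop = FALSE],
              origin = c(ext[["xmin"]] + (min(cols) - 1) * tile$res,
                         ext[["ymax"]] - (min(rows) - 1) * tile$res),
              res = tile$res)
}

#' Locate the cell containing a polygon's centroid
#'
#' Under the half-open convention a centroid lying exactly on a cell edge
#' belongs to the cell with the larger index along that axis. Indices are
#' 1-based, row 1 at the northern edge.
#'
#' @inheritParams clip_raster
#' @return Integer vector `c(row, col)`.
#' @export
centroid_pixel <- function(tile, polygon) {
  bb <- as_bbox(polygon)
  ctr <- bbox_centroid(bb)
  ext <- tile_extent(tile)
  d <- dim(tile$values)
  if (ctr[["x"]] < ext[["xmin"]] || ctr[["x"]] >= ext[["xmax"]] ||
      ctr[["y"]] <= ext[["ymin"]] || ctr[["y"]] > ext[["ymax"]]) {
    stop("polygon centroid lies outside the tile extent")
  }
  col <- floor((ctr[["x"]] - ext[["xmin"]]) / tile$res) + 1L
  row <- floor((ext[["ymax"]] - ctr[["y"]]) / tile$res) + 1L
  c(row = as.integer(min(row, d[1])), col = as.integer(min(col, d[2])))
}

## ---- raster file I/O ------------------------------------------------------

#' Write a raster tile to disk
#'
#' Tiles with up to 4 channels are written as TIFF; wider stacks (e.g. the
#' 426-band reflectance cube) as CSV with one row per cell in row-major
#' order. Either way a JSON sidecar `<path>.json` records the georeferencing
#' (origin, resolution, dimensions) and any extra metadata such as band
#' wavelengths.
#'
#' @param tile a [raster_tile()].
#' @param path output path (`.tif` or `.csv`).
#' @param metadata named list merged into the sidecar.
#' @export
write_raster_tile <- function(tile, path, metadata = list()) {
  d <- dim(tile$values)
  side <- c(list(origin = tile$origin, res = tile$res, dim = d), metadata)
  if (grepl("\\.tiff?$", path)) {
    assert_that(d[3] <= 4L, "TIFF output supports at most 4 channels; use .csv")
    tiff::writeTIFF(clamp(tile$values), path, bits.per.sample = 16L)
  } else {
    flat <- matrix(aperm(tile$values, c(3, 2, 1)), nrow = d[1] * d[2],
                   ncol = d[3], byrow = TRUE)
    utils::write.table(flat, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster tile written by [write_raster_tile()]
#' @param path path to the `.tif` or `.csv` payload.
#' @return A `raster_tile`; sidecar metadata is attached as attribute `"metadata"`.
#' @export
read_raster_tile <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dim)
  if (grepl("\\.tiff?$", path)) {
    vals <- tiff::readTIFF(path)
    if (is.matrix(vals)) vals <- array(vals, c(dim(vals), 1L))
  } else {
    flat <- as.matrix(utils::read.table(path, sep = ","))
    vals <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  }
  tile <- raster_tile(vals, origin = as.numeric(side$origin), res = side$res)
  attr(tile, "metadata") <- side[setdiff(names(side), c("origin", "res", "dim"))]
  tile
}

## ---- point clouds ---------------------------------------------------------

#' Read/write point clouds as whitespace-delimited XYZ text
#'
#' Columns are x, y, height-above-ground in meters.
#' @param path file path.
#' @return `read_xyz`: data.frame with columns `x`, `y`, `h`.
#' @export
read_xyz <- function(path) {
  pts <- utils::read.table(path, col.names = c("x", "y", "h"))
  assert_that(all(is.finite(pts$h)), "point heights must be finite")
  pts
}

#' @rdname read_xyz
#' @param points data.frame with columns `x`, `y`, `h`.
#' @export
write_xyz <- function(points, path) {
  utils::write.table(format(points[, c("x", "y", "h")], digits = 15, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- crown polygons and field data ---------------------------------------

#' Write crown bounding boxes as GeoJSON
#'
#' One Polygon feature per crown with `individual_id` (and any other supplied
#' columns) as properties.
#'
#' @param crowns data.frame with columns `individual_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (plus optional extras kept as properties).
#' @param path output `.geojson` path.
#' @export
write_crowns_geojson <- function(crowns, path) {
  prop_cols <- setdiff(names(crowns), c("xmin", "ymin", "xmax", "ymax"))
  feats <- lapply(seq_len(nrow(crowns)), function(i) {
    r <- crowns[i, ]
    ring <- list(
      c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
      c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = as.list(r[prop_cols]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_crowns_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  assert_that(identical(gj$type, "FeatureCollection"), "not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    bb <- as_bbox(xy)
    cbind(as.data.frame(f$properties, stringsAsFactors = FALSE),
          data.frame(xmin = bb[["xmin"]], ymin = bb[["ymin"]],
                     xmax = bb[["xmax"]], ymax = bb[["ymax"]]))
  })
  if (!length(rows)) {
    return(data.frame(individual_id = character(), xmin = numeric(),
                      ymin = numeric(), xmax = numeric(), ymax = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Load crown records: polygons joined to field data
#'
#' Reads crown bounding-box polygons (GeoJSON) and joins each feature to its
#' row in the tabular field data by `individual_id`. Polygons with no field
#' match are retained with an absent (`NA`) taxon code and a warning, so that
#' unlabeled evaluation sets pass through.
#'
#' @param vector_path GeoJSON file of crown polygons with an `individual_id`
#'   property.
#' @param field_table_path CSV with columns `individual_id`, `taxon_code`,
#'   `site_id`, `plot_id` (`taxon_code` may be missing for withheld labels).
#' @return data.frame of crown records: `individual_id`, `taxon_code`,
#'   `site_id`, `plot_id`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
load_crowns <- function(vector_path, field_table_path) {
  polys <- read_crowns_geojson(vector_path)
  if (!nrow(polys)) return(empty_crown_records())
  assert_that("individual_id" %in% names(polys),
              "crown polygons lack an individual_id property")
  field <- utils::read.csv(field_table_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  assert_that("individual_id" %in% names(field),
              "field table lacks the individual_id join key")
  for (col in c("taxon_code", "site_id", "plot_id")) {
    if (!col %in% names(field)) field[[col]] <- NA_character_
  }
  idx <- match(polys$individual_id, field$individual_id)
  if (anyNA(idx)) {
    warning(sprintf("%d crown polygon(s) had no field-data match; retained with NA taxon",
                    sum(is.na(idx))))
  }
  out <- data.frame(
    individual_id = polys$individual_id,
    taxon_code = field$taxon_code[idx],
    site_id = field$site_id[idx],
    plot_id = field$plot_id[idx],
    polys[, c("xmin", "ymin", "xmax", "ymax")],
    stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(out$individual_id),
              "individual_id values must be unique within a collection")
  assert_that(all(out$xmax > out$xmin & out$ymax > out$ymin),
              "all crown polygons must have positive area")
  rownames(out) <- NULL
  out
}

empty_crown_records <- function() {
  data.frame(individual_id = character(), taxon_code = character(),
             site_id = character(), plot_id = character(),
             xmin = numeric(), ymin = numeric(),
             xmax = numeric(), ymax = numeric(), stringsAsFactors = FALSE)
}

#' Partition individuals into training and holdout sets
#'
#' Each individual lands in exactly one partition; `|train| = round(fraction * n)`.
#'
#' @param records data.frame of crown records (or anything with rows).
#' @param fraction training fraction in (0, 1); 0.75 reproduces a 75/25
#'   crown-level split, 0.8 an 80/20 split.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train` and `holdout`.
#' @export
split_individuals <- function(records, fraction, seed = 1L) {
  assert_that(fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  n <- nrow(records)
  n_train <- round(fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       holdout = records[setdiff(seq_len(n), idx), , drop = FALSE])
}
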