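# Synthetic multi-sensor plot generator. Emulates the structure of NEON-style
# airborne products over 20 m x 20 m forest plots: 10 cm RGB orthoimagery,
# a 1 m 426-band reflectance cube, and a discrete-return point cloud at
# ~3.15 points/m^2, with rectangular crown bounding boxes whose color,
# spectrum and vertical point-height profile depend on a known taxon
# archetype. Class abundances follow a geometric decay by default so one
# taxon dominates, mirroring the strong class imbalance of real crown
# censuses. Every stage downstream of data ingest is testable against the
# generator's known ground truth.

#' Scene configuration
#'
#' @param plot_side plot side length in meters (default 20).
#' @param rgb_resolution RGB cell size in meters (default 0.10).
#' @param hs_resolution hyperspectral cell size in meters (default 1.0).
#' @param n_bands number of spectral bands (default 426).
#' @param point_density lidar returns per square meter (default 3.15).
#' @param n_taxa number of taxon archetypes (default 31).
#' @param class_weights relative abundance per taxon; default geometric decay
#'   `decay^(k-1)` with `decay = 0.72`, giving one dominant class.
#' @param decay geometric decay ratio used when `class_weights` is `NULL`.
#' @param crowns_per_plot integer range `c(min, max)` of crowns attempted per
#'   plot.
#' @param rgb_noise_sd,hs_noise_sd additive Gaussian noise on crown colors
#'   and spectra (set both to 0 for exactly recoverable labels).
#' @param hs_scale integer scale factor applied when storing reflectance
#'   (NEON-style convention, default 10000).
#' @param anomaly_low,anomaly_high below-ground / above-canopy anomalous
#'   points injected per plot.
#' @param seed integer seed.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(plot_side = 20, rgb_resolution = 0.10,
                         hs_resolution = 1.0, n_bands = 426L,
                         point_density = 3.15, n_taxa = 31L,
                         class_weights = NULL, decay = 0.72,
                         crowns_per_plot = c(4L, 8L),
                         rgb_noise_sd = 0.02, hs_noise_sd = 0.01,
                         hs_scale = 10000, anomaly_low = 2L, anomaly_high = 1L,
                         seed = 1L) {
  assert_that(point_density > 0, "point_density must be positive")
  for (res in c(rgb_resolution, hs_resolution)) {
    k <- plot_side / res
    assert_that(abs(k - round(k)) < 1e-9,
                "resolutions must divide plot_side evenly")
  }
  if (is.null(class_weights)) class_weights <- decay^(seq_len(n_taxa) - 1)
  assert_that(length(class_weights) == n_taxa,
              "class_weights must have one entry per taxon")
  assert_that(all(class_weights >= 0) && sum(class_weights) > 0,
              "class_weights must be nonnegative and not all zero")
  structure(list(plot_side = plot_side, rgb_resolution = rgb_resolution,
                 hs_resolution = hs_resolution, n_bands = as.integer(n_bands),
                 point_density = point_density, n_taxa = as.integer(n_taxa),
                 class_weights = class_weights / sum(class_weights),
                 crowns_per_plot = as.integer(crowns_per_plot),
                 rgb_noise_sd = rgb_noise_sd, hs_noise_sd = hs_noise_sd,
                 hs_scale = hs_scale, anomaly_low = as.integer(anomaly_low),
                 anomaly_high = as.integer(anomaly_high),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Smooth vegetation-like baseline reflectance over a wavelength grid:
# low visible reflectance with a green bump, a red-edge rise to a NIR
# plateau, and decay into the shortwave infrared.
baseline_spectrum <- function(wl) {
  vis <- 0.05 + 0.04 * exp(-((wl - 550) / 40)^2)
  red_edge <- 0.45 / (1 + exp(-(wl - 715) / 15))
  swir <- -0.25 / (1 + exp(-(wl - 1350) / 200))
  clamp(vis + red_edge + swir, 0.01, 0.95)
}

#' Generate taxon archetypes
#'
#' Each archetype carries a distinct 426-band mean reflectance spectrum
#' (quantized to 1e-4 so stored integer reflectance round-trips exactly), a
#' distinct crown color, a crown side-length range and a vertical
#' point-height profile. Archetypes are resampled until every pair differs
#' by more than `separation` in at least one band, in color and in height
#' profile; generation is deterministic given the seed.
#'
#' @param n_taxa number of archetypes (at least 2).
#' @param seed integer seed.
#' @param n_bands number of spectral bands.
#' @param separation minimum pairwise max-absolute spectral difference.
#' @return list of `taxon_archetype` objects with fields `taxon_code`,
#'   `mean_spectrum`, `crown_color`, `crown_size_range`, `height_profile`.
#' @export
make_archetypes <- function(n_taxa, seed = 1L, n_bands = 426L,
                            separation = 0.05) {
  assert_that(n_taxa >= 2, "at least 2 taxa are required")
  wl <- build_wavelength_grid(n_bands)
  base <- baseline_spectrum(wl)
  withr::with_seed(seed, {
    draw_spectrum <- function() {
      # smooth taxon perturbation: a few random Gaussian bumps
      pert <- rep(0, n_bands)
      for (j in seq_len(6)) {
        ctr <- runif(1, min(wl), max(wl))
        wid <- runif(1, 60, 400)
        amp <- runif(1, -0.12, 0.12)
        pert <- pert + amp * exp(-((wl - ctr) / wid)^2)
      }
      round(clamp(base + pert + runif(1, -0.04, 0.04), 0.005, 0.99), 4)
    }
    draw_color <- function() round(c(runif(1, 0.05, 0.5), runif(1, 0.2, 0.8),
                                     runif(1, 0.05, 0.5)), 4)
    arch <- lapply(seq_len(n_taxa), function(k) {
      size_min <- runif(1, 1.5, 3)
      structure(list(
        taxon_code = sprintf("TAX%02d", k),
        mean_spectrum = draw_spectrum(),
        crown_color = draw_color(),
        crown_size_range = c(size_min, size_min + runif(1, 0.5, 2.5)),
        height_profile = list(mean = runif(1, 6, 32), sd = runif(1, 0.5, 2.5))),
        class = "taxon_archetype")
    })
    # enforce pairwise separation by resampling the later member of a pair
    repeat {
      ok <- TRUE
      for (i in seq_len(n_taxa - 1)) for (j in (i + 1):n_taxa) {
        if (max(abs(arch[[i]]$mean_spectrum - arch[[j]]$mean_spectrum)) <= separation ||
            sqrt(sum((arch[[i]]$crown_color - arch[[j]]$crown_color)^2)) <= 0.1 ||
            abs(arch[[i]]$height_profile$mean - arch[[j]]$height_profile$mean) <= 0.5) {
          arch[[j]]$mean_spectrum <- draw_spectrum()
          arch[[j]]$crown_color <- draw_color()
          arch[[j]]$height_profile$mean <- runif(1, 6, 32)
          ok <- FALSE
        }
      }
      if (ok) break
    }
    arch
  })
}

# Rejection-sample non-overlapping crown bounding boxes inside the plot.
place_crowns <- function(config, archetypes, taxa_idx) {
  placed <- list()
  for (t in taxa_idx) {
    a <- archetypes[[t]]
    for (try in seq_len(100)) {
      w <- runif(1, a$crown_size_range[1], a$crown_size_range[2])
      h <- runif(1, a$crown_size_range[1], a$crown_size_range[2])
      x0 <- runif(1, 0, config$plot_side - w)
      y0 <- runif(1, 0, config$plot_side - h)
      bb <- c(xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h)
      overlaps <- any(vapply(placed, function(p) {
        bb[["xmin"]] < p$bb[["xmax"]] && bb[["xmax"]] > p$bb[["xmin"]] &&
          bb[["ymin"]] < p$bb[["ymax"]] && bb[["ymax"]] > p$bb[["ymin"]]
      }, logical(1)))
      if (!overlaps) {
        placed[[length(placed) + 1]] <- list(taxon = t, bb = bb)
        break
      }
    }
  }
  placed
}

#' Generate one synthetic plot
#'
#' Builds the RGB raster, reflectance cube and point cloud for a single
#' plot. Crown pixels take the taxon archetype's color/spectrum plus
#' additive Gaussian noise; points falling inside a crown footprint draw
#' heights from the taxon's vertical profile, other points are low
#' ground/understory returns; the point count is Poisson with mean
#' `point_density * plot_side^2`. Height anomalies are injected per the
#' config. With noise set to zero, each crown's centroid reflectance equals
#' its archetype's mean spectrum exactly.
#'
#' @param config a [scene_config()].
#' @param archetypes from [make_archetypes()].
#' @param seed integer seed (bit-identical output for identical
#'   config + archetypes + seed).
#' @param plot_id identifier recorded on the crown records.
#' @return A `synthetic_plot`: list with `rgb` and `hs` ([raster_tile()]s),
#'   `points` (data.frame `x`, `y`, `h`), and `crowns` (crown records with
#'   true taxon labels).
#' @export
generate_plot <- function(config, archetypes, seed = 1L, plot_id = "PLOT001") {
  assert_that(length(archetypes) >= 1, "archetypes must be nonempty")
  assert_that(length(config$class_weights) >= length(archetypes),
              "config must provide a class weight for every archetype")
  side <- config$plot_side
  withr::with_seed(seed, {
    n_crowns <- sample(config$crowns_per_plot[1]:config$crowns_per_plot[2], 1)
    taxa_idx <- sample(seq_along(archetypes), n_crowns, replace = TRUE,
                       prob = config$class_weights[seq_along(archetypes)])
    placed <- place_crowns(config, archetypes, taxa_idx)

    # RGB raster: soil background plus crown rectangles (origin = NW corner)
    nrgb <- as.integer(round(side / config$rgb_resolution))
    rgb_vals <- array(rep(c(0.30, 0.25, 0.18), each = nrgb * nrgb),
                      c(nrgb, nrgb, 3))
    # hyperspectral cube stored as scaled integers
    nhs <- as.integer(round(side / config$hs_resolution))
    soil <- round(clamp(0.18 + 0.10 * exp(-((build_wavelength_grid(config$n_bands) -
                                               2000) / 800)^2), 0, 1), 4)
    hs_vals <- array(rep(round(soil * config$hs_scale), each = nhs * nhs),
                     c(nhs, nhs, config$n_bands))
    fill_cells <- function(n, res, bb) {
      cx <- (seq_len(n) - 0.5) * res
      dy <- (seq_len(n) - 0.5) * res   # distance south of the top edge
      list(rows = which(dy >= side - bb[["ymax"]] & dy < side - bb[["ymin"]]),
           cols = which(cx >= bb[["xmin"]] & cx < bb[["xmax"]]))
    }
    for (p in placed) {
      a <- archetypes[[p$taxon]]
      rc <- fill_cells(nrgb, config$rgb_resolution, p$bb)
      if (length(rc$rows) && length(rc$cols)) {
        blk <- array(rep(a$crown_color, each = length(rc$rows) * length(rc$cols)),
                     c(length(rc$rows), length(rc$cols), 3))
        if (config$rgb_noise_sd > 0) {
          blk <- clamp(blk + array(rnorm(length(blk), sd = config$rgb_noise_sd),
                                   dim(blk)))
        }
        rgb_vals[rc$rows, rc$cols, ] <- blk
      }
      rc <- fill_cells(nhs, config$hs_resolution, p$bb)
      if (length(rc$rows) && length(rc$cols)) {
        spec <- matrix(rep(a$mean_spectrum, each = length(rc$rows) * length(rc$cols)),
                       ncol = config$n_bands)
        if (config$hs_noise_sd > 0) {
          spec <- clamp(spec + matrix(rnorm(length(spec), sd = config$hs_noise_sd),
                                      nrow(spec)))
        }
        hs_vals[rc$rows, rc$cols, ] <- array(round(spec * config$hs_scale),
                                             c(length(rc$rows), length(rc$cols),
                                               config$n_bands))
      }
    }

    # point cloud
    n_pts <- rpois(1, config$point_density * side^2)
    pts <- data.frame(x = runif(n_pts, 0, side), y = runif(n_pts, 0, side),
                      h = abs(rnorm(n_pts, 0, 0.4)))
    for (p in placed) {
      a <- archetypes[[p$taxon]]
      inside <- pts$x >= p$bb[["xmin"]] & pts$x < p$bb[["xmax"]] &
        pts$y >= p$bb[["ymin"]] & pts$y < p$bb[["ymax"]]
      pts$h[inside] <- pmax(rnorm(sum(inside), a$height_profile$mean,
                                  a$height_profile$sd), 0)
    }
    pts <- inject_height_anomalies(pts, config$anomaly_low, config$anomaly_high,
                                   seed = seed + 7L)

    crowns <- if (length(placed)) {
      data.frame(
        individual_id = sprintf("%s_IND%03d", plot_id, seq_along(placed)),
        taxon_code = vapply(placed, function(p) archetypes[[p$taxon]]$taxon_code, ""),
        site_id = "SYN1", plot_id = plot_id,
        xmin = vapply(placed, function(p) p$bb[["xmin"]], 0),
        ymin = vapply(placed, function(p) p$bb[["ymin"]], 0),
        xmax = vapply(placed, function(p) p$bb[["xmax"]], 0),
        ymax = vapply(placed, function(p) p$bb[["ymax"]], 0),
        stringsAsFactors = FALSE)
    } else empty_crown_records()

    structure(list(
      rgb = raster_tile(rgb_vals, origin = c(0, side), res = config$rgb_resolution),
      hs = raster_tile(hs_vals, origin = c(0, side), res = config$hs_resolution),
      points = pts, crowns = crowns, plot_id = plot_id),
      class = "synthetic_plot")
  })
}

#' Inject artificial height anomalies into a point cloud
#'
#' Adds `n_low` below-ground points (heights strictly below the input
#' minimum) and `n_high` above-canopy points (strictly above the input
#' maximum), emulating lidar timing errors and bird strikes. With both
#' counts zero the input is returned unchanged.
#'
#' @param points data.frame with columns `x`, `y`, `h`.
#' @param n_low,n_high number of low/high anomalies to add.
#' @param seed integer seed.
#' @return data.frame with `nrow(points) + n_low + n_high` rows.
#' @export
inject_height_anomalies <- function(points, n_low = 0L, n_high = 0L, seed = 1L) {
  assert_that(n_low >= 0 && n_high >= 0, "anomaly counts must be nonnegative")
  if (n_low + n_high == 0L) return(points)
  rng <- list(x = range(points$x), y = range(points$y), h = range(points$h))
  extra <- withr::with_seed(seed, {
    data.frame(
      x = runif(n_low + n_high, rng$x[1], rng$x[2]),
      y = runif(n_low + n_high, rng$y[1], rng$y[2]),
      h = c(rng$h[1] - runif(n_low, 5, 60), rng$h[2] + runif(n_high, 5, 60)))
  })
  rbind(points, extra)
}

#' @export
print.synthetic_plot <- function(x, ...) {
  cat(sprintf("synthetic_plot %s: %d crowns, %d lidar points, RGB %dx%d, cube %dx%dx%d\n",
              x$plot_id, nrow(x$crowns), nrow(x$points),
              dim(x$rgb$values)[1], dim(x$rgb$values)[2],
              dim(x$hs$values)[1], dim(x$hs$values)[2], dim(x$hs$values)[3]))
  invisible(x)
}

#' Write a set of plots to disk as a scene directory
#'
#' Materializes, per plot, `rgb_<plot>.tif` (+ JSON sidecar),
#' `hs_<plot>.csv` (+ sidecar with band wavelengths), and
#' `points_<plot>.xyz`, plus scene-wide `crowns.geojson` and `field.csv`.
#' When `withhold_labels` is `TRUE` the field table omits the taxon column
#' and the true labels go to `labels_withheld.csv` instead, mimicking an
#' evaluation release.
#'
#' @param plots list of `synthetic_plot` objects.
#' @param dir output directory (created if needed).
#' @param withhold_labels write taxon labels to a separate withheld file.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(plots, dir, withhold_labels = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- NULL
  for (p in plots) {
    write_raster_tile(p$rgb, file.path(dir, sprintf("rgb_%s.tif", p$plot_id)))
    if (is.null(wl)) wl <- build_wavelength_grid(dim(p$hs$values)[3])
    write_raster_tile(p$hs, file.path(dir, sprintf("hs_%s.csv", p$plot_id)),
                      metadata = list(wavelengths_nm = wl))
    write_xyz(p$points, file.path(dir, sprintf("points_%s.xyz", p$plot_id)))
  }
  crowns <- do.call(rbind, lapply(plots, `[[`, "crowns"))
  write_crowns_geojson(crowns[, c("individual_id", "xmin", "ymin", "xmax", "ymax")],
                       file.path(dir, "crowns.geojson"))
  field <- crowns[, c("individual_id", "taxon_code", "site_id", "plot_id")]
  if (withhold_labels) {
    utils::write.csv(field[, c("individual_id", "taxon_code")],
                     file.path(dir, "labels_withheld.csv"), row.names = FALSE)
    field$taxon_code <- NULL
  }
  utils::write.csv(field, file.path(dir, "field.csv"), row.names = FALSE)
  invisible(dir)
}

#' Generate and write a full train/test scene set
#'
#' The single fixture command: generates archetypes, a set of training plots
#' and a set of test plots (labels withheld on disk), and writes both under
#' `out_dir/train` and `out_dir/test`.
#'
#' @param config a [scene_config()].
#' @param out_dir output directory.
#' @param n_train_plots,n_test_plots number of plots per partition.
#' @param archetypes optionally precomputed archetypes.
#' @return list with `archetypes`, `train` and `test` plot lists, invisibly.
#' @export
make_scene_set <- function(config, out_dir, n_train_plots = 8L,
                           n_test_plots = 4L, archetypes = NULL) {
  if (is.null(archetypes)) {
    archetypes <- make_archetypes(config$n_taxa, seed = config$seed,
                                  n_bands = config$n_bands)
  }
  gen <- function(tag, n, seed0) {
    lapply(seq_len(n), function(i) {
      generate_plot(config, archetypes, seed = seed0 + i,
                    plot_id = sprintf("%s%03d", tag, i))
    })
  }
  train <- gen("TRN", n_train_plots, config$seed * 1000L)
  test <- gen("TST", n_test_plots, config$seed * 1000L + 500L)
  write_scene(train, file.path(out_dir, "train"), withhold_labels = FALSE)
  write_scene(test, file.path(out_dir, "test"), withhold_labels = TRUE)
  invisible(list(archetypes = archetypes, train = train, test = test))
}
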