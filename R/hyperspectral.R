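# Crown-centroid reflectance extraction and water-absorption bad-band
# removal. The imaging-spectrometer grid is 426 bands at 5 nm spacing
# starting at 380 nm; removing the two default water-vapor windows leaves
# the 369 good-band reflectance block used by the fusion network.

#' Build the spectrometer wavelength grid
#'
#' Wavelengths are `start_nm + spacing_nm * (0:(n_bands-1))`; the defaults
#' give 426 bands from 380 nm at 5 nm spacing (ending at 2505 nm).
#'
#' @param n_bands number of bands.
#' @param start_nm first wavelength in nm.
#' @param spacing_nm band spacing in nm.
#' @return numeric vector of wavelengths (nm), strictly increasing.
#' @export
build_wavelength_grid <- function(n_bands = 426L, start_nm = 380, spacing_nm = 5) {
  assert_that(n_bands >= 1, "n_bands must be at least 1")
  start_nm + spacing_nm * (seq_len(n_bands) - 1)
}

#' Default water-absorption bad-band windows
#'
#' Inclusive wavelength intervals, in nm, flagged as noise-dominated by
#' atmospheric water vapor. On the default grid these remove 22 + 35 = 57
#' bands, leaving 369 good bands.
#'
#' @return list of length-2 numeric intervals `c(lo, hi)` in nm.
#' @export
default_bad_band_windows <- function() {
  list(c(1340, 1445), c(1790, 1960))
}

#' Remove bad bands from a spectrum
#'
#' Drops every value whose wavelength falls inside any window (inclusive
#' endpoints), preserving order. Re-masking an already-masked vector removes
#' nothing.
#'
#' @param spectrum numeric reflectance vector aligned to `wavelengths`.
#' @param wavelengths wavelength grid in nm, same length as `spectrum`.
#' @param windows list of inclusive `c(lo, hi)` intervals in nm; `list()`
#'   keeps every band.
#' @return list with `values` (good-band reflectances), `wavelengths`
#'   (retained grid) and `removed` (number of bands dropped).
#' @export
apply_bad_bands <- function(spectrum, wavelengths = build_wavelength_grid(length(spectrum)),
                            windows = default_bad_band_windows()) {
  assert_that(length(spectrum) == length(wavelengths),
              "spectrum and wavelength grid lengths differ")
  bad <- rep(FALSE, length(wavelengths))
  for (w in windows) {
    bad <- bad | (wavelengths >= w[1] & wavelengths <= w[2])
  }
  if (all(bad)) stop("bad-band mask removes every band; mask is over-broad")
  list(values = spectrum[!bad], wavelengths = wavelengths[!bad],
       removed = sum(bad))
}

#' Extract the crown-centroid reflectance spectrum
#'
#' Reads the full band vector at the cell containing the crown polygon's
#' spatial centroid and rescales stored integers to reflectance.
#'
#' @param hs_tile a [raster_tile()] whose channels are spectral bands.
#' @param polygon crown bounding box (see [as_bbox] conventions).
#' @param scale_factor divisor converting stored values to reflectance
#'   (10000 by convention for NEON-style products).
#' @return numeric reflectance vector of length `n_bands`.
#' @export
extract_crown_spectrum <- function(hs_tile, polygon, scale_factor = 10000) {
  rc <- centroid_pixel(hs_tile, polygon)
  as.numeric(hs_tile$values[rc[["row"]], rc[["col"]], ]) / scale_factor
}
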