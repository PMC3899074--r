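## On-disk RF container: a directory with JSON metadata plus one raw
## little-endian float32 array per slice, axial index fastest.  The format
## is deliberately language-neutral and diff-able.

CONTAINER_SCHEMA_VERSION <- 1L

#' Write an RF volume to an on-disk container
#'
#' The container is a directory holding \code{metadata.json} (transducer,
#' grid, kind, schema version, provenance) and one file
#' \code{slice_NNN.raw} per elevational slice, each a little-endian 32-bit
#' float array in axial-fastest order.  Reading the container back yields a
#' volume identical at 32-bit float precision.
#'
#' @param volume an \linkS4class{RFVolume}.
#' @param path directory to create (must not exist unless
#'   \code{overwrite = TRUE}).
#' @param overwrite replace an existing container.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readRFContainer}}
#' @export
writeRFContainer <- function(volume, path, overwrite = FALSE) {
  stopifnot(is(volume, "RFVolume"))
  validObject(volume)
  if (dir.exists(path)) {
    if (!overwrite) stop("container path already exists: ", path)
    unlink(path, recursive = TRUE)
  }
  if (!dir.create(path, recursive = TRUE))
    stop("cannot create container directory: ", path)
  g <- volume@grid; tr <- volume@transducer
  meta <- list(
    schema_version = CONTAINER_SCHEMA_VERSION,
    kind = volume@kind,
    transducer = list(
      center_frequency_mhz = tr@centerFrequency,
      band_low_mhz = tr@bandLow, band_high_mhz = tr@bandHigh,
      focal_distance_mm = tr@focalDistance,
      depth_of_focus_mm = tr@depthOfFocus,
      sampling_rate_hz = tr@samplingRate),
    grid = list(
      axial_dt_s = g@axialDt, lateral_spacing_um = g@lateralSpacing,
      slice_spacing_um = g@sliceSpacing,
      n_samples = g@nSamples, n_lines = g@nLines, n_slices = g@nSlices),
    sample_format = "float32-le",
    provenance = list(writer = "susi", r_version = as.character(getRversion()))
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_len(g@nSlices)) {
    con <- file(file.path(path, sprintf("slice_%03d.raw", k)), "wb")
    writeBin(as.numeric(volume@samples[, , k]), con, size = 4L,
             endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read an RF volume from an on-disk container
#'
#' @param path container directory written by \code{\link{writeRFContainer}}.
#' @return An \linkS4class{RFVolume}.
#' @export
readRFContainer <- function(path) {
  metaPath <- file.path(path, "metadata.json")
  if (!file.exists(metaPath))
    stop("not a container (missing metadata.json): ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      meta$schema_version > CONTAINER_SCHEMA_VERSION)
    stop("unsupported container schema version")
  tr <- transducerSpec(
    centerFrequency = meta$transducer$center_frequency_mhz,
    bandLow = meta$transducer$band_low_mhz,
    bandHigh = meta$transducer$band_high_mhz,
    focalDistance = meta$transducer$focal_distance_mm,
    depthOfFocus = meta$transducer$depth_of_focus_mm,
    samplingRate = meta$transducer$sampling_rate_hz)
  g <- acquisitionGrid(meta$grid$n_samples, meta$grid$n_lines,
                       meta$grid$n_slices, axialDt = meta$grid$axial_dt_s,
                       lateralSpacing = meta$grid$lateral_spacing_um,
                       sliceSpacing = meta$grid$slice_spacing_um)
  files <- sort(list.files(path, pattern = "^slice_[0-9]+\\.raw$"))
  if (length(files) != g@nSlices)
    stop(sprintf("container dimension error: metadata promises %d slices, %d present",
                 g@nSlices, length(files)))
  n <- g@nSamples * g@nLines
  arr <- array(0, dim = c(g@nSamples, g@nLines, g@nSlices))
  for (k in seq_along(files)) {
    con <- file(file.path(path, files[k]), "rb")
    x <- readBin(con, what = "numeric", n = n + 1L, size = 4L,
                 endian = "little")
    close(con)
    if (length(x) != n)
      stop(sprintf("container dimension error in %s: expected %d samples, got %d",
                   files[k], n, length(x)))
    arr[, , k] <- x
  }
  vol <- new("RFVolume", samples = arr, grid = g, transducer = tr,
             kind = meta$kind)
  validObject(vol)
  vol
}
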