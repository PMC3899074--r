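## Envelope detection and B-mode conversion.

#' Envelope of an RF trace via the analytic signal
#'
#' Magnitude of the quadrature (analytic) signal built in the frequency
#' domain: negative frequencies zeroed, positive frequencies doubled.
#'
#' @param x real RF trace (or matrix, one trace per column).
#' @return Envelope of the same shape as \code{x}.
#' @export
rfEnvelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, rfEnvelope))
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE)) / n
}

#' B-mode image of one RF slice
#'
#' Per-A-line envelope (analytic-signal magnitude), log-compressed as
#' \code{20*log10} relative to the slice maximum and clipped to
#' \code{[-dynamicRange, 0]} dB.  An all-zero slice maps to a uniform floor
#' at \code{-dynamicRange} dB.  The map is invariant to global positive
#' scaling of the RF amplitude.
#'
#' @param volume an \linkS4class{RFVolume}.
#' @param sliceIndex slice to convert.
#' @param dynamicRange display dynamic range, dB (> 0).
#' @return A \linkS4class{BModeImage}.
#' @export
bmodeImage <- function(volume, sliceIndex = 1L, dynamicRange = 50) {
  stopifnot(is(volume, "RFVolume"), dynamicRange > 0)
  g <- volume@grid
  if (sliceIndex < 1L || sliceIndex > g@nSlices)
    stop("sliceIndex out of range")
  env <- rfEnvelope(volume@samples[, , sliceIndex])
  env <- matrix(env, nrow = g@nSamples)
  mx <- max(env)
  if (mx == 0) {
    db <- matrix(-dynamicRange, g@nSamples, g@nLines)
  } else {
    db <- 20 * log10(pmax(env / mx, 10^(-dynamicRange / 20) * 1e-3))
    db <- pmin(pmax(db, -dynamicRange), 0)
  }
  new("BModeImage", values = db, dynamicRange = dynamicRange,
      axialDt = g@axialDt, lateralSpacing = g@lateralSpacing,
      sliceIndex = as.integer(sliceIndex))
}

#' Export a B-mode image as PNG and CSV
#'
#' Writes an 8-bit grayscale PNG (0 = -dynamicRange dB, 255 = 0 dB) and a
#' CSV of the dB values.
#'
#' @param bmode a \linkS4class{BModeImage}.
#' @param pngPath,csvPath output paths; either may be NULL to skip.
#' @return Invisibly, a list of the written paths.
#' @export
exportBMode <- function(bmode, pngPath = NULL, csvPath = NULL) {
  v <- bmode@values
  out <- list()
  if (!is.null(pngPath)) {
    gray <- (v + bmode@dynamicRange) / bmode@dynamicRange
    png::writePNG(gray, pngPath)
    out$png <- pngPath
  }
  if (!is.null(csvPath)) {
    utils::write.csv(as.data.frame(v), csvPath, row.names = FALSE)
    out$csv <- csvPath
  }
  invisible(out)
}
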