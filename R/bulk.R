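## Bulk acoustics: surface detection, time-of-flight thickness and speed
## of sound, spectral-ratio attenuation, and construct volume from serial
## B-mode contours.

## Parabolic sub-sample refinement of an envelope peak index.
.refinePeak <- function(env, idx) {
  if (idx <= 1L || idx >= length(env)) return(idx)
  y1 <- env[idx - 1L]; y2 <- env[idx]; y3 <- env[idx + 1L]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(idx)
  idx + 0.5 * (y1 - y3) / den
}

## Cluster above-threshold envelope samples into echoes separated by at
## least minSeparation samples; return the refined peak position of each.
.echoPeaks <- function(env, thresholdDb, minSeparation) {
  thr <- max(env) * 10^(thresholdDb / 20)
  above <- which(env >= thr)
  if (!length(above)) return(numeric(0))
  breaks <- which(diff(above) > minSeparation)
  starts <- c(above[1], above[breaks + 1])
  ends <- c(above[breaks], above[length(above)])
  vapply(seq_along(starts), function(j) {
    seg <- starts[j]:ends[j]
    .refinePeak(env, seg[which.max(env[seg])])
  }, numeric(1))
}

#' Detect surface echo times in a scan pair
#'
#' For each A-line of the sample scan, locates the envelope peaks of the
#' first three threshold-crossing echoes (construct top surface, bottom
#' surface, gel pad) and, in the matching reference A-line, the gel-pad
#' echo.  Times are round-trip, with sub-sample parabolic refinement.
#' A-lines without three echoes (or whose times are out of order) are
#' flagged invalid and excluded from the median aggregation.
#'
#' @param volume sample \linkS4class{RFVolume}.
#' @param reference reference \linkS4class{RFVolume} on the same grid.
#' @param thresholdDb detection threshold relative to the A-line envelope
#'   maximum, dB (negative).
#' @param minSeparation minimum echo separation, samples.
#' @return An \linkS4class{EchoTimes} (median aggregate plus per-line
#'   table).
#' @export
detectSurfaces <- function(volume, reference, thresholdDb = -15,
                           minSeparation = 100L) {
  stopifnot(is(volume, "RFVolume"), is(reference, "RFVolume"))
  g <- volume@grid
  if (!identical(dim(volume@samples), dim(reference@samples)))
    stop("sample and reference scans must share the acquisition grid")
  dt <- g@axialDt
  rows <- vector("list", g@nLines * g@nSlices)
  idx <- 0L
  for (k in seq_len(g@nSlices)) {
    for (i in seq_len(g@nLines)) {
      idx <- idx + 1L
      envS <- rfEnvelope(volume@samples[, i, k])
      envR <- rfEnvelope(reference@samples[, i, k])
      pkS <- .echoPeaks(envS, thresholdDb, minSeparation)
      pkR <- .echoPeaks(envR, thresholdDb, minSeparation)
      ok <- length(pkS) >= 3L && length(pkR) >= 1L
      tS <- if (ok) (pkS[1:3] - 1) * dt else rep(NA_real_, 3)
      tR <- if (ok) (pkR[1] - 1) * dt else NA_real_
      if (ok && !(tS[1] < tS[2] && tS[2] < tS[3])) ok <- FALSE
      rows[[idx]] <- data.frame(slice = k, line = i, tTop = tS[1],
                                tBot = tS[2], tGel = tS[3], tRef = tR,
                                valid = ok)
    }
  }
  perLine <- do.call(rbind, rows)
  if (!any(perLine$valid))
    stop("no A-line produced a full echo set; threshold too high or no sample present")
  v <- perLine[perLine$valid, ]
  echoTimes(stats::median(v$tTop), stats::median(v$tBot),
            stats::median(v$tGel), stats::median(v$tRef), perLine = perLine)
}

#' Thickness and speed of sound from echo times
#'
#' Substitution method with a reflecting gel pad below the sample.  With
#' round-trip times t_top/t_bot/t_gel (sample present) and t_ref (sample
#' absent), and fluid sound speed c_f:
#' \deqn{L = c_f [ (t_{bot} - t_{top}) + (t_{ref} - t_{gel}) ] / 2}
#' \deqn{c_t = 2 L / (t_{bot} - t_{top})}
#' These satisfy the substitution identities 2L/c_t = t_bot - t_top and
#' 2L/c_f = (t_ref - t_gel) + (t_bot - t_top); any fluid gap between the
#' sample bottom and the gel pad cancels.
#'
#' @param times an \linkS4class{EchoTimes}.
#' @param medium a \linkS4class{MediumSpec} (c_f = 1480 m/s by default).
#' @return List with \code{thickness} (mm) and \code{soundSpeed} (m/s).
#' @export
thicknessAndSpeed <- function(times, medium = mediumSpec()) {
  stopifnot(is(times, "EchoTimes"))
  validObject(times)
  if (times@tGel <= times@tBot)
    stop("non-physical times: gel-pad echo must follow the bottom surface")
  dtSample <- times@tBot - times@tTop
  Lm <- medium@cFluid * (dtSample + (times@tRef - times@tGel)) / 2   # m
  if (Lm <= 0) stop("non-physical times: non-positive thickness")
  ct <- 2 * Lm / dtSample
  if (ct < 1300 || ct > 1700)
    warning(sprintf("speed of sound %.0f m/s outside the 1300-1700 m/s sanity band", ct))
  list(thickness = Lm * 1000, soundSpeed = ct)
}

## Hamming-windowed amplitude spectrum of a segment centered at `center`
## (fractional sample index), on the FFT grid of length nwin.
.echoSpectrum <- function(trace, center, nwin) {
  half <- nwin %/% 2
  i0 <- round(center) - half
  if (i0 < 1L || i0 + nwin - 1L > length(trace)) return(NULL)
  seg <- trace[i0:(i0 + nwin - 1L)]
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  abs(stats::fft(seg * w))[seq_len(half + 1L)]
}

#' Attenuation coefficient from gel-pad insertion loss
#'
#' Frequency-dependent attenuation computed from the windowed gel-pad echo
#' spectra with (|A(f)|) and without (|A_0(f)|) the sample:
#' \deqn{\alpha(f) = \frac{20 \log_{10}( |A_0(f)| / |A(f)| )}{2 L}}
#' in dB/cm (round-trip path 2L), averaged across A-lines; the attenuation
#' coefficient in dB/(cm MHz) is the slope of a linear fit of alpha(f)
#' over the fit band (default 20--55 MHz).
#'
#' @param volume sample \linkS4class{RFVolume}.
#' @param reference reference \linkS4class{RFVolume}.
#' @param times an \linkS4class{EchoTimes} from
#'   \code{\link{detectSurfaces}} (per-line gel/reference times are used).
#' @param thicknessMm sample thickness L, mm.
#' @param fitBand linear-fit band, MHz.
#' @param windowLength spectral window length, samples (Hamming taper).
#' @return List with \code{coefficient} (dB/(cm MHz)), \code{r2},
#'   \code{band}, and \code{alphaOfF} (data.frame of frequency vs mean
#'   alpha in dB/cm).
#' @export
attenuationCoefficient <- function(volume, reference, times, thicknessMm,
                                   fitBand = c(20, 55),
                                   windowLength = 256L) {
  if (thicknessMm <= 0) stop("thickness must be positive")
  g <- volume@grid
  fs <- 1 / g@axialDt
  freq <- (0:(windowLength %/% 2)) * fs / windowLength / 1e6
  inBand <- freq >= fitBand[1] & freq <= fitBand[2]
  if (sum(inBand) < 5L) stop("fit band resolves to fewer than 5 points")
  perLine <- times@perLine
  Lcm <- thicknessMm / 10
  acc <- numeric(sum(inBand)); nUsed <- 0L
  for (r in seq_len(nrow(perLine))) {
    if (!perLine$valid[r]) next
    k <- perLine$slice[r]; i <- perLine$line[r]
    gelIdx <- perLine$tGel[r] / g@axialDt + 1
    refIdx <- perLine$tRef[r] / g@axialDt + 1
    ## the gel window must clear the construct interior below its bottom
    if ((gelIdx - windowLength / 2) <= perLine$tBot[r] / g@axialDt + 1)
      stop("gel-pad echo window overlaps the construct interior; increase the gap or shorten the window")
    A <- .echoSpectrum(volume@samples[, i, k], gelIdx, windowLength)
    A0 <- .echoSpectrum(reference@samples[, i, k], refIdx, windowLength)
    if (is.null(A) || is.null(A0)) next
    acc <- acc + 20 * log10(A0[inBand] / A[inBand]) / (2 * Lcm)
    nUsed <- nUsed + 1L
  }
  if (nUsed == 0L) stop("no usable gel-pad echo windows")
  alphaF <- acc / nUsed
  fit <- stats::lm(alphaF ~ freq[inBand])
  coefficient <- unname(stats::coef(fit)[2])
  if (coefficient < 0)
    warning("fitted attenuation coefficient is negative")
  list(coefficient = coefficient,
       r2 = summary(fit)$r.squared,
       band = fitBand,
       alphaOfF = data.frame(freqMhz = freq[inBand], alphaDbCm = alphaF))
}

#' Estimate bulk properties of a scan pair
#'
#' Convenience wrapper running surface detection, time-of-flight inversion
#' and attenuation estimation.
#'
#' @inheritParams detectSurfaces
#' @param medium a \linkS4class{MediumSpec}.
#' @param fitBand attenuation fit band, MHz.
#' @return A \linkS4class{BulkProperties}.
#' @export
bulkProperties <- function(volume, reference, medium = mediumSpec(),
                           thresholdDb = -15, fitBand = c(20, 55)) {
  times <- detectSurfaces(volume, reference, thresholdDb = thresholdDb)
  ts <- thicknessAndSpeed(times, medium)
  att <- attenuationCoefficient(volume, reference, times, ts$thickness,
                                fitBand = fitBand)
  new("BulkProperties", thickness = ts$thickness, soundSpeed = ts$soundSpeed,
      attenuation = att$coefficient, attenuationBand = fitBand,
      fitR2 = att$r2)
}

#' Construct volume from a B-mode stack
#'
#' Threshold-based contour detection per slice: pixels above threshold are
#' masked, each A-line column is filled between its first and last
#' above-threshold sample, and the largest laterally connected run of
#' non-empty columns is kept as the construct cross-section.  The per-slice
#' area is the filled-pixel area and the volume is the rectangular-rule sum
#' of areas times the slice spacing (a trapezoidal option is available).
#'
#' @param bmodes list of \linkS4class{BModeImage}s (serial slices).
#' @param thresholdDb threshold relative to the slice maximum, dB
#'   (negative).
#' @param sliceSpacingUm slice spacing, um.
#' @param soundSpeed speed used to convert axial sample period to depth,
#'   m/s.
#' @param axialLimit optional c(first, last) sample range to search (e.g.
#'   to exclude the gel-pad echo).
#' @param rule "rectangular" (default) or "trapezoidal" integration.
#' @param boundary "edge" places the contour at the outermost
#'   above-threshold pixels (exact for filled bright regions); "peak"
#'   places it at the envelope peaks of the first and last echo clusters,
#'   which removes the pulse-width smear when surfaces appear as thin
#'   echo bands in RF-derived B-modes (same rationale as the envelope-peak
#'   surface timing in \code{\link{detectSurfaces}}).
#' @return List with \code{volumeMm3}, \code{perSliceAreaMm2}, and
#'   \code{contours} (one data.frame per slice: line, zTop, zBot in mm).
#' @export
constructVolume <- function(bmodes, thresholdDb = -20, sliceSpacingUm = 200,
                            soundSpeed = 1540, axialLimit = NULL,
                            rule = c("rectangular", "trapezoidal"),
                            boundary = c("edge", "peak")) {
  rule <- match.arg(rule)
  boundary <- match.arg(boundary)
  stopifnot(length(bmodes) >= 1L)
  areas <- numeric(length(bmodes))
  contours <- vector("list", length(bmodes))
  for (s in seq_along(bmodes)) {
    bm <- bmodes[[s]]
    v <- bm@values
    if (!is.null(axialLimit)) {
      keep <- seq(max(1L, axialLimit[1]), min(nrow(v), axialLimit[2]))
      mask0 <- matrix(FALSE, nrow(v), ncol(v))
      mask0[keep, ] <- v[keep, ] >= thresholdDb
    } else mask0 <- v >= thresholdDb
    axialMm <- bm@axialDt * soundSpeed / 2 * 1000   # one-way mm per sample
    latMm <- bm@lateralSpacing / 1000
    if (boundary == "edge") {
      first <- apply(mask0, 2, function(col) if (any(col)) which(col)[1] else NA)
      last <- apply(mask0, 2, function(col) if (any(col)) max(which(col)) else NA)
    } else {
      bounds <- vapply(seq_len(ncol(v)), function(j) {
        idx <- which(mask0[, j])
        if (!length(idx)) return(c(NA_real_, NA_real_))
        breaks <- which(diff(idx) > 20L)
        starts <- c(idx[1], idx[breaks + 1]); ends <- c(idx[breaks], idx[length(idx)])
        s1 <- starts[1]:ends[1]
        s2 <- starts[length(starts)]:ends[length(ends)]
        c(s1[which.max(v[s1, j])], s2[which.max(v[s2, j])])
      }, numeric(2))
      first <- bounds[1, ]; last <- bounds[2, ]
    }
    nonEmpty <- !is.na(first)
    if (!any(nonEmpty)) {
      warning(sprintf("slice %d: no above-threshold region; zero area recorded", s))
      areas[s] <- 0
      contours[[s]] <- data.frame(line = integer(0), zTop = numeric(0),
                                  zBot = numeric(0))
      next
    }
    ## largest laterally connected run of non-empty columns
    r <- rle(nonEmpty)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    cols <- starts[best]:ends[best]
    extent <- (last[cols] - first[cols] + 1)
    areas[s] <- sum(extent) * axialMm * latMm
    contours[[s]] <- data.frame(line = cols,
                                zTop = (first[cols] - 1) * axialMm,
                                zBot = (last[cols] - 1) * axialMm)
  }
  sliceMm <- sliceSpacingUm / 1000
  vol <- if (rule == "rectangular" || length(areas) == 1L)
    sum(areas) * sliceMm
  else sum((areas[-1] + areas[-length(areas)]) / 2) * sliceMm
  list(volumeMm3 = vol, perSliceAreaMm2 = areas, contours = contours)
}
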