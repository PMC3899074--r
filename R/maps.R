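## Parametric color maps overlaid on B-mode images.

.MAP_COLUMNS <- c(diameter = "diameterUm", calcium = "calciumConcUgMl",
                  mbf = "mbf", slope = "slope", cq2 = "cq2")

#' Build a parametric map aligned to a B-mode slice
#'
#' Rasterizes window-level parameter values onto the pixel grid of a
#' B-mode slice.  Under the default nearest-window mode each masked pixel
#' takes the value of the nearest window center (so values at window
#' centers are exact); bilinear mode interpolates across the window grid.
#' Pixels outside the construct interior, on lines without windows, or
#' whose windows were excluded as non-physical stay unmasked
#' (transparent).
#'
#' @param bmode a \linkS4class{BModeImage}.
#' @param windowTable per-window table from \code{\link{susiAnalysis}}
#'   (columns slice, line, center plus the parameter column).
#' @param parameter one of "diameter", "calcium", "mbf", "slope", "cq2".
#' @param interpolation "nearest" or "bilinear".
#' @param windowLength window length used for the analysis, samples (sets
#'   the masked axial extent around each window center).
#' @param colormap colormap name for grDevices::hcl.colors.
#' @return A \linkS4class{ParametricMap}.
#' @export
buildParametricMap <- function(bmode, windowTable,
                               parameter = c("diameter", "calcium", "mbf",
                                             "slope", "cq2"),
                               interpolation = c("nearest", "bilinear"),
                               windowLength = 256L, colormap = "viridis") {
  parameter <- match.arg(parameter)
  interpolation <- match.arg(interpolation)
  column <- .MAP_COLUMNS[[parameter]]
  if (!column %in% names(windowTable))
    stop("window table lacks column '", column, "' for parameter ", parameter)
  wt <- windowTable[windowTable$slice == bmode@sliceIndex, ]
  wt <- wt[is.finite(wt[[column]]), ]
  dims <- dim(bmode@values)
  values <- matrix(NA_real_, dims[1], dims[2])
  mask <- matrix(FALSE, dims[1], dims[2])
  if (nrow(wt)) {
    half <- windowLength %/% 2
    ## physical scale of one line spacing in axial samples (for nearest
    ## distances); axial step is c/2 per sample period -- use fluid speed
    ## scale, precision is not critical for assignment
    axStepUm <- bmode@axialDt * 1540 / 2 * 1e6
    lineScale <- bmode@lateralSpacing / axStepUm
    for (i in unique(wt$line)) {
      sub <- wt[wt$line == i, ]
      rows <- max(1L, floor(min(sub$center) - half)):
        min(dims[1], ceiling(max(sub$center) + half))
      mask[rows, i] <- TRUE
    }
    px <- which(mask, arr.ind = TRUE)
    if (interpolation == "nearest") {
      for (j in seq_len(nrow(px))) {
        d2 <- (wt$center - px[j, 1])^2 +
          ((wt$line - px[j, 2]) * lineScale)^2
        values[px[j, 1], px[j, 2]] <- wt[[column]][which.min(d2)]
      }
    } else {
      ## two-pass linear interpolation over the window grid
      lines <- sort(unique(wt$line))
      prof <- matrix(NA_real_, dims[1], length(lines))
      for (li in seq_along(lines)) {
        sub <- wt[wt$line == lines[li], ]
        rows <- which(mask[, lines[li]])
        if (nrow(sub) == 1L) prof[rows, li] <- sub[[column]]
        else prof[rows, li] <- stats::approx(sub$center, sub[[column]],
                                             xout = rows, rule = 2)$y
      }
      for (j in seq_len(nrow(px))) {
        row <- px[j, 1]
        avail <- which(is.finite(prof[row, ]))
        if (!length(avail)) next
        if (length(avail) == 1L) values[row, px[j, 2]] <- prof[row, avail]
        else values[row, px[j, 2]] <- stats::approx(lines[avail],
                                                    prof[row, avail],
                                                    xout = px[j, 2],
                                                    rule = 2)$y
      }
      mask <- mask & is.finite(values)
    }
  }
  rng <- if (any(mask)) range(values[mask]) else c(0, 0)
  new("ParametricMap", parameter = parameter, values = values, mask = mask,
      range = rng, colormap = colormap)
}

#' Render a B-mode image with a parametric color overlay
#'
#' Writes a PNG with the grayscale B-mode underlay, the parametric map
#' alpha-blended on top wherever its mask is true, and a colorbar strip
#' along the right edge.  Output is deterministic: identical inputs give a
#' byte-identical file.
#'
#' @param bmode a \linkS4class{BModeImage}.
#' @param map a \linkS4class{ParametricMap} on the same geometry.
#' @param path output PNG path.
#' @param alpha overlay opacity in [0, 1].
#' @param range optional fixed display range c(lo, hi); defaults to the
#'   map's own range.
#' @return \code{path}, invisibly.
#' @export
renderOverlay <- function(bmode, map, path, alpha = 0.6, range = NULL) {
  if (!identical(dim(bmode@values), dim(map@values)))
    stop("B-mode and map geometries are misaligned")
  if (is.null(range)) range <- map@range
  gray <- (bmode@values + bmode@dynamicRange) / bmode@dynamicRange
  d <- dim(gray)
  img <- array(rep(gray, 3), dim = c(d[1], d[2], 3))
  pal <- grDevices::hcl.colors(256, map@colormap)
  rgbPal <- grDevices::col2rgb(pal) / 255
  if (any(map@mask) && diff(range) > 0) {
    idx <- which(map@mask, arr.ind = TRUE)
    v <- (map@values[map@mask] - range[1]) / diff(range)
    ci <- pmin(pmax(floor(v * 255) + 1L, 1L), 256L)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- (1 - alpha) * plane[idx] + alpha * rgbPal[ch, ci]
      img[, , ch] <- plane
    }
  }
  ## colorbar strip (top = high) on the right edge
  barW <- max(4L, round(d[2] * 0.03))
  bar <- array(0, dim = c(d[1], barW, 3))
  ci <- pmin(pmax(floor((1 - (seq_len(d[1]) - 1) / (d[1] - 1)) * 255) + 1L,
                  1L), 256L)
  for (ch in 1:3) bar[, , ch] <- matrix(rgbPal[ch, ci], d[1], barW)
  out <- array(0, dim = c(d[1], d[2] + barW + 2L, 3))
  out[, seq_len(d[2]), ] <- img
  out[, d[2] + 1:2, ] <- 1
  out[, (d[2] + 3L):(d[2] + barW + 2L), ] <- bar
  png::writePNG(out, path)
  invisible(path)
}
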