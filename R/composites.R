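## Three-frequency RGB composites of MVBS.

#' Linear colour-index rescaling of MVBS
#'
#' Maps MVBS linearly onto the 256-level colour scale:
#' 255 * (MVBS - min) / (max - min), clipped to [0, 255]. The minimum and
#' maximum MVBS of the entire transect (per frequency) serve as the
#' rescaling reference, so the transect-maximum cell maps to 255 and the
#' minimum to 0.
#'
#' @param mvbsValue MVBS of the cell(s) being transformed, dB.
#' @param minMvbs,maxMvbs transect-wide reference MVBS, dB (max > min).
#' @return colour-index value(s) in [0, 255]; NA propagates.
#' @export
colorIndex <- function(mvbsValue, minMvbs, maxMvbs) {
  if (maxMvbs <= minMvbs) stop("maxMvbs must exceed minMvbs")
  pmin(255, pmax(0, 255 * (mvbsValue - minMvbs) / (maxMvbs - minMvbs)))
}

#' Build a three-frequency RGB composite
#'
#' Assigns red = 18 kHz, green = 38 kHz, blue = 120 kHz. Each channel is
#' colour-index rescaled against its own transect min/max (computed over
#' defined cells, after masking), gamma normalized as
#' 255 * (x/255)^(1/gamma) (default gamma = 2), then multiplicatively
#' brightened and clipped at 255. Cells with no defined MVBS render 0.
#' Distance cells from ship back-tracking or circling can be removed via
#' \code{excludeDist}.
#'
#' @param m18,m38,m120 co-registered \linkS4class{MvbsGrid}s.
#' @param gamma gamma-normalization exponent (default 2; 1 = identity).
#' @param brighten multiplicative brightening factor (default 1 = none).
#' @param excludeDist integer indices of distance cells to drop.
#' @return an \linkS4class{RgbComposite}.
#' @export
buildRgb <- function(m18, m38, m120, gamma = 2, brighten = 1,
                     excludeDist = NULL) {
  grids <- list(m18, m38, m120)
  for (g in grids[-1])
    if (!isTRUE(all.equal(g@depthEdges, m18@depthEdges)) ||
        !isTRUE(all.equal(g@distEdges, m18@distEdges)))
      stop("composite channels must share grid geometry")
  keep <- seq_len(nrow(m18@mvbs))
  if (!is.null(excludeDist)) keep <- setdiff(keep, excludeDist)
  chan <- function(g) {
    m <- g@mvbs[keep, , drop = FALSE]
    rng <- range(m, na.rm = TRUE)
    x <- if (diff(rng) > 0) colorIndex(m, rng[1], rng[2]) else m * 0
    x <- 255 * (x / 255)^(1 / gamma)
    x <- pmin(255, x * brighten)
    x[is.na(x)] <- 0
    x
  }
  arr <- array(0, c(length(keep), ncol(m18@mvbs), 3))
  arr[, , 1] <- chan(m18); arr[, , 2] <- chan(m38); arr[, , 3] <- chan(m120)
  new("RgbComposite", rgb = arr, depthEdges = m18@depthEdges,
      distEdges = m18@distEdges[c(keep, max(keep) + 1L)],
      gamma = gamma, channels = c(red = 18, green = 38, blue = 120))
}

#' Write an RGB composite to a PNG file
#'
#' Renders depth down the image rows and along-transect distance across
#' the columns.
#'
#' @param composite an \linkS4class{RgbComposite}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeComposite <- function(composite, path) {
  a <- composite@rgb / 255
  img <- array(0, c(dim(a)[2], dim(a)[1], 3))
  for (k in 1:3) img[, , k] <- t(a[, , k])
  png::writePNG(img, path)
  invisible(path)
}
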