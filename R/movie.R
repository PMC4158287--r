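# Pixel-movie rendering and ROI trace extraction.
#
# Purkinje cell dendrites imaged from above appear as parasagittally
# aligned, tube-like structures; the movie renderer paints each dendrite as
# a narrow vertical stripe at its mediolateral position.

#' Render a CalciumExperiment to a pixel movie
#'
#' Paints each dendrite as a 1-3 pixel wide vertical stripe at its
#' mediolateral position, adds per-pixel Gaussian noise, and returns the
#' movie with its ROI masks. Optionally writes a multi-frame TIFF plus a
#' CSV pixel list of the masks. Movies are written in raw-fluorescence
#' units divided by \code{scale} so values fit the [0, 1] TIFF range;
#' dF/F is invariant to this gain.
#'
#' @param x a \linkS4class{CalciumExperiment} at frame resolution with an
#'   \code{"F"} assay.
#' @param config the \linkS4class{GeneratorConfig} (for movie geometry and
#'   noise).
#' @param file optional TIFF path.
#' @param maskFile optional CSV path for the mask pixel list.
#' @param pixelNoiseSd per-pixel noise SD in raw-fluorescence units
#'   (default \code{config@noiseSd * config@f0}).
#' @param seed RNG seed for pixel noise.
#' @return list with \code{movie} (rows x cols x frames array),
#'   \code{masks} (list of two-column pixel index matrices per dendrite)
#'   and \code{scale}.
#' @export
renderMovie <- function(x, config, file = NULL, maskFile = NULL,
                        pixelNoiseSd = config@noiseSd * config@f0,
                        seed = NULL) {
  stopifnot(is(x, "CalciumExperiment"))
  if (abs(samplePeriod(x) - config@framePeriod) > 1e-9)
    stop("movies are rendered at frame resolution; bin the traces first")
  if (is.null(seed)) seed <- config@seed
  Fm <- assay(x, "F")
  n <- nrow(Fm)
  nr <- config@movieShape[1]
  ncp <- config@movieShape[2]
  pos <- rowData(x)$position_um
  col0 <- round(pos / config@umPerPx) + 1L
  width <- max(1L, min(3L, floor(config@dendriteSpacing / config@umPerPx) - 1L))
  cols <- lapply(col0, function(cc) cc + seq_len(width) - 1L)
  if (any(unlist(cols) > ncp) || any(duplicated(unlist(cols))))
    stop("more dendrites than representable stripes in a ",
         nr, " x ", ncp, " field")
  masks <- lapply(cols, function(cc)
    cbind(row = rep(seq_len(nr), length(cc)),
          col = rep(cc, each = nr)))

  nf <- ncol(Fm)
  bg <- config@f0 / 2
  movie <- array(bg, dim = c(nr, ncp, nf))
  for (d in seq_len(n)) {
    for (cc in cols[[d]]) movie[, cc, ] <- rep(Fm[d, ], each = nr)
  }
  if (pixelNoiseSd > 0) {
    movie <- movie + .withSeed(seed * 307L + 11L,
                               array(stats::rnorm(length(movie), 0, pixelNoiseSd),
                                     dim = dim(movie)))
  }
  scale <- max(movie) * 1.05
  if (!is.null(file)) {
    frames <- lapply(seq_len(nf), function(f) movie[, , f] / scale)
    tiff::writeTIFF(frames, file, bits.per.sample = 16L)
  }
  if (!is.null(maskFile)) {
    df <- do.call(rbind, lapply(seq_len(n), function(d)
      data.frame(dendrite_id = d, row = masks[[d]][, "row"],
                 col = masks[[d]][, "col"])))
    utils::write.csv(df, maskFile, row.names = FALSE)
  }
  list(movie = movie, masks = masks, scale = scale)
}

#' Read a multi-frame TIFF movie
#'
#' @param file TIFF path.
#' @return rows x cols x frames numeric array.
#' @export
readMovie <- function(file) {
  frames <- tiff::readTIFF(file, all = TRUE)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Read an ROI mask pixel list
#'
#' @param file CSV with columns dendrite_id, row, col.
#' @return list of two-column pixel index matrices, one per dendrite.
#' @export
readMasks <- function(file) {
  df <- utils::read.csv(file)
  lapply(split(df, df$dendrite_id), function(m)
    cbind(row = m$row, col = m$col))
}

#' Extract mean ROI fluorescence from a movie
#'
#' Per frame, the mean over the mask's pixels; one trace per dendrite.
#' Overlapping masks are allowed (shared pixels contribute to both means).
#'
#' @param movie rows x cols x frames array.
#' @param masks list of two-column (row, col) pixel index matrices.
#' @return dendrite x frame matrix of raw fluorescence.
#' @export
extractRoiFluorescence <- function(movie, masks) {
  stopifnot(length(dim(movie)) == 3L)
  nf <- dim(movie)[3]
  flat <- matrix(movie, dim(movie)[1] * dim(movie)[2], nf)
  out <- matrix(NA_real_, length(masks), nf)
  for (d in seq_along(masks)) {
    m <- masks[[d]]
    if (is.null(dim(m)) || nrow(m) == 0L)
      stop("empty ROI mask for dendrite ", d)
    if (any(m[, 1] < 1 | m[, 1] > dim(movie)[1] |
            m[, 2] < 1 | m[, 2] > dim(movie)[2]))
      stop("mask for dendrite ", d, " exceeds movie bounds")
    idx <- (m[, 2] - 1L) * dim(movie)[1] + m[, 1]
    out[d, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  out
}
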