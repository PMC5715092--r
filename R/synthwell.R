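# Synthetic nanoliter-well plate generator. Emulates the statistical
# structure of real plates -- Poisson well occupancy with a mild multi-cell
# excess, square or round well walls, bright roughly circular cells,
# occasional debris and defocus, per-image illumination offsets -- so the
# whole counting pipeline can be exercised without a microscope.
#
# All randomness flows through R's RNG: callers fix results with set.seed()
# or via the seed argument of generatePlate().

#' Sample cell counts from an occupancy model
#'
#' Draws from Poisson(lambda), then with probability `clusterExcess`
#' increments each nonzero draw by one. With `clusterExcess = 0` the counts
#' are exactly Poisson; with `clusterExcess = 1` a count of exactly 1
#' becomes impossible (every occupied well gains a cell) while empty wells
#' remain possible.
#'
#' @param model an [OccupancyModel-class].
#' @param n number of wells to draw (default 1).
#' @return integer vector of non-negative cell counts.
#' @examples
#' set.seed(1)
#' table(sampleCellCount(occupancyModel(lambda = 0.2, clusterExcess = 0), 1e4))
#' @export
sampleCellCount <- function(model, n = 1L) {
  stopifnot(is(model, "OccupancyModel"))
  validObject(model)
  counts <- rpois(n, model@lambda)
  if (model@clusterExcess > 0) {
    nz <- counts > 0L
    counts[nz] <- counts[nz] + rbinom(sum(nz), 1L, model@clusterExcess)
  }
  counts
}

# uniform cell radius range at the native 511-px frame; scaled linearly for
# smaller frames (no pixel-size calibration is published, so the range is a
# plausible lymphocyte size on this optics)
.CELL_RADIUS_RANGE_511 <- c(8, 20)

# well interior mask and wall drawing; returns list(img, interior)
.drawWell <- function(geometry) {
  side <- geometry@imageSide
  wt <- geometry@wallThickness
  margin <- max(2, round(side / 128))
  img <- matrix(geometry@backgroundIntensity, side, side)
  xs <- matrix(seq_len(side), side, side)
  ys <- t(xs)
  if (geometry@shape == "square") {
    lo <- margin + 1
    hi <- side - margin
    inFrame <- xs >= lo & xs <= hi & ys >= lo & ys <= hi
    inInner <- xs >= lo + wt & xs <= hi - wt & ys >= lo + wt & ys <= hi - wt
    img[inFrame & !inInner] <- geometry@wallIntensity
    interior <- inInner
  } else {
    cx <- (side + 1) / 2
    r <- side / 2 - margin
    d <- sqrt((xs - cx)^2 + (ys - cx)^2)
    img[d <= r & d > r - wt] <- geometry@wallIntensity
    interior <- d <= r - wt
  }
  list(img = img, interior = interior, xs = xs, ys = ys)
}

# place nCells non-overlapping disk centers strictly inside the interior
.placeCells <- function(nCells, geometry, well, maxAttempts = 500L) {
  side <- geometry@imageSide
  radRange <- .CELL_RADIUS_RANGE_511 * side / 511
  radRange <- pmax(radRange, 2)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(nCells)) {
    placed <- FALSE
    for (att in seq_len(maxAttempts)) {
      r <- runif(1, radRange[1], radRange[2])
      cx <- runif(1, 1 + r, side - r)
      cy <- runif(1, 1 + r, side - r)
      # whole disk strictly inside the well interior
      probe <- rbind(c(cx + r, cy), c(cx - r, cy), c(cx, cy + r),
                     c(cx, cy - r), c(cx, cy))
      pi_ <- cbind(pmin(pmax(round(probe[, 1]), 1), side),
                   pmin(pmax(round(probe[, 2]), 1), side))
      if (!all(well$interior[pi_])) next
      if (nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
              radii + r + 1)) next
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", nCells, " non-overlapping cells in a ",
           geometry@shape, " well of side ", side,
           " after ", maxAttempts, " attempts")
  }
  list(centers = centers, radii = radii)
}

# paint one cell: bright dome with a darker rim, the bright-field look of an
# unstained lymphocyte
.paintCell <- function(img, well, cx, cy, r) {
  peak <- runif(1, 150, 230)
  d <- sqrt((well$xs - cx)^2 + (well$ys - cy)^2)
  rim <- d <= r & d > 0.7 * r
  body <- d <= 0.7 * r
  img[rim] <- 0.5 * img[rim]
  img[body] <- peak * (1 - 0.3 * (d[body] / (0.7 * r))^2)
  img
}

# low-contrast irregular polygon blob (debris)
.paintDebris <- function(img, well, geometry) {
  side <- geometry@imageSide
  nPieces <- sample.int(3L, 1L)
  for (p in seq_len(nPieces)) {
    ok <- FALSE
    for (att in 1:50) {
      cx <- runif(1, 1, side)
      cy <- runif(1, 1, side)
      ci <- c(pmin(pmax(round(cx), 1), side), pmin(pmax(round(cy), 1), side))
      if (well$interior[ci[1], ci[2]]) { ok <- TRUE; break }
    }
    if (!ok) next
    nv <- sample(5:8, 1L)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 8) * side / 511
    rad <- pmax(rad, 1.5)
    vx <- cx + rad * cos(ang)
    vy <- cy + rad * sin(ang)
    # even-odd point-in-polygon over a local window
    win <- max(rad) + 1
    xr <- max(1, floor(cx - win)):min(side, ceiling(cx + win))
    yr <- max(1, floor(cy - win)):min(side, ceiling(cy + win))
    px <- well$xs[xr, yr]
    py <- well$ys[xr, yr]
    inside <- matrix(FALSE, length(xr), length(yr))
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- xor(inside, crosses)
      j <- i
    }
    shade <- runif(1, -25, 25)
    img[xr, yr][inside] <- img[xr, yr][inside] + shade
  }
  img
}

#' Render one well image
#'
#' Draws the well wall (rectilinear for square wells, a circular ring for
#' round wells), places `min(count, maxRender)` non-overlapping bright cell
#' disks strictly inside the well boundary, then applies artifacts: debris
#' polygons, whole-image Gaussian defocus blur, a per-image uniform
#' intensity offset and pixel noise. Values are clipped to \[0, 255\] and
#' rounded to 8-bit gray levels. Given a fixed RNG state the render is a
#' pure function of its inputs.
#'
#' @param count non-negative integer number of cells in the well.
#' @param geometry a [WellGeometry-class].
#' @param artifacts an [ArtifactModel-class].
#' @param maxRender cap on drawn cells (default 5).
#' @return integer matrix of gray levels with attributes `debris` and
#'   `defocus` (logical artifact flags) and `count` (the input count).
#' @examples
#' set.seed(7)
#' img <- renderWell(1, wellGeometry("square", 128), artifactModel())
#' range(img)
#' @export
renderWell <- function(count, geometry, artifacts = artifactModel(),
                       maxRender = 5L) {
  stopifnot(count >= 0, is(geometry, "WellGeometry"),
            is(artifacts, "ArtifactModel"))
  validObject(geometry); validObject(artifacts)
  well <- .drawWell(geometry)
  img <- well$img
  nDraw <- min(count, maxRender)
  if (nDraw > 0) {
    pl <- .placeCells(nDraw, geometry, well)
    for (i in seq_len(nDraw))
      img <- .paintCell(img, well, pl$centers[i, 1], pl$centers[i, 2],
                        pl$radii[i])
  }
  debris <- runif(1) < artifacts@debrisProb
  if (debris) img <- .paintDebris(img, well, geometry)
  defocus <- runif(1) < artifacts@defocusProb
  if (defocus && artifacts@defocusBlurSigma > 0)
    img <- EBImage::gblur(img, sigma = artifacts@defocusBlurSigma)
  img <- img + runif(1, artifacts@intensityOffsetRange[1],
                     artifacts@intensityOffsetRange[2])
  if (artifacts@noiseSigma > 0)
    img <- img + matrix(rnorm(length(img), 0, artifacts@noiseSigma),
                        nrow(img))
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nrow(img))
  attr(img, "debris") <- debris
  attr(img, "defocus") <- defocus
  attr(img, "count") <- count
  img
}

#' Generate a labeled synthetic plate
#'
#' Draws a cell count per well from the occupancy model, renders every well
#' image and assembles the plate manifest. With `dir` set, images are
#' written as 8-bit grayscale PNGs plus a tab-separated manifest
#' (`<plateId>_manifest.tsv`); without it the images stay in memory. Two
#' runs with identical arguments (including `seed`) produce identical
#' plates.
#'
#' @param nWells number of wells on the plate (a physical plate has 3984).
#' @param geometry a [WellGeometry-class].
#' @param occupancy an [OccupancyModel-class].
#' @param artifacts an [ArtifactModel-class].
#' @param seed RNG seed for the plate.
#' @param plateId plate identifier used in well IDs and filenames.
#' @param dir output directory (created if needed), or `NULL` to keep the
#'   plate in memory.
#' @param keepImages keep rendered images in the returned object (default:
#'   only when not writing to disk, since a full-size plate is large).
#' @return a [WellDataset-class]; its manifest has columns `plate_id`,
#'   `well_id`, `filename`, `count`, `category`, `debris`, `defocus`.
#' @examples
#' pl <- generatePlate(10, wellGeometry("square", 128), occupancyModel(),
#'                     artifactModel(), seed = 1, plateId = "demo")
#' wellInfo(pl)[1:3, ]
#' @export
generatePlate <- function(nWells, geometry, occupancy = occupancyModel(),
                          artifacts = artifactModel(), seed = 1L,
                          plateId = "plate1", dir = NULL,
                          keepImages = is.null(dir)) {
  stopifnot(nWells >= 1, is(occupancy, "OccupancyModel"))
  validObject(occupancy)
  set.seed(seed)
  counts <- sampleCellCount(occupancy, nWells)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  images <- vector("list", nWells)
  debris <- logical(nWells)
  defocus <- logical(nWells)
  fnames <- sprintf("%s_w%05d.png", plateId, seq_len(nWells))
  for (i in seq_len(nWells)) {
    img <- renderWell(counts[i], geometry, artifacts,
                      maxRender = occupancy@maxRender)
    debris[i] <- attr(img, "debris")
    defocus[i] <- attr(img, "defocus")
    if (!is.null(dir))
      png::writePNG(img / 255, file.path(dir, fnames[i]))
    if (keepImages) {
      attributes(img) <- attributes(img)["dim"]
      images[[i]] <- img
    }
  }
  info <- data.frame(
    plate_id = plateId,
    well_id = sprintf("%s_w%05d", plateId, seq_len(nWells)),
    filename = fnames,
    count = counts,
    category = as.character(countToCategory(counts)),
    debris = debris,
    defocus = defocus,
    stringsAsFactors = FALSE)
  ds <- new("WellDataset", images = if (keepImages) images else list(),
            info = info)
  if (!is.null(dir))
    writeManifest(ds, file.path(dir, paste0(plateId, "_manifest.tsv")))
  ds
}
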