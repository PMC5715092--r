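# Dataset I/O, min-max normalization and geometric augmentation.
#
# The manifest dialect is a TSV with header
#   well_id  filename  count  category  debris  defocus
# with categories serialized as 0,1,2,gt2 and the artifact flags as 0/1.
# One manifest describes one plate; the plate ID is the part of the file
# name before "_manifest.tsv" (or the full base name).

#' Write a plate manifest
#'
#' @param dataset a [WellDataset-class] holding one plate.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(dataset, path) {
  info <- wellInfo(dataset)
  out <- data.frame(well_id = info$well_id, filename = info$filename,
                    count = info$count,
                    category = as.character(info$category),
                    debris = as.integer(info$debris),
                    defocus = as.integer(info$defocus))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.plateIdFromPath <- function(path) {
  base <- sub("\\.tsv$", "", basename(path))
  sub("_manifest$", "", base)
}

#' Read a plate manifest
#'
#' Round-trips losslessly with [writeManifest()]. Each record is validated;
#' a malformed row (e.g. category `3`, which lies beyond `gt2`) is an error
#' naming the offending row.
#'
#' @param path manifest TSV path.
#' @param plateId plate identifier; by default derived from the file name.
#' @return manifest data.frame with a `plate_id` column prepended.
#' @export
readManifest <- function(path, plateId = .plateIdFromPath(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  info <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(well_id = "character",
                                    filename = "character",
                                    category = "character"))
  need <- c("well_id", "filename", "count", "category", "debris", "defocus")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("manifest ", path, " lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!info$category %in% CATEGORY_LEVELS)
  if (length(bad))
    stop("manifest ", path, ": invalid category '", info$category[bad[1]],
         "' in row ", bad[1], " (valid: ",
         paste(CATEGORY_LEVELS, collapse = ", "), ")")
  badc <- which(is.na(info$count) | info$count < 0)
  if (length(badc))
    stop("manifest ", path, ": invalid count in row ", badc[1])
  data.frame(plate_id = plateId, info[, need],
             stringsAsFactors = FALSE)
}

#' Load a dataset of well images from manifests
#'
#' Reads one or more plate manifests and the PNG images they reference
#' (resolved relative to each manifest's directory). Each image must exist,
#' be square, and be 8-bit grayscale; violations are reported with the
#' offending record.
#'
#' @param manifestPaths character vector of manifest TSV paths (one per
#'   plate).
#' @param readImages read the pixel data (default TRUE); with FALSE only
#'   manifests are loaded.
#' @return a [WellDataset-class] with one record per manifest row, plates
#'   preserved via the `plate_id` column.
#' @export
loadDataset <- function(manifestPaths, readImages = TRUE) {
  parts <- lapply(manifestPaths, function(path) {
    info <- readManifest(path)
    images <- list()
    if (readImages) {
      dirn <- dirname(path)
      images <- lapply(seq_len(nrow(info)), function(i) {
        f <- file.path(dirn, info$filename[i])
        if (!file.exists(f))
          stop("image missing for well ", info$well_id[i], ": ", f)
        px <- png::readPNG(f)
        if (length(dim(px)) == 3L) {
          if (dim(px)[3] > 1 &&
              !all(px[, , 1] == px[, , 2] & px[, , 1] == px[, , 3]))
            stop("image for well ", info$well_id[i], " is not grayscale: ", f)
          px <- px[, , 1]
        }
        if (nrow(px) != ncol(px))
          stop("image for well ", info$well_id[i], " is not square: ", f,
               " (", nrow(px), " x ", ncol(px), ")")
        matrix(as.integer(round(px * 255)), nrow(px))
      })
    }
    new("WellDataset", images = images, info = info)
  })
  Reduce(function(a, b) c(a, b), parts)
}

#' Min-max normalize a well image
#'
#' Affinely rescales gray levels so the minimum maps to 0 and the maximum
#' to 255, removing per-image illumination offsets. The map is idempotent:
#' an image already spanning \[0, 255\] is returned unchanged. A constant
#' image (no content) maps to all zeros.
#'
#' @param image numeric matrix of gray levels.
#' @return numeric matrix with min 0 and max 255 (all 0 for constant
#'   input). Values are kept at full precision, not re-quantized.
#' @examples
#' m <- matrix(c(10, 60, 110, 60), 2)
#' normalizeImage(m)   # 60 maps to 127.5
#' @export
normalizeImage <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) return(matrix(0, nrow(image), ncol(image)))
  (image - lo) * (255 / (hi - lo))
}

# counter-clockwise quarter rotations of a matrix stored row-major with the
# origin at top-left (fixed so augmented fixtures are bit-reproducible)
.rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Randomly augment a well image
#'
#' With probability `1 - transformProb` the image is returned unchanged;
#' otherwise one transform is drawn uniformly from mirror flip and
#' counter-clockwise rotation by 90, 180 or 270 degrees. These are pixel
#' permutations: the label and the multiset of gray levels never change.
#' `invert = "intensity"` replaces the mirror flip with gray-level
#' inversion (255 - p), the alternative reading of "inverted".
#'
#' @param image numeric matrix (square).
#' @param transformProb probability of applying a transform (default 0.2).
#' @param invert `"mirror"` (default) or `"intensity"`.
#' @return the (possibly transformed) image matrix.
#' @export
augmentImage <- function(image, transformProb = 0.2,
                         invert = c("mirror", "intensity")) {
  invert <- match.arg(invert)
  stopifnot(is.matrix(image), nrow(image) == ncol(image),
            transformProb >= 0, transformProb <= 1)
  if (runif(1) >= transformProb) return(image)
  k <- sample.int(4L, 1L)
  switch(k,
    if (invert == "mirror") image[, ncol(image):1, drop = FALSE]
    else 255 - image,
    .rot90(image),
    .rot90(.rot90(image)),
    .rot90(.rot90(.rot90(image))))
}

# network input conditioning: min-max normalize, then scale to [0, 1]
.prepareImage <- function(image) normalizeImage(image) / 255

# stack a list of equally-sized matrices into an (h, w, n) array
.stackImages <- function(images) {
  h <- nrow(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(h, h, length(images)))
}
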