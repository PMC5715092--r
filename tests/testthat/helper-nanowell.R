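# Shared fixture builders. Everything is generated in code at test time;
# desk-scale runs use 64-px frames so the whole suite stays fast.

smallGeometry <- function(shape = "square", side = 64L) {
  wellGeometry(shape, imageSide = side)
}

cleanArtifacts <- function() {
  artifactModel(debrisProb = 0, defocusProb = 0,
                intensityOffsetRange = c(0, 0), noiseSigma = 0)
}

# benchmark evaluation tables printed for the square-well test set
# (7,920 wells): concordant diagonal plus the discordance off-diagonals
benchmarkDiagonal <- c(6420L, 1150L, 193L, 24L)
benchmarkOffDiagonal <- matrix(c(
   0, 38,  0, 0,
  47,  0, 28, 0,
   0, 15,  0, 1,
   0,  0,  4, 0), 4L, 4L, byrow = TRUE)

# synthetic prediction table with a given concordance structure: h values
# and agreement flags are supplied directly
makePredictions <- function(h, concordant,
                            truth = rep("0", length(h))) {
  truth <- asCategory(truth)
  predicted <- as.character(truth)
  wrong <- which(!concordant)
  predicted[wrong] <- vapply(as.character(truth[wrong]), function(tc)
    setdiff(CATEGORY_LEVELS, tc)[1], character(1))
  data.frame(well_id = sprintf("w%03d", seq_along(h)),
             predicted = factor(predicted, levels = CATEGORY_LEVELS),
             highest_output = h, stringsAsFactors = FALSE)
}

# independent cell counter used as rendering oracle: threshold the clean
# render above the brightest non-cell structure, then count connected
# components with EBImage
countBlobs <- function(img) {
  mask <- img > 140
  max(EBImage::bwlabel(mask))
}
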