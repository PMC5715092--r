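# Evaluation arithmetic: confusion matrices and their rates, the
# discordance matrix, the censored-Poisson occupancy fit, and the two
# hypothesis tests used to characterize the benchmark (chi-square on the
# majority-vote comparison, Mann-Whitney on confidence separation).

#' Build a 4x4 technician-versus-predictor confusion matrix
#'
#' @param truth factor/character of true categories (technician calls).
#' @param predicted factor/character of predicted categories, same length.
#' @return a [ConfusionMatrix-class]; entry (i, j) counts wells with truth
#'   category i and predicted category j.
#' @examples
#' confusionMatrix(c("0", "1", "1"), c("0", "1", "2"))
#' @export
confusionMatrix <- function(truth, predicted) {
  truth <- asCategory(truth)
  predicted <- asCategory(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  m <- table(truth = truth, predicted = predicted)
  counts <- matrix(as.integer(m), 4L, 4L,
                   dimnames = list(truth = CATEGORY_LEVELS,
                                   predicted = CATEGORY_LEVELS))
  new("ConfusionMatrix", counts = counts)
}

#' Assemble a ConfusionMatrix from concordant and discordant counts
#'
#' Convenience constructor from the two published table forms: the
#' concordant diagonal and the off-diagonal discordance matrix.
#'
#' @param diagonal length-4 vector of concordant counts per category.
#' @param offDiagonal 4x4 matrix of discordant counts (diagonal ignored;
#'   rows = truth, cols = predicted).
#' @return a [ConfusionMatrix-class].
#' @export
confusionFromTables <- function(diagonal, offDiagonal) {
  stopifnot(length(diagonal) == 4L, all(dim(offDiagonal) == c(4L, 4L)))
  counts <- offDiagonal
  diag(counts) <- diagonal
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(truth = CATEGORY_LEVELS,
                                   predicted = CATEGORY_LEVELS))
  new("ConfusionMatrix", counts = counts)
}

#' Reference benchmark confusion matrix (square wells)
#'
#' The published square-well benchmark evaluation: 7,920 independent test
#' wells labeled by two trained technicians and classified by the trained
#' network, with concordant diagonal (6420, 1150, 193, 24) and 133
#' discordant wells. Shipped as package data so the evaluation arithmetic
#' can be exercised against printed values.
#'
#' @return a [ConfusionMatrix-class].
#' @examples
#' categoryRates(referenceConfusionMatrix())$overall   # 0.98321
#' @export
referenceConfusionMatrix <- function() {
  off <- matrix(c(
     0, 38,  0, 0,
    47,  0, 28, 0,
     0, 15,  0, 1,
     0,  0,  4, 0), 4L, 4L, byrow = TRUE)
  confusionFromTables(c(6420L, 1150L, 193L, 24L), off)
}

#' Reference majority-vote comparison table
#'
#' For the 133 discordant benchmark wells, a panel of 10 independent
#' observers produced majority-vote labels; this 2x2 table counts wells on
#' which the majority agreed with the technicians versus with the network
#' (concordant/discordant x rater pair).
#'
#' @return 2x2 integer matrix (rows concordant/discordant, columns
#'   technicians/network).
#' @export
referenceMajorityVoteTable <- function() {
  matrix(c(87L, 46L, 36L, 97L), 2L, 2L,
         dimnames = list(c("concordant", "discordant"),
                         c("technicians", "network")))
}

#' Sensitivities, positive predictive values and overall concordance
#'
#' Per truth category the sensitivity is concordant / row total; per
#' predicted category the positive predictive value is concordant / column
#' total; overall concordance is trace / n. Rates whose marginal is zero
#' are undefined and reported as NA rather than silently 0.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with `sensitivity` (named length-4), `ppv` (named
#'   length-4), `overall`, and `n`. All rates at full precision.
#' @examples
#' categoryRates(referenceConfusionMatrix())
#' @export
categoryRates <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cmCounts(cm)
  n <- sum(m)
  if (n == 0L) stop("all-zero confusion matrix")
  rs <- rowSums(m)
  cs <- colSums(m)
  sens <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  ppv <- ifelse(cs > 0, diag(m) / cs, NA_real_)
  names(sens) <- names(ppv) <- CATEGORY_LEVELS
  list(sensitivity = sens, ppv = ppv, overall = sum(diag(m)) / n, n = n)
}

#' Discordance matrix and totals
#'
#' Masks the concordant diagonal and tabulates the discordant wells per
#' truth row, per predicted column, and overall (n minus the trace).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with `matrix` (diagonal NA), `rowTotals`, `colTotals` and
#'   `total`.
#' @examples
#' discordanceMatrix(referenceConfusionMatrix())$total   # 133
#' @export
discordanceMatrix <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cmCounts(cm)
  off <- m
  diag(off) <- NA_integer_
  list(matrix = off,
       rowTotals = rowSums(off, na.rm = TRUE),
       colTotals = colSums(off, na.rm = TRUE),
       total = sum(m) - sum(diag(m)))
}

# censored-Poisson multinomial log-likelihood of categorized counts
.occLogLik <- function(lambda, n0, n1, n2, ngt2) {
  p <- dpois(0:2, lambda)
  ps <- c(p, max(1 - sum(p), 0))
  ns <- c(n0, n1, n2, ngt2)
  sum(ifelse(ns > 0, ns * log(ps), 0))
}

#' Censored-Poisson maximum-likelihood fit of well occupancy
#'
#' Fits the Poisson rate lambda (mean cells per well) to the categorized
#' counts (n0, n1, n2, n_gt2) by maximizing the multinomial likelihood with
#' cell probabilities P(0), P(1), P(2) and 1 - P(0) - P(1) - P(2): the
#' more-than-2 class is treated as right-censored, since counts above 2 are
#' not resolved. The optimum is located numerically to better than 1e-7 in
#' lambda; the all-empty boundary (n0 = total) yields lambda = 0 exactly.
#'
#' @param n0,n1,n2,ngt2 non-negative well counts per category.
#' @return a [PoissonOccupancyFit-class].
#' @examples
#' lambdaHat(fitPoissonOccupancy(8169, 1651, 167, 13))
#' @export
fitPoissonOccupancy <- function(n0, n1, n2, ngt2) {
  counts <- c(n0, n1, n2, ngt2)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total < 1) stop("total count must be at least 1")
  if (n0 == total)
    return(new("PoissonOccupancyFit", lambdaHat = 0,
               logLik = 0, counts = counts))
  if (n0 == 0 && n1 == 0 && n2 == 0)
    stop("all wells censored at >2 cells: lambda is unbounded")
  ll <- function(l) .occLogLik(l, n0, n1, n2, ngt2)
  # crude bracket from the uncensored mean, then refine
  upper <- max(10, 3 * (n1 + 2 * n2 + 3 * ngt2) / total)
  opt <- optimize(ll, interval = c(1e-10, upper), maximum = TRUE,
                  tol = 1e-9)
  new("PoissonOccupancyFit", lambdaHat = opt$maximum,
      logLik = opt$objective, counts = counts)
}

#' Expected category proportions under a Poisson occupancy
#'
#' @param lambda Poisson rate (>= 0).
#' @return named length-4 vector (P(0), P(1), P(2), P(>2)); non-negative
#'   and summing to 1.
#' @examples
#' expectedPoissonProportions(0.202247)
#' @export
expectedPoissonProportions <- function(lambda) {
  stopifnot(lambda >= 0)
  p <- dpois(0:2, lambda)
  out <- c(p, max(1 - sum(p), 0))
  names(out) <- CATEGORY_LEVELS
  out
}

#' Chi-square comparison of two concordance rates
#'
#' Pearson chi-square test on a 2x2 concordant/discordant-by-rater-pair
#' table, two sided. Without continuity correction the statistic is the
#' closed form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); a Yates-corrected
#' variant is available by flag.
#'
#' @param table 2x2 matrix of non-negative counts with positive marginals.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `pValue` and `df` (= 1).
#' @examples
#' compareConcordanceChi2(referenceMajorityVoteTable())$pValue   # < 1e-4
#' @export
compareConcordanceChi2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  ht <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), pValue = ht$p.value, df = 1L)
}

#' Confidence separation between concordant and discordant wells
#'
#' Two-sided Mann-Whitney U test comparing the log-transformed highest
#' outputs of concordant and discordant wells. As a rank statistic it is
#' invariant to the (monotone) log transform; the transform matches how the
#' confidence distributions are usually displayed. Exact enumeration is
#' used for small tie-free samples, the tie-corrected normal approximation
#' otherwise.
#'
#' @param hConcordant,hDiscordant numeric vectors of highest outputs (both
#'   non-empty, values in (0, 1\]).
#' @return list with `U` (statistic for the concordant group) and `pValue`.
#' @export
confidenceSeparationTest <- function(hConcordant, hDiscordant) {
  if (!length(hConcordant) || !length(hDiscordant))
    stop("both groups must be non-empty")
  stopifnot(all(hConcordant > 0), all(hDiscordant > 0))
  ht <- suppressWarnings(
    wilcox.test(log(hConcordant), log(hDiscordant),
                alternative = "two.sided", exact = NULL))
  list(U = unname(ht$statistic), pValue = ht$p.value)
}
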