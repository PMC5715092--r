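# The enhanced system: confidence-threshold triage. A well whose highest
# posterior output h(s) falls strictly below a threshold t is "ambiguous"
# and routed to a human (who is assumed to resolve it correctly) or
# excluded; the remaining wells keep the network's call. Because a 4-class
# softmax maximum is always >= 0.25, thresholds at or below 0.25 flag
# nothing.

.triagePolicies <- c("resolve_by_human", "exclude")

.getH <- function(predictions) {
  if (is.data.frame(predictions)) {
    stopifnot(all(c("well_id", "highest_output") %in% names(predictions)))
    list(h = predictions$highest_output,
         ids = as.character(predictions$well_id))
  } else {
    h <- as.numeric(predictions)
    ids <- if (!is.null(names(predictions))) names(predictions)
           else as.character(seq_along(h))
    list(h = h, ids = ids)
  }
}

#' Flag ambiguous wells by thresholding the highest output
#'
#' Partitions the wells into the ambiguous set `{s : h(s) < t}` (strict
#' inequality; ties at t are retained) and its complement.
#'
#' @param predictions data.frame from [predictWells()], or a numeric vector
#'   of highest outputs (optionally named by well ID).
#' @param t highest-output cutoff in (0, 1].
#' @return a [TriageResult-class] (no concordance; see
#'   [concordanceWithTriage()]).
#' @examples
#' flagAmbiguous(c(a = 0.9, b = 0.6, c = 0.4), t = 0.5)  # only c ambiguous
#' @export
flagAmbiguous <- function(predictions, t) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0, t <= 1)
  g <- .getH(predictions)
  amb <- g$h < t
  new("TriageResult", threshold = t, policy = "none",
      ambiguousIds = g$ids[amb], retainedIds = g$ids[!amb],
      realizedProportion = mean(amb), concordance = NA_real_)
}

#' Derive the threshold achieving a target ambiguous proportion
#'
#' Returns the largest observed highest-output value usable as threshold
#' such that the realized ambiguous fraction does not exceed `p` (the
#' empirical quantile convention that never overshoots the human workload).
#' With duplicated h values the realized fraction can undershoot the
#' target, never overshoot it. At `p = 0` the threshold is the minimum
#' observed h, flagging nothing.
#'
#' @param predictions as in [flagAmbiguous()].
#' @param p target ambiguous proportion in \[0, 1).
#' @return list with `threshold` and `realizedProportion`.
#' @examples
#' thresholdForProportion(c(0.3, 0.5, 0.7, 0.9), p = 0.25)  # t = 0.5
#' @export
thresholdForProportion <- function(predictions, p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p < 1)
  g <- .getH(predictions)
  h <- g$h
  if (!length(h)) stop("no predictions supplied")
  cand <- sort(unique(h))
  frac <- vapply(cand, function(t) mean(h < t), numeric(1))
  t <- cand[max(which(frac <= p))]
  list(threshold = t, realizedProportion = mean(h < t))
}

#' Concordance rate under a triage policy
#'
#' Computes the concordance between predictions and truth after triage at
#' threshold `t`. Under `resolve_by_human` the ambiguous wells are assumed
#' to be judged by technicians and all become concordant, so the rate is
#' (concordant retained + ambiguous) / total; under `exclude` the ambiguous
#' wells are dropped and the rate is concordant retained / retained. At a
#' threshold at or below the minimum h both equal the raw concordance.
#'
#' @param predictions data.frame from [predictWells()] (needs `well_id`,
#'   `predicted`, `highest_output`).
#' @param truth factor/character of true categories, parallel to
#'   `predictions`.
#' @param t threshold in (0, 1].
#' @param policy `"resolve_by_human"` or `"exclude"`.
#' @return a [TriageResult-class] with the concordance filled in.
#' @export
concordanceWithTriage <- function(predictions, truth, t,
                                  policy = c("resolve_by_human",
                                             "exclude")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(predictions),
            all(c("well_id", "predicted", "highest_output") %in%
                  names(predictions)))
  truth <- asCategory(truth)
  if (length(truth) != nrow(predictions))
    stop("predictions (", nrow(predictions), ") and truth (", length(truth),
         ") differ in length")
  res <- flagAmbiguous(predictions, t)
  amb <- predictions$highest_output < t
  conc <- asCategory(predictions$predicted) == truth
  n <- nrow(predictions)
  rate <- if (policy == "resolve_by_human") {
    (sum(conc & !amb) + sum(amb)) / n
  } else {
    nRet <- sum(!amb)
    if (nRet == 0L) NA_real_ else sum(conc & !amb) / nRet
  }
  initialize(res, policy = policy, concordance = rate)
}

#' Concordance as a function of the ambiguous proportion
#'
#' Sweeps a grid of target ambiguous proportions; for each, derives the
#' threshold via [thresholdForProportion()] and evaluates the concordance
#' under both policies. Under the resolve policy the curve is monotone
#' non-decreasing in the proportion.
#'
#' @param predictions,truth as in [concordanceWithTriage()].
#' @param proportions numeric grid in \[0, 1) (default
#'   `c(0, 0.01, 0.05, 0.10)`).
#' @return data.frame with one row per (proportion, policy): `proportion`,
#'   `threshold`, `realizedProportion`, `policy`, `concordance`.
#' @export
concordanceCurve <- function(predictions, truth,
                             proportions = c(0, 0.01, 0.05, 0.10)) {
  stopifnot(length(proportions) > 0, all(proportions >= 0),
            all(proportions < 1))
  rows <- lapply(sort(proportions), function(p) {
    th <- thresholdForProportion(predictions, p)
    do.call(rbind, lapply(.triagePolicies, function(pol) {
      r <- concordanceWithTriage(predictions, truth, th$threshold, pol)
      data.frame(proportion = p, threshold = th$threshold,
                 realizedProportion = th$realizedProportion, policy = pol,
                 concordance = r@concordance, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
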