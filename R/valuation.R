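#' Opposite normalization of an interval onto [-1, 1]
#'
#' Affine map sending the lower endpoint a to +1 and the upper endpoint b to
#' -1: \eqn{x \mapsto \frac{2}{b-a}\left(\frac{a+b}{2} - x\right)}. Applied
#' to data values on [0, 1] this gives \eqn{\tilde D = 2(0.5 - D)} and to
#' contribution credits on [0, 0.5] it gives \eqn{\tilde r = 4(0.25 - r)}.
#'
#' @param x value(s) in [a, b].
#' @param a,b interval endpoints, a < b.
#' @return The mapped value(s) in [-1, 1].
#' @examples
#' scaleOpposite(0, 0, 1)     # +1
#' scaleOpposite(0.25, 0, 0.5) # 0
#' @export
scaleOpposite <- function(x, a, b) {
  if (length(a) != 1L || length(b) != 1L || !is.finite(a) || !is.finite(b) ||
      a >= b)
    stop("interval endpoints must satisfy a < b", call. = FALSE)
  if (any(x < a | x > b, na.rm = TRUE))
    stop(sprintf("values must lie in [%g, %g]", a, b), call. = FALSE)
  (2 / (b - a)) * ((a + b) / 2 - x)
}

#' Reward factors from a sheet and its pseudo truth
#'
#' Computes the factor set of the reward algorithm. For each (label, image)
#' cell, the correct-answer rate \eqn{p_{kj}} is the fraction of annotators
#' whose value matches the pseudo answer; the data value is
#' \eqn{D_{kj} = 1 - p_{kj}}, so harder, more-contested cells are worth
#' more. The task value \eqn{T_k} averages \eqn{D_{kj}} over images; the
#' contribution credit is \eqn{r_{kji} = 0.5} for a wrong answer and 0 for a
#' correct one; the normalized time mean \eqn{\bar t_k} divides each label's
#' mean labeling time by the sum over labels. Scaled forms come from
#' [scaleOpposite()] on the stated ranges.
#'
#' @param sheet an [AnnotationSheet-class].
#' @param pseudo a [PseudoTruth-class] with the same (label, image) domain;
#'   defaults to \code{pseudoAnswer(sheet)}.
#' @return A [RewardFactors-class] with an all-inclusive quality-gate mask.
#' @export
computeFactors <- function(sheet, pseudo = pseudoAnswer(sheet)) {
  stopifnot(is(sheet, "AnnotationSheet"), is(pseudo, "PseudoTruth"))
  I <- nAnnotators(sheet); J <- nImages(sheet); K <- nLabels(sheet)
  if (!identical(dim(pseudo@consensus), c(K, J)))
    stop("pseudo truth does not match the sheet's (label, image) domain",
         call. = FALSE)
  a <- sheet@annotations                       # I x J x K
  consIJK <- aperm(array(pseudo@consensus, dim = c(K, J, I)), c(3L, 2L, 1L))
  correct <- a == consIJK                      # I x J x K
  p <- t(colSums(correct, dims = 1L)) / I      # K x J correct-answer rate
  D <- 1 - p
  Tk <- rowMeans(D)
  r <- 0.5 * aperm(1 - (correct * 1), c(3L, 2L, 1L))  # K x J x I
  ## timings is I x J x K column-major, so matrix(., ncol = K) stacks all
  ## (i, j) entries of label k into column k
  labelTime <- colMeans(matrix(sheet@timings, ncol = K))
  tbar <- labelTime / sum(labelTime)
  dnKJ <- list(label = labelNames(sheet), image = imageIds(sheet))
  dimnames(D) <- dnKJ
  dimnames(r) <- c(dnKJ, list(annotator = annotatorIds(sheet)))
  names(Tk) <- names(tbar) <- labelNames(sheet)
  incl <- matrix(TRUE, I, K,
                 dimnames = list(annotator = annotatorIds(sheet),
                                 label = labelNames(sheet)))
  new("RewardFactors", D = D, taskValue = Tk, timeMean = tbar, r = r,
      Dscaled = scaleOpposite(D, 0, 1), rscaled = scaleOpposite(r, 0, 0.5),
      included = incl)
}

#' Allocate a token budget across annotators
#'
#' Turns reward factors into per-annotator token shares. Each annotator's
#' unnormalized score is
#' \deqn{S_i = \sum_k \chi_{ik} (T_k + \bar t_k) \sum_j W_{kj}\,
#'   \tilde r_{kji},}
#' where \eqn{\chi_{ik}} is the quality-gate mask, and \eqn{W_{kj}} is the
#' opposite-scaled data value \eqn{\tilde D_{kj}} (mode \code{"scaled_D"},
#' the default) or the raw \eqn{D_{kj}} (mode \code{"unscaled_D"}, in which
#' unanimous cells contribute nothing and only contested cells carry
#' value — but below-average annotators can then score negative, which is
#' an error). Shares are \eqn{B \cdot S_i / \sum_i S_i}, so the budget is
#' conserved exactly.
#'
#' @param factors a [RewardFactors-class].
#' @param budget total token amount, > 0.
#' @param mode \code{"scaled_D"} (default) or \code{"unscaled_D"}.
#' @param rounding if TRUE, round shares to integer tokens by largest
#'   remainder, preserving the budget total.
#' @return A [RewardAllocation-class].
#' @section Errors and fallbacks:
#' When every score is zero (e.g. a fully unanimous sheet in unscaled
#' mode) the budget is split equally with a warning. A strictly negative or
#' zero score for some — but not all — annotators is an error: a scheme
#' paying negative tokens is meaningless, and the sanctioned remedy is the
#' quality gate, not clamping.
#' @export
rewardAllocation <- function(factors, budget,
                             mode = c("scaled_D", "unscaled_D"),
                             rounding = FALSE) {
  stopifnot(is(factors, "RewardFactors"))
  mode <- match.arg(mode)
  if (length(budget) != 1L || !is.finite(budget) || budget <= 0)
    stop("budget must be a single positive number", call. = FALSE)
  W <- if (mode == "unscaled_D") factors@D else factors@Dscaled
  I <- dim(factors@r)[3L]
  ids <- dimnames(factors@r)[[3L]]
  weight <- factors@taskValue + factors@timeMean       # length K
  S <- vapply(seq_len(I), function(i) {
    rs <- array(factors@rscaled[, , i], dim = dim(W))
    sum(factors@included[i, ] * weight * rowSums(W * rs))
  }, numeric(1))
  names(S) <- ids
  note <- character()
  if (all(abs(S) < 1e-12)) {
    note <- "all annotator scores are zero (no discordance); splitting the budget equally"
    warning(note, call. = FALSE)
    share <- rep(budget / I, I)
  } else if (any(S <= 0)) {
    stop("degenerate annotator score (S <= 0 for ",
         paste(ids[S <= 0], collapse = ", "),
         ") - apply the quality gate or drop the annotator first",
         call. = FALSE)
  } else {
    share <- budget * S / sum(S)
  }
  names(share) <- ids
  if (rounding) share <- roundLargestRemainder(share, budget)
  new("RewardAllocation", budget = as.numeric(budget), score = S,
      share = share, mode = mode, note = note)
}

## Largest-remainder rounding to integer tokens; totals are preserved.
roundLargestRemainder <- function(share, budget) {
  if (abs(budget - round(budget)) > 1e-9)
    stop("integer rounding needs an integer budget", call. = FALSE)
  fl <- floor(share)
  left <- round(budget - sum(fl))
  rem <- share - fl
  add <- rep(0, length(share))
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    add[ord[seq_len(left)]] <- 1
  }
  out <- fl + add
  names(out) <- names(share)
  out
}

#' End-to-end evaluation of an annotated dataset
#'
#' Runs the full pipeline: agreement accounting, majority-vote pseudo
#' truth, optional kappa quality gate against an AI reference, reward
#' factors, and budget allocation.
#'
#' @param sheet an [AnnotationSheet-class].
#' @param budget total token amount to distribute.
#' @param ai optional [AIReference-class]; when supplied the quality gate is
#'   applied before allocation and ties in the consensus defer to the AI.
#' @param threshold kappa inclusion threshold for the gate.
#' @param mode data-value weight mode passed to [rewardAllocation()].
#' @param rounding integer-token rounding flag.
#' @return Named list with elements \code{summary}
#'   ([AgreementSummary-class]), \code{pseudo}, \code{factors}, \code{gate}
#'   (a [GateReport-class] or NULL), and \code{allocation}.
#' @examples
#' sc <- cxrScenario(seed = 11)
#' sim <- simulateStudy(sc$world, sc$profiles, sc$aiAccuracy)
#' res <- evaluateDataset(sim$sheet, budget = 1000, ai = sim$ai)
#' shares(res$allocation)
#' @export
evaluateDataset <- function(sheet, budget, ai = NULL, threshold = 0.05,
                            mode = c("scaled_D", "unscaled_D"),
                            rounding = FALSE) {
  mode <- match.arg(mode)
  summ <- agreementSummary(sheet)
  pseudo <- pseudoAnswer(sheet, ai = ai)
  factors <- computeFactors(sheet, pseudo)
  gate <- NULL
  if (!is.null(ai)) {
    gate <- qcGate(sheet, ai, threshold = threshold)
    factors <- applyGate(factors, gate)
  }
  alloc <- rewardAllocation(factors, budget, mode = mode,
                            rounding = rounding)
  list(summary = summ, pseudo = pseudo, factors = factors, gate = gate,
       allocation = alloc)
}
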