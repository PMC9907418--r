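#' Quality gate: screen annotators against an AI reference
#'
#' Treats the AI reference predictions as a temporary ground truth and
#' computes Cohen's kappa between each annotator and the AI on each label.
#' A pair (annotator, label) passes the gate iff kappa exceeds the
#' threshold — the operational test that the annotator predicts better than
#' random selection (coin tossing) on that label. A label on which the 2x2
#' table is degenerate (no chance variation) is excluded with reason
#' \code{"degenerate"} rather than crashing.
#'
#' @param sheet an [AnnotationSheet-class].
#' @param ai an [AIReference-class] covering every (image, label) of the
#'   sheet.
#' @param threshold inclusion threshold on kappa (default 0.05).
#' @return A [GateReport-class].
#' @examples
#' sc <- cxrScenario(seed = 3)
#' sim <- simulateStudy(sc$world, sc$profiles, sc$aiAccuracy)
#' report <- qcGate(sim$sheet, sim$ai)
#' table(report@included)
#' @export
qcGate <- function(sheet, ai, threshold = 0.05) {
  stopifnot(is(sheet, "AnnotationSheet"), is(ai, "AIReference"))
  if (length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a single finite number", call. = FALSE)
  if (!all(imageIds(sheet) %in% imageIds(ai)) ||
      !all(labelNames(sheet) %in% labelNames(ai)))
    stop("AI reference must cover every (image, label) of the sheet",
         call. = FALSE)
  pred <- ai@predictions[imageIds(sheet), labelNames(sheet), drop = FALSE]
  I <- nAnnotators(sheet); K <- nLabels(sheet)
  dn <- list(annotator = annotatorIds(sheet), label = labelNames(sheet))
  kap <- matrix(NA_real_, I, K, dimnames = dn)
  for (i in seq_len(I)) for (k in seq_len(K)) {
    kap[i, k] <- withCallingHandlers(
      cohenKappa(sheet@annotations[i, , k], pred[, k]),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  incl <- !is.na(kap) & kap > threshold
  reason <- matrix("", I, K, dimnames = dn)
  reason[is.na(kap)] <- "degenerate"
  reason[!incl & !is.na(kap)] <- "kappa<=threshold"
  new("GateReport", kappa = kap, threshold = as.numeric(threshold),
      included = incl, reason = reason)
}

#' Apply a gate report to reward factors
#'
#' Masks the factor set so that excluded (annotator, label) pairs
#' contribute zero to that annotator's score sum. With an all-pass report
#' the factors are returned unchanged. An annotator excluded on every label
#' is flagged with a warning; [rewardAllocation()] will then refuse to pay
#' a zero score unless the sheet is fully unanimous.
#'
#' @param factors a [RewardFactors-class].
#' @param report a [GateReport-class] with matching annotator and label
#'   dimensions.
#' @return The factors with the updated inclusion mask.
#' @export
applyGate <- function(factors, report) {
  stopifnot(is(factors, "RewardFactors"), is(report, "GateReport"))
  if (!identical(dim(report@included), dim(factors@included)))
    stop("gate report does not match the factor dimensions", call. = FALSE)
  if (all(report@included)) return(factors)
  factors@included <- factors@included & report@included
  allOut <- rowSums(factors@included) == 0L
  if (any(allOut))
    warning("annotator(s) excluded on every label: ",
            paste(rownames(factors@included)[allOut], collapse = ", "),
            "; their scores will be zero", call. = FALSE)
  factors
}

#' Export a gate report as a data.frame
#'
#' One row per (annotator, label) pair with the kappa, inclusion flag and
#' reason, in the CSV layout \code{annotator_id,label,kappa,included,reason}.
#'
#' @param report a [GateReport-class].
#' @return data.frame.
#' @export
gateReportTable <- function(report) {
  stopifnot(is(report, "GateReport"))
  dn <- dimnames(report@kappa)
  g <- expand.grid(annotator_id = dn[[1L]], label = dn[[2L]],
                   stringsAsFactors = FALSE)
  idx <- cbind(match(g$annotator_id, dn[[1L]]), match(g$label, dn[[2L]]))
  data.frame(annotator_id = g$annotator_id, label = g$label,
             kappa = report@kappa[idx], included = report@included[idx],
             reason = report@reason[idx], stringsAsFactors = FALSE)
}
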