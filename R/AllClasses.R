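#' @import methods
NULL

## Confidence grades permitted on an annotation record: six iterative steps
## of 20 percentage points.
CONFIDENCE_GRADES <- c(0L, 20L, 40L, 60L, 80L, 100L)

## Actions a ledger event may record.
LEDGER_ACTIONS <- c("upload", "annotate", "export", "reward")

#' LabelSchema: an ordered, immutable label set for a project
#'
#' Holds the ordered list of classification labels attached to an annotation
#' project. The number of labels K is fixed for the life of any sheet built
#' against the schema.
#'
#' @slot labels character vector of unique, non-empty label names (K >= 1).
#' @slot projectName single character string naming the project.
#'
#' @examples
#' LabelSchema(c("cardiomegaly", "pneumothorax"), "demo")
#' @export
setClass("LabelSchema",
  representation(labels = "character", projectName = "character"))

setValidity("LabelSchema", function(object) {
  msg <- character()
  if (length(object@labels) < 1L)
    msg <- c(msg, "at least one label is required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "label names must be unique")
  if (any(!nzchar(object@labels)) || anyNA(object@labels))
    msg <- c(msg, "label names must be non-empty")
  if (length(object@projectName) != 1L)
    msg <- c(msg, "projectName must be a single string")
  if (length(msg)) msg else TRUE
})

#' @rdname LabelSchema-class
#' @param labels character vector of label names.
#' @param projectName project name.
#' @return A \code{LabelSchema} object.
#' @export
LabelSchema <- function(labels, projectName = "unnamed") {
  new("LabelSchema", labels = as.character(labels),
      projectName = as.character(projectName))
}

#' AnnotationSheet: complete annotator x image x label tensor
#'
#' The central container of the package: a dense boolean tensor
#' \eqn{a_{ijk}} over I annotators, J images and K labels, together with the
#' per-cell labeling times (seconds) and the stored-but-inert confidence
#' grades. Every (i, j, k) cell holds exactly one value; index order is
#' lexicographic in the annotator, image and label identifiers.
#'
#' @slot annotations logical array, dim I x J x K, no missing entries.
#' @slot timings numeric array of positive finite seconds, same dimensions.
#' @slot confidence integer array of grades in \{0, 20, 40, 60, 80, 100\},
#'   same dimensions. Confidence is carried through I/O but never enters
#'   valuation.
#' @slot projectName single character string.
#'
#' @seealso [buildSheet()], [annotationRecords()], [pseudoAnswer()]
#' @export
setClass("AnnotationSheet",
  representation(annotations = "array", timings = "array",
                 confidence = "array", projectName = "character"))

setValidity("AnnotationSheet", function(object) {
  a <- object@annotations
  msg <- character()
  if (length(dim(a)) != 3L)
    return("annotations must be a 3-d array (annotator x image x label)")
  if (any(dim(a) < 1L))
    msg <- c(msg, "all of I, J, K must be >= 1")
  if (!is.logical(a) || anyNA(a))
    msg <- c(msg, "annotations must be logical with no missing cells")
  dn <- dimnames(a)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    msg <- c(msg, "annotator, image and label ids must be set as dimnames")
  if (!identical(dim(object@timings), dim(a)))
    msg <- c(msg, "timings must share the annotation index domain")
  else if (anyNA(object@timings) || any(!is.finite(object@timings)) ||
           any(object@timings <= 0))
    msg <- c(msg, "all labeling times must be finite and > 0 seconds")
  if (!identical(dim(object@confidence), dim(a)))
    msg <- c(msg, "confidence must share the annotation index domain")
  else if (anyNA(object@confidence) ||
           !all(object@confidence %in% CONFIDENCE_GRADES))
    msg <- c(msg, "confidence grades must be one of 0, 20, 40, 60, 80, 100")
  if (length(msg)) msg else TRUE
})

#' PseudoTruth: majority-vote consensus per (label, image) cell
#'
#' The pseudo ground truth \eqn{a_{kj}}: the value held by the majority of
#' annotators for each (label, image) cell, with the supporting vote count
#' and a flag for even-split ties. With an odd number of annotators the
#' support is always at least \code{ceiling(I/2)}.
#'
#' @slot consensus logical K x J matrix of consensus values.
#' @slot support integer K x J matrix: number of annotators matching the
#'   consensus value.
#' @slot tie logical K x J matrix: TRUE where the vote was an even split and
#'   the documented tie rule (negative, or the AI prediction when supplied)
#'   decided the cell.
#' @slot nAnnotators integer: the I of the sheet the truth was derived from.
#' @export
setClass("PseudoTruth",
  representation(consensus = "matrix", support = "matrix", tie = "matrix",
                 nAnnotators = "integer"))

setValidity("PseudoTruth", function(object) {
  msg <- character()
  d <- dim(object@consensus)
  if (!is.logical(object@consensus))
    msg <- c(msg, "consensus must be logical")
  if (!identical(dim(object@support), d) || !identical(dim(object@tie), d))
    msg <- c(msg, "support and tie must match consensus dimensions")
  I <- object@nAnnotators
  if (length(I) != 1L || I < 1L)
    msg <- c(msg, "nAnnotators must be a single positive integer")
  else if (I %% 2L == 1L && is.integer(object@support) &&
           any(object@support < ceiling(I / 2)))
    msg <- c(msg, "with odd I the consensus support must reach a strict majority")
  if (length(msg)) msg else TRUE
})

#' AgreementSummary: unanimity accounting and chance-corrected agreement
#'
#' Counts of unanimous-positive, unanimous-negative and discordant
#' (label, image) cells, the unanimity fraction, the mean pairwise percent
#' agreement, and Fleiss's kappa over all pooled cells. The partition
#' identity allPositive + allNegative + discordant = J*K always holds.
#'
#' @slot allPositive integer count of cells every annotator marked positive.
#' @slot allNegative integer count of cells every annotator marked negative.
#' @slot discordant integer count of cells with any disagreement.
#' @slot total integer, J * K.
#' @slot unanimityFraction (allPositive + allNegative) / total.
#' @slot pairwiseAgreement mean over annotator pairs and cells of the
#'   agreement indicator (secondary statistic).
#' @slot fleissKappa Fleiss's kappa pooled over all J x K cells with two
#'   categories; NA when chance agreement is degenerate.
#' @export
setClass("AgreementSummary",
  representation(allPositive = "integer", allNegative = "integer",
                 discordant = "integer", total = "integer",
                 unanimityFraction = "numeric", pairwiseAgreement = "numeric",
                 fleissKappa = "numeric"))

setValidity("AgreementSummary", function(object) {
  if (object@allPositive + object@allNegative + object@discordant !=
      object@total)
    return("partition identity violated: allPositive + allNegative + discordant != total")
  TRUE
})

#' AIReference: reference predictions used as temporary ground truth
#'
#' Boolean predictions of a reference model over the (image, label) grid,
#' used by the quality-control gate as a temporary ground truth to screen
#' annotators, and optionally by the consensus tie rule. The reference is an
#' input (file or simulator output); no model inference happens here.
#'
#' @slot predictions logical J x K matrix with image and label dimnames.
#' @slot probability numeric J x K matrix of prediction scores in [0, 1]
#'   (all 0.5 when the source provides none).
#' @export
setClass("AIReference",
  representation(predictions = "matrix", probability = "matrix"))

setValidity("AIReference", function(object) {
  msg <- character()
  if (!is.logical(object@predictions) || anyNA(object@predictions))
    msg <- c(msg, "predictions must be logical with no missing entries")
  if (is.null(dimnames(object@predictions)) ||
      any(vapply(dimnames(object@predictions), is.null, logical(1))))
    msg <- c(msg, "image and label ids must be set as dimnames")
  if (!identical(dim(object@probability), dim(object@predictions)))
    msg <- c(msg, "probability must match prediction dimensions")
  else if (any(object@probability < 0 | object@probability > 1, na.rm = TRUE))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RewardFactors: per-cell data values, task values and contribution credits
#'
#' The factor set entering the reward allocation. With
#' \eqn{p_{kj}} the correct-answer rate (fraction of annotators matching the
#' pseudo answer), the data value is \eqn{D_{kj} = 1 - p_{kj} \in [0, 1]}
#' (more disagreement, more value), the task value is the per-label mean
#' \eqn{T_k = \mathrm{mean}_j D_{kj}}, the contribution credit is
#' \eqn{r_{kji} = 0.5\,\chi[a_{ijk} \ne a_{kj}] \in [0, 0.5]}, and the
#' normalized time mean \eqn{\bar t_k} is each label's mean labeling time
#' divided by the sum over labels (so \eqn{\sum_k \bar t_k = 1}). The scaled
#' forms map those ranges onto [-1, 1] by opposite normalization.
#'
#' @slot D numeric K x J matrix, data values in [0, 1].
#' @slot taskValue numeric length-K vector, per-label task values.
#' @slot timeMean numeric length-K vector, normalized per-label time means
#'   summing to 1.
#' @slot r numeric K x J x I array, contribution credits in \{0, 0.5\}.
#' @slot Dscaled numeric K x J matrix, \eqn{2(0.5 - D)} in [-1, 1].
#' @slot rscaled numeric K x J x I array, \eqn{4(0.25 - r)} in \{-1, +1\}.
#' @slot included logical I x K matrix: quality-gate mask. Excluded
#'   (annotator, label) pairs contribute zero to that annotator's score.
#' @seealso [computeFactors()], [rewardAllocation()], [applyGate()]
#' @export
setClass("RewardFactors",
  representation(D = "matrix", taskValue = "numeric", timeMean = "numeric",
                 r = "array", Dscaled = "matrix", rscaled = "array",
                 included = "matrix"))

setValidity("RewardFactors", function(object) {
  msg <- character()
  K <- nrow(object@D); J <- ncol(object@D)
  if (any(object@D < 0 | object@D > 1))
    msg <- c(msg, "data values D must lie in [0, 1]")
  if (length(object@taskValue) != K || length(object@timeMean) != K)
    msg <- c(msg, "taskValue and timeMean must have one entry per label")
  if (abs(sum(object@timeMean) - 1) > 1e-8)
    msg <- c(msg, "normalized time means must sum to 1")
  rd <- dim(object@r)
  if (length(rd) != 3L || rd[1] != K || rd[2] != J)
    msg <- c(msg, "r must be a K x J x I array")
  else {
    if (any(object@r < 0 | object@r > 0.5))
      msg <- c(msg, "contribution credits r must lie in [0, 0.5]")
    if (!identical(dim(object@rscaled), rd) ||
        any(object@rscaled < -1 | object@rscaled > 1))
      msg <- c(msg, "scaled credits must lie in [-1, 1]")
    if (!identical(dim(object@included), c(rd[3], K)))
      msg <- c(msg, "included mask must be I x K")
  }
  if (!identical(dim(object@Dscaled), dim(object@D)) ||
      any(object@Dscaled < -1 | object@Dscaled > 1))
    msg <- c(msg, "scaled data values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' RewardAllocation: budget-conserving per-annotator token shares
#'
#' Per-annotator scores \eqn{S_i} and shares
#' \eqn{\mathrm{share}_i = B \cdot S_i / \sum_i S_i} of a total budget B.
#' Shares always sum to the budget (to 1e-9 relative tolerance) and are
#' non-negative; negative scores are an error upstream, not clamped here.
#'
#' @slot budget total token amount distributed.
#' @slot score named numeric vector of unnormalized annotator scores.
#' @slot share named numeric vector of token amounts, summing to budget.
#' @slot mode "unscaled_D" or "scaled_D": which data-value form weighted the
#'   per-cell terms.
#' @slot note character vector of warnings raised during allocation (e.g.
#'   the equal-split fallback on a fully unanimous sheet).
#' @export
setClass("RewardAllocation",
  representation(budget = "numeric", score = "numeric", share = "numeric",
                 mode = "character", note = "character"))

setValidity("RewardAllocation", function(object) {
  msg <- character()
  if (length(object@budget) != 1L || object@budget <= 0)
    msg <- c(msg, "budget must be a single positive number")
  if (length(object@share) != length(object@score))
    msg <- c(msg, "share and score must have one entry per annotator")
  if (any(object@share < 0))
    msg <- c(msg, "shares must be non-negative")
  if (abs(sum(object@share) - object@budget) >
      1e-9 * max(1, abs(object@budget)))
    msg <- c(msg, "shares must sum to the budget")
  if (length(msg)) msg else TRUE
})

#' GateReport: kappa-based quality screening against an AI reference
#'
#' Cohen's kappa of each annotator against the AI reference on each label,
#' and the resulting inclusion mask: an (annotator, label) pair is included
#' iff its kappa exceeds the threshold, the working definition of "better
#' than random selection". Included and excluded sets partition all pairs.
#'
#' @slot kappa numeric I x K matrix of Cohen's kappa values (NA where the
#'   2 x 2 table is degenerate).
#' @slot threshold the inclusion threshold (default 0.05).
#' @slot included logical I x K matrix.
#' @slot reason character I x K matrix: "" for included pairs, otherwise
#'   "kappa<=threshold" or "degenerate".
#' @seealso [qcGate()], [applyGate()]
#' @export
setClass("GateReport",
  representation(kappa = "matrix", threshold = "numeric",
                 included = "matrix", reason = "matrix"))

setValidity("GateReport", function(object) {
  d <- dim(object@kappa)
  if (!identical(dim(object@included), d) ||
      !identical(dim(object@reason), d))
    return("kappa, included and reason must share dimensions")
  if (any(object@included & nzchar(object@reason)))
    return("included pairs must carry an empty reason")
  if (any(!object@included & !nzchar(object@reason)))
    return("excluded pairs must carry a reason")
  TRUE
})

#' LedgerChain: append-only hash-chained activity log
#'
#' A sequence of activity events (upload, annotate, export, reward), each
#' carrying a SHA-256 digest over the canonical serialization of its fields
#' and the previous event's digest, so any retroactive edit is detectable by
#' [ledgerVerify()]. Event 0 links back to 64 zero hex characters.
#'
#' @slot events data.frame with columns index, timestamp, actor, action,
#'   payload_digest, prev_digest, digest.
#' @seealso [ledgerAppend()], [ledgerVerify()], [writeLedger()]
#' @export
setClass("LedgerChain", representation(events = "data.frame"))

setValidity("LedgerChain", function(object) {
  ev <- object@events
  needed <- c("index", "timestamp", "actor", "action", "payload_digest",
              "prev_digest", "digest")
  if (!all(needed %in% names(ev)))
    return(paste("events must have columns:", paste(needed, collapse = ", ")))
  ## index/linkage integrity is deliberately NOT enforced here: a tampered
  ## chain must still load so that ledgerVerify can report the bad index
  TRUE
})

#' AnnotatorProfile: simulation profile for one annotator
#'
#' Configures one synthetic annotator: probability of reporting a true
#' positive (sensitivity), probability of reporting a true negative
#' (specificity), and a per-label log-normal labeling-time model given by
#' the mean time in seconds and the log-scale standard deviation.
#'
#' @slot annotatorId single character id.
#' @slot sensitivity probability in [0, 1].
#' @slot specificity probability in [0, 1].
#' @slot timeMeanSec numeric length-K vector of mean labeling seconds per
#'   label.
#' @slot timeSdLog positive log-scale standard deviation of labeling time.
#' @seealso [simulateStudy()], [cxrScenario()]
#' @export
setClass("AnnotatorProfile",
  representation(annotatorId = "character", sensitivity = "numeric",
                 specificity = "numeric", timeMeanSec = "numeric",
                 timeSdLog = "numeric"))

setValidity("AnnotatorProfile", function(object) {
  msg <- character()
  if (length(object@annotatorId) != 1L || !nzchar(object@annotatorId))
    msg <- c(msg, "annotatorId must be a single non-empty string")
  for (s in c("sensitivity", "specificity")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste(s, "must be a single probability in [0, 1]"))
  }
  if (any(object@timeMeanSec <= 0))
    msg <- c(msg, "mean labeling times must be positive")
  if (length(object@timeSdLog) != 1L || object@timeSdLog <= 0)
    msg <- c(msg, "timeSdLog must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname AnnotatorProfile-class
#' @param annotatorId annotator identifier.
#' @param sensitivity,specificity per-annotator accuracy probabilities.
#' @param timeMeanSec per-label mean labeling time in seconds.
#' @param timeSdLog log-scale sd of the labeling-time distribution.
#' @return An \code{AnnotatorProfile}.
#' @export
AnnotatorProfile <- function(annotatorId, sensitivity, specificity,
                             timeMeanSec, timeSdLog = 0.45) {
  new("AnnotatorProfile", annotatorId = as.character(annotatorId),
      sensitivity = as.numeric(sensitivity),
      specificity = as.numeric(specificity),
      timeMeanSec = as.numeric(timeMeanSec),
      timeSdLog = as.numeric(timeSdLog))
}

#' WorldSpec: the simulated study population
#'
#' The ground-truth side of a synthetic reader study: how many images, which
#' labels, each label's prevalence (probability a truly positive finding is
#' present), and the integer seed from which all randomness flows.
#'
#' @slot nImages number of images J.
#' @slot schema a [LabelSchema-class].
#' @slot prevalence numeric length-K vector of per-label positive
#'   probabilities.
#' @slot seed single integer seed.
#' @export
setClass("WorldSpec",
  representation(nImages = "integer", schema = "LabelSchema",
                 prevalence = "numeric", seed = "integer"))

setValidity("WorldSpec", function(object) {
  msg <- character()
  if (object@nImages < 1L)
    msg <- c(msg, "nImages must be >= 1")
  if (length(object@prevalence) != length(object@schema@labels))
    msg <- c(msg, "one prevalence per label is required")
  if (any(object@prevalence < 0 | object@prevalence > 1))
    msg <- c(msg, "prevalences must lie in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @rdname WorldSpec-class
#' @param nImages number of images.
#' @param schema a \code{LabelSchema} (or character vector of labels).
#' @param prevalence per-label positive probability.
#' @param seed integer seed.
#' @return A \code{WorldSpec}.
#' @export
WorldSpec <- function(nImages, schema, prevalence, seed = 1L) {
  if (is.character(schema)) schema <- LabelSchema(schema)
  new("WorldSpec", nImages = as.integer(nImages), schema = schema,
      prevalence = as.numeric(prevalence), seed = as.integer(seed))
}
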