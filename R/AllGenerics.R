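#' @rdname AnnotationSheet-class
#' @param x an object with an annotator/image/label index domain.
#' @export
setGeneric("nAnnotators", function(x) standardGeneric("nAnnotators"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("annotatorIds", function(x) standardGeneric("annotatorIds"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("timings", function(x) standardGeneric("timings"))

#' @rdname AnnotationSheet-class
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))

#' Majority-vote pseudo ground truth
#'
#' Derives the per-(label, image) pseudo answer as the value held by the
#' majority of annotators. With an even number of annotators an exact tie is
#' resolved to negative and flagged, unless an AI reference is supplied, in
#' which case the tie defers to the AI prediction.
#'
#' @param sheet an [AnnotationSheet-class].
#' @param ai optional [AIReference-class] consulted only on exact ties.
#' @return A [PseudoTruth-class].
#' @examples
#' sim <- simulateStudy(WorldSpec(20, c("a", "b"), c(0.3, 0.5), seed = 7),
#'                      list(AnnotatorProfile("r1", 0.9, 0.95, c(5, 5)),
#'                           AnnotatorProfile("r2", 0.8, 0.9, c(5, 5)),
#'                           AnnotatorProfile("r3", 0.85, 0.9, c(5, 5))))
#' pt <- pseudoAnswer(sim$sheet)
#' table(consensus(pt))
#' @export
setGeneric("pseudoAnswer", function(sheet, ai = NULL)
  standardGeneric("pseudoAnswer"))

#' @rdname PseudoTruth-class
#' @param x a \code{PseudoTruth}.
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname PseudoTruth-class
#' @export
setGeneric("support", function(x) standardGeneric("support"))

#' Unanimity accounting and pooled agreement statistics
#'
#' Counts unanimous-positive, unanimous-negative and discordant cells over
#' the J x K grid, and computes the unanimity fraction, the mean pairwise
#' agreement, and Fleiss's kappa pooled over all cells.
#'
#' @param sheet an [AnnotationSheet-class] with at least two annotators.
#' @return An [AgreementSummary-class].
#' @export
setGeneric("agreementSummary", function(sheet)
  standardGeneric("agreementSummary"))

#' Per-label pairwise disagreement counts
#'
#' For each label, the symmetric annotator-by-annotator matrix counting the
#' images on which each pair disagreed — the discrepancy heatmap of a review
#' session. Diagonals are zero.
#'
#' @param sheet an [AnnotationSheet-class] with at least two annotators.
#' @return A K x I x I numeric array, label by annotator pair.
#' @export
setGeneric("discrepancyMatrix", function(sheet)
  standardGeneric("discrepancyMatrix"))

#' @rdname RewardAllocation-class
#' @param x a \code{RewardAllocation}.
#' @export
setGeneric("shares", function(x) standardGeneric("shares"))

#' @rdname RewardAllocation-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
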