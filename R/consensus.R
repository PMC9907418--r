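#' @rdname pseudoAnswer
#' @export
setMethod("pseudoAnswer", "AnnotationSheet", function(sheet, ai = NULL) {
  a <- sheet@annotations
  I <- dim(a)[1L]
  ## positive votes per (label, image): K x J
  pos <- t(colSums(a, dims = 1L))
  cons <- pos > I / 2
  tie <- pos * 2L == I
  if (any(tie)) {
    if (!is.null(ai)) {
      stopifnot(is(ai, "AIReference"))
      aiKJ <- t(ai@predictions[imageIds(sheet), labelNames(sheet),
                               drop = FALSE])
      cons[tie] <- aiKJ[tie]
    } else {
      cons[tie] <- FALSE  # conservative tie rule: resolve to negative
    }
  }
  supp <- ifelse(cons, pos, I - pos)
  dn <- list(label = labelNames(sheet), image = imageIds(sheet))
  dimnames(cons) <- dimnames(supp) <- dimnames(tie) <- dn
  new("PseudoTruth", consensus = cons,
      support = matrix(as.integer(supp), nrow(supp), ncol(supp),
                       dimnames = dn),
      tie = tie, nAnnotators = I)
})

#' Fleiss's kappa over pooled annotation cells
#'
#' Chance-corrected agreement among I >= 2 raters, treating each of the
#' J x K (image, label) cells as one item with two categories (positive /
#' negative). Per-item agreement is
#' \eqn{P_m = [\sum_c n_c (n_c - 1)] / [I (I - 1)]}; kappa is
#' \eqn{(\bar P - \bar P_e) / (1 - \bar P_e)} with \eqn{\bar P_e = p^2 +
#' (1-p)^2} from the pooled positive fraction p.
#'
#' @param sheet an [AnnotationSheet-class] with I >= 2.
#' @param perLabel if TRUE, return a length-K vector of per-label kappas
#'   (items are that label's J images) instead of the pooled value.
#' @return Kappa in [-1, 1], or NA with a warning when every rating falls in
#'   one category so chance agreement is degenerate.
#' @export
fleissKappa <- function(sheet, perLabel = FALSE) {
  stopifnot(is(sheet, "AnnotationSheet"))
  I <- nAnnotators(sheet)
  if (I < 2L) stop("Fleiss's kappa needs at least two annotators",
                   call. = FALSE)
  kappaFromPos <- function(pos) {
    # pos: positive votes per item
    p <- sum(pos) / (length(pos) * I)
    Pe <- p^2 + (1 - p)^2
    Pitem <- (pos * (pos - 1) + (I - pos) * (I - pos - 1)) / (I * (I - 1))
    if (Pe >= 1) {
      warning("Fleiss's kappa undefined: all ratings in a single category",
              call. = FALSE)
      return(NA_real_)
    }
    (mean(Pitem) - Pe) / (1 - Pe)
  }
  pos <- t(colSums(sheet@annotations, dims = 1L))  # K x J
  if (perLabel) {
    k <- vapply(seq_len(nrow(pos)), function(i) kappaFromPos(pos[i, ]),
                numeric(1))
    names(k) <- labelNames(sheet)
    k
  } else {
    kappaFromPos(as.vector(pos))
  }
}

#' Cohen's kappa for two boolean raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} from
#' the 2 x 2 contingency of two equal-length boolean vectors, with
#' \eqn{p_e} the product-marginal chance agreement.
#'
#' @param x,y logical vectors of equal length >= 1.
#' @return Kappa in [-1, 1], or NA with a warning when \eqn{p_e = 1} (both
#'   raters constant in the same category).
#' @examples
#' cohenKappa(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
cohenKappa <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be equal-length vectors of length >= 1", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing ratings are not allowed",
                                 call. = FALSE)
  po <- mean(x == y)
  px <- mean(x); py <- mean(y)
  pe <- px * py + (1 - px) * (1 - py)
  if (pe >= 1) {
    warning("Cohen's kappa undefined: no chance variation", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' @rdname agreementSummary
#' @export
setMethod("agreementSummary", "AnnotationSheet", function(sheet) {
  I <- nAnnotators(sheet)
  if (I < 2L) stop("agreement needs at least two annotators", call. = FALSE)
  pos <- colSums(sheet@annotations, dims = 1L)  # J x K positive votes
  allPos <- sum(pos == I)
  allNeg <- sum(pos == 0L)
  total <- length(pos)
  disc <- total - allPos - allNeg
  ## mean pairwise agreement: item with n positive votes has
  ## [n(n-1) + (I-n)(I-n-1)] / [I(I-1)] agreeing pairs
  pairAgr <- mean((pos * (pos - 1) + (I - pos) * (I - pos - 1)) /
                    (I * (I - 1)))
  fk <- withCallingHandlers(fleissKappa(sheet),
                            warning = function(w) invokeRestart("muffleWarning"))
  new("AgreementSummary",
      allPositive = as.integer(allPos), allNegative = as.integer(allNeg),
      discordant = as.integer(disc), total = as.integer(total),
      unanimityFraction = (allPos + allNeg) / total,
      pairwiseAgreement = pairAgr,
      fleissKappa = if (is.null(fk)) NA_real_ else fk)
})

#' @rdname discrepancyMatrix
#' @export
setMethod("discrepancyMatrix", "AnnotationSheet", function(sheet) {
  I <- nAnnotators(sheet)
  if (I < 2L) stop("discrepancy needs at least two annotators", call. = FALSE)
  K <- nLabels(sheet)
  ids <- annotatorIds(sheet)
  out <- array(0, dim = c(K, I, I),
               dimnames = list(label = labelNames(sheet), ids, ids))
  a <- sheet@annotations
  JK <- dim(a)[2:3]
  for (i1 in seq_len(I - 1L)) for (i2 in (i1 + 1L):I) {
    d <- colSums(array(a[i1, , ], dim = JK) != array(a[i2, , ], dim = JK))
    out[, i1, i2] <- out[, i2, i1] <- d
  }
  out
})
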