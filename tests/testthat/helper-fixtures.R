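# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

# A complete record data.frame for the given ids, with values supplied in
# (annotator, image, label) nesting order (label fastest).
makeRecords <- function(annotators, images, labels, values,
                        confidence = 80L, elapsed = 5) {
  g <- expand.grid(label = labels, image_id = images,
                   annotator_id = annotators, stringsAsFactors = FALSE)
  data.frame(image_id = g$image_id, annotator_id = g$annotator_id,
             label = g$label, value = as.logical(values),
             confidence = as.integer(rep_len(confidence, nrow(g))),
             elapsed_sec = as.numeric(rep_len(elapsed, nrow(g))),
             stringsAsFactors = FALSE)
}

# Direct sheet constructor from an I x J x K logical array.
makeSheet <- function(a, timings = NULL, confidence = NULL) {
  d <- dim(a)
  dn <- dimnames(a)
  if (is.null(dn))
    dn <- list(sprintf("a%02d", seq_len(d[1])),
               sprintf("img%03d", seq_len(d[2])),
               sprintf("lab%02d", seq_len(d[3])))
  dimnames(a) <- dn
  if (is.null(timings)) timings <- array(5, d, dimnames = dn)
  else timings <- array(timings, d, dimnames = dn)
  if (is.null(confidence)) confidence <- array(80L, d, dimnames = dn)
  new("AnnotationSheet", annotations = a, timings = timings,
      confidence = confidence, projectName = "fixture")
}

# Random sheet where annotator i matches a Bernoulli(prevalence) truth with
# probability acc[i], independently per cell.
randomSheet <- function(I, J, K, acc = NULL, prevalence = 0.3) {
  if (is.null(acc)) acc <- runif(I, 0.75, 0.95)
  truth <- matrix(runif(J * K) < prevalence, J, K)
  a <- array(NA, c(I, J, K))
  for (i in seq_len(I)) {
    hit <- matrix(runif(J * K) < acc[i], J, K)
    a[i, , ] <- ifelse(hit, truth, !truth)
  }
  makeSheet(a, timings = array(runif(I * J * K, 2, 10), c(I, J, K)))
}

# AI reference matching a sheet's index domain, agreeing with `truth`
# (J x K logical) with probability accuracy.
makeAI <- function(sheet, truth, accuracy = 1) {
  J <- nImages(sheet); K <- nLabels(sheet)
  agree <- matrix(runif(J * K) < accuracy, J, K)
  pred <- ifelse(agree, truth, !truth)
  dimnames(pred) <- list(imageIds(sheet), labelNames(sheet))
  new("AIReference", predictions = pred,
      probability = matrix(0.5, J, K, dimnames = dimnames(pred)))
}
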