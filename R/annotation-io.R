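ANNOT_CSV_HEADER <- c("image_id", "annotator_id", "label", "value",
                      "confidence", "elapsed_sec")
AI_CSV_HEADER <- c("image_id", "label", "value", "probability")

## Column names that mark a record as ROI/object-detection geometry, which
## this package does not handle.
ROI_COLUMNS <- c("x", "y", "w", "h", "width", "height", "bbox", "roi",
                 "polygon", "geometry", "x1", "y1", "x2", "y2")

#' @rdname AnnotationSheet-class
#' @export
setMethod("nAnnotators", "AnnotationSheet", function(x) dim(x@annotations)[1L])

#' @rdname AnnotationSheet-class
#' @export
setMethod("nImages", "AnnotationSheet", function(x) dim(x@annotations)[2L])

#' @rdname AnnotationSheet-class
#' @export
setMethod("nLabels", "AnnotationSheet", function(x) dim(x@annotations)[3L])

#' @rdname AnnotationSheet-class
#' @export
setMethod("annotatorIds", "AnnotationSheet",
          function(x) dimnames(x@annotations)[[1L]])

#' @rdname AnnotationSheet-class
#' @export
setMethod("imageIds", "AnnotationSheet",
          function(x) dimnames(x@annotations)[[2L]])

#' @rdname AnnotationSheet-class
#' @export
setMethod("labelNames", "AnnotationSheet",
          function(x) dimnames(x@annotations)[[3L]])

#' @rdname AnnotationSheet-class
#' @export
setMethod("annotations", "AnnotationSheet", function(x) x@annotations)

#' @rdname AnnotationSheet-class
#' @export
setMethod("timings", "AnnotationSheet", function(x) x@timings)

#' @rdname AnnotationSheet-class
#' @export
setMethod("confidences", "AnnotationSheet", function(x) x@confidence)

#' @rdname PseudoTruth-class
#' @export
setMethod("consensus", "PseudoTruth", function(x) x@consensus)

#' @rdname PseudoTruth-class
#' @export
setMethod("support", "PseudoTruth", function(x) x@support)

#' @rdname AIReference-class
#' @param x an \code{AIReference}.
#' @export
setMethod("nImages", "AIReference", function(x) nrow(x@predictions))

#' @rdname AIReference-class
#' @export
setMethod("nLabels", "AIReference", function(x) ncol(x@predictions))

#' @rdname AIReference-class
#' @export
setMethod("imageIds", "AIReference", function(x) rownames(x@predictions))

#' @rdname AIReference-class
#' @export
setMethod("labelNames", "AIReference", function(x) colnames(x@predictions))

#' @rdname AIReference-class
#' @export
setMethod("annotations", "AIReference", function(x) x@predictions)

#' @rdname RewardAllocation-class
#' @export
setMethod("shares", "RewardAllocation", function(x) x@share)

#' @rdname RewardAllocation-class
#' @export
setMethod("scores", "RewardAllocation", function(x) x@score)

validateRecords <- function(records) {
  needed <- ANNOT_CSV_HEADER
  if (!is.data.frame(records) || !all(needed %in% names(records)))
    stop("annotation records need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(tolower(names(records)), needed)
  if (any(extra %in% ROI_COLUMNS))
    stop("classification-only: ROI/object-detection records are not supported ",
         "(offending columns: ",
         paste(intersect(extra, ROI_COLUMNS), collapse = ", "), ")",
         call. = FALSE)
  if (nrow(records) == 0L)
    stop("no annotation records supplied", call. = FALSE)
  bad <- which(!(records$confidence %in% CONFIDENCE_GRADES))
  if (length(bad))
    stop(sprintf(
      "row %d: confidence %s is not one of the six permitted grades (0, 20, 40, 60, 80, 100)",
      bad[1L], format(records$confidence[bad[1L]])), call. = FALSE)
  bad <- which(!is.finite(records$elapsed_sec) | records$elapsed_sec <= 0)
  if (length(bad))
    stop(sprintf("row %d: elapsed_sec must be finite and > 0 (got %s)",
                 bad[1L], format(records$elapsed_sec[bad[1L]])), call. = FALSE)
  if (!is.logical(records$value) || anyNA(records$value))
    stop("annotation values must be boolean", call. = FALSE)
  invisible(records)
}

#' Assemble a complete annotation sheet from record-level data
#'
#' Builds the dense I x J x K annotation, timing and confidence tensors from
#' a data.frame of annotation records (one row per annotator, image and
#' label). Dimensions and index order are inferred from the distinct ids,
#' sorted lexicographically, so the result is invariant to the row order of
#' the input.
#'
#' @param records data.frame with columns \code{image_id}, \code{annotator_id},
#'   \code{label}, \code{value} (logical), \code{confidence} (one of 0, 20,
#'   40, 60, 80, 100) and \code{elapsed_sec} (positive seconds).
#' @param projectName stored on the sheet.
#' @return An [AnnotationSheet-class].
#' @section Errors:
#' A duplicated (annotator, image, label) triple or a missing cell is an
#' error; the message names the first offending triple.
#' @examples
#' recs <- expand.grid(image_id = c("img1", "img2"),
#'                     annotator_id = c("a", "b", "c"),
#'                     label = "pneumonia", stringsAsFactors = FALSE)
#' recs$value <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
#' recs$confidence <- 80L
#' recs$elapsed_sec <- 5.0
#' sheet <- buildSheet(recs)
#' dim(annotations(sheet))
#' @export
buildSheet <- function(records, projectName = "unnamed") {
  validateRecords(records)
  ann <- sort(unique(as.character(records$annotator_id)))
  img <- sort(unique(as.character(records$image_id)))
  lab <- sort(unique(as.character(records$label)))
  I <- length(ann); J <- length(img); K <- length(lab)

  key <- paste(records$annotator_id, records$image_id, records$label,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    d <- records[dup[1L], ]
    stop(sprintf("duplicate record for (annotator=%s, image=%s, label=%s)",
                 d$annotator_id, d$image_id, d$label), call. = FALSE)
  }
  if (nrow(records) < I * J * K) {
    full <- expand.grid(annotator_id = ann, image_id = img, label = lab,
                        stringsAsFactors = FALSE)
    fullkey <- paste(full$annotator_id, full$image_id, full$label, sep = "\r")
    ## lexicographic order of (annotator, image, label)
    ord <- order(full$annotator_id, full$image_id, full$label)
    missing <- setdiff(fullkey[ord], key)
    m <- strsplit(missing[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "incomplete sheet: no record for (annotator=%s, image=%s, label=%s)",
      m[1L], m[2L], m[3L]), call. = FALSE)
  }

  dn <- list(annotator = ann, image = img, label = lab)
  mk <- function(what, init) {
    a <- array(init, dim = c(I, J, K), dimnames = dn)
    a[cbind(match(as.character(records$annotator_id), ann),
            match(as.character(records$image_id), img),
            match(as.character(records$label), lab))] <- what
    a
  }
  new("AnnotationSheet",
      annotations = mk(as.logical(records$value), NA),
      timings = mk(as.numeric(records$elapsed_sec), NA_real_),
      confidence = mk(as.integer(records$confidence), NA_integer_),
      projectName = as.character(projectName))
}

#' Flatten a sheet back to record-level rows
#'
#' The inverse of [buildSheet()]: one row per (annotator, image, label) cell
#' in deterministic lexicographic order, so re-exporting a sheet is
#' byte-stable.
#'
#' @param sheet an [AnnotationSheet-class].
#' @return data.frame with the annotation-CSV columns.
#' @export
annotationRecords <- function(sheet) {
  stopifnot(is(sheet, "AnnotationSheet"))
  ann <- annotatorIds(sheet); img <- imageIds(sheet); lab <- labelNames(sheet)
  g <- expand.grid(label = lab, image_id = img, annotator_id = ann,
                   stringsAsFactors = FALSE)
  idx <- cbind(match(g$annotator_id, ann), match(g$image_id, img),
               match(g$label, lab))
  out <- data.frame(image_id = g$image_id, annotator_id = g$annotator_id,
                    label = g$label,
                    value = sheet@annotations[idx],
                    confidence = sheet@confidence[idx],
                    elapsed_sec = sheet@timings[idx],
                    stringsAsFactors = FALSE)
  out[order(out$annotator_id, out$image_id, out$label), , drop = FALSE] |>
    `rownames<-`(NULL)
}

parseCsvBoolean <- function(x, what, rows) {
  v <- rep(NA, length(x))
  lx <- tolower(trimws(x))
  v[lx %in% c("true", "t", "1")] <- TRUE
  v[lx %in% c("false", "f", "0")] <- FALSE
  if (anyNA(v)) {
    i <- which(is.na(v))[1L]
    stop(sprintf("row %d: malformed boolean %s value '%s'",
                 rows[i], what, x[i]), call. = FALSE)
  }
  v
}

#' Read an annotations CSV
#'
#' Reads the package's annotation dialect: comma-separated, UTF-8, header
#' \code{image_id,annotator_id,label,value,confidence,elapsed_sec}, booleans
#' \code{true}/\code{false}. Confidence grades and elapsed times are
#' validated per row; files with ROI geometry columns are rejected.
#'
#' @param path file path.
#' @return data.frame of annotation records, one per data row (possibly zero
#'   rows), suitable for [buildSheet()].
#' @export
readAnnotationsCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!all(ANNOT_CSV_HEADER %in% names(raw)))
    stop("missing columns in ", path, ": ",
         paste(setdiff(ANNOT_CSV_HEADER, names(raw)), collapse = ", "),
         call. = FALSE)
  extra <- setdiff(tolower(names(raw)), ANNOT_CSV_HEADER)
  if (any(extra %in% ROI_COLUMNS))
    stop("classification-only: ROI/object-detection records are not supported",
         call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(image_id = character(), annotator_id = character(),
                      label = character(), value = logical(),
                      confidence = integer(), elapsed_sec = numeric(),
                      stringsAsFactors = FALSE))
  rows <- seq_len(nrow(raw)) + 1L  # header is row 1
  value <- parseCsvBoolean(raw$value, "annotation", rows)
  conf <- suppressWarnings(as.integer(raw$confidence))
  bad <- which(is.na(conf) | !(conf %in% CONFIDENCE_GRADES))
  if (length(bad))
    stop(sprintf(
      "row %d: confidence '%s' is not one of the six permitted grades (0, 20, 40, 60, 80, 100)",
      rows[bad[1L]], raw$confidence[bad[1L]]), call. = FALSE)
  secs <- suppressWarnings(as.numeric(raw$elapsed_sec))
  bad <- which(is.na(secs) | !is.finite(secs) | secs <= 0)
  if (length(bad))
    stop(sprintf("row %d: elapsed_sec '%s' must be a finite positive number",
                 rows[bad[1L]], raw$elapsed_sec[bad[1L]]), call. = FALSE)
  data.frame(image_id = raw$image_id, annotator_id = raw$annotator_id,
             label = raw$label, value = value, confidence = conf,
             elapsed_sec = secs, stringsAsFactors = FALSE)
}

#' Write an annotations CSV
#'
#' Serializes a sheet in the dialect read by [readAnnotationsCsv()], rows in
#' lexicographic (annotator, image, label) order, booleans lowercase, times
#' rounded to 3 decimal places. The round trip
#' \code{buildSheet(readAnnotationsCsv(writeAnnotationsCsv(sheet, p)))}
#' reproduces the sheet exactly (times at 3-decimal precision).
#'
#' @param sheet an [AnnotationSheet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationsCsv <- function(sheet, path) {
  recs <- annotationRecords(sheet)
  lines <- c(paste(ANNOT_CSV_HEADER, collapse = ","),
             sprintf("%s,%s,%s,%s,%d,%.3f",
                     recs$image_id, recs$annotator_id, recs$label,
                     ifelse(recs$value, "true", "false"),
                     recs$confidence, recs$elapsed_sec))
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE); TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write annotations to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Read an AI-reference CSV
#'
#' Dialect: header \code{image_id,label,value,probability}, one row per
#' (image, label). The probability column may be empty; missing scores are
#' stored as 0.5.
#'
#' @param path file path.
#' @return An [AIReference-class].
#' @export
readAIReferenceCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!all(AI_CSV_HEADER[1:3] %in% names(raw)))
    stop("missing columns in ", path, ": ",
         paste(setdiff(AI_CSV_HEADER[1:3], names(raw)), collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) stop("empty AI reference: ", path, call. = FALSE)
  rows <- seq_len(nrow(raw)) + 1L
  value <- parseCsvBoolean(raw$value, "prediction", rows)
  img <- sort(unique(raw$image_id)); lab <- sort(unique(raw$label))
  pred <- matrix(NA, length(img), length(lab), dimnames = list(img, lab))
  prob <- matrix(0.5, length(img), length(lab), dimnames = list(img, lab))
  idx <- cbind(match(raw$image_id, img), match(raw$label, lab))
  if (anyDuplicated(idx))
    stop("duplicate (image, label) rows in AI reference", call. = FALSE)
  pred[idx] <- value
  if ("probability" %in% names(raw)) {
    p <- suppressWarnings(as.numeric(raw$probability))
    prob[idx[!is.na(p), , drop = FALSE]] <- p[!is.na(p)]
  }
  if (anyNA(pred)) {
    miss <- which(is.na(pred), arr.ind = TRUE)[1L, ]
    stop(sprintf("incomplete AI reference: no prediction for (image=%s, label=%s)",
                 img[miss[1L]], lab[miss[2L]]), call. = FALSE)
  }
  new("AIReference", predictions = pred, probability = prob)
}

#' Write an AI-reference CSV
#'
#' @param ai an [AIReference-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAIReferenceCsv <- function(ai, path) {
  stopifnot(is(ai, "AIReference"))
  img <- imageIds(ai); lab <- labelNames(ai)
  g <- expand.grid(label = lab, image_id = img, stringsAsFactors = FALSE)
  idx <- cbind(match(g$image_id, img), match(g$label, lab))
  lines <- c(paste(AI_CSV_HEADER, collapse = ","),
             sprintf("%s,%s,%s,%.6f", g$image_id, g$label,
                     ifelse(ai@predictions[idx], "true", "false"),
                     ai@probability[idx]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
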