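setMethod("show", "LabelSchema", function(object) {
  cat("LabelSchema '", object@projectName, "' with ",
      length(object@labels), " labels:\n  ",
      paste(object@labels, collapse = ", "), "\n", sep = "")
})

setMethod("show", "AnnotationSheet", function(object) {
  d <- dim(object@annotations)
  cat("AnnotationSheet '", object@projectName, "': ",
      d[1L], " annotators x ", d[2L], " images x ", d[3L], " labels\n",
      sep = "")
  cat("  positive fraction: ",
      format(mean(object@annotations), digits = 3),
      "; mean labeling time: ",
      format(mean(object@timings), digits = 3), " s\n", sep = "")
})

setMethod("show", "PseudoTruth", function(object) {
  cat("PseudoTruth over ", nrow(object@consensus), " labels x ",
      ncol(object@consensus), " images (I = ", object@nAnnotators, ")\n",
      "  positive consensus cells: ", sum(object@consensus),
      "; ties flagged: ", sum(object@tie), "\n", sep = "")
})

setMethod("show", "AgreementSummary", function(object) {
  cat("AgreementSummary over ", object@total, " cells\n",
      "  unanimous positive: ", object@allPositive,
      "\n  unanimous negative: ", object@allNegative,
      "\n  discordant:         ", object@discordant,
      "\n  unanimity fraction: ",
      format(object@unanimityFraction, digits = 4),
      "\n  pairwise agreement: ",
      format(object@pairwiseAgreement, digits = 4),
      "\n  Fleiss's kappa:     ", format(object@fleissKappa, digits = 4),
      "\n", sep = "")
})

setMethod("show", "AIReference", function(object) {
  cat("AIReference: ", nrow(object@predictions), " images x ",
      ncol(object@predictions), " labels; positive fraction ",
      format(mean(object@predictions), digits = 3), "\n", sep = "")
})

setMethod("show", "RewardFactors", function(object) {
  d <- dim(object@r)
  cat("RewardFactors: ", d[1L], " labels x ", d[2L], " images x ", d[3L],
      " annotators\n  task values: ",
      paste(format(object@taskValue, digits = 3), collapse = ", "),
      "\n  time means:  ",
      paste(format(object@timeMean, digits = 3), collapse = ", "),
      "\n  gate-excluded pairs: ", sum(!object@included), "\n", sep = "")
})

setMethod("show", "RewardAllocation", function(object) {
  cat("RewardAllocation of ", format(object@budget), " tokens (mode ",
      object@mode, ")\n", sep = "")
  for (id in names(object@share))
    cat(sprintf("  %-14s score %10.4f  share %10.4f\n", id,
                object@score[[id]], object@share[[id]]))
  if (length(object@note)) cat("  note: ", object@note, "\n", sep = "")
})

setMethod("show", "GateReport", function(object) {
  cat("GateReport (threshold ", format(object@threshold), "): ",
      sum(object@included), " of ", length(object@included),
      " (annotator, label) pairs included\n", sep = "")
  if (any(!object@included)) {
    bad <- which(!object@included, arr.ind = TRUE)
    for (n in seq_len(min(nrow(bad), 10L)))
      cat("  excluded: ", rownames(object@kappa)[bad[n, 1L]], " / ",
          colnames(object@kappa)[bad[n, 2L]], " (",
          object@reason[bad[n, 1L], bad[n, 2L]], ")\n", sep = "")
  }
})

setMethod("show", "LedgerChain", function(object) {
  n <- nrow(object@events)
  cat("LedgerChain with ", n, " event(s)\n", sep = "")
  if (n) {
    tail <- object@events[n, ]
    cat("  head digest: ", substr(tail$digest, 1, 16), "... (",
        tail$action, " by ", tail$actor, ")\n", sep = "")
  }
})

setMethod("show", "AnnotatorProfile", function(object) {
  cat("AnnotatorProfile '", object@annotatorId, "': sens ",
      format(object@sensitivity), ", spec ", format(object@specificity),
      ", mean time ", format(mean(object@timeMeanSec), digits = 3),
      " s\n", sep = "")
})

setMethod("show", "WorldSpec", function(object) {
  cat("WorldSpec: ", object@nImages, " images x ",
      length(object@schema@labels), " labels (seed ", object@seed, ")\n",
      sep = "")
})
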