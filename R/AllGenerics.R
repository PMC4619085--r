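## Generics and accessors. Slot access everywhere else goes through these.

#' @name crisprDel-accessors
#' @title Accessors for crisprDel classes
#' @description Accessor generics for the package's S4 classes.
#' @param x,object An object of the documented class.
#' @return The corresponding slot or derived value.
NULL

#' @rdname crisprDel-accessors
#' @export
setGeneric("protospacer", function(x) standardGeneric("protospacer"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("pam", function(x) standardGeneric("pam"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("guideScore", function(x) standardGeneric("guideScore"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("guideFlags", function(x) standardGeneric("guideFlags"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("u6Guide", function(x) standardGeneric("u6Guide"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("h1Guide", function(x) standardGeneric("h1Guide"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("deletionRegion", function(x) standardGeneric("deletionRegion"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("deletionLength", function(x) standardGeneric("deletionLength"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("pairScore", function(x) standardGeneric("pairScore"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("oligoSeq", function(x) standardGeneric("oligoSeq"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("segmentMap", function(x) standardGeneric("segmentMap"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("constructElements", function(x) standardGeneric("constructElements"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("constructStage", function(x) standardGeneric("constructStage"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("genotypeCategory", function(x) standardGeneric("genotypeCategory"))
#' @rdname crisprDel-accessors
#' @export
setGeneric("genotypeEvidence", function(x) standardGeneric("genotypeEvidence"))

#' @rdname crisprDel-accessors
setMethod("protospacer", "GuideSet", function(x) mcols(x)$protospacer)
#' @rdname crisprDel-accessors
setMethod("pam", "GuideSet", function(x) mcols(x)$pam)
#' @rdname crisprDel-accessors
setMethod("cutSite", "GuideSet", function(x) mcols(x)$cut)
#' @rdname crisprDel-accessors
setMethod("guideScore", "GuideSet", function(x) mcols(x)$score)
#' @rdname crisprDel-accessors
setMethod("guideFlags", "GuideSet", function(x)
  as.data.frame(mcols(x)[, c("startsWithG", "containsBsmbi",
                             "containsPolyT", "containsN")]))

#' @rdname crisprDel-accessors
setMethod("u6Guide", "GuidePair", function(x) x@u6)
#' @rdname crisprDel-accessors
setMethod("h1Guide", "GuidePair", function(x) x@h1)
#' @rdname crisprDel-accessors
setMethod("deletionRegion", "GuidePair", function(x) x@deletion)
#' @rdname crisprDel-accessors
setMethod("deletionLength", "GuidePair", function(x) x@deletionLen)
#' @rdname crisprDel-accessors
setMethod("pairScore", "GuidePair", function(x) x@pairScore)
#' @rdname crisprDel-accessors
setMethod("cutSite", "GuidePair", function(x)
  sort(c(u6 = mcols(x@u6)$cut, h1 = mcols(x@h1)$cut)))

#' @rdname crisprDel-accessors
setMethod("oligoSeq", "Insert1Oligo", function(x) x@seq)
#' @rdname crisprDel-accessors
setMethod("segmentMap", "Insert1Oligo", function(x) x@segments)

#' @rdname crisprDel-accessors
setMethod("constructElements", "ConstructModel", function(x) x@elements)
#' @rdname crisprDel-accessors
setMethod("constructStage", "ConstructModel", function(x) x@stage)

#' @rdname crisprDel-accessors
setMethod("genotypeCategory", "GenotypeCall", function(x) x@category)
#' @rdname crisprDel-accessors
setMethod("genotypeEvidence", "GenotypeCall", function(x) x@evidence)

## show methods -------------------------------------------------------------

#' @rdname crisprDel-accessors
setMethod("show", "GuidePair", function(object) {
  cat("GuidePair\n")
  cat("  U6 :", protospacer(object@u6), paste0("(", pam(object@u6), ")"),
      "cut", cutSite(object@u6),
      if (object@prependedG) "[+G transcript]" else "", "\n")
  cat("  H1 :", protospacer(object@h1), paste0("(", pam(object@h1), ")"),
      "cut", cutSite(object@h1), "\n")
  cat("  deletion:", as.character(seqnames(object@deletion)[1]), ":",
      start(object@deletion), "-", end(object@deletion),
      paste0("(", object@deletionLen, " bp)"),
      " pair score ", signif(object@pairScore, 3), "\n", sep = "")
})

#' @rdname crisprDel-accessors
setMethod("show", "Insert1Oligo", function(object) {
  cat("Insert1Oligo of length", nchar(object@seq), "nt\n")
  seg <- object@segments
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  %-14s %3d-%3d  %s\n", seg$name[i], seg$start[i], seg$end[i],
                substr(object@seq, seg$start[i], seg$end[i])))
})

#' @rdname crisprDel-accessors
setMethod("show", "ConstructModel", function(object) {
  cat("ConstructModel (stage:", object@stage, ")\n")
  el <- object@elements
  for (i in seq_len(nrow(el)))
    cat(sprintf("  %d. %-16s %d nt\n", i, el$name[i], nchar(el$seq[i])))
  cat("  physical sequence:", nchar(object@seq), "nt,",
      .countMatches(object@seq, "CGTCTC") + .countMatches(object@seq, "GAGACG"),
      "BsmBI site(s)\n")
})

#' @rdname crisprDel-accessors
setMethod("show", "GenotypingPlan", function(object) {
  cat("GenotypingPlan:", object@name, "\n")
  cat("  nominal cut", object@nominalLen, "bp, position", object@positionLabel, "\n")
  cat("  expected PCR sizes: WT", object@wtSize, "| KO", object@koSize,
      "| internal", object@int2Size, "| inversion", object@invSize, "bp\n")
  cat("  band tolerance:", object@toleranceBp, "bp\n")
})

#' @rdname crisprDel-accessors
setMethod("show", "GenotypeCall", function(object) {
  ev <- object@evidence
  cat("GenotypeCall:", object@category, "\n  evidence:",
      paste(names(ev), unname(ev), sep = "=", collapse = ", "), "\n")
})
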