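#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges mcols mcols<- strand start end width seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## GuideSet: SpCas9 guide candidates as a GRanges subclass
## ---------------------------------------------------------------------------

#' Guide candidate container
#'
#' A [GenomicRanges::GRanges] subclass holding SpCas9 guide candidates.  The
#' range is the genomic interval of the 20-nt protospacer; metadata columns
#' carry the protospacer (read 5'->3' on its own strand), the 3-nt PAM
#' (`NGG`), the predicted blunt-cut gap coordinate `cut` (the break falls
#' between plus-strand bases `cut` and `cut + 1`), a specificity `score` in
#' `[0, 1]` (`NA` until scored) and the constraint flags `startsWithG`,
#' `containsBsmbi`, `containsPolyT` and `containsN`.
#'
#' @export
setClass("GuideSet", contains = "GRanges")

GUIDE_MCOLS <- c("protospacer", "pam", "cut", "score",
                 "startsWithG", "containsBsmbi", "containsPolyT", "containsN")

setValidity("GuideSet", function(object) {
  msg <- character(0)
  mc <- mcols(object)
  miss <- setdiff(GUIDE_MCOLS, colnames(mc))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (any(nchar(mc$protospacer) != 20L))
      msg <- c(msg, "protospacer length must be exactly 20")
    if (any(substr(mc$pam, 2L, 3L) != "GG"))
      msg <- c(msg, "PAM must match NGG")
    inside <- mc$cut >= start(object) & mc$cut < end(object)
    if (any(!inside))
      msg <- c(msg, "cut site must lie strictly inside the protospacer interval")
    gflag <- substr(mc$protospacer, 1L, 1L) == "G"
    if (any(gflag != mc$startsWithG))
      msg <- c(msg, "startsWithG flag inconsistent with protospacer")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DesignConfig
## ---------------------------------------------------------------------------

#' Pair-design configuration
#'
#' @slot windowBp Width (bp) of the candidate window around each target
#'   boundary; cut sites must fall within `windowBp / 2` of the boundary they
#'   serve. Default 200.
#' @slot maxPairs Maximum number of ranked pairs returned.
#' @slot requireGForU6 Must the U6-slotted guide start with G? Default `TRUE`
#'   (U6 is a Pol III promoter whose transcripts conventionally start with G).
#' @slot allowPrependG If no guide of a pair starts with G, model the U6
#'   transcript with a prepended G instead of rejecting the pair.
#' @slot minPairScore Minimum pair score (min of member specificity scores).
#' @slot maxMismatch Mismatch radius for the specificity scan.
#' @slot pam PAM motif (fixed to `NGG` for SpCas9).
#' @export
setClass("DesignConfig", representation(
  windowBp = "integer", maxPairs = "integer", requireGForU6 = "logical",
  allowPrependG = "logical", minPairScore = "numeric",
  maxMismatch = "integer", pam = "character"))

setValidity("DesignConfig", function(object) {
  msg <- character(0)
  if (object@windowBp < 23L) msg <- c(msg, "windowBp must be >= 23")
  if (object@maxPairs < 1L) msg <- c(msg, "maxPairs must be >= 1")
  if (object@pam != "NGG") msg <- c(msg, "only the SpCas9 NGG PAM is supported")
  if (length(msg)) msg else TRUE
})

#' Create a pair-design configuration
#'
#' @param windowBp,maxPairs,requireGForU6,allowPrependG,minPairScore,maxMismatch
#'   See the slot documentation in [DesignConfig-class].
#' @return A `DesignConfig` object.
#' @examples
#' designConfig(windowBp = 100)
#' @export
designConfig <- function(windowBp = 200L, maxPairs = 5L, requireGForU6 = TRUE,
                         allowPrependG = FALSE, minPairScore = 0,
                         maxMismatch = 3L) {
  new("DesignConfig", windowBp = as.integer(windowBp),
      maxPairs = as.integer(maxPairs), requireGForU6 = requireGForU6,
      allowPrependG = allowPrependG, minPairScore = minPairScore,
      maxMismatch = as.integer(maxMismatch), pam = "NGG")
}

## ---------------------------------------------------------------------------
## GuidePair
## ---------------------------------------------------------------------------

#' A slotted guide pair bracketing a deletion
#'
#' @slot u6 Single-row `GuideSet` assigned to the U6 promoter slot.
#' @slot h1 Single-row `GuideSet` assigned to the H1 promoter slot.
#' @slot deletion [GenomicRanges::GRanges] of the predicted deletion (the
#'   bases between the two blunt cuts).
#' @slot deletionLen Deletion length in bp (difference of cut coordinates).
#' @slot pairScore Pair score, min of the member specificity scores.
#' @slot prependedG `TRUE` when neither guide starts with G and the U6
#'   transcript is modeled with a prepended G (the oligo still carries the
#'   exact 20-nt genomic match).
#' @export
setClass("GuidePair", representation(
  u6 = "GuideSet", h1 = "GuideSet", deletion = "GRanges",
  deletionLen = "integer", pairScore = "numeric", prependedG = "logical"))

setValidity("GuidePair", function(object) {
  msg <- character(0)
  if (length(object@u6) != 1L || length(object@h1) != 1L)
    return("u6 and h1 slots must each hold exactly one guide")
  cuts <- sort(c(mcols(object@u6)$cut, mcols(object@h1)$cut))
  if (start(object@deletion) != cuts[1] + 1L || end(object@deletion) != cuts[2])
    msg <- c(msg, "deletion interval must span the two cut coordinates")
  if (object@deletionLen != cuts[2] - cuts[1] || object@deletionLen <= 0L)
    msg <- c(msg, "deletionLen must equal the positive cut-coordinate difference")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## InsertTemplate / Insert1Oligo / ConstructModel
## ---------------------------------------------------------------------------

#' Insert-1 oligo template
#'
#' Constant segments of the single-oligo template.  The assembled oligo is
#' `gibson5 + t_u6 + scaffoldFrag + bsmbiCassette + t_h1' + h1Frag + gibson3`,
#' where the two 20-nt targeting sequences are the only variable parts and
#' `t_h1'` is `t_h1` or its reverse complement per `t2Orientation`.
#'
#' @slot gibson5 5' Gibson assembly overhang.
#' @slot scaffoldFrag Leading fragment of the first gRNA scaffold.
#' @slot bsmbiCassette Removable cloning cassette; contains exactly one
#'   `CGTCTC` and one `GAGACG` (the two BsmBI sites, pointing outward so that
#'   digestion excises both recognition sites).
#' @slot h1Frag Fragment of the H1 promoter.
#' @slot gibson3 3' Gibson assembly overhang.
#' @slot t2Orientation `"sense"` or `"revcomp"`, orientation in which the
#'   second targeting sequence is written into the oligo.
#' @export
setClass("InsertTemplate", representation(
  gibson5 = "character", scaffoldFrag = "character",
  bsmbiCassette = "character", h1Frag = "character", gibson3 = "character",
  t2Orientation = "character"))

setValidity("InsertTemplate", function(object) {
  msg <- character(0)
  segs <- c(gibson5 = object@gibson5, scaffoldFrag = object@scaffoldFrag,
            h1Frag = object@h1Frag, gibson3 = object@gibson3)
  cas <- object@bsmbiCassette
  if (.countMatches(cas, "CGTCTC") != 1L || .countMatches(cas, "GAGACG") != 1L)
    msg <- c(msg, "bsmbiCassette must contain CGTCTC exactly once and GAGACG exactly once")
  bad <- vapply(segs, function(s)
    .countMatches(s, "CGTCTC") + .countMatches(s, "GAGACG") > 0, logical(1))
  if (any(bad))
    msg <- c(msg, paste("BsmBI site in constant segment:",
                        paste(names(segs)[bad], collapse = ", ")))
  if (!object@t2Orientation %in% c("sense", "revcomp"))
    msg <- c(msg, "t2Orientation must be 'sense' or 'revcomp'")
  if (length(msg)) msg else TRUE
})

#' Assembled Insert-1 oligo
#'
#' @slot seq The full oligo sequence (165 nt with the default template).
#' @slot segments `data.frame` with columns `name`, `start`, `end`: an
#'   ordered, contiguous, non-overlapping segment map covering the oligo.
#' @export
setClass("Insert1Oligo", representation(seq = "character",
                                        segments = "data.frame"))

setValidity("Insert1Oligo", function(object) {
  seg <- object@segments
  n <- nchar(object@seq)
  if (!all(c("name", "start", "end") %in% colnames(seg)))
    return("segments must have columns name, start, end")
  if (seg$start[1] != 1L || seg$end[nrow(seg)] != n ||
      (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)] + 1L)))
    return("segments must tile the oligo contiguously")
  TRUE
})

#' Cloning-stage construct model
#'
#' Element-level model of the plasmid at one cloning stage.  `elements` is a
#' `data.frame` (columns `name`, `seq`) in functional order; `seq` is the
#' physical (circular) plasmid sequence written from an arbitrary origin.
#'
#' @slot elements Ordered named genetic elements.
#' @slot seq Physical plasmid sequence (plus strand, circular).
#' @slot stage One of `"parental"`, `"intermediate"`, `"final"`.
#' @export
setClass("ConstructModel", representation(
  elements = "data.frame", seq = "character", stage = "character"))

setValidity("ConstructModel", function(object) {
  if (!object@stage %in% c("parental", "intermediate", "final"))
    return("stage must be parental, intermediate or final")
  if (object@stage == "final" &&
      .countMatches(object@seq, "CGTCTC") + .countMatches(object@seq, "GAGACG") > 0)
    return("final construct must contain zero BsmBI recognition sites")
  TRUE
})

## ---------------------------------------------------------------------------
## Genotyping classes
## ---------------------------------------------------------------------------

#' Diagnostic primer set
#'
#' @slot extFwd,extRev External primers flanking the deletion (PCR 1, and the
#'   external member of PCRs 2-3).
#' @slot intPrimer Internal primer inside the deleted region, oriented toward
#'   `extFwd` (PCR 2; amplifies wild-type alleles only).
#' @slot invPrimer Internal primer in inverted orientation (PCR 3; amplifies
#'   inverted alleles only, paired with `extFwd`).
#' @export
setClass("PrimerSet", representation(
  extFwd = "character", extRev = "character",
  intPrimer = "character", invPrimer = "character"))

setValidity("PrimerSet", function(object) {
  p <- c(object@extFwd, object@extRev, object@intPrimer, object@invPrimer)
  if (any(nchar(p) < 15L)) return("all primers must be >= 15 nt")
  TRUE
})

#' Create a diagnostic primer set
#' @param extFwd,extRev,intPrimer,invPrimer Primer sequences (5'->3'); see
#'   [PrimerSet-class].
#' @return A `PrimerSet`.
#' @export
primerSet <- function(extFwd, extRev, intPrimer, invPrimer) {
  new("PrimerSet", extFwd = .assertDna(extFwd, "extFwd"),
      extRev = .assertDna(extRev, "extRev"),
      intPrimer = .assertDna(intPrimer, "intPrimer"),
      invPrimer = .assertDna(invPrimer, "invPrimer"))
}

#' Expected amplicon sizes for one targeting construct
#'
#' Houses the per-construct genotyping arithmetic: expected PCR-1 sizes for
#' the wild-type and deleted allele, the PCR-2 (internal, WT-only) size and
#' the PCR-3 (inversion) size, plus the band-size tolerance used when calling
#' genotypes.
#'
#' @slot name Construct name.
#' @slot nominalLen Nominal length of cut (bp) requested by the user.
#' @slot positionLabel Free-text position annotation (e.g. "-70/+30").
#' @slot wtSize,koSize Expected PCR-1 product sizes (bp) on wild-type and
#'   deleted alleles; `koSize == wtSize - deletionLen` for indel-free
#'   junctions.
#' @slot int2Size Expected PCR-2 product size (bp) on wild-type alleles.
#' @slot invSize Expected PCR-3 product size (bp) on inverted alleles
#'   (`NA` when no inversion primer is supplied).
#' @slot toleranceBp Band-size matching tolerance (bp).
#' @export
setClass("GenotypingPlan", representation(
  name = "character", nominalLen = "integer", positionLabel = "character",
  wtSize = "integer", koSize = "integer", int2Size = "integer",
  invSize = "integer", toleranceBp = "numeric"))

setValidity("GenotypingPlan", function(object) {
  msg <- character(0)
  if (!is.na(object@koSize) && object@koSize >= object@wtSize)
    msg <- c(msg, "expected KO size must be smaller than expected WT size")
  if (object@toleranceBp < 0) msg <- c(msg, "toleranceBp must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Observed band pattern of one clone
#'
#' @slot pcr1,pcr2,pcr3 Numeric vectors of observed fragment sizes (bp) in
#'   the flanking, internal and inversion PCRs (possibly empty).
#' @slot toleranceBp Size tolerance (bp); `NA` defers to the plan's.
#' @export
setClass("BandPattern", representation(
  pcr1 = "numeric", pcr2 = "numeric", pcr3 = "numeric",
  toleranceBp = "numeric"))

setValidity("BandPattern", function(object) {
  if (any(c(object@pcr1, object@pcr2, object@pcr3) <= 0))
    return("band sizes must be positive")
  TRUE
})

#' Create a band pattern
#' @param pcr1,pcr2,pcr3 Observed fragment sizes (bp) per reaction.
#' @param toleranceBp Optional size tolerance; defaults to the plan's.
#' @return A `BandPattern`.
#' @export
bandPattern <- function(pcr1 = numeric(0), pcr2 = numeric(0),
                        pcr3 = numeric(0), toleranceBp = NA_real_) {
  new("BandPattern", pcr1 = as.numeric(pcr1), pcr2 = as.numeric(pcr2),
      pcr3 = as.numeric(pcr3), toleranceBp = as.numeric(toleranceBp))
}

#' Genotype call for one clone
#'
#' @slot category One of `WT`, `HET`, `HOM_KO`, `INV_HET`, `INV_HOM`,
#'   `AMBIGUOUS`.
#' @slot evidence Named logical vector: `long`, `short`, `internal`,
#'   `inversion` band presence.
#' @export
setClass("GenotypeCall", representation(category = "character",
                                        evidence = "logical"))

GENOTYPE_CATEGORIES <- c("WT", "HET", "HOM_KO", "INV_HET", "INV_HOM",
                         "AMBIGUOUS")

setValidity("GenotypeCall", function(object) {
  if (!object@category %in% GENOTYPE_CATEGORIES)
    return("unknown genotype category")
  if (!identical(names(object@evidence),
                 c("long", "short", "internal", "inversion")))
    return("evidence must be named long, short, internal, inversion")
  TRUE
})

## ---------------------------------------------------------------------------
## Allele simulation classes
## ---------------------------------------------------------------------------

#' Specification of one simulated allele
#'
#' @slot kind `"WT"`, `"DEL"` or `"INV"`.
#' @slot junctionIndel Signed junction indel (bp) for `DEL` alleles:
#'   positive values insert random bases at the repair junction, negative
#'   values resect extra bases beyond the cut. Must satisfy
#'   `abs(junctionIndel) <= 20`; ignored (0) for `WT`/`INV`.
#' @slot seed Seed for the inserted junction bases.
#' @export
setClass("AlleleSpec", representation(
  kind = "character", junctionIndel = "integer", seed = "integer"))

setValidity("AlleleSpec", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("WT", "DEL", "INV"))
    msg <- c(msg, "kind must be WT, DEL or INV")
  if (abs(object@junctionIndel) > 20L)
    msg <- c(msg, "abs(junctionIndel) must be <= 20")
  if (object@kind != "DEL" && object@junctionIndel != 0L)
    msg <- c(msg, "junction indels apply to DEL alleles only")
  if (length(msg)) msg else TRUE
})

#' Create an allele specification
#' @param kind `"WT"`, `"DEL"` or `"INV"`.
#' @param junctionIndel Signed junction indel in bp (DEL only).
#' @param seed Seed for inserted junction bases.
#' @return An `AlleleSpec`.
#' @export
alleleSpec <- function(kind = c("WT", "DEL", "INV"), junctionIndel = 0L,
                       seed = 1L) {
  kind <- match.arg(kind)
  new("AlleleSpec", kind = kind, junctionIndel = as.integer(junctionIndel),
      seed = as.integer(seed))
}

#' Specification of one simulated clone
#'
#' @slot ploidy Number of alleles (1-4; HeLa-like pseudo-triploid clones use
#'   ploidy 3).
#' @slot alleles List of [AlleleSpec-class] of length `ploidy`.
#' @export
setClass("CloneSpec", representation(ploidy = "integer", alleles = "list"))

setValidity("CloneSpec", function(object) {
  msg <- character(0)
  if (object@ploidy < 1L || object@ploidy > 4L)
    msg <- c(msg, "ploidy must be in [1, 4]")
  if (length(object@alleles) != object@ploidy)
    msg <- c(msg, "number of alleles must equal ploidy")
  if (!all(vapply(object@alleles, is, logical(1), "AlleleSpec")))
    msg <- c(msg, "alleles must be AlleleSpec objects")
  if (length(msg)) msg else TRUE
})

#' Create a clone specification
#' @param alleles List of [AlleleSpec-class] objects (or kind strings).
#' @param ploidy Number of alleles; defaults to `length(alleles)`.
#' @return A `CloneSpec`.
#' @examples
#' cloneSpec(list("WT", "DEL"))               # diploid heterozygote
#' cloneSpec(list("WT", "DEL", "DEL"))        # pseudo-triploid heterozygote
#' @export
cloneSpec <- function(alleles, ploidy = length(alleles)) {
  alleles <- lapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (is.character(a)) alleleSpec(a, seed = i) else a
  })
  new("CloneSpec", ploidy = as.integer(ploidy), alleles = alleles)
}
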