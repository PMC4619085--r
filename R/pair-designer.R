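## pair_designer: select and slot guide pairs bracketing a target region.

## Gap coordinates of the two target boundaries: the deletion should open
## just before the first target base and close just after the last.
.boundaryGaps <- function(target) {
  c(left = start(target) - 1L, right = end(target))
}

#' Assign a guide pair to the U6/H1 promoter slots
#'
#' U6-driven transcripts are required to start with G, so the G-starting
#' guide takes the U6 slot; if both start with G the left (lower-coordinate)
#' guide takes U6. If neither starts with G the pair is rejected unless
#' `allowPrependG` is set, in which case the left guide takes U6 and its
#' transcript is modeled with a prepended G (the oligo still carries the
#' exact 20-nt genomic match).
#'
#' @param left,right Single-row [GuideSet-class] candidates, `left` having
#'   the lower cut coordinate.
#' @param cfg A [designConfig()] object.
#' @return A [GuidePair-class].
#' @export
assignSlots <- function(left, right, cfg = designConfig()) {
  stopifnot(is(left, "GuideSet"), is(right, "GuideSet"),
            length(left) == 1L, length(right) == 1L)
  cuts <- c(cutSite(left), cutSite(right))
  if (cuts[1] == cuts[2])
    stop("degenerate pair: both guides cut at coordinate ", cuts[1],
         call. = FALSE)
  if (cuts[1] > cuts[2]) { tmp <- left; left <- right; right <- tmp
                           cuts <- rev(cuts) }
  gL <- mcols(left)$startsWithG
  gR <- mcols(right)$startsWithG
  prepended <- FALSE
  if (!cfg@requireGForU6 || gL) {
    u6 <- left; h1 <- right
  } else if (gR) {
    u6 <- right; h1 <- left
  } else if (cfg@allowPrependG) {
    u6 <- left; h1 <- right; prepended <- TRUE
  } else {
    stop("slot rejection: neither guide starts with G; ",
         "set allowPrependG = TRUE to model a G-prepended U6 transcript",
         call. = FALSE)
  }
  del <- GRanges(seqnames(left)[1], IRanges(cuts[1] + 1L, cuts[2]))
  score <- suppressWarnings(min(guideScore(left), guideScore(right)))
  new("GuidePair", u6 = u6, h1 = h1, deletion = del,
      deletionLen = cuts[2] - cuts[1], pairScore = as.numeric(score),
      prependedG = prepended)
}

#' Predicted deletion interval of a pair
#'
#' The deletion is the interval between the two blunt-cut coordinates; its
#' length is their exact difference, which guarantees that the KO amplicon is
#' `deletionLength` bp shorter than the WT amplicon for indel-free junctions.
#'
#' @param pair A [GuidePair-class].
#' @return List with elements `region` ([GenomicRanges::GRanges]) and
#'   `length` (bp).
#' @export
predictedDeletion <- function(pair) {
  stopifnot(is(pair, "GuidePair"))
  cuts <- cutSite(pair)
  if (cuts[1] == cuts[2])
    stop("degenerate pair: identical cut sites", call. = FALSE)
  list(region = deletionRegion(pair), length = deletionLength(pair))
}

#' Design ranked guide pairs deleting a target region
#'
#' Candidates are drawn from windows of width `windowBp` centered on the two
#' target boundaries; a pair is kept when its left cut lies within
#' `windowBp / 2` of the target start, its right cut within `windowBp / 2` of
#' the target end, the left cut precedes the right cut and the two
#' protospacers do not overlap. Kept pairs are slotted under the U6 G rule,
#' scored as the minimum of the member specificity scores, and ranked by
#' score, then by closeness of the realized deletion length to the requested
#' target length, then by genomic position.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character).
#' @param target Single-range [GenomicRanges::GRanges]: the region to delete.
#' @param cfg A [designConfig()].
#' @param score Logical; compute specificity scores (set `FALSE` for a quick
#'   unscored design, ranking then falls back to deletion-length fit).
#' @return List of [GuidePair-class], best first (at most `maxPairs`).
#' @export
designPairs <- function(genome, target, cfg = designConfig(), score = TRUE) {
  genome <- .asGenomeSet(genome)
  stopifnot(is(target, "GRanges"), length(target) == 1L)
  chrom <- as.character(seqnames(target))
  if (!chrom %in% names(genome))
    stop("unknown sequence identifier: ", chrom, call. = FALSE)
  n <- length(genome[[chrom]])
  half <- cfg@windowBp %/% 2L
  gaps <- .boundaryGaps(target)

  candidatesFor <- function(b, side) {
    ## pad so protospacers whose cut is in-window but body pokes out are seen
    lo <- max(1L, b - half - 22L)
    hi <- min(n, b + half + 22L)
    gs <- findProtospacers(genome, GRanges(chrom, IRanges(lo, hi)))
    gs <- filterCandidates(gs)
    gs <- gs[abs(cutSite(gs) - b) <= half]
    if (!length(gs))
      stop("no usable guide candidate in the ", side,
           " window (", cfg@windowBp, " bp centered on boundary ", b, ")",
           call. = FALSE)
    gs
  }
  leftC <- candidatesFor(gaps["left"], "left")
  rightC <- candidatesFor(gaps["right"], "right")
  if (score) {
    leftC <- scoreGuides(leftC, genome, cfg@maxMismatch)
    rightC <- scoreGuides(rightC, genome, cfg@maxMismatch)
  }

  targetLen <- width(target)
  ## enumerate candidate combinations on plain vectors; S4 pair objects are
  ## built only for the top-ranked ones
  cutL <- cutSite(leftC); cutR <- cutSite(rightC)
  startL <- start(leftC); endL <- end(leftC)
  startR <- start(rightC); endR <- end(rightC)
  gFlagL <- mcols(leftC)$startsWithG; gFlagR <- mcols(rightC)$startsWithG
  scL <- guideScore(leftC); scR <- guideScore(rightC)
  grid <- expand.grid(i = seq_along(leftC), j = seq_along(rightC))
  ordered <- cutL[grid$i] < cutR[grid$j]
  nonOverlap <- endL[grid$i] < startR[grid$j] | endR[grid$j] < startL[grid$i]
  geom <- ordered & nonOverlap
  slottable <- if (!cfg@requireGForU6 || cfg@allowPrependG) geom
               else geom & (gFlagL[grid$i] | gFlagR[grid$j])
  pairSc <- pmin(scL[grid$i], scR[grid$j])
  keep <- slottable
  if (score) keep <- keep & (is.na(pairSc) | pairSc >= cfg@minPairScore)
  if (!any(keep)) {
    if (any(geom) && cfg@requireGForU6 && !cfg@allowPrependG &&
        !any(slottable))
      stop("no slottable pair: no candidate combination satisfies the U6 ",
           "G-start rule; consider allowPrependG = TRUE", call. = FALSE)
    stop("no valid guide pair for target ", chrom, ":", start(target), "-",
         end(target), call. = FALSE)
  }
  grid <- grid[keep, , drop = FALSE]
  sc <- pairSc[keep]
  sc[is.na(sc)] <- 0
  lenDev <- abs((cutR[grid$j] - cutL[grid$i]) - targetLen)
  ord <- order(-sc, lenDev, cutL[grid$i], cutR[grid$j])
  top <- head(ord, cfg@maxPairs)
  lapply(top, function(k)
    assignSlots(leftC[grid$i[k]], rightC[grid$j[k]], cfg))
}

#' Summarize designed pairs as a report table
#'
#' @param pairs List of [GuidePair-class] (as returned by [designPairs()]).
#' @param name Target name recorded in the first column.
#' @return One row per pair: protospacers, PAMs, cut coordinates, deletion
#'   interval/length and pair score.
#' @export
pairTable <- function(pairs, name = "target") {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(target = name,
               u6_protospacer = protospacer(u6Guide(p)),
               u6_pam = pam(u6Guide(p)),
               u6_cut = cutSite(u6Guide(p)),
               h1_protospacer = protospacer(h1Guide(p)),
               h1_pam = pam(h1Guide(p)),
               h1_cut = cutSite(h1Guide(p)),
               chrom = as.character(seqnames(deletionRegion(p))),
               deletion_start = start(deletionRegion(p)),
               deletion_end = end(deletionRegion(p)),
               deletion_len = deletionLength(p),
               pair_score = pairScore(p),
               prepended_g = p@prependedG)
  }))
}
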