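## guide_finder: protospacer enumeration, cut-site prediction, constraint
## filtering and a brute-force mismatch-weighted specificity score.

## Build a GuideSet from parallel vectors.
.newGuideSet <- function(chrom, start, strand, protospacer, pam, cut,
                         score = NA_real_) {
  n <- length(start)
  gr <- GRanges(seqnames = rep(chrom, n),
                ranges = IRanges(start = start, width = 20L),
                strand = strand)
  mcols(gr) <- DataFrame(
    protospacer = protospacer, pam = pam, cut = as.integer(cut),
    score = rep_len(as.numeric(score), n),
    startsWithG = substr(protospacer, 1L, 1L) == "G",
    containsBsmbi = grepl("CGTCTC|GAGACG", protospacer),
    containsPolyT = grepl("TTTT", protospacer),
    containsN = grepl("N", protospacer))
  new("GuideSet", gr)
}

.emptyGuideSet <- function() {
  .newGuideSet(character(0), integer(0), character(0), character(0),
               character(0), integer(0))
}

#' Enumerate SpCas9 protospacer candidates in a region
#'
#' Scans both strands of `search` for every 20-mer immediately followed by an
#' `NGG` PAM, fully contained in the search interval. Minus-strand candidates
#' report the protospacer as read 5'->3' on the minus strand. The predicted
#' blunt cut falls between protospacer nucleotides 17 and 18 (counting from
#' the PAM-distal end), i.e. 3 bp from the PAM; `cut` is the plus-strand gap
#' coordinate of the break (between bases `cut` and `cut + 1`).
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character).
#' @param search Single-range [GenomicRanges::GRanges] search interval.
#' @return A [GuideSet-class], sorted by genomic position then strand.
#'   Intervals shorter than 23 bp yield an empty set.
#' @export
findProtospacers <- function(genome, search) {
  genome <- .asGenomeSet(genome)
  stopifnot(is(search, "GRanges"), length(search) == 1L)
  chrom <- as.character(seqnames(search))
  if (width(search) < 23L) return(.emptyGuideSet())
  win <- extractRegion(genome, GRanges(chrom, IRanges(start(search),
                                                      end(search))))
  off <- start(search) - 1L     # local position i -> genomic off + i
  n <- nchar(win)

  ## plus strand: protospacer [s, s+19], PAM [s+20, s+22] with GG at
  ## [s+21, s+22]; so each "GG" start g gives s = g - 21.
  gg <- .allMatches(win, "GG")
  sPlus <- gg - 21L
  sPlus <- sPlus[sPlus >= 1L & sPlus + 22L <= n]
  ## minus strand: "CC" start j => PAM genomic-local [j, j+2],
  ## protospacer [j+3, j+22], read on the minus strand.
  cc <- .allMatches(win, "CC")
  jMinus <- cc[cc >= 1L & cc + 22L <= n]

  if (!length(sPlus) && !length(jMinus)) return(.emptyGuideSet())

  protoP <- pamP <- protoM <- pamM <- character(0)
  cutP <- cutM <- integer(0)
  if (length(sPlus)) {
    protoP <- .substrs(win, sPlus, 20L)
    pamP <- .substrs(win, sPlus + 20L, 3L)
    cutP <- off + sPlus + 16L                # break after nt 17 of protospacer
  }
  if (length(jMinus)) {
    protoM <- revComp(.substrs(win, jMinus + 3L, 20L))
    pamM <- revComp(.substrs(win, jMinus, 3L))
    cutM <- off + jMinus + 5L                # mirror of the plus-strand rule
  }

  startG <- off + c(sPlus, jMinus + 3L)
  strandV <- c(rep("+", length(sPlus)), rep("-", length(jMinus)))
  gs <- .newGuideSet(chrom, startG, strandV,
                     c(protoP, protoM), c(pamP, pamM), c(cutP, cutM))
  ord <- order(start(gs), as.character(strand(gs)))
  gs[ord]
}

#' Filter guide candidates on cloning and expression constraints
#'
#' Removes candidates whose protospacer contains a BsmBI recognition site
#' (`CGTCTC`/`GAGACG`, which would be cleaved during cloning), a `TTTT` run
#' (Pol III terminator) or an `N`. The G-start property is kept as a flag:
#' slot assignment, not filtering, decides U6 eligibility.
#'
#' @param guides A [GuideSet-class].
#' @param bsmbi,polyT,n Logical; apply the corresponding filter.
#' @return The filtered `GuideSet`.
#' @export
filterCandidates <- function(guides, bsmbi = TRUE, polyT = TRUE, n = TRUE) {
  stopifnot(is(guides, "GuideSet"))
  keep <- rep(TRUE, length(guides))
  mc <- mcols(guides)
  if (bsmbi) keep <- keep & !mc$containsBsmbi
  if (polyT) keep <- keep & !mc$containsPolyT
  if (n) keep <- keep & !mc$containsN
  guides[keep]
}

MISMATCH_WEIGHTS <- c(`0` = 10, `1` = 3, `2` = 1, `3` = 0.2)

## All genomic sites matching `proto` with <= maxMismatch mismatches and an
## NGG PAM, on both strands. Returns data.frame(chrom, start, strand, mm).
.offTargetSites <- function(proto, genome, maxMismatch) {
  out <- list()
  pat <- Biostrings::DNAString(proto)
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    n <- length(subj)
    for (str in c("+", "-")) {
      s <- if (str == "+") subj else Biostrings::reverseComplement(subj)
      hits <- Biostrings::matchPattern(pat, s, max.mismatch = maxMismatch,
                                       with.indels = FALSE)
      if (!length(hits)) next
      st <- BiocGenerics::start(hits)
      ok <- st + 22L <= n
      st <- st[ok]
      if (!length(st)) next
      schar <- as.character(s)
      pamOk <- .substrs(schar, st + 21L, 2L) == "GG"
      st <- st[pamOk]
      if (!length(st)) next
      hitSeq <- .substrs(schar, st, 20L)
      mm <- vapply(hitSeq, function(h)
        sum(charToRaw(h) != charToRaw(proto)), integer(1), USE.NAMES = FALSE)
      gStart <- if (str == "+") st else n - st - 18L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = gStart, strand = str, mm = mm)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mm = integer(0)))
  do.call(rbind, out)
}

#' Brute-force mismatch-weighted specificity score
#'
#' Exhaustively counts genomic sites (both strands) matching the protospacer
#' with at most `maxMismatch` mismatches and carrying an `NGG` PAM, excluding
#' the on-target site itself, and returns
#' `1 / (1 + sum(w(m)))` with weights `w(0) = 10`, `w(1) = 3`, `w(2) = 1`,
#' `w(3) = 0.2`. The score is 1 exactly when no off-target site exists within
#' the mismatch radius. Mismatch counting is ungapped and protospacer-only.
#'
#' @param guide Single-row [GuideSet-class] (or the set; then vectorized).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param maxMismatch Mismatch radius, 0-3.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
specificityScore <- function(guide, genome, maxMismatch = 3L) {
  stopifnot(is(guide, "GuideSet"), maxMismatch >= 0L, maxMismatch <= 3L)
  genome <- .asGenomeSet(genome)
  vapply(seq_along(guide), function(i) {
    g <- guide[i]
    sites <- .offTargetSites(protospacer(g), genome, maxMismatch)
    own <- sites$chrom == as.character(seqnames(g)) &
      sites$start == start(g) & sites$strand == as.character(strand(g)) &
      sites$mm == 0L
    if (!any(own))
      stop("on-target site for guide ", protospacer(g),
           " not found in the genome (candidate/genome mismatch)",
           call. = FALSE)
    sites <- sites[!(seq_len(nrow(sites)) %in% which(own)[1]), , drop = FALSE]
    1 / (1 + sum(MISMATCH_WEIGHTS[as.character(sites$mm)]))
  }, numeric(1))
}

#' Fill specificity scores into a guide set
#'
#' @inheritParams specificityScore
#' @param guides A [GuideSet-class].
#' @return The `GuideSet` with its `score` column populated.
#' @export
scoreGuides <- function(guides, genome, maxMismatch = 3L) {
  if (length(guides))
    mcols(guides)$score <- specificityScore(guides, genome, maxMismatch)
  guides
}

#' Export guide candidates as a TSV table
#'
#' @param guides A [GuideSet-class].
#' @return `data.frame` with columns chrom, start, end, strand, protospacer,
#'   pam, cut_pos, score, flags.
#' @export
guideTable <- function(guides) {
  stopifnot(is(guides, "GuideSet"))
  fl <- guideFlags(guides)
  flagStr <- apply(fl, 1L, function(r)
    paste(colnames(fl)[as.logical(r)], collapse = ","))
  if (!length(guides)) flagStr <- character(0)
  data.frame(chrom = as.character(seqnames(guides)), start = start(guides),
             end = end(guides), strand = as.character(strand(guides)),
             protospacer = protospacer(guides), pam = pam(guides),
             cut_pos = cutSite(guides), score = guideScore(guides),
             flags = flagStr)
}
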