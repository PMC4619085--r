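## allele_sim: seeded synthetic loci and clone allele sets. This generator
## is the toolkit's closed-loop oracle: simulated clones must be classified
## back to their true genotype by the genotyping module.

## Does a design window centered on gap coordinate `b` hold a filter-passing
## G-starting candidate cutting within `half` bp of `b`?
.windowCandidate <- function(locusSet, b, half) {
  n <- length(locusSet[[1]])
  lo <- max(1L, b - half - 22L)
  hi <- min(n, b + half + 22L)
  gs <- findProtospacers(locusSet, GRanges(names(locusSet)[1],
                                          IRanges(lo, hi)))
  gs <- filterCandidates(gs)
  gs <- gs[abs(cutSite(gs) - b) <= half & mcols(gs)$startsWithG]
  length(gs) > 0L
}

## A random filter-clean G-starting protospacer.
.cleanProtospacer <- function() {
  repeat {
    p <- paste0("G", paste(sample(c("A", "C", "G", "T"), 19L, TRUE),
                           collapse = ""))
    ## the junction guards (GAGAC$/CGTCT$) keep engineered protospacers from
    ## completing a BsmBI site across an oligo segment boundary
    if (!grepl("TTTT|CGTCTC|GAGACG|GAGAC$|CGTCT$", p)) return(p)
  }
}

#' Generate a reproducible synthetic locus with valid SpCas9 sites
#'
#' Draws a random sequence of the requested length and GC content, then
#' guarantees that each design window (width `windowBp`, centered on the two
#' target boundaries) contains at least one filter-passing, G-starting guide
#' candidate whose cut lies in the window - engineering a protospacer + AGG
#' PAM in place when the random draw lacks one. The same seed always yields
#' the identical sequence.
#'
#' @param seed Integer seed.
#' @param length Locus length (bp).
#' @param gc GC fraction in `(0, 1)`.
#' @param target Either a single-range [GenomicRanges::GRanges] or
#'   `c(start, end)` (1-based, closed) of the region to delete.
#' @param windowBp Design window width (bp), matching the designer's.
#' @param name Sequence identifier.
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @export
makeSyntheticLocus <- function(seed, length = 5000L, gc = 0.5,
                               target = c(2200L, 2800L), windowBp = 200L,
                               name = "synthetic_locus") {
  if (is(target, "GRanges")) target <- c(start(target), end(target))
  stopifnot(length(target) == 2L, target[1] < target[2], gc > 0, gc < 1)
  half <- as.integer(windowBp) %/% 2L
  margin <- half + 160L   # room for design windows and flanking primers
  if (target[1] - margin < 1L || target[2] + margin > length)
    stop("impossible geometry: locus of length ", length,
         " leaves no room for design windows and primers around target [",
         target[1], ", ", target[2], "]", call. = FALSE)
  .withSeed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(probs), length, TRUE, prob = probs),
               collapse = "")
    gaps <- c(left = target[1] - 1L, right = target[2])
    for (b in gaps) {
      set <- Biostrings::DNAStringSet(s)
      names(set) <- name
      if (!.windowCandidate(set, b, half)) {
        proto <- .cleanProtospacer()
        site <- paste0(proto, "AGG")          # cut lands exactly at gap b
        at <- b - 16L
        substr(s, at, at + 22L) <- site
      }
    }
    out <- Biostrings::DNAStringSet(s)
    names(out) <- name
    out
  })
}

#' Apply a deletion allele to a locus
#'
#' Joins the sequence flanks at the pair's two blunt-cut coordinates.
#' A positive `junctionIndel` inserts that many random bases (seeded from
#' the spec) at the repair junction; a negative value resects extra bases
#' from the downstream flank. The allele length is
#' `length(locus) - deletionLength(pair) + junctionIndel`.
#'
#' @param locus Single sequence (character, [Biostrings::DNAStringSet], ...).
#' @param pair A [GuidePair-class].
#' @param spec An [AlleleSpec-class] with `kind == "DEL"`.
#' @return Character allele sequence.
#' @export
applyDeletion <- function(locus, pair, spec = alleleSpec("DEL")) {
  stopifnot(is(pair, "GuidePair"), is(spec, "AlleleSpec"),
            spec@kind == "DEL")
  s <- as.character(.asGenomeSet(locus)[[1]])
  n <- nchar(s)
  cuts <- cutSite(pair)
  k <- spec@junctionIndel
  prefix <- substr(s, 1L, cuts[1])
  suffixFrom <- cuts[2] + 1L + if (k < 0L) -k else 0L
  ins <- if (k > 0L)
    .withSeed(spec@seed,
              paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""))
  else ""
  paste0(prefix, ins, substr(s, suffixFrom, n))
}

#' Apply an inversion allele to a locus
#'
#' Replaces the segment between the two cut coordinates by its reverse
#' complement; total length is preserved and applying the operation twice
#' restores the original locus.
#'
#' @inheritParams applyDeletion
#' @return Character allele sequence.
#' @export
applyInversion <- function(locus, pair) {
  stopifnot(is(pair, "GuidePair"))
  s <- as.character(.asGenomeSet(locus)[[1]])
  cuts <- cutSite(pair)
  paste0(substr(s, 1L, cuts[1]),
         revComp(substr(s, cuts[1] + 1L, cuts[2])),
         substr(s, cuts[2] + 1L, nchar(s)))
}

#' Simulate the allele sequences of a clone
#'
#' @param locus Single wild-type sequence.
#' @param pair A [GuidePair-class].
#' @param clone A [CloneSpec-class].
#' @param seed Optional integer; when given, per-allele insertion seeds are
#'   derived from it deterministically (overriding the specs' own seeds).
#' @return Named character vector of allele sequences (`allele1`, ...).
#' @export
simulateClone <- function(locus, pair, clone, seed = NULL) {
  stopifnot(is(clone, "CloneSpec"))
  wt <- as.character(.asGenomeSet(locus)[[1]])
  out <- vapply(seq_along(clone@alleles), function(i) {
    a <- clone@alleles[[i]]
    if (!is.null(seed))
      a@seed <- .childSeed(seed, i)
    switch(a@kind,
           WT = wt,
           DEL = applyDeletion(wt, pair, a),
           INV = applyInversion(wt, pair))
  }, character(1))
  names(out) <- paste0("allele", seq_along(out))
  out
}

#' True genotype category implied by a clone specification
#'
#' The category the band classifier should recover: clones with any inverted
#' allele are `INV_HET` (a wild-type allele remains) or `INV_HOM` (none
#' does); otherwise all-WT is `WT`, mixed WT/DEL is `HET` and all-DEL is
#' `HOM_KO`.
#'
#' @param clone A [CloneSpec-class].
#' @return Category string.
#' @export
expectedCategory <- function(clone) {
  stopifnot(is(clone, "CloneSpec"))
  kinds <- vapply(clone@alleles, function(a) a@kind, "")
  if (any(kinds == "INV")) {
    if (any(kinds == "WT")) "INV_HET" else "INV_HOM"
  } else if (all(kinds == "WT")) "WT"
  else if (any(kinds == "WT")) "HET"
  else "HOM_KO"
}
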