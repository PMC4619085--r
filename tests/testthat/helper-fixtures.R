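suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Independent character-level reverse complement (used by test oracles so
## they do not lean on the package's own revComp).
oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

randomDna <- function(n, seed = NULL, letters = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## Naive double-strand sliding-window protospacer scan: the oracle for
## findProtospacers. Returns a data.frame sorted by (start, strand).
oracleScan <- function(seq, offset = 0L) {
  n <- nchar(seq)
  out <- list()
  if (n >= 23L) {
    for (i in seq_len(n - 22L)) {
      w23 <- substr(seq, i, i + 22L)
      if (substr(w23, 22L, 23L) == "GG") {        # plus: N20 + NGG
        out[[length(out) + 1L]] <- data.frame(
          start = offset + i, strand = "+",
          protospacer = substr(w23, 1L, 20L), pam = substr(w23, 21L, 23L),
          cut = offset + i + 16L)
      }
      if (substr(w23, 1L, 2L) == "CC") {          # minus: CCN + N20
        out[[length(out) + 1L]] <- data.frame(
          start = offset + i + 3L, strand = "-",
          protospacer = oracleRevComp(substr(w23, 4L, 23L)),
          pam = oracleRevComp(substr(w23, 1L, 3L)),
          cut = offset + i + 5L)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      cut = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## A low-complexity AT backbone with exactly one engineered guide site per
## target boundary (no other NGG/CCN sites exist), so designs are fully
## predictable. Cut gaps land `outside` bp outside each boundary.
engineeredLocus <- function(length = 5000L, target = c(2200L, 2800L),
                            outside = 50L,
                            protoL = "GACTACTAGTCATGCATGCA",
                            protoR = "GTCATCATGACTGATCATCA") {
  backbone <- strrep("AT", ceiling(length / 2))
  s <- substr(backbone, 1L, length)
  cutL <- target[1] - 1L - outside
  cutR <- target[2] + outside
  siteL <- paste0(protoL, "AGG")
  siteR <- paste0(protoR, "AGG")
  substr(s, cutL - 16L, cutL + 6L) <- siteL
  substr(s, cutR - 16L, cutR + 6L) <- siteR
  g <- DNAStringSet(s)
  names(g) <- "engineered"
  g
}

## Shared synthetic fixture: locus, target, designed pair, primers, plan.
## Computed once per test session.
fixtureEnv <- new.env()
getFixture <- function() {
  if (is.null(fixtureEnv$fx)) {
    locus <- makeSyntheticLocus(seed = 101L, length = 5000L, gc = 0.5,
                                target = c(2200L, 2800L))
    target <- GRanges("synthetic_locus", IRanges(2200L, 2800L))
    pairs <- designPairs(locus, target)
    pair <- pairs[[1]]
    primers <- pickPrimers(locus, pair)
    plan <- predictAmplicons(locus, pair, primers, name = "fixture")
    fixtureEnv$fx <- list(locus = locus, target = target, pairs = pairs,
                          pair = pair, primers = primers, plan = plan)
  }
  fixtureEnv$fx
}

## Build a single-guide GuideSet row for slotting/arithmetic tests.
makeGuide <- function(start, strand = "+", proto = NULL, chrom = "c1") {
  if (is.null(proto)) proto <- paste0("G", randomDna(19))
  cut <- if (strand == "+") start + 16L else start + 2L
  crisprDel:::.newGuideSet(chrom, as.integer(start), strand, proto,
                           pam = "AGG", cut = cut, score = 1)
}
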