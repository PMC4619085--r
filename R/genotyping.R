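## genotyping: in-silico PCR, expected amplicon-size prediction for WT /
## deleted / inverted alleles, and the three-stage band-pattern classifier.

#' Exact-match in-silico PCR
#'
#' Finds every product where one primer binds the plus strand and the other
#' the minus strand downstream of it (exact matches only). The product size
#' is the inclusive span between the outermost primer 5' ends. Both
#' orientation assignments of the two primers are considered; only products
#' of at most `maxLen` bp are reported.
#'
#' @param templates Character vector (optionally named) or
#'   [Biostrings::DNAStringSet] of template sequences.
#' @param fwd,rev Primer sequences, 5'->3', each at least 15 nt.
#' @param maxLen Maximum reported product size (bp).
#' @return `data.frame` with columns `template` and `size`; zero rows when
#'   nothing amplifies.
#' @export
inSilicoPcr <- function(templates, fwd, rev, maxLen = 10000L) {
  templates <- .asGenomeSet(templates)
  fwd <- .assertDna(fwd, "fwd primer", allowN = FALSE)
  rev <- .assertDna(rev, "rev primer", allowN = FALSE)
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  out <- list()
  for (id in names(templates)) {
    tp <- as.character(templates[[id]])
    for (pair in list(c(fwd, rev), c(rev, fwd))) {
      fStarts <- .allMatches(tp, pair[1])
      rEnds <- .allMatches(tp, revComp(pair[2])) + nchar(pair[2]) - 1L
      if (!length(fStarts) || !length(rEnds)) next
      for (fs in fStarts) {
        sizes <- rEnds[rEnds >= fs + nchar(pair[1]) - 1L] - fs + 1L
        sizes <- sizes[sizes <= maxLen]
        if (length(sizes))
          out[[length(out) + 1L]] <- data.frame(template = id, size = sizes)
      }
    }
  }
  if (!length(out))
    return(data.frame(template = character(0), size = integer(0)))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res[order(res$template, res$size), , drop = FALSE]
}

#' Default band-size tolerance
#'
#' Agarose-resolution heuristic: `max(10, 0.05 * expected)` bp.
#'
#' @param expected Expected band size (bp).
#' @return Tolerance in bp.
#' @export
bandTolerance <- function(expected) pmax(10, 0.05 * expected)

#' Create a genotyping plan from known expected sizes
#'
#' Constructor for externally supplied expectations (e.g. a published table
#' of expected WT/KO PCR sizes) when no locus model is available;
#' [predictAmplicons()] builds the same object from a designed pair.
#'
#' @param name Construct name.
#' @param wtSize,koSize Expected PCR-1 sizes (bp) on WT and deleted alleles.
#' @param int2Size Expected PCR-2 (internal, WT-only) size; `NA` if unused.
#' @param invSize Expected PCR-3 (inversion) size; `NA` if unused.
#' @param nominalLen Nominal cut length (bp).
#' @param positionLabel Free-text position annotation.
#' @param toleranceBp Band tolerance; default [bandTolerance()] of `koSize`.
#' @return A [GenotypingPlan-class].
#' @export
genotypingPlan <- function(name, wtSize, koSize, int2Size = NA_integer_,
                           invSize = NA_integer_, nominalLen = wtSize - koSize,
                           positionLabel = "", toleranceBp = NULL) {
  if (is.null(toleranceBp)) toleranceBp <- bandTolerance(koSize)
  new("GenotypingPlan", name = name, nominalLen = as.integer(nominalLen),
      positionLabel = positionLabel, wtSize = as.integer(wtSize),
      koSize = as.integer(koSize), int2Size = as.integer(int2Size),
      invSize = as.integer(invSize), toleranceBp = as.numeric(toleranceBp))
}

#' Predict diagnostic amplicon sizes for a designed deletion
#'
#' Runs [inSilicoPcr()] against the wild-type locus, the simulated deletion
#' allele and the simulated inversion allele to fill a [GenotypingPlan-class]:
#' PCR 1 (external primers) sizes on WT and KO alleles (the KO product is
#' exactly `deletionLength(pair)` bp shorter), PCR 2 (external + internal
#' primer, WT alleles only) and PCR 3 (external + inverted internal primer,
#' inverted alleles only; the inversion allele gives a WT-sized PCR-1
#' product).
#'
#' @param locus Named single-sequence genome ([Biostrings::DNAStringSet] or
#'   named character).
#' @param pair A [GuidePair-class].
#' @param primers A [PrimerSet-class].
#' @param name Construct name.
#' @param nominalLen Nominal cut length (bp); defaults to the realized
#'   deletion length.
#' @param positionLabel Free-text position annotation.
#' @param toleranceBp Band tolerance; default [bandTolerance()] of the KO size.
#' @return A [GenotypingPlan-class].
#' @export
predictAmplicons <- function(locus, pair, primers, name = "target",
                             nominalLen = NULL, positionLabel = "",
                             toleranceBp = NULL) {
  stopifnot(is(pair, "GuidePair"), is(primers, "PrimerSet"))
  locus <- .asGenomeSet(locus)
  wt <- as.character(locus[[1]])
  del <- applyDeletion(wt, pair, alleleSpec("DEL"))
  inv <- applyInversion(wt, pair)
  cuts <- cutSite(pair)

  ## primer geometry checks against the wild-type locus
  fPos <- .allMatches(wt, primers@extFwd)
  rPos <- .allMatches(wt, revComp(primers@extRev))
  iPos <- .allMatches(wt, revComp(primers@intPrimer))
  if (length(fPos) != 1L || fPos + nchar(primers@extFwd) - 1L > cuts[1])
    stop("primer extFwd must bind uniquely upstream of the deletion",
         call. = FALSE)
  if (length(rPos) != 1L || rPos <= cuts[2])
    stop("primer extRev must bind uniquely downstream of the deletion",
         call. = FALSE)
  if (length(iPos) != 1L || iPos <= cuts[1] ||
      iPos + nchar(primers@intPrimer) - 1L > cuts[2])
    stop("primer intPrimer must bind uniquely and strictly inside the ",
         "deleted region", call. = FALSE)

  one <- function(tmpl, fwd, rev, what, required = TRUE) {
    r <- inSilicoPcr(c(allele = tmpl), fwd, rev)
    if (nrow(r) == 0L) {
      if (required)
        stop("primer pair for ", what, " produced no product", call. = FALSE)
      return(NA_integer_)
    }
    as.integer(min(r$size))
  }
  wtSize <- one(wt, primers@extFwd, primers@extRev, "PCR 1 on WT")
  koSize <- one(del, primers@extFwd, primers@extRev, "PCR 1 on KO allele")
  int2 <- one(wt, primers@extFwd, primers@intPrimer, "PCR 2 on WT")
  invSize <- one(inv, primers@extFwd, primers@invPrimer,
                 "PCR 3 on inversion allele")
  if (koSize != wtSize - deletionLength(pair))
    stop("internal inconsistency: KO product is not WT - deletion length",
         call. = FALSE)
  invPcr1 <- one(inv, primers@extFwd, primers@extRev, "PCR 1 on inversion")
  if (invPcr1 != wtSize)
    stop("inversion allele must give a WT-sized PCR-1 product", call. = FALSE)
  if (is.null(toleranceBp)) toleranceBp <- bandTolerance(koSize)
  new("GenotypingPlan", name = name,
      nominalLen = as.integer(if (is.null(nominalLen))
        deletionLength(pair) else nominalLen),
      positionLabel = positionLabel, wtSize = wtSize, koSize = koSize,
      int2Size = int2, invSize = invSize, toleranceBp = toleranceBp)
}

#' Classify a clone genotype from its band pattern
#'
#' Reduces the observed bands to four evidence booleans (PCR-1 long band at
#' the WT size, PCR-1 short band at the KO size, PCR-2 internal band, PCR-3
#' inversion band), matching within the size tolerance, then applies the
#' three-stage truth table: an inversion band gives `INV_HET` when the
#' internal (WT-allele) band is also present and `INV_HOM` when a long or
#' short band is present without the internal band; otherwise
#' long+internal without short is `WT`, long+short+internal is `HET` (the
#' internal band is authoritative for WT-allele presence), short alone is
#' `HOM_KO`, and anything else is `AMBIGUOUS` with the evidence attached.
#' The classifier is total: unmatched bands never crash, they simply leave
#' their evidence flag unset.
#'
#' @param plan A [GenotypingPlan-class].
#' @param bands A [BandPattern-class].
#' @return A [GenotypeCall-class].
#' @export
classifyGenotype <- function(plan, bands) {
  stopifnot(is(plan, "GenotypingPlan"), is(bands, "BandPattern"))
  tol <- if (is.na(bands@toleranceBp)) plan@toleranceBp else bands@toleranceBp
  near <- function(obs, expected) {
    !is.na(expected) && length(obs) > 0 && any(abs(obs - expected) <= tol)
  }
  ev <- c(long = near(bands@pcr1, plan@wtSize),
          short = near(bands@pcr1, plan@koSize),
          internal = near(bands@pcr2, plan@int2Size),
          inversion = near(bands@pcr3, plan@invSize))
  cat <- if (ev[["inversion"]]) {
    if (ev[["internal"]]) "INV_HET"
    else if (ev[["long"]] || ev[["short"]]) "INV_HOM"
    else "AMBIGUOUS"
  } else if (ev[["long"]] && !ev[["short"]] && ev[["internal"]]) "WT"
  else if (ev[["long"]] && ev[["short"]] && ev[["internal"]]) "HET"
  else if (ev[["short"]] && !ev[["long"]] && !ev[["internal"]]) "HOM_KO"
  else "AMBIGUOUS"
  new("GenotypeCall", category = cat, evidence = ev)
}

#' Naive unique-primer picker for a designed deletion
#'
#' Optional convenience: picks an external flanking pair, an internal
#' (WT-only) primer and an inverted internal primer for PCR 3, requiring
#' each primer to map uniquely in the locus (both strands). Primers are
#' plain 20-mers placed `flank` bp outside the deletion and at its center;
#' no melting-temperature modeling is attempted.
#'
#' @param locus Named single-sequence genome.
#' @param pair A [GuidePair-class].
#' @param flank Distance (bp) from the deletion boundaries to the external
#'   primer 5' ends.
#' @param primerLen Primer length (15-30 nt).
#' @return A [PrimerSet-class].
#' @export
pickPrimers <- function(locus, pair, flank = 130L, primerLen = 20L) {
  stopifnot(is(pair, "GuidePair"), primerLen >= 15L, primerLen <= 30L)
  locus <- .asGenomeSet(locus)
  wt <- as.character(locus[[1]])
  n <- nchar(wt)
  cuts <- cutSite(pair)
  uniqueHere <- function(p) {
    .countMatches(wt, p) + .countMatches(wt, revComp(p)) == 1L
  }
  slide <- function(startPos, dir, lo, hi, orient) {
    for (s in seq(startPos, by = dir, length.out = 60L)) {
      if (s < lo || s + primerLen - 1L > hi) break
      w <- substr(wt, s, s + primerLen - 1L)
      if (grepl("N", w)) next
      p <- if (orient == "+") w else revComp(w)
      if (uniqueHere(p)) return(p)
    }
    NULL
  }
  fStart <- cuts[1] - flank
  if (fStart < 1L || cuts[2] + flank > n)
    stop("locus too short for the requested primer flank", call. = FALSE)
  extFwd <- slide(fStart, 1L, 1L, cuts[1], "+")
  extRev <- slide(cuts[2] + flank - primerLen + 1L, -1L, cuts[2] + 1L, n, "-")
  mid <- (cuts[1] + cuts[2]) %/% 2L - primerLen %/% 2L
  intW <- slide(mid, 1L, cuts[1] + 1L, cuts[2], "+")
  if (is.null(extFwd) || is.null(extRev) || is.null(intW))
    stop("could not place unique primers around the deletion", call. = FALSE)
  ## intPrimer points back toward extFwd (reverse orientation inside the
  ## deletion); invPrimer is the same site in inverted orientation, which
  ## pairs with extFwd only on inversion alleles.
  primerSet(extFwd = extFwd, extRev = extRev, intPrimer = revComp(intW),
            invPrimer = intW)
}

#' Simulate the three genotyping PCRs on a clone's alleles
#'
#' @param alleles Character vector of allele sequences (one per allele), as
#'   returned by [simulateClone()].
#' @param primers A [PrimerSet-class].
#' @param maxLen Maximum product size considered.
#' @return A [BandPattern-class] pooling the products of all alleles.
#' @export
simulateBands <- function(alleles, primers, maxLen = 10000L) {
  stopifnot(is(primers, "PrimerSet"))
  tmpl <- .asGenomeSet(alleles)
  names(tmpl) <- paste0("allele", seq_along(tmpl))
  run <- function(fwd, rev) unique(inSilicoPcr(tmpl, fwd, rev, maxLen)$size)
  bandPattern(pcr1 = run(primers@extFwd, primers@extRev),
              pcr2 = run(primers@extFwd, primers@intPrimer),
              pcr3 = run(primers@extFwd, primers@invPrimer))
}

#' Export a genotyping plan as a one-row table
#' @param plan A [GenotypingPlan-class].
#' @return `data.frame` mirroring the per-construct table of expected sizes.
#' @export
planTable <- function(plan) {
  data.frame(name = plan@name, nominal_len = plan@nominalLen,
             position = plan@positionLabel, expected_wt = plan@wtSize,
             expected_ko = plan@koSize, expected_internal = plan@int2Size,
             expected_inversion = plan@invSize,
             tolerance_bp = plan@toleranceBp)
}
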