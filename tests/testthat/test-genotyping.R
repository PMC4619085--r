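test_that("in-silico PCR measures span between outermost primer 5' ends", {
  set.seed(8)
  core <- randomDna(260)
  fwd <- randomDna(20)
  revSite <- randomDna(20)
  tmpl <- paste0(fwd, core, revSite)      # 300 nt
  rev <- oracleRevComp(revSite)
  r <- inSilicoPcr(c(t1 = tmpl), fwd, rev)
  expect_identical(r$size, 300L)
  ## primer order must not matter
  expect_identical(inSilicoPcr(c(t1 = tmpl), rev, fwd)$size, 300L)
  ## two forward-strand primers cannot amplify
  expect_identical(nrow(inSilicoPcr(c(t1 = tmpl), fwd, revSite)), 0L)
  ## products above maxLen are suppressed
  expect_identical(nrow(inSilicoPcr(c(t1 = tmpl), fwd, rev, maxLen = 299L)),
                   0L)
  expect_error(inSilicoPcr(c(t1 = tmpl), "ACGTACGTAC", rev), "15 nt")
})

test_that("deletion alleles shorten the flanking product by the deletion length", {
  fx <- getFixture()
  wt <- as.character(fx$locus[[1]])
  del <- applyDeletion(wt, fx$pair)
  rWt <- inSilicoPcr(c(wt = wt), fx$primers@extFwd, fx$primers@extRev)
  rDel <- inSilicoPcr(c(del = del), fx$primers@extFwd, fx$primers@extRev)
  expect_identical(rWt$size - rDel$size, deletionLength(fx$pair))
})

test_that("predicted amplicons obey the WT/KO/inversion size rules", {
  fx <- getFixture()
  plan <- fx$plan
  expect_identical(plan@koSize, plan@wtSize - deletionLength(fx$pair))
  inv <- applyInversion(fx$locus, fx$pair)
  rInv <- inSilicoPcr(c(inv = inv), fx$primers@extFwd, fx$primers@extRev)
  expect_identical(rInv$size, plan@wtSize)       # WT-like PCR-1 product
  rInv3 <- inSilicoPcr(c(inv = inv), fx$primers@extFwd, fx$primers@invPrimer)
  expect_identical(rInv3$size, plan@invSize)     # inversion-only PCR-3 band
  rWt3 <- inSilicoPcr(c(wt = as.character(fx$locus[[1]])),
                      fx$primers@extFwd, fx$primers@invPrimer)
  expect_identical(nrow(rWt3), 0L)

  ## an internal primer placed outside the deletion is a reported error
  wt <- as.character(fx$locus[[1]])
  outside <- substr(wt, 101, 120)
  badPrimers <- primerSet(fx$primers@extFwd, fx$primers@extRev,
                          intPrimer = oracleRevComp(outside),
                          invPrimer = fx$primers@invPrimer)
  expect_error(predictAmplicons(fx$locus, fx$pair, badPrimers), "intPrimer")
})

test_that("published-style expected sizes classify a heterozygote", {
  ## frozen example: expected WT 278 bp / KO 166 bp (112 bp deletion)
  plan <- genotypingPlan("MALAT1_prom", wtSize = 278L, koSize = 166L,
                         int2Size = 150L, invSize = 320L,
                         positionLabel = "-70/+30")
  het <- classifyGenotype(plan, bandPattern(pcr1 = c(278, 166), pcr2 = 150))
  expect_identical(genotypeCategory(het), "HET")
  wt <- classifyGenotype(plan, bandPattern(pcr1 = 278, pcr2 = 150))
  expect_identical(genotypeCategory(wt), "WT")
  hom <- classifyGenotype(plan, bandPattern(pcr1 = 166))
  expect_identical(genotypeCategory(hom), "HOM_KO")
})

test_that("the genotype call equals the truth table on all 16 evidence patterns", {
  plan <- genotypingPlan("tt", wtSize = 600L, koSize = 300L,
                         int2Size = 200L, invSize = 450L, toleranceBp = 10)
  ## hand-written oracle: inversion evidence first, then the three-stage
  ## single-category rows, everything else ambiguous
  oracle <- function(long, short, internal, inv) {
    if (inv) {
      if (internal) "INV_HET"
      else if (long || short) "INV_HOM"
      else "AMBIGUOUS"
    } else if (long && !short && internal) "WT"
    else if (long && short && internal) "HET"
    else if (short && !long && !internal) "HOM_KO"
    else "AMBIGUOUS"
  }
  for (long in c(FALSE, TRUE)) for (short in c(FALSE, TRUE))
    for (internal in c(FALSE, TRUE)) for (inv in c(FALSE, TRUE)) {
      bands <- bandPattern(
        pcr1 = c(if (long) 600, if (short) 300),
        pcr2 = if (internal) 200 else numeric(0),
        pcr3 = if (inv) 450 else numeric(0))
      call <- classifyGenotype(plan, bands)
      expect_identical(genotypeCategory(call),
                       oracle(long, short, internal, inv))
      expect_identical(unname(genotypeEvidence(call)),
                       c(long, short, internal, inv))
    }
})

test_that("the classifier is total on arbitrary band patterns", {
  plan <- genotypingPlan("t", wtSize = 600L, koSize = 300L, int2Size = 200L,
                         invSize = 450L, toleranceBp = 5)
  set.seed(9)
  for (i in 1:50) {
    bands <- bandPattern(pcr1 = sample(20:2000, sample(0:3, 1)),
                         pcr2 = sample(20:2000, sample(0:2, 1)),
                         pcr3 = sample(20:2000, sample(0:2, 1)))
    call <- classifyGenotype(plan, bands)
    expect_true(genotypeCategory(call) %in%
                  c("WT", "HET", "HOM_KO", "INV_HET", "INV_HOM", "AMBIGUOUS"))
  }
})

test_that("band matching respects the size tolerance", {
  plan <- genotypingPlan("t", wtSize = 600L, koSize = 300L, int2Size = 200L,
                         invSize = NA, toleranceBp = 10)
  near <- classifyGenotype(plan, bandPattern(pcr1 = c(605, 292), pcr2 = 205))
  expect_identical(genotypeCategory(near), "HET")
  far <- classifyGenotype(plan, bandPattern(pcr1 = c(630, 292), pcr2 = 205))
  expect_false(genotypeEvidence(far)[["long"]])
})
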