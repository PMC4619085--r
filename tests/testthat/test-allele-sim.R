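test_that("synthetic loci are seed-reproducible with the stated GC content", {
  a <- makeSyntheticLocus(7L, length = 5000L, gc = 0.5)
  b <- makeSyntheticLocus(7L, length = 5000L, gc = 0.5)
  expect_identical(as.character(a[[1]]), as.character(b[[1]]))
  c <- makeSyntheticLocus(8L, length = 5000L, gc = 0.5)
  expect_false(identical(as.character(a[[1]]), as.character(c[[1]])))
  gcFrac <- mean(strsplit(as.character(a[[1]]), "")[[1]] %in% c("G", "C"))
  expect_gt(gcFrac, 0.45)
  expect_lt(gcFrac, 0.55)
})

test_that("each design window holds a usable G-starting candidate", {
  for (seed in c(1L, 2L, 3L)) {
    ## a GC-poor locus would rarely carry PAM sites without engineering
    locus <- makeSyntheticLocus(seed, length = 4000L, gc = 0.2,
                                target = c(1800L, 2300L))
    target <- GRanges("synthetic_locus", IRanges(1800, 2300))
    pairs <- designPairs(locus, target, score = FALSE)
    expect_gte(length(pairs), 1L)
  }
  expect_error(makeSyntheticLocus(1L, length = 800L, target = c(300L, 700L)),
               "impossible geometry")
})

test_that("deletion alleles follow the junction model exactly", {
  fx <- getFixture()
  wt <- as.character(fx$locus[[1]])
  cuts <- unname(cutSite(fx$pair))
  dlen <- deletionLength(fx$pair)

  clean <- applyDeletion(wt, fx$pair, alleleSpec("DEL"))
  expect_identical(nchar(wt) - nchar(clean), dlen)
  ## indel-free junction is the exact concatenation of the two flanks
  expect_identical(clean, paste0(substr(wt, 1, cuts[1]),
                                 substr(wt, cuts[2] + 1, nchar(wt))))

  plus1 <- applyDeletion(wt, fx$pair, alleleSpec("DEL", junctionIndel = 1L,
                                                 seed = 3L))
  expect_identical(nchar(plus1), nchar(clean) + 1L)
  expect_identical(substr(plus1, 1, cuts[1]), substr(wt, 1, cuts[1]))

  minus4 <- applyDeletion(wt, fx$pair, alleleSpec("DEL", junctionIndel = -4L))
  expect_identical(nchar(minus4), nchar(clean) - 4L)

  ## inserted junction bases are seed-deterministic
  again <- applyDeletion(wt, fx$pair, alleleSpec("DEL", junctionIndel = 8L,
                                                 seed = 12L))
  again2 <- applyDeletion(wt, fx$pair, alleleSpec("DEL", junctionIndel = 8L,
                                                  seed = 12L))
  expect_identical(again, again2)
})

test_that("inversion preserves length and is an involution", {
  fx <- getFixture()
  wt <- as.character(fx$locus[[1]])
  inv <- applyInversion(wt, fx$pair)
  expect_identical(nchar(inv), nchar(wt))
  expect_false(identical(inv, wt))
  expect_identical(applyInversion(inv, fx$pair), wt)
})

test_that("allele and clone specs enforce their invariants", {
  expect_error(alleleSpec("DEL", junctionIndel = 25L), "<= 20")
  expect_error(alleleSpec("INV", junctionIndel = 2L), "DEL alleles only")
  expect_error(cloneSpec(list("WT", "DEL"), ploidy = 3L), "equal ploidy")
  expect_silent(cloneSpec(list("WT", "DEL", "DEL")))
})

test_that("simulated clones are classified back to their true genotype", {
  fx <- getFixture()
  kinds <- c("WT", "DEL", "INV")
  for (ploidy in 2:3) {
    combos <- do.call(expand.grid, rep(list(kinds), ploidy))
    for (r in seq_len(nrow(combos))) {
      clone <- cloneSpec(as.list(as.character(unlist(combos[r, ]))))
      alleles <- simulateClone(fx$locus, fx$pair, clone, seed = 100L + r)
      call <- classifyGenotype(fx$plan, simulateBands(alleles, fx$primers))
      expect_identical(genotypeCategory(call), expectedCategory(clone),
                       label = paste(unlist(combos[r, ]), collapse = "/"))
    }
  }
})

test_that("junction indels below the band tolerance do not change the call", {
  fx <- getFixture()
  for (k in c(-5L, -1L, 1L, 5L)) {
    clone <- new("CloneSpec", ploidy = 2L,
                 alleles = list(alleleSpec("WT"),
                                alleleSpec("DEL", junctionIndel = k,
                                           seed = 40L + k)))
    call <- classifyGenotype(fx$plan,
                             simulateBands(simulateClone(fx$locus, fx$pair,
                                                         clone),
                                           fx$primers))
    expect_identical(genotypeCategory(call), "HET")
  }
})
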