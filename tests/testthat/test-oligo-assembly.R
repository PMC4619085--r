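cleanTargeting <- function() {
  repeat {
    p <- paste0(sample(c("A", "C", "G", "T"), 1), randomDna(19))
    ## also avoid motif halves that would complete a BsmBI site across a
    ## segment junction of the default template
    if (!grepl("CGTCTC|GAGACG|GAGAC$|CGTCT$|^AGACG|^TCTC", p)) return(p)
  }
}

test_that("default template yields a 165-nt oligo for any targeting pair", {
  tpl <- defaultInsertTemplate()
  expect_identical(templateConstantLength(tpl), 125L)
  set.seed(1)
  for (i in 1:10) {
    ol <- assembleInsert1(cleanTargeting(), cleanTargeting(), tpl)
    expect_identical(nchar(oligoSeq(ol)), 165L)
    seg <- segmentMap(ol)
    expect_identical(seg$start[1], 1L)
    expect_identical(seg$end[nrow(seg)], 165L)
    expect_identical(seg$end[-nrow(seg)] + 1L, seg$start[-1])
    expect_true(all(seg[seg$name %in% c("t_u6", "t_h1"), "end"] -
                      seg[seg$name %in% c("t_u6", "t_h1"), "start"] == 19L))
  }
})

test_that("assemble and parse are mutually inverse", {
  tpl <- defaultInsertTemplate()
  set.seed(2)
  for (i in 1:50) {
    t1 <- cleanTargeting(); t2 <- cleanTargeting()
    got <- parseInsert1(assembleInsert1(t1, t2, tpl), tpl)
    expect_identical(unname(got), c(t1, t2))
  }
  ## and with the reverse-complement orientation of the second cassette
  tplRc <- insertTemplate(tpl@gibson5, tpl@scaffoldFrag, tpl@bsmbiCassette,
                          tpl@h1Frag, tpl@gibson3, t2Orientation = "revcomp")
  t1 <- "GACTACTAGTCATGCATGCA"; t2 <- "GTCATCATGACTGATCATCA"
  ol <- assembleInsert1(t1, t2, tplRc)
  expect_identical(unname(parseInsert1(ol, tplRc)), c(t1, t2))
  expect_true(grepl(oracleRevComp(t2), oligoSeq(ol), fixed = TRUE))
})

test_that("parse reports the first mismatching segment and wrong lengths", {
  tpl <- defaultInsertTemplate()
  ol <- oligoSeq(assembleInsert1("GACTACTAGTCATGCATGCA",
                                 "GTCATCATGACTGATCATCA", tpl))
  bad <- ol
  substr(bad, 3, 3) <- if (substr(bad, 3, 3) == "A") "C" else "A"
  expect_error(parseInsert1(bad, tpl), "gibson5")
  expect_error(parseInsert1(substr(ol, 1, 150), tpl), "length")
})

test_that("template length changes propagate additively", {
  tpl <- defaultInsertTemplate()
  shorter <- insertTemplate(tpl@gibson5, tpl@scaffoldFrag, tpl@bsmbiCassette,
                            substr(tpl@h1Frag, 1, nchar(tpl@h1Frag) - 10L),
                            tpl@gibson3)
  ol <- assembleInsert1("GACTACTAGTCATGCATGCA", "GTCATCATGACTGATCATCA",
                        shorter)
  expect_identical(nchar(oligoSeq(ol)), 155L)
})

test_that("BsmBI-containing targeting sequences are refused at assembly", {
  tpl <- defaultInsertTemplate()
  expect_error(assembleInsert1("GCGTCTCAAAAAAAAAAAAA",
                               "GTCATCATGACTGATCATCA", tpl), "BsmBI")
})

test_that("bsmbiDigest applies the N1/N5 cut arithmetic", {
  d <- bsmbiDigest("AAACGTCTCATTTTGGGCCC")
  expect_identical(nrow(d), 2L)
  expect_identical(d$topEnd[1], 10L)          # top-strand cut after 10
  expect_identical(d$overhangRight[1], "TTTT") # 4-nt 5' overhang, pos 11-14
  expect_identical(d$overhangLeft[2], "TTTT")
  expect_identical(d$seq[2], "TTTTGGGCCC")

  ## no recognition site: single uncut fragment
  u <- bsmbiDigest("ACGTACGTACGTACGT")
  expect_identical(nrow(u), 1L)
  expect_identical(u$seq, "ACGTACGTACGTACGT")

  ## circular molecule with two sites yields exactly two fragments
  tpl <- defaultInsertTemplate()
  circ <- paste0(tpl@bsmbiCassette, strrep("AT", 40))
  d2 <- bsmbiDigest(circ, circular = TRUE)
  expect_identical(nrow(d2), 2L)
  expect_identical(sum(d2$topLength), nchar(circ))
})

test_that("linear fragment top-strand lengths sum to the input length", {
  set.seed(3)
  for (i in 1:20) {
    s <- paste0(randomDna(sample(20:60, 1)), "CGTCTC", randomDna(30),
                if (i %% 2 == 0) "GAGACG" else "", randomDna(sample(20:60, 1)))
    d <- bsmbiDigest(s)
    expect_identical(sum(d$topLength), nchar(s))
  }
})

test_that("simulated cloning produces a valid final dual-gRNA construct", {
  fx <- getFixture()
  fin <- simulateCloning(fx$pair)
  expect_identical(constructStage(fin), "final")
  expect_identical(constructElements(fin)$name,
                   c("U6_promoter", "gRNA1_targeting", "scaffold",
                     "H1_promoter", "gRNA2_targeting", "scaffold"))
  seqFinal <- fin@seq
  expect_identical(length(gregexpr("CGTCTC", seqFinal, fixed = TRUE)[[1]][
    gregexpr("CGTCTC", seqFinal, fixed = TRUE)[[1]] > 0]) +
      length(gregexpr("GAGACG", seqFinal, fixed = TRUE)[[1]][
        gregexpr("GAGACG", seqFinal, fixed = TRUE)[[1]] > 0]), 0L)
  for (t in c(protospacer(u6Guide(fx$pair)), protospacer(h1Guide(fx$pair)))) {
    hits <- gregexpr(t, seqFinal, fixed = TRUE)[[1]]
    expect_identical(sum(hits > 0), 1L)
  }
})

test_that("a bypassed BsmBI-containing targeting sequence fails cloning", {
  tpl <- defaultInsertTemplate()
  tBad <- "GCGTCTCAATATATATATAT"   # carries a BsmBI site
  rawOligo <- paste0(tpl@gibson5, "GACTACTAGTCATGCATGCA", tpl@scaffoldFrag,
                     tpl@bsmbiCassette, tBad, tpl@h1Frag, tpl@gibson3)
  expect_error(simulateCloning(rawOligo, tpl), "BsmBI")
})
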