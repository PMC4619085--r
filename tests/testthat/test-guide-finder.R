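test_that("short search intervals yield no candidates", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 20)))
  expect_length(findProtospacers(g, GRanges("c1", IRanges(1, 22))), 0L)
})

test_that("protospacer enumeration matches the naive sliding-window oracle", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(200:1000, 1)
    s <- randomDna(n)
    g <- Biostrings::DNAStringSet(c(chr = s))
    found <- guideTable(findProtospacers(g, GRanges("chr", IRanges(1, n))))
    oracle <- oracleScan(s)
    expect_equal(nrow(found), nrow(oracle))
    expect_identical(found$start, oracle$start)
    expect_identical(found$strand, oracle$strand)
    expect_identical(found$protospacer, oracle$protospacer)
    expect_identical(found$pam, oracle$pam)
    expect_identical(found$cut_pos, oracle$cut)
    expect_true(all(nchar(found$protospacer) == 20L))
  }
})

test_that("a single engineered plus-strand site is found with exact coordinates", {
  ## 30 nt: 4 nt pad + 20-mer + AGG + 3 nt pad; the protospacer avoids GG/CC
  proto <- "GACTACTAGTCATGCATGCA"
  s <- paste0("ATAT", proto, "AGG", "ATA")
  g <- Biostrings::DNAStringSet(c(chr = s))
  found <- findProtospacers(g, GRanges("chr", IRanges(1, nchar(s))))
  oracle <- oracleScan(s)
  expect_length(found, nrow(oracle))
  expect_identical(protospacer(found), proto)
  expect_identical(start(found), 5L)
  expect_identical(cutSite(found), 5L + 16L)
})

test_that("blunt cut falls between protospacer nucleotides 17 and 18", {
  ## plus strand: protospacer occupies positions 101..120, PAM 121..123
  proto <- "GACTACTAGTCATGCATGCA"
  sPlus <- paste0(randomDna(100, seed = 5, letters = c("A", "T")), proto,
                  "AGG", randomDna(80, letters = c("A", "T")))
  gP <- Biostrings::DNAStringSet(c(chr = sPlus))
  fP <- findProtospacers(gP, GRanges("chr", IRanges(1, nchar(sPlus))))
  onP <- fP[start(fP) == 101L & as.character(strand(fP)) == "+"]
  expect_length(onP, 1L)
  expect_identical(cutSite(onP), 117L)

  ## minus strand: PAM (CCN on plus) at 98..100, protospacer 101..120
  sMinus <- paste0(randomDna(97, seed = 6, letters = c("A", "T")), "CCT",
                   oracleRevComp(proto), randomDna(80, letters = c("A", "T")))
  gM <- Biostrings::DNAStringSet(c(chr = sMinus))
  fM <- findProtospacers(gM, GRanges("chr", IRanges(1, nchar(sMinus))))
  onM <- fM[start(fM) == 101L & as.character(strand(fM)) == "-"]
  expect_length(onM, 1L)
  expect_identical(protospacer(onM), proto)
  expect_identical(cutSite(onM), 103L)

  ## boundedness: every cut strictly inside its protospacer interval
  for (tab in list(guideTable(fP), guideTable(fM)))
    expect_true(all(tab$cut_pos >= tab$start & tab$cut_pos < tab$end))
})

test_that("designing on the reverse complement mirrors cut coordinates", {
  set.seed(77)
  s <- randomDna(600)
  n <- nchar(s)
  g1 <- Biostrings::DNAStringSet(c(chr = s))
  g2 <- Biostrings::DNAStringSet(c(chr = oracleRevComp(s)))
  c1 <- findProtospacers(g1, GRanges("chr", IRanges(1, n)))
  c2 <- findProtospacers(g2, GRanges("chr", IRanges(1, n)))
  expect_length(c2, length(c1))
  expect_setequal(n - cutSite(c2), cutSite(c1))
  expect_setequal(protospacer(c2), protospacer(c1))
})

test_that("filterCandidates removes BsmBI, polyT and N protospacers only", {
  mk <- function(proto) makeGuide(10L, proto = proto)
  gs <- suppressWarnings(do.call(c, lapply(
    c("GCGTCTCAAAAAAAAAAAAA",   # BsmBI site
      "GACGTTTTACGTACGTACGT",   # polyT
      "GACTACTAGTCATGCATGCA",   # clean
      "GATCGATCGATCGATCGATC"),  # clean
    function(p) makeGuide(10L, proto = p))))
  gs <- new("GuideSet", gs)
  kept <- filterCandidates(gs)
  expect_length(kept, 2L)
  expect_false(any(grepl("CGTCTC|GAGACG|TTTT", protospacer(kept))))
  ## a set with no flagged members is returned unchanged
  expect_identical(protospacer(filterCandidates(kept)), protospacer(kept))
})

test_that("specificity score follows the mismatch-weighted formula", {
  proto <- "GACTACTAGTCATGCATGCA"
  pad <- function(n, seed) randomDna(n, seed = seed, letters = c("A", "T"))
  site <- paste0(proto, "AGG")

  locate <- function(s) {
    g <- Biostrings::DNAStringSet(c(chr = s))
    f <- findProtospacers(g, GRanges("chr", IRanges(1, nchar(s))))
    list(g = g, onTarget = f[protospacer(f) == proto][1])
  }

  ## unique site in an AT background: no neighbor at <= 3 mismatches
  uni <- locate(paste0(pad(2000, 1), site, pad(2000, 2)))
  expect_identical(specificityScore(uni$onTarget, uni$g), 1.0)

  ## identical 23-mer twice: one 0-mm off-target, score 1/(1+10)
  dup <- locate(paste0(pad(1000, 3), site, pad(500, 4), site, pad(1000, 5)))
  expect_equal(specificityScore(dup$onTarget, dup$g), 1 / 11)

  ## one extra site at exactly 2 mismatches: 1/(1+1)
  proto2mm <- proto
  substr(proto2mm, 2, 2) <- "C"
  substr(proto2mm, 12, 12) <- "G"
  stopifnot(sum(charToRaw(proto2mm) != charToRaw(proto)) == 2L)
  two <- locate(paste0(pad(1000, 6), site, pad(500, 7),
                       proto2mm, "AGG", pad(1000, 8)))
  expect_equal(specificityScore(two$onTarget, two$g), 0.5)

  ## monotonicity: score never increases as off-target sites are injected
  scores <- c(specificityScore(uni$onTarget, uni$g),
              specificityScore(two$onTarget, two$g),
              specificityScore(dup$onTarget, dup$g))
  expect_true(all(diff(scores) <= 0))

  ## candidate absent from the genome is an error
  other <- Biostrings::DNAStringSet(c(chr = pad(500, 9)))
  expect_error(specificityScore(uni$onTarget, other), "not found")
})
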