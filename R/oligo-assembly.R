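## oligo_assembly: the single-oligo (Insert-1) format, Type IIS (BsmBI)
## digestion arithmetic, and an element/sequence-level simulation of the
## two-step cloning that produces the final dual-gRNA construct.

## Synthetic constant elements of the minimal abstract backbone model. The
## real parental plasmid and universal second insert are not modeled by their
## published sequences; these stand-ins are BsmBI-free and carry the same
## functional roles (see the methods vignette).
U6_CORE <- "ACGATTCAGGTTGCACCTTAGGATCGTTACAGGCATTACA"
POST_FILLER <- "TTGACCATGATTACGCCAAGCTATCAGGCATCAAGCTTGGCACTGGCCGTCGTTATACAA"
INSERT2_SCAFFOLD <- "GCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"
INSERT2_H1CORE <- "CATTTGCATGTCGCTATGTGTTCTGGGAAATCACCATAAACGCGAACTCA"

#' Create an Insert-1 oligo template
#'
#' @param gibson5,scaffoldFrag,bsmbiCassette,h1Frag,gibson3 Constant segment
#'   sequences; see [InsertTemplate-class].
#' @param t2Orientation Orientation in which the second targeting sequence is
#'   written into the oligo (`"sense"` or `"revcomp"`).
#' @return An [InsertTemplate-class].
#' @export
insertTemplate <- function(gibson5, scaffoldFrag, bsmbiCassette, h1Frag,
                           gibson3, t2Orientation = "sense") {
  new("InsertTemplate",
      gibson5 = .assertDna(gibson5, "gibson5", allowN = FALSE),
      scaffoldFrag = .assertDna(scaffoldFrag, "scaffoldFrag", allowN = FALSE),
      bsmbiCassette = .assertDna(bsmbiCassette, "bsmbiCassette", allowN = FALSE),
      h1Frag = .assertDna(h1Frag, "h1Frag", allowN = FALSE),
      gibson3 = .assertDna(gibson3, "gibson3", allowN = FALSE),
      t2Orientation = t2Orientation)
}

#' Total length of a template's constant segments
#' @param tpl An [InsertTemplate-class].
#' @return Integer; 125 for the default template (so that adding two 20-nt
#'   targeting sequences yields a 165-nt oligo).
#' @export
templateConstantLength <- function(tpl) {
  stopifnot(is(tpl, "InsertTemplate"))
  sum(nchar(c(tpl@gibson5, tpl@scaffoldFrag, tpl@bsmbiCassette, tpl@h1Frag,
              tpl@gibson3)))
}

#' Read an Insert-1 template from a key=sequence text config
#'
#' The file holds one `key=sequence` pair per line (`#` comments allowed)
#' with keys `gibson5`, `scaffold_frag`, `bsmbi_cassette`, `h1_frag`,
#' `gibson3` and optionally `t2_orientation`.
#'
#' @param path Path to the template config file.
#' @return An [InsertTemplate-class].
#' @export
readInsertTemplate <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path, call. = FALSE)
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  need <- c("gibson5", "scaffold_frag", "bsmbi_cassette", "h1_frag", "gibson3")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("template file missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  insertTemplate(vals[["gibson5"]], vals[["scaffold_frag"]],
                 vals[["bsmbi_cassette"]], vals[["h1_frag"]],
                 vals[["gibson3"]],
                 t2Orientation = if ("t2_orientation" %in% keys)
                   vals[["t2_orientation"]] else "sense")
}

#' The default (synthetic) Insert-1 template
#'
#' Loads the template shipped in
#' `inst/extdata/insert1_template_synthetic.txt` and enforces the 125-nt
#' constant-segment total, so that any two 20-nt targeting sequences yield a
#' 165-nt oligo. The segment sequences are synthetic stand-ins satisfying the
#' structural constraints of the single-oligo format (see the vignette).
#'
#' @return An [InsertTemplate-class].
#' @export
defaultInsertTemplate <- function() {
  tpl <- readInsertTemplate(system.file("extdata",
                                        "insert1_template_synthetic.txt",
                                        package = "crisprDel",
                                        mustWork = TRUE))
  if (templateConstantLength(tpl) != 125L)
    stop("default template constant segments must total 125 nt", call. = FALSE)
  tpl
}

#' Assemble the single starting oligo from two targeting sequences
#'
#' Concatenates `gibson5 + tU6 + scaffoldFrag + bsmbiCassette + tH1' + h1Frag
#' + gibson3`, where `tH1'` is `tH1` or its reverse complement per the
#' template's `t2Orientation`, and records the segment map. With the default
#' template the oligo is exactly 165 nt for any two 20-nt targeting
#' sequences.
#'
#' @param tU6,tH1 20-nt targeting sequences (protospacers, 5'->3' as
#'   transcribed); must be BsmBI-free.
#' @param tpl An [InsertTemplate-class].
#' @return An [Insert1Oligo-class].
#' @export
assembleInsert1 <- function(tU6, tH1, tpl = defaultInsertTemplate()) {
  stopifnot(is(tpl, "InsertTemplate"))
  for (t in list(tU6 = tU6, tH1 = tH1)) {
    if (nchar(t) != 20L)
      stop("targeting sequence must be exactly 20 nt, got ", nchar(t),
           call. = FALSE)
  }
  tU6 <- .assertDna(tU6, "tU6", allowN = FALSE)
  tH1 <- .assertDna(tH1, "tH1", allowN = FALSE)
  if (grepl("CGTCTC|GAGACG", tU6) || grepl("CGTCTC|GAGACG", tH1))
    stop("targeting sequence contains a BsmBI recognition site and would ",
         "be cleaved during cloning", call. = FALSE)
  t2 <- if (tpl@t2Orientation == "revcomp") revComp(tH1) else tH1
  parts <- c(gibson5 = tpl@gibson5, t_u6 = tU6,
             scaffold_frag = tpl@scaffoldFrag,
             bsmbi_cassette = tpl@bsmbiCassette, t_h1 = t2,
             h1_frag = tpl@h1Frag, gibson3 = tpl@gibson3)
  seq <- paste(parts, collapse = "")
  ## the cassette must remain the only source of BsmBI sites; a site formed
  ## across a segment junction would be cleaved in cloning step 2
  if (.countMatches(seq, "CGTCTC") != 1L || .countMatches(seq, "GAGACG") != 1L)
    stop("assembly would create a BsmBI site outside the cloning cassette ",
         "(segment-junction site); choose different targeting sequences",
         call. = FALSE)
  ends <- cumsum(nchar(parts))
  segs <- data.frame(name = names(parts),
                     start = c(1L, head(ends, -1L) + 1L),
                     end = as.integer(ends))
  new("Insert1Oligo", seq = seq, segments = segs)
}

#' Recover the two targeting sequences from an Insert-1 oligo
#'
#' Inverse of [assembleInsert1()]: verifies every constant segment at its
#' expected offset (reporting the first mismatching segment) and extracts the
#' two 20-nt variable regions, undoing the template's `t2Orientation`.
#'
#' @param oligo Character oligo sequence or an [Insert1Oligo-class].
#' @param tpl An [InsertTemplate-class].
#' @return Named character vector `c(tU6 = ..., tH1 = ...)`.
#' @export
parseInsert1 <- function(oligo, tpl = defaultInsertTemplate()) {
  if (is(oligo, "Insert1Oligo")) oligo <- oligoSeq(oligo)
  oligo <- .assertDna(oligo, "oligo", allowN = FALSE)
  expLen <- templateConstantLength(tpl) + 40L
  if (nchar(oligo) != expLen)
    stop("oligo length ", nchar(oligo), " does not match template length ",
         expLen, call. = FALSE)
  consts <- c(gibson5 = tpl@gibson5, scaffold_frag = tpl@scaffoldFrag,
              bsmbi_cassette = tpl@bsmbiCassette, h1_frag = tpl@h1Frag,
              gibson3 = tpl@gibson3)
  w <- nchar(consts)
  starts <- c(gibson5 = 1L,
              scaffold_frag = w[["gibson5"]] + 21L,
              bsmbi_cassette = w[["gibson5"]] + w[["scaffold_frag"]] + 21L,
              h1_frag = w[["gibson5"]] + w[["scaffold_frag"]] +
                w[["bsmbi_cassette"]] + 41L,
              gibson3 = w[["gibson5"]] + w[["scaffold_frag"]] +
                w[["bsmbi_cassette"]] + w[["h1_frag"]] + 41L)
  for (nm in names(consts)) {
    got <- substr(oligo, starts[[nm]], starts[[nm]] + w[[nm]] - 1L)
    if (got != consts[[nm]])
      stop("constant-region mismatch in segment '", nm, "'", call. = FALSE)
  }
  tU6 <- substr(oligo, w[["gibson5"]] + 1L, w[["gibson5"]] + 20L)
  t2 <- substr(oligo, starts[["bsmbi_cassette"]] + w[["bsmbi_cassette"]],
               starts[["bsmbi_cassette"]] + w[["bsmbi_cassette"]] + 19L)
  tH1 <- if (tpl@t2Orientation == "revcomp") revComp(t2) else t2
  c(tU6 = tU6, tH1 = tH1)
}

#' Digest a sequence with BsmBI (in silico)
#'
#' BsmBI (`CGTCTC(1/5)`) is a Type IIS enzyme cutting downstream of its
#' recognition site: for a top-strand site starting at `s`, the top strand is
#' cut after position `s + 6` and the bottom strand after `s + 10`, leaving a
#' 4-nt 5' overhang; bottom-strand sites (`GAGACG` on the top strand) cut
#' mirror-symmetrically upstream. Sites whose cut positions run off the end
#' of a linear molecule are not cut.
#'
#' @param seq DNA string (top strand).
#' @param circular Logical; treat the molecule as circular.
#' @return `data.frame` with one row per fragment: `seq` (full-span top
#'   strand including overhang extents), `topStart`, `topEnd`, `topLength`
#'   (top-strand lengths sum to the input length for linear molecules), and
#'   the 4-nt 5' overhangs `overhangLeft`/`overhangRight` (`""` at blunt
#'   ends). A circular molecule with `n` sites yields `n` fragments, a
#'   linear one `n + 1`.
#' @examples
#' bsmbiDigest("AAACGTCTCATTTTGGGCCC")  # cut after 10 (top), overhang TTTG
#' @export
bsmbiDigest <- function(seq, circular = FALSE) {
  seq <- .assertDna(toupper(as.character(seq)), "seq")
  n <- nchar(seq)
  uncut <- function() data.frame(seq = seq, topStart = 1L, topEnd = n,
                                 topLength = n, overhangLeft = "",
                                 overhangRight = "")
  scanStr <- if (circular) paste0(seq, substr(seq, 1L, min(n, 12L))) else seq
  f <- .allMatches(scanStr, "CGTCTC")
  r <- .allMatches(scanStr, "GAGACG")
  if (circular) { f <- f[f <= n]; r <- r[r <= n] }
  tops <- c(f + 6L, r - 6L)       # gap coordinate of the top-strand cut;
  if (!length(tops)) return(uncut())   # bottom cut is always top + 4
  if (circular) {
    tops <- sort(unique(tops %% n))
    d <- paste0(seq, seq)
    k <- length(tops)
    nxt <- c(tops[-1L], tops[1L] + n)
    data.frame(
      seq = substring(d, tops + 1L, nxt + 4L),
      topStart = tops + 1L, topEnd = nxt,
      topLength = nxt - tops,
      overhangLeft = substring(d, tops + 1L, tops + 4L),
      overhangRight = substring(d, nxt + 1L, nxt + 4L))
  } else {
    tops <- sort(unique(tops[tops >= 1L & tops + 4L <= n]))
    if (!length(tops)) return(uncut())
    lo <- c(0L, tops)             # gap before each fragment's top strand
    hi <- c(tops, n)              # gap after it
    botHi <- c(tops + 4L, n)
    data.frame(
      seq = substring(seq, lo + 1L, botHi),
      topStart = lo + 1L, topEnd = hi,
      topLength = hi - lo,
      overhangLeft = c("", substring(seq, tops + 1L, tops + 4L)),
      overhangRight = c(substring(seq, tops + 1L, tops + 4L), ""))
  }
}

#' Minimal abstract parental backbone
#'
#' A circular element-level model of the parental plasmid: a U6 promoter
#' ending in the template's 5' Gibson overhang, the removable BsmBI cloning
#' cassette, the 3' Gibson overhang and synthetic backbone filler. All
#' element sequences are synthetic stand-ins.
#'
#' @param tpl An [InsertTemplate-class].
#' @return A [ConstructModel-class] at stage `"parental"`.
#' @export
parentalBackbone <- function(tpl = defaultInsertTemplate()) {
  seq <- paste0(U6_CORE, tpl@gibson5, tpl@bsmbiCassette, tpl@gibson3,
                POST_FILLER)
  if (.countMatches(seq, "CGTCTC") != 1L || .countMatches(seq, "GAGACG") != 1L)
    stop("parental backbone must carry exactly the two cassette BsmBI sites",
         call. = FALSE)
  el <- data.frame(
    name = c("U6_promoter", "cloning_cassette", "backbone"),
    seq = c(paste0(U6_CORE, tpl@gibson5), tpl@bsmbiCassette,
            paste0(tpl@gibson3, POST_FILLER)))
  new("ConstructModel", elements = el, seq = seq, stage = "parental")
}

## Positions of the excisable cassette interior (between the two BsmBI
## top-strand cuts), relative to the cassette string.
.cassetteInner <- function(cassette) {
  sR <- .allMatches(cassette, "GAGACG")   # left site, cuts upstream
  sF <- .allMatches(cassette, "CGTCTC")   # right site, cuts downstream
  stopifnot(length(sR) == 1L, length(sF) == 1L, sR < sF)
  c(start = sR - 5L, end = sF + 6L)
}

#' Simulate the two-step cloning of the dual-gRNA construct
#'
#' Step 1 inserts the assembled Insert-1 oligo into the BsmBI-opened parental
#' backbone by Gibson assembly (overlap search on the two Gibson overhangs);
#' step 2 re-digests the intermediate at the cassette's two BsmBI sites and
#' ligates the universal constant insert (scaffold + H1 promoter), removing
#' both recognition sites. The final construct is checked for zero residual
#' BsmBI sites and exactly one copy of each targeting sequence, and its
#' functional element list (U6, gRNA1, scaffold, H1, gRNA2, scaffold) is
#' returned.
#'
#' @param x A [GuidePair-class], an [Insert1Oligo-class], or a raw oligo
#'   character string.
#' @param tpl An [InsertTemplate-class].
#' @param backbone A parental [ConstructModel-class]; defaults to
#'   [parentalBackbone()].
#' @return A [ConstructModel-class] at stage `"final"`.
#' @export
simulateCloning <- function(x, tpl = defaultInsertTemplate(),
                            backbone = parentalBackbone(tpl)) {
  if (is(x, "GuidePair")) {
    oligo <- assembleInsert1(protospacer(u6Guide(x)), protospacer(h1Guide(x)),
                             tpl)
  } else if (is(x, "Insert1Oligo")) {
    oligo <- x
  } else {
    oligo <- new("Insert1Oligo", seq = .assertDna(x, "oligo", allowN = FALSE),
                 segments = data.frame(name = "oligo", start = 1L,
                                       end = nchar(x)))
  }
  oseq <- oligoSeq(oligo)

  ## --- step 1: BsmBI opening + Gibson insertion ---------------------------
  frags <- bsmbiDigest(backbone@seq, circular = TRUE)
  if (nrow(frags) != 2L)
    stop("parental backbone digestion must yield exactly two fragments, got ",
         nrow(frags), call. = FALSE)
  g5pos <- .allMatches(backbone@seq, tpl@gibson5)
  g3pos <- .allMatches(backbone@seq, tpl@gibson3)
  if (length(g5pos) != 1L || length(g3pos) != 1L)
    stop("Gibson overhang sequences must occur exactly once in the backbone",
         call. = FALSE)
  if (!startsWith(oseq, tpl@gibson5) || !endsWith(oseq, tpl@gibson3))
    stop("oligo ends do not carry the template's Gibson overhangs", call. = FALSE)
  ## rewrite the circle from the 5' overhang: oligo replaces the arc from
  ## gibson5 through gibson3
  rot <- paste0(substr(backbone@seq, g5pos, nchar(backbone@seq)),
                substr(backbone@seq, 1L, g5pos - 1L))
  g3rot <- .allMatches(rot, tpl@gibson3)[1]
  intermediate <- paste0(oseq, substr(rot, g3rot + nchar(tpl@gibson3),
                                      nchar(rot)))

  ## --- step 2: cassette excision + ligation of the constant insert --------
  frags2 <- bsmbiDigest(intermediate, circular = TRUE)
  if (nrow(frags2) != 2L)
    stop("residual BsmBI site: intermediate digestion yielded ",
         nrow(frags2), " fragments instead of 2 (a targeting sequence or ",
         "junction carries an unexpected site)", call. = FALSE)
  casPos <- .allMatches(intermediate, tpl@bsmbiCassette)
  if (length(casPos) != 1L)
    stop("cloning cassette not found intact in the intermediate plasmid",
         call. = FALSE)
  inner <- .cassetteInner(tpl@bsmbiCassette)
  insert2 <- paste0(INSERT2_SCAFFOLD, INSERT2_H1CORE)
  finalSeq <- paste0(substr(intermediate, 1L, casPos + inner[["start"]] - 2L),
                     insert2,
                     substr(intermediate, casPos + inner[["end"]],
                            nchar(intermediate)))

  ## --- final-construct invariants -----------------------------------------
  if (.countMatches(finalSeq, "CGTCTC") + .countMatches(finalSeq, "GAGACG") > 0)
    stop("residual BsmBI recognition site in the final construct", call. = FALSE)
  t12 <- tryCatch(parseInsert1(oseq, tpl), error = function(e) NULL)
  if (is.null(t12))
    stop("cannot locate targeting sequences in the cloned oligo", call. = FALSE)
  t2written <- if (tpl@t2Orientation == "revcomp") revComp(t12[["tH1"]])
               else t12[["tH1"]]
  countBoth <- function(t)
    .countMatches(finalSeq, t) + .countMatches(finalSeq, revComp(t))
  if (countBoth(t12[["tU6"]]) != 1L)
    stop("U6 targeting sequence must appear exactly once in the final ",
         "construct, found ", countBoth(t12[["tU6"]]), call. = FALSE)
  if (countBoth(t2written) != 1L)
    stop("H1 targeting sequence must appear exactly once in the final ",
         "construct, found ", countBoth(t2written), call. = FALSE)
  ## the U6 guide must sit immediately downstream of the U6 promoter block
  if (.allMatches(finalSeq, t12[["tU6"]])[1] !=
      .allMatches(finalSeq, tpl@gibson5)[1] + nchar(tpl@gibson5))
    stop("U6 targeting sequence is not immediately downstream of the U6 ",
         "promoter", call. = FALSE)

  el <- data.frame(
    name = c("U6_promoter", "gRNA1_targeting", "scaffold", "H1_promoter",
             "gRNA2_targeting", "scaffold"),
    seq = c(paste0(U6_CORE, tpl@gibson5), t12[["tU6"]],
            paste0(tpl@scaffoldFrag, INSERT2_SCAFFOLD),
            paste0(INSERT2_H1CORE, tpl@h1Frag), t12[["tH1"]],
            INSERT2_SCAFFOLD))
  new("ConstructModel", elements = el, seq = finalSeq, stage = "final")
}

#' Write an oligo pool as FASTA and an order sheet
#'
#' @param oligos Named list of [Insert1Oligo-class] (names = target names).
#' @param fastaPath,tsvPath Output paths (`NULL` to skip one of them).
#' @return Invisibly, the order-sheet `data.frame` (name, sequence, length,
#'   segment checksum).
#' @export
writeOligoPool <- function(oligos, fastaPath = NULL, tsvPath = NULL) {
  seqs <- vapply(oligos, oligoSeq, "")
  if (!is.null(fastaPath)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(oligos)
    Biostrings::writeXStringSet(x, fastaPath)
  }
  sheet <- data.frame(name = names(oligos), sequence = seqs,
                      length = nchar(seqs),
                      segment_checksum = vapply(oligos, function(o)
                        sum(utf8ToInt(oligoSeq(o))), numeric(1)))
  if (!is.null(tsvPath))
    write.table(sheet, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sheet)
}
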