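## genome_io: FASTA/BED input-output and coordinate-safe extraction.
## Parsing is delegated to Biostrings (FASTA) and rtracklayer (BED); the
## wrappers add the validation and error reporting the toolkit relies on.

#' Read a (multi-record) FASTA genome
#'
#' Reads FASTA via [Biostrings::readDNAStringSet()], uppercases sequences,
#' and rejects duplicate identifiers, empty sequences and non-`{A,C,G,T,N}`
#' letters. Record order is preserved; identifiers are truncated at the
#' first whitespace, as genome tools conventionally do.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence for record(s): ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "),
         call. = FALSE)
  chr <- toupper(as.character(x))
  .assertDna(chr, "genome sequence")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write sequences as FASTA
#'
#' @param x Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path, width = 60L) {
  x <- .asGenomeSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read target regions from a BED file
#'
#' BED (0-based half-open on disk) is read through [rtracklayer::import()]
#' and returned as 1-based closed [GenomicRanges::GRanges]. Unnamed records
#' are given names `target_1, target_2, ...` in file order.
#'
#' @param path Path to a BED file (BED3-BED6).
#' @return A [GenomicRanges::GRanges] with a `name` metadata column.
#' @export
readTargetsBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(mcols(gr)$name) || anyNA(mcols(gr)$name))
    mcols(gr)$name <- paste0("target_", seq_along(gr))
  gr
}

#' Write regions to a BED6 file
#'
#' @param gr A [GenomicRanges::GRanges]; `name` and `score` metadata columns
#'   are used when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Extract the sequence of a genomic region
#'
#' Returns `genome[[chrom]][start..end]` as a character string; for
#' minus-strand regions the reverse complement is returned. Coordinates are
#' 1-based closed (GRanges convention).
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character).
#' @param region A single-range [GenomicRanges::GRanges].
#' @return Character scalar DNA string.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "AACGGT"))
#' extractRegion(g, GenomicRanges::GRanges("c1", IRanges::IRanges(2, 4)))
#' @export
extractRegion <- function(genome, region) {
  genome <- .asGenomeSet(genome)
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  chrom <- as.character(seqnames(region))
  if (!chrom %in% names(genome))
    stop("unknown sequence identifier: ", chrom, call. = FALSE)
  n <- length(genome[[chrom]])
  if (start(region) < 1L)
    stop("region start ", start(region), " is below 1 on ", chrom,
         call. = FALSE)
  if (end(region) > n)
    stop("region end ", end(region), " exceeds length ", n, " of ", chrom,
         call. = FALSE)
  s <- as.character(Biostrings::subseq(genome[[chrom]], start(region),
                                       end(region)))
  if (as.character(strand(region)) == "-") s <- revComp(s)
  s
}

#' @importFrom GenomicRanges strand
NULL
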