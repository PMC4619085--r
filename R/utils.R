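#' @import methods
#' @importFrom stats runif
#' @importFrom utils head write.table read.delim packageVersion
NULL

DNA_LETTERS <- c("A", "C", "G", "T", "N")

.assertDna <- function(x, what = "sequence", allowN = TRUE) {
  x <- toupper(as.character(x))
  pat <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains non-DNA characters: ",
         paste(unique(gsub(if (allowN) "[ACGTN]" else "[ACGT]", "", x[bad])),
               collapse = ""), call. = FALSE)
  }
  x
}

#' Reverse complement of DNA strings
#'
#' Thin character-level convenience over [Biostrings::reverseComplement()]
#' that enforces the `{A,C,G,T,N}` alphabet used throughout the package.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length; `N` is self-complementary.
#' @examples
#' revComp(c("ACGT", "AAA", "ACGN"))
#' @export
revComp <- function(x) {
  x <- .assertDna(x, "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## All positions (1-based starts) of fixed pattern `pat` in `x`, overlapping.
.allMatches <- function(x, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), x, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

.countMatches <- function(x, pat) length(.allMatches(x, pat))

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## Derive a child seed from a parent seed (kept below 2^31).
.childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

.substrs <- function(x, starts, width) {
  substring(x, starts, starts + width - 1L)
}

## One-record plus-strand character sequence from various genome containers.
.asGenomeSet <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "seq"
    return(g)
  }
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(.assertDna(genome, "genome"))
    if (is.null(names(genome))) {
      names(g) <- if (length(g) == 1L) "seq" else paste0("seq", seq_along(g))
    } else {
      names(g) <- names(genome)
    }
    return(g)
  }
  stop("cannot interpret 'genome' as a set of DNA sequences", call. = FALSE)
}
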