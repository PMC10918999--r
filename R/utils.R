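#' @import methods
#' @import data.table
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom stats rlnorm runif rbinom pbinom setNames
#' @importFrom utils head modifyList packageVersion
NULL

## residues accepted in reference sequences: the 20 proteinogenic amino
## acids plus X for ambiguous positions
AA_ALLOWED <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' The seven taxonomic ranks used throughout, highest first
#'
#' Ranks are totally ordered from superkingdom down to species; a lineage
#' present at some rank is present at every higher rank.
#'
#' @return Character vector of rank names, superkingdom first.
#' @export
#' @examples
#' taxRanks()
taxRanks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Normalize a peptide sequence for indexing and lookup
#'
#' Uppercases and, when `collapseIL = TRUE`, maps isoleucine to leucine so
#' that the isobaric residues I and L (indistinguishable by the tandem-MS
#' fragmentation the upstream search engines use) compare equal. The same
#' normalization must be applied when the index is built and when it is
#' queried.
#'
#' @param x Character vector of peptide sequences.
#' @param collapseIL Collapse I to L (default `TRUE`).
#' @return Normalized character vector.
#' @export
#' @examples
#' normalizePeptide("pepTIde")   # "PEPTLDE"
normalizePeptide <- function(x, collapseIL = TRUE) {
  x <- toupper(x)
  if (collapseIL) x <- chartr("I", "L", x)
  x
}

## validate sequence alphabet; error names the first offending character
.checkAlphabet <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALLOWED)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d (allowed: %s)",
                 chars[bad[1]], bad[1], paste(AA_ALLOWED, collapse = "")),
         call. = FALSE)
  }
  invisible(TRUE)
}

## derive a stage seed from the master seed; keeps all sub-seeds < 2^31
.deriveSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage)
}

## coerce a data.frame-ish to data.table without touching the caller's copy
.asDT <- function(x) data.table::as.data.table(x)
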