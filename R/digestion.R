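#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves the sequence C-terminal of every K or R (optionally skipping
#' sites followed by proline) and returns all products with at most
#' `params@missedCleavages` internal sites whose length falls within the
#' configured bounds. Products are ordered by start position then length;
#' within one protein each distinct product is returned once (set
#' semantics).
#'
#' @param sequence Uppercase amino-acid string (20 residues plus X).
#' @param params A [DigestionParams] object.
#' @return Character vector of peptide sequences (not normalized; apply
#'   [normalizePeptide()] for index lookups).
#' @export
#' @examples
#' digestProtein("AAAKCCCRDDDD",
#'               DigestionParams(missedCleavages = 0, minLength = 3))
digestProtein <- function(sequence, params = DigestionParams()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  sequence <- toupper(sequence)
  .checkAlphabet(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]

  ## cleavage happens after position i when chars[i] is K/R (and, under the
  ## proline rule, chars[i+1] is not P); the protein C-terminus never counts
  sites <- which(chars == "K" | chars == "R")
  sites <- sites[sites < n]
  if (params@prolineRule && length(sites))
    sites <- sites[chars[sites + 1L] != "P"]

  bounds <- c(0L, sites, n)          # fragment i spans bounds[i]+1 .. bounds[i+1]
  nf <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(nf)) {
    for (m in 0:params@missedCleavages) {
      j <- i + m
      if (j > nf) break
      len <- bounds[j + 1L] - bounds[i]
      if (len < params@minLength || len > params@maxLength) next
      out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  unique(out)
}

## digest many proteins at once; returns data.table(peptide, accession,
## species) with normalized peptides. Vectorized over the fragment lists to
## keep index construction linear-ish in total sequence length.
.digestTable <- function(accessions, sequences, species, params) {
  stopifnot(length(accessions) == length(sequences),
            length(species) == length(sequences))
  pieces <- vector("list", length(sequences))
  for (k in seq_along(sequences)) {
    peps <- digestProtein(sequences[k], params)
    if (length(peps))
      pieces[[k]] <- data.table::data.table(
        peptide = normalizePeptide(peps, params@collapseIL),
        accession = accessions[k],
        species = species[k])
  }
  dt <- data.table::rbindlist(pieces)
  if (!nrow(dt))
    dt <- data.table::data.table(peptide = character(0),
                                 accession = character(0),
                                 species = character(0))
  dt <- unique(dt)
  data.table::setkeyv(dt, "peptide")
  dt[]
}
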