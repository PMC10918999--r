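setOldClass(c("data.table", "data.frame"))

#' Tryptic digestion parameters
#'
#' Parameters of the in-silico proteolysis used to build and query the
#' peptide-taxon index. Defaults follow common DIA search settings: up to 2
#' missed cleavages and peptide length 7-30 residues. Trypsin cleaves
#' C-terminal of K/R; with `prolineRule = TRUE` (the default) a following
#' proline blocks cleavage. `collapseIL = TRUE` treats I and L as
#' equivalent, since the two isobaric residues cannot be distinguished by
#' the mass spectrometry producing the identifications.
#'
#' @slot missedCleavages integer, maximum internal K/R sites left uncut.
#' @slot minLength,maxLength integer peptide length bounds (residues).
#' @slot prolineRule logical, block cleavage before proline.
#' @slot collapseIL logical, I/L equivalence when normalizing peptides.
#' @export
setClass("DigestionParams",
         representation(missedCleavages = "integer",
                        minLength = "integer",
                        maxLength = "integer",
                        prolineRule = "logical",
                        collapseIL = "logical"),
         prototype(missedCleavages = 2L, minLength = 7L, maxLength = 30L,
                   prolineRule = TRUE, collapseIL = TRUE))

setValidity("DigestionParams", function(object) {
  if (object@missedCleavages < 0L) return("missedCleavages must be >= 0")
  if (object@minLength < 1L) return("minLength must be >= 1")
  if (object@minLength > object@maxLength)
    return("minLength must not exceed maxLength")
  TRUE
})

#' @param missedCleavages,minLength,maxLength,prolineRule,collapseIL see slots.
#' @return A `DigestionParams` object.
#' @rdname DigestionParams-class
#' @export
#' @examples
#' DigestionParams(missedCleavages = 0, minLength = 6)
DigestionParams <- function(missedCleavages = 2, minLength = 7,
                            maxLength = 30, prolineRule = TRUE,
                            collapseIL = TRUE) {
  new("DigestionParams",
      missedCleavages = as.integer(missedCleavages),
      minLength = as.integer(minLength),
      maxLength = as.integer(maxLength),
      prolineRule = prolineRule,
      collapseIL = collapseIL)
}

setMethod("show", "DigestionParams", function(object) {
  cat("DigestionParams: trypsin",
      if (object@prolineRule) "(K/R, not before P)" else "(K/R)",
      sprintf("| <=%d missed cleavages | length %d-%d | I/L %s\n",
              object@missedCleavages, object@minLength, object@maxLength,
              if (object@collapseIL) "collapsed" else "distinct"))
})

#' Peptide-to-taxon index over a reference proteome collection
#'
#' Maps every normalized tryptic peptide of the reference proteomes to the
#' set of (accession, species) pairs containing it, with the taxonomy table
#' needed to resolve specificity at each of the seven ranks. This is the
#' central lookup structure of proteotyping: a peptide observed in a sample
#' is taxon-specific at rank r when all its source organisms agree on a
#' single taxon at r.
#'
#' @slot peptides data.table with columns `peptide` (normalized),
#'   `accession`, `species`; keyed by peptide.
#' @slot taxonomy data.frame with `species_id` plus the seven rank columns.
#' @slot params the [DigestionParams] used to build the index.
#' @export
setClass("PeptideTaxonIndex",
         representation(peptides = "data.table",
                        taxonomy = "data.frame",
                        params = "DigestionParams"))

setValidity("PeptideTaxonIndex", function(object) {
  need <- c("peptide", "accession", "species")
  if (!all(need %in% names(object@peptides)))
    return(sprintf("peptides table must have columns %s",
                   paste(need, collapse = ", ")))
  if (!all(c("species_id", taxRanks()) %in% names(object@taxonomy)))
    return("taxonomy must have species_id and the seven rank columns")
  missing <- setdiff(unique(object@peptides$species),
                     object@taxonomy$species_id)
  if (length(missing))
    return(sprintf("species not in taxonomy: %s",
                   paste(missing, collapse = ", ")))
  TRUE
})

setMethod("show", "PeptideTaxonIndex", function(object) {
  cat("PeptideTaxonIndex\n")
  cat(sprintf("  %d distinct peptides | %d proteins | %d species\n",
              data.table::uniqueN(object@peptides$peptide),
              data.table::uniqueN(object@peptides$accession),
              data.table::uniqueN(object@peptides$species)))
  show(object@params)
})

#' Per-rank TSM signal profile
#'
#' Summarizes the taxonomic attribution of a set of identified spectra:
#' per-rank totals of attributed Taxon-to-Spectrum Matches (TSMs) and, per
#' (rank, taxon), the TSM count and the number of distinct taxon-specific
#' peptide sequences (spePEP). Totals are non-increasing from superkingdom
#' down to species, because specificity at a rank implies specificity at
#' every higher rank.
#'
#' @slot totals named numeric, attributed TSMs per rank (superkingdom
#'   first).
#' @slot taxa data.frame with columns `rank`, `taxon`, `tsm`, `spePEP`.
#' @slot nSpectra total spectra considered.
#' @slot nUnattributed spectra with no attribution at any rank.
#' @export
setClass("RankSignalProfile",
         representation(totals = "numeric", taxa = "data.frame",
                        nSpectra = "integer", nUnattributed = "integer"))

setValidity("RankSignalProfile", function(object) {
  if (!identical(names(object@totals), taxRanks()))
    return("totals must be named by the seven ranks, superkingdom first")
  if (any(diff(object@totals) > 1e-9))
    return("per-rank totals must be non-increasing from superkingdom to species")
  TRUE
})

setMethod("show", "RankSignalProfile", function(object) {
  cat(sprintf("RankSignalProfile: %d spectra, %d unattributed\n",
              object@nSpectra, object@nUnattributed))
  print(object@totals)
})

#' Per-taxon protein biomass profile
#'
#' Per-taxon biomass fractions (percent, summing to 100 over attributed
#' signal) computed at a single rank, with the surrogate signal recorded:
#' TSM counts (`tsm_count` mode, from data-dependent acquisition) or summed
#' protein-group precursor intensity (`intensity` mode, from
#' data-independent acquisition).
#'
#' @slot data data.frame with columns `taxon`, `fraction` (percent),
#'   `signal` (TSMs or summed intensity), `spePEP` (distinct specific
#'   peptides; `NA` in intensity mode).
#' @slot mode `"tsm_count"` or `"intensity"`.
#' @slot rank the taxonomic rank of the profile.
#' @slot unattributed signal excluded from the denominator (unmatched
#'   spectra or mixed-taxon protein groups).
#' @export
setClass("BiomassProfile",
         representation(data = "data.frame", mode = "character",
                        rank = "character", unattributed = "numeric"))

setValidity("BiomassProfile", function(object) {
  d <- object@data
  if (!all(c("taxon", "fraction", "signal") %in% names(d)))
    return("data must have columns taxon, fraction, signal")
  if (nrow(d)) {
    if (any(d$fraction < -1e-9 | d$fraction > 100 + 1e-9))
      return("fractions must lie in [0, 100]")
    if (abs(sum(d$fraction) - 100) > 1e-6)
      return("fractions must sum to 100 over attributed taxa")
  }
  if (!object@mode %in% c("tsm_count", "intensity"))
    return("mode must be tsm_count or intensity")
  if (!object@rank %in% taxRanks())
    return("rank must be one of the seven ranks")
  TRUE
})

setMethod("show", "BiomassProfile", function(object) {
  cat(sprintf("BiomassProfile (%s mode, %s rank): %d taxa, %g unattributed\n",
              object@mode, object@rank, nrow(object@data),
              object@unattributed))
  d <- object@data[order(-object@data$fraction), ]
  print(utils::head(d, 10), row.names = FALSE)
  if (nrow(d) > 10) cat(sprintf("  ... and %d more taxa\n", nrow(d) - 10))
})

#' Customized sample-specific protein database
#'
#' The FASTA database restricted to the organisms proteotyped as most
#' abundant in a sample, with entry statistics and the cumulative biomass
#' coverage of the source profile the selection achieves. Headers carry the
#' source organism (`>accession organism=<species_id>`) so downstream
#' intensity-mode quantification can resolve protein groups to taxa.
#'
#' @slot organisms character, selected species ids in selection order.
#' @slot sequences an [Biostrings::AAStringSet] of the retained entries.
#' @slot organismOf named character, accession -> species id.
#' @slot stats list: `entries`, `aminoAcids`, `perOrganism` (data.frame),
#'   `duplicates` (accessions dropped as cross-organism duplicates).
#' @slot coverage cumulative biomass coverage (percent) of the selection.
#' @export
setClass("CustomDatabase",
         representation(organisms = "character",
                        sequences = "AAStringSet",
                        organismOf = "character",
                        stats = "list",
                        coverage = "numeric"))

setValidity("CustomDatabase", function(object) {
  if (length(object@sequences) != object@stats$entries)
    return("stats$entries must equal the number of sequence records")
  if (sum(Biostrings::width(object@sequences)) != object@stats$aminoAcids)
    return("stats$aminoAcids must equal the summed sequence lengths")
  if (anyDuplicated(names(object@organismOf)))
    return("duplicate accessions in database")
  TRUE
})

setMethod("show", "CustomDatabase", function(object) {
  cat(sprintf(
    "CustomDatabase: %d organisms, %d entries, %d amino acids (%.2f%% biomass coverage)\n",
    length(object@organisms), object@stats$entries,
    object@stats$aminoAcids, object@coverage))
})
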