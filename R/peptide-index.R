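#' Build the peptide-to-taxon index from reference proteomes
#'
#' Digests every reference protein in silico (see [digestProtein()]) and
#' records, for each normalized peptide, every (accession, species) pair
#' containing it. The index underlies all taxonomic attribution: a
#' peptide's specificity at a rank is decided by the agreement of its
#' source organisms' lineages at that rank.
#'
#' @param proteome data.frame with columns `accession`, `species`,
#'   `sequence` (see [readProteomeFasta()]).
#' @param taxonomy data.frame with `species_id` plus the seven rank
#'   columns; every organism in `proteome` must appear.
#' @param params A [DigestionParams].
#' @return A [PeptideTaxonIndex].
#' @export
#' @examples
#' tx <- data.frame(species_id = "S1", superkingdom = "B", phylum = "P",
#'                  class = "C", order = "O", family = "F", genus = "G",
#'                  species = "S1")
#' pr <- data.frame(accession = "p1", species = "S1",
#'                  sequence = "AAAKCCCR")
#' buildPeptideIndex(pr, tx, DigestionParams(missedCleavages = 0,
#'                                           minLength = 3))
buildPeptideIndex <- function(proteome, taxonomy,
                              params = DigestionParams()) {
  taxonomy <- validateTaxonomy(taxonomy)
  if (nrow(proteome)) {
    if (anyDuplicated(proteome$accession))
      stop("duplicate accessions in proteome", call. = FALSE)
    missing <- setdiff(unique(proteome$species), taxonomy$species_id)
    if (length(missing))
      stop("organisms missing from taxonomy: ",
           paste(missing, collapse = ", "), call. = FALSE)
    peps <- .digestTable(proteome$accession, proteome$sequence,
                         proteome$species, params)
  } else {
    peps <- .digestTable(character(0), character(0), character(0), params)
  }
  new("PeptideTaxonIndex", peptides = peps, taxonomy = taxonomy,
      params = params)
}

#' Restrict an index to a set of species
#'
#' Keeps only (peptide, accession, species) entries of the given species.
#' Peptide specificity is re-evaluated against the restricted source sets,
#' exactly as if the index had been rebuilt from the restricted proteomes —
#' this is the second-round database of the cascade.
#'
#' @param index A [PeptideTaxonIndex].
#' @param species Character vector of species ids to retain.
#' @return A [PeptideTaxonIndex] over the retained species.
#' @export
subsetIndex <- function(index, species) {
  keepSpecies <- species
  tab <- index@peptides
  keep <- tab[tab[["species"]] %in% keepSpecies]
  data.table::setkeyv(keep, "peptide")
  new("PeptideTaxonIndex", peptides = keep, taxonomy = index@taxonomy,
      params = index@params)
}

## per-rank specificity for a set of normalized peptides.
## Returns data.table: peptide + one column per rank holding the attributed
## taxon or NA ("not specific" / rank absent in some source lineage).
## Peptides containing X are never taxon-specific (ambiguous residue).
## Peptides absent from the index are absent from the result (unmatched).
.specificityWide <- function(peptides, index) {
  ranks <- taxRanks()
  peptides <- unique(peptides)
  hits <- index@peptides[list(peptides), nomatch = NULL,
                         on = "peptide"]
  empty <- data.table::data.table(peptide = character(0))
  for (r in ranks) empty[[r]] <- character(0)
  if (!nrow(hits)) return(empty)
  src <- unique(hits[, c("peptide", "species")])
  tx <- .asDT(index@taxonomy)
  src <- merge(src, tx, by.x = "species", by.y = "species_id",
               all.x = TRUE, sort = FALSE)
  species <- NULL # appease R CMD check-style lints for NSE columns
  agg <- src[, {
    res <- lapply(ranks, function(r) {
      v <- .SD[[r]]
      if (!anyNA(v) && length(unique(v)) == 1L) v[1] else NA_character_
    })
    names(res) <- ranks
    res
  }, by = "peptide", .SDcols = ranks]
  ambiguous <- grepl("X", agg$peptide, fixed = TRUE)
  if (any(ambiguous))
    for (r in ranks) agg[[r]][ambiguous] <- NA_character_
  agg[]
}

#' Per-rank taxonomic specificity of one peptide
#'
#' Looks the peptide up in the index and reports, for each of the seven
#' ranks, the unique taxon shared by all source organisms — the taxon the
#' peptide is specific to at that rank — or `"not specific"` when the
#' sources disagree (or some lineage lacks the rank). A peptide absent
#' from the index is `"unmatched"` at every rank. Peptides containing the
#' ambiguous residue X are matched but never taxon-specific.
#'
#' @param peptide A single peptide sequence (normalized with the index's
#'   settings via [normalizePeptide()]; this is applied automatically).
#' @param index A [PeptideTaxonIndex].
#' @return data.frame with columns `rank`, `taxon` (NA unless specific),
#'   `status` (`"specific"`, `"not_specific"` or `"unmatched"`).
#' @export
querySpecificity <- function(peptide, index) {
  stopifnot(length(peptide) == 1L)
  pep <- normalizePeptide(peptide, index@params@collapseIL)
  wide <- .specificityWide(pep, index)
  ranks <- taxRanks()
  if (!nrow(wide)) {
    return(data.frame(rank = ranks, taxon = NA_character_,
                      status = "unmatched"))
  }
  taxon <- unlist(wide[1, ranks, with = FALSE], use.names = FALSE)
  data.frame(rank = ranks, taxon = taxon,
             status = ifelse(is.na(taxon), "not_specific", "specific"))
}
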