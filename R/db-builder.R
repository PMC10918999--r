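#' Select the most abundant proteotyped organisms
#'
#' Chooses the organisms that will make up the customized sample-specific
#' database. An organism passes when it meets the biomass threshold and/or
#' the species-specific-peptide threshold (`combine` picks the logic;
#' disjunctive by default, so a low-biomass organism backed by many
#' specific peptides is retained). Selected organisms are sorted by
#' descending biomass then taxon id. When `coverageTarget` is set,
#' organisms are taken in that order until the cumulative biomass reaches
#' the target (or the passing set is exhausted). `maxOrganisms` caps the
#' final list.
#'
#' @param profile A species-rank [BiomassProfile] (typically from the
#'   merged proteotyping results).
#' @param minBiomass Minimum biomass fraction, percent (default 0.1).
#' @param minSpePep Minimum species-specific peptide count (default 10).
#' @param combine `"or"` (default) or `"and"`: how the two thresholds
#'   combine.
#' @param maxOrganisms Optional cap on the number of organisms.
#' @param coverageTarget Optional cumulative biomass target, percent.
#' @return list with `organisms` (data.frame taxon, fraction, spePEP,
#'   cumulative) and `coverage` (summed selected fractions, percent). An
#'   empty profile yields an empty selection with a warning.
#' @export
selectOrganisms <- function(profile, minBiomass = 0.1, minSpePep = 10,
                            combine = c("or", "and"),
                            maxOrganisms = NULL, coverageTarget = NULL) {
  combine <- match.arg(combine)
  stopifnot(minBiomass >= 0, minSpePep >= 0)
  if (biomassRank(profile) != "species")
    stop("organism selection needs a species-rank profile", call. = FALSE)
  d <- biomassTable(profile)
  d <- d[d$taxon != "__unattributed__", , drop = FALSE]
  if (!nrow(d)) {
    warning("empty biomass profile: empty selection")
    return(list(organisms = data.frame(taxon = character(0),
                                       fraction = numeric(0),
                                       spePEP = integer(0),
                                       cumulative = numeric(0)),
                coverage = 0))
  }
  spe <- if (all(is.na(d$spePEP))) rep(0L, nrow(d)) else d$spePEP
  passB <- d$fraction >= minBiomass
  passS <- spe >= minSpePep
  pass <- if (combine == "or") passB | passS else passB & passS
  d <- d[pass, , drop = FALSE]
  d <- d[order(-d$fraction, d$taxon), , drop = FALSE]
  if (!is.null(coverageTarget) && nrow(d)) {
    cum <- cumsum(d$fraction)
    keep <- seq_len(min(which(cum >= coverageTarget - 1e-9)[1],
                        nrow(d), na.rm = TRUE))
    d <- d[keep, , drop = FALSE]
  }
  if (!is.null(maxOrganisms))
    d <- utils::head(d, maxOrganisms)
  out <- data.frame(taxon = d$taxon, fraction = d$fraction,
                    spePEP = d$spePEP, cumulative = cumsum(d$fraction),
                    row.names = NULL)
  list(organisms = out, coverage = sum(out$fraction))
}

#' Build the customized sample-specific FASTA database
#'
#' Concatenates the reference proteomes of the selected organisms into one
#' database with provenance-tagged headers
#' (`>accession organism=<species_id>`). Accessions appearing under more
#' than one organism are kept once (first selected organism wins) and the
#' duplicates logged in the statistics.
#'
#' @param organisms Character vector of selected species ids, in selection
#'   order (see [selectOrganisms()]).
#' @param proteome data.frame `accession`, `species`, `sequence` holding
#'   at least the selected organisms' records.
#' @param coverage Cumulative biomass coverage of the selection (percent),
#'   recorded in the object (default `NA`).
#' @return A [CustomDatabase].
#' @export
buildCustomFasta <- function(organisms, proteome, coverage = NA_real_) {
  sub <- proteome[proteome$species %in% organisms, , drop = FALSE]
  haveOrg <- unique(sub$species)
  missing <- setdiff(organisms, haveOrg)
  if (length(missing))
    stop("no protein records for organism(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ## selection order, then accession, decides which duplicate survives
  sub <- sub[order(match(sub$species, organisms), sub$accession), ,
             drop = FALSE]
  dup <- duplicated(sub$accession)
  dupped <- unique(sub$accession[dup])
  sub <- sub[!dup, , drop = FALSE]

  aa <- Biostrings::AAStringSet(sub$sequence)
  names(aa) <- sprintf("%s organism=%s", sub$accession, sub$species)
  perOrg <- as.data.frame(table(factor(sub$species, levels = organisms)),
                          stringsAsFactors = FALSE)
  names(perOrg) <- c("organism", "entries")
  stats <- list(entries = length(aa),
                aminoAcids = sum(Biostrings::width(aa)),
                perOrganism = perOrg,
                duplicates = dupped)
  new("CustomDatabase", organisms = organisms, sequences = aa,
      organismOf = stats::setNames(sub$species, sub$accession),
      stats = stats, coverage = as.numeric(coverage))
}

#' Write a custom database to FASTA (with a JSON stats sidecar)
#'
#' @param db A [CustomDatabase].
#' @param path Output FASTA path; statistics are written alongside as
#'   `<path>.stats.json`.
#' @return `path`, invisibly.
#' @export
writeCustomDatabase <- function(db, path) {
  Biostrings::writeXStringSet(dbSequences(db), path, width = 60L)
  stats <- dbStats(db)
  jsonlite::write_json(
    list(organisms = dbOrganisms(db), entries = stats$entries,
         aminoAcids = stats$aminoAcids, duplicates = stats$duplicates,
         coverage = db@coverage),
    paste0(path, ".stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
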