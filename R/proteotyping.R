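#' Select the highest-quality spectra
#'
#' Keeps the `n` highest-scoring PSM records (the survey stage is run on
#' the best spectra only, as ranked by an upstream spectral-quality tool
#' whose score column is consumed here). Ties are broken by
#' (run, spectrum_id) lexicographic order so the selection is
#' deterministic.
#'
#' @param psms data.frame of PSM records (`run`, `spectrum_id`, `peptide`,
#'   `score`, optionally `intensity`).
#' @param n Number of spectra to keep; if `n` exceeds the table, all
#'   records are returned.
#' @return data.frame of the selected records, best first.
#' @export
selectTopSpectra <- function(psms, n = 100000L) {
  stopifnot(n >= 0)
  if (!"score" %in% names(psms) || anyNA(psms$score)) {
    bad <- if ("score" %in% names(psms)) which(is.na(psms$score))[1] else 1L
    stop(sprintf("missing quality score (record %d: run=%s spectrum=%s)",
                 bad, psms$run[bad], psms$spectrum_id[bad]), call. = FALSE)
  }
  ord <- order(-psms$score, psms$run, psms$spectrum_id)
  psms[utils::head(ord, n), , drop = FALSE]
}

#' Assign identified spectra to taxa (TSMs)
#'
#' Each spectrum whose peptide is taxon-specific at rank r contributes one
#' Taxon-to-Spectrum Match (TSM) to that taxon at rank r — and, through
#' lineage agreement, to the taxon's ancestors at every higher rank.
#' Spectra whose peptides are unmatched, or specific at no rank, are
#' counted as unattributed. spePEP counts distinct peptide sequences per
#' (rank, taxon), not spectra.
#'
#' @param psms data.frame of PSM records.
#' @param index A [PeptideTaxonIndex] built with the same normalization as
#'   the PSM peptides.
#' @return list with `assignments` (one row per spectrum: run,
#'   spectrum_id, peptide, one attributed-taxon column per rank, NA where
#'   not specific) and `profile` (a [RankSignalProfile]).
#' @export
assignTsms <- function(psms, index) {
  ranks <- taxRanks()
  psmdt <- .asDT(psms)
  psmdt[, `:=`(peptide = normalizePeptide(peptide,
                                          index@params@collapseIL))]
  spec <- .specificityWide(unique(psmdt$peptide), index)
  asg <- merge(psmdt[, c("run", "spectrum_id", "peptide")], spec,
               by = "peptide", all.x = TRUE, sort = FALSE)
  data.table::setorderv(asg, c("run", "spectrum_id"))
  data.table::setcolorder(asg, c("run", "spectrum_id", "peptide", ranks))

  totals <- vapply(ranks, function(r) sum(!is.na(asg[[r]])), numeric(1))
  pieces <- lapply(ranks, function(r) {
    sub <- asg[!is.na(asg[[r]]), c("peptide", r), with = FALSE]
    if (!nrow(sub))
      return(data.table::data.table(rank = character(0),
                                    taxon = character(0), tsm = integer(0),
                                    spePEP = integer(0)))
    data.table::setnames(sub, r, "taxon")
    sub[, list(rank = r, tsm = .N,
               spePEP = data.table::uniqueN(peptide)), by = "taxon"]
  })
  taxa <- data.table::rbindlist(pieces, use.names = TRUE)
  data.table::setcolorder(taxa, c("rank", "taxon", "tsm", "spePEP"))
  data.table::setorderv(taxa, c("rank", "taxon"))

  unatt <- sum(rowSums(!is.na(as.matrix(asg[, ranks, with = FALSE]))) == 0L)
  profile <- new("RankSignalProfile",
                 totals = stats::setNames(totals, ranks),
                 taxa = as.data.frame(taxa),
                 nSpectra = nrow(asg),
                 nUnattributed = as.integer(unatt))
  list(assignments = as.data.frame(asg), profile = profile)
}

#' Per-rank signal retention
#'
#' The attributed TSM total at each rank as a percentage of the
#' superkingdom total. Retention erodes moving down the hierarchy as
#' peptides shared across taxa lose specificity — the drop from genus to
#' species measures how well species-level reference sequences cover the
#' community.
#'
#' @param profile A [RankSignalProfile].
#' @param perTaxonAt Optional grouping rank (e.g. `"phylum"`): additionally
#'   partition retention within each taxon at that rank, for ranks at and
#'   below it. Requires `taxonomy`.
#' @param taxonomy Taxonomy table (`species_id` + rank columns) used to
#'   fold lower-rank taxa up to the grouping rank; only needed with
#'   `perTaxonAt`.
#' @return data.frame with `rank` and `retention` (percent); with
#'   `perTaxonAt`, additional rows carry a `taxon` column and retention is
#'   relative to that taxon's total at the grouping rank (overall rows have
#'   `taxon = NA`).
#' @export
rankSignalRetention <- function(profile, perTaxonAt = NULL,
                                taxonomy = NULL) {
  totals <- profile@totals
  if (totals[["superkingdom"]] == 0)
    stop("no attributable signal at superkingdom rank", call. = FALSE)
  out <- data.frame(rank = taxRanks(), taxon = NA_character_,
                    retention = 100 * as.numeric(totals) /
                      totals[["superkingdom"]],
                    row.names = NULL)
  if (is.null(perTaxonAt)) return(out[, c("rank", "retention")])
  stopifnot(perTaxonAt %in% taxRanks(), !is.null(taxonomy))
  ranks <- taxRanks()
  below <- ranks[seq(match(perTaxonAt, ranks), length(ranks))]
  taxa <- .asDT(profile@taxa)
  tx <- .asDT(taxonomy)
  groups <- list()
  for (r in below) {
    ## ancestor of an r-rank taxon at the grouping rank, via any lineage
    ## carrying that value at r (lineages folding to two different groups
    ## would be malformed taxonomy)
    anc <- unique(tx[, c(perTaxonAt, r), with = FALSE])
    data.table::setnames(anc, c("group", "taxon"))
    sub <- merge(taxa[taxa$rank == r], anc, by = "taxon", sort = FALSE)
    if (nrow(sub))
      groups[[r]] <- sub[, list(rank = r, tsm = sum(tsm)), by = "group"]
  }
  g <- data.table::rbindlist(groups)
  base <- g[g$rank == perTaxonAt, c("group", "tsm")]
  data.table::setnames(base, "tsm", "baseTsm")
  g <- merge(g, base, by = "group", sort = FALSE)
  g <- g[g$baseTsm > 0]
  per <- data.frame(rank = g$rank, taxon = g$group,
                    retention = 100 * g$tsm / g$baseTsm)
  rbind(out, per)
}

#' Two-round proteotyping cascade: genera, then species
#'
#' Round 1 attributes spectra against the generic index and accepts every
#' genus meeting the evidence thresholds. Round 2 restricts the index to
#' the accepted genera's descendant species (the second-round database),
#' re-attributes the same spectra — peptides shared only across rejected
#' genera may become specific — and accepts species meeting the same
#' thresholds. Detection carries no priors: any taxon present in the
#' generic index can be accepted.
#'
#' @param psms data.frame of PSM records.
#' @param index The generic [PeptideTaxonIndex].
#' @param minSpePep Minimum distinct taxon-specific peptides per accepted
#'   taxon (default 3).
#' @param minTsm Minimum TSMs per accepted taxon (default 5).
#' @param binomialScreen Additionally require a binomial tail test: the
#'   probability of observing at least the taxon's TSM count under a
#'   uniform-assignment null (each attributed spectrum equally likely to
#'   hit any taxon at that rank) must fall below `alpha`.
#' @param alpha Significance level of the optional screen (default 0.05).
#' @return list with `round1` and `round2` evidence tables (taxon, tsm,
#'   spePEP, accepted), `acceptedGenera`, `acceptedSpecies`, both rounds'
#'   [RankSignalProfile]s, and `assignments2` (the second-round per-spectrum
#'   attributions, ready for [estimateBiomass()]).
#' @export
cascadeSearch <- function(psms, index, minSpePep = 3L, minTsm = 5L,
                          binomialScreen = FALSE, alpha = 0.05) {
  if (!nrow(psms)) {
    empty <- data.frame(taxon = character(0), tsm = integer(0),
                        spePEP = integer(0), accepted = logical(0))
    return(list(round1 = empty, round2 = empty,
                acceptedGenera = character(0),
                acceptedSpecies = character(0),
                profile1 = NULL, profile2 = NULL,
                assignments2 = NULL))
  }
  r1 <- assignTsms(psms, index)
  tab1 <- .acceptTaxa(r1$profile, "genus", minSpePep, minTsm,
                      binomialScreen, alpha)
  genera <- tab1$taxon[tab1$accepted]

  tx <- index@taxonomy
  keepSpecies <- tx$species_id[!is.na(tx$genus) & tx$genus %in% genera]
  idx2 <- subsetIndex(index, keepSpecies)
  r2 <- assignTsms(psms, idx2)
  tab2 <- .acceptTaxa(r2$profile, "species", minSpePep, minTsm,
                      binomialScreen, alpha)
  list(round1 = tab1, round2 = tab2,
       acceptedGenera = genera,
       acceptedSpecies = tab2$taxon[tab2$accepted],
       profile1 = r1$profile, profile2 = r2$profile,
       assignments2 = r2$assignments)
}

## threshold (and optional binomial) acceptance at one rank
.acceptTaxa <- function(profile, rank, minSpePep, minTsm, binomialScreen,
                        alpha) {
  taxa <- profile@taxa
  tab <- taxa[taxa$rank == rank, c("taxon", "tsm", "spePEP")]
  if (!nrow(tab))
    return(data.frame(taxon = character(0), tsm = integer(0),
                      spePEP = integer(0), accepted = logical(0)))
  tab$accepted <- tab$spePEP >= minSpePep & tab$tsm >= minTsm
  if (binomialScreen && nrow(tab) > 0) {
    total <- sum(tab$tsm)
    p0 <- 1 / nrow(tab)
    pval <- stats::pbinom(tab$tsm - 1L, total, p0, lower.tail = FALSE)
    tab$pValue <- pval
    tab$accepted <- tab$accepted & pval < alpha
  }
  rownames(tab) <- NULL
  tab[order(-tab$tsm, tab$taxon), ]
}

#' Merge proteotyping results across analytical runs
#'
#' Consolidates per-run cascade outputs into one reliable taxon list: the
#' union of accepted taxa with TSM counts summed across runs and, per
#' taxon, the best single-run spePEP count retained (the count reported
#' for "the best analytical run").
#'
#' @param results list of per-run evidence tables (as returned in
#'   `round2`/`round1` of [cascadeSearch()]; columns `taxon`, `tsm`,
#'   `spePEP`, `accepted`).
#' @param taxonomies Optional list of the taxonomy tables the runs used;
#'   they must be identical (all runs must share the generic index).
#' @return data.frame `taxon`, `tsm` (summed), `spePEP` (best run),
#'   `nRuns` (runs accepting the taxon), sorted by descending TSM.
#' @export
mergeProteotypingRuns <- function(results, taxonomies = NULL) {
  if (!is.null(taxonomies) && length(taxonomies) > 1) {
    for (k in seq_along(taxonomies)[-1])
      if (!identical(taxonomies[[1]], taxonomies[[k]]))
        stop("runs used inconsistent taxonomy tables", call. = FALSE)
  }
  acc <- lapply(results, function(r) r[r$accepted, , drop = FALSE])
  all <- data.table::rbindlist(acc, use.names = TRUE, fill = TRUE)
  if (!nrow(all))
    return(data.frame(taxon = character(0), tsm = integer(0),
                      spePEP = integer(0), nRuns = integer(0)))
  merged <- all[, list(tsm = sum(tsm), spePEP = max(spePEP), nRuns = .N),
                by = "taxon"]
  data.table::setorderv(merged, c("tsm", "taxon"), order = c(-1L, 1L))
  as.data.frame(merged)
}
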