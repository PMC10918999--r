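#' Pathway coverage from KO annotations
#'
#' For each pathway, coverage is the percentage of its KO terms observed
#' among the annotated proteins:
#' `100 * |observed KOs in pathway| / |pathway KOs|`. Proteins without a
#' KO are excluded from the observation set and counted; observed KOs
#' belonging to no pathway are reported as unmapped.
#'
#' @param annotations data.frame `protein_group`, `KO`, `taxon`,
#'   `abundance` (see [readKoAnnotations()]); `KO` may be NA.
#' @param pathways Long-format data.frame `pathway`, `category`, `KO`.
#' @return list with `coverage` (data.frame pathway, category, observed,
#'   total, coverage), `nUnannotated` (proteins without KO) and
#'   `unmappedKOs` (observed KOs in no pathway).
#' @export
computePathwayCoverage <- function(annotations, pathways) {
  obs <- unique(annotations$KO[!is.na(annotations$KO)])
  pw <- .asDT(pathways)
  cov <- pw[, list(category = category[1],
                   observed = sum(unique(KO) %in% obs),
                   total = data.table::uniqueN(KO)),
            by = "pathway"]
  cov[, `:=`(coverage = 100 * observed / total)]
  data.table::setorderv(cov, "pathway")
  list(coverage = as.data.frame(cov),
       nUnannotated = sum(is.na(annotations$KO)),
       unmappedKOs = sort(setdiff(obs, unique(pw$KO))))
}

#' Abundance-weighted pathway profile
#'
#' Weights each pathway by the summed mean abundance of the proteins whose
#' KO belongs to it, per group of interest (host vs microbiota, or per
#' taxon). The KO-to-pathway mapping is many-to-many: a protein whose KO
#' sits in k pathways contributes its full abundance to each of them
#' (standard KEGG practice); `uniquenessWeighted = TRUE` divides the
#' contribution by k instead, so total abundance is conserved across
#' pathways.
#'
#' @param annotations data.frame `protein_group`, `KO`, `taxon`,
#'   `abundance` (mean across replicates).
#' @param pathways Long-format pathway definitions.
#' @param grouping `"taxon"` (default) groups by the taxon column; or a
#'   named character vector taxon -> group (e.g. host/microbiota) applied
#'   before grouping.
#' @param uniquenessWeighted Divide a protein's contribution by the number
#'   of pathways its KO maps to (default `FALSE`).
#' @param normalize Also return per-group fractional weights (percent of
#'   the group's total; default `TRUE`).
#' @return data.frame `group`, `pathway`, `category`, `weight` (and
#'   `fraction` when `normalize`).
#' @export
pathwayAbundance <- function(annotations, pathways, grouping = "taxon",
                             uniquenessWeighted = FALSE,
                             normalize = TRUE) {
  ann <- .asDT(annotations)
  ann <- ann[!is.na(ann$KO)]
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping == "taxon") {
    ann[, `:=`(group = taxon)]
  } else {
    ann[, `:=`(group = unname(grouping[taxon]))]
    ann <- ann[!is.na(ann$group)]
  }
  pw <- .asDT(pathways)
  if (uniquenessWeighted) {
    k <- pw[, list(nPathways = data.table::uniqueN(pathway)), by = "KO"]
    ann <- merge(ann, k, by = "KO", sort = FALSE)
    ann[, `:=`(abundance = abundance / nPathways)]
  }
  j <- merge(ann[, c("KO", "group", "abundance")],
             pw[, c("KO", "pathway", "category")],
             by = "KO", allow.cartesian = TRUE, sort = FALSE)
  if (!nrow(j))
    return(data.frame(group = character(0), pathway = character(0),
                      category = character(0), weight = numeric(0)))
  out <- j[, list(weight = sum(abundance)),
           by = c("group", "pathway", "category")]
  if (normalize)
    out[, `:=`(fraction = 100 * weight / sum(weight)), by = "group"]
  data.table::setorderv(out, c("group", "pathway"))
  as.data.frame(out)
}

#' Genus-by-function contribution matrix
#'
#' Sums abundance per (taxon at the requested rank, pathway category) —
#' the input of a chord/Circos diagram of which genera carry which
#' functional categories. Taxa that cannot be resolved to the rank fall
#' into an `"unclassified"` row.
#'
#' @param annotations data.frame with `KO`, `taxon`, `abundance`.
#' @param pathways Long-format pathway definitions (for KO -> category).
#' @param taxonomy Taxonomy table to resolve taxa (species ids) to the
#'   requested rank.
#' @param rank Grouping rank (default `"genus"`).
#' @return numeric matrix, rows = taxa at `rank` (plus possibly
#'   `"unclassified"`), columns = pathway categories.
#' @export
taxonFunctionMatrix <- function(annotations, pathways, taxonomy,
                                rank = "genus") {
  stopifnot(rank %in% taxRanks())
  ann <- .asDT(annotations)
  ann <- ann[!is.na(ann$KO)]
  grp <- taxonomy[[rank]][match(ann$taxon, taxonomy$species_id)]
  grp[is.na(grp)] <- "unclassified"
  ann[, `:=`(group = grp)]
  pw <- unique(.asDT(pathways)[, c("KO", "category")])
  j <- merge(ann[, c("KO", "group", "abundance")], pw, by = "KO",
             allow.cartesian = TRUE, sort = FALSE)
  if (!nrow(j))
    return(matrix(numeric(0), 0, 0))
  tab <- j[, list(weight = sum(abundance)), by = c("group", "category")]
  m <- data.table::dcast(tab, group ~ category, value.var = "weight",
                         fill = 0)
  rn <- m$group
  m <- as.matrix(m[, -1])
  rownames(m) <- rn
  m
}

#' Write a taxon-function matrix as a Circos-style link table
#'
#' Long-format TSV (`taxon`, `category`, `weight`) directly consumable as
#' chord-diagram input.
#'
#' @param m Matrix from [taxonFunctionMatrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCircosTable <- function(m, path) {
  long <- data.table::as.data.table(as.table(m))
  data.table::setnames(long, c("taxon", "category", "weight"))
  .writeTsv(long[long$weight > 0], path)
}

#' Compare the pathway repertoires of two taxa
#'
#' Splits the observed KO terms of two taxa into three disjoint sets —
#' shared, A-specific, B-specific — whose union is everything observed in
#' either taxon, and classifies each pathway touched by those KOs:
#' `"shared"` when both taxa hit it with the same KO set, `"mixed"` when
#' both hit it with different KOs, `"A_only"`/`"B_only"` otherwise.
#'
#' @param annotations data.frame with `KO`, `taxon`.
#' @param taxonA,taxonB The two taxon ids to compare.
#' @param pathways Optional pathway definitions for the per-pathway
#'   classification.
#' @return list with `shared`, `onlyA`, `onlyB` (sorted KO vectors) and,
#'   when pathways are given, `pathwayLabels` (data.frame pathway, label).
#' @export
compareTaxaPathways <- function(annotations, taxonA, taxonB,
                                pathways = NULL) {
  koOf <- function(t) {
    unique(annotations$KO[annotations$taxon == t &
                            !is.na(annotations$KO)])
  }
  a <- koOf(taxonA)
  b <- koOf(taxonB)
  out <- list(shared = sort(intersect(a, b)),
              onlyA = sort(setdiff(a, b)),
              onlyB = sort(setdiff(b, a)))
  if (!is.null(pathways)) {
    pw <- .asDT(pathways)
    lab <- pw[, {
      sa <- intersect(KO, a)
      sb <- intersect(KO, b)
      label <- if (length(sa) && length(sb)) {
        if (setequal(sa, sb)) "shared" else "mixed"
      } else if (length(sa)) "A_only"
      else if (length(sb)) "B_only"
      else NA_character_
      list(label = label)
    }, by = "pathway"]
    out$pathwayLabels <- as.data.frame(lab[!is.na(lab$label)])
  }
  out
}

#' KO annotation rate per group
#'
#' Fraction of protein groups carrying a KO annotation, per group (host,
#' microbiota, taxon...). Groups with zero proteins are reported with
#' `NA` percentage rather than raising a division error.
#'
#' @param annotations data.frame with `protein_group`, `KO`, `taxon`.
#' @param grouping `"taxon"` or a named character vector taxon -> group.
#' @return data.frame `group`, `annotated`, `total`, `rate` (percent).
#' @export
annotationRate <- function(annotations, grouping = "taxon") {
  ann <- .asDT(annotations)
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping == "taxon") {
    ann[, `:=`(group = taxon)]
  } else {
    ann[, `:=`(group = unname(grouping[taxon]))]
  }
  out <- ann[, list(annotated = sum(!is.na(KO)), total = .N),
             by = "group"]
  out[, `:=`(rate = ifelse(total > 0, 100 * annotated / total,
                           NA_real_))]
  data.table::setorderv(out, "group")
  as.data.frame(out)
}
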