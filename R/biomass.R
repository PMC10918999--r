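#' Estimate per-taxon protein biomass
#'
#' Converts the taxonomically attributed signal into biomass fractions:
#' `fraction(T) = 100 * signal(T) / sum(signal)` over attributed taxa.
#' Two surrogate signals are supported, mirroring the two acquisition
#' strategies: `tsm_count` counts Taxon-to-Spectrum Matches at the
#' requested rank (DDA), `intensity` sums protein-group precursor
#' intensity (DIA), averaging each group's intensity across runs before
#' summing.
#'
#' In intensity mode a protein group is resolved to a taxon only when all
#' member accessions map to the same taxon at the requested rank; mixed
#' groups are excluded and their summed intensity reported as
#' unattributed. By default unattributed signal is excluded from the
#' denominator (fractions are "of attributed biomass");
#' `includeUnattributed = TRUE` adds it to the denominator instead.
#'
#' @param x For `tsm_count` mode the `assignments` data.frame of
#'   [assignTsms()]; for `intensity` mode a protein-group quantification
#'   table (see [readQuantTable()]).
#' @param rank Rank at which to compute the profile (default
#'   `"species"`).
#' @param mode `"tsm_count"` or `"intensity"`.
#' @param organismOf Named character accession -> species id (intensity
#'   mode only; a [CustomDatabase] carries one).
#' @param taxonomy Taxonomy table, needed in intensity mode when `rank`
#'   is above species.
#' @param includeUnattributed Include unattributed signal in the
#'   denominator (default `FALSE`).
#' @return A [BiomassProfile].
#' @export
estimateBiomass <- function(x, rank = "species",
                            mode = c("tsm_count", "intensity"),
                            organismOf = NULL, taxonomy = NULL,
                            includeUnattributed = FALSE) {
  mode <- match.arg(mode)
  stopifnot(rank %in% taxRanks())
  if (mode == "tsm_count") {
    .biomassFromTsms(x, rank, includeUnattributed)
  } else {
    .biomassFromIntensity(x, rank, organismOf, taxonomy,
                          includeUnattributed)
  }
}

.biomassFromTsms <- function(assignments, rank, includeUnattributed) {
  stopifnot(rank %in% names(assignments))
  dt <- .asDT(assignments)
  att <- dt[!is.na(dt[[rank]])]
  if (!nrow(att))
    stop("no attributable signal at rank ", rank, call. = FALSE)
  data.table::setnames(att, rank, "..taxon")
  tab <- att[, list(signal = as.numeric(.N),
                    spePEP = data.table::uniqueN(peptide)),
             by = "..taxon"]
  data.table::setnames(tab, "..taxon", "taxon")
  unatt <- nrow(dt) - nrow(att)
  .makeBiomassProfile(as.data.frame(tab), "tsm_count", rank,
                      as.numeric(unatt), includeUnattributed)
}

.biomassFromIntensity <- function(quant, rank, organismOf, taxonomy,
                                  includeUnattributed) {
  if (is.null(organismOf))
    stop("intensity mode needs organismOf (accession -> species)",
         call. = FALSE)
  runCols <- setdiff(names(quant), c("protein_group", "member_accessions"))
  if (!length(runCols))
    stop("quant table has no intensity columns", call. = FALSE)
  inten <- rowMeans(as.matrix(quant[, runCols, drop = FALSE]),
                    na.rm = TRUE)
  if (any(inten < 0, na.rm = TRUE))
    stop("negative intensities", call. = FALSE)

  toRank <- function(sp) {
    if (rank == "species") return(sp)
    if (is.null(taxonomy))
      stop("taxonomy needed for rank above species", call. = FALSE)
    taxonomy[[rank]][match(sp, taxonomy$species_id)]
  }
  members <- strsplit(as.character(quant$member_accessions), ";",
                      fixed = TRUE)
  taxon <- vapply(members, function(acc) {
    sp <- organismOf[acc]
    if (anyNA(sp)) return(NA_character_)
    tr <- unique(toRank(unname(sp)))
    if (length(tr) == 1L && !is.na(tr)) tr else NA_character_
  }, character(1))

  resolved <- !is.na(taxon)
  if (!any(resolved))
    stop("no attributable signal: no protein group resolves to a single ",
         rank, call. = FALSE)
  dt <- data.table::data.table(taxon = taxon[resolved],
                               signal = inten[resolved])
  tab <- dt[, list(signal = sum(signal)), by = "taxon"]
  tab$spePEP <- NA_integer_
  unatt <- sum(inten[!resolved])
  .makeBiomassProfile(as.data.frame(tab), "intensity", rank, unatt,
                      includeUnattributed)
}

.makeBiomassProfile <- function(tab, mode, rank, unattributed,
                                includeUnattributed) {
  denom <- sum(tab$signal) + if (includeUnattributed) unattributed else 0
  if (denom <= 0) stop("no attributable signal", call. = FALSE)
  tab$fraction <- 100 * tab$signal / denom
  tab <- tab[order(-tab$fraction, tab$taxon),
             c("taxon", "fraction", "signal", "spePEP")]
  rownames(tab) <- NULL
  if (includeUnattributed && unattributed > 0) {
    ## keep the class invariant (fractions sum to 100 over listed rows)
    tab <- rbind(tab, data.frame(taxon = "__unattributed__",
                                 fraction = 100 * unattributed / denom,
                                 signal = unattributed,
                                 spePEP = NA_integer_))
  }
  new("BiomassProfile", data = tab, mode = mode, rank = rank,
      unattributed = as.numeric(unattributed))
}
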