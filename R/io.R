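#' Read a taxonomy table
#'
#' Expects a TSV with a `species_id` column plus the seven rank columns
#' (superkingdom ... species). Any rank may be empty/NA (unranked
#' placeholder), but a value at some rank requires values at all higher
#' ranks — lineages grow top-down.
#'
#' @param path Path to a tab-separated file.
#' @return data.frame with `species_id` and the seven rank columns.
#' @export
readTaxonomy <- function(path) {
  tx <- .freadTsv(path, colClasses = "character",
                  na.strings = c("", "NA"))
  validateTaxonomy(as.data.frame(tx))
}

#' Validate a taxonomy table
#'
#' Checks column presence, species-id uniqueness and the top-down lineage
#' rule (a present rank implies all higher ranks present).
#'
#' @param taxonomy data.frame with `species_id` plus the seven rank columns.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validateTaxonomy <- function(taxonomy) {
  need <- c("species_id", taxRanks())
  miss <- setdiff(need, names(taxonomy))
  if (length(miss))
    stop("taxonomy missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(taxonomy$species_id))
    stop("duplicate species_id in taxonomy", call. = FALSE)
  rk <- taxRanks()
  m <- as.matrix(taxonomy[, rk])
  present <- !is.na(m) & nzchar(m)
  ## a present rank requires every higher (left-ward) rank present
  for (j in seq_along(rk)[-1]) {
    bad <- present[, j] & !present[, j - 1L]
    if (any(bad))
      stop(sprintf("lineage for %s has rank %s without %s",
                   taxonomy$species_id[which(bad)[1]], rk[j], rk[j - 1L]),
           call. = FALSE)
  }
  taxonomy[, need]
}

#' Read a reference proteome FASTA
#'
#' The accession is the first whitespace-delimited token of each header.
#' The source organism is taken from an `organism=<species_id>` tag in the
#' header when present, else from the supplied accession-to-species map.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param organismOf Optional named character vector, accession ->
#'   species id; used for records without an `organism=` header tag.
#' @return data.frame with columns `accession`, `species`, `sequence`.
#' @export
readProteomeFasta <- function(path, organismOf = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  tag <- regmatches(headers, regexpr("organism=\\S+", headers))
  species <- rep(NA_character_, length(headers))
  hasTag <- grepl("organism=", headers, fixed = TRUE)
  species[hasTag] <- sub("^organism=", "", tag)
  if (!is.null(organismOf)) {
    fill <- is.na(species) & accession %in% names(organismOf)
    species[fill] <- organismOf[accession[fill]]
  }
  if (anyNA(species))
    stop("no organism for accession(s): ",
         paste(utils::head(accession[is.na(species)], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(accession))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  data.frame(accession = accession, species = species,
             sequence = as.character(aa), row.names = NULL)
}

#' Write a proteome table as FASTA
#'
#' Emits headers of the form `>accession organism=<species_id>` so taxon
#' provenance survives the round trip.
#'
#' @param proteome data.frame with `accession`, `species`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeProteomeFasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- sprintf("%s organism=%s", proteome$accession,
                       proteome$species)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a PSM table
#'
#' Tab-separated with columns `run`, `spectrum_id`, `peptide`, `score` and
#' optionally `intensity`. One peptide per spectrum (chimeric deconvolution
#' is the search engine's job, upstream of this package).
#'
#' @param path Path to the TSV.
#' @return data.frame of PSM records.
#' @export
readPsmTable <- function(path) {
  dt <- .freadTsv(path)
  need <- c("run", "spectrum_id", "peptide", "score")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("PSM table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(dt[, c("run", "spectrum_id")]))
    stop("(run, spectrum_id) pairs must be unique", call. = FALSE)
  if (any(!nzchar(dt$peptide)))
    stop("empty peptide sequence in PSM table", call. = FALSE)
  as.data.frame(dt)
}

#' Read a DIA protein-group quantification table
#'
#' Tab-separated with columns `protein_group`, `member_accessions`
#' (semicolon-separated accessions) and one or more intensity columns
#' (every remaining numeric column is treated as a run).
#'
#' @param path Path to the TSV.
#' @return data.frame with `protein_group`, `member_accessions` and
#'   intensity columns.
#' @export
readQuantTable <- function(path) {
  dt <- .freadTsv(path)
  need <- c("protein_group", "member_accessions")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("quant table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  runs <- setdiff(names(dt), need)
  if (!length(runs))
    stop("quant table has no intensity columns", call. = FALSE)
  as.data.frame(dt)
}

#' Read KO annotations
#'
#' Tab-separated with columns `protein_group`, `KO` (may be empty for
#' unannotated proteins), `taxon`, `abundance` (mean across replicates).
#'
#' @param path Path to the TSV.
#' @return data.frame of annotations.
#' @export
readKoAnnotations <- function(path) {
  dt <- .freadTsv(path, na.strings = c("", "NA"))
  need <- c("protein_group", "KO", "taxon", "abundance")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(dt$abundance)))
    stop("non-finite abundance in annotation table", call. = FALSE)
  as.data.frame(dt)
}

#' Read pathway definitions (long format)
#'
#' Tab-separated with columns `pathway`, `category`, `KO`: one row per
#' (pathway, KO) membership. The KO-to-pathway mapping is many-to-many.
#'
#' @param path Path to the TSV.
#' @return data.frame of pathway memberships.
#' @export
readPathwayDefinitions <- function(path) {
  dt <- .freadTsv(path)
  need <- c("pathway", "category", "KO")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("pathway table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.data.frame(unique(data.table::as.data.table(dt[, need])))
}

## fread wrapper that skips leading '#' comment lines (written by .writeTsv)
.freadTsv <- function(path, ...) {
  first <- readLines(path, n = 50L)
  skip <- match(FALSE, startsWith(first, "#"), nomatch = 1L) - 1L
  data.table::fread(path, sep = "\t", header = TRUE, skip = skip, ...)
}

## uniform TSV writer used by the pipeline; header comment names the
## producing version so outputs are self-describing
.writeTsv <- function(x, path, comment = TRUE) {
  if (comment) {
    con <- file(path, "w")
    writeLines(sprintf("# produced by proteotypeR %s",
                       as.character(utils::packageVersion("proteotypeR"))),
               con)
    close(con)
    data.table::fwrite(x, path, sep = "\t", append = TRUE,
                       col.names = TRUE)
  } else {
    data.table::fwrite(x, path, sep = "\t")
  }
  invisible(path)
}
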