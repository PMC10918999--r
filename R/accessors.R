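#' Accessors for proteotypeR classes
#'
#' Small generics to reach the contents of the S4 containers without
#' touching slots directly.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @return `indexPeptides()`: the (peptide, accession, species) table.
#' @export
setGeneric("indexPeptides", function(x) standardGeneric("indexPeptides"))

#' @rdname accessors
#' @export
setMethod("indexPeptides", "PeptideTaxonIndex",
          function(x) data.table::copy(x@peptides))

#' @rdname accessors
#' @return `indexTaxonomy()`: the taxonomy table of the index.
#' @export
setGeneric("indexTaxonomy", function(x) standardGeneric("indexTaxonomy"))

#' @rdname accessors
#' @export
setMethod("indexTaxonomy", "PeptideTaxonIndex", function(x) x@taxonomy)

#' @rdname accessors
#' @return `digestionParams()`: the [DigestionParams] of the index.
#' @export
setGeneric("digestionParams", function(x) standardGeneric("digestionParams"))

#' @rdname accessors
#' @export
setMethod("digestionParams", "PeptideTaxonIndex", function(x) x@params)

#' @rdname accessors
#' @return `rankTotals()`: named per-rank attributed TSM totals.
#' @export
setGeneric("rankTotals", function(x) standardGeneric("rankTotals"))

#' @rdname accessors
#' @export
setMethod("rankTotals", "RankSignalProfile", function(x) x@totals)

#' @rdname accessors
#' @return `taxonCounts()`: per-(rank, taxon) TSM and spePEP counts.
#' @export
setGeneric("taxonCounts", function(x) standardGeneric("taxonCounts"))

#' @rdname accessors
#' @export
setMethod("taxonCounts", "RankSignalProfile", function(x) x@taxa)

#' @rdname accessors
#' @return `biomassTable()`: per-taxon fraction/signal/spePEP table.
#' @export
setGeneric("biomassTable", function(x) standardGeneric("biomassTable"))

#' @rdname accessors
#' @export
setMethod("biomassTable", "BiomassProfile", function(x) x@data)

#' @rdname accessors
#' @return `biomassMode()`: `"tsm_count"` or `"intensity"`.
#' @export
setGeneric("biomassMode", function(x) standardGeneric("biomassMode"))

#' @rdname accessors
#' @export
setMethod("biomassMode", "BiomassProfile", function(x) x@mode)

#' @rdname accessors
#' @return `biomassRank()`: rank at which the profile was computed.
#' @export
setGeneric("biomassRank", function(x) standardGeneric("biomassRank"))

#' @rdname accessors
#' @export
setMethod("biomassRank", "BiomassProfile", function(x) x@rank)

#' @rdname accessors
#' @return `dbSequences()`: the [Biostrings::AAStringSet] of a database.
#' @export
setGeneric("dbSequences", function(x) standardGeneric("dbSequences"))

#' @rdname accessors
#' @export
setMethod("dbSequences", "CustomDatabase", function(x) x@sequences)

#' @rdname accessors
#' @return `dbStats()`: entry statistics of a database.
#' @export
setGeneric("dbStats", function(x) standardGeneric("dbStats"))

#' @rdname accessors
#' @export
setMethod("dbStats", "CustomDatabase", function(x) x@stats)

#' @rdname accessors
#' @return `dbOrganisms()`: selected organisms in selection order.
#' @export
setGeneric("dbOrganisms", function(x) standardGeneric("dbOrganisms"))

#' @rdname accessors
#' @export
setMethod("dbOrganisms", "CustomDatabase", function(x) x@organisms)
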