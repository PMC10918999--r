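# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: digestion enumerates every substring of the sequence and
# checks its boundaries; index queries are linear scans over all proteins.

# all tryptic products of `seq` with <= maxMissed internal sites, by
# exhaustive substring enumeration
oracleDigest <- function(seq, maxMissed, minLen, maxLen,
                         prolineRule = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  isSite <- function(i) {
    i >= 1 && i < n && chars[i] %in% c("K", "R") &&
      (!prolineRule || chars[i + 1] != "P")
  }
  out <- character(0)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (!(s == 1 || isSite(s - 1))) next
      if (!(e == n || isSite(e))) next
      len <- e - s + 1
      if (len < minLen || len > maxLen) next
      internal <- if (e > s) sum(vapply(s:(e - 1), isSite, logical(1))) else 0
      if (internal > maxMissed) next
      out <- c(out, substr(seq, s, e))
    }
  }
  unique(out)
}

# linear scan: which (accession, species) contain `pep` as a digestion
# product (normalized comparison)
oracleLookup <- function(pep, proteome, maxMissed, minLen, maxLen,
                         collapseIL = TRUE) {
  pep <- normalizePeptide(pep, collapseIL)
  hits <- list()
  for (i in seq_len(nrow(proteome))) {
    prods <- normalizePeptide(
      oracleDigest(proteome$sequence[i], maxMissed, minLen, maxLen),
      collapseIL)
    if (pep %in% prods)
      hits[[length(hits) + 1L]] <- proteome[i, c("accession", "species")]
  }
  if (!length(hits))
    return(data.frame(accession = character(0), species = character(0)))
  do.call(rbind, hits)
}

# per-rank specificity from a set of source species, straight off the
# taxonomy table
oracleSpecificity <- function(speciesSet, taxonomy) {
  vapply(taxRanks(), function(r) {
    v <- taxonomy[[r]][match(speciesSet, taxonomy$species_id)]
    if (length(v) && !anyNA(v) && length(unique(v)) == 1L) v[1]
    else NA_character_
  }, character(1))
}

# a fully resolved lineage table where grouping at higher ranks is
# controlled through explicit genus/family assignments
makeTaxonomy <- function(species, genus = NULL, family = NULL,
                         phylum = NULL) {
  if (is.null(genus)) genus <- paste0("g_", species)
  if (is.null(family)) family <- paste0("f_", genus)
  if (is.null(phylum)) phylum <- rep("p_main", length(species))
  data.frame(species_id = species,
             superkingdom = "Bacteria",
             phylum = phylum,
             class = paste0("c_", phylum),
             order = paste0("o_", family),
             family = family,
             genus = genus,
             species = species)
}

# random protein sequence over the full 20-residue alphabet
randomSequence <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# small random proteome over a few species (full alphabet, so shared
# peptides arise only by chance)
randomProteome <- function(nProteins = 20, species = c("S1", "S2", "S3"),
                           len = 60) {
  data.frame(
    accession = sprintf("prot%03d", seq_len(nProteins)),
    species = rep_len(species, nProteins),
    sequence = vapply(seq_len(nProteins), function(i)
      randomSequence(len), character(1)))
}
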