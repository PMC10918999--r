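#' Specify a synthetic microbial community
#'
#' Describes the community a simulation will emulate: member species with
#' lineages and biomass fractions, per-species proteome size, the rate and
#' scope of cross-taxon peptide sharing, and the intensity model. The
#' default is a three-component design mirroring a spiked reference
#' sample: two bacteria added at 2% and 1% on top of a 97% background —
#' the mixing ratio 2:1:97.
#'
#' Sharing is realized structurally: a fraction `sharedPeptideRate` of
#' each species' peptides is drawn from a pool common to its sharing-scope
#' group (same genus, same family, or the whole community) and the shared
#' peptides are literally present in every group member's proteins, so the
#' peptide index discovers the sharing naturally.
#'
#' @param species Character vector of species ids.
#' @param fractions Biomass fractions, percent; must sum to 100.
#' @param taxonomy Optional taxonomy table (`species_id` + seven ranks);
#'   by default every species gets its own genus/family/... under one
#'   bacterial superkingdom, so all peptides are species-informative when
#'   sharing is off.
#' @param proteinsPerSpecies Proteins simulated per species (default 20).
#' @param peptidesPerProtein Tryptic peptides per protein (default 15).
#' @param sharedPeptideRate Fraction of each species' peptides shared
#'   within the sharing scope, in `[0, 1]` (default 0).
#' @param sharingScope `"within-genus"`, `"within-family"` or `"global"`.
#' @param intensityMeanlog,intensitySdlog Log-normal precursor intensity
#'   model (defaults 14 and 1, a typical orders-of-magnitude spread).
#' @param missedCleavageProbs Probabilities of emitting a peptide with
#'   0, 1, 2 missed cleavages (defaults 0.902/0.095/0.003, the proportions
#'   a clean tryptic digest shows).
#' @return A validated `communitySpec` list.
#' @export
communitySpec <- function(species = c("SpikeA", "SpikeB", "Background"),
                          fractions = c(2, 1, 97),
                          taxonomy = NULL,
                          proteinsPerSpecies = 20L,
                          peptidesPerProtein = 15L,
                          sharedPeptideRate = 0,
                          sharingScope = c("within-genus",
                                           "within-family", "global"),
                          intensityMeanlog = 14,
                          intensitySdlog = 1,
                          missedCleavageProbs = c(0.902, 0.095, 0.003)) {
  sharingScope <- match.arg(sharingScope)
  stopifnot(length(species) == length(fractions),
            !anyDuplicated(species),
            all(fractions >= 0),
            sharedPeptideRate >= 0, sharedPeptideRate <= 1,
            proteinsPerSpecies >= 1, peptidesPerProtein >= 1,
            length(missedCleavageProbs) == 3,
            all(missedCleavageProbs >= 0))
  if (abs(sum(fractions) - 100) > 1e-6)
    stop("biomass fractions must sum to 100", call. = FALSE)
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(
      species_id = species,
      superkingdom = "Bacteria",
      phylum = paste0("p__", species),
      class = paste0("c__", species),
      order = paste0("o__", species),
      family = paste0("f__", species),
      genus = paste0("g__", species),
      species = species)
  }
  taxonomy <- validateTaxonomy(taxonomy)
  if (!all(species %in% taxonomy$species_id))
    stop("species missing from taxonomy", call. = FALSE)
  structure(list(species = species, fractions = fractions,
                 taxonomy = taxonomy,
                 proteinsPerSpecies = as.integer(proteinsPerSpecies),
                 peptidesPerProtein = as.integer(peptidesPerProtein),
                 sharedPeptideRate = sharedPeptideRate,
                 sharingScope = sharingScope,
                 intensityMeanlog = intensityMeanlog,
                 intensitySdlog = intensitySdlog,
                 missedCleavageProbs = missedCleavageProbs /
                   sum(missedCleavageProbs)),
            class = "communitySpec")
}

## residues for peptide bodies: no K/R (tryptic interior), no P (would
## interact with the proline rule), no I (so I/L collapse cannot merge two
## generated peptides), no X. Terminal K/R makes basic-residue frequency
## realistic for tryptic products.
.BODY_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "L", "M", "N",
                    "Q", "S", "T", "V", "W", "Y")

## draw n distinct tryptic peptides, lengths uniform in [7, 30]
.randomPeptides <- function(n, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- (n - length(out)) * 2L + 10L
    lens <- sample(7:30, need, replace = TRUE)
    body <- vapply(lens - 1L, function(l)
      paste(sample(.BODY_ALPHABET, l, replace = TRUE), collapse = ""),
      character(1))
    pep <- paste0(body, sample(c("K", "R"), need, replace = TRUE))
    pep <- setdiff(unique(pep), c(out, avoid))
    out <- c(out, pep)
  }
  out[seq_len(n)]
}

#' Generate a synthetic community with recorded ground truth
#'
#' Builds reference proteomes and a taxonomy realizing a [communitySpec()]:
#' every protein is a concatenation of in-bounds tryptic peptides (so
#' digestion recovers them exactly), shared peptides are copied into every
#' member of their sharing group, and the truth object records the per-
#' peptide source-taxon sets and per-protein peptide layout used later by
#' the PSM simulator. Deterministic given `seed`.
#'
#' @param spec A [communitySpec()].
#' @param seed Integer seed; all randomness of the generation flows from
#'   it.
#' @return list with `proteome` (data.frame accession/species/sequence),
#'   `taxonomy`, and `truth` (list: `fractions`, `peptidesOf` per-species
#'   peptide sets, `proteinPeptides` per-accession ordered peptide lists,
#'   `sourcesOf` data.frame peptide/species, `spec`).
#' @export
generateCommunity <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "communitySpec"))
  set.seed(.deriveSeed(seed, 1L))
  nSp <- length(spec$species)
  perSpecies <- spec$proteinsPerSpecies * spec$peptidesPerProtein
  nShared <- round(spec$sharedPeptideRate * perSpecies)

  scopeRank <- switch(spec$sharingScope,
                      "within-genus" = "genus",
                      "within-family" = "family",
                      "global" = NULL)
  groupOf <- if (is.null(scopeRank)) rep("all", nSp) else
    spec$taxonomy[[scopeRank]][match(spec$species,
                                     spec$taxonomy$species_id)]

  ## shared pools per scope group, then private complements per species
  sharedPool <- list()
  used <- character(0)
  for (g in unique(groupOf)) {
    sharedPool[[g]] <- .randomPeptides(nShared, avoid = used)
    used <- c(used, sharedPool[[g]])
  }
  peptidesOf <- list()
  for (i in seq_len(nSp)) {
    priv <- .randomPeptides(perSpecies - nShared, avoid = used)
    used <- c(used, priv)
    peptidesOf[[spec$species[i]]] <- c(sharedPool[[groupOf[i]]], priv)
  }

  ## assemble proteins: shuffle each species' peptides into equal blocks
  accs <- character(0); orgs <- character(0); seqs <- character(0)
  proteinPeptides <- list()
  for (i in seq_len(nSp)) {
    sp <- spec$species[i]
    peps <- sample(peptidesOf[[sp]])
    idx <- matrix(seq_len(perSpecies), nrow = spec$peptidesPerProtein)
    for (p in seq_len(spec$proteinsPerSpecies)) {
      acc <- sprintf("%s_P%04d", sp, p)
      ordered <- peps[idx[, p]]
      proteinPeptides[[acc]] <- ordered
      accs <- c(accs, acc)
      orgs <- c(orgs, sp)
      seqs <- c(seqs, paste(ordered, collapse = ""))
    }
  }
  proteome <- data.frame(accession = accs, species = orgs,
                         sequence = seqs, row.names = NULL)
  sources <- data.frame(
    peptide = normalizePeptide(unlist(peptidesOf, use.names = FALSE)),
    species = rep(names(peptidesOf), lengths(peptidesOf)),
    row.names = NULL)
  truth <- list(fractions = stats::setNames(spec$fractions, spec$species),
                peptidesOf = peptidesOf,
                proteinPeptides = proteinPeptides,
                sourcesOf = unique(sources),
                spec = spec)
  list(proteome = proteome, taxonomy = spec$taxonomy, truth = truth)
}

#' Simulate identified spectra (and optionally DIA quantification)
#'
#' Each spectrum samples a source taxon with probability proportional to
#' its biomass fraction, then a protein of that taxon and a tryptic
#' peptide position uniformly; with the spec's missed-cleavage
#' probabilities the emitted peptide spans 1-3 adjacent tryptic products.
#' Precursor intensities are log-normal, quality scores uniform. In DIA
#' mode, spectrum intensities are additionally aggregated per source
#' protein into a protein-group quantification table (one group per
#' protein). Deterministic given `seed`.
#'
#' @param truth The `truth` element of [generateCommunity()].
#' @param n Number of spectra (>= 0).
#' @param seed Integer seed.
#' @param run Run id recorded in the table (default `"run1"`).
#' @param dia Also build the protein-group quant table (default `FALSE`).
#' @return list with `psms` (data.frame run, spectrum_id, peptide, score,
#'   intensity), `sourceTaxon` (true species per spectrum) and, with
#'   `dia = TRUE`, `quant` (protein_group, member_accessions, intensity).
#' @export
simulatePsms <- function(truth, n, seed = 1L, run = "run1", dia = FALSE) {
  stopifnot(n >= 0)
  spec <- truth$spec
  set.seed(.deriveSeed(seed, 2L))
  if (n == 0) {
    psms <- data.frame(run = character(0), spectrum_id = character(0),
                       peptide = character(0), score = numeric(0),
                       intensity = numeric(0))
    return(list(psms = psms, sourceTaxon = character(0)))
  }
  species <- names(truth$fractions)
  k <- spec$peptidesPerProtein
  spIdx <- sample.int(length(species), n, replace = TRUE,
                      prob = truth$fractions)
  prIdx <- sample.int(spec$proteinsPerSpecies, n, replace = TRUE)
  acc <- sprintf("%s_P%04d", species[spIdx], prIdx)
  m <- sample(0:2, n, replace = TRUE, prob = spec$missedCleavageProbs)
  start <- sample.int(k, n, replace = TRUE)
  m <- pmin(m, k - start)           # clamp at the protein C-terminus

  ## per-protein peptide layout as a matrix for vectorized lookup
  accAll <- names(truth$proteinPeptides)
  pepMat <- matrix(unlist(truth$proteinPeptides[accAll]), nrow = k)
  col <- match(acc, accAll)
  pep <- pepMat[cbind(start, col)]
  w1 <- m >= 1L
  pep[w1] <- paste0(pep[w1], pepMat[cbind(start[w1] + 1L, col[w1])])
  w2 <- m >= 2L
  pep[w2] <- paste0(pep[w2], pepMat[cbind(start[w2] + 2L, col[w2])])

  psms <- data.frame(run = run,
                     spectrum_id = sprintf("scan%07d", seq_len(n)),
                     peptide = pep,
                     score = stats::runif(n),
                     intensity = stats::rlnorm(n, spec$intensityMeanlog,
                                               spec$intensitySdlog),
                     row.names = NULL)
  out <- list(psms = psms, sourceTaxon = species[spIdx])
  if (dia) {
    dt <- data.table::data.table(accession = acc,
                                 intensity = psms$intensity)
    q <- dt[, list(intensity = sum(intensity)), by = "accession"]
    data.table::setorderv(q, "accession")
    out$quant <- data.frame(protein_group = q$accession,
                            member_accessions = q$accession,
                            intensity = q$intensity, row.names = NULL)
  }
  out
}

#' Generate a KO/pathway fixture with known coverage
#'
#' Builds `nPathways` pathways of `kosPerPathway` distinct KO terms each,
#' spread over five functional categories, and one protein group per
#' (pathway, KO); every protein carries its KO with probability
#' `annotationRate` and is otherwise unannotated. The truth table records
#' the realized per-pathway coverage. Deterministic given `seed`.
#'
#' @param nPathways,kosPerPathway Fixture dimensions (positive).
#' @param annotationRate Probability a protein is KO-annotated, `[0, 1]`.
#' @param taxa Taxon ids cycled over the proteins (default two).
#' @param seed Integer seed.
#' @return list with `annotations`, `pathways` (long format) and `truth`
#'   (data.frame pathway, expectedCoverage).
#' @export
generateKoFixture <- function(nPathways = 20L, kosPerPathway = 10L,
                              annotationRate = 0.7,
                              taxa = c("taxonA", "taxonB"), seed = 1L) {
  stopifnot(nPathways >= 1, kosPerPathway >= 1,
            annotationRate >= 0, annotationRate <= 1)
  set.seed(.deriveSeed(seed, 3L))
  categories <- c("metabolism", "genetic information processing",
                  "environmental information processing",
                  "cellular processes", "human diseases")
  pwIds <- sprintf("map%05d", seq_len(nPathways))
  kos <- sprintf("K%05d", seq_len(nPathways * kosPerPathway))
  pathways <- data.frame(
    pathway = rep(pwIds, each = kosPerPathway),
    category = rep(categories[(seq_len(nPathways) - 1L) %%
                                length(categories) + 1L],
                   each = kosPerPathway),
    KO = kos, row.names = NULL)
  annotated <- stats::runif(nrow(pathways)) < annotationRate
  annotations <- data.frame(
    protein_group = sprintf("PG%05d", seq_len(nrow(pathways))),
    KO = ifelse(annotated, pathways$KO, NA_character_),
    taxon = rep_len(taxa, nrow(pathways)),
    abundance = stats::rlnorm(nrow(pathways), 10, 1),
    row.names = NULL)
  truthDt <- data.table::data.table(pathway = pathways$pathway,
                                    annotated = annotated)
  truth <- truthDt[, list(expectedCoverage = 100 * mean(annotated)),
                   by = "pathway"]
  list(annotations = annotations, pathways = pathways,
       truth = as.data.frame(truth))
}

#' Write all simulated tables of a community to disk
#'
#' Emits exactly the file formats the readers consume: proteome FASTA,
#' taxonomy TSV, PSM TSV and (DIA) quant TSV.
#'
#' @param community Output of [generateCommunity()].
#' @param sim Output of [simulatePsms()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
writeCommunityTables <- function(community, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             psms = file.path(dir, "psms.tsv"))
  writeProteomeFasta(community$proteome, paths[["proteome"]])
  .writeTsv(community$taxonomy, paths[["taxonomy"]])
  .writeTsv(sim$psms, paths[["psms"]])
  if (!is.null(sim$quant)) {
    paths[["quant"]] <- file.path(dir, "quant.tsv")
    .writeTsv(sim$quant, paths[["quant"]])
  }
  paths
}
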