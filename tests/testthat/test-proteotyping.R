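simpleParams <- DigestionParams(missedCleavages = 0, minLength = 3,
                                maxLength = 30)

makePsms <- function(peptides, run = "run1", scores = NULL) {
  data.frame(run = rep_len(run, length(peptides)),
             spectrum_id = sprintf("sc%04d", seq_along(peptides)),
             peptide = peptides,
             score = if (is.null(scores)) seq_along(peptides) else scores)
}

test_that("top-spectrum selection keeps the n best with deterministic ties", {
  psms <- makePsms(c("AAAK", "CCCK", "DDDK"), scores = c(5, 1, 3))
  top <- selectTopSpectra(psms, 2)
  expect_equal(top$score, c(5, 3))
  expect_equal(nrow(selectTopSpectra(psms, 0)), 0)
  expect_equal(nrow(selectTopSpectra(psms, 10)), 3)

  tied <- makePsms(rep("AAAK", 4), scores = rep(1, 4))
  tied$spectrum_id <- c("b", "a", "d", "c")
  expect_equal(selectTopSpectra(tied, 2)$spectrum_id, c("a", "b"))

  noScore <- makePsms("AAAK", scores = NA_real_)
  expect_error(selectTopSpectra(noScore, 1), "missing quality score")
})

test_that("top-spectrum selection matches a full-sort oracle", {
  set.seed(11)
  psms <- makePsms(rep("AAAK", 1000), scores = stats::runif(1000))
  got <- selectTopSpectra(psms, 100)
  want <- psms[order(-psms$score), ][1:100, ]
  expect_setequal(got$spectrum_id, want$spectrum_id)
})

test_that("TSMs propagate up ranks and spePEP counts distinct peptides", {
  tx <- makeTaxonomy(c("S1", "S2"), genus = c("gA", "gA"))
  pr <- data.frame(
    accession = c("p1", "p2"),
    species = c("S1", "S2"),
    sequence = c("AAAGGGKTTTGGGR", "AAAGGGKMMMGGGR"))
  idx <- buildPeptideIndex(pr, tx, simpleParams)

  # 10 spectra over 2 distinct species-specific peptides of S1
  res <- assignTsms(makePsms(rep(c("TTTGGGR", "TTTGGGR", "AAAGGGK"),
                                 length.out = 9)), idx)
  taxa <- taxonCounts(res$profile)
  spTab <- taxa[taxa$rank == "species", ]
  expect_equal(spTab$taxon, "S1")
  expect_equal(spTab$tsm, 6)            # AAAGGGK is shared -> genus only
  expect_equal(spTab$spePEP, 1)
  gnTab <- taxa[taxa$rank == "genus", ]
  expect_equal(gnTab$tsm, 9)            # all spectra genus-specific to gA
  expect_equal(gnTab$spePEP, 2)
  expect_equal(unname(rankTotals(res$profile)["species"]), 6)
  expect_equal(unname(rankTotals(res$profile)["genus"]), 9)
})

test_that("assignment counts equal a per-spectrum specificity recount", {
  set.seed(55)
  spec <- communitySpec(species = c("A1", "A2", "B1"),
                        fractions = c(30, 30, 40),
                        taxonomy = makeTaxonomy(c("A1", "A2", "B1"),
                                                genus = c("gA", "gA", "gB")),
                        proteinsPerSpecies = 4, peptidesPerProtein = 6,
                        sharedPeptideRate = 0.3)
  comm <- generateCommunity(spec, seed = 9)
  idx <- buildPeptideIndex(comm$proteome, comm$taxonomy)
  sim <- simulatePsms(comm$truth, 300, seed = 9)
  res <- assignTsms(sim$psms, idx)

  # recount: per spectrum, attribute via querySpecificity
  counts <- new.env()
  unatt <- 0
  for (i in seq_len(nrow(sim$psms))) {
    q <- querySpecificity(sim$psms$peptide[i], idx)
    if (all(q$status != "specific")) { unatt <- unatt + 1; next }
    for (j in which(q$status == "specific")) {
      key <- paste(q$rank[j], q$taxon[j])
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  taxa <- taxonCounts(res$profile)
  for (k in ls(counts)) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    expect_equal(taxa$tsm[taxa$rank == parts[1] & taxa$taxon == parts[2]],
                 counts[[k]], info = k)
  }
  expect_equal(res$profile@nUnattributed, unatt)
})

test_that("rank totals never increase from superkingdom to species", {
  set.seed(77)
  for (f in c(0, 0.4, 1)) {
    spec <- communitySpec(species = c("A1", "A2"), fractions = c(50, 50),
                          taxonomy = makeTaxonomy(c("A1", "A2"),
                                                  genus = c("gA", "gA")),
                          proteinsPerSpecies = 4, peptidesPerProtein = 5,
                          sharedPeptideRate = f)
    comm <- generateCommunity(spec, seed = 3)
    idx <- buildPeptideIndex(comm$proteome, comm$taxonomy)
    sim <- simulatePsms(comm$truth, 500, seed = 3)
    totals <- rankTotals(assignTsms(sim$psms, idx)$profile)
    expect_true(all(diff(totals) <= 0))
  }
})

test_that("rank-signal retention reflects the share of shared peptides", {
  tx <- makeTaxonomy(c("S1", "S2"), genus = c("gA", "gA"))
  pr <- data.frame(
    accession = c("p1", "p2"),
    species = c("S1", "S2"),
    sequence = c("AAAGGGKTTTGGGR", "AAAGGGKMMMGGGR"))
  idx <- buildPeptideIndex(pr, tx, simpleParams)

  # all species-specific -> 100% everywhere
  allSpec <- assignTsms(makePsms(rep("TTTGGGR", 4)), idx)
  expect_true(all(rankSignalRetention(allSpec$profile)$retention == 100))

  # half the spectra only genus-specific -> species retention 50%
  half <- assignTsms(makePsms(c("TTTGGGR", "AAAGGGK",
                                "MMMGGGR", "AAAGGGK")), idx)
  ret <- rankSignalRetention(half$profile)
  expect_equal(ret$retention[ret$rank == "species"], 50)
  expect_equal(ret$retention[ret$rank == "genus"], 100)

  empty <- assignTsms(makePsms("ZZZZZZZZK"[0]), idx)
  expect_error(rankSignalRetention(empty$profile), "no attributable")
})

test_that("species retention tracks 100*(1 - sharedPeptideRate) on simulations", {
  set.seed(99)
  f <- 0.3
  spec <- communitySpec(species = c("A1", "A2"), fractions = c(50, 50),
                        taxonomy = makeTaxonomy(c("A1", "A2"),
                                                genus = c("gA", "gA")),
                        proteinsPerSpecies = 10, peptidesPerProtein = 10,
                        sharedPeptideRate = f,
                        missedCleavageProbs = c(1, 0, 0))
  comm <- generateCommunity(spec, seed = 12)
  idx <- buildPeptideIndex(comm$proteome, comm$taxonomy)
  sim <- simulatePsms(comm$truth, 20000, seed = 12)
  ret <- rankSignalRetention(assignTsms(sim$psms, idx)$profile)
  expect_equal(ret$retention[ret$rank == "species"], 100 * (1 - f),
               tolerance = 0.05)
  expect_equal(ret$retention[ret$rank == "genus"], 100)
})

test_that("per-phylum retention partitions the overall profile", {
  tx <- makeTaxonomy(c("S1", "S2"), genus = c("gA", "gB"),
                     phylum = c("pX", "pY"))
  pr <- data.frame(accession = c("p1", "p2"), species = c("S1", "S2"),
                   sequence = c("AAAGGGKTTTGGGR", "WWWGGGKMMMGGGR"))
  idx <- buildPeptideIndex(pr, tx, simpleParams)
  res <- assignTsms(makePsms(c("AAAGGGK", "TTTGGGR", "WWWGGGK")), idx)
  ret <- rankSignalRetention(res$profile, perTaxonAt = "phylum",
                             taxonomy = tx)
  px <- ret[!is.na(ret$taxon) & ret$taxon == "pX", ]
  expect_true(all(px$retention == 100))  # fully species-resolved phylum
  expect_equal(nrow(ret[is.na(ret$taxon), ]), 7)
})

test_that("merging runs sums TSMs and keeps the best-run spePEP", {
  r1 <- data.frame(taxon = c("S1", "S2"), tsm = c(10L, 5L),
                   spePEP = c(4L, 2L), accepted = c(TRUE, TRUE))
  r2 <- data.frame(taxon = c("S1", "S3"), tsm = c(6L, 7L),
                   spePEP = c(9L, 3L), accepted = c(TRUE, TRUE))
  m <- mergeProteotypingRuns(list(r1, r2))
  expect_setequal(m$taxon, c("S1", "S2", "S3"))
  expect_equal(m$tsm[m$taxon == "S1"], 16)
  expect_equal(m$spePEP[m$taxon == "S1"], 9)   # best run retained
  expect_equal(m$nRuns[m$taxon == "S1"], 2)

  # identical runs double TSMs, spePEP unchanged
  mm <- mergeProteotypingRuns(list(r1, r1))
  expect_equal(mm$tsm[mm$taxon == "S1"], 20)
  expect_equal(mm$spePEP[mm$taxon == "S1"], 4)

  # disjoint runs union; rejected taxa are dropped
  r3 <- data.frame(taxon = "S9", tsm = 3L, spePEP = 1L, accepted = FALSE)
  expect_setequal(mergeProteotypingRuns(list(r1, r3))$taxon,
                  c("S1", "S2"))

  tx1 <- makeTaxonomy("S1")
  tx2 <- makeTaxonomy("S2")
  expect_error(mergeProteotypingRuns(list(r1, r2), list(tx1, tx2)),
               "inconsistent taxonomy")
})
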