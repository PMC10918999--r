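annTable <- function(ko, taxon = "T1", abundance = 1) {
  data.frame(protein_group = sprintf("PG%03d", seq_along(ko)),
             KO = ko, taxon = taxon, abundance = abundance)
}

pwTable <- function(...) {
  sets <- list(...)
  data.frame(pathway = rep(names(sets), lengths(sets)),
             category = "metabolism",
             KO = unlist(sets, use.names = FALSE))
}

test_that("coverage is the observed share of a pathway's KO set", {
  pws <- pwTable(pw1 = sprintf("K%05d", 1:10))
  ann <- annTable(sprintf("K%05d", 1:4))
  res <- computePathwayCoverage(ann, pws)
  expect_equal(res$coverage$coverage, 40)
  expect_equal(res$coverage$observed, 4)
  expect_equal(res$coverage$total, 10)

  allObs <- computePathwayCoverage(annTable(sprintf("K%05d", 1:10)), pws)
  expect_equal(allObs$coverage$coverage, 100)
  noneObs <- computePathwayCoverage(annTable(NA_character_), pws)
  expect_equal(noneObs$coverage$coverage, 0)
  expect_equal(noneObs$nUnannotated, 1)
})

test_that("coverage equals a set-intersection oracle on random fixtures", {
  set.seed(29)
  for (i in 1:10) {
    koUniverse <- sprintf("K%05d", 1:200)
    sets <- lapply(1:30, function(j)
      sample(koUniverse, sample(3:20, 1)))
    names(sets) <- sprintf("pw%02d", 1:30)
    pws <- do.call(pwTable, sets)
    obs <- sample(koUniverse, 60)
    res <- computePathwayCoverage(annTable(obs), pws)$coverage
    for (j in seq_along(sets)) {
      want <- 100 * length(intersect(unique(sets[[j]]), obs)) /
        length(unique(sets[[j]]))
      expect_equal(res$coverage[res$pathway == names(sets)[j]], want)
    }
    expect_true(all(res$coverage >= 0 & res$coverage <= 100))
  }
})

test_that("observed KOs outside every pathway are reported as unmapped", {
  pws <- pwTable(pw1 = c("K00001", "K00002"))
  res <- computePathwayCoverage(annTable(c("K00001", "K99999")), pws)
  expect_equal(res$unmappedKOs, "K99999")
})

test_that("pathway weights sum protein abundances, multi-counting shared KOs", {
  pws <- pwTable(pw1 = "K00001")
  ann <- annTable(c("K00001", "K00001"), abundance = c(1, 3))
  w <- pathwayAbundance(ann, pws)
  expect_equal(w$weight, 4)

  # one KO in two pathways: full abundance to each
  pws2 <- pwTable(pw1 = "K00001", pw2 = "K00001")
  w2 <- pathwayAbundance(annTable("K00001", abundance = 5), pws2)
  expect_equal(w2$weight, c(5, 5))

  # uniqueness weighting splits the contribution instead
  w3 <- pathwayAbundance(annTable("K00001", abundance = 5), pws2,
                         uniquenessWeighted = TRUE)
  expect_equal(w3$weight, c(2.5, 2.5))
})

test_that("grouped weights equal a brute-force join-and-sum recount", {
  set.seed(37)
  kos <- sprintf("K%05d", 1:50)
  sets <- lapply(1:12, function(j) sample(kos, sample(2:10, 1)))
  names(sets) <- sprintf("pw%02d", 1:12)
  pws <- do.call(pwTable, sets)
  ann <- data.frame(protein_group = sprintf("PG%03d", 1:80),
                    KO = sample(c(kos, NA), 80, replace = TRUE),
                    taxon = sample(c("tA", "tB"), 80, replace = TRUE),
                    abundance = stats::runif(80))
  w <- pathwayAbundance(ann, pws)
  for (r in sample(nrow(w), min(25, nrow(w)))) {
    want <- sum(ann$abundance[!is.na(ann$KO) &
                                ann$taxon == w$group[r] &
                                ann$KO %in% sets[[w$pathway[r]]]])
    expect_equal(w$weight[r], want)
  }
  # host/microbiota grouping conserves totals for single-pathway KOs
  grouping <- c(tA = "host", tB = "microbiota")
  wg <- pathwayAbundance(ann, pws, grouping = grouping)
  pooled <- pathwayAbundance(transform(ann, taxon = "all"), pws)
  byPw <- tapply(wg$weight, wg$pathway, sum)
  expect_equal(as.numeric(byPw[pooled$pathway]), pooled$weight)
})

test_that("the taxon-function matrix is consistent with pathway weights", {
  tx <- makeTaxonomy(c("S1", "S2", "S3"), genus = c("gA", "gA", "gB"))
  pws <- data.frame(pathway = c("pw1", "pw2"),
                    category = c("metabolism", "cellular processes"),
                    KO = c("K00001", "K00002"))
  ann <- data.frame(protein_group = sprintf("PG%d", 1:4),
                    KO = c("K00001", "K00001", "K00002", "K00002"),
                    taxon = c("S1", "S2", "S3", "Smystery"),
                    abundance = c(1, 2, 4, 8))
  m <- taxonFunctionMatrix(ann, pws, tx)
  expect_equal(m["gA", "metabolism"], 3)
  expect_equal(m["gB", "cellular processes"], 4)
  expect_equal(m["unclassified", "cellular processes"], 8)
  # block structure: disjoint categories stay disjoint
  expect_equal(m["gA", "cellular processes"], 0)
  # marginals match the per-taxon pathway weights
  w <- pathwayAbundance(ann, pws)
  expect_equal(sum(m), sum(w$weight))
})

test_that("two-taxon KO comparison partitions the observed universe", {
  ann <- data.frame(protein_group = sprintf("PG%d", 1:6),
                    KO = c("K1", "K2", "K3", "K2", "K3", "K4"),
                    taxon = rep(c("A", "B"), each = 3),
                    abundance = 1)
  cmp <- compareTaxaPathways(ann, "A", "B")
  expect_equal(cmp$shared, c("K2", "K3"))
  expect_equal(cmp$onlyA, "K1")
  expect_equal(cmp$onlyB, "K4")
  expect_length(intersect(cmp$shared, cmp$onlyA), 0)
  expect_setequal(c(cmp$shared, cmp$onlyA, cmp$onlyB),
                  c("K1", "K2", "K3", "K4"))

  same <- compareTaxaPathways(ann[ann$taxon == "A", ], "A", "A")
  expect_length(same$onlyA, 0)

  pws <- pwTable(shared = c("K2", "K3"), mixedPw = c("K1", "K4"),
                 aOnly = "K1", untouched = "K9")
  lab <- compareTaxaPathways(ann, "A", "B", pws)$pathwayLabels
  expect_equal(lab$label[lab$pathway == "shared"], "shared")
  expect_equal(lab$label[lab$pathway == "mixedPw"], "mixed")
  expect_equal(lab$label[lab$pathway == "aOnly"], "A_only")
  expect_false("untouched" %in% lab$pathway)
})

test_that("set comparisons match a set-algebra oracle on random inputs", {
  set.seed(41)
  kos <- sprintf("K%03d", 1:60)
  for (i in 1:100) {
    a <- sample(kos, sample(0:25, 1))
    b <- sample(kos, sample(0:25, 1))
    ann <- data.frame(
      protein_group = sprintf("PG%03d", seq_len(length(a) + length(b))),
      KO = c(a, b),
      taxon = rep(c("A", "B"), c(length(a), length(b))),
      abundance = 1)
    cmp <- compareTaxaPathways(ann, "A", "B")
    expect_setequal(cmp$shared, intersect(a, b))
    expect_setequal(cmp$onlyA, setdiff(a, b))
    expect_setequal(cmp$onlyB, setdiff(b, a))
  }
})

test_that("annotation rates count annotated proteins per group", {
  ann <- data.frame(protein_group = sprintf("PG%d", 1:5),
                    KO = c("K1", "K2", "K3", "K4", NA),
                    taxon = "T1", abundance = 1)
  r <- annotationRate(ann)
  expect_equal(r$rate, 80)
  expect_equal(r$annotated, 4)

  grouping <- c(T1 = "microbiota", T2 = "host")
  r2 <- annotationRate(ann, grouping)
  expect_equal(r2$group, "microbiota")
  # recount oracle on a random fixture
  set.seed(43)
  big <- data.frame(protein_group = sprintf("PG%03d", 1:100),
                    KO = sample(c("K1", NA), 100, replace = TRUE),
                    taxon = sample(c("T1", "T2"), 100, replace = TRUE),
                    abundance = 1)
  r3 <- annotationRate(big)
  for (g in r3$group)
    expect_equal(r3$rate[r3$group == g],
                 100 * mean(!is.na(big$KO[big$taxon == g])))
})
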