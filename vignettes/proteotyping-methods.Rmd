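---
title: "Methods: taxonomic proteotyping, biomass estimation and functional profiling"
author: "proteotypeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomic proteotyping, biomass estimation and functional profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteotypeR)
```

# The model

proteotypeR implements the informatics of a two-stage metaproteomics
strategy: a survey acquisition is proteotyped to discover which organisms
a sample contains and at what protein biomass, a compact sample-specific
database is assembled from the most abundant of them, and the deep
acquisition is then quantified and functionally profiled against that
database. The package consumes the outputs of upstream search engines
(peptide-spectrum matches with quality scores, or protein-group
intensity tables) and never re-implements spectrum identification
itself.

## Peptide-level taxonomic specificity

The elementary object is the peptide-to-taxon index: every reference
protein is digested in silico with trypsin and each normalized peptide
is mapped to the set of (protein, organism) pairs containing it.
A peptide is *specific* at taxonomic rank $r$ when all of its source
organisms carry the same taxon at $r$; otherwise it is *not specific* at
$r$. Because lineages grow top-down (a taxon present at some rank is
present at every higher rank), specificity is monotone: specific at $r$
implies specific at every rank above $r$. This is the property the
`RankSignalProfile` validity check and the property tests rely on.

Each identified spectrum whose peptide is specific at rank $r$
contributes one Taxon-to-Spectrum Match (TSM) at $r$ and at every higher
rank; the number of *distinct* specific peptide sequences per taxon
(spePEP) is tracked separately, as spectra and sequences carry different
evidential weight: many spectra of one peptide could be one abundant
protein, while many distinct peptides are hard to explain without the
organism being present.

Assumptions worth stating: one peptide per spectrum (chimeric spectra
are deconvolved upstream or not at all); peptide identifications are
correct at the FDR controlled upstream; and the reference proteomes are
representative enough that specificity is meaningful. The last
assumption is exactly what rank-signal retention measures — the TSM
total at each rank as a percentage of the superkingdom total. Retention
erodes where reference coverage is poor, typically fastest from genus to
species.

## The two-round cascade

Searching a generic index resolves genera well but species poorly,
because close relatives share most peptides. The cascade therefore
accepts genera first (round 1), restricts the index to the accepted
genera's descendant species, and re-attributes the same spectra against
the restricted index (round 2). Restriction shrinks every peptide's
source set, so peptides shared only with rejected organisms regain
specificity — this is why round 2 can resolve species that round 1
could not. `subsetIndex()` implements the restriction as an exact
equivalent of rebuilding the index from the restricted proteomes (a
tested invariant).

Acceptance uses two count thresholds, spePEP ≥ 3 and TSM ≥ 5 per taxon
by default. Both are configurable; the defaults are deliberately mild —
they exclude taxa "detected" by one or two shared-by-chance sequences
while keeping low-biomass organisms backed by a handful of distinct
specific peptides. An optional binomial screen
(`binomialScreen = TRUE`) additionally requires the tail probability of
a taxon's TSM count under a uniform-assignment null (every attributed
spectrum equally likely to hit any taxon at that rank) to fall below
`alpha` (0.05 by default). The screen is off by default because the
uniform null is crude for strongly skewed communities; it exists for
users who want a significance-style filter rather than raw counts.

Detection carries no priors: any taxon present in the generic index can
be accepted, which is what makes the approach suitable for samples
containing organisms never reported in that sample type.

## Biomass estimation

Per-taxon biomass fractions are computed as

$$\mathrm{fraction}(T) \;=\; 100 \cdot
  \frac{\mathrm{signal}(T)}{\sum_{T'} \mathrm{signal}(T')}$$

with two surrogate signals mirroring the two acquisition modes:

* `tsm_count` — TSMs at the requested rank (spectral counting, DDA);
* `intensity` — summed protein-group precursor intensity (DIA), with
  each group's intensity averaged across runs before summing.

Unattributed signal (unmatched spectra, or protein groups whose members
span several taxa) is excluded from the denominator by default, so
fractions are "of attributed biomass". The alternative — counting the
unattributed signal in the denominator — is exposed via
`includeUnattributed = TRUE` because neither convention is canonical;
the default was chosen so that the estimate of a taxon does not depend
on how much signal a *different*, unidentifiable fraction of the sample
produced. In intensity mode a protein group resolves to a taxon only if
*all* member accessions agree at the requested rank (species by
default, genus optionally); anything else would silently assign shared
proteins to an arbitrary member.

Spectral counting inherits the known bias of shared-peptide parsimony:
adding peptides shared between two taxa can only increase their common
ancestor's signal (a tested invariant), so TSM-based estimates of taxa
with many close relatives in the database tend to run high, while
intensity-based estimates of resolvable groups are less affected. The
package implements the documented baseline and does not attempt to
improve the parsimony rule.

## Database construction

Organisms are selected for the custom database when they pass biomass ≥
0.1% **or** spePEP ≥ 10 (the combination logic is a flag). The
disjunctive default reflects what retention of low-biomass organisms
requires in practice: an organism contributing ~0.1% of biomass but
identified by ten distinct species-specific peptides is a confident
detection and belongs in the database. A `coverageTarget` adds organisms
in descending-biomass order until the requested cumulative coverage is
reached. The emitted FASTA tags every header with
`organism=<species_id>` so that downstream intensity-mode taxon
resolution needs no side table.

## Functional profiling

Pathway coverage is a set computation:
$100 \cdot |O \cap P| / |P|$ for observed KO set $O$ and pathway KO set
$P$. Abundance weighting interprets "averaged protein abundance" as the
mean across analytical replicates per protein, *then* sums within
pathway — the aggregation order is fixed and documented because
sum-then-mean gives different numbers when replicates are incomplete.
KO terms belonging to several pathways contribute their full abundance
to each (standard KEGG practice, kept as the default); a
uniqueness-weighted option divides by the pathway count instead so that
total abundance is conserved.

# The synthetic-data generator

`generateCommunity()` builds proteomes whose proteins are concatenations
of in-bounds tryptic peptides: bodies are drawn from a 16-residue
alphabet excluding K/R (interior cleavage sites), P (would interact
with the proline rule) and I (so I/L collapse cannot merge two designed
peptides), and every peptide ends in K or R. This makes the terminal
basic-residue frequency about 1 in 9–30 positions (~3–11%), comparable
to real tryptic proteomes, and guarantees that a 0-missed-cleavage
digest recovers the designed peptides exactly.

The default community is a three-component design mirroring a spiked
reference sample: two bacteria at 2% and 1% over a 97% background —
the 2:1:97 mixing ratio. Each species carries 20 proteins of 15
peptides; peptide sharing is off. These defaults are the study
conditions of the acceptance checks and are not tuned per test.

Cross-taxon sharing is structural: a fraction $f$ of each species'
peptides comes from a pool common to its sharing-scope group
(same genus, same family, or global) and those peptides are literally
present in every member's proteins, so the index discovers sharing by
digestion rather than by annotation. Under uniform peptide sampling the
expected species-rank retention is $100(1-f)$, which the property tests
check. One subtlety: peptides spanning a missed cleavage concatenate
two designed peptides, and since each species arranges its peptides in
a different random order, junction peptides can stay species-specific
even at $f = 1$ — as in real proteomes, where homologous proteins
differ in peptide context. Tests about "no species-specific peptides at
$f = 1$" therefore index at 0 missed cleavages.

`simulatePsms()` samples, per spectrum, a source taxon proportional to
biomass, a protein and a tryptic position uniformly, and a
missed-cleavage count with probabilities 0.902/0.095/0.003 (the
proportions of a clean digest); intensities are log-normal
(meanlog 14, sdlog 1 — an orders-of-magnitude dynamic range), scores
uniform. All randomness flows from one seed: stage seeds are derived
arithmetically from the master seed (generation, spectrum simulation
and KO fixtures use distinct offsets), so every table is byte-identical
under a repeated seed and no stage perturbs another's stream.

What the generator does **not** emulate: real sequence homology (shared
peptides are exact copies, not evolutionary divergence), chimeric
spectra, identification error (every simulated PSM is correct),
retention-time or m/z structure, protein-abundance heterogeneity within
a species, and incomplete reference databases. Passing tests therefore
demonstrate the correctness of the attribution, estimation and
selection logic under controlled conditions — not robustness to search
engine error or database incompleteness on real data.

# Numerical and degenerate-input choices

* Top-$N$ spectrum selection breaks score ties by (run, spectrum id)
  lexicographic order, so selections are reproducible across platforms.
* Biomass fractions must sum to 100 within $10^{-9}$ (validity check);
  zero attributable signal is an error, never a silent empty profile.
* Peptides containing X are indexed but never taxon-specific; the
  ambiguous residue could make two different sequences compare equal.
* A lineage missing a rank is simply never specific at that rank, which
  attributes such organisms at their nearest present ancestor rank;
  taxonomy validation enforces that lineages grow top-down.
* Empty PSM tables produce empty, well-formed cascade results; empty
  biomass profiles produce an empty selection with a warning.
* The proline-blocked trypsin rule is the default; the unconditional
  K/R rule is available (`prolineRule = FALSE`) for comparison, since
  upstream engines differ on this point.
* I/L equivalence is on by default — the isobaric residues cannot be
  distinguished by the fragmentation that produced the identifications —
  and can be disabled for engines that report resolved residues.

# Problem sizes

The test-suite simulations use communities of 2–6 species with 3–20
proteins each and $10^3$–$10^5$ spectra; oracle-equivalence checks run
100+ randomized fixtures per operation against brute-force
recomputations (substring-enumeration digestion, linear-scan index
lookup, full-sort selection, set-arithmetic coverage). The estimator
recovery checks use the default three-component 2:1:97 community at
$10^5$ spectra, where the binomial sampling error of a 1% component is
about 0.03 percentage points. These sizes were chosen to make sampling
error small relative to the tolerances being asserted.

# Known limitations

* The TSM parsimony baseline overestimates taxa whose peptides are
  widely shared; no correction is attempted.
* Species-rank attribution is only as good as species-rank reference
  coverage; the cascade mitigates but cannot eliminate this.
* Intensity-mode quantification discards mixed-taxon protein groups
  rather than apportioning them; communities of very close relatives
  will leave more signal unattributed.
* The simulator's uniform peptide sampling ignores protein abundance
  structure within a species; estimator variance on real data will be
  larger than the simulated binomial floor.
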