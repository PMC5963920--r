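---
title: "Autozygosity mapping and recessive variant prioritization with autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and recessive variant prioritization with autozyg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The mapping problem

In a consanguineous family segregating a rare recessive disorder, the
causal allele is expected to be *autozygous* in affected children: both
copies descend from a single ancestral allele carried through the
consanguineous loop. On a SNP array this manifests as a long run of
homozygosity (ROH) shared identically by the affected siblings. The
mapping strategy implemented here is the classical one:

1. call ROH per individual, tolerating a small amount of genotyping
   error and missingness;
2. intersect the affected siblings' runs and keep only stretches where
   all affecteds are homozygous **for the same allele** at every
   informative marker (biallelic arrays cannot separate
   identity-by-descent from identity-by-state, so shared allele-identical
   homozygosity plus a genetic-length threshold is the standard
   surrogate);
3. remove territory that unaffected family members share homozygously
   with the affecteds — an unaffected sibling autozygous for the same
   haplotype disproves that stretch as the disease locus;
4. keep candidates of at least a minimum genetic length (default 5 cM),
   the confidence criterion that separates true autozygosity from chance
   stretches of homozygosity;
5. intersect a table of homozygous coding variants from exome sequencing
   of the proband with the candidate loci, discard known polymorphisms
   and variants with population minor allele frequency above 1%, verify
   recessive segregation (affecteds homozygous alternate, parents
   heterozygous carriers, no unaffected homozygous alternate), and rank
   the survivors.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_markers` | 25 | markers | minimum evidence for a run on a dense array |
| `max_het_in_run` | 1 | calls | one genotyping error tolerated per run (call rates ~99%) |
| `max_missing_in_run` | 2 | calls | array dropout tolerance |
| `min_length_bp` | 1 Mb | bp | short homozygous stretches are common in outbred genomes |
| `min_genetic_length_cM` | 5 | cM | confidence criterion for a candidate IBD block |
| `maf_max` | 0.01 | frequency | recessive disease alleles are rare in populations |
| `fallback_rate_cM_per_Mb` | 1 | cM/Mb | genome-wide average when no genetic map is supplied |

All are overridable through `roh_params()`, `mapping_config()`,
`prioritization_config()` and the pipeline's key–value configuration
file. Genetic positions come from piecewise-linear interpolation of a
bp↔cM anchor table when one is supplied; otherwise the constant fallback
rate makes the 5 cM criterion usable without external map files. With a
single anchor on a chromosome, the fallback rate is applied relative to
that anchor; outside the anchor range, extrapolation continues at the
nearest interval's rate. These choices keep interpolation total and
non-decreasing in position.

## Run semantics and numerical choices

A run of homozygosity is defined by hard per-run counts, not by a
sliding-window density: a qualifying window begins and ends on
homozygous calls, contains at most `max_het_in_run` heterozygous and
`max_missing_in_run` missing calls, and meets the marker-count and
physical-span minima. The package reports **all maximal qualifying
windows** (windows not strictly contained in a larger qualifying
window). When the tolerances are nonzero, two maximal windows can
overlap — for example `hom^5 het hom^5 het hom^5` with one tolerated
heterozygote yields two overlapping maximal runs — and both are
reported. This is deliberate: downstream region delineation works on
per-marker *coverage* (the union of runs), so a long autozygous tract
interrupted by two isolated genotyping errors stays fully covered
instead of being split. The definition is simple enough to check
exactly: the test suite compares the scan against brute-force
enumeration of maximal windows on thousands of random genotype strings.

Other numerical conventions:

* coordinates are 1-based inclusive; regions are closed intervals and a
  region's span is `end − start + 1`;
* segment and region boundaries always snap to observed homozygous
  (for regions: allele-identical) markers — no extension into
  inter-marker gaps, a conservative convention the candidate regions
  inherit;
* a region's genetic length is the difference of its end markers'
  interpolated cM positions, not a sum over marker intervals;
* regions of exactly the minimum genetic length are retained (≥);
* variant ranking is deterministic: segregation-consistent first
  (unknown segregation sorts between true and false), then variants
  never seen in databases (`known_polymorphism = FALSE`, absent MAF
  before any recorded MAF), then ascending MAF, with a final
  (chromosome, position) tie-break;
* chromosome labels are opaque strings compared literally; a
  `normalize_chromosomes` switch strips a leading `"chr"` when two
  inputs disagree;
* degenerate inputs are reported, not guessed at: an empty candidate
  list is a valid pipeline outcome, a missing family genotype makes the
  segregation check signal *incomplete data* (a distinct condition,
  never silently `FALSE`), and all format violations raise classed
  errors naming the offending line.

## Design choices where the design was open

**Exclusion mode.** "Removing homozygous segments shared with unaffected
members" is ambiguous between trimming the shared portion and discarding
the whole candidate. The default is `subtract` (trim and keep the
flanks, re-snapped to informative markers), which preserves flanking
autozygosity; `drop` mode is provided for the stricter reading.

**What an unaffected member must show to exclude.** By default an
unaffected individual excludes only where homozygous for the *same*
allele as the affecteds (`unaffected_identity_required = TRUE`): a
sibling homozygous for the opposite allele is evidence for, not against,
linkage. The stricter any-homozygosity reading is available behind the
same flag. Exclusion intervals are found with the same maximal-run
machinery and minimum-size thresholds as ROH calling, so a single
chance-matching marker never cuts a candidate.

**Variants without frequency annotations pass the rarity filter.** For a
private mutation, absence from population databases is precisely the
evidence of rarity; treating a missing MAF as disqualifying would
exclude the most interesting candidates. The known-polymorphism flag is
carried separately from the MAF threshold because published analyses of
this kind apply both a ~1% exome-wide frequency cut and a much stricter
"previously observed at all" criterion inside the mapped locus; the two
are exposed as independent switches rather than merged into one rule.

**The packaged variant table.** The bundled
`inst/extdata/table1_variants.tsv` transcribes a published table of 73
homozygous exome variants. The source text describes the same call set
as both 72 and 73 variants in different sections; the fixture records
the printed table verbatim and the discrepancy is documented here rather
than resolved.

## What the simulator emulates — and what it does not

`simulate_study()` generates the study family: a first-cousin parental
loop (the two parents are children of siblings who share a founder
couple) with five children, two affected. Founder haplotypes are drawn
marker-wise from a uniform minor-allele-frequency law on [0.05, 0.5];
transmission follows the Haldane model (Poisson crossover counts with
mean equal to the chromosome's length in Morgans, crossover positions
uniform in cM, no interference); genotyping errors flip one allele of a
call at rate 0.002 and calls go missing at rate 0.005, matching arrays
with call rates above 99%. A causal variant is implanted on one founder
haplotype and its descent is forced by rejection sampling over meioses
(each transmission chain is redrawn until the required carrier state
holds), so that both affecteds are autozygous at the causal locus,
parents are heterozygous carriers, and no unaffected sibling is
homozygous — while tract lengths around the locus remain faithful to the
recombination model. Every haplotype carries a founder label through all
meioses, so the realized autozygous tract (the truth region) and every
member's causal genotype are known exactly, and the analytic inbreeding
coefficient of first-cousin offspring (F = 1/16) is recoverable as the
mean autozygous fraction across simulated offspring
(`simulate_offspring_autozygosity()`).

Default problem sizes — one 150 Mb chromosome with 5,000 markers for
mapping studies, 100 replicates for recovery experiments, 500 offspring
for the inbreeding check — were chosen as the smallest sizes at which
the relevant statistics are stable; unit tests use smaller grids.

The simulator deliberately omits: linkage disequilibrium among founder
markers (markers are independent given their frequencies), demographic
history, non-uniform recombination maps (the simulated genome
recombines at a constant 1 cM/Mb), crossover interference, and
sequencing-read-level artifacts. Background rows of the simulated
variant table are homozygous in the proband with database frequencies
from the founder law, but their family genotypes are drawn independently
per member under Hardy–Weinberg — they are table rows to be filtered,
not variants placed on the simulated haplotypes. Consequently, passing
the simulation-based tests demonstrates correct mechanics of run
calling, sharing, exclusion, length filtering and segregation logic
under the stated model — not robustness to LD structure, batch effects
or map misspecification in real array data.

## Known limitations

* **Families whose identifiable region is short are unrecoverable by
  construction.** The shared autozygous tract around the causal locus
  breaks at eight independent meioses, so its genetic length is
  approximately Gamma(2, 8 per Morgan)-distributed, and a few percent of
  first-cousin families have tracts shorter than the 5 cM confidence
  criterion. More importantly, unaffected siblings are frequently
  genuinely autozygous for the causal haplotype over sub-intervals away
  from the causal variant (only the variant position itself is
  constrained by the disease model); subtract-mode exclusion then
  correctly trims or splits the candidate, and the identifiable
  remainder around the locus can itself fall under 5 cM. Both effects
  are properties of the method under these family structures, not of the
  implementation; the acceptance script reports the measured recovery
  rate over 100 replicates without adjustment.
* Biallelic array genotypes cannot distinguish IBD from long
  identity-by-state homozygosity; the genetic-length criterion is the
  only guard.
* The X chromosome is treated as autosomal (or excluded upstream);
  there is no X-specific recessive model, no phasing, no imputation and
  no LOD-score linkage.
* cDNA-to-protein annotation covers simple substitutions within a
  supplied CDS under the standard genetic code; indels, splice-site
  consequences and deleteriousness prediction are out of scope (the
  latter can be consumed as annotation columns but is never computed).

## A worked pipeline run

```{r pipeline, eval = FALSE}
study <- simulate_study(simulation_config(seed = 7))
dir <- tempfile()
write_study(study, dir)
report <- run_pipeline(list(
  ped = file.path(dir, "genotypes.ped"),
  map = file.path(dir, "genotypes.map"),
  variants = file.path(dir, "variants.tsv")))
report$candidate_regions
report$top_candidate$gene  # the implanted causal variant
```

The same computation is available from the shell through the thin
`autozyg` script installed under `exec/` (`autozyg simulate`,
`autozyg run --config <file>`).
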