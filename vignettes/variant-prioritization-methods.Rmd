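---
title: "Longitudinal variant prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal variant prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprior)
```

## The problem

Modern meat-producing chicken lines are the product of a few decades of
intense artificial selection. Comparing the genome of a current commercial
broiler (Ross 308) with genomes representative of the breeding stock of
1957 and 1978 gives a rare longitudinal view of that process: variants that
appear and accumulate along the 1957 → 1978 → Ross 308 axis are candidates
for the genetic changes that came with selection for growth — including
changes that may have degraded other functions, such as innate immunity.

`varprior` implements the computational core of that comparison as a
reusable, fully testable pipeline. It consumes per-line annotated variant
tables (consequence classes, SIFT scores, transcript assignments), a
transcript catalog, per-line CNV calls and per-line coverage masks, and
produces per-transcript burden metrics, a five-strategy combinatorial
prioritization, gene-set enrichment of SNP-dense genes, cross-line CNV
comparisons, and a concatenated SNP alignment ready for tree inference.
Read mapping, variant calling, CNV detection and SIFT scoring are upstream
of the package: it starts from their outputs.

## Per-transcript burden metrics

For each transcript $t$ and line $\ell$, `transcript_metrics()` computes

* the nonsynonymous SNP density $d_{t\ell} = n^{\mathrm{nonsyn}}_{t\ell} / L_t$,
  where $L_t$ is the CDS length in bp;
* the mean SIFT score over scored variants (undefined when nothing is
  scored);
* the deleterious count $n^{\mathrm{del}}_{t\ell} = \#\{\mathrm{SIFT} < 0.05\}$ and
  the corresponding density;
* the count of high-impact variants (frameshift, start-loss, stop-gain).

Two interpretation choices deserve a note. First, the density denominator
is CDS length, not genomic gene span: these are coding-impact densities,
and CDS length is the defensible normalizer for them. Second, the mean
SIFT score is a plain arithmetic mean; a per-bp-normalized "global" SIFT
variant is sometimes described in the literature, but dividing an average
score by gene length mixes units and makes between-transcript comparisons
length-confounded, so the plain mean is what the decreasing-SIFT strategy
consumes. Each variant record carries exactly one transcript assignment
(the annotation's canonical transcript); no fan-out to sibling transcripts
is performed, so summing counts over transcripts conserves record counts.

The deleterious cutoff is strict: SIFT $< 0.05$. A score of exactly 0.05
is tolerated.

## Percentile semantics

Every selection in the package is a threshold set, never a top-$k$ cut.
Thresholds come from the nearest-rank percentile: the value at rank
$\lceil q\,n \rceil$ of the ascending sort, with selection by $\ge$ (or
$\le$ for bottom-percentile selections), ties always included. This is
deterministic, attained by a real data value, and independent of the
interpolation choices that differ between quantile algorithms.

## The five strategies

1. **Accumulating density** — per-epoch changes
   $\Delta_1 = d_{1978} - d_{1957}$ and $\Delta_2 = d_{Ross} - d_{1978}$
   must both be strictly positive, and at least one must reach the 95th
   percentile of its population. The percentile population is the
   transcripts passing the both-positive precondition (the eligibility
   clause precedes the percentile clause in the method's definition); a
   `population = "all"` switch ranks against the whole catalog instead.
   The two epochs are ranked separately — a joint ranking is a coherent
   alternative, but separate populations keep each epoch's null scale
   intact, and the choice is exposed rather than buried.
2. **Line-exclusive burden** — two per-transcript densities of coding SNPs
   (synonymous + nonsynonymous; a flag restricts to nonsynonymous):
   variants exclusive to the 1978-and/or-Ross subset, and variants
   exclusive to Ross alone, each against *all* other lines including 1957.
   Selection at the 90th percentile of either statistic, populations being
   transcripts with at least one qualifying variant.
3. **Late high impact** — a high-impact variant key present in 1978 or
   Ross 308 and absent (as a key) from 1957. Non-percentile and therefore
   deterministic given the key sets.
4. **Decreasing SIFT** — mean SIFT defined in all three lines, strictly
   decreasing at both steps (plateaus fail), and in the bottom 50th
   percentile of the 1978 or the Ross 308 line's scored transcripts.
5. **Deleterious accumulation** — deleterious counts non-decreasing per
   step with a strict overall increase (a strict-per-step switch exists),
   and deleterious density in Ross 308 at the 99th percentile among
   transcripts with at least one deleterious variant there.

`prioritize()` combines the five sets, tallies every realized combination
(the upset-plot accounting; the counts always sum to the union of the five
sets), and keeps transcripts selected by at least three strategies.

## Enrichment

`snp_dense_genes()` pools transcripts to the gene level (summed
nonsynonymous counts over summed CDS lengths) and takes the 90th
percentile among genes with at least one nonsynonymous SNP.
`hypergeom_enrich()` then tests each GO/KEGG-style category for
over-representation with the exact hypergeometric upper tail
$P[X \ge k]$, Benjamini–Hochberg adjustment across tested categories, and
a reporting threshold of $q < 0.05$. Categories with fewer than three
universe genes are dropped before testing; the minimum counts universe
genes, not query genes. The universe is the set of genes carrying at least
one category annotation (the usual over-representation default); nothing
is silently dropped from the output — every tested category is returned
with a significance flag.

## CNV comparison

Raw calls are filtered to size $> 1000$ bp and multi-mapping read fraction
$< 0.5$, both strict. Two calls are *shared* when they lie on the same
chromosome, have the same type (a gain never shares with a loss — the
rule's purpose is biological comparability), and overlap reciprocally by
more than 50% of both lengths; exactly 50% is not shared. A one-directional
mode exists behind a flag because the convention is genuinely ambiguous in
parts of the literature. A call is *common to all three lines* when it has
a shared partner in each other line (mutual pairwise sharing; a chained
definition would make the relation non-local and order-dependent). Genes
overlap a CNV class when at least half of their genomic span — inclusive,
so exactly half counts — is covered by the union of same-type calls.
Coverage breadth is computed on the merged union of intervals, so
overlapping calls are never double-counted.

## Phylogenetic SNP matrix

Only genomic positions covered by more than 10 uniquely-mapped reads in
every Illumina line and more than 5 in every SOLiD line qualify (both
strict: depth exactly 10 in an Illumina line disqualifies the position).
Of the SNPs inside qualifying regions, those present in at least one
Illumina and at least two SOLiD lines are retained, sorted by position and
concatenated into a character matrix — alt allele for carriers, reference
otherwise, heterozygotes represented by the alt allele (presence
semantics; ambiguity codes were considered and rejected as the default
because downstream tree programs differ in how they weight them). The
outgroup row is all-reference unless its calls are in the panel. FASTA and
relaxed PHYLIP serializations decode to identical matrices.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis
assumes, with no sequence-level realism:

* 2,000 transcripts, CDS lengths log-normal (median ≈ 1.5 kb, clamped at
  500 bp so length-normalized noise stays bounded);
* a panel of 3 Illumina focal lines + 2 Illumina and 5 SOLiD background
  lines;
* per transcript, a Poisson pool of variants (≈ 10 per kb of CDS across
  the whole panel) with presence patterns — shared by all lines, by the
  three focal lines, by a uniform focal pair, by one focal line, or by one
  background line — that are exchangeable across the focal lines under the
  null, so every between-line contrast is centered;
* null missense SIFT scores from a Beta(2, 1) skewed toward tolerated,
  with a 5% uniform-on-[0, 0.05) deleterious tail so the deleterious-count
  machinery has a non-degenerate null;
* 20 planted transcripts engineered per strategy: all receive a
  Ross-exclusive nonsynonymous burden (≈ 25 SNPs per kb), a late-line
  stop-gain, and deleterious variants appearing in 1978 and dropping
  further in Ross 308 (driving both the decreasing-SIFT and the
  increasing-deleterious clauses); ten additionally receive large
  per-epoch density increments, and three receive extreme deleterious
  densities.

One structural fact is worth stating plainly: percentile clauses select a
fixed *fraction* of their eligible population, so planting many strong
signals cannot make them all pass a 99th-percentile clause — in a cohort
with a few hundred deleterious-eligible transcripts, roughly 1% pass by
definition, planted or not. The generator therefore flags only the three
extreme-density transcripts as engineered for Strategy 5, and recovery by
the ≥ 3-strategy filter rests on Strategies 1–4, whose clause capacities
(5%, 10%, deterministic, 50%) accommodate all 20 planted transcripts.
This is a property of the method being modeled, not of the simulation.

What the generator does *not* model: linkage structure, mutation-rate
heterogeneity along the genome, annotation error, shared ancestry between
background lines, or genotype uncertainty. Passing tests on this cohort
demonstrate that the *computations* are correct and calibrated — not that
the five strategies would rank real transcripts in any particular order.

## Numerical and degenerate-input choices

* Variant identity is the exact tuple (chrom, pos, ref, alt); indel
  alleles are reduced to a minimal left-aligned form at load time so
  caller dialects compare equal. Zygosity is ignored: a line carries a
  variant iff it has at least one alt allele call.
* Empty eligible populations make a percentile clause select nothing
  (rather than erroring), except `nearest_rank_percentile()` itself, which
  refuses empty input loudly.
* Transcripts with no scored variants have undefined mean SIFT and are
  ineligible for the decreasing-SIFT strategy (a decrease cannot be
  shown).
* An alignment with zero retained SNPs raises an error that points at the
  thresholds, because an empty alignment silently written to disk is a
  trap for downstream tree tools.
* All generators take an explicit seed and use a local RNG scope; the same
  seed gives byte-identical output.

## Problem sizes used by the test-suite

The oracle-equivalence checks run brute-force reimplementations on over a
thousand random instances of 10–35 transcripts, up to 40 CNV intervals, or
2 kb toy genomes — sizes chosen so the naive O(n²)/base-by-base oracles
stay trivially correct and the whole suite runs in minutes. Calibration
checks use 50 null cohorts of 400 transcripts; recovery checks use the
default 2,000-transcript cohort at three fixed seeds. The pipeline's
end-to-end determinism is asserted by running it twice into separate
directories and comparing every output file byte-for-byte.

## Worked example

```{r example, eval = FALSE}
run <- run_pipeline(run_config(), seed = 1)
run
glance(run)
tidy(run) |> dplyr::filter(prioritized)
autoplot(run$priority)
```

## Known limitations

* Venn-style counts on synthetic data bear no numeric relation to real
  multi-million-SNP intersections; reproducing them needs the original
  genomes and annotation versions, which is out of scope by design.
* The enrichment module uses annotations as given (no GO-graph
  propagation).
* The combination accounting enumerates realized strategy subsets (at most
  31 non-empty subsets of five strategies).
* CNV sharing is evaluated between call sets as provided; the package does
  not re-genotype or merge calls across lines before comparison.
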