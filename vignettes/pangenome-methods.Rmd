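---
title: "Methods: pan-genome classification, SV impact and expression analysis"
author: "pangene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome classification, SV impact and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangene)
```

# Scope and model

`pangene` implements family-level pan-genome analysis for small panels of
fungal genomes, together with the downstream layers that such studies chain
onto it: structural-variant (SV) impact annotation on gene models,
count-based differential expression, association testing between SV-affected
homologs and differential expression, and GO term over-representation. A
synthetic-data generator with planted ground truth exercises every stage, so
the pipeline can be validated end to end without any sequencing data.

## Occupancy bands

The unit of analysis is the orthogroup family: a set of genes across genomes
descended from one ancestral gene, as produced by orthology inference. A
family's *occupancy* is the number of genomes in which it has at least one
member. For a panel of $N$ genomes the default classification is

* **core**: occupancy $N$,
* **softcore**: occupancy $N-2$ to $N-1$,
* **dispensable**: occupancy $2$ to $N-3$,
* **private**: occupancy exactly $1$.

These bands generalize the scheme used for 15-genome panels (core 15,
softcore 13–14, dispensable 2–12, private 1). For $N < 5$ the interior bands
cannot all be non-empty; rather than failing, the softcore lower bound clamps
at 2 so the dispensable band empties first, and at $N = 2$ the softcore band
empties too, leaving only core and private. `defaultScheme(N)` encodes this;
`classifyFamilies()` applies it and carries *singleton* genes — genes that
never entered a family — as a separate private-unit tally, never merged into
the private-family count, because published panels report them separately.

```{r bands}
defaultScheme(15)
```

## Rarefaction

Pan/core rarefaction asks how the union (pan) and intersection (core) of
family sets grow and shrink as genomes are added. `rarefy()` samples genome
*orderings* uniformly (not bootstrap resamples: the construction mirrors
"adding one genome at a time") and records, for each prefix length $k$, the
number of families present in at least one, and in all, of the first $k$
genomes. A single integer seed drives one generator for the whole run;
orderings are drawn independently and may repeat. For $N \le 8$,
`method = "exhaustive"` enumerates all $N!$ orderings, which is the oracle
the sampling mode is tested against. Within any ordering the pan curve is
non-decreasing and the core curve non-increasing; this is asserted by the
class validity every time a result is built. The number of sampled orderings
is not prescribed by published panels; the default of 100 is a documented
convention, and tests requiring Monte-Carlo agreement use 10 000.

## SV impact rule table

Published panels delegate SV effect categorization to variant-effect
predictors and report only the four severity classes. `pangene` makes that
layer explicit as a normative rule table over (SV type, gene region, frame
effect); the table is the contract, tested exhaustively against a per-base
oracle:

| variant | condition | impact |
|---|---|---|
| DEL over CDS | removed CDS length $\not\equiv 0 \pmod 3$, or removes the start/stop-bearing CDS terminus | high |
| DEL over CDS | in-frame, termini intact | moderate |
| DUP over CDS | duplicated CDS length $\not\equiv 0 \pmod 3$ | high, else moderate |
| INV touching CDS | a breakpoint inside CDS | high |
| INV spanning CDS | both breakpoints outside CDS (incl. whole-gene) | moderate |
| INS in CDS | length $\not\equiv 0 \pmod 3$ | high, else moderate |
| any, exon outside CDS (UTR) | | low |
| any, intronic only | | modifier |
| any, promoter/downstream window | | modifier |
| TRA breakend | in CDS / in gene body / in windows | high / moderate / modifier |

Insertions and translocation breakends are width-1 anchors at their
position, so each localizes to exactly one feature — the behaviour needed
for a promoter insertion to be attributed to a single gene. With several
transcripts the most severe call wins (the "most severe consequence"
convention of variant annotators). An inversion that contains a whole gene
is *moderate*, not high: its coding sequence is preserved and orientation
effects are uncertain. The promoter window defaults to 1000 bp upstream of
the transcription start (strand-aware) and the downstream window to 500 bp;
no published window sizes exist for these panels, so both are explicit,
configurable parameters. SNP-level consequences (e.g. amino-acid changes)
are out of scope: this is an SV classifier.

Coordinates are held as Bioconductor `GRanges`/`IRanges` (1-based, closed)
throughout — the single-convention rationale usually argued for 0-based
half-open internals, realized with the containers idiomatic to R. GFF3 and
VCF are both natively 1-based, so parsing introduces no shifts; the VCF
`POS` of a spanning SV is the padding base, so a deletion's affected range is
`[POS+1, END]`.

## Differential expression

The DE layer is deliberately a fully specified simple test, not a
negative-binomial GLM: per gene, the log2 fold change of group-mean CPM with
a pseudo-count of 0.5, a two-sided Welch $t$-test on $\log_2(\mathrm{CPM} +
0.5)$, and a hand-rolled Benjamini–Hochberg step-up (cross-checked against
`p.adjust` in the tests). A gene is a DEG when $|\log_2 FC| > 1$ and FDR
$< 0.05$ — the standard reporting thresholds. The pseudo-count bounds
behaviour at zero counts. With four biological replicates per group this
test is defensible and transparent; it does not reproduce shrinkage
estimators, and analyses requiring them should use a dedicated DE package.

Cross-genome comparisons need aligned rows: `singleCopyHomologs()` takes
families with exactly one member in each panel genome as homolog groups
(the natural reading of "homologous genes present in all five genomes"),
and `homologCountMatrix()` rebases the count matrix onto them.

The omnibus test across the four category expression distributions is
Kruskal–Wallis: a single "among the groups" p-value without distributional
assumptions, matching how such figures are annotated. Expression breadth
counts the genomes (of the panel) where a homolog's mean CPM in a tissue
reaches a threshold; the threshold (CPM $\ge 1$, mean over replicates,
per tissue) is a documented default, not a published value.

The SV–DEG association is a continuity-corrected Pearson chi-square on the
2×2 table of {SV-affected, not} × {DEG, not} over homolog groups; published
figures do not name the test, so chi-square is chosen and labelled, with
Fisher's exact substituted (and noted) when a margin is zero.

## GO enrichment

`goEnrich()` is the one-sided hypergeometric over-representation test with
the raw-p reporting cutoff ($p < 0.05$) used by GO tools in this setting. A
Benjamini–Hochberg column is reported for reference but does not drive the
flag. Associations are taken as flat gene → term sets: no ontology-graph
propagation to ancestor terms is performed (that would require an ontology
file, which is outside this package's scope); users wanting
ancestor-inherited annotations should propagate before input. The default
population is every gene of the genome under test, annotated or not.

# The synthetic-data generator

`simulationConfig()` states the world the tests operate in. Its defaults are
the study conditions the package emulates, not tuning knobs:

* 15 genomes; family-category counts 5917/1937/5058/575
  (core/softcore/dispensable/private) and 368 singleton genes, all scaled by
  `scaleFactor` (default 0.05, ≈675 families, so the suite runs in seconds;
  `scaleFactor = 1` reproduces the full 13 487-family scale and remains
  desk-scale);
* five expression-profiled genomes with four biological replicates of two
  tissues (mycelium, fruiting body) each;
* negative-binomial counts, variance $\mu + \phi\mu^2$ with $\phi = 0.1$ —
  the standard RNA-seq noise model, with a dispersion typical of biological
  replicates (no published value exists for these panels);
* category-graded mean counts with strictly ordered multipliers 8/4/2/1 on a
  base mean of 50, emulating the observed decline in expression from core to
  private families;
* one planted SV on 10% of genes per genome, cycling through region/type
  combinations with known impact classes; 80% of SV-hit genes receive a
  planted expression shift of $\log_2 FC = 2$ on the carrier genome's copy;
* one guaranteed 440 bp promoter insertion with an expression effect in the
  designated genome (the motivating promoter-variant narrative), whenever
  SVs are enabled;
* per-sample library sizes jittered ±20% (removed by CPM normalization).

Families draw an occupancy uniformly within their category's band and a
uniform random genome subset of that size; every present genome contributes
exactly one member gene, so planted categories are recovered *exactly* by
classification and single-copy homolog groups are simply the families
covering the expression panel. Gene models alternate intronless and
two-exon/UTR structures and strands, laid out with intergenic gaps wide
enough that every planted SV touches exactly one gene — which is what makes
"recovered tallies equal planted tallies" a meaningful exact check.

What the generator does **not** emulate: sequence content (no FASTA),
multi-copy families, overlapping genes, alternative isoforms, tissue-specific
effects, batch structure, or background (non-SV) differential expression. A
green end-to-end test therefore establishes that the statistical machinery
recovers planted structure under the stated noise model — not that the
pipeline is robust to every artefact of real sequencing data.

# Numerical and design choices

* **Ties and determinism.** Annotation output is sorted by (sv_id, gene_id);
  identical inputs give byte-identical TSVs. All stochastic stages are
  driven by one integer seed; generator stages use fixed small offsets of
  the master seed so they are independently reproducible.
* **Degenerate inputs.** Zero-total samples are excluded from normalization
  and flagged; zero-variance genes get $p = 1$ when means agree and $p = 0$
  otherwise; categories with no genes are dropped from the omnibus test with
  a warning; an all-constant expression matrix yields a Kruskal–Wallis
  statistic of 0 and $p = 1$.
* **Percentage reporting.** Category percentages are computed over families
  only (singletons excluded from the denominator), which reproduces
  published pie-chart percentages; the 74.1%-style shared-family figures in
  the literature can be truncations rather than roundings (9177/12376 =
  74.15%), and the tests treat them as such.
* **Pipeline restartability.** `runPipeline()` is file-based: each stage
  reads its inputs from and writes its outputs to the run directory, and a
  manifest of input checksums lets unchanged stages be skipped; checksum
  equality guarantees a warm re-run equals a cold one, which the tests
  verify.

# Known limitations

* The DE test is Welch-on-log2-CPM; at very low counts or extreme
  dispersion a count-model test has more power.
* Breakend (TRA) records are treated as isolated points; mates are not
  resolved.
* GO enrichment does not parse ontologies or propagate terms.
* The impact rule table is normative for this package; real variant-effect
  predictors differ in corner cases (e.g. transcript-ablation calls,
  UTR-specific classes).

# Session info

```{r sessioninfo, eval = FALSE}
sessionInfo()
```
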