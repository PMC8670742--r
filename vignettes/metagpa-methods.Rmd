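---
title: "Case-control metagenomic genome-phenome association with metagpa"
author: "metagpa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control metagenomic genome-phenome association with metagpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagpa)
```

## The problem

Some phenotypes of a microbial community — for instance, carrying a
chemically modified DNA base — can be physically selected for: one
sequencing library is prepared from the phenotype-selected material
(the *case* library) and one from the total community (the *control*
library), both mapped against the same assembled contigs. Genes whose
protein domains are responsible for, or travel with, the phenotype will
concentrate on the contigs that survive the selection. `metagpa`
implements the downstream statistics of this design: scoring contigs
for enrichment, testing protein-domain families for association with
the enriched set, and refining candidates by residue-level
conservation, domain co-occurrence, and tree clustering.

The package consumes the standard interchange formats of the upstream
tools (FASTA contigs, per-contig mapped-read counts, HMMER `domtblout`
domain tables, GFF3 ORF calls, aligned FASTA, newick trees) and never
runs assembly, mapping, HMM search or alignment itself.

## Enrichment model

For each contig $i$ with length $L_i$ bp and mapped-read count $c_i$ in
a library of $T$ total mapped reads, coverage is normalised as reads
per kilobase per million mapped reads,

$$\mathrm{RPKM}_i = \frac{c_i}{(L_i/1000)\,(T/10^6)},$$

and the enrichment score is the ratio
$\mathrm{RPKM}^{\mathrm{case}}_i / \mathrm{RPKM}^{\mathrm{control}}_i$.
Contigs scoring $\ge 3$ are called **modified**, the rest
**unmodified**. The threshold of 3 and the 1000 bp minimum contig
length are the field's working conventions for this design and are the
package defaults (`classifyContigs(threshold = 3, minLength = 1000)`);
both are ordinary arguments.

Three normalisation choices deserve to be explicit:

* **Library totals.** Unless totals are supplied in the counts file
  (`# totals: case=... control=...`), totals are the mapped reads on
  the *retained* (length-filtered) contig set, keeping normalisation
  internally consistent with filtering. Scores depend only on count
  ratios and the totals ratio, so any common rescaling of both totals
  cancels.
* **Zero control coverage.** The ratio is deliberately unguarded: a
  contig with case reads but zero control reads scores `Inf`, is
  labelled modified, and is flagged (`zero_control = TRUE`). A
  `pseudocount` argument adds a constant to both counts for users who
  want finite scores; it defaults to 0 because the plain ratio is the
  reference behaviour.
* **Indeterminate contigs.** Contigs with zero coverage in both
  libraries have no defined score; they are labelled `indeterminate`
  and excluded from both groups rather than silently assigned.

A read-level QC view is provided by `kmerFrequencyCompare()`, which
counts canonical 16-mers (each word pooled with its reverse
complement) per cohort and normalises to counts per million; identical
cohorts give identical frequency columns, and the per-cohort
frequencies close to $10^6$ by construction.

## Domain-family association

Each domain family (identified by its version-stripped accession, so
database releases do not fragment counts) is tested with a 2×2 table:
modified contigs carrying / lacking the family versus unmodified
contigs carrying / lacking it. A contig counts at most once per family
regardless of hit multiplicity. The two-sided Fisher exact p-value is
computed by minimum-likelihood summation — with margins fixed, the
hypergeometric point probabilities of all tables no more probable than
the observed one (ties included, with the conventional $1+10^{-7}$
relative tie guard) are summed in log space. Degenerate margins give
$p = 1$. Bonferroni correction multiplies by $m$, the number of
families with at least one hit on a labelled contig; a family is
reported significant when the adjusted $p < 0.01$ **and** it is
over-represented on modified contigs. Families leaning the other way
are reported with direction `unmodified-enriched` and never flagged —
a deliberately conservative tie-break (equal proportions count as
unmodified-enriched).

ORFs on modified contigs carrying at least one hit of a significant
family are the **candidate genes**. Hits can be attached to ORFs
either by target name (`by = "target"`, for searches run on predicted
proteins) or by coordinate containment on the contig
(`by = "overlap"`); hits matching no ORF are reported as orphans, not
dropped silently.

## Differential conservation

For a protein family of interest, member sequences are aligned
externally and each row labelled by whether it was encoded on modified
or unmodified DNA (`GroupedAlignment`; both groups need at least two
sequences). Columns with less than 50% residues present are ignored
(the boundary occupancy is kept; the denominator is all rows). At each
retained column, with $N_1, N_2$ the per-group counts of non-gap
residues and $M$ the BLOSUM80 matrix,

$$I_g = \sum_{i<j} M(a_i,a_j)\,\frac{2}{N_g(N_g-1)}, \qquad
  J = \sum_{i,j} M(a_i,b_j)\,\frac{1}{N_1 N_2}, \qquad
  S = \frac{I_1 + I_2}{2} - J.$$

$S = 0$ exactly for perfectly conserved columns; columns where each
group is fixed on a different residue score
$(M(x,x)+M(y,y))/2 - M(x,y)$, which is positive for every distinct
BLOSUM80 residue pair. Ranking columns by $S$ (ties broken by column
index) surfaces positions conserved *differently* in the two groups —
the residues most likely to discriminate the phenotype-linked variant
of the protein. Positions are reported both as alignment columns and,
when a reference row is set, as positions on the ungapped reference.

Numerical conventions: $N_1, N_2$ count non-gap residues per column
(the pair formulas are undefined for gaps); columns where a group has
fewer than two residues get `S = NA` rather than 0, so unscorable
columns cannot masquerade as nulls; ambiguous residues are scored via
the matrix when it contains them (the packaged BLOSUM80 includes B, Z,
X and `*`), otherwise treated as missing. One property worth knowing:
because $I_g$ is a mean over *distinct* unordered pairs, duplicating
every sequence does not leave $I_g$ exactly unchanged — self-copy
pairs enter the mean, giving the exact identity
$I^{dup} = ((2N-2)I + \bar D)/(2N-1)$ with $\bar D$ the mean diagonal
score, which converges to invariance as groups grow. $J$, a mean over
ordered cross-pairs, is exactly duplication-invariant. The test suite
asserts both identities.

## Domain co-occurrence and tree clustering

Presence of each family on each contig is collapsed to a boolean
matrix. For a pair of families with presence counts $n_1, n_2$ over
$N$ contigs, the null model fixes both counts and places them
uniformly, making the joint count $j$ hypergeometric:

$$P(j) = \binom{n_2}{j}\binom{N-n_2}{n_1-j}\Big/\binom{N}{n_1}.$$

The upper tail $p_{\ge} = \sum_{k \ge j_{obs}} P(k)$ flags positive
association; edges with raw $p_{\ge} < 0.05$ form the co-occurrence
network. No cross-pair multiplicity correction is applied by default
(an optional Benjamini–Hochberg flag exists), and by convention the
pipeline tests the top 20 modified-enriched families. The
`domainNeighborhood()` view complements the network with literal
genomic context: all domains within 3 kb (nearest-edge distance) of
each hit of an anchor family, offsets reported in contig coordinates
and therefore independent of the anchor's strand.

`cladePurity()` quantifies whether modified-encoded proteins form a
distinct branch of an externally inferred tree: every edge of the
unrooted tree bipartitions the leaves, and the side maximising the F1
of purity (modified fraction within the side) and coverage (fraction
of all modified leaves captured) is reported.

## The synthetic fixture generator

`simulationConfig()` + `writeFixtures()` generate complete,
seed-deterministic case/control datasets with truth side-cars (truth
is never encoded in sequence names, so parsers cannot shortcut it).
The defaults are the package's reference study conditions, used by the
test suite and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `nContigs`, `fractionModified` | 500, 0.1 | community size and modified fraction |
| `lengthRange` | 1000–10000 bp | contig lengths (uniform) |
| `meanCoverage` | 50 reads/kb | expected control coverage, a typical shotgun assembly depth |
| `countModel`, `dispersion` | NB, 0.3 | variance $\mu + 0.3\mu^2$; Poisson by option |
| `enrichmentFactor`, `depletionFactor` | 10, 0.1 | case-coverage multipliers for modified / unmodified contigs |
| `nPlantedDomains`, `plantedPrevalence` | 3, 0.9 | phenotype-linked families and their rate on modified contigs |
| `nDomains`, `backgroundPrevalence` | 50, 0.02 | background families, status-independent rate |
| `hitDuplicationRate` | 0.1 | duplicate hits exercising once-per-contig counting |
| `msaRowsPerGroup`, `msaWidth`, `msaPlantedColumns` | 20, 100, 1 | grouped-alignment geometry |
| `msaNoise`, `msaGapRate` | 0.05, 0.05 | per-cell substitution and gap rates |

The negative binomial (rather than Poisson) default makes recovery
tests honest about the overdispersion real coverage data shows; at
dispersion 0.3 the case/control count ratio of a single contig has a
heavy enough tail that a small percentage of contigs is misclassified
at threshold 3 even with a 100-fold separation of expected scores —
which is exactly the situation the association stage must tolerate.
What the generator does **not** emulate: read-level errors, assembly
artefacts and chimeras, redundancy between case and control
assemblies, compositional correlation between neighbouring domains,
and phylogenetic correlation among contigs. Passing recovery tests on
these fixtures therefore validates the statistics and the plumbing,
not robustness to assembly pathology.

Problem sizes in the validation suite are chosen to keep the full run
desk-scale: 20 replicate simulations for signal recovery, 100 for null
calibration, exhaustive exact-test checks up to table total
$N \le 40$, and $10^5$-draw permutation checks of the co-occurrence
tail on 20 random instances.

## Worked example

```{r example}
cfg <- simulationConfig(seed = 42)
com <- simulateCommunity(cfg)
cov <- simulateCounts(cfg, com)
et <- classifyContigs(cov)
et
ann <- simulateDomainHits(cfg, com)
at <- associateDomains(ann$hits, et)
at
setequal(significantDomains(at), ann$planted)
```

## Known limitations

* The Fisher stage pools everything into one composite case/control
  comparison; per-environment testing with meta-analysis across
  experiments is out of scope.
* BAM parsing is not implemented; counts arrive as tables (any
  multicov-style counter produces them).
* Whether upstream RPKM totals should be raw or mapped reads is not
  standardised across tools; the package documents and defaults to
  mapped-reads-on-retained-contigs, and accepts explicit totals for
  any other convention.
* The two-sided convention of the exact test (minimum-likelihood
  summation) matches the mainstream scientific libraries; doubling
  the one-sided tail would give slightly different p-values.
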