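---
title: "Characterizing a miRNAome from small RNA-seq discovery output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a miRNAome from small RNA-seq discovery output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaomekit)
```

## The problem

Discovery tools for miRNA genes (miRDeep2 and relatives) emit scored hairpin
candidates, but for a species without reference miRNAs the bulk of the
scientific work happens afterwards: separating real miRNA genes from
repetitive sequence, rRNA/tRNA fragments and noise; deciding which candidates
are orthologs of known miRNAs and naming them accordingly; and characterizing
the resulting gene set — which arm of each hairpin is used, where the genes
sit in the genome, how the reads vary around each canonical mature, and what
the novel, species-specific miRNAs might target. `mirnaomekit` implements
that post-processing as a set of composable, individually testable
operations, with a synthetic-data generator that plants known structure into
every input so the whole pipeline can be validated end to end.

All coordinates are held 0-based half-open internally (BED convention); the
1-based inclusive tabular alignment dialect is converted at the I/O boundary.
Sequences are RNA (`U`) internally; DNA inputs are normalized on read.

## Filtering model

Two quantities drive candidate filtering:

* **Score threshold.** Discovery scores are calibrated against a
  permuted-genome control run. For cumulative counts $S(t)$ (real candidates
  with score $\ge t$) and $C(t)$ (control candidates), the threshold is the
  smallest $t$ with $S(t)/C(t) > r$, default $r = 10$ (the 10:1 convention).
  The ratio is $+\infty$ when $C(t) = 0$ and $S(t) > 0$; if no threshold
  qualifies the operation errors rather than guessing.
* **Filter cascade.** Each candidate is rejected for at most one reason, in
  a fixed order chosen to make reports reproducible (the underlying screens
  are order-free): score, structural RNA, repetitive, expression. A
  structural-RNA match is any hit at E $\le 0.1$ against a subject whose id
  carries an rRNA/tRNA/snRNA/snoRNA/scaRNA class prefix — the most permissive
  E-value used anywhere in the pipeline, deliberately conservative for a
  contamination screen. "Repetitive" counts *distinct chromosomal areas*:
  genome hits at E $< 2 \times 10^{-8}$ are merged per subject when they
  overlap, and more than 5 merged loci rejects the candidate (raw hit rows
  would over-count tandem hits). Expression requires $\ge 10$ reads for some
  mature of the candidate in at least one single sample — a detectability
  floor, not a normalized quantity, so it is applied to raw counts.

## Conservation, families, names

A precursor is **conserved** when any miRBase hairpin hit has
E $< 10^{-5}$ (strict); its ortholog species are the three/four-letter
prefixes of qualifying subject ids, and the *best ortholog* is the lowest-E
hit with ties broken by bit score then subject id, making naming
deterministic. **Families** are assigned by exact lookup of the 7-nt seed
(mature positions 2–8). We fixed the seed at 2–8 everywhere — family
assignment, "complete seed" in recovery, and reporting — because a single
unambiguous definition beats the looser "6–8 nt" folklore, and 2–8 is the
miRBase family convention.

Naming follows community practice: conserved precursors inherit their best
ortholog's stem (`fca-mir-122`); several loci matching one stem get
`-1`, `-2`, … in coordinate order; species-specific precursors get
chromosome-serial names (`fca-mir-chrX_1`), again in coordinate order so the
map is stable under input permutation. Serials are small per-chromosome
integers rather than opaque genome-wide indices: the scheme only needs to be
deterministic and collision-free.

**Missed-family recovery** asks whether families conserved in $\ge 5$
species including human, but absent from the detected set, leave traces in
the genome. Statuses are assigned per *gene* with a fixed precedence —
detected, family-member-detected, genomic-evidence, absent — and families
roll up to their best member status. Genomic evidence from a mature probe
requires the hit to cover probe positions 2–8 at E $\le 0.1$; because the
12-column hit format does not locate mismatches, a hit with mismatches only
counts when per-probe mismatch positions are supplied and none falls in the
seed. A precursor probe needs $\ge 70\%$ of its bases aligned (also gated at
E $\le 0.1$; an uncapped E-value would let junk alignments count as
evidence). The gene-level table additionally records the raw evidence flags,
since a gene inside an already-detected family can still carry its own
genomic evidence.

## Arm usage and switching

Replicate samples are summed per tissue before any comparison ("reads per
tissue" is the unit of evidence), and the dominant arm is the *strict*
majority of raw 5p vs 3p reads; exact ties are recorded as `tie` and never
counted as dominance, so they can never manufacture a switch. A precursor
arm-switches when its per-tissue dominant arm takes both values across
tissues, with only tissues reaching `min_tissue_reads` (default 10, the same
detectability floor as the expression filter) allowed to vote — without the
gate, one stray read in an otherwise silent tissue could flip dominance.
Arm *presence* defaults to $\ge 1$ read in some tissue (a separate
`presence_min_reads` raises it to 10 for users who prefer symmetric
definitions; both are reported by the same summary).

Duplicate matures ("same or highly similar products" from distinct loci) are
connected components under the relation *identical or Levenshtein distance
$\le 2$* on dominant matures; 2 nt is a small fixed radius that tolerates
the 1–2-base divergence seen between paralogs while keeping random 18–22-mers
apart, and exact and similar groups are labeled separately so the choice is
auditable. Sample clustering uses $1 - \rho_s$ (Spearman) with average
linkage on the most expressed mature per precursor (CPM-normalized, ties to
5p), which makes the tree invariant under monotone per-sample transforms; a
constant sample column makes $\rho_s$ undefined and errors with the sample
named. Reference-miRNA selection for qPCR normalization ranks matures by
coefficient of variation (SD/mean of normalized counts) ascending.

## Genomic clusters

A cluster is a maximal same-strand chain with inter-gene gaps strictly below
10 kb. The gap is measured end-to-start between the next gene and the
rightmost end seen so far in the chain (a configurable choice; intergenic
separation is the natural reading of "inter-gene distance"), which makes the
sorted sweep exactly equivalent to the transitive closure of the pairwise
relation — verified against a brute-force union-find in the tests. Unplaced
assembly fragments are clustered exactly like chromosomes. Cluster
conservation per species is `conserved` only when every member maps and all
mapped chromosomes agree; any partial mapping *or* chromosome disagreement is
`partial` (both readings of partial conservation collapse to one status by
design), and `none` requires no mapped member.

## isomiR model

Reads are anchored by sliding over the precursor within ±5 nt of the
canonical mature start, minimizing mismatches (ties: smaller shift, then
5′-ward), and discarded as `unassigned` above 2 mismatches. The defaults
cover every category the taxonomy distinguishes (extensions/trims of 1–2 nt,
single internal substitutions) while rejecting unrelated reads; both are
configurable. Classification is a cascade:

1. any mismatch *inside the region shared with the canonical mature* →
   `polymorphic` (internal variation outranks end variation; there is no
   combined class);
2. else changes at both ends → `mixed_5p3p` (all simultaneous 5′/3′ variants
   are lumped);
3. else a single-end extension whose extra bases all match the precursor
   flank, or any single-end trim → `5p`/`3p_templated` — a removal cannot
   introduce foreign bases, so trimming is always templated;
4. else a single-end extension with a foreign base → `5p`/`3p_nontemplated`;
5. else `canonical`.

A→G substitutions at internal positions are flagged as possible A-to-I
editing signatures but remain `polymorphic` — editing is an interpretation,
not a sequence category. Distributions are read-count weighted; `unassigned`
reads are excluded from the denominator and reported separately. Each read
is assigned to a single best (precursor, arm) — no fractional multi-mapping.

## Canonical seed sites

A UTR locus is a site when a window equals the reverse complement of miRNA
positions 2–7; the flanks decide the type (8mer > 7mer-m8 > 7mer-A1 > 6mer,
the canonical efficacy hierarchy), and each core locus is reported once at
its strongest type while overlapping cores are all reported. The `A` of
7mer-A1/8mer must be an adenine in the UTR regardless of miRNA position 1 —
the standard convention, since the A is recognized by the silencing complex
rather than paired. Matching is exact after alphabet normalization; there is
no thermodynamic or accessibility scoring.

## The synthetic-data generator

The generator exists so that every module can be tested against planted
truth without any external download. Its defaults encode the study design
the package was built around: 12 tissues sequenced as 27 libraries (1–5
replicates per tissue), 1182 raw candidates of which 378 reach score 5 and
271 survive filtering (804 low-score decoys, 105 low-expression decoys
capped at 9 reads per sample, 2 structural-RNA decoys of which one is also
repetitive), 204 precursors encoding both arms for 475 matures in total,
expression classes 201/27/43 (both/5p-only/3p-only), a 53/47 overall 5p/3p
dominance split, 19 planted arm switches, 25 species-specific precursors, 17
pairs + 3 triples of duplicate-mature loci, and 31 planted genomic clusters
(109 precursors, largest cluster 29 members) with singletons spaced 50 kb
apart. IsomiR proportions default to 46.3% canonical, 33.4% 3′ templated,
11.2% polymorphic, 6.0% 3′ non-templated, 2.4% 5′ templated, with the
remainder split over the rare classes; a configuration that specifies only
some categories has its remainder assigned to the rare classes, never to the
named ones.

Hairpins are built constructively — a random stem, a loop, and the stem's
reverse complement with up to 2 substitutions — rather than folded:
downstream modules never inspect secondary structure, so thermodynamic
realism would buy nothing. Matures sit at least 3 nt from the hairpin ends
so templated extensions always have a flank to copy. Abundances are
log-normal (a standard heavy-tailed expression model; `meanlog = 2`,
`sdlog = 1.2` by default), multiplied by planted per-tissue enrichment
factors. Read allocation is exact: a guaranteed base of 40 reads per
expressed precursor in its anchor tissue (and in a switcher's flip tissue),
fixed sub-threshold counts for low-expression decoys, and a multinomial over
the remainder, summing to `reads_per_sample` exactly. The split between arms
is *deterministic rounding* of `arm_ratio` (default 0.75) toward the
tissue's dominant arm, so planted dominance is noise-free and switch
recovery can be required to be exact; the isomiR category of each read is
multinomial, so category recovery is tested statistically (3 binomial
standard errors). Orthology is emitted directly as hit-table rows honoring
the module thresholds — alignment itself is out of scope, and what needs
exercising is the thresholds, not BLAST.

What the generator does *not* emulate: sequencing error and quality,
adapter artifacts, colorspace chemistry, multi-mapping between near-identical
precursors, or correlated biological replicate structure beyond shared
tissue means. Passing tests therefore demonstrate the correctness of the
decision rules under their stated models, not robustness to raw-data
artifacts upstream of the candidate table.

## Numerical and degenerate-input choices

* Strict inequalities follow the rule definitions exactly: score `< 5`
  rejects, orthology needs E `< 1e-5`, clusters need gaps `< 10 kb` (a gap of
  exactly 10 kb does not chain), structural-RNA and recovery screens use
  `<= 0.1`.
* Dominance and per-tissue votes never break ties arbitrarily: equal counts
  are `tie`, zero counts are `none`, and neither participates in switching.
* Mature-per-precursor selection and reference-miRNA ranking break ties by
  the 5p arm and by id, respectively.
* Empty inputs flow through every stage (an over-strict threshold yields an
  empty but well-formed report); malformed inputs (wrong column counts,
  non-integer or negative counts, matures absent from their hairpin,
  all-zero or constant sample columns) error with the offending record
  named.
* Cat-specific serials, cluster ids and leaf order depend only on
  coordinates and input content, never on row order.

## Problem sizes

The test-suite and acceptance runs use the generator at the study scale
(1182 candidates, 27 libraries at 50 000 reads each) for the end-to-end
accounting, 50 000 reads for isomiR proportion recovery, 200 precursors
across the 12-tissue panel for switch recovery, 1000 random interval sets
(n ≤ 50) for the cluster oracle, 200 random miRNA/UTR pairs for the seed
scanner, and a 3-tissue × 3-sample design for clustering recovery. These
sizes make every stochastic check well-powered while keeping a full run in
the low minutes on one core.

## Known limitations

* Conservation is called from precomputed hit tables; the package neither
  aligns nor fetches miRBase, so calls inherit whatever search produced the
  hits.
* Family assignment is exact-seed only; "highly similar" matures with a
  shifted or mutated seed will not inherit a family.
* The isomiR classifier assumes reads derive from their assigned precursor
  and lie within it; templated status of an extension is judged against the
  precursor sequence alone.
* Differential expression (tissue-enrichment testing) is intentionally not
  reimplemented; count matrices are exported in a form directly consumable
  by DESeq2/edgeR.
* The recovery module's family universe is supplied by the caller; the
  package does not derive it from miRBase.
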