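---
title: "Comparative analysis of multipartite bacterial genomes with panreplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of multipartite bacterial genomes with panreplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panreplicon)
library(dplyr)
```

## The problem

Many alpha-proteobacteria, including the rhizobial genus *Ensifer*
(*Sinorhizobium*), carry their genome on several replicons: a chromosome,
one or two megaplasmids (in *E. meliloti* called pSymA and pSymB) and,
in some strains, small accessory plasmids. The replicons differ in gene
content, G+C composition, repeat load and evolutionary history, and genes
occasionally move between them. Quantifying that structure across a strain
collection requires a chain of analyses: clustering genes into families,
separating core from accessory content per replicon, discovering repeat
elements and transposon-associated loci (TALs), detecting inter-replicon
gene movement and large translocations, and testing whether the replicons
of a strain diverge together or independently.

`panreplicon` implements that chain as composable tibble-in/tibble-out
functions, together with a seeded synthetic-genome generator that plants
every feature of interest with machine-readable truth, so each stage has a
parameter-recovery test.

## Gene families: similarity graph and Markov clustering

Protein-coding genes are compared all-vs-all. Candidate pairs share at
least one amino-acid k-mer (default k = 5, chosen for sensitivity around
the 80% identity scale); candidates are scored by gapped local alignment
(BLOSUM62, affine gap costs 10/4). An edge is kept when alignment identity
is at least `min_identity` and the aligned span covers at least
`min_coverage` of the shorter protein; both default to 0.80, the
conventional within-species thresholds for this kind of analysis. The
retained alignment *scores* (not identities) weight the clustering graph.

Families are the clusters of Markov clustering (MCL): the column-stochastic
score matrix, with self-loops equal to each node's maximum incident weight,
is iterated through expansion (matrix squaring) and inflation (entrywise
power followed by column renormalisation) until stable. The inflation
default is 10, appropriate for a single-species collection where paralogs
rather than distant orthologs are the main confounder. Numerical choices:
entries below 1e-5 are pruned *after* renormalisation (pruning raw powered
entries would remove entire near-uniform columns), convergence is a maximal
entrywise change below 1e-6, and 100 iterations is an error, not a silent
stop. A node drawn to attractors of two different clusters joins the
cluster with the larger flow, with ties broken by attractor weight and then
by the smallest cluster label, so results are deterministic. MCL runs per
connected component; flow cannot cross components, so this equals a
whole-graph run at much lower cost.

`single_copy_core()` identifies families with exactly one member in every
strain; these feed the divergence analyses.

## Core/pan structure and accessory-plasmid sharing

`core_pan_counts()` and `core_pan_curve()` implement the usual rarefaction
view: for every subset size, all subsets are enumerated when their number
is below `max_enumeration`, otherwise subsets are sampled uniformly under
the given seed. All subset points are returned (with a mean line in the
plot) rather than only averages, since the spread across strain
combinations is itself informative. `core_replicon()` restricts the
all-strains test to one replicon class and honours strain exclusions, the
usual device for removing strains with large rearrangements from
core-structure summaries. `percent_core()` reports gene (not family)
fractions, because per-replicon tables conventionally count genes.

Accessory-plasmid genes are classified by where their family occurs on the
main replicons elsewhere in the population: exclusive to one main class,
on multiple classes, or unclassified when the family is accessory-only.
Accessory plasmids are treated as one replicon class throughout.

## Repeat elements

Repeat discovery follows the self-comparison idiom: every replicon is
compared against itself for maximal exact matches in both orientations
(`find_self_repeats()`, the maxmatch/nosimplify behaviour: all repeated
placements reported, trivial identity excluded). Because point divergence
fragments exact matches, anchors (default minimum 15 bp) lying on nearly
the same diagonal with gaps up to 90 bp are chained into match regions,
and region ends are extended along the diagonal while local identity stays
above 60% in a 15 bp window. Regions shorter than 65 bp are discarded —
just under the shortest repeat element this pipeline is designed to
recover (66 bp). The interval sequences from both sides of every match are
pooled across all strains.

Pooled sequences are clustered by pairwise match coverage (fraction of the
shorter sequence covered by exact matches to the other) using the shared
MCL implementation at inflation 2; the method names MCL for this step but
no inflation value, and 2 is the common default for coverage-style graphs.
Each multi-member cluster becomes a family: members are center-star
aligned (the center is the member with the maximal summed pairwise
alignment score), members whose residues are poorly supported by the rest
of the alignment are dropped (a residue is well-aligned when at least 60%
of the other members have a residue in its column; a member survives when
at least 60% of its residues are well-aligned), survivors are re-aligned
and a per-column base-frequency profile with pseudocount 1 is taken over
the columns where fewer than half the members gap.

Scanning is a gapless log-odds sweep of each profile along both strands of
each replicon. E-values come from a decoy: one dinucleotide-preserving
shuffle of the replicon per run (Altschul–Erickson Eulerian-path shuffle,
seeded), scored identically; an exponential tail is fitted to the decoy's
top block-maxima scores and hits above the score at which the expected
decoy count falls below the cutoff (default 1e-4) are reported. The
profile model is deliberately a position-frequency model rather than a
full profile HMM: it captures the scan contract at this scale, and a full
HMM is an extension point, not a requirement, for substitution-only
divergence.

Overlapping instances are resolved by ownership: within each set of
mutually overlapping instances the winner is chosen by length, then
identity to consensus, then score, with any remaining tie going to the
lower start coordinate; the procedure repeats until the per-replicon
interval set is disjoint (a hard invariant, asserted in the tests).

## Transposon-associated loci

TALs are flagged from functional labels: a gene is a TAL when any of its
labels contains any vocabulary term (case-insensitive substring). The
default vocabulary covers transposase, integrase, recombinase, phage
integrase and IS/transposon categories; a fuller category list can be
loaded from a plain-text file, one term per line. This label interface
replaces profile-database matching so the classification contract is
testable without an external HMM database; genes without labels are never
flagged and are counted separately. TAL families reuse the
similarity+MCL machinery restricted to flagged genes, and
`tal_statistics()` reports densities per Mb (replicon length as the
denominator, as in per-megabase tables), occurrence spectra, and
replicon-exclusivity counts with accessory plasmids switchable as a single
class.

## Inter-replicon movement and large translocations

A movement event is a genome-core family absent from the core-replicon of
every main class: some strain carries it on a different replicon than the
rest. The modal member class must be a strict majority; ties are flagged
ambiguous and excluded from counts but listed, since a 2-vs-2 pattern in a
small collection genuinely cannot be polarised. TAL families can be
excluded (movement of mobile elements is a separate question), and a
single-copy-core filter is exposed because both the all-core and the
single-copy-core variant of this analysis are in common use.

Large translocations are called from synteny: maximal exact anchors
(default minimum 65 bp) are chained greedily in query order when colinear
with gaps at most 10 kb on both sides. Block identity counts anchor bases
plus matches inside equal-length inter-anchor gaps — exact under the
substitution-only model, a lower bound otherwise. A region of a query
replicon whose blocks lie, in a majority of reference strains, on a
replicon of a different class is a translocation of that class into the
query's class; events below `min_span` (default 50 kb, separating
multi-hundred-kb events from single-gene movement) are dropped.
`flanking_tal_check()` then asks whether a TAL gene lies within a window
(default 5 kb, a typical IS-element neighbourhood) of each breakpoint.

## Divergence between replicons

For each main class, single-copy core families whose members all lie on
that class are center-star aligned, gap-containing columns removed, and
the per-family blocks concatenated in family order. Pairwise distances use
the Tamura–Nei (TN93) model, distinguishing the two transition types and
transversions with unequal base frequencies; sites with gaps or ambiguous
bases are removed pairwise (not listwise, to keep usable sites), and base
frequencies are pooled over the two sequences being compared. A log
argument at or below zero raises a saturation error naming the pair rather
than returning NaN.

The Mantel test correlates two distance matrices through their lower
triangles and permutes strain labels of the second matrix (10 000
permutations by default); the one-sided "greater" p-value
`(1 + #{r_perm >= r_obs}) / (1 + n_perm)` is the default, matching the
convention of the reference implementation, with a two-sided option.
Neighbour-joining trees (via ape, negatives clamped to zero with a
message) and a covariance PCA of repeat/TAL family counts per replicon
(column-centred, unscaled, component signs fixed by the largest loading)
complete the picture.

## The synthetic generator and what it does (not) emulate

`generate_strain_set()` builds per-class ancestral replicons — genes laid
out with intergenic spacers sampled i.i.d. at the class G+C target — and
derives strains by per-site point substitution. Specific choices:

* **Class G+C targets** default to 62.7 (chromosome), 60.3 (pSymA), 62.4
  (pSymB) and 59.2 (accessory) mol%, the characteristic spread of
  multipartite rhizobial genomes; emitted replicons land within ±0.5 mol%
  of target for replicons of 100 kb and above.
* **Family placement** is class-biased (default 50/25/25 over
  chromosome/pSymA/pSymB), and the probability of a family being core is
  lower on pSymA than on the chromosome or pSymB (multipliers 0.55 vs
  1.15), mirroring the core-poor character of the symbiotic megaplasmid.
* **Non-core families are structurally non-universal**: one strain per
  family never carries it on any replicon. This makes the observed core
  equal the designed core even in small collections, and guarantees
  accessory plasmids carry no core genes.
* **Accessory plasmids** are up to three shared ancestral layouts whose
  gene content is sampled from the non-core pool with a pSymA bias
  (default 0.7), emulating the accessory/pSymA shared gene pool.
* **Mutations are substitutions only** (no indels), and substitutions
  creating an in-frame stop are rejected — a crude stand-in for purifying
  selection that keeps planted coordinates exact and proteins alignable.
  Replacement bases are drawn G+C-biased at the class target so
  composition is stationary.
* `plant_repeat_family()`, `plant_translocation()` and `plant_gene_move()`
  edit the assembled genomes in place, shifting all downstream gene and
  repeat coordinates, and append truth rows; every truth coordinate slices
  back to the stored planted sequence (a tested invariant). The first two
  repeat copies per strain share a replicon so self-comparison can
  discover the family. Translocation windows grow to the nearest
  intergenic positions so genes are never split.

What the generator does **not** emulate: indels and rearrangements other
than the planted ones, recombination, phylogenetic (tree-shaped) descent —
strains are i.i.d. draws from one ancestor — gene gain/loss dynamics along
a genealogy, and realistic repeat-element biology (terminal inverted
repeats, nested elements). Passing parameter-recovery tests therefore
demonstrates algorithmic correctness under the stated model, not
performance on real assemblies; with real data, indel-induced frame
changes, fragmented assemblies and annotation noise will all lower
recovery.

## Problem sizes and tolerances used by the test-suite

The packaged checks run at desk scale by design: the parameter-recovery
configuration is four strains with 300 kb main replicons and one 80 kb
accessory plasmid each at 1% per-site divergence (about 400 genes in ~100
families), carrying five planted single-gene moves and one 100 kb
chromosome-to-pSymB translocation; repeat recovery uses two strains with
30 kb replicons and planted families of 300 bp at 2% and 150 bp at 3%
divergence. Oracle-equivalence checks run MCL against a dense no-pruning
reference on random graphs of up to 12 nodes, self-matching against an
exhaustive diagonal scan on ~2 kb sequences, and chaining against an
exhaustive oracle on 5 kb pairs. Mantel calibration uses 500 independent
8x8 matrix pairs at 199 permutations, whose type-I error must sit inside
the 95% binomial interval around 0.05; TN93 must match the Jukes–Cantor
closed form to 1e-9 in the balanced limit. Published headline counts from
full-scale strain collections (thousands of families across 16 genomes)
depend on the external annotation stack and full-size assemblies and are
not reproduced at this scale.

## Known limitations

* The MEM engine seeds with 24-mers (or the minimum match length, if
  smaller); matches are exact-run based, so alignments across indels are
  represented as chained blocks rather than single gapped alignments.
* Profile scanning assumes the instance length equals the consensus
  length (gapless model); long insertions inside an element split it into
  two instances.
* The greedy synteny chaining is order-based, not optimal-weight DP; on
  pathological anchor sets the decomposition can differ from a
  maximum-weight chain (the tests constrain it to agree with an
  exhaustive oracle on clean cases).
* `gc_tests()` interprets the main-replicon comparisons as paired t-tests
  by strain and uses Welch tests against the accessory class, whose strain
  coverage is unequal; variances are reported in both population and
  sample form because the σ² convention differs between reports, and the
  "main" entry is the mean within-class population variance of the three
  main classes.

## A short worked example

```{r example, eval = FALSE}
sim <- generate_strain_set(
  pan_genome_spec(n_families = 40), n_strains = 3,
  mutation_rate = 0.01,
  replicon_sizes = c(chromosome = 6e4, pSymA = 5e4, pSymB = 5e4,
                     accessory = 2e4),
  n_accessory_range = c(1, 1), seed = 42
)
families <- cluster_genes(sim$genomes$genes)
core_pan_counts(families, unique(families$strain_id))
plot_core_pan_curve(core_pan_curve(families, seed = 1))

tal_ids <- flag_tals(sim$genomes$genes)
tal_families <- cluster_tals(sim$genomes$genes, tal_ids)
tal_statistics(tal_families, sim$genomes$replicons)$exclusivity_counts

aln <- concat_core_alignment(families, sim$genomes$genes, "chromosome")
D <- tn93_matrix(aln)
nj_tree(D)
```

`run_pipeline(pipeline_config(outdir, seed))` chains all stages with
stage-level caching and writes TSV/FASTA/Newick reports; identical configs
and seeds give byte-identical reports.
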