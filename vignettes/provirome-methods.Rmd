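---
title: "Methods: mining and characterising viral sequences from microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterising viral sequences from microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provirome)
```

Microbial genome projects are full of viruses: integrated prophages, but also
circular or large contigs that assemble alongside the chromosome and represent
extrachromosomal prophages, chronic infections, or carrier-state lytic
viruses. `provirome` implements the post-detection analysis of such viral
predictions: curation, genus-level clustering by shared gene content,
taxonomic affiliation, virus–host network modularity, genome-composition
adaptation, composition-based host prediction, and co-infection statistics.
Detection itself (the upstream prediction of viral regions) is out of scope;
the package consumes prediction tables, gene annotations and protein
similarity tables.

## Curation

Predictions are filtered in a fixed order, and each dropped row is logged
with the *first* rule it violates, which makes rejection accounting
reproducible:

1. rows labelled as the PhiX174 Illumina control,
2. category-3 predictions (gene enrichment only, no viral hallmark gene),
3. prophage predictions without a hallmark gene (likely defective prophages),
4. linear sequences < 10 kb — except predictions carrying the
   non-Caudovirales detection tag, where the cutoff is 5 kb because many
   ssDNA viruses have genomes well below 10 kb,
5. circular sequences < 3 kb (likely short repeat regions; the smallest known
   bacterial or archaeal virus genome is ~5 kb),
6. ids on a manual exclusion list. Manual curation is inherently
   non-algorithmic, so it enters only as this input list and is never
   recomputed.

The 5 kb exception keys on the detection tag, not on the final affiliation;
the tag is available for every row at filter time, the affiliation is not.
Plasmid-labelled rows that pass the filters are retained with an
`ambiguous_plasmid` flag rather than dropped: sequences with viral-like gene
enrichment but plasmid annotations cannot be resolved automatically.

Retained sequences are classified by replication mode: prophages are
`integrated`; sequences free of microbial genes are `extrachromosomal` when
circular or > 30 kb (long enough to be a credible complete genome) and
`undetermined` otherwise, since a short linear fragment may come from either
an integrated prophage or an extrachromosomal genome. The 30 kb rule is
deliberately conservative: the fragmentation experiment below quantifies how
the misclassification rate of integrated prophages falls as this threshold
rises.

Enrichment of plasmid partition genes (ParA/ParB) in extrachromosomal
sequences is tested with an exact conditional two-sample rate-ratio test:
conditional on the total marker count, the group-1 count is binomial with
success probability $n_1/(n_1+n_2)$ under equal per-sequence rates, and the
reported p-value is the upper tail $P(X \ge k_1)$. This is the classical
exact construction of the two-sample Poisson ("poisson test") comparison.

## Gene-sharing network and virus clusters

Protein clusters (PCs) are built from an all-vs-all similarity table:
hits are filtered at bit score ≥ 50 and e-value ≤ 0.001, reciprocal best
hits (ties at the maximal score all count as best) define an undirected
graph weighted by the mean of the two directed scores, and Markov clustering
(MCL) at inflation 2 partitions it. The MCL numeric policy is fixed: unit
self loops, column normalisation, expansion by squaring, element-wise
inflation, pruning at 1e-6, convergence when the iterate changes by less
than 1e-8, 100-iteration cap.

Two genomes carrying $a$ and $b$ distinct PCs out of $n$, sharing $c$, are
connected with significance
$S = \max(0, -\log_{10}(P \cdot n_\mathrm{pairs}))$ where $P$ is the
hypergeometric upper tail $\sum_{i=c}^{\min(a,b)}
\binom{a}{i}\binom{n-a}{b-i}/\binom{n}{b}$, evaluated as a log-space sum so
small tails survive, and $n_\mathrm{pairs}$ is a Bonferroni-style correction
by the number of genome pairs. Shared content is presence/absence of
distinct PCs, not copy number, and singleton proteins that never clustered
do not count towards $a$, $b$ or $n$. MCL at inflation 4 on the
significance-weighted genome network yields virus clusters (VCs),
approximately genera; isolated genomes are reported as unclustered rather
than forced into singleton VCs.

Cluster homogeneity is scored by the intra-cluster clustering coefficient
(ICCC): the mean, over nodes of degree ≥ 1, of the fraction of a node's
neighbours sharing its cluster. `sweep_parameters()` evaluates the full
threshold × inflation grid (defaults: thresholds 1–50, inflation 1.5–5 by
0.25) and breaks ICCC ties by lower threshold, then lower inflation, so the
argmax is deterministic.

A VC is a *putative genus* only when at least one member is circular, a
known complete genome, or > 30 kb — otherwise a cluster of short fragments
would be called a genus — and a *new* putative genus when additionally no
member is a reference genome. Note that an alternative reading of the
completeness guard uses "> 30 predicted genes" rather than > 30 kb; the
length rule is implemented here, and at typical phage gene densities
(~1 gene/kb) the two nearly coincide.

## Taxonomic affiliation

Affiliation uses two rules throughout:

* **Strict > 75 % majority**, rank by rank from the top, for affiliating a
  group from its members (reference profiles from their member sequences,
  VCs from their members' affiliations). Members unassigned at a rank stay
  in the denominator — a conservative choice; exactly 75 % fails.
* **LCA over relevant hits** for affiliating a sequence from its genes'
  best reference hits: the relevant set is the absolute best hit plus every
  other gene's best hit scoring > 75 % of that absolute best; the sequence
  takes the deepest rank on which all relevant hits agree. A sequence is
  therefore affiliated only when its best hits are consistent. The result
  is invariant to gene order and to positive rescaling of scores; score
  ties are broken by lexicographic target id.

## Virus–host network modularity

The incidence matrix has one row per VC with more than 10 member sequences
(configurable) and one column per host class; a cell is 1 when at least one
member was detected in a genome of that class. Barber's bipartite modularity
$$Q = \frac{1}{m} \sum_{ij} \left(A_{ij} - \frac{k_i d_j}{m}\right)
\delta(g^r_i, g^c_j)$$
is maximised by BRIM alternation (fix row modules, assign each column to its
Q-maximising module, swap sides) seeded by label propagation on the
bipartite graph. Because BRIM can only coarsen from a poor start, each run
also evaluates a deterministic maximally-fine start (every row and column
its own module) and alternates label-propagation and random initialisations
across the 20 default restarts; the trivial one-module partition is the
floor, so reported Q is never below it. On all matrices up to 5×4 the
search matches an exhaustive-partition oracle (enumerating row partitions
and assigning each column optimally, which is exact because columns decouple
given row modules).

The permutation null shuffles the positions of the $m$ one-cells uniformly
over the grid, preserving fill but not margins, as the plain reading of
"randomly permuted matrices"; empty rows or columns arising in a permutation
are retained so Q stays comparable. A margin-preserving alternative
(curveball swaps via vegan's null models) is available behind
`scheme = "margin"`. The empirical p-value is
$(1 + \#\{Q_\mathrm{perm} \ge Q_\mathrm{obs}\})/(n_\mathrm{perm}+1)$ with 99
permutations by default. (Published analyses of this design report the
permuted-null mean inconsistently as 0.07 or 0.08; the discrepancy is noted
here and not resolved — this package simply reports the computed mean.)

## Genome composition and host prediction

K-mer frequencies (k = 1–4) are counted on the given strand over
overlapping windows; windows containing non-ACGT characters match nothing
and are skipped, and a sequence with no valid window is an error. Counts are
not collapsed with reverse complements by default (`canonical = FALSE`),
since single-strand counting is the common default of k-mer counters; a
`canonical` flag is provided. The distance between frequency vectors is the
mean absolute error (MAE). Codon usage tables give each codon its frequency
within its synonymous family and relative adaptiveness
$w_c = f_c / \max f_\mathrm{synonyms}$; unseen codons in an observed family
are floored at $w = 10^{-3}$ so the geometric mean stays positive, and a
family never observed is uninformative ($w = 1$). CAI is the geometric mean
of $w$ over a gene's codons, excluding stop codons and the single-codon
families Met and Trp, which carry no usage information.

The adaptation experiment compares, per metric, the distribution of
virus-to-host distances with pooled virus-to-non-host distances using the
two-sample Kolmogorov–Smirnov distance $D = \sup|F_1 - F_2|$. Non-host
genomes are drawn per virus: 10 random genomes from the host's genus, 10
from its family, and 10 from a different order ("different order" means
genomes whose order differs from the host's, not exclusion of the whole
order from the pool). Host TNF vectors are computed on the concatenated
genome with integrated prophage regions masked when their coordinates are
known, so a prophage is not compared against a genome that contains it. The
subsampling experiment cuts contiguous fragments of 2–20 kb from viral
genomes and reports mean host and non-host distances per size with the
least-squares slope of distance versus size.

Host prediction assigns each virus the eligible genome with minimal
tetranucleotide MAE (ties broken by lexicographic genome id) under three
exclusion modes — none, leave-species-out, leave-genus-out — and evaluates
accuracy at order/family/genus per distance bin (`d < 4e-4`,
`4e-4 ≤ d < 1e-3`, `d ≥ 1e-3`; closed on the left, open on the right).

## Co-infection

A genome project with ≥ 2 distinct curated viral sequences is a candidate
co-infection. Mis-assembly can split one Caudovirales genome into several
contigs, so a candidate whose sequences are all Caudovirales-affiliated is
counted only when the summed terminase large-subunit copies reach 2 (terL is
single copy in Caudovirales and highly conserved). Whether the terL gate
should also apply to mixed Caudovirales/ssDNA candidates is ambiguous; the
default counts mixed candidates (the mis-assembly argument does not apply
across families), and `terl_gate = "always"` applies the gate everywhere.

## The synthetic world

`generate_world()` builds the ground-truth world every stage is tested
against. Design choices, and what they do and do not emulate:

* **Composition.** Each host group (one host class per viral genus) draws a
  composition signature: amino-acid usage (Dirichlet, concentration 8 over
  20 residues), within-family codon preferences (Dirichlet, concentration
  1.2 per synonym — strong codon bias), and a GC skew $\beta \in
  [-0.45, 0.45]$ multiplying codon probability by $e^{\beta \cdot
  \mathrm{GC}(codon)}$, spanning roughly 40–60 % genomic GC. GC content and
  amino-acid usage are what actually dominate k-mer divergence between real
  genomes. Two host genera nest inside each group as mild perturbations
  (codon Dirichlet concentration 60, amino-acid 400, GC jitter ±0.04), and
  host genomes of one genus share the genus signature. Viral composition is
  the mixture $\alpha \cdot \pi_\mathrm{host} + (1-\alpha) \cdot
  \pi_\mathrm{background}$ with a neutral background; $\alpha$ defaults to
  0.9. ssDNA genera get $0.6\alpha$, reflecting the empirically weaker
  composition adaptation of ssDNA viruses; this also populates the distant
  host-prediction distance bin, where accuracy degrades, reproducing the
  qualitative accuracy-by-distance gradient. At desk scale the full-library
  bin `d ≥ 1e-3` is nearly empty, so that gradient is read across the three
  exclusion blocks pooled.
* **Gene content.** Each viral genus has a protein-family pool (40 families
  for a 30 kb Caudovirales-sized genus, scaled by typical gene count), with
  a core/accessory structure: every member carries a fixed prefix of the
  pool (70 % of its own-pool draw, always including the capsid and terL
  families) plus sampled accessory and global background families (12 % of
  genes). Genus members share a typical genome length ±15 %, as real genera
  do; Caudovirales genera draw 15–50 kb linear genomes at ~1 gene/1.2 kb,
  ssDNA genera 4.5–7 kb mostly circular genomes at ~1 gene/550 bp.
* **Similarity table.** Within-family protein pairs get one conserved bit
  score per family, uniform in [60, 300], e-value 1e-20; across-family hits
  are absent. One score per family (rather than per pair) reflects a
  family-wide conservation level and makes the within-family reciprocal
  best-hit graph a clique — with unique per-pair scores a strict
  reciprocal-best graph is a matching and cannot represent families larger
  than two.
* **Decoys and markers.** 10 % of prediction rows are decoys violating
  exactly one curation rule each (cycling through the six rules), so filter
  outcomes are countable. PhiX contamination is emulated by label.
  ParA/ParB flags are drawn at 13 % for extrachromosomal genomes (circular
  or > 30 kb, non-prophage) and 1 % elsewhere.
* **Scale.** The default world has 8 genera × 4 hosts × 2 viruses
  (64 viral genomes, 100 kb hosts) — large enough for every stage to have
  signal, small enough that the full test suite runs in ~2 minutes. VCs
  then have ~8 members, so the pipeline default for the incidence-matrix
  cutoff is `min_vc_size = 5`, while the function default keeps the
  "more than 10 sequences" rule used at study scale.
* **Not emulated.** Read-level sequencing and assembly (fragmentation at
  random breakpoints replaces them), phylogenetic sequence evolution (gene
  sequences are drawn i.i.d. from composition signatures, so there is no
  within-family sequence divergence), strand structure (all genes are
  forward-strand), tRNA detection, and functional annotation. Passing tests
  therefore demonstrate correctness of the statistics and the recovery
  machinery under the stated generative assumptions, not performance on
  real genomes, where composition signals are weaker and similarity tables
  noisier.

`fragment_genomes()` splits host genomes at random breakpoints into
draft-like contigs with provenance retained; a contig fully inside a
prophage with no host gene is exactly the case that the > 30 kb
extrachromosomal rule can misclassify. Because the set of such contigs
longer than a threshold shrinks as the threshold grows, the
misclassification rate decreases monotonically across 10/20/30 kb — the
package verifies this on 100 seeded fragmentations.

## Determinism and problem sizes

Every stochastic operation takes a seed; the pipeline derives one substream
per stage from a master seed, and identical configs produce byte-identical
output bundles. Tests and the acceptance script run on the default world
(64 viruses), with 99-permutation modularity nulls, 100-matrix exhaustive
modularity comparisons (up to 5×4), 100 seeded fragmentations, and a
10⁶-draw Monte-Carlo check of the hypergeometric tail.
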