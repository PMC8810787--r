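---
title: "Reconstructing ancestral eudicot-like genomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral eudicot-like genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protochrom)
```

# The problem

Early-diverging eudicot lineages carry independent histories of
whole-genome duplication (WGD): single WGDs, two successive WGDs, and the
two-step hexaploidy of the core eudicots in which a third subgenome was
donated to an initial tetraploid. Post-polyploid diploidization then
reshuffles and downsizes these genomes, so a modern chromosome is a mosaic
of ancestral chromosome segments and most duplicated genes survive as a
single copy. `protochrom` reconstructs ancestral gene orders at internal
nodes of a species tree from exactly the data such studies produce --
per-genome gene orders and syntenically validated homolog pairs -- and
provides the downstream genome-history analyses: chromosome painting with
an inter-chromosomal exchange count, syntenic-depth (ploidy-ratio)
profiling, and a topology-consistency scan over the peaks of Ks and
similarity distributions.

# The reconstruction model

**Gene families.** Families are connected components of the homology
graph: any gene homologous to a member of a family is itself a member.
Families with more than `max_copies_per_genome` copies in any single
genome (default 5, enough for a lineage with two rounds of WGD) are almost
always promiscuous repeat-like clusters; they are flagged oversize and
excluded from inference but retained for reporting.

**Generalized adjacencies.** For every pair of genes on the same
chromosome separated by fewer than `w` positions (default `w = 7`, i.e.
windows of seven consecutive genes) we record one adjacency joining the
two *facing* gene ends -- the ends that would fuse if the intervening
genes were lost. Facing ends are resolved by strand, so the
representation survives both fractionation (lost intermediates shrink the
distance) and inversions with breakpoints inside the window (which
preserve the pair but flip reading directions). At `w = 2` this reduces
to the classical immediate-neighbor adjacency.

**Candidates and weights.** An ancestor node of a binary species tree has
three incident branches partitioning the leaves into three subtrees (two
descendant clades and the outgroup side). A family pair observed in
genomes of two or three subtrees is a candidate ancestral adjacency with
weight 2 or 3 -- the number of supporting *subtrees*, not genomes or
occurrences, so a pair seen many times within one clade is still not a
candidate. For the root only two subtrees exist; `root_mode = TRUE`
performs the degenerate two-subtree analysis with weights capped at 2, and
the bundled analyses only reconstruct non-root ancestors.

**Maximum-weight matching.** Each family contributes two protogene ends;
candidates become edges between ends, and an exact maximum-weight matching
(a blossom primal-dual implementation in C++, validated against an
exhaustive dynamic-programming oracle) selects a compatible adjacency set
in which each end is used at most once. Matched edges plus the intrinsic
gene edges decompose into simple paths -- the ancestral contigs -- and
occasionally cycles, which are opened at their minimum-weight join (ties:
the lexicographically smallest family pair).

Two design points here were genuinely open:

* *Edge ports.* Adjacency identity ignores reading direction, but the
  matching edge still needs to connect two specific ends. Connecting all
  four end combinations at full weight ("free ports") lets the optimizer
  pair families into weight-maximal 2-cycles -- two port edges of the same
  pair always outweigh any chain -- and contigs collapse to length 2. We
  therefore anchor each candidate to its *modal observed end pair* across
  all supporting observations. Orientation is thus recorded at extraction,
  ignored for adjacency identity and support counting, and consulted only
  to place the matching edge. Under this rule cycles are rare, matching
  the expectation that contigs are linearly, occasionally circularly,
  ordered. `ports = "free"` remains available for exploration.

* *Tie-breaking by distance.* In any conserved region *every*
  within-window pair is a candidate, typically at weight 3, so matchings
  of equal total weight abound and the optimum is barely above the true
  chain. We resolve this with a secondary criterion: candidates observed
  at smaller modal gene-rank distance win ties. Internally the integer
  matching weight is `16 * support - (modal_distance - 1)` (penalty capped
  at 15), which keeps subtree support strictly dominant per edge. The
  modal (not minimal) distance matters: in fractionated genomes a
  distance-2 pair is often *observed* at distance 1 where the intervening
  gene was lost, but its consensus distance across genomes still exposes
  it. Reported join weights and total matched weight remain on the
  original 2/3 scale.

**Protochromosome assembly.** Contigs are mapped to modern chromosomes
(counts of member families with at least one gene on each chromosome),
rows are normalized to proportions so contig length does not drive
similarity, and complete-linkage clustering of `1 - Pearson correlation`
is cut at exactly `k` clusters (default `k = 7`, the ancestral eudicot
chromosome number; `k` is a user decision, never auto-selected -- the
cut-at-k rule is our declared stopping criterion). Pearson on row
proportions was preferred over Spearman because the rows are sparse and
dominated by zeros. Contigs within a protochromosome are ordered by the
median rank of their families on the best-matching chromosome of a
reference genome, ties by contig id; a contig absent from the reference is
placed last and logged.

# Painting, choppiness and syntenic depth

Painting labels each gene with the protochromosome carrying its family,
optionally smooths labels by sliding-window majority (`smooth_window`,
default 1 = off), and absorbs painted runs shorter than `min_segment`
genes (default 5) into the flanking majority label -- long enough to
suppress single-gene transpositions, short enough to keep genuine
translocated segments. Segments are half-open gene-rank intervals tiling
each chromosome.

The exchange count ("choppiness") is the number of boundaries between
adjacent painted segments with different labels, summed over chromosomes.
Unpainted runs are transparent (a boundary across them counts once if the
flanking labels differ) and chromosome ends are not boundaries, making the
count invariant to whole-chromosome reversal. Whether chromosome
fusions/fissions should additionally count as exchanges is not decidable
from first principles; this boundary-count definition is declared, and is
exactly calibrated on simulations: each reciprocal translocation creates
two boundaries.

Syntenic depth tiles a target genome into bins of `bin` gene ranks
(default 50) and counts overlapping synteny blocks per query genome; the
modal depth over covered bins reads out the query's subgenome number, and
the reciprocal pair of modal depths forms the ploidy-ratio string (a
one-WGD lineage against a three-subgenome hexaploid reads `2:3`). Blocks
may be supplied externally or chained from ortholog anchors (runs broken
at rank gaps above `max_gap = 15` on either genome, kept at `min_anchors
= 5`).

# Peaks and 'Trees in the Peaks'

Ks (or similarity) distributions are summarized by Gaussian kernel density
estimation -- Silverman's rule bandwidth by default, a fixed numeric
bandwidth for exact reproducibility -- and peaks are local maxima whose
basin carries at least `min_mass = 0.05` of the total mass. A peak's
"range" is operationalized as its half-height interval within the basin,
since the source analyses use ranges without defining them. Degenerate
all-equal inputs yield a single zero-width peak; fewer than 30 values is
an error advising pooling.

The topology scan enumerates all rooted binary topologies on the leaves
((2n-3)!! of them; n is capped at 8) and maps each genome pair's *primary*
(highest-mass) peak to the pair's most recent common ancestor. A topology
is consistent iff peaks sharing a node mutually overlap and every
ancestral node *precedes or overlaps* its descendants: greater Ks, or
lower similarity, or overlapping half-height intervals. Paralog (WGD)
peaks are reported but not used as constraints by default, because the
topology argument rests on speciation peaks; `use_paralog_peaks = TRUE`
additionally requires each lineage's WGD peak to be younger than (or
overlap) all nodes above that leaf.

# The simulator: what it emulates and what it does not

`simulate_evolution()` evolves an ancestral genome of `n_chromosomes = 7`
times `genes_per_chromosome = 150` single-copy genes along a species tree
whose branch lengths are Ks units. Per branch, in order: WGDs (doubling),
subgenome additions (the donation step of a two-step hexaploidy -- one
extra copy per family, so the lineage reads three subgenomes in depth
profiles), one fractionation round (each *duplicate-copy* gene born of the
branch's polyploidies deleted independently with the branch's
probability; the resident copy is not at risk), inversions (strand
flipping, lengths uniform on 2..15 genes), reciprocal terminal-segment
translocations, fusions and fissions. Translocation breakpoints are
rejection-sampled to lie inside single-origin territory and to join two
different origins, so each translocation contributes exactly two painted
boundaries -- the property behind the choppiness calibration. All gene
copies are relabeled at every speciation and polyploidy, which keeps the
gene genealogy exact: ortholog Ks is the path length through the species
MRCA and paralog Ks twice the distance from the WGD, both plus truncated
Gaussian noise (`ks_sigma = 0.05`), with similarity `100 * exp(-Ks)`.
Every realized event is logged with its breakpoints and deletions, and
`replay_events()` regenerates all genomes from the log exactly.

`preset_eudicot()` encodes the inferred early-eudicot event map on a
six-leaf clock tree: one WGD on the Buxus-like branch, two successive WGDs
on the Tetracentron-like branch, WGD + donation on the core stem, light
fractionation (0.1) beneath each polyploidy, and two inversions plus one
reciprocal translocation per branch. Those rates give modal family copy
numbers of 2, 4 and 3 and reciprocal syntenic depths of 2:3, 4:3 and 4:2
for the three polyploid lineages -- the observed signature of the real
genomes. Node depths (0.25 to 0.9 Ks) are separated by at least 0.1,
several times the Ks noise, so speciation peaks are resolvable.

The simulator deliberately omits: substitution-rate variation across
lineages (Ks doubles as the branch-length unit, which is what makes
peak-based topology recovery exact by construction), tandem duplication,
gene conversion and homoeologous exchange between subgenomes, biased
subgenome fractionation, missing or mis-assigned homology calls, and any
sequence-level noise in Ks estimation beyond the Gaussian term. Passing
tests therefore demonstrate that the inference machinery is correct under
its own model assumptions -- clock-like divergence, window-survivable
rearrangement scales, unbiased gene loss -- not that real SynMap exports
from fragmented assemblies would reconstruct equally well.

# Numerical and interface choices

* Gene order is the primary coordinate; physical coordinates are 0-based,
  half-open and used only to assign ranks (ties broken lexicographically
  by gene id) and for painting output.
* SynMap export dialects vary; the reader accepts a documented minimal
  column set (`gene_a`, `gene_b`, `ks`, `similarity`, `pair_class`) with
  either value axis optional per row.
* No inference step uses the RNG; matchings are made reproducible by
  sorting edges (weight descending, family pair, port sides), clustering
  by sorting contigs before linkage, and every tie rule is lexicographic.
* Correlation of constant occurrence rows is undefined; identical constant
  rows get distance 0, anything else distance 1.
* Test and acceptance runs use 7 x 150-gene genomes for full-pipeline
  checks and 2-5 x 30-100-gene genomes for focused properties -- sizes at
  which exhaustive oracles (matching enumeration, hand-traceable
  paintings) remain feasible while every code path is exercised.

# Known limitations

Inter-contig orientation is not assigned (contigs are ordered, not
oriented, within protochromosomes); gaps between contigs are not
estimated; candidate weights do not grow with the number of supporting
genomes within a subtree (strictly 2 or 3); and the topology scan is
limited to 8 leaves by factorial growth. Ancestors adjacent to heavily
rearranged branches are intrinsically ambiguous near the rearrangement
junctions: an adjacency created just above or below the node differs by
one branch assignment, and no weighting of two- versus three-subtree
support can separate the two cases.
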