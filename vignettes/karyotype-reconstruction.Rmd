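---
title: "Reconstructing vertebrate karyotype evolution from ohnolog macrosynteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing vertebrate karyotype evolution from ohnolog macrosynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevo)
```

## The model

Two rounds of whole-genome duplication (the 2R events) on the vertebrate stem
doubled every chromosome twice. A chromosome of the pre-duplication chordate
ancestor therefore has up to four homologous descendant chromosomes in a
modern vertebrate genome, and a genome that diverged before the duplications
(an amphioxus-like outgroup) shows the classic 1:4 macrosynteny signature:
orthologs of one outgroup chromosome concentrate on four ingroup chromosomes.
Chromosome fusions before, between and after the two duplications distort
this signature in characteristic ways, and that distortion is exactly what
`karyevo` decodes.

The package works entirely at the level of *chromosome membership* of
orthologous genes -- no gene order, no sequence. Its inputs are an
orthogroup table (the `Orthogroups.tsv` dialect emitted by
orthology-clustering software) and per-species gene position tables (BED-like,
0-based half-open; only the chromosome column is used by the inference).

### Homology by relative ortholog abundance

For each outgroup chromosome (anchor) the package tallies where its orthologs
land in the ingroup genome. With counts $n_c$ on ingroup chromosome $c$, the
relative abundance is $r_c = n_c / \sum_c n_c$. Chromosomes with
$r_c \ge$ `min_fraction` become homology slots, ordered by decreasing
abundance and labelled A--D. Defaults and rationale:

* `max_homologs = 4` -- forced by two duplication rounds.
* `min_fraction = 0.05` -- a slot must carry at least 5% of an anchor's
  placed orthologs; large enough to suppress sporadic translocation noise,
  small enough that a heavily degraded fourth copy (a dot-chromosome-like
  remnant) still qualifies. Exposed everywhere.
* counting mode `"gene"` (one count per ingroup gene per distinct outgroup
  chromosome in the group) rather than `"pair"` (one per ortholog pair):
  per-pair counting inflates large gene families quadratically. Both modes
  are implemented; which one the original analysis used is not documented,
  and on 1:1-dominated tables they agree.
* anchors with fewer than `min_placed = 10` placed orthologs are flagged
  low-confidence rather than dropped, so sparse micro- and dot-chromosome
  anchors stay visible.

### Ancestral linkage groups are maximal cliques

An outgroup chromosome may itself be the product of a lineage-specific
fusion, in which case it carries two ancestral linkage groups (ALGs) and maps
to two 2R quartets. `infer_algs()` separates them by co-occurrence: two
candidate ingroup chromosomes are connected when at least `min_shared = 2`
anchored orthogroups have members on both (copies of one ancestral gene land
only on its own quartet). The ALGs are the *maximal cliques* of this graph,
not its connected components: an ingroup chromosome formed by fusing copies
from two ALGs genuinely belongs to both quartets, and such a chromosome
bridges two otherwise disjoint cliques without making their union a clique.
Clique enumeration is delegated to igraph; candidate sets are small (at most
about eight chromosomes per anchor) so this is never a bottleneck.

An outgroup chromosome containing $k \ge 2$ ALGs is reported as $k - 1$
outgroup-branch (cephalochordate-epoch) fusion events.

### The epoch sharing rule

Each fused ingroup chromosome carries substantial ortholog fractions from two
or more units (ALGs); `detect_fused_chromosomes()` calls a contribution when
a unit supplies at least `fusion_min_fraction = 0.10` of a chromosome's
placed orthologs (unstated in the source analyses; exposed on every
interface). `assign_epochs()` then classifies every co-occurring unit pair
by how many of the four 2R copies share it:

* present in all **four** copies -- the units were joined before the first
  duplication (**pre-1R**); units so joined are merged into pre-1R linkage
  groups, each merge counting one fusion;
* present in exactly **two** copies -- joined between the duplications
  (**post-1R**), provided those two chromosomes can consistently be 1R
  siblings; the partition of each quartet into sibling pairs is chosen
  greedily by decreasing orthogroup support, maximising the number of
  single-event explanations (parsimony);
* present in **one** copy -- joined after the second duplication
  (**post-2R**); per chromosome, pre-1R blocks explained by accepted
  pre-/post-1R events are merged first and every remaining join counts one
  event, so chains of fusions are counted once per join.

Two refinements matter in practice. A pair shared by **three** copies is
pre-1R only when three chromosomes are all either unit occupies (one copy
pair was itself merged by a later fusion); if either unit still occupies four
distinct chromosomes, the pattern decomposes into one post-1R plus one
independent post-2R fusion -- assigning it pre-1R would both misplace the
epoch and miscount events. And fusions joining two copies of the *same* unit
leave no pair signal at all; they surface as a unit whose four copy shares
concentrate on fewer chromosomes (a chromosome carrying about half of a
unit's orthologs), handled per pre-1R group so that co-travelling units are
not double-counted. Three-copy sharing is flagged `ambiguous` in the event
table.

### Count reconstruction

`reconstruct_history()` reverses the inferred events: the chordate ancestor
has one chromosome per unit (equivalently, pre-1R linkage groups plus pre-1R
fusions), and the fixed scaffold pre-1R $\to$ 1R $\to$ post-1R fusions
$\to$ 2R $\to$ post-2R fusions yields every node count by pure arithmetic
(fusion $-1$, duplication $\times 2$). Fusions on branches after the
jawed-vertebrate node (for example the five leading to the large bird
macrochromosomes) cannot be placed automatically from a single
outgroup/ingroup comparison -- that requires additional taxa -- so they are
accepted as user-supplied branch annotations (`lineage_fusions`).

```{r trajectory}
h <- vertebrate_event_history()
cat(render_trajectory(h, c("chordate_ancestor", "pre_1R", "post_1R",
                           "pre_2R", "post_2R", "jawed_vertebrate",
                           "bird_ancestor")))
```

## The simulator

`simulate_history()` is the package's verification instrument: a forward
model whose truth log lets every inference stage be tested without external
data. It emulates:

* an ancestral genome of `n_ancestral_chromosomes` $\times$
  `genes_per_chromosome` genes, each gene founding one orthogroup;
* ordered branch events -- fusions (partners drawn uniformly among extant
  chromosomes) and up to two WGDs -- on the ingroup stem, and fusions only on
  the outgroup branch;
* per-copy gene retention in each ingroup species with probability
  `retention_prob`, optionally multiplied by a per-chromosome weight drawn
  once from `asymmetry_range` (asymmetric sequence loss between duplicated
  chromosomes, the mechanism behind micro- and dot-chromosome gene
  depletion); weights are shared by the ingroup species, modelling bias
  established at duplication time;
* conditioning on orthogroup survival (`min_one_copy`): retention vectors
  are rejection-sampled until at least one copy survives per species, which
  realises the exact conditional Bernoulli distribution -- the quantity the
  retention tests enumerate independently;
* optional translocation noise (`translocation_rate`) moving single genes to
  random chromosomes;
* two ingroup species generated from the same post-2R genome with
  independent loss, to exercise ohnology transfer. Divergence-time realism
  is a non-goal.

The defaults are the reference study conditions: 23 ancestral chromosomes,
six stem fusions, 1R, nine fusions, 2R, five fusions, three outgroup-branch
fusions, two ingroup species. `genes_per_chromosome = 100` is of the order
of the real per-chromosome ortholog yield and gives co-occurrence counts
(about $p^2 G \approx 80$ shared orthogroups per quartet pair) that dwarf
every threshold.

One generator design choice deserves emphasis. Fusion partners are sampled
uniformly, but draws that would make the history *in principle*
unreconstructable from chromosome-level gene content are rejected
(`identifiable_fusions = TRUE`): the same chromosome pair fusing
independently on the outgroup branch and the vertebrate stem produces a
clean 1:4 pattern indistinguishable from no outgroup fusion at all, and two
post-1R fusions joining copies of the same pre-1R pair are indistinguishable
from a single pre-1R fusion. Such histories do occur under unconstrained
sampling (we observed them in roughly a third of unconstrained replicates at
these event densities) and they carry no information about the correctness
of the inference -- they test the data, not the method. The reference
history being emulated is itself fully resolved. Unconstrained sampling
remains available via `identifiable_fusions = FALSE`.

What the simulator does **not** emulate, and what green tests therefore do
not show about real data: sequence evolution and ortholog-calling error
(orthogroups are perfect by construction), gene families (every orthogroup
is single-copy per ancestor), gene order and breakpoint structure,
chromosome arms and centromeres, fissions (the modelled history contains
none), and assembly artefacts. On real tables the thresholds -- not the
algorithmic skeleton -- absorb these imperfections.

## The chromosome-level statistics

* **Tau expression breadth**: for TPM-scale expression $x_1..x_n$ over
  $n \ge 2$ tissues, $\tau = \sum_i (1 - x_i/\max x) / (n-1)$; 0 for
  uniform (housekeeping-like) expression, 1 for single-tissue specificity,
  invariant to rescaling. Computed on linear TPM by default; a
  `log_transform` flag computes it on $\log_2(x+1)$, since the source
  method leaves the scale unstated. All-zero genes are undefined, returned
  `NA` and reported.
* **Interchromosomal Hi-C enrichment**: observed trans contacts $O_{ab}$
  between chromosomes $a, b$ are compared to $E_{ab} \propto T_a T_b$,
  where $T_a$ is $a$'s total trans contacts, rescaled so
  $\sum E = \sum O$ (enforced exactly, tested to $10^{-6}$ relative);
  the result is $\log_2(O/E)$. Cis contacts never enter the marginals --
  whether the original expectation included intrachromosomal totals cannot
  be determined from the methods text, so the trans-marginal model is the
  documented implemented choice. Pericentromeric bins (supplied as a BED
  mask over 40 kb bins) are excluded by default so the statistic describes
  euchromatin; chromosomes left with zero trans contacts yield `NA` pairs
  rather than infinities.
* **Relative ChIP level**: mean ChIP/input ratio over 10 kb windows of a
  repeat class divided by the mean over unique-sequence windows.
* **Amplicon expression**: mean read count across a multicopy gene's copies
  normalised by their total mRNA length.

## Numerical and interface choices

Everything is deterministic given a seed: slot order breaks abundance ties
lexicographically by chromosome name, clique and component enumerations are
sorted, greedy sibling acceptance orders occurrence sets by support and then
lexicographically, and all writers emit UTF-8 with Unix newlines so
identical runs are byte-identical. Degenerate inputs fail loudly: fusions on
a single chromosome, start $\ge$ end coordinates, ragged orthogroup rows
(with line numbers), duplicate group ids, empty profiles, a zero
unique-window mean.

The ohnolog-group count reported in summaries uses "at least three distinct
occupied slots" (`report_min_slots = 3`): the published phrasing "at least
three ohnolog members" is read as three distinct homologous chromosomes, not
three genes, since tandem duplicates on one chromosome are not extra
ohnologs; `count_ohnolog_groups()` takes the threshold as an argument, so
the sensitivity of any count to this reading is one function call.

The supplementary-dataset reader (`read_ohnolog_dataset()`) takes a
column-mapping configuration instead of hard-coded headers, because
externally produced exports vary; it reads TSV directly and XLSX through
readxl.

## Problem sizes used by the test suite

The suite verifies oracle equivalence on simulations of 23 chromosomes
$\times$ 100 genes (about 9,200 genes per ingroup species after loss) --
ten replicates at retention 0.9 and three lossless replicates, a scale at
which every stage is exact and the whole suite runs in about a minute.
Retention statistics are checked against exact $2^4$-outcome enumeration on
a 5,000-orthogroup simulation. These sizes are the package's chosen
trade-off between statistical resolution (three-standard-error bands on all
stochastic checks) and keeping the suite fast enough to run habitually.

## Known limitations

* Fusions joining two 2R copies of the same unit are recovered by the
  copy-share heuristic only when the shares are well estimated; under heavy
  loss (retention well below 0.8) shares drift and such events can be
  missed or mislocated.
* A unit pair fused twice independently in the same epoch pattern is
  unidentifiable from membership data (see the simulator notes); on real
  genomes such events would need gene-order evidence to resolve.
* Epoch assignment presumes exactly two duplication rounds; polyploid
  lineages with further rounds (teleost 3R) are out of scope.
* Placement of post-jawed-vertebrate fusions onto specific descendant
  branches requires more than one ingroup; the pipeline takes them as
  annotations.
* The statistics module computes the defined quantities; it does not
  normalise Hi-C matrices (ICE or otherwise) nor call A/B compartments.
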