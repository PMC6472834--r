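---
title: "Scored taxonomic trees and robust contamination removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scored taxonomic trees and robust contamination removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxclean)
```

## The problem

In low microbial biomass metagenomics — plasma, skin, clean-room and other
oligotrophic samples — the DNA that reaches the sequencer is often dominated
by contamination: the extraction-kit background ("kitome"), reagents, host
material, and crossover between samples processed in the same run. Naively
subtracting every taxon seen in a negative control throws away genuine
signal, because real negative controls are themselves polluted by
low-frequency misclassification, index hopping and crossover from the real
samples. taxclean implements a removal algorithm that grades control-derived
contaminants, and rescues a taxon from removal in exactly those samples
where robust statistics say the sample is the *source* of a crossover rather
than a victim of it.

## Scored taxonomic trees and folding

Each sample is a tree on the NCBI Taxonomy. A node holds the reads assigned
exactly to that taxon (`self_count`, written $n_p$) and their mean
classification score ($\sigma_p$). Before samples are compared at a rank of
interest $k$, each tree is *folded*: recursively, leaves first, a node is
accumulated into its parent when its subtree holds fewer than `mintaxa`
reads or its rank lies below $k$. Accumulating descendants $i = 1..D$
updates the parent score as the weighted average

$$\sigma_p' = \frac{\sigma_p n_p + \sum_i^D \sigma_i n_i}{n_p + \sum_i^D n_i},$$

so two quantities are invariant under folding and asserted in the tests to
1e-9 relative: the total read count and the total "score mass"
$\sum n \sigma$. Folding is idempotent, and raising `mintaxa` can only
shrink the set of surviving taxa.

Worked example: a genus G1 with three species leaves (4 reads @ 60,
2 @ 35, 2 @ 45) folded to genus with `mintaxa = 10` accumulates to
$n = 8$ reads at score $(60 \cdot 4 + 35 \cdot 2 + 45 \cdot 2)/8 = 50$;
still below `mintaxa`, it is absorbed by its family F1 (2 reads @ 100),
giving $(50 \cdot 8 + 100 \cdot 2)/10 = 60$:

```{r fig1}
g1 <- scored_node(20, "genus", 0, NA, list(
  scored_node(31, "species", 4, 60),
  scored_node(32, "species", 2, 35),
  scored_node(33, "species", 2, 45)))
f1 <- scored_node(10, "family", 2, 100, list(g1))
folded <- fold_tree(f1, fold_params(mintaxa = 10, rank_floor = "genus"))
c(count = folded$self_count, score = folded$self_score)
```

Numerical and structural choices:

* **Accumulation order** is strict post-order. Within a sibling batch the
  weighted mean is associative, so sibling order is irrelevant; children are
  nevertheless kept sorted by taxid so every serialization is
  byte-deterministic.
* **The mintaxa test uses the accumulated subtree count**, not the bare
  self count — a parent that has just absorbed its children is re-tested
  with its new total, as the worked example requires.
* **A parent with no reads of its own** enters the weighted mean with
  weight zero; only the accumulating descendants contribute.
* **Unranked nodes** (strains, unranked clades): a node with no rank folds
  upward when its nearest ranked ancestor is at or below the rank floor
  (a strain under a species, folding to species) and survives when it sits
  above the ranked region (e.g. "cellular organisms"). This keeps the
  leaf ranks of a folded tree well defined.
* **Default mintaxa** is the nearest integer (half up) of the decimal
  logarithm of the reads passing the score filter, clamped to at least 1,
  computed per sample; controls may override it independently.
* **include/exclude filters** are applied before folding so removed reads
  never contaminate parent scores. Ancestors connecting the root to an
  included clade are kept as structure but stripped of their directly
  assigned reads, which belong to no included clade.
* The per-taxon profile of a folded tree is the set of nodes with
  `self_count > 0`; those self counts partition the retained reads, so the
  relative frequencies used downstream sum to exactly 1 per sample. (At
  the leaves, where essentially all reads live after folding, self and
  subtree counts coincide.)

## Derived samples

With the first $N$ of $S$ samples being negative controls and $T_{s\to k}$
the taxa of sample $s$ folded to rank $k$, the comparative sets are plain
set algebra:

* CTRL: $T_{s\to k} \setminus \bigcup_n^N T_{n\to k}$ (the robust version
  below replaces this naive difference in the pipeline output);
* EXCLUSIVE: $T_{s\to k} \setminus \bigcup_{m\neq s}^S T_{m\to k}$ — the
  union runs over *all* other samples, controls included;
* SHARED: $\bigcap_m^S T_{m\to k}$;
* SHARED_CONTROL: $\bigcap_{m>N}^S T_{m\to k} \setminus \bigcup_n^N T_{n\to k}$.

Counts for SHARED-type profiles are not dictated by the set equations; the
package uses the minimum count across contributing samples (a conservative
lower bound on co-occurrence) and the unweighted mean of their scores,
switchable to sum/weighted mean. The cross-rank SUMMARY reports each taxon
once, at the most specific rank where it survived, preserving maximal
resolution without duplicating lineage counts.

## Robust contamination removal

Candidates are the taxa observed in any folded control. Each candidate is
graded by its maximum relative frequency across the controls:
`critical` ($\geq 0.1$), `severe` ($\geq 0.01$), `mild` ($\geq 0.001$), else
`other`; candidates absent from every real sample also fall to `other`
because there is nothing to remove. The three named levels are removed from
every real sample unconditionally. The thresholds are defaults of this
package (they are configurable), chosen so that the classic kit analogs in
the packaged mock (human ~0.9, *C. acnes* ~0.07, *M. globosa* ~0.007 of the
control reads) land in the intended groups.

An `other`-level candidate is removed from a real sample *unless* that
sample passes both strict crossover tests on the taxon's relative
frequency $f$:

$$f_{t_s^k} > \mathrm{median}\{f_{t_1^k},\dots,f_{t_S^k}\} + \delta\, Q_n
\qquad\text{and}\qquad
f_{t_s^k} > 10^{\xi} \max\{f_{t_1^k},\dots,f_{t_N^k}\},$$

with defaults $\delta = 3$ (typical range 3–5) and $\xi = 2$ (2–3). The
scale estimator is $Q_n = d\,\{|f_i - f_j|\colon i<j\}_{(m)}$ with
$d = 3.4760$, $h = \lfloor S/2\rfloor + 1$ and $m = \binom{h}{2}$, which
for even $S$ reduces to $\frac{S}{4}(\frac{S}{2}+1)$. $Q_n$ has a 50%
breakdown point, a smooth influence function and works for the asymmetric,
heavy-tailed frequency distributions at hand — the reason it is preferred
over the MAD here. With tens of samples at most, the plain $O(S^2\log S)$
enumeration is used; the only constant is $d$, with no further
finite-sample correction.

Samples passing both tests are the inferred *sources* of the crossover:
the taxon is kept there with counts and scores untouched and removed
everywhere else. An `other` candidate with no passing sample is removed
from all real samples (the `keep_other` switch inverts that one rule for
users preferring the lenient reading). Controls are never modified, removal
never adds taxa nor re-normalizes the survivors, and every decision is
recorded in an audit-trail report. Both tests are monotone: raising
$\delta$ or $\xi$ can only shrink a source set.

## The synthetic study

`mock_design()` encodes the packaged validation study: 3 negative controls
and 5 real samples, including a high-complexity sample with 241 species.
It emulates, with exact designed read counts:

* a dominant host contaminant (human), a severe and a mild kit contaminant
  (*C. acnes*, *M. globosa*), and two sub-mild kit species;
* two crossover species with distinct single sources (*M. mazei* from
  `smpl1`; *M. barkeri* from `smpl3`, scarce in controls and absent from
  one of them);
* a two-strain species (*M. formicicum*): one strain native to `smpl2`,
  the other a mild-level contaminant everywhere. At species rank both
  strains fold together; the species is graded `mild` and removed
  unconditionally, so the native strain is the study's single designed
  false negative — the price of the conservative strategy;
* control noise: the six highest-abundance native species are spiked into
  the controls at 3–7 parts in 10^4 of their source abundance, emulating
  low-frequency misclassification and index hopping. These natives thus
  become removal candidates and must be rescued by the crossover tests in
  their own samples, which is the property the ROC harness checks.

Abundances span 40–16000 reads (four orders of magnitude); every designed
real-sample species carries at least 40 reads so that it survives the
automatic `mintaxa` (4–5 at these sample sizes), keeping the species-rank
truth table exact. Scores are truncated normals per taxon (so `minscore`
filtering can be exercised); read ids encode sample, taxon and serial; the
generator is seeded and byte-reproducible. The design materializes the
spike counts in its abundance matrix, so generated files always match the
design exactly.

What the mock does *not* emulate: sequence-level error models (classifier
output is simulated directly), database incompleteness, abundance noise
between replicates, and the specific species roster of published benchmark
communities (only the 241-species cardinality and role structure are
reproduced). Passing the suite therefore demonstrates the correctness of
the algorithmic chain on designed frequencies, not classifier accuracy on
real reads.

## Evaluation semantics

Sensitivity is the fraction of native taxa retained, specificity the
fraction of contaminant taxa removed, per sample, against the design truth
table. The evaluation universe is the folded raw sample restricted to taxa
at the analyzed rank: reads that cannot resolve to that rank fold into
higher residue nodes (a genus, a domain, ultimately the root), which are
bookkeeping artifacts of the folding, not designed taxa. Absent taxa are
never credited as true negatives. On the packaged mock the removal takes
every real sample from specificity 0 (everything retained) to 1, at the
cost of exactly one false negative in the sample carrying the two-strain
collision.

A note on sweeps: monotone pruning guarantees the evaluation universe
shrinks as `mintaxa` grows, but post-removal retention is *not* monotone —
folding a low-count contaminant out of the controls removes it from the
candidate set, so real samples can retain more taxa at a higher `mintaxa`.
The sweep harness therefore asserts monotonicity of the universe and
determinism of the rest.

## Determinism and problem sizes

Every writer fixes its ordering (children by taxid; stats rows by sample,
descending subtree count, taxid) and its float format (scores with 6
significant digits — hence a round-trip agreement of 5e-6 relative, half an
ulp of the sixth digit — frequencies in scientific notation), and the run
log carries no timestamps, so a pipeline run is byte-identical across
repetitions and worker counts; parsing and per-rank analysis fork with
`parallel::mclapply` when `workers > 1`. The test suite validates the
folding recursion against an independent read-reassignment oracle on
random taxonomies, the $Q_n$ implementation against an exhaustive
pairwise-distance enumeration (1000 random vectors, up to 40 samples,
1e-12 relative), the set equations against naive set algebra on 200 random
fixtures, and the full removal chain on the packaged mock (~315k designed
reads, parsed and analyzed in a few seconds).
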