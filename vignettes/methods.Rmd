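---
title: "Genome-based taxonomic delimitation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based taxonomic delimitation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Prokaryotic taxonomy increasingly rests on whole-genome comparisons rather
than single marker genes. The operational consensus combines a genome-based
phylogeny with pairwise similarity indexes: two genomes are conspecific when
they are monophyletic in the genome tree, show at least 70% digital
DNA--DNA hybridization (dDDH) *and* at least 95% average nucleotide
identity (ANI), and differ by less than one percentage point in G+C
content; congeneric genomes are monophyletic clades whose members share at
least 71% average amino acid identity (AAI). The percentage of conserved
proteins (POCP) with its proposed 50% genus boundary is computed as a
diagnostic but deliberately not used for delimitation: applied to real
genera it routinely conflicts with monophyly, splitting established genera
and merging unrelated ones, which is why this package reports it but
delimits on AAI.

`phylodelim` implements this whole procedure end to end -- similarity
indexes, distance phylogeny with pseudo-bootstrap support, delimitation
with nomenclature-priority name resolution -- plus a simulator that plants
a known taxonomy so every stage can be validated against truth.

# Alignment engine

All indexes consume local alignments (HSPs) produced by a seed-and-extend
engine implemented in C++:

* **Seeding.** Exact k-mer matches against a hashed subject index
  (k = 11 for nucleotides; k = 4 with a two-hit same-diagonal rule for
  proteins). Seeds are clustered by diagonal; clusters below a minimum
  seed count are discarded. For large clusters the alignment band is set
  from the 2%/98% diagonal quantiles so a handful of stray near-diagonal
  seeds cannot widen it.
* **Extension.** Banded affine-gap Smith--Waterman over each candidate
  window (nucleotide +1/-2 with gaps 5/2, legacy BLASTN-style; proteins
  BLOSUM62 with gaps 11/1), followed by x-drop segmentation of the optimal
  local path: the running column score is tracked and the alignment is cut
  wherever it falls `x_drop` below its running maximum, so alignments
  crossing strongly diverged patches break into separate HSPs, as BLAST
  extensions would.
* **Statistics.** Raw scores are placed on a bit scale with fixed
  Karlin--Altschul constants (`pd_constants()`), and
  `E = m n 2^(-bits)`. Only the relative behaviour of the E-value filters
  matters here (1e-8 for whole-genome distances, 1e-5 for the proteome
  search, 1e-15 for ANI fragments, where 30% identity / 70% coverage
  retention does the real work).

The engine is deterministic: ties between equal-scoring HSPs are broken by
`(q_start, s_start)` order, and there is no randomized heuristic anywhere
in the alignment path. Against a full Smith--Waterman oracle on sequences
up to 2 kb the top HSP attains the optimal score when `x_drop` is large,
and its identity tracks the oracle within a point (see `test-align.R`).

The seeding sensitivity bounds what the engine can align: with k = 11
nucleotide seeds and a two-seed cluster floor, homology below roughly 70%
identity is found only patchily, and below ~65% not at all -- adequate
here because every threshold of interest sits far above that, but not a
general-purpose aligner for twilight-zone similarity. The protein search
uses exact k = 4 two-hit seeding rather than BLASTP's neighbourhood
(inexact) seeding; at the divergences relevant to AAI (down to ~40%
amino-acid divergence, where an intact 4-mer survives with probability
0.6^4 per position, i.e. dozens of expected seeds per 300-residue
protein) the two approaches have equivalent sensitivity, and exact seeding
is considerably cheaper.

# Similarity indexes

**ANI** follows the fragment procedure: the query is cut into 1,020-bp
windows (per contig; a trailing window is kept when at least 100 bp -- the
cited procedure leaves the trailer unspecified, and a fixed rule keeps
fragment counts deterministic); each fragment's best HSP against the
reference is retained iff identity >= 30% and aligned length >= 70% of the
fragment; ANI is the mean identity over retained fragments, averaged over
both directions (the pair is canonically oriented first, so
`compute_ani(a, b)` is bitwise equal to `compute_ani(b, a)`).

**AAI** is the mean identity over reciprocal best hits between the two
proteomes under the same 30%/70% retention with E <= 1e-5; the RBH count
is the shared-gene count `S`. **POCP** is exactly `2S/(T1+T2) x 100`,
computed as `200*S/(T1+T2)` so integer-valued cases are exact in floating
point.

**Intergenomic distances** come from the whole-genome HSP set (contigs
concatenated with a 60-N spacer; both strands; E <= 1e-8) reduced by
greedy-with-trimming: HSPs are accepted in descending score order, and a
candidate overlapping already-accepted query or subject regions is trimmed
to its non-covered columns when the overlap is at most half its length and
dropped otherwise. With `I` total identities, `H` total columns and
genome lengths `L1, L2`:

| formula | definition | use |
|---|---|---|
| `d0` | `1 - 2H/(L1+L2)` | coverage diagnostic |
| `d4` | `1 - I/H` | feeds the dDDH transform ("formula 2" style) |
| `d5` | `-ln(I/H)` | tree branch lengths (log-transformed identity) |
| `d6` | `1 - 2I/(L1+L2)` | identity-per-genome diagnostic |

`d4`/`d5` depend only on aligned columns, which makes them robust to
incomplete assemblies (a property the package's incompleteness test
exercises directly). A pair with no HSPs at all gets a configured capped
maximum and a `capped` flag.

**dDDH** is a logistic transform of `d4`:
`dDDH = 100 / (1 + exp(a + b d))`. The coefficients shipped in
`pd_constants()` are this package's own calibration, anchored at
dDDH = 99.9 for identical genomes (`d = 0`) and at the published
correspondence of the two species boundaries, 70% dDDH at 95% ANI
(`d = 0.05` under uniform substitution divergence). They are *not* the
regression coefficients of the Genome-to-Genome Distance Calculator, which
are not reproduced in the literature available to this package; absolute
dDDH values are therefore calibration-specific, while the transform's
monotonicity and its agreement with the ANI species boundary hold by
construction. Users with access to the original coefficients can swap them
in through the constants file without touching any other code.

# Phylogeny

Distance trees are inferred with the balanced minimum evolution criterion
(`ape::fastme.bal`, the FastME algorithm) by default, neighbor joining as
the alternative; negative branch-length estimates are clamped to zero.
Pseudo-bootstrap support resamples each pair's retained post-trimming HSP
set with replacement (same cardinality), recomputes the distance matrix
and re-infers a tree per replicate -- resampling alignment segments rather
than alignment columns, at the granularity the distance is actually
computed from. Support for each internal bipartition is the percentage of
replicate trees containing it (bipartitions are normalized to the side not
containing the alphabetically first taxon, so the counting is
rooting-invariant). Edges with support at or below 50% can be collapsed to
polytomies ("50% or less"); the boundary is deliberately inclusive.

For delimitation the tree must be rooted: with a configured outgroup the
tree is rooted on the outgroup's stem (erroring if the outgroup is not
monophyletic in the unrooted sense); without one, midpoint rooting
(`phangorn::midpoint`) is applied. On the simulated clade sets the deepest
divergence separates genera, so midpoint rooting recovers the intended
root; on real data with a known outgroup, outgroup rooting should be
preferred.

# Delimitation

Both ranks are delimited top-down on the rooted tree: starting from the
root, a clade is accepted as a cluster when *every* leaf pair inside it
passes the rank's criteria, otherwise its children are visited. This
yields maximal monophyletic complete-linkage clusters -- complete linkage
prevents threshold chaining, and clusters are clades by construction so
paraphyletic clusters cannot arise. Species criteria are the conjunction
dDDH >= 70 AND ANI >= 95 AND deltaGC < 1 (an absent value fails); genus
criterion is pairwise AAI >= 71. Species clustering runs inside each genus
clade, so the species partition refines the genus partition structurally;
genomes without a proteome become flagged genus singletons. Because
top-down recursion visits nested clades deterministically, the
"ambiguous refinement" case (a genome passing with two mutually
incompatible groups) cannot occur: the two groups would have to be
overlapping non-nested clades, which do not exist in a tree.

Raising any species threshold can only remove same-species edges, and
complete linkage over fewer edges can only split clusters, so the
delimitation is monotone in its thresholds (tested).

**Name resolution.** Within a cluster carrying two or more names the
retained name is chosen by (1) type-species status, then (2) validly over
effectively published, then (3) earlier publication year, then (4) lower
page rank within the same publication; losers are recorded as later
heterotypic synonyms. Clusters of only unnamed genomes (e.g.
metagenome-assembled genomes, which cannot carry validly published names)
receive placeholders. Two contenders that cannot be ordered (both missing
a year) are flagged `priority_unresolved` for manual curation; the
package never guesses. The "validly over effectively published"
tie-break is this package's addition between the documented rules: it can
only matter when type-species status does not already decide, and it
encodes the Code's preference for validly published names.

**Phyly report.** Each input genus label with two or more genomes is
classified monophyletic (its leaves form a clade), paraphyletic
(non-monophyletic, but every foreign leaf inside the label's most recent
common ancestor is unnamed or enters through a single nested clade) or
polyphyletic (its pieces attach at two or more independent points among
other named labels). The para/poly boundary has no single canonical
formalization; this operational rule reproduces the intuitive examples
(a genus interrupted by one nested group is paraphyletic; a genus whose
members scatter across the tree is polyphyletic) and is validated against
a brute-force clade-enumeration checker on random labeled trees.

# The simulator and what it does (not) show

`simulate_clade_set()` evolves one ancestor down a genus/species/genome
tree. Branch lengths realize pairwise divergence targets per tier; the
defaults -- chosen once as the package's standard study conditions -- are:

| parameter | default | rationale |
|---|---|---|
| structure | 3 genera x 2 species x 2 genomes | smallest set with non-trivial partitions at both ranks |
| genome length | 100 kb | desk-scale; every stage runs in seconds per pair |
| G+C target | 50% | mid-range of typical bacterial genomes |
| nucleotide tiers | 1% / 15% / 25% | species pairs sit safely above 95% ANI; genus pairs well below it; cross-genus pairs remain alignable so tree distances are measured, not capped |
| protein tiers | 1% / 15% / 40% | within-genus AAI ~85 (above the 71 floor), cross-genus AAI ~60-66 (below it), matching the separations reported for real genera |
| indels | 3e-5 /site/branch, mean 3 bp | light realistic indel load; keeps homology maps exact |
| proteome | 500 genes x 300 aa, 90% sharing within genus | POCP in the 90s within genera, like real congeners |

Substitution fractions are realized targets, not rates: the truth oracle
(`truth_index()`) recomputes each pair's divergence directly from the
simulation's homology maps (per-site coordinate tracking through indels),
so estimator-recovery tests compare against exact truth rather than a
parametric expectation. Proteins are simulated directly rather than
translated from the genome, deliberately decoupling AAI/POCP validation
from gene calling, which is outside this package's scope (proteomes are
an input).

What passing these tests shows: the estimators are unbiased to within
their stated tolerances on sequences whose divergence is dominated by
substitutions with light indels, and the delimitation logic recovers a
planted partition whose tier separations mirror published between-rank
gaps. What it does not show: robustness to rearrangements, horizontal
transfer, repeat families, contamination or heavy assembly
fragmentation -- real genomes have all of these, and the indexes (not this
implementation specifically) are known to degrade under them. The
simulator's `SimulationParams` expose the dials to probe milder versions
of such conditions (e.g. contig splitting, lower shared-gene fractions).

# Numerical and procedural choices

* Problem sizes in the test-suite: unit tests run on 5-30 kb genomes and
  tens of genes; estimator-recovery and pipeline-recovery checks use the
  standard 100-kb/12-genome preset (10 seeds).
* Canonical pair orientation (lexicographically smaller id as query)
  makes ANI and the whole-genome HSP set exactly symmetric rather than
  symmetric-in-expectation.
* The whole-genome banded alignment holds an O(length x band) traceback;
  at desk scale (100 kb x ~150) this is ~15 MB, but multi-megabase
  genome pairs would need a linear-space (Hirschberg) variant that is not
  implemented.
* All pipeline randomness (only the pseudo-bootstrap resampling and the
  simulator) flows from the single configured seed; equal seeds give
  byte-identical artifacts, which the test suite asserts.
* Degenerate inputs: an all-ambiguity genome has undefined G+C (error,
  and `NA` within a batch); unrelated genomes yield absent ANI and a
  capped distance rather than a fake number; empty HSP resamples keep the
  cap in every bootstrap replicate.
* `collapse_low_support` contracts edges by marking them zero-length and
  delegating to `ape::di2multi` after shifting genuine lengths, avoiding
  hand-written edge-matrix surgery.

# Reproducing a run

```{r example}
library(phylodelim)
sim <- simulate_clade_set(sim_params(seed = 1))
dir <- tempfile()
write_clade_set(sim, dir)
cfg <- pipeline_config(file.path(dir, "samples.tsv"),
                       file.path(dir, "out"),
                       replicates = 100, seed = 1)
state <- run_pipeline(cfg)
read.delim(file.path(dir, "out", "clusters.tsv"))
```

Each step writes a manifest of input checksums; rerunning skips completed
steps, and editing any input (even one base) triggers recomputation of the
affected steps only.
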