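---
title: "Inferring gene gain and loss in giant virus genomes under the accordion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene gain and loss in giant virus genomes under the accordion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvaccordion)
```

## The scientific question

Giant viruses (Mimiviridae and Phycodnaviridae, order Megavirales) carry
genomes of hundreds of kilobases to more than a megabase. Whether such
gigantism arose by progressive reduction of a cellular-like ancestor or by
expansion of a simpler virus is debated. The *accordion model* proposes a
third reading: these genomes neither steadily grow nor steadily shrink, but
cycle through expansions (gene duplication, lateral gene transfer, insertion
of mobile genetic elements) compensated by contractions (gene loss,
mobile-element excision), with no net directional trend.

`gvaccordion` implements the comparative-genomics machinery needed to test
that picture on clusters of closely related genomes:

1. a **simulator** that evolves annotated gene orders and marker sequences
   along a phylogeny under the accordion model, with a replayable
   ground-truth event log;
2. **positional homology**: anchor detection and collinear block chaining,
   variable-segment extraction, ORF finding, translocation detection;
3. **event inference**: copy-number parsimony on a whole-genome tree, with
   an equal-parsimony ambiguity rule and the gain/loss classification rules;
4. **marker divergence**: conserved-column filtering, marginal ancestral
   reconstruction under Jukes–Cantor, percent identity to the group
   ancestor as a relative clock;
5. **statistics**: per-genome event tables, the events-per-kb
   molecular-clock regression, mobile-element fractions, paralog-family and
   terminal-hotspot statistics.

## The inference model

### Copy-number parsimony

For each gene family the observed data are copy numbers at the tips of a
rooted whole-genome tree. Ancestral states are integers $0..C$ and a branch
from state $a$ to state $b$ costs $|a-b|$ — each unit of copy change is one
genomic event. A Sankoff-style dynamic program computes, per family:

* the minimum total cost over all ancestral labelings;
* the exact number of co-optimal labelings (a second DP pass with counts);
* for every node, the set of states realised in at least one co-optimal
  labeling, via the standard "cost below + cost above = optimum" criterion.

The signed change on a terminal branch is the tip count minus the parental
state. When co-optimal labelings disagree about that change, the family is
recorded as **ambiguous** on that branch, never typed: equally parsimonious
scenarios must not be resolved arbitrarily. Because the cost is linear,
every optimal labeling lies inside the observed copy range, so the state
space is truncated at the largest observed count without changing either
the optimum or the co-optimal count; `max_copy` (default 20) is only a
sanity cap, and observed counts above it raise an error.

### Classifying the changes

An unambiguous terminal change $\Delta$ is typed as:

| change | parental copies | family flag | event |
|---|---|---|---|
| $\Delta > 0$ | $\ge 1$ | any | duplication |
| $\Delta > 0$ | $0$ | MGE | insertion |
| $\Delta > 0$ | $0$ | donor-labelled | lgt |
| $\Delta > 0$ | $0$ | orphan candidate | orphan |
| $\Delta > 0$ | $0$ | none | ambiguous (unknown origin) |
| $\Delta < 0$ | — | MGE | excision |
| $\Delta < 0$ | — | other | loss |

One event record is emitted per unit of change. Orphans have no homolog
anywhere, so their origin cannot be polarised; following the accounting of
the published per-virus table they are reported inside the
unknown/ambiguous column (with the orphan subset alongside) and are never
counted as gains. Events on internal branches are computed by the same DP
but not emitted into the per-virus table, which by construction counts only
what happened after each genome diverged from its group's ancestor.

A gain from zero parental copies in a family that carries no flag but has
homologs elsewhere in the set cannot be attributed to duplication, transfer
or orphan genesis from copy numbers alone; it is reported as ambiguous
(unknown origin) rather than guessed.

### Translocations

Copy-number profiles are blind to position, so translocations are detected
from synteny. Anchors are families single-copy in both genomes of a pair;
collinear blocks are maximal strictly monotone runs of anchor positions
(longest-increasing-subsequence chaining, with decreasing runs reported as
inverted). `detect_translocations()` reports anchors outside every block —
displaced genes with conserved copy number.

Across a set of $n$ genomes, `infer_translocations()` classifies each
anchor by whether it lies in **every** maximum-length chain, in **some**
but not all (a tie: an adjacent swap cannot tell which of the two genes
moved), or in **none**. The pairs in which a family is anomalous are
collected; the family is attributed to the genome common to all anomalous
pairs, as a translocation when it is fully displaced in every comparison
involving that genome and as ambiguous otherwise (ties, or moves across
non-anchor genes, which weaken the signal in some pairs). Conflicting
anomaly patterns are flagged ambiguous on the most-implicated genomes
rather than typed.

### Marker divergence

Four taxonomic markers (DNA polymerase, A2L transcription factor, D5
primase–helicase, packaging ATPase) are carried as a concatenated
nucleotide alignment. Columns are filtered with a two-criterion
conserved-block rule (gap fraction, majority-residue frequency, minimum run
length — defaults 0, 0.5, 10). The root sequence is reconstructed by
marginal posterior under Jukes–Cantor with Felsenstein pruning;
ties take the fixed base order A < C < G < T. Percent identity of each tip
to that reconstruction, over retained columns and excluding gaps, is the
relative clock on the x-axis of the events-per-kb regression. Jukes–Cantor
was chosen because the reported statistic is coarse (integer percent) and
the model admits closed-form expectations that the tests exploit
($\mathbb{E}[\text{identity}] = \tfrac14 + \tfrac34 e^{-4\mu t/3}$); the
transition-matrix code is isolated so a richer model can be slotted in.
Note one caveat measured by the tests: the maximum-posterior reconstruction
is slightly attracted to the tip consensus, so tip-to-reconstruction
identity sits a fraction of a percent above tip-to-true-root identity.

### Trees

Whole-genome trees are neighbor joining (via the `ape` package) on
$d = \alpha\,(1-\text{Jaccard on family presence}) + (1-\alpha)\,p$
with $\alpha = 0.5$ and $p$ the marker p-distance, rooted on the branch to
a designated outgroup — each virus group is rooted with its nearest
neighbouring group. NJ in `ape` is deterministic, and tiny negative branch
lengths are clamped to zero.

## The simulator as a stated world

`accordion_config()` fixes the world the tests live in:

* **Root genome**: 100 genes by default; 8 paralogous families of 4 copies
  (so members have at least three additional representatives, the
  multigene-family threshold of the context statistic), 3 mobile-element
  families of 2 copies, the rest single-copy. Gene lengths are gamma with
  mean 900 nt (minimum 300 nt, the ORF/segment filter), spacers 200 nt.
  Family copies are scattered uniformly along the genome.
* **Events**: per-branch counts are Poisson(rate × branch length), applied
  in uniform random time order — equivalent to a Gillespie scheme for
  constant rates but testable against closed forms. A duplicated copy
  inserts adjacent to its template with probability 0.5, else uniformly.
  Losses and excisions remove one gene; translocations move a single-copy
  gene to a different position; LGT and orphan genes found new families
  (donor labels drawn from a configurable weight table over bacterial,
  eukaryotic-host, other-eukaryote and viral sources).
* **Presets** encode the group-specific signatures of the published
  21-genome comparison, scaled so one unit of branch length reproduces each
  group's mean terminal-branch event counts: duplication/loss dominance
  with strong terminal bias (`positional_bias = 0.8`) for mimivirus- and
  megavirus-like genomes, LGT dominance with no mobile elements for
  Ostreococcus- and Micromonas-virus-like genomes, and active
  insertion/excision for Chlorella-virus-like genomes. No absolute rates
  per year exist in the source data; only the ratios are meaningful, and
  the simulated genomes are an order of magnitude smaller than the real
  1-Mb genomes for test economy.
* **Markers** evolve site-independently under Jukes–Cantor on a separate
  4 × 1000 nt concatenated alignment, untouched by genomic events: marker
  divergence is purely a clock proxy.
* **Determinism**: the seed makes every output byte-identical; the event
  log carries all random choices, so replaying it from the root genome
  reproduces each tip exactly (a tested invariant).

What the generator does **not** emulate: nucleotide-level rearrangement
breakpoints (coordinates are re-laid out with fixed spacers), genome-wide
sequence evolution (gene/genome sequences are optional), inversions of
whole blocks, within-branch rate variation, and gene length change. A green
recovery test therefore establishes that the inference machinery is correct
on annotated gene orders, not that a full alignment pipeline on raw genomes
would be.

### Identifiability

Terminal-branch parsimony cannot be exact for arbitrary event histories.
Two non-obvious failure modes matter:

* a tip attached directly to the root has no anchored parent, so every
  event on it ties with the sister branch (the reason the published groups
  are rooted with an outgroup); recovery experiments therefore use trees
  whose root children are both internal;
* the same family hit on two sister terminal branches (e.g. parallel
  losses) is more parsimoniously explained by one internal-branch event —
  a unique optimum, so no ambiguity flag is raised and the terminal events
  are silently absorbed. A per-branch "at most one event per family" rule
  does **not** exclude this.

The simulator therefore exposes an `identifiability` switch: `"none"`
(free), `"branch"` (no family hit twice on one branch), and `"tree"` (no
family hit twice anywhere). Only `"tree"` guarantees that every terminal
truth event is recoverable or explicitly flagged ambiguous, and that is the
regime the recovery tests assert: across 100 simulations per preset, every
unambiguously typed family must match the truth, and every miss must carry
an ambiguity flag. In the same spirit, mobile-element insertions in the
identifiability modes always found a new family: re-insertion of a resident
family raises its copy number, which copy-number parsimony correctly — but
confusingly for a truth comparison — reads as a duplication.

## Numerical and accounting choices

* Coordinates are 0-based half-open; the source material states no
  convention. Genome sizes are carried in kb; conversion to nucleotides
  rounds half away from zero.
* Variable segments must be strictly longer than `min_len` (default 300 nt,
  the published filter) and contain an ORF; with no sequence attached, one
  fully contained annotated gene stands in for the ORF requirement (the
  published rule does not say which was used). ORFs are ATG-to-stop spans,
  all six frames, span ≥ 300 nt, `N` matching nothing.
* Summary accounting: `total_gain = duplication + lgt + insertion`,
  `total_loss = loss + excision`, `genomic_events = total_gain + total_loss
  + unknown + translocation`; orphans live inside `unknown`. Column totals
  are always recomputed from rows. Two rows of the bundled transcription of
  the published table were internally inconsistent as printed (components
  not summing to their printed totals); they are repaired minimally, in the
  direction supported by the printed column totals, and the repairs are the
  only departures from the printed values.
* The clock regression is plain OLS of events-per-kb on the integer
  percent identities as printed; $r^2$ is the squared Pearson correlation.
  Rounding (e.g. the 23% Chlorella mobile-element fraction) happens only at
  report time, half away from zero.

## Known limitations

* Donor attribution of transfers comes from annotation (simulator labels);
  single-gene phylogenies against reference databases are out of scope.
* The translocation attribution rule assumes most comparisons are
  informative; histories dense in rearrangements will push families into
  the ambiguous class rather than mistype them.
* Presence/absence-only data lose duplication information; the copy-number
  DP subsumes the presence/absence analysis (cap the matrix at 1 to get it).
* Real-genome workflows (alignment, ORF calling on raw sequence, homology
  search) are represented by stand-ins operating on annotated gene tables.

## A worked example

```{r example, eval = FALSE}
tree <- ape::read.tree(text =
  "((A:0.1,B:0.1):0.1,((C:0.1,D:0.1):0.1,(E:0.1,F:0.1):0.1):0.1);")
cfg <- accordion_preset("chlorella_like", seed = 42, identifiability = "tree")
sim <- simulate_accordion(cfg, tree)
res <- run_accordion_pipeline(sim$genomes, markers = sim$markers,
                              tree = sim$tree,
                              marker_rate = cfg$marker_sub_rate)
res$summary
glance(res)
autoplot(res$regression)
plot_event_map(res$events, sim$genomes)

# and the published-table surface:
reproduce_table1()
```
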