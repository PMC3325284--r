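---
title: "Finding variable plastome markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding variable plastome markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cphotspot)
```

## The problem

Chloroplast genomes evolve slowly, and at low taxonomic levels —
congeneric species, recent radiations — most of the classical loci are
nearly invariant. What variation exists clusters in mutational hotspots.
Given complete plastomes for two or more species of a genus, those
hotspots can be located directly: align the genomes, slide a window
along the alignment, and keep the windows that are unusually
polymorphic. Repeating this over many genera and intersecting the
results yields loci that are variable *and* broadly available — the
properties a species-level phylogenetic marker or DNA barcode needs.
`cphotspot` packages that comparative procedure end to end, together
with a simulator that generates congener-like alignments with known
truth, so every stage is testable without any external genome.

## The scan

For each genus one aligned set of congeneric sequences is scanned on
**alignment coordinates** (windows are then well defined across all
sequences simultaneously; a scan on ungapped reference coordinates would
make windows sequence-specific). Defaults: window $W = 600$ bp — the
typical usable length of one Sanger read, hence of one barcode — and
step $s = 50$ bp, small enough to position a hotspot to within one step.
A trailing stretch shorter than $W$ is not scanned rather than shrunk,
because $S$ scales with analyzable length and a short window would not
be comparable. Per window the scan reports:

* $S$ — segregating sites: retained columns with ≥ 2 distinct residue
  states among non-missing characters;
* $\pi$ — nucleotide diversity per site,
  $\pi = \frac{2}{n(n-1)} \sum_{i<j} d_{ij}/L_{ij}$, the mean proportion
  of differing sites over sequence pairs;
* indel events — maximal gap runs, counted once even when identical runs
  are shared by several sequences, assigned to windows by their first
  gap column so that each event is counted exactly once per tiling
  position;
* inversion events — re-oriented segments recorded by
  `apply_inversions()`.

**Missing data.** Two site-deletion policies are exposed, because the
treatment of gapped sites in the upstream literature of this procedure
is implicit in the software that was used rather than stated. The
default, *complete deletion*, drops a column from a window if any
sequence has a gap or IUPAC-ambiguous character there (ambiguity codes
are retained at load but treated as missing throughout: calling them
states would manufacture polymorphism). *Pairwise deletion* keeps all
columns and filters per sequence pair inside the $\pi$ computation, so
$L_{ij}$ differs between pairs. Under complete deletion and $n = 2$,
$\pi \cdot L = S$ exactly — a property the test suite checks on every
window of a simulated 30 kb pair.

A window in which no pair has any analyzable column has **undefined**
$\pi$ (reported `NA`, excluded from summaries), never 0: zero would fake
perfect conservation.

**Inversions.** Minute inversions in fast-evolving spacers look like
dense substitution clusters if scanned as-is. They are therefore
declared by the analyst (a 4-column TSV: sample, start, end, note — the
package does not attempt auto-detection, whose criteria would be
arbitrary at these scales) and separated by `apply_inversions()`, which
reverse-complements the declared segment in place among residue
positions. The operation is an involution, counts once per declaration
toward the per-window inversion indicator, and is applied before any
statistic is computed.

## Hotspot loci

Windows qualify when $S > \bar S + k \cdot \mathrm{sd}(S)$ with $k = 2$
by default; the inequality is strict, and the standard deviation is the
sample (n−1) estimator — the conventional choice; it is isolated in
`summarize_profile()` if a different convention is wanted. Qualifying
windows that overlap, or are separated by at most one step (`max_gap`,
default = step), merge into one locus. Unlimited merging would be wrong
— one long gene can host two genuinely distinct variable regions, which
must surface as `-a`/`-b` sub-loci — while zero tolerance splits loci on
one-window staircase artifacts; one step is the narrowest bridge that
fixes the latter.

Loci are then mapped through the reference row's gap structure onto
ungapped reference coordinates and classified by **majority (≥ 50 %)
overlap**: `coding` (named by the gene), `intron` (named
"`<gene> intron`"), `intergenic_spacer` (named "`<left>-<right>`" in
genome order), else `mixed`. Mixed loci are named by the dominant
overlapped feature alone: appending flank qualifiers would make the name
depend on locus extent, and cross-genus matching (below) requires names
that are stable against ±1-window boundary noise. tRNA names carry their
anticodon (`trnS^UGA^`) only when the bare name is ambiguous within the
annotation — paralogous tRNAs are the one case where the bare name
misleads.

## Cross-genus intersection

Plastome coordinates are not comparable between genera; annotation-
derived names are. The shared-locus table therefore matches loci across
genera by exact name (anticodon-aware). Loci present in fewer than
`min_genera` = 3 genera are excluded; the cumulative breakdown (present
in ≥ 1, ≥ 2, … genera) is always reported so the narrowing of the
candidate list is visible. Survivors are ranked by genus count first —
a marker that is variable in many genera is the broader tool — then mean
$\pi$, then name, giving a deterministic order. A locus variable in
genus A that only partially overlaps its namesake region in genus B
still matches: name identity is the working definition of homology here,
and its limits (differently annotated or renamed genes across annotation
vintages) are accepted rather than papered over with coordinate
heuristics.

## Primer design

Candidates are substrings of *conserved runs*: maximal blocks of flank
columns (up to `flank_span` = 400 bp each side of the locus) in which
every sequence carries the same unambiguous residue. Universality is
therefore by construction — zero mismatches against every input genome —
and degenerate bases are never emitted. Screening uses length 18–27 nt,
GC fraction 0.30–0.75, Tm 50–65 °C, homopolymer runs ≤ 4, with a missing
3′ G/C clamp flagged but not fatal. The length bounds and the GC window
are calibrated against a published set of universal plastome primers
(19–27 nt; GC up to 14/19 ≈ 0.74), which is why the GC ceiling sits at
0.75 rather than a textbook 0.70. Tm uses the basic GC formula
$T_m = 64.9 + 41\,(n_{GC} - 16.4)/L$ — parameter-free, adequate for
ranking candidates that are amplified at a single fixed annealing
temperature in practice; nearest-neighbor thermodynamics is out of
scope. Pairs must bracket the entire locus with a product of
300–2500 bp (what a standard 2-minute extension amplifies) and a Tm gap
≤ 5 °C, ranked by Tm gap then product length. When flanks are long and
perfectly conserved the candidate pool is capped at the 300 candidates
per side nearest the locus before pairing — a deterministic cut that
cannot remove the shortest-product optima the ranking prefers.

## Parsimony and resolution

The case-study engine answers "does this locus separate all the
species?" for desk-scale groups. For 4–9 taxa every unrooted binary
topology — $(2n-5)!!$ of them — is enumerated and scored with Fitch
parsimony (bitmask implementation, pattern compression; gaps and
ambiguity are wildcards, the conventional default, so they never force a
change). Exhaustive scoring is exact, which beats emulating any
particular heuristic search. Neighbor joining runs on uncorrected
p-distances with pairwise deletion: at congeneric divergences
(π ≪ 0.05) a model correction would not move the topology, and
deterministic first-minimum tie-breaking in the Q-scan keeps results
reproducible. Bootstrap consensus resamples columns with replacement;
in maximum-parsimony replicates every co-optimal tree contributes
$1/\text{ties}$ credit to its splits — deterministic and unbiased,
instead of picking one arbitrary tie — and NJ replicates collapse
internal branches of length ≤ 0 before split counting, so invariant data
yield a star rather than spuriously supported resolution. Splits above
50 % form the majority-rule consensus; the resolution metric is the
number of internal edges recovered out of the maximum $n-3$, and a group
is "solved" when all $n-3$ are present.

## The simulator

`simulate_genus()` emulates exactly the features the scan must cope
with, in ancestral coordinates so the emitted alignment is the *true*
alignment (no realignment stage exists to confound the tests):

* **Substitutions** under Jukes–Cantor on a star phylogeny: each taxon
  diverges independently from the ancestor by
  `background_branch_length` $t_b$ = 0.002 substitutions/site (a
  typical congeneric plastome background), applied as the exact
  single-branch transition probabilities, so two taxa differ with the
  closed-form probability
  $p = \tfrac34\left(1 - e^{-4(2t_b)/3}\right)$ — the oracle used in the
  recovery tests. A star is sufficient because window statistics see
  only pairwise divergence, and congener sets here number 2–4 taxa.
* **Hotspots**: 6 intervals of 800 bp at multiplier $f$ = 10, placed
  alternately centered on genes and on intergenic gaps (both contexts
  are represented), at least ~2 windows apart — closer hotspots would
  be unresolvable as distinct loci by any 600 bp scan.
* **Indels**: Poisson events (2×10⁻⁴ /site/branch) of geometric length
  (mean 4 bp) deleted from single taxa; events never overlap one
  another or the special tracts, keeping the true alignment well
  defined.
* **Microsatellites**: (AT)$_n$ tracts with taxon-specific repeat
  numbers (5–8 units), the stutter pattern that makes these tracts
  indel-rich in real spacers.
* **Inversions**: small (30 bp) segments reverse-complemented in one
  taxon; the matching declaration (ungapped sample coordinates) is
  emitted in the truth table, and the pipeline separates them before
  scanning — mirroring the analyst's workflow.
* **Annotation**: `gene_count` = 40 genes tiling the 30 kb genome in
  equal slots (genes occupy the middle 60 % of each slot; every fifth
  gene carries an intron). Genome length 30 kb rather than a full 130 kb
  plastome keeps the full test suite inside minutes while leaving ~590
  windows per scan; nothing in the code depends on the length.

A `layout_seed` separate from the evolution seed lets several simulated
genera share one annotation layout and hotspot placement — the
cross-genus tests use this so shared loci carry comparable names, with
`private_hotspot_count` extra hotspots drawn per genus from the
evolution seed.

What the simulator does **not** emulate: the quadripartite IR/LSC/SSC
plastome architecture, realistic gene content and lengths, codon-aware
or among-site rate variation beyond the hotspot dichotomy, alignment
error (the emitted alignment is true by construction), base
composition bias, and recombination. Passing tests therefore
demonstrate the correctness of the statistics and the selection logic
under a clean model — not that real plastome alignments are free of
alignment artifacts, nor which real loci are best; the latter depends
on the genomes analyzed.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 8–30 kb simulated
genomes; 20 replicates for the hotspot recovery check (recall ≥ 0.9,
precision ≥ 0.8 against the planted truth); a three-genus toy
(8 genes, 4 shared + 2 private hotspots at $f$ = 20, stronger than the
default so the cross-genus *rule* is tested rather than detection
sensitivity at threshold); 200 bootstrap replicates on an 800-column
7-taxon matrix with per-edge substitution probability 0.05 for the
resolution case study. Floating-point comparisons of π use tolerance
10⁻¹²; window statistics are compared to brute-force oracles exactly.
The tie-break conventions (first minimum in row order for NJ, start-
then-length candidate order for primers, lexicographic name order in
rankings) exist solely to make every output deterministic under a fixed
seed — `run_discovery()` reproduces byte-identical run directories, and
that is itself a tested contract.

## Known limitations

* Cross-genus locus identity is nominal; structural rearrangements or
  divergent annotation practice across genera break matching silently.
* The 50 % category rule makes a locus's *category* (not its interval)
  sensitive to extent changes near the threshold; names of borderline
  loci spanning a gene and its surroundings can differ between genera.
* The GC-formula Tm is a ranking device, not a thermodynamic
  prediction; primer candidates are not screened for hairpins, dimers
  or off-target binding.
* Exhaustive parsimony stops at 9 taxa by design; larger case studies
  need a heuristic search tool.
* The threshold mean + 2·sd adapts to each genus's own variability; in
  a genus where hotspots occupy a large fraction of the genome the
  elevated mean/sd make the rule conservative.
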