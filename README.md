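# cphotspot

Discovery and evaluation of highly variable chloroplast (plastome) markers
from aligned congeneric genomes.

Plant phylogenetics and DNA barcoding at low taxonomic levels — closely
related species, recently diverged groups — suffer from the slow
evolution of the standard chloroplast loci: most candidate regions carry
too few informative sites. The limited variation that does exist is
concentrated in a small number of mutational hotspots. `cphotspot`
implements, as a tested and reproducible pipeline, the comparative
scanning strategy used to find such hotspots in congeneric plastome
alignments:

1. **Sliding-window scan** of each genus's alignment: per-window
   segregating sites *S*, nucleotide diversity per site
   *π* = 2/(n(n−1)) · Σ_{i<j} d_ij/L_ij, and indel/inversion event counts,
   with DnaSP-style complete- or pairwise-deletion treatment of gapped and
   ambiguous sites. Defaults: 600 bp windows (the typical DNA-barcode
   length) advancing in 50 bp steps.
2. **Hotspot selection**: windows with *S* > mean + 2·stdev of the
   profile, merged into loci, mapped onto the reference annotation and
   named the way the field names variable plastome regions — gene names
   for coding loci, `clpP intron`-style names for introns,
   `trnH-psbA`-style names for intergenic spacers (anticodon-suffixed
   tRNAs where paralogs are ambiguous), `-a`/`-b` suffixes when one gene
   hosts two disjoint hotspots.
3. **Cross-genus intersection**: loci are matched across genera by
   annotation-derived name; loci found in fewer than three genera are
   excluded, survivors ranked by breadth and mean π.
4. **Universal primer design** from conserved flanks: primer candidates
   are substrings of alignment columns identical in every sequence, so
   every primer matches every input genome exactly; screening by length
   (18–27 nt), GC (0.30–0.75), Tm (50–65 °C; Tm = 64.9 + 41(nGC − 16.4)/L)
   and homopolymer content, pairs ranked so the product brackets the
   entire locus.
5. **Resolution case study**: exact Fitch parsimony over all (2n−5)!!
   unrooted topologies (4–9 taxa), neighbor joining on p-distances, and
   bootstrap majority-rule consensus with support values — the machinery
   to ask whether a locus, or a combination of loci, separates all the
   species of a small group.

A sequence-evolution simulator (Jukes–Cantor background with planted
rate hotspots, single-taxon indels, (AT)n microsatellites, small
inversions, and a matching gene/intron/spacer annotation) generates the
congener alignments the pipeline is tested against, with a truth table
for every planted feature.

## Worked example

```r
library(cphotspot)

cfg <- sim_config(seed = 42, n_taxa = 3)      # 30 kb congener triple
sim <- simulate_genus(cfg)
# separate the declared inversions before any statistics
aln <- apply_inversions(sim$alignment, sim$truth$inversion_declarations)

prof <- scan_windows(aln, window = 600, step = 50)
prof
#> scan_profile 'SimGenus': 589 windows (600 bp / step 50, complete deletion)
#>   S_max = 49, S_mean = 8.37, S_stdev = 9.93

loci <- find_hotspots(prof, aln, sim$features, k = 2)
loci[, c("name", "category", "start", "end", "S_locus", "pi")]
#>      name category start   end S_locus         pi
#> 1     g02    mixed   301  1250      35 0.03273495
#> 2 g07-g08    mixed  4851  5700      38 0.03333333
#> 3     g11    mixed  6901  8150      49 0.03496130
#> 4     g18    mixed 12651 13750      36 0.02909091
#> 5     g25    mixed 17851 18800      34 0.02889359
#> 6     g37   coding 27001 27700      29 0.03142857
```

Six loci exceed the threshold 8.37 + 2·9.93 = 28.2 segregating sites per
600 bp window; their π (≈ 0.03) is roughly eight times the genome
background (≈ 0.004, the Jukes–Cantor expectation for two branches of
0.002 substitutions/site). Primer design on the first locus:

```r
des <- design_primers(aln, loci$start[1], loci$end[1])
des$pairs[1, c("fwd_seq", "rev_seq", "product_length", "tm_difference")]
#>              fwd_seq            rev_seq product_length tm_difference
#> 1 GTCGTCGGAAAGCAGTTG ACCTGTGTATATGGCGGC            998             0
```

Both primers sit in runs conserved across all three genomes, so they
match each input sequence exactly, and the 998 bp product contains the
whole locus. A full multi-genus run —
simulate → scan → hotspots → cross-genus table → primers — is one call:

```r
res <- run_discovery(run_config(seed = 1), "run_out/")
res$breakdown     # loci present in >=1, >=2, >=3 genera
```

The same pipeline runs from the shell via `exec/cphotspot`
(`simulate`, `scan`, `hotspots`, `run`, `resolve` subcommands), and real
data enter through `run_config(genera = ...)` manifests (aligned FASTA +
GFF3 + optional inversion declarations per genus).

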