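# barbellr

Tools for analysing the RNA secondary structures that make adenosine-to-inosine
(A-to-I) editing efficient at selectively edited sites.

## The problem

ADAR enzymes deaminate adenosines in double-stranded RNA. A handful of sites —
the Q/R site of the glutamate receptor subunit GluA2 being the canonical
example — are edited in nearly 100% of transcripts, while structurally similar
sites elsewhere are edited in only a few percent. The difference is explained
by *editing inducer elements* (EIEs): long, stable stems that sit next to the
edited duplex but are separated from it by a large internal loop, forming a
"barbell" — two helices joined by a loop that the enzyme reads as a helix end.
The EIE recruits ADAR and raises its local concentration; the separating loop
confines catalysis to the short edited stem, giving both efficiency and
specificity.

`barbellr` implements the computational side of this model as a reusable
pipeline:

* **Structure model and I/O** — pair-table structures with validated
  invariants (involution, no pseudoknots, minimum hairpin), read/written as
  FASTA, Vienna dot-bracket and CT files, plus a deterministic base-pair
  maximisation folder (Nussinov-style dynamic programming with an optional
  stacking bonus) for designed substrates. Externally predicted structures are
  first-class inputs.
* **Segmentation** — decomposition of a structure into stems, bulges,
  internal loops, hairpin loops and junctions under the ADAR helix-end rule:
  two-sided interruptions of up to 4 nt extend a helix, internal loops larger
  than 6 nt terminate it, and one-sided bulges never terminate a stem.
* **EIE scanning** — locating the edited stem, detecting flanking stems with
  at least 20 bp (the duplex length sufficient for the ADAR2 deaminase
  domain), and measuring each candidate the way substrate tables report them:
  stem span in nt, base pairs, distance to the edit site, 5′/3′ side,
  stability.
* **Conservation** — Needleman–Wunsch alignment of ortholog pairs and
  classification of every substitution as compensatory, wobble-preserving,
  loop-located or disruptive, aggregated into a conserved/not-conserved
  verdict.
* **Editing quantification** — percent editing from Sanger peak heights,
  `100·G/(A+G)`, with replicate means and sample standard deviations, and the
  relative-coordinate bookkeeping for reporter constructs (deletions,
  relocations) used to probe the model experimentally.
* **Synthetic data** — generators for barbell substrates, diverged orthologs
  with planted substitution classes, noisy peak heights and whole screening
  cohorts with known ground truth.
* **Screening pipeline** — `run_screen()` tabulates EIE presence against
  editing efficiency over a substrate table, and a packaged compendium of 23
  mammalian recoding sites reproduces the published efficiency-by-stem
  contingency. A thin CLI (`inst/cli/eiescan`) exposes every stage as a
  subcommand.

## Worked example

Build a GluA2-like barbell substrate (28-bp edited stem with two mismatches, a
20+15-nt internal loop, a 43-bp EIE interrupted by four mismatches and an 8-nt
bulge), segment it and scan for inducer elements:

```r
library(barbellr)
bb <- make_barbell(barbell_spec(seed = 1))
bb
#> barbell_substrate (221 nt): edited stem 28 bp, EIE 43 bp / 102 nt,
#>   loop 35 nt, distance 45 nt (3p), edit site at 15

seg <- segment_structure(bb$structure)
seg$segments
#>   segment_id          kind start_5p end_5p start_3p end_3p bp_count left_unpaired right_unpaired
#> 1          1      exterior        1     10       NA     NA        0            10              0
#> 2          2          stem       11     40      182    211       28             2              2
#> 3          3 internal_loop       41     60      167    181        0            20             15
#> 4          4          stem       61    115      120    166       43            12              4
#> 5          5  hairpin_loop      116    119       NA     NA        0             4              0
#> 6          6      exterior      212    221       NA     NA        0            10              0

find_eie_candidates(seg, bb$site)
#>   segment_id side length_nt bp_count distance_nt stable
#> 1          4   3p       102       43          45   TRUE
```

The scan reads exactly like one row of a substrate screen: a stable 102-nt,
43-bp stem on the 3′ side, 45 nt downstream of the edited adenosine.
Quantifying simulated Sanger peaks at a true editing level of 66%:

```r
summarize_editing(simulate_peaks(0.66, noise_sd = 0.05, n_replicates = 3,
                                 seed = 2))
#>   site n mean_percent sd_percent
#> 1    0 3     65.28097   0.748575
```

`mean_percent` is the mean of the per-replicate `100·G/(A+G)` ratios and
`sd_percent` their sample standard deviation.

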