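---
title: "Barbell structures and editing inducer elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barbell structures and editing inducer elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barbellr)
```

## The model

Site-selective A-to-I editing happens in short duplexes, typically formed
between an exon and an editing complementary sequence (ECS) in the adjacent
intron. A duplex of roughly 20 bp is enough for the ADAR2 deaminase domain to
engage, yet editing levels at such sites range from a few percent to
essentially complete. The barbell model attributes efficient editing to an
*editing inducer element* (EIE): a second, longer and more stable stem that
flanks the edited stem but is separated from it by a large internal loop.
The EIE is an ADAR recruitment platform — it raises local enzyme
concentration without itself being a good catalysis substrate — while the
internal loop acts as a helix end that confines the deaminase to the short
edited stem, preserving site selectivity. Deleting the EIE collapses
editing; moving it to the other side of the edited stem, or swapping in an
EIE from an unrelated substrate, restores it.

`barbellr` operationalises each part of that picture: a structure
segmentation that decides what counts as "one stem", a scanner that measures
candidate EIEs the way substrate compendia tabulate them, a conservation
module for the compensatory-substitution signature of a maintained duplex,
quantification of editing from Sanger peak heights, and generators that
produce substrates with all of these properties planted and known.

## Structures and the internal folder

Structures are pair tables over 1-based positions with three enforced
invariants: the table is an involution without self-pairs, pairs never
cross (no pseudoknots), and every pair encloses at least `min_hairpin = 3`
nucleotides — the steric minimum for a hairpin turn. Dot-bracket and CT
readers and writers round-trip exactly; `T` is accepted everywhere and
normalised to `U`.

The built-in folder, `fold_rna()`, is a Nussinov-style base-pair
maximisation with an optional stacking bonus: it maximises
`pairs + stacking_bonus × stacked_pairs` over canonical pairs (AU, GC, and
GU wobble by default, since wobble pairs occur in real edited stems). It is
*not* a thermodynamic model and makes no claim of parity with free-energy
folders; its role is to be a deterministic, dependency-free structure oracle
for designed substrates, while structures predicted by external tools enter
the pipeline as ordinary dot-bracket or CT input. Determinism is guaranteed
by fixed tie-breaking: each position pairs with the smallest admissible
partner that achieves the optimum, a position is left unpaired only when no
partner does, and inside a closed pair the stacked continuation is preferred
when it ties the alternatives. The default `stacking_bonus = 0.5` favours
contiguous helices over scattered isolated pairs without changing the
optimal pair count on unambiguous inputs; the test suite checks the folder
against exhaustive enumeration of all structures of short random sequences
at bonuses 0, 0.5 and 1.

## Segmentation and the helix-end rule

Segmentation converts a pair table into the vocabulary of the barbell
model. Maximal stacked runs (helices) are merged into *stems* across small
interruptions, and the merge rule encodes how the editing machinery reads
imperfections in a duplex:

* a **two-sided interruption** (unpaired nucleotides on both strands,
  mismatches included) extends the stem when its *total* across both strands
  is at most `merge_tolerance = 4` nt;
* an internal loop with a total above `helix_end_threshold = 6` nt always
  terminates the stem;
* totals of 5–6 nt fall between the two published anchor points; the default
  `boundary_policy = "helix_end"` terminates the stem there (conservative
  stem calling), and `"merge"` is available for sensitivity analyses;
* a **one-sided bulge** never terminates a stem, at any size. One strand of
  the helix is covalently continuous through a bulge, so the two flanking
  helices remain a single recruitment surface; this is also the only reading
  under which a long EIE "interrupted by four mismatches and a bulge of
  8 nt" is one stem, which is how such elements are tabulated in practice.

Loop sizes are always quoted as the *total over both strands* (a 20+15
internal loop is "35 nt"), matching how barbell substrates are described in
the literature; the per-strand split is retained in the segment table.
Junction loops with three or more emerging stems and unenclosed exterior
runs are recorded as their own segment kinds. The segments partition every
position exactly once, which the tests assert on random folded structures.

## EIE candidates and their metrics

Given an edit site, the stem containing it is the *edited stem*; an edit
site falling in a loop is an error by design, because the barbell model has
nothing to say about unpaired sites. Every other stem with at least
`min_bp = 20` base pairs is a candidate EIE — 20 bp being the duplex length
sufficient for deaminase-domain engagement. Because bulges never split
stems, any two distinct stems are automatically separated by an internal
loop, junction or exterior run, so candidacy never rests on a mere bulge.

Each candidate is measured in the conventions of published substrate
tables:

* `length_nt` — nucleotides inside the stem's two spans, including merged
  interruptions (a 43-bp stem with four mismatches and an 8-nt bulge spans
  102 nt);
* `distance_nt` — nucleotides strictly between the edit site and the
  nearest stem nucleotide along the transcript;
* `side` — 5′ or 3′, from the position of that nearest nucleotide;
* `stable` — at least `min_bp` pairs *and* a paired fraction
  `2·bp/length_nt ≥ 0.6`, a sequence-level stand-in for the
  base-pairing-probability judgement that thermodynamic folders provide.

One tabulation quirk is worth stating: for the canonical GluA2-like element
the literature variously quotes "43 bp" (tabulated) and a "45-bp stem"
(running text) alongside a 45-nt distance. The package follows the
tabulated convention throughout — 43 bp, 102 nt span, 45 nt distance — and
treats the 45-bp phrasing as a conflation of the distance with the pair
count; the two numbers are computed independently here and can never
contaminate each other.

## Conservation logic

A maintained EIE duplex leaves a recognisable evolutionary signature:
substitutions concentrate in loops or arrive in partner-coordinated pairs.
`classify_substitutions()` judges every aligned difference by its
structural consequence only — the two residues, the partner residues and
paired/unpaired status: `compensatory` (both partners changed, canonical
pairing retained), `wobble_preserving` (single change retaining a canonical
pair), `loop_located`, or `disruptive`. A pair must be canonical in *both*
species to count as retained, which makes the call symmetric under swapping
the species. Indels count against identity but are disruptive only when
they delete a paired position.

The published screens give no quantitative conservation criterion, so the
verdict is explicitly parameterised and reported with its thresholds:
conserved means aligned identity ≥ 0.85 *and* disruptive changes ≤ 5% of
paired columns. Alignment is Needleman–Wunsch with match +1, mismatch −1,
linear gap −2 and fixed tie-breaking (diagonal, then up). For generated
orthologs — which never contain indels — `ungapped_alignment()` aligns
position-by-position; an optimal scored alignment can otherwise slide
within repetitive stem sequence and manufacture spurious indel columns.
One consequence of the identity term: heavily compensatory divergence is
eventually called "not conserved" on sequence grounds alone, so the
conserved call should be read as "sequence and structure conserved", not as
a pure structure statement. Both components are reported separately in the
verdict object.

## Editing quantification and construct coordinates

Editing is quantified from Sanger peak heights as `100·G/(A+G)`; replicate
sets are summarised by mean and sample (n−1) standard deviation, matching
the error-bar convention of triplicate transfection experiments. A site
with `A + G = 0` is unquantifiable and raises an error rather than
returning a silent zero. No correction is applied for overlapping A/G
peaks; heights are taken as read from the trace viewer.

Reporter-construct operations use relative coordinates — edit site = 0,
downstream positive — with deletion ranges inclusive at both ends: this is
the only reading under which deleting "+24 to +44 and +276 to +291"
removes 37 nt, and that arithmetic is a frozen test case. Deletions and
relocations return old-to-new coordinate maps; structures are carried
through the map, opening any pair that loses a partner. A relocation moves
a contiguous element so that its 3′ end lands at a requested offset; an
element whose 3′ end sits at −(k+1) has exactly k nucleotides between
itself and the edit site. Relocation tests carry the *designed* pair table
through the coordinate map rather than refolding: an EIE is a
self-contained hairpin element whose pairs move rigidly, so the mapped
structure is exact, while refolding is exercised separately by the
fold-recovery property below.

## What the generators emulate — and what they do not

`make_barbell()` realises a structural specification exactly: stem pair
counts, interruption sizes and placement, internal-loop split, edit-site
distance and side. Stems are GC-biased (80% GC pairs by default) and loops
are adenosine runs, so base-pair maximisation folding of the bare sequence
recovers at least the designed pair count — the recovery property tests
use `stacking_bonus = 0`, where the designed structure is itself a feasible
solution and the bound is sharp. The default specification is a GluA2-like
substrate (28-bp edited stem with two mismatches, 20+15 loop, 43-bp EIE
with four mismatches and an 8-nt bulge, 45 nt away on the 3′ side), the
geometry used as the worked example throughout.

Peak-height noise is multiplicative truncated Gaussian:
`A = H(1−f)(1+ε)`, `G = Hf(1+ε)`, `ε ~ N(0, σ²)` truncated at −0.9 so
heights stay positive. This is a stand-in chosen for plausibility
(intensities are non-negative and roughly scale-proportional), not a
calibrated chromatogram model. Ortholog generation plants substitution
classes directly (per-pair and per-loop-position Bernoulli events with
deterministic residue maps), so downstream classification can be checked
exactly.

What passing tests on this synthetic material shows is that the analysis
chain is *internally consistent*: every planted parameter is recovered
exactly, estimators converge at the expected Monte-Carlo rate, and planted
conservation patterns produce the intended verdicts. What it cannot show
is fidelity to real substrates, whose structures are thermodynamic (not
pair-count-optimal), whose stems are not GC-biased, whose orthologs
contain indels, and whose chromatogram noise is not Gaussian. For real
data the intended route is external structure prediction plus the
dot-bracket/CT readers.

## Numerical and design choices

* Coordinates 1-based inclusive, sense strand only; relative coordinates
  have the edit site at 0.
* Folder scores compared with a 10⁻⁹ tolerance in traceback; scores are
  small integers plus half-integer bonuses, so this is exact in practice.
* `min_hairpin = 3`, `allow_gu = TRUE` by default everywhere.
* Efficiency classes: high ≥ 50%, low ≤ 45%, the 45–50 gap reported as
  `unclassified` rather than forced into either class.
* Screen summaries assert their own count identities on every call, not
  only in tests.
* The packaged 23-substrate compendium transcribes published annotations;
  a few 5′/3′ side marks could not be verified from the source material and
  carry an `ambiguous_side` flag rather than a guessed side. The
  efficiency-by-stem contingency (10 of 11 high, 1 of 12 low with a
  conserved stable stem) does not depend on those marks.
* Problem sizes in the test suite — 500 enumeration cross-checks at ≤ 12 nt,
  100 generator round-trips, 200 estimator replicates, cohorts of ~23
  substrates — were chosen to exercise every code path at interactive
  runtimes; all scale linearly if larger runs are wanted.

## Known limitations

* The folder ignores thermodynamics entirely; it must not be used to
  predict real structures, only to realise designed ones.
* Stability is judged from pair counts and paired fraction, not from
  base-pairing probabilities; borderline real elements may be called
  differently than a partition-function analysis would.
* Conservation verdicts conflate sequence and structure conservation in a
  single boolean (both components are reported for users who need them
  separately).
* Multibranch junctions are recorded but not analysed further — no coaxial
  stacking, no junction topology.
* Pseudoknots are rejected, matching the scope of the barbell model.
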