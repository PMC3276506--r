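---
title: "Mapping crossovers and modelling strand-annealing recombination in hybrid phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crossovers and modelling strand-annealing recombination in hybrid phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagerec)
```

## The scientific problem

Closely related lytic coliphages such as T3 and T7 have collinear genomes of
roughly 38--40 kb whose local nucleotide identity varies from near-identity
down to ~77% in the tail-fiber region. Natural recombinants between such
phages ("hybrids") carry a mosaic genome: long stretches from one parent
interrupted by one or more exchanged segments from the other. Characterising
such a hybrid from sequence raises four connected questions, and each maps
onto one module of this package:

1. **Where does the hybrid's restriction pattern differ from its parents?**
   (`digest_linear()`, `diff_digests()`, `gel_bands()`) -- the classical
   first look, emulating what an agarose gel shows.
2. **Which parent does every position of the hybrid come from, and where
   exactly are the crossovers?** (`three_way_align()`, `paint()`,
   `call_crossovers()`, `microhomology_window()`).
3. **Could the crossover neighbourhood form the branched DNA structures
   (cruciforms / four-way junctions) that junction-resolving nucleases such
   as phage endonuclease I cleave?** (`scan_inverted_repeats()`,
   `fold_hairpin()`, `build_four_way_junction()`, `assign_endoI_cuts()`).
4. **Can a concrete sequence-level mechanism reproduce the observed hybrid
   exactly?** (`cesa()`, `cnsa()` -- cleavage at equivalent or nonequivalent
   sites followed by single-strand annealing).

A fifth module (`synthetic_spec()`, `generate_parent_pair()`,
`splice_hybrid()`) manufactures parent pairs and hybrids with known truth,
so that every stage above is testable without any external download.

## Parentage painting and crossover intervals

The hybrid is aligned to both parents at once. Because the genomes are
near-collinear, an anchor-and-fill strategy is used: k-mers (default
`k = 16`) occurring exactly once in each of the three sequences are chained
monotonically (longest chain, ties broken leftmost -- the procedure is fully
deterministic), anchor blocks are clipped to be non-overlapping and trimmed
by 5 bp at their edges so the gap aligner retains freedom near block
boundaries, and the inter-anchor gaps are filled by affine-gap global
alignment (match +1, mismatch −2, gap open 5, gap extend 2; `N` mismatches
everything including itself). For equal-length gaps with few mismatches the
gapless diagonal is used directly; this is not a heuristic but an exact
shortcut, because a gapped global alignment of equal-length strings carries
at least two gap runs, whose penalty `2*(open + ext)` exceeds the largest
possible gain `(match − mismatch)` per converted mismatch plus one `match`
whenever `mismatches ≤ 5` under the default scores. The package verifies in
its test suite that the anchored alignment reaches exactly the score of a
full quadratic dynamic-programming run.

Each alignment column is then classified by deterministic parsimony:
*A-diagnostic* (hybrid = A ≠ B), *B-diagnostic* (hybrid = B ≠ A), *shared*,
*private* (hybrid differs from both parents -- a mutation private to the
hybrid, never interpreted as a switch), or *gap*. A **crossover** is called
between every adjacent pair of opposite diagnostics. It is deliberately
reported as an *interval*, never a point: between the two flanking
diagnostic columns the parents are (essentially) identical, so no method can
localise the switch further. The **microhomology window** is the maximal
run of parent-identical columns containing that interval, reported in
parent-A coordinates with its length in bp. For a hybrid whose left
crossover sits in an 8-bp identity window this reproduces the window
exactly; a long right-side identity tract (tens of bp) is likewise
recovered in full. Private columns inside an interval are listed with the
call but do not split it. Two parents identical over the whole alignment
give a degenerate whole-genome window, which is flagged as such.

## Restriction-digest comparison

Digestion is simulated on the top strand: every match of the recognition
site (IUPAC-aware, overlapping tandem sites included, `N` windows never
matching) contributes a cut bond at `site start + cut_top − 1`. Fragments
are inter-cut distances including both genome ends, so their sum always
equals the genome length. The bundled enzyme table (users can extend the
TSV) carries standard cut geometry: MboI `^GATC`, NdeI `CA^TATG`, HpaI
`GTT^AAC`, AvrII `C^CTAGG`, StuI `AGG^CCT`. Only the top-strand offset
affects fragment sizes.

`diff_digests()` compares two digests the way a gel reader would: fragment
sizes are matched as multisets with a relative band tolerance (default 5%,
emulating agarose resolution; 0 gives exact mode), and cut positions are
paired by walking both sorted lists with a running offset learned from
shared flanking cuts, so a hybrid 13 bp shorter than its parent still pairs
its shared sites. The diff is antisymmetric under argument swap, and on a
synthetic hybrid every lost/gained site falls inside the exchanged segment
-- a property the test suite asserts against the generator's truth.

## Pseudo-palindromes, cruciforms, and Endo I cuts

A pseudo-palindrome is an imperfect inverted repeat `X . spacer .
revcomp(X)`; when it extrudes from duplex DNA it forms two opposed hairpins
-- a cruciform, i.e. a four-way junction with two duplex flank arms and two
stem arms. The scanner enumerates, for every loop placement (loop length
3--10 nt by default; 3 nt is the steric floor), the maximal arm whose
mismatch count stays within budget; maximality means extending the arms by
one more pair would exceed the budget or the sequence bounds. Tie-breaking
is everywhere longest arm, then shortest loop, then leftmost locus, so
results are deterministic, and the output is proven equal to an exhaustive
enumeration for sequences up to 500 nt. Watson--Crick pairs only by
default; a `wobble` flag additionally accepts G·T for RNA-mode folding of
transcribed terminator stem-loops. `fold_hairpin()` folds *exactly* a given
interval (contiguous stem, outermost pairs first), which is how the
terminator geometries are measured: a 39-nt window planted with a 17-bp
stem and 5-nt loop folds to (17, 5), and breaking the loop-proximal pair
yields (16, 7) -- one pairing fewer, two more loop nucleotides.

Junction-resolving endonuclease I cleaves the two continuous strands near
the branch points and tolerates very short duplex arms, so the junction
constructor accepts stem arms down to 2 bp. Published data give example cut
bonds rather than a placement rule, so cleavage placement is a single
configurable `offset` (default 0 = at the branch bonds): the top strand is
cut after `locus start − 1` and the bottom strand after `locus end`,
releasing complementary 5' overhangs that span the extruded region; a
nonzero offset translates both bonds together and leaves the overhang
length unchanged. With a 16-nt extruded pseudo-palindrome this yields the
16-bond cut separation seen in the gene-17-type junction reading.

## The CESA and CNSA recombination models

Both simulators are purely sequence-level and deterministic given explicit
cut sites; the enzymes that would perform each step (Endo I, the gp2.5
annealase, gp6 exonuclease, gp5/Trx polymerase, ligase) appear only in the
event log. A double-strand-break piece tracks both strand extents in
top-strand coordinates, so end chemistry (blunt, 5' or 3' overhang) is
derived rather than stored, and resection is a coordinate update.

**CESA** (cleavage at equivalent sites + strand annealing): both parents
are cut at junctions whose complementary 5' overhangs cover the same
homology. `anneal()` scans all registers of the two single-stranded tails
and keeps the longest contiguous complementary run (≥ `min_match`, default
6; an optional internal mismatch budget, default 0; ties resolved towards
the smaller register shift). Tail portions outside the paired run are
resolved by a single rule derived from the mechanism's geometry: an
unpaired *terminal* segment (pointing across the joint) is a displaced flap
and is excised -- the 5' flap in CESA; an unpaired segment on the *duplex*
side is retained and serves as the template for gap filling, and filled
positions carry provenance `"fill"`. In the worked 17-nt-tail case (8
complementary bases followed by 9 divergent ones) this excises the
acceptor's 9-nt flap and copies the donor's 9 bases -- the product switches
parent exactly at the end of the 8-bp homology.

**CNSA** (cleavage at nonequivalent sites): the four break ends are first
5'-resected (`resect` parameter; no principled value exists beyond "long
enough to expose the microhomology", and the default 40 nt comfortably
exposes a 7-bp microhomology plus context in the geometries studied), so
the joints anneal 3' tails (`min_match` default 7). The donor tail's
non-homologous 3' terminal nucleotides are excised by the same
terminal-flap rule, gaps are filled from the intact strand, and nicks are
ligated. With equivalent cuts and zero resection CNSA degenerates to CESA.

Both mechanisms satisfy, and the tests assert: provenance never lies (every
position labelled A or B matches that parent at its mapped coordinate),
products equal the independent `splice_hybrid()` oracle, the breakpoint
caller round-trips the products into the intended windows, and re-running
from the logged parameters reproduces the product byte for byte. A
stochastic wrapper (`sample_recombinants()`) samples cut-site pairings from
candidate lists under a mandatory seed -- multiple cleavable junctions per
region is precisely what raises recombination frequency.

One modelling caveat: annealing picks the *longest* identity run in the
tails. If the divergent context around a planted window accidentally
contains a longer identity run (likely when per-site divergence is below
~20% and tails are long), the simulated switch lands in that run instead.
The product is still a clean parental splice -- just localised to a
different, equally legitimate microhomology.

## What the synthetic generator does and does not emulate

`generate_parent_pair()` derives parent B from parent A by i.i.d.
substitutions (uniform over the three alternative bases -- no
base-composition model is imposed) at a configurable per-site rate, with
optional 1--20 bp indels (off by default so the trio stays collinear, which
matches the near-collinear biology and keeps the alignment stage simple;
enabling them is the stress test for the aligner). Identity windows are
forced identical *and* their immediately flanking positions are forced to
differ, so a planted window is the exact microhomology truth rather than a
lower bound. Planted pseudo-palindromes are written into both parents
identically. A seed is mandatory; there is no implicit global RNG, and the
same seed gives byte-identical output.

What this does **not** emulate: real phage genomes have gene-structured,
regionally varying divergence (near-identical early genes, ~23% divergent
tail-fiber region), codon bias, terminal repeats, and genome-wide palindrome
avoidance. Passing the planted-truth suites therefore demonstrates that the
algorithms are correct under the stated model -- uniform divergence with
embedded identity windows -- not that every real crossover would be equally
clean; in particular, regions of locally *low* divergence widen crossover
ambiguity intervals on real data exactly as they do here.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `k` | anchors | 16 | unique in all three ~40 kb sequences with overwhelming probability, short enough to survive 5--10% divergence |
| match/mismatch/gap | aligner | +1/−2/5+2L | standard affine scores; chosen so a single mismatch never beats opening a gap pair |
| `tolerance` | digest diff | 0.05 | agarose band-size resolution; 0 = exact regression mode |
| `min_arm`, `max_loop`, `max_mismatch` | scanner | 4 / 10 / 0 | smallest stem Endo I-type junctions need is 2--4 bp; 3-nt loop floor is steric |
| `offset` | Endo I cuts | 0 | cuts at the branch bonds; example data give bonds, not a rule |
| `min_match` | anneal | 6 (5' joints), 7 (3' joints) | the worked joints pair 8 and 7 bases respectively; defaults sit just below |
| `resect` | CNSA | 40 nt | long enough to expose a 7-bp microhomology plus context |
| `site_slack` | digest diff | 32 bp | pairs shared cut sites across small length offsets between collinear genomes |

## Problem sizes and reproducibility

The test-suite property checks use trio lengths of 1.2--8 kb, 200 seeded
trios for the planted-recovery sweep (identity windows of 4, 8 and 15 bp,
divergence drawn from 0.01--0.1), exhaustive scanner comparisons up to
500 nt, and a 2-kb dynamic-programming oracle for the aligner -- sizes at
which every independent oracle is exactly computable while the full suite
stays in the minutes range. `scripts/acceptance.R` re-runs the same
computations from scratch at a fixed seed, including one 38-kb
genome-scale trio carrying an 8-bp left window and an 81-bp right identity
tract, the geometry of the hybrid that motivated the package. Regression
against the two published ~40-kb reference genomes requires their FASTA
records on disk; the package deliberately performs no network access, and a
documented test block activates when the records are supplied under
`inst/extdata/`.

## Known limitations

* Painting is deterministic parsimony over exactly two parents; probabilistic
  (HMM) painting and >2-parent recombination detection are out of scope.
* No thermodynamics: hairpin folding counts Watson--Crick (optionally G·T)
  pairs; it does not compute folding energies or extrusion kinetics.
* Digestion ignores methylation sensitivity, star activity, partial digests
  and double digests.
* The strand-transfer / double-Holliday-junction pathway is not modelled;
  the simulators cover the two strand-annealing mechanisms only.
* Circular topologies and IUPAC-ambiguous bases other than `N` are not
  supported.
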