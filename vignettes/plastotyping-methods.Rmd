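---
title: "Methods: plasmotyping mixed-organelle NGS panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasmotyping mixed-organelle NGS panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `plastotyper`, in the spirit of a methods supplement.
Everything quantitative stated here is recomputed by the test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not verify.

## The problem and its assumptions

A panel of plant samples is sequenced from a co-purified mixture of
chloroplast (cp) and mitochondrial (mt) DNA. Three biological assumptions
shape every downstream choice:

1. **Homoplasmy.** Organelle genomes within a sample are treated as a
   single haplotype, so consensus genotypes are haploid (VCF GT "0"/"1").
   Columns where no allele reaches the consensus fraction are reported as
   *mixed* and never genotyped — heteroplasmy estimation is explicitly out
   of scope.
2. **Maternal co-inheritance.** cp and mt types are inherited together, so
   the joint (cp type, mt type) pair — the plasmotype — is the unit of
   interest, yet the two partitions need not coincide and are computed
   independently.
3. **Cross-homology exists.** Chloroplast-like sequence occurs in
   mitochondrial genomes (and in nuclei); reads from such regions cannot
   be assigned and must be excluded rather than guessed.

## Read assignment to the double reference

Reads are trimmed with a 5'→3' sliding window (width 4, mean quality
threshold Q15): at the first window whose mean falls below the threshold
the read is cut at the first individual sub-threshold base inside that
window, so a good prefix of a failing window survives. Pairs with a mate
shorter than 36 bp are dropped whole. All three values are the customary
short-read defaults; none is critical because the simulated quality
profile only decays to Q15.

Mapping is seed-and-extend: an exact-match index of all 31-mers of both
strands of every replicon (circular genomes indexed on sequence +
prefix(k−1) so origin-spanning k-mers are found), three seeds per mate
(start, middle, end), and candidate loci verified by a unit-cost edit
alignment restricted to a window of the candidate start ± a band
(default 8 bp, enough for the largest planted indel plus slack). Two fast
paths keep this cheap: an exact/Hamming comparison resolves the vast
majority of reads, and the full banded dynamic program with traceback runs
only when the Hamming path fails. The DP row recursion uses the standard
unit-cost running-minimum closure, and the traceback prefers continuing
the current gap on ties so one biological indel yields one contiguous gap
run at a reproducible (rightmost, then left-normalized) position.

A pair is assigned to the replicon with the best total score under proper
(opposite-strand) orientation within a 2 kb insert bound. When the best
scores on two replicons tie within 1 unit the pair is
`ambiguous_between_genomes` and excluded from the pileup — a deliberately
conservative rule: a read that fits the shared cp/mt segment equally well
carries no assignment information. Within-genome ties are likewise
excluded.

## Consensus calling

* **SNPs:** called where depth ≥ `min_depth` (10) and the top
  non-reference allele fraction is ≥ `min_fraction` (0.8).
* **Indels:** every mate contributes left-normalized gap *events*; an
  event is called when its count reaches `min_fraction` of the mates that
  span the event with a right flank of k + 6 bp (k = indel length). The
  flank matters: under unit costs a mate ending fewer than ~k bases past
  an indel is better explained by a short mismatched tail than by a gap,
  so such mates can never report the event and must not dilute its
  fraction.
* **SSR tracts:** pileup columns inside microsatellites are unreliable, so
  tract length is the mode over mates spanning the tract plus 5 bp flanks,
  and a whole-unit difference becomes an `ssr_length` variant anchored
  before the tract. SSR tracts are defined as maximal tandem runs with ≥ 8
  mono-, ≥ 5 di- or ≥ 4 trinucleotide units — common microsatellite-survey
  thresholds, chosen once.
* Positions below `min_depth` are emitted as no-call intervals (BED,
  0-based half-open, in the report bundle; 1-based closed in R).

All external coordinates are 1-based inclusive (VCF/GFF3 convention);
indels use VCF anchoring (ref and alt share their first base) and are
left-aligned, so planted, called and hand-written variants compare by
simple key equality. The VCF dialect is v4.2 with haploid GT and a `VC`
INFO tag that lets `ssr_length` survive a round trip.

## Annotation and the editing screen

Codon arithmetic runs on the exon-concatenated CDS, so codons may straddle
exon junctions. Translation uses the plastid/bacterial genetic code (NCBI
table 11); a valid initiator codon at position 1 translates as Met, any
other first codon by straight lookup. Amino-acid changes are written as
HGVS p. strings with `=` for synonymous changes.

The editing screen encodes the geometry of plastid C→U editing: an exonic
SNP is *eligible* when its coding-strand alleles are {C, T}; the reported
conversion is always read in the editing direction (from the C-bearing to
the T-bearing codon), which makes the screen's central invariant testable:
the T allele's residue must equal what editing the C allele would produce.
Tier 1 requires second codon position and Ser→Leu; tier 2 second position
or a conversion in the configurable common set (Ser>Leu, Ser>Phe, Pro>Leu,
Pro>Ser, His>Tyr, Thr>Ile, Arg>Trp, Ala>Val); tier 3 is any other eligible
site, including synonymous ones. Coding G/A transitions cannot be C→U on
the coding strand; they are flagged `atypical` and, only when
`allow_reverse = TRUE`, screened as putative reverse (U→C) events — off by
default because such events are rare and the evidence for them weaker.

## Typing, the cladogram and homoplasy

cp and mt types are equivalence classes of state vectors over the
molecule's characters, labeled by Roman numerals in order of first
appearance; all cross-run comparisons are partition-based, never
label-based. SSR characters are excluded from typing and from the tree by
default (microsatellite length homoplasy is rampant); the packaged panel
plants its SSR character congruent with an existing split so the exclusion
is observable but harmless.

The cladogram is built from the **chloroplast characters only**: mt
characters partition the panel along different lines and would distort a
cp genome tree; they enter the plasmotype table instead. Tree search
collapses identical state vectors first (duplicates re-attach as
zero-change cherries), scores trees with a bit-parallel Fitch pass (equal
to unit-cost Sankoff, which the tests verify by brute force), enumerates
all unrooted topologies exhaustively for ≤ 8 distinct vectors
((2n−5)!! ≤ 10395) and otherwise uses stepwise addition in input order
followed by nearest-neighbour-interchange hill climbing capped at 200
accepted moves — panels of ~20 samples with near-perfect characters never
approach the cap. Equally parsimonious trees are resolved to the
lexicographically smallest canonical newick, making the search
deterministic; the tree is then rooted on the branch to the outgroup.

Ancestral states come from a Fitch final pass with ties resolved toward
the parent (the root toward the outgroup state). A character is *clean*
when its changes equal its observed states − 1; otherwise *parallel* when
some derived state arises on two or more branches, and *reverse* when a
change re-enters a state that is ancestral on its path to the root; both
flags can co-occur.

## The synthetic panel: what it emulates, and what it does not

`table2_panel()` (seed 20200202) generates a 6 kb circular cp-like
replicon with six CDSs (one intron-containing, alternating strands, each
guaranteed to contain an editable Ser codon and a silent third-position C
site), an A₁₂ and an (AT)₆ tract, and a 400 bp segment copied into a 9 kb
circular mt-like replicon; then 15 samples in 8 cp types and 5 mt types
(8 plasmotypes). Type-defining variants form a nested chain — so the true
type tree is a caterpillar with the all-reference type as outgroup —
cycling through nonsynonymous (one Ser→Leu at codon position 2 of a
minus-strand gene), synonymous, intronic and intergenic SNPs, a 4 bp
anchored deletion and an SSR unit loss; the mt chain is three SNPs plus
one insertion. One parallel character (derived in the two non-adjacent
types 2 and 8) and one reverse character (derived on the deepest three
types, reverted in the middle one) are planted with known ground truth.

A reversal makes the clade it sits in ambiguous when the contradicted true
split is supported by a single character: an alternative topology resolves
the reversal as a clade at equal parsimony cost. The planter therefore
reinforces that split with a second clean character — the common situation
of two substitutions on one branch — so the planted tree is the unique
optimum and the "!"/">" ground truth is identifiable. This is a property
of the generator's design, not a tuning of the analysis.

Reads are 2 × 150 bp pairs, fragment length N(350, 30²), uniform starts
with wrap-around on circular replicons, i.i.d. substitution errors at
0.002, qualities Q37 with a linear decay to Q15 over the last 20% of
cycles, and a 0.5 cp fraction at 50× total depth — a balanced organelle
mix that keeps both replicons near 25×, comfortably above the calling
threshold. The mixture ratio of a real organelle preparation varies
widely; 0.5 was fixed once as the neutral default and is a parameter, not
a finding.

Deliberately **not** emulated: indel sequencing errors, PCR duplicates,
learned quality-by-cycle profiles, nuclear genomes beyond optional decoy
contigs, heteroplasmy, and real MiSeq scale (the replicons are ~20×
smaller than real organelle genomes). Passing the closed-loop tests
therefore demonstrates correctness of the algorithms under clean,
planted-truth conditions — not calling performance on real libraries.

## In-silico restriction analysis

Sites are IUPAC matches on the top strand (reverse strand additionally for
non-palindromic enzymes, reported at top-strand coordinates); circular
genomes are scanned on sequence + prefix(site − 1) with positions reduced
modulo length; `N` never matches. Fragments are produced by cutting at
site starts — the cleavage offset within the recognition site is
immaterial for counts and fragment multisets up to rotation, which is all
a gel comparison uses. Conservation invariants (fragments sum to genome
length; a circular genome has as many fragments as sites, one uncut
circle otherwise) are fuzz-tested. BclI is flagged Dam-sensitive and
GATC-overlapping sites are reported, but Dam masking is off by default:
plant organelle DNA is not Dam-methylated, so the flag only matters when
emulating historical bacterially-propagated probe work. Per-sample
digests apply the sample's variants (descending-position order, with an
old↔new coordinate map), attribute each gained or lost site to the unique
variant whose edit window overlaps it, and group samples by
fragment-length multisets with an optional gel-resolution tolerance
(binning; 0 = exact). Sequence-level types always refine or equal these
RFLP groups on site-pattern-identical samples.

## Numerical and degenerate-input conventions

* Character states are encoded as bits; Fitch processes all characters as
  vectorized integer operations (≤ 31 states per character, far above any
  realistic panel).
* Ties: tree search → smallest canonical newick; Fitch final pass →
  parent's state, then lowest state index; SSR mode → smallest length;
  insertion consensus → highest count at an anchor.
* Degenerate inputs: panels with < 3 distinct vectors return star/cherry
  trees; a k_cp = 1 panel plants zero variants; empty variant sets write
  header-only VCFs; uncut circular digests report one full-length
  fragment.
* Problem sizes were chosen so the full suite (including one complete
  15-sample pipeline run and the exhaustive 10395-topology check) runs in
  a few minutes on one core: 6/9 kb replicons, ~1250 pairs per sample.

## Known limitations

* The double reference carries exactly one cp and one mt replicon in the
  default pipeline; multi-contig references work in the mapper but the
  mixture model splits coverage by molecule class and length only.
* Wrap-around gene models (features spanning the circular origin) are not
  supported; GenBank ingest skips such features.
* The checks that reproduce literature restriction-site counts and exonic
  annotations on the real barley chloroplast genome (NC_008590) require
  the user to supply that sequence and its feature table locally (see
  `?hv_reference_path`); the package does not redistribute or download it.
* Parsimony is unweighted and unbootstrapped by design; likelihood or
  distance methods and branch support are out of scope.
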