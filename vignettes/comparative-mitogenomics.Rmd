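---
title: "Comparative mitogenomics with mitocompare: models, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

## The biological setting

Fungal mitochondrial genomes are small circular molecules — in Hypocreales
typically 25–40 kb — that carry a near-constant gene complement: 14 core
protein-coding genes (*nad1–6*, *nad4L*, *cob*, *cox1–3*, *atp6/8/9*), the
two rRNA genes *rnl* and *rns*, and a few dozen tRNAs, usually all
transcribed from one strand. What varies between individuals and species is
almost everything else: intergenic spacer lengths, free-standing ORFs,
group I intron presence and position, the circular order of the genes, and
the fine structure of gene junctions. mitocompare turns each of those axes
of variation into an explicit, testable statistic.

This vignette records the models and conventions behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## Coordinates and the circular topology

Internally all coordinates are 0-based half-open; all I/O (GenBank, TSV
feature tables) is 1-based inclusive. A feature spanning the circular
origin is stored as multiple segments, each inside `[0, L)`; no coordinate
ever exceeds the genome length. This keeps modular arithmetic confined to
one normalization step, and makes every downstream computation — region
unions, junction intervals, gene orders — provably invariant under rotation
of the origin, a property the test suite checks directly by rotating
synthetic genomes and comparing reports.

## Region accounting

The genic region is the union of the *hulls* of all gene-level features
(PCGs, rRNAs, tRNAs, free-standing ORFs): the hull of a gene runs from its
first to its last transcription boundary, so introns sitting inside a host
gene are genic by construction. Overlapping genes (the one-base
*nad4L*/*nad5* overlap) are counted once; the intergenic region is the set
complement. Consequently `genic_nt + intergenic_nt == size_bp` is an exact
identity, not an approximation — the invariant that makes published genome
tables internally consistent. Intronic nucleotides are totalled over intron
features, intronic ORFs included, since those ORFs lie inside the introns.

Composition statistics use the standard definitions AT% = 100·(A+T)/(A+C+G+T),
AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C). Ambiguous bases (`N`) count
toward genome size but are excluded from all composition denominators;
public records rarely state their convention, so ours is documented here
and applied uniformly. Reports format percentages to one decimal and skews
to two, matching the precision of published mitogenome tables.

## Gene orders as signed circular permutations

A genome's arrangement is reduced to the ordered list of its core genes
(default: the 14 core PCGs plus *rnl* and *rns*) with transcription strand
as a sign. Because the molecule is circular and either strand could have
been deposited, two normalizations define the canonical form:

1. **Orientation** — if the majority of genes carry the minus sign, the
   order is reflected (reversed with all signs toggled). In single-strand
   transcribed genomes this leaves all genes positive, and a genuinely
   inverted gene pair survives as a minority of negative signs.
2. **Rotation** — the list is rotated to start at *rnl* (the conventional
   anchor for mitogenome comparisons); if *rnl* is missing, the
   lexicographically smallest rotation is used as a deterministic
   tie-break.

Pattern identity is *exact equality of canonical forms* — the field
enumerates discrete arrangement patterns (A, B, C, …), it does not measure
breakpoint distances, and the package follows that practice. Labels are
assigned by descending group size with input order breaking ties. A genome
lacking core genes joins the pattern whose order, after deleting those
genes, matches it, and is recorded as a partial match rather than founding
a spurious new pattern. Each non-dominant pattern carries a minimal edit
note derived from the difference of gene adjacencies: a gene whose both
neighbors changed is reported as relocated, a sign change as inverted.

## Junction intervals

For two adjacent genes on the same strand the joining interval is the
signed distance, along the transcription direction and unwrapped across
the origin, from the upstream gene's end to the downstream gene's start:
0 for abutting genes, −1 when the last base of the upstream stop codon is
also the first base of the downstream ATG, positive for a spacer. The
convention is fixed by the biology: the stop/start overlap observed at
*nad4L*/*nad5* must read −1. Multi-segment (intron-containing) genes use
their outermost boundaries, so introns never perturb junction arithmetic.
Genes on opposite strands have no shared transcription direction; they are
flagged `opposite_strands` rather than assigned a number. Intervals map to
lettered states (default: 0→A, −1→B, 1→C, 4→D, 6→E); unseen intervals
receive fresh letters in order of appearance.

## Intron naming and ORFs

Positional nomenclature names an intron by the coordinate, on a homologous
reference gene, of the base immediately 5′ of the insertion (mL2450 for an
*rnl* intron behind reference position 2450; cox1P1125 for a *cox1*
intron). The spliced host is aligned globally to the reference
(Biostrings `pairwiseAlignment`, match 2 / mismatch −2, affine gaps
10/0.5); when the junction base aligns to a reference gap the nearest
upstream reference-aligned base is used; alignments under 40% identity are
an error, not a number — a wrong name is worse than no name. Reference
sequences are user-supplied configuration: published names are reproduced
only when the same reference is used, so the reference is recorded in the
output. Without a reference the insertion index on the host itself is
reported (exact for the synthetic fixtures, where the host is its own
reference).

ORF detection scans the three sense-strand frames only — these genomes are
transcribed from one strand — for ATG-to-stop ORFs of ≥300 nt (stop
included) under translation table 4, keeps the longest ORF per stop, and
suppresses ORFs nested inside a longer ORF's span. Names follow `orf<aa>`
(an `orf450` spans 1353 nt). Homing-endonuclease classes are a heuristic
motif match on the translation (a LAGLIDADG block, or GIY…YIG with a 6–12
residue spacer); `unknown` means no motif matched, never the absence of an
endonuclease. Group I subgroup labels (IA/IB) are annotation passthrough —
structural RNA classification is out of scope.

## Intraspecific variation

Near-identical genomes are aligned by banded global dynamic programming
with affine gaps (match +1, mismatch −1, gap open 10, extension 0.5 per
base), each sequence against the first (anchor), and the pairwise
alignments are merged on anchor coordinates. The band is anchored on both
the start and the end diagonal, so the net length difference is always
inside the corridor: any single indel, however long, aligns exactly. The
guarantee required of the band half-width (default 200) is that the
*cumulative balanced excursion* of indels stays inside it — generously
satisfied by intraspecific mitogenome data, where indels are a handful of
1–9 nt events. If the optimal path touches the band edge the band doubles,
up to four times the requested width, before erroring; with these
penalties a mismatch-through path usually wins before the edge is ever
touched, so this mechanism is defensive, and pathological inputs
(rearranged, not merely diverged, sequences) are outside the method's
contract. Pre-aligned FASTA can bypass the aligner entirely
(`as_mito_alignment()`), so externally produced alignments are tallied
identically.

Site classification is column-wise and disjoint: a column containing any
gap is an indel site; a gap-free column with ≥2 distinct bases is a
variable site. Divergence is reported as
100·(indel + variable sites)/alignment length — with the published counts
for a three-individual *Stachybotrys* comparison (33 + 36 over ≈30.7 kb)
this is the definition that reproduces the printed 0.22% — and the
substitutions-only rate is reported alongside, since source texts rarely
state which definition they used. Every variable site maps through the
reference row to genic/intergenic space and, inside coding genes, receives
a synonymous/nonsynonymous call by translating the reference and alternate
codons under translation table 4 (the mold mitochondrial code, TGA = Trp —
the appropriate code for fungal mitochondria even when a source does not
name it). A variable site whose codon is disrupted by an alignment gap is
flagged `indel_adjacent` and excluded from the coding census rather than
guessed.

## Ancestral states under the Mk model

Discrete mitogenomic characters — arrangement pattern, joining state — are
reconstructed on a rooted, branch-length tree under the equal-rates k-state
Markov (Mk) model with transition probability
P(i→j, t) = 1/k + (δ<sub>ij</sub> − 1/k)·e<sup>−k·r·t/(k−1)</sup> and a
uniform root prior. Likelihoods come from Felsenstein pruning with
per-node rescaling; multifurcations are handled natively (no arbitrary
resolution); taxa missing from the state matrix contribute all-ones
partials (no information) rather than being dropped. The rate is estimated
by one-dimensional ML over log-rate on [10⁻⁶, 10³] (Brent's method,
tolerance 10⁻⁶); an invariant character is reported at the interval's
lower bound with an explicit flag, since its likelihood is maximized as
the rate tends to zero. Marginal node probabilities combine upward
partials with downward messages; the per-node "occurrence" of a state is
that probability as a percentage, and transition events are counted
parsimony-style as branches where the maximum-probability state changes.

This is a deliberate re-design of the Bayesian binary MCMC tools often
used for such characters: the scientific conclusions at stake are *which
state is ancestral* and its approximate support, which marginal ML
probabilities address directly, deterministically, and testably — the test
suite proves the pruning likelihood equal to full enumeration over
internal-node states on small trees to 10⁻¹⁰, a guarantee no MCMC run
offers. Numeric equality with any particular MCMC tool's "occurrence"
values is not claimed.

A known sensitivity: root recovery on simulated slow characters (k = 6,
100 leaves, rate 0.1 changes per tree depth) exceeds 95% on Yule
(speciation) trees, the appropriate null model for interspecific surveys,
and is used at that setting in the acceptance checks. On coalescent tree
shapes, whose basal internodes are vanishingly short, the Bayes-optimal
recovery itself is only ≈94–96% — an irreducible-information limit of the
tree shape, not an implementation artifact.

## What the synthetic generator emulates — and what it does not

`generate_mitogenome()` builds the default "stachybotrys-like" fixture:
a ~30.7 kb circular molecule (AT 73.7%, AT skew −0.02, GC skew 0.12), all
genes on one strand in the arrangement with *cox1* between *rnl* and
*nad2*, 14 core PCGs + 2 rRNAs + 28 tRNAs + 2 free-standing ORFs, a
one-base *nad4L*/*nad5* overlap and an abutting *nad2*/*nad3* junction,
GTG/TTG starts on *cob*/*cox3* and TAG stops on *atp9*/*nad5*, and two
group I introns — mL2450 in *rnl* carrying an rps3-like 450-aa ORF and
cox1P1125 in *cox1* carrying a 712-aa LAGLIDADG-motif ORF (1600 + 2284 =
3884 intronic nt). Coding sequences are sampled codon-wise from the
non-stop codons of table 4, so spliced CDSs never contain internal stops;
intron boundaries honor the upstream-exon-T/intron-final-G signature;
spacers are drawn uniformly from 60–180 nt, which lands total size near
the 30.7 kb target. Every random draw is governed by one explicit seed and
each planted property is logged, so downstream reports are predictable
exactly — the round-trip property the acceptance suite exercises.

Deliberate non-realism, and hence what passing tests do **not** show about
real data: spacer and RNA-gene sequences are i.i.d. base draws (no
repeats, no secondary structure, no promoter-like motifs); codon usage is
composition-driven, not organism-specific (realized AT% sits a few tenths
below target because start/stop codons are fixed and stops are excluded
from interior sampling); tRNAs are random sequences of plausible length,
not foldable cloverleaves; mutation planting keeps events ≥20 nt apart and
away from region boundaries, so the aligner's column-to-event
correspondence is exact by construction — real data can place variants
adjacently where alignment ambiguity is irreducible. The generator
validates the *machinery*; claims about real genomes rest on the deposited
records the machinery was built to process.

`mutate_individuals()` defaults mirror the intraspecific splits observed
in these fungi (substitutions 23/36 genic, indels 9/33 genic, indel
lengths 1–9 nt, echoing the observed 9 nt deletion), with
synonymous/nonsynonymous ground truth computed at plant time.
`simulate_characters()` evolves a k-state character by drawing the root
uniformly and applying the exact Mk transition kernel along each branch,
logging true internal states.

## Problem sizes and numerical choices in the test suite

Unit and property tests run on full-size (~30 kb) synthetic genomes for
the pipeline stages and on reduced sizes where an oracle is the
bottleneck: unbanded-DP score equivalence at 150–400 bp, likelihood
enumeration at ≤6 leaves and k ≤ 4 (10⁻¹⁰ tolerance), Monte-Carlo
transition frequencies at 10⁴ branch simulations (2% tolerance), rate
recovery at 50 seeded replicates on a 64-leaf tree with the true rate
chosen so the tree carries ~15 expected changes (the regime where a single
character is informative about its rate), and root-state recovery at 50
seeded replicates on a 100-leaf Yule tree. Composition targets are
verified within ±1.5 percentage points at 30 kb, the binomial sampling
width plus the small codon-constraint bias noted above.

## Known limitations

- GenBank parsing covers the feature grammar of organelle records (LOCUS
  topology, CDS/tRNA/rRNA/intron keys, join/complement locations, quoted
  multi-line qualifiers); it is not a general-purpose flat-file parser.
- tRNA duplicate numbering (`trnM_1`, `trnM_2`, …) follows genome order
  from the canonical start; public records that numbered duplicates by
  anticodon will match in content but may differ in suffix assignment.
- The banded aligner targets ≥95% identity; balanced insertion/deletion
  excursions larger than the band can silently produce a locally optimal
  but globally suboptimal alignment (see the variation section), so the
  band default is set far above anything intraspecific data produce.
- Intron positional names are only as comparable as the reference
  sequences supplied; the package records the reference used rather than
  assuming one.
- The Mk model assumes exchangeable states and rate homogeneity across the
  tree; characters whose transitions are strongly asymmetric (e.g.
  intron gain vs. loss) would need a richer model than the one offered.
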