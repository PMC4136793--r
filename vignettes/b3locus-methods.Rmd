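---
title: "Methods: annotating a fungal B mating-type locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating a fungal B mating-type locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b3locus)
```

## Scope and model

Tetrapolar basidiomycetes mate under the control of two loci; the *B*
locus encodes lipopeptide pheromones and STE3-class G-protein-coupled
receptors. `b3locus` re-implements, as reusable and testable functions,
the desk analyses used to characterize such a locus from clone
sequences: physical-map assembly from two overlapping fosmid-scale
contigs, six-frame small-ORF mining, pheromone-precursor classification
from the CaaX prenylation motif and a cleavage-site consensus, 7-TM
receptor topology from hydropathy, pairwise global-alignment identity,
in-silico PCR for the locus-specific marker, and calibrated qRT-PCR
relative expression with one-way ANOVA/Tukey group tests. Wet-lab
steps (library construction, transformation, crossing), intron-aware
gene prediction and remote homology searches are out of scope; receptor
genes are supplied as cDNA or protein sequences.

## Pheromone grammar

Precursors are small ORFs (the mining window is 10–100 translated
residues, initiator Met counted, stop excluded). Classification
requires:

* a **CaaX motif**: cysteine at the 4th position from the C-terminus.
  The two "a" positions are deliberately unconstrained because
  characterized basidiomycete pheromones include CXXX variants (CVCH,
  CVRG, CVVA) whose third residue is not aliphatic.
* a **cleavage doublet**: ER or TR whose second residue (the cut-site
  reference) lies at C-terminal offset 13–19 by default. Each site is
  scored 1 for the doublet, +1 for Pro at cut-site position −4, +1 for
  Asp/Asn at −2.

The mature pheromone is the segment strictly after the doublet through
the CaaX cysteine inclusive (the three terminal residues are removed
during prenylation processing), so a doublet at offset *o* gives a
mature length of *o* − 4. The default window therefore spans mature
lengths 9–15, with 12–13 preferred. The source analyses describe the
doublet "at the 9–15th sites from the C-terminus" while also inferring
12–13-residue matures; those two counts are arithmetically
incompatible under the doublet-to-Cys rule, so the window is exposed as
configuration (`window`, `accept_len`, `preferred_len`) rather than
hard-coded, and the default is the one consistent with the mature-length
evidence. Site choice orders by score, then membership of the preferred
length band, then the smaller offset; strict mode demands an acceptable
site, permissive mode keeps CaaX-only candidates with a warning. ORF
mining returns every ATG-initiated, first-stop-terminated candidate
(no nested-ORF suppression): recall matters more than parsimony because
a downstream grammar does the selecting.

## Receptor topology

Transmembrane calling is a single-sequence hydropathy method (the
published analyses delegated this to external topology servers, which
an offline pipeline cannot depend on): Kyte–Doolittle values are
averaged in a centered window (default 19 residues, truncated at the
edges), maximal runs at or above a threshold (default 1.6) are found,
runs closer than `merge_gap` (default 3) merge, boundaries are refined
to the underlying hydrophobic stretch by extending/trimming on the sign
of per-residue hydropathy, and refined segments shorter than `min_len`
(default 15) are dropped. The refinement step makes the reported
segment ends coincide with the hydrophobic stretch itself rather than
with the smoothed run, which is what makes tail lengths exact on
sequences with crisp hydrophobic/hydrophilic boundaries; on real
proteins boundaries remain predictor-dependent, so only the segment
count and tail lengths should be treated as the asserted quantities.

Topology alternates from an extracellular N-terminus (the STE3
convention; no signal-peptide modelling), so with seven segments the
C-terminal tail is cytoplasmic. A protein is flagged *receptor-like*
when it has exactly 7 TM segments and a C-tail shorter than
`tail_threshold` (default 50 aa — short-tailed receptors of 26–35 aa
fall below it, conventional 300+ aa tails far above; the threshold is
configurable because known receptors sit near 54 aa).

## Alignment identity

`global_identity()` is a hand-written Needleman–Wunsch/Gotoh global
aligner (BLOSUM62 default, affine gaps with open 10 and extend 0.5; a
gap of length L costs open + extend·L, terminal gaps included, matching
the convention of Biostrings' `pairwiseAlignment`, which the test suite
uses as an independent cross-check). Identity is matches over aligned
columns, gapped columns included ("full length"). `mode = "truncated"`
first cuts the longer sequence to `truncate_len` (default: the shorter
length), mirroring comparisons against a receptor whose
non-corresponding C-terminal extension is removed.

## Physical map

`merge_contigs()` joins two clones on their longest exact
suffix/prefix match (both orientations of the second contig are
tried). Exact matching is a design choice: both clones derive from one
genome, and mismatch-tolerant assembly is a different problem. All
public coordinates are 1-based inclusive; BED's 0-based half-open
convention is confined to the writer/reader (via rtracklayer), and the
GFF3↔BED↔CSV round trip is lossless for name, kind, coordinates and
strand (BED carries the kind inside its name column as `name|kind`).
The mating-gene span is computed over pheromone and receptor features
only, excluding flanking homologs — on the packaged coordinate fixture
it is 38,224 − 26,325 + 1 = 11,900 nt. In-silico PCR is exact-match by
contract: one mismatch yields no product.

## Expression

Target Ct values are normalized per replicate against the duplexed
internal-standard gene (ΔCt), averaged per condition, and calibrated so
the calibrator condition (monokaryon by default) is exactly 1:
fold = E^(ΔCt_cal − ΔCt_cond). The instrument software's standard-curve
settings are not recoverable from deposited Ct values, so the default
efficiency is E = 2 (the ΔΔCt assumption), overridable per analysis.
Group separation uses `stats::aov` plus Tukey HSD at α = 0.05 with
compact letter display via multcomp; the degenerate all-zero-variance
case is flagged rather than tested.

## The synthetic locus

`generate_locus()` emulates the study conditions end to end: a 60,000-nt
region carried on clones of 40,400 and 32,700 nt sharing a 13,100-nt
exact overlap (the published clone sizes; the overlap size is this
package's construction), i.i.d. background at GC 0.5, four intron-free
precursor genes of 57–61 codons with mature lengths 12–13 and four
receptor genes placed at the published start coordinates, a 2.1-kb
marker amplicon inside the overlap region, grammar-ablated decoy ORFs
(CaaX without doublet, doublet without CaaX, oversize) in the flanks,
and triplicate Ct tables with Gaussian cycle noise (default sd 0.1) and
injected monokaryon/dikaryon folds inside the reported ranges
(receptors 3.8–12.2, pheromones 1.5–31.4). Receptor geometry (57-aa
N-tail, 21-aa TMs, 15-aa loops, C-tails 34/126/264/176 aa) reproduces
the deposited protein lengths 328/420/558/470 aa. The published genomic
spans include introns and UTRs, so the intron-free genes keep the
published starts but take CDS-derived ends; the published end
coordinates are preserved verbatim in the packaged fixture.

Two generator details matter for interpretation. First, precursor
bodies avoid internal Met and avoid Arg at offsets where it could seed
a competing cleavage site, so each truth gene has a unique,
maximum-score site — recovery tests test the annotator, not tie-break
luck. Second, after embedding, the assembly is *sanitized*: any
background ORF that would pass the strict grammar by chance (about one
per 60 kb is expected under i.i.d. composition) is disrupted by a
single deterministic base edit, or by a synonymous codon swap when it
lies inside a truth gene, so the emitted truth set is exhaustive and
generator precision is 1.0 by construction. Consequently, end-to-end
recovery tests demonstrate correctness of the implementation under the
generative model — not the false-positive rate of the grammar on real
genomes, which the decoy and shuffled-composition tests measure
instead. The generator does not simulate introns, repeats, sequencing
error or read-level data.

All randomness flows from one seed (`locus_spec(seed = )`, default 42,
also the default of the command-line `simulate`); identical spec and
seed give byte-identical FASTA/GFF3/CSV outputs (the GFF3 writer drops
the volatile `##date` pragma for this reason).

## Numerical and testing choices

Codons containing N translate to X unless every resolution agrees
(GCN → Ala does; CTN → Leu does too, and is resolved by this package's
own expander since the delegated translator is more conservative).
Trailing partial codons are dropped silently — frame scans depend on
it. Test problem sizes are chosen to keep the oracle comparisons
exhaustive where claimed: brute-force ORF enumeration on ≤ 2-kb
contigs, exhaustive alignment enumeration on ≤ 8-residue pairs, a
1,000-feature annotation round trip, 100-receptor topology recovery,
and 200-simulation fold-recovery checks. The qPCR ±10% recovery check
runs at the generator defaults (triplicates, 0.1-cycle noise), where
the sampling error of a fold estimate is about 8% — the tolerance is
tight by design and is evaluated at the package's fixed default seed.

## Known limitations

* The TM caller is a hydropathy heuristic, not an HMM; segment
  boundaries on real receptors are approximate even though counts and
  tails are stable.
* Identity percentages depend on the documented scoring; other
  matrices/penalties give different values.
* The locus assembler requires an exact overlap and two contigs.
* Expression analysis assumes one reference gene and a shared
  amplification efficiency unless overridden per gene.
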