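# b3locus

Annotation toolkit for the pheromone/receptor (*B*) mating-type locus
of agaricomycete fungi.

Tetrapolar mushrooms mate only when both mating loci are compatible;
the *B* locus carries lipopeptide **pheromone precursor** genes and
STE3-class **7-transmembrane receptor** genes. Characterizing such a
locus from clone sequences is a chain of small, well-defined desk
analyses, and `b3locus` packages that chain for people studying
mating-type genetics in edible and model mushrooms:

* **Physical map** — merge two overlapping clone contigs on their
  longest exact suffix/prefix match; place typed gene features; compute
  the mating-gene span; localize the locus-specific SCAR amplicon by
  exact in-silico PCR; read/write GFF3, BED and CSV losslessly.
* **Pheromone mining** — six-frame extraction of small ORFs
  (10–100 aa), then classification by the precursor grammar: a
  C-terminal CaaX motif (Cys at −4; the "a" positions unconstrained, so
  CXXX variants such as CVCH/CVRG/CVVA count) plus an ER/TR cleavage
  doublet with Pro at −4 and Asp/Asn at −2 of the cut site. The mature
  pheromone is the segment after the doublet through the farnesylated
  Cys: a doublet at C-terminal offset *o* gives a mature length
  *o* − 4 (defaults span 9–15 aa, preferring 12–13).
* **Receptor topology** — Kyte–Doolittle hydropathy TM calling
  (window 19, threshold 1.6, min length 15, merge gap 3, boundary
  refinement), alternating topology from an extracellular N-terminus,
  C-tail measurement, and a *receptor-like* flag for 7-TM proteins with
  a short (< 50 aa) cytoplasmic tail.
* **Alignment identity** — global Needleman–Wunsch with affine gaps
  (BLOSUM62, open 10, extend 0.5), identity = matches / aligned columns
  including gaps, with a truncated mode for C-terminally diverged pairs.
* **Expression** — calibrated qRT-PCR: fold = E^(ΔCt_cal − ΔCt_cond)
  with the calibrator condition ≡ 1, then one-way ANOVA + Tukey HSD
  (α = 0.05) group letters.
* **Synthetic locus** — a truth-labelled simulator (contigs, genes,
  decoys, primers, Ct tables) so the whole pipeline is testable
  offline; see the methods vignette for what it does and does not
  emulate.

## Worked example

```r
library(b3locus)

sim <- generate_locus(locus_spec(seed = 42))
res <- run_pipeline(sim$contigs[[1]], sim$contigs[[2]],
                    receptors = Biostrings::DNAStringSet(sim$truth$receptor_cdna),
                    ct = sim$ct, primers = sim$truth$primers)
res
#> <b3 locus pipeline>
#>   assembly: 60000 nt (overlap 13100 nt)
#>   small ORFs scanned: 1206
#>   pheromone precursors: 4
#>   7-TM receptors: 4 ( receptor-like: 1 )
#>   mating-gene span: 11667 nt
#>   marker amplicon: 33000 - 35099
```

The two 40.4-kb/32.7-kb contigs merged into a 60-kb assembly on their
13.1-kb overlap; of ~1,200 small ORFs, exactly the four embedded
precursors pass the strict grammar; all four receptors are 7-TM, one of
them receptor-like; the eight mating genes span under 12 kb and the
marker amplicon is recovered at its true interval.

```r
res$pheromone_report[, c("name", "start", "end", "strand", "caax",
                         "doublet", "mature_peptide")]
#>          name start   end strand caax doublet mature_peptide
#> 1 pheromone_1 26325 26501      + CRYR      ER   IAYDQFQCKGSC
#> 2 pheromone_2 27056 27241      - CKYD      TR  TVNNLEWNILRDC
#> 3 pheromone_3 29629 29808      + CITY      TR   PHSVVKCEGKDC
#> 4 pheromone_4 35693 35866      - CCGV      TR   GHQAENPVQSKC

res$receptors$report[, c("id", "length_aa", "n_tm", "c_tail_len", "receptor_like")]
#>           id length_aa n_tm c_tail_len receptor_like
#> 1 PESTE3.3.1       328    7         34          TRUE
#> 2 PESTE3.3.2       420    7        126         FALSE
#> 3 PESTE3.3.3       558    7        264         FALSE
#> 4 PESTE3.3.4       470    7        176         FALSE
```

Each predicted mature peptide ends in the farnesylated Cys; the
simulated receptors reproduce the deposited protein lengths, and the
34-residue C-tail marks the receptor-like gene. Calibrated expression
recovers the injected monokaryon/dikaryon folds (receptors 3.8–12.2,
pheromones 1.5–31.4):

```r
round(condition_ratio(relative_expression(sim$ct), "monokaryon", "dikaryon"), 2)
#>   PEphb3.1   PEphb3.2   PEphb3.3   PEphb3.4 PESTE3.3.1 PESTE3.3.2 PESTE3.3.3
#>       1.53      32.13       4.46       9.98       3.58       4.63       8.81
#> PESTE3.3.4
#>       8.81
```

A published coordinate table for the locus ships as a fixture:
`mating_span(locus_feature_fixture())` returns `11900` (nt), the
mating-gene span implied by the printed gene positions.

A thin command-line front end is installed as `exec/b3locus`
(`b3locus simulate --seed 42 --out dir`, `orfs`, `scan-pheromones`,
`annotate-receptors`, `identity`, `merge`, `pcr`, `map`, `expression`,
`run`, `--version`).

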