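---
title: "Quantifying CRISPR editing outcomes and screening HDR-enhancing variants with ampedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes and screening HDR-enhancing variants with ampedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## Background

When Cas9 cuts a locus such as *HBB* in hematopoietic stem and progenitor
cells, the double-strand break is resolved by competing repair pathways:
homology-directed repair (HDR) copies a supplied donor template; classical
non-homologous end joining (NHEJ) produces short indels; and
microhomology-mediated end joining (MMEJ), which depends on polymerase
theta (POLQ), produces a characteristic subset of those indels. At *HBB*
an additional outcome exists: the break can be repaired by gene conversion
from the neighbouring homolog *HBD*, recognisable by up to six
homolog-specific SNPs appearing in the amplicon.

ampedit implements the computational side of a screening-and-validation
workflow around these outcomes:

1. **Library design** (`enumerate_nnk()`, `enumerate_combinatorial()`,
   `build_whitelist()`): enumerate saturation-mutagenesis (NNK) and
   fixed-codon combinatorial protein variant libraries and emit the exact
   whitelist of coding sequences expected in a pooled screen.
2. **Screen enrichment** (`count_variants()`, `qc_sample()`,
   `compute_fold_change()`, `call_hits()`): turn sorted HDR-positive
   (GFP+) and HDR-negative (GFP-) pool counts into QC-gated per-variant
   fold changes and hit calls.
3. **Outcome classification** (`align_global()`, `classify_read()`,
   `tally_reads()`): assign each amplicon read to
   WT / HDR / gene-conversion / indel-species classes by global alignment
   against a five-amplicon reference panel.
4. **Pathway partitioning** (`classify_mmej()`, `summarize_outcomes()`,
   `inhibition_by_length()`): split indel species into MMEJ vs NHEJ using
   paired POLQ-knockdown samples and produce the summary percentages.
5. **Colony genotyping** (`filter_and_call()`, `genotype_rates()`): call
   per-colony genotypes from CFU amplicon reads under depth and
   allele-fraction filters.
6. **Structure metrics** (`load_structure()`, `min_distance()`,
   `hbond_check()`): verify protein-interface hydrogen-bond contacts as
   heavy-atom distance computations on coordinate files.
7. **Synthetic data** (`make_panel()`, `simulate_reads()`,
   `simulate_screen_counts()`, `simulate_polq_arms()`,
   `simulate_colonies()`): generate every input above with hidden ground
   truth, so the whole pipeline is testable without external downloads.

## Library design

Combinatorial libraries use a fixed one-codon-per-amino-acid table
(`one_codon_table()`), so each protein variant has exactly one coding
sequence and the whitelist is injective. NNK saturation libraries carry
all 32 codons with third base G or T: 20 amino acids plus the TAG stop.
The stop codon stays in the nucleotide whitelist under the reserved id
`STOP` — reads carrying it are genuine library members — but it is
excluded from protein-level ranking. Codons that restore the parent amino
acid through a non-parent codon are *internal controls*, distinct from
*parent carry-over* (the parent's own codon, appended to the whitelist
when it is not itself an NNK codon). Screens resolve individual codons,
so amino acids with several NNK codons get codon-qualified ids
(`L67R.CGG`).

A two-position combinatorial library over the 18-residue alphabet that
excludes cysteine and methionine has `18^2 = 324` members; the full
alphabet gives `20^2 = 400`.

```{r library}
lib <- enumerate_nnk(paste0("ATG", "CTG", "GAG"), 2L)
table(lib$members$class)
```

## Screen enrichment scoring

Counting is exact full-sequence matching against the whitelist; anything
else is discarded, never fuzzily rescued, so `mapped + discarded` always
equals the input read count. Three QC gates follow the screening
protocol: a mapped-read floor (default `1e5`), a library-skew gate
(no single variant above 50% of mapped reads by default; the underlying
protocol requires "minimal skewing" without printing a number, so this is
configurable), and an internal-control gate. The internal-control gate
compares the pooled internal-control frequency with the parent carry-over
frequency as a relative difference `|f_ic - f_parent| / f_parent` and
fails above 0.10. The exact formula behind the published 10% rule is not
printed; the relative-difference reading is this package's documented
choice, with the boundary inclusive (exactly 10% passes, since the rule
is stated as a strict exceedance).

Fold change is the GFP+ relative frequency over the GFP- relative
frequency within the same replicate. Frequencies use a Haldane–Anscombe
pseudocount of 0.5 (`f = (count + 0.5) / (total + 0.5 n)`), keeping fold
changes finite at zero counts; the source protocol is silent on zero
counts. A variant is flagged *better than parent* when its mean fold
change is strictly above 1.0 or every replicate is strictly above 1.0
("over 1.0" is read as a strict inequality). Ranking is by mean fold
change, ties broken lexicographically so output is deterministic.

Note one subtlety the simulator makes visible: enriching some variants in
the HDR-positive pool necessarily *depletes* the rest after
renormalisation, so under a truth with 16 of 324 variants enriched the
null variants sit below fold change 1 and the flag rule recovers exactly
the enriched set at adequate depth.

## Read classification

### Alignment

`align_global()` is a global Needleman–Wunsch alignment with affine gaps
(Gotoh's three-state recurrence), written in C++ for speed. A gap of
length L scores `gap_open + L * gap_extend`; defaults are match +5,
mismatch -4, gap open -20, gap extend -2 — needle-style scoring of the
kind commonly used by amplicon indel callers (the exact parameter table
of the published pipeline is in an unavailable supplement, so these
defaults are a stated surrogate and fully configurable). Tie-breaking is
deterministic: substitutions are preferred over gaps, and equal-scoring
gaps are placed leftmost. `N` matches nothing and scores as a mismatch.
Coordinates are 0-based; deletions are half-open intervals; insertions
are anchored to the reference offset they precede. The aligner is tested
against an independently implemented exhaustive dynamic program and
against `Biostrings::pairwiseAlignment()` as a second oracle.

### The five-amplicon panel and the decision rule

A read is aligned to all five references (WT, HDR, full conversion, two
partial conversions) and assigned to the best score, ties resolved by the
fixed precedence HDR > WT > full > 5' partial > 3' partial. Then:

1. identity below the floor (default 0.6 of read length) discards the
   read rather than force-classifying it;
2. any indel overlapping the quantification window makes the read
   `INDEL`, with its species signature — (net length, leftmost offset
   relative to the cut, inserted bases) — computed from the WT-referenced
   alignment;
3. otherwise the class is the assigned amplicon, except that a
   WT-assigned read with a substitution at a window base and no indel
   anywhere is a `CUTSITE_MISMATCH` — the minimal gene-conversion tract,
   counted into the aggregated conversion estimate together with full and
   partial conversion reads.

A partial-conversion read that also carries a window indel counts as
`INDEL` (rule 2 precedes rule 3); the source does not state this case, so
the precedence is a documented choice. Substitutions outside the window
never change the class.

### The quantification window

The window has half-width `w` around the cut bond (default `w = 1`, the
narrowest conventional choice; the published value is not printed).
Overlap is assessed on the bond interval `[cut - w, cut + w]` with
inclusive ends, for deletions and insertion anchors alike. The inclusive
ends matter: leftmost gap placement can shift an indel by one position
along a homopolymer run, and a strictly interior window would then miss a
genuine cut-site insertion whose inserted base happens to equal its
neighbour. Widening the window never decreases the indel count
(a tested invariant).

Because signatures are reported from the leftmost-placed alignment, a
species defined at the cut may be reported at an equivalent shifted
position; comparisons against generator truth therefore canonicalise
species labels by classifying the pure template once.

## MMEJ vs NHEJ partitioning

For each indel species observed in paired POLQ-knockdown vs control
samples, a one-sided Welch *t*-test asks whether the species' allele
fraction is lower under knockdown. The test flavour is not stated in the
source; Welch is chosen for robustness at the n = 2–3 replicates typical
of these designs. Species below a control-fraction floor (default 0.1% of
alleles; *t*-tests on near-zero fractions are uninformative) or with
fewer than two replicates per arm stay untested and default to NHEJ.
p-values are Benjamini–Hochberg adjusted across the tested species of one
experiment (not across experiments), and q < 0.1 labels the species
POLQ-dependent, i.e. MMEJ. Degenerate constant-data cases resolve by
symmetry (identical arms give p = 0.5). The BH step is `stats::p.adjust`,
verified against a brute-force step-up oracle in the test suite.

Summaries report `%WT`, `%HDR`, `%HBD` (full + partial conversion +
cut-site mismatches), `%MMEJ` and `%NHEJ` over non-discarded reads; the
five always sum to 100. The edited-allele view divides each edit by
`(100 - %WT)` and is reported as unavailable (not zero) when `%WT = 100`.
Length-class inhibition compares NHEJ-derived indel fractions (MMEJ
species excluded from both sides) between a treated and a control sample
for net lengths {-1, -2, +2} versus all other lengths, as
`100 * (1 - treated/control)`; enrichment reports as negative inhibition
and a zero control fraction as unavailable.

## Colony genotyping

Colonies with fewer than 2000 aligned (classified, non-discarded) reads
are NoCall `low_depth`. Alleles are present at >= 10% of aligned reads;
more than two present alleles is NoCall `too_many_alleles` (likely not a
single clone). Two present alleles give a heterozygous call; one present
allele is called homozygous by default — the most parsimonious reading
for a diploid clone, with a flag to treat such colonies as NoCall
instead, since the source does not state its handling. Category rates
(e.g. colonies bearing >= 1 HDR allele, or two indel alleles) are
computed over called colonies, with the NoCall rate reported separately
over all colonies.

## Structure metrics

`load_structure()` reads PDB or mmCIF via bio3d, keeps the first model,
resolves altlocs by occupancy, and retains waters so water-mediated
bridges can be inspected as chained distance checks. An H-bond is
declared when the minimum heavy-atom distance between donor and acceptor
selections is at most 3.5 Å — no hydrogen positions or angle terms, since
deposited structures at typical resolution lack hydrogens, and the exact
donor/acceptor atom behind a printed distance is generally unstated (the
minimum-over-set convention is the implemented surrogate). Distances are
reported rounded half-up to 0.1 Å.

The package bundles two *synthetic* interface models
(`synthetic_L67R_interface.pdb`, `synthetic_T14E_interface.pdb`) whose
hand-designed geometry mimics the described arginine-to-aspartate
(2.8 Å) and glutamate-to-tyrosine (2.6 Å, plus a 2.9 Å backbone-amide
contact) interactions; they exercise selection, distance and verdict
machinery. They are stand-ins, not deposited data.
`verify_reported_contacts()` runs the same computation on user-downloaded
deposited entries (8SVH, 8T2D); the library itself performs no network
access.

## What the synthetic data do and do not emulate

The generators reproduce: multinomial sampling of outcome classes,
substitution sequencing error at a configurable per-base rate, paired
sorted-pool counts with known enrichment factors, knockdown arms with
known per-species multipliers (renormalised, as expected when a pathway
is suppressed), and diploid colonies with ~50/50 allele sampling, low
depth and three-allele contamination. Reads are single full-length
amplicon spans — the 142-bp amplicon of the motivating assay fits inside
one 150-nt read, so paired-end merging is out of scope. Sequencing error
is substitution-only by default (indel sequencing errors would make truth
labels near the cut ambiguous); qualities are constant and no trimming is
performed anywhere. Not emulated: PCR bias, chimeras, UMIs, paired-end
overlap, donor-template sequence structure. Real amplicon coordinates are
not published, so panel coordinates (SNP offsets, cut placement) are
synthetic and labelled as such; the default layout puts three homolog
SNPs on each side of the cut with one within 2 nt of the bond so the
cut-site-mismatch rule is exercised. Passing tests therefore demonstrate
correctness of the algorithms under these idealised error models, not
robustness to every artefact of real sequencing.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100-nt and 142-nt
panels; 10^4 reads at substitution rate 10^-3 for classifier recovery
(recovery is exact at zero noise); screens at depth 10^6 with 3
replicates for enrichment recovery and hit-fraction computation; 100
simulated experiments each for MMEJ type-I error (all multipliers 1) and
power (multiplier 0.2 on a species at 5% control fraction, depth 10^5, 3
replicates per arm); and 40 colonies spanning low-depth and contaminated
cases. These sizes give Monte-Carlo errors comfortably inside the
tolerances asserted while keeping a full run in well under a minute of
compute for any single stage.

All generator RNG flows through explicit integer seeds; identical seeds
give bit-identical outputs. Alignment scores are small integers stored in
doubles, so score comparisons are exact.

## Known limitations

- The classifier is a desk-scale reimplementation of the decision rules,
  not a drop-in replacement for a full amplicon pipeline (no batch mode,
  base-editing modes, or plots).
- Species signatures are exact by default; a net-length-only matching
  mode is available for cross-sample comparisons, which is how lengths
  are typically reported.
- The heavy-atom H-bond criterion cannot distinguish donors from
  acceptors and will accept any close polar contact.
- The off-target assay is the same classifier run with a WT-only panel;
  only %WT and %indels are meaningful there.
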