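---
title: "Methods: restorer-gene discovery and CMS chimera analysis with rflscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restorer-gene discovery and CMS chimera analysis with rflscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflscan)
```

## The problem

Cytoplasmic male sterility (CMS) in wheat carrying *Triticum timopheevii*
cytoplasm is caused by an aberrant mitochondrial gene, and is suppressed by
nuclear restorer-of-fertility (Rf) genes. The molecular logic of such
systems is now well established: the CMS determinant is typically a
*chimeric* mitochondrial open reading frame that fuses the 5′ portion of a
conserved gene (often an ATP-synthase subunit such as *atp8*) to novel
sequence encoding a hydrophobic extension; the restorers are typically
members of the RFL clade of P-class pentatricopeptide-repeat (PPR)
proteins, which bind the CMS transcript sequence-specifically and trigger
its cleavage a short distance 3′ of the binding site.

`rflscan` implements the complete computational chain needed to identify
both sides of such a system from sequence and expression data:

1. six-frame ORF discovery (`find_orfs`),
2. PPR motif scanning, chaining and RFL classification (`scan_motifs`,
   `chain_motifs`, `classify_rfl`),
3. greedy identity clustering of RFL genes into cross-genotype
   orthogroups, plus capture-bait design (`greedy_cluster`,
   `design_capture_baits`),
4. phenotype-panel candidate selection (`select_candidates`),
5. pairwise mitochondrial genome comparison and chimera annotation
   (`unique_regions`, `species_specific_orfs`, `annotate_chimera`),
6. PPR-code binding-site prediction (`scan_transcript`),
7. RNA-seq normalisation, contrasts and coverage-based cleavage-site
   localisation (`size_factors`, `tpm`, `contrast_cluster`,
   `detect_cleavage`),
8. synthetic-data generators with planted ground truth for all of the
   above (`simulate_*`).

Everything runs on plain FASTA/GFF3/bedGraph/TSV inputs, and the whole
pipeline is exercisable end to end with `run_workflow()` on synthetic data
— no downloads required.

## Coordinate and sequence conventions

Internally every interval is 0-based half-open on the forward strand with
a strand flag; GFF3 input/output converts to and from 1-based inclusive
coordinates, and the conversion is an exact bijection. RNA input is
canonicalised to DNA letters (U→T) on read, so transcript and genomic
sequence behave identically. `N` (DNA) and `X` (protein) are neutral: they
score 0 in motif scanning, code-pair scoring and alignment.

## ORF discovery

`find_orfs` reproduces the getorf-style screen: in `between_stops` mode an
ORF is a maximal stop-free translated stretch between two stops (or
sequence ends) in each of six frames, with `min_nt = 279` (93 codons) as
default. Stretches touching a contig end are kept and flagged
`open_ended`, because capture contigs truncate genes. Codon counts are
sense codons (stop excluded); "more than 100 codons" screens are expressed
as `min_codons = 101`, keeping the strict reading of "exceeding" while the
inclusive variant remains one parameter away.

## PPR motif models and scanning

PPR motifs are fixed-length tandem repeats, so the package scans with
ungapped position-specific scoring matrices instead of profile HMMs: the
scan is deterministic, dependency-free, and exactly testable. The shipped
P (35 aa), L (36 aa) and S (31 aa) models are *synthetic*: they are built
by `build_motif_model()` from PPR-style consensus strings with a
documented emission mixture (55% consensus, 25% spread over the
consensus's conservative substitution group, the remainder uniform),
scored as log2 odds against a uniform background. Original profile HMMs
from curated alignments are not redistributable here; any model can be
replaced by editing the TSVs under `inst/extdata/ppr_models/` or calling
`build_motif_model()` directly.

Per-model hit thresholds (30 bits for P and L, 26 for S) were calibrated
once against the generators' planted-motif constructions: a planted motif
scores roughly 68 ± 13 bits, a random window roughly −58 ± 10, so the
threshold sits many standard deviations from both and planted-motif
recovery is essentially exact. These thresholds are a design decision of
the package, not a quantity derivable from any particular HMM pipeline.

`chain_motifs` resolves overlapping hits by dynamic programming over the
non-overlapping-subset objective `sum(score) + 2 bits × (adjacent pairs)`,
where adjacent means a gap of at most 2 aa. The adjacency bonus encodes
the biology — RFL proteins carry tandem arrays of 15–20 P motifs — and is
verified against exhaustive subset enumeration in the tests. Ties break
toward more motifs, then smaller start-coordinate sum, making the chain
unique and reproducible.

The PPR code residues are positions 5 and 35, *1-based within the motif*.
This indexing is stated everywhere it matters because an off-by-one here
silently corrupts every downstream binding-site prediction.

## RFL classification

A protein with ≥ 10 P-class motifs is an RFL. `full_length` additionally
requires an initiator M, no internal stop, and ≥ 500 codons — the length
rule that separates functional restorer candidates from frameshift
fragments. Proteins under 500 codons are `partial`; proteins that are long
enough but fail the other requirements, or that end ≥ 35 aa short of
their orthogroup's longest member with the C-terminal motif running into
the premature end, are `truncated`. Whether truncation should be judged
absolutely or relative to the orthogroup is genuinely open; the package
implements the orthogroup-relative rule as the stricter, better-grounded
choice and only applies it when orthogroup context is supplied.

## Orthogrouping

`greedy_cluster` is a CD-HIT-style greedy clusterer at 96% identity:
sequences sorted by length descending join the first cluster whose
representative they match at identity ≥ 0.96 with alignment length ≥ 105
aa and at most 60 unaligned aa on the shorter sequence. Two deliberate
design choices:

* **Full alignment for every comparison.** CD-HIT's k-mer word filters are
  heuristics for million-sequence inputs; RFL panels are a few hundred
  sequences, so every comparison is a full Smith–Waterman–Gotoh local
  alignment (BLOSUM62, gap open 10 / extend 1, compiled kernel). This
  keeps the procedure deterministic, order-invariant, and exactly
  checkable against an independent alignment engine.
* **Inclusive threshold, "first" match mode.** A pair at exactly 96.0%
  joins; `match_mode = "best"` is available but not default.

The `-AS`/`-A`-style coverage options are interpreted as "max unaligned
length of the shorter sequence" and "minimum alignment length"; CD-HIT
versions differ subtly here, so the interpretation is fixed and
documented rather than inherited.

`design_capture_baits` tiles 95-nt probes every 36 nt with a final probe
flush to the target end, trimming or dropping probes that overlap mask
intervals (minimum probe 50 nt) — the geometry used for RFL sequence
capture.

## Candidate selection

`select_candidates` encodes the restorer screen as five orthogonal,
reportable rules: full-length presence in restorers, absence (or only
partial copies) in non-restorers, placement inside the genetic interval,
provenance, and the 500-codon length rule. The provenance rules differ by
gene: an Rf1 candidate group must contain a *T. timopheevii* member
(Rf1 introgressed from that species), while an Rf3 candidate group must
not contain a *T. timopheevii* member *identical* (100% identity over the
shorter sequence) to a restorer member (Rf3 is native wheat; a merely
similar paralog does not disqualify). Presence defaults to
all-restorers-required with an any-restorer relaxation flag. Genetic
mapping itself is out of scope: intervals enter as physical coordinates,
and `place_in_interval` maps genes by best local alignment, declaring
`unknown` on sub-90% identity or a second locus within 1% of the best
score (multi-copy genes cannot be placed).

The weak-restorer question — whether a partially restoring accession
counts as restorer or non-restorer — is left to the panel table on
purpose; the default panel contains only clear-cut genotypes.

## Mitochondrial comparison and chimera annotation

`unique_regions` defines a position of genome A as unique when *no* k-mer
window (k = 31) containing it occurs in genome B on either strand; maximal
runs of unique positions are the k-mer-mode report. This coverage-style
definition recovers a planted insert exactly on clean constructions,
which is why it replaces a literal "trim flank from raw window runs" rule
(window-start runs overhang an insert by k−1 on one side, and no fixed
trim is simultaneously correct for both ends). Anchor mode then refines
each run: the flanking shared k-mers are located in B (they must be
unique there, otherwise the run falls back to k-mer boundaries with a
warning) and exact matches are extended inward; the inter-anchor gap is
the reported insert. Anchor extension is exact-match, so a planted
boundary is only well-defined if the first and last inserted bases differ
from the bases they displace — the generators guarantee this.

`species_specific_orfs` calls an ORF genome-specific iff no single local
alignment against the partner genome covers ≥ 95% of the ORF at ≥ 95%
identity. The single-alignment requirement is the point: a chimera shares
its donor prefix with the partner genome, yet no one alignment covers the
intact ORF, so chimeras are correctly called specific.

`annotate_chimera` measures the donor prefix codon-exactly (ties toward
the longest donor CDS), the identical 5′ flank base-by-base, and the
unique region. Codon bookkeeping deserves a note: the ORF's codon count
is sense codons only, while `unique_codons` counts reading-frame triplets
fully inside the unique region *including the stop triplet*. A
279-sense-codon chimera with a 96-codon donor prefix and a 552-nt unique
region therefore reports 184 unique codons (183 sense + stop); the two
tallies overlap by design and both are reported, since summing 96 + 184
naively over-counts the ORF by its stop codon.

## PPR-code binding-site prediction

The code table maps (position-5, position-35) residue pairs to base
affinities over A/C/G/U. The quantitative in vitro affinity data behind
published tables is not redistributable, so the shipped default encodes
the canonical qualitative code (TN→A, TD→G, SN→A, SD→G, ND→U then C,
NS→C, NN→pyrimidines) as probabilities; every value is overridable from a
TSV. Scores are `log2(4·affinity)`, so an unseen combination or an N base
scores exactly 0 (uninformative). Motif N-terminus pairs with the RNA 5′
end; windows have the length of the code-pair list (a 20-motif RFL
predicts a 20-nt site); ranking ties break to the 5′-most window. All 20
P-motif pairs are scored — whether a C-terminal subset would be better is
open, and scoring all pairs is the neutral default. Reverse-strand genes
are handled by reporting-layer coordinate conversion only; the scan
itself is always transcript 5′→3′.

`site_cleavage_offset` classifies a site/cleavage pair as mechanistically
consistent when the cleavage lies 0–100 nt 3′ of the site end, the
empirical spacing for RFL-induced cleavage.

## Coverage normalisation and cleavage localisation

Coverage tracks are normalised to mean 1 over unmasked positions, so
masked rRNA or plastid-identical regions cannot distort scaling; masks
are consumed as input (computing them is an upstream alignment concern).
Normalisation is idempotent and the pre-normalisation mean is retained so
raw-depth thresholds remain applicable.

`detect_cleavage` scans the per-base fertile/sterile ratio
`r = (f + 0.05)/(s + 0.05)` with the two-window statistic
`mean(r over w bases 3′) / mean(r over w bases 5′)` (w = 50 nt) in
transcript orientation, calling the argmax. The orientation matters: in
restored plants the 5′ cleavage product is degraded and the 3′ product
persists, so the signature is low→high read 5′→3′. A call passes at fold
≥ 3 with raw sterile depth ≥ 10× in both windows. Pseudocounts (0.5 for
count ratios, 0.05 for normalised coverage) stabilise ratios at zero
coverage; both are configurable. At 100× depth and fold 5 the localisation
error is ≤ 2 nt (100-seed suite); calls are coverage-only, so ±2 nt is the
stated resolution — RACE-style wet-lab confirmation is outside this
package's scope. Power degrades with depth; at 10× the call still passes
but the statistic is visibly noisier.

For expression summaries the package uses the pseudoreference
(median-of-ratios) size factors, TPM, log2 fertile/sterile ratios with
pseudocount 0.5, average-linkage hierarchical clustering on Euclidean
distances (the clustering method is not dictated by the data; average
linkage is the conventional choice for expression ratio matrices and is
fixed for determinism), and SVD-based PCA of log2(normalised counts + 1).

## The synthetic-data generators

The generators are first-class, tested code, and their defaults *are* the
study conditions:

* `simulate_rfl_panel`: 21 paralog families (one planted
  restorer-specific family among 20 decoys) across the default
  8-genotype panel; founders are M + leader + 17–20 planted 35-aa P
  motifs + tail at 741–790 codons, the size range of full-length RFL
  proteins; members are substitution-only mutants at half the
  `1 − within_id` budget each (pairwise within-family identity ≈ 0.98 by
  default), and independent founders put between-family identity far
  below the 0.96 threshold. The planted family is full-length only in
  restorer genotypes, absent or truncated (< 500 aa) elsewhere;
  optionally one family is emitted as a frameshift pair 200 bp apart on
  one contig.
* `simulate_chimeric_genomes`: a 12-kb genome pair, identical except that
  genome A replaces the donor CDS (147 sense codons, atp8-sized) from
  codon 97 with a hydrophobic-biased unique extension: prefix 96 codons,
  unique region 552 nt including the chimera's own stop (TAG, distinct
  from the donor's TAA), giving a 279-sense-codon ORF. An in-frame stop
  sits immediately upstream so the between-stops ORF is exactly the CDS.
* `simulate_ppr_target`: 20 code pairs planted into a 20-motif protein
  and their argmax base string planted into a 1-kb transcript.
* `simulate_coverage`: Poisson coverage at 100× with the fertile track at
  depth/5 5′ of the planted cleavage position; the default plants the two
  restorer classes 110 nt apart on a 6-kb reference.
* `simulate_counts`: negative-binomial counts (dispersion 0.1) for 4
  genotypes × 3 anther stages, 10% up- and 10% down-regulated genes at
  4-fold in fertile samples, planted library-size multipliers in
  [0.5, 2].

Every generator is a pure function of (params, seed), restores the
caller's RNG state, and emits a machine-readable truth list
(`write_truth` serialises it).

**What the generators do not emulate** — and hence what passing tests do
not show about real data: capture and assembly artefacts, indel mutation
within families (substitution-only by default so identity arithmetic is
exact; an indel mode would change alignment-length bookkeeping),
mitochondrial recombination and substoichiometric variants, multi-mapping
coverage artefacts, and real codon usage (back-translation uses one fixed
codon per amino acid). Conclusions about algorithmic correctness transfer
to real data; conclusions about robustness to assembly noise do not.

## Problem sizes used by the test suite

The repeated-simulation checks run at the sizes stated by their claims:
100 selection panels, 100 binding-site transcripts, 100 coverage seeds,
20 clustering seeds, a 1–200-codon prefix sweep, and 100 planted-insert
constructions. For the repeated panel loops the generator keeps its
family structure (21 families, full-size proteins) but runs on a
4-genotype subset of the panel (two Rf1 restorers, the *T. timopheevii*
line, one maintainer); the phenotype logic being tested is unchanged and
the 5-family/4-genotype clustering panels match the scale at which the
partition claim is stated.

## Known limitations

* PSSM scanning cannot model insertions within a motif; a single indel
  inside a repeat shifts the register for that repeat. The chaining step
  tolerates this (the shifted motif simply scores lower or drops out),
  but motif counts can undercount by one in such cases.
* `greedy_cluster` is quadratic in panel size; it is meant for capture
  panels of hundreds to a few thousand sequences, not genome-wide PPR
  complements.
* `place_in_interval` takes the best hit per contig; two identical copies
  on one contig are not separately detected (cross-contig duplicates are,
  and return `unknown`).
* Cleavage calls are single-change-point: one transition per search
  region. Transcripts with multiple processing sites need per-region
  scans.
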