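---
title: "Tracking annotation errors behind MHD-only fungal transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking annotation errors behind MHD-only fungal transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbdrescue)
```

## The problem

The largest fungal transcription-factor family pairs an N-terminal
Zn(II)2Cys6 binuclear-cluster zinc finger (Zn2C6, the GAL4-type DBD, motif
`CX{2}CX{6}CX{5,16}CX{2}CX{6,8}C`) with a downstream middle homology domain
(MHD, "fungal_trans", an all-alpha domain of roughly 225-405 residues).
Public protein databases nevertheless contain large numbers of predicted
fungal proteins annotated with an MHD but no DNA-binding domain at all.
Since an MHD essentially never occurs without an upstream DBD in
experimentally supported proteins, these "MHD-only" records are prime
suspects for genome annotation artifacts: a frameshifted assembly, a gene
split across scaffolds, a start codon predicted downstream of the true one,
or a missed 5' exon all truncate the short N-terminal zinc finger while
leaving the long MHD intact.

`dbdrescue` implements the two protocols that turn this observation into a
sequence-curation tool, plus the synthetic benchmark machinery needed to
validate them without any external database access.

## Protocol 1: diagnosing a motif-less ortholog (`diagnose_missing_dbd`)

Given a reference full-architecture protein and the genome assembly in
which its annotated ortholog lacks the Zn2C6 motif, the protocol runs a
six-frame translated local search (a TBLASTN stand-in) of the reference
against every scaffold, keeps hits with identity above 95% and more than 20
aligned residues, and classifies in fixed order:

1. qualifying hits on two or more scaffolds: **assembly_split**;
2. hits on one scaffold in two or more reading frames: **frameshift**
   (a 1-2 nt insertion shifts all downstream codons into another frame);
3. a single hit covering 100% of the reference: **wrong_start**;
4. otherwise **undetermined**.

Coverage is the fraction of reference residues inside the union of
qualifying hit query spans, rounded to integer percent; the rule order
mirrors the order in which the causes are most safely distinguished (a
multi-scaffold signal is unambiguous; frame disagreement trumps coverage).
The diagnosis depends only on the hit set, never on input order.
`reconstruct_protein` then rebuilds a corrected protein by translating the
qualifying hits of one scaffold in their own frames, resolving overlaps in
favour of the higher-scoring hit, and checking the concatenation for the
full motif.

Two numerical choices matter here.  First, the translated search is a full
Smith-Waterman per frame (queries are desk-scale, so no word-seeding
heuristics are needed), iterated into the unaligned flanks so that several
separated segments per frame are all reported.  Second, optimal local
alignment keeps any net-positive extension, so a hit will occasionally
creep across a frameshift boundary into unrelated translation and dilute
its identity below the 95% filter; hits are therefore end-trimmed while a
15-column terminal window falls below 75% identity (or a 5-column window
below 70%), which is the same effect BLAST's X-drop termination has in
practice.  Trimming is disabled (`trim_ends = FALSE`) when the query is a
diverged homolog rather than a near-identical reference, because a 70%
identity alignment legitimately contains such windows.

## Protocol 2: recovering the missing DBD (`recover_dbd`)

For an MHD-only gene with no reference ortholog, the rescue protocol
searches the gene body plus 1000 nt upstream of the annotated start:

1. **Nearest neighbor** (`find_nearest_neighbor`): the query protein is
   aligned against reference panels of full-architecture proteins (one
   panel per DBD type); entries with E < 0.005 qualify and the best by
   E-value, then bitscore, then id, is the template.
2. **Local route**: the neighbor's DBD segment is searched against the
   genomic context by translated alignment; hits with E < 1e-4 become
   candidates (hit span plus 6 residues of slack each side).
3. **Global route**: the full neighbor protein is splice-aligned to the
   context; the candidate is the peptide aligned opposite the neighbor's
   DBD coordinates, again with 6 residues of slack.  The two routes are
   complementary: the spliced aligner recovers DBDs interrupted by introns,
   which fragment the local hits, while the local route is immune to the
   frame disruption that breaks the codon-structured global alignment.
4. **Validation**: each candidate is scored against a position-specific
   profile of the panel's own DBD segments (empirical E < 0.1) and must
   contain the conserved-residue patterns (two `C-x(2)-C` for Zn2C6; one
   `C-x(2,4)-C` and one `H-x(3,5)-H` for C2H2).  Candidates overlapping
   the annotated MHD are rejected.  The best validated candidate by
   profile score wins; the method is recorded as `both` when the two
   routes agree on the region.  An accepted Zn2C6 peptide is trimmed to
   its full-motif span, so the reported peptide is the domain itself.

Failures are triaged in this order: an undetermined-base (`N`) run of at
least 10 nt covering all candidate regions (`n_region`); a qualifying hit
appearing only when the window is widened to 2000 nt (`too_distant` — the
DBD sits beyond the search window); a candidate passing the profile but
failing the residue patterns (`partial_hit`, typically a mispredicted
short exon clipping one of the six cysteines); otherwise
`low_similarity`.  The distance probe deliberately runs before
`partial_hit` so a by-chance profile hit cannot mask a DBD sitting just
beyond the window.  `cterm_control` applies the identical machinery to the
region downstream of the MHD, where no DBD is expected, as the protocol's
false-positive control.

## Alignment engines and score statistics

All protein scoring uses BLOSUM62 with BLAST's default affine gaps
(open 11, extend 1).  `*` (stop) is rescored to -4 against everything:
a stop codon can never support homology evidence.  E-values follow
Karlin-Altschul, `E = K m n exp(-lambda S)` with the gapped BLOSUM62
defaults `lambda = 0.267`, `K = 0.041` and search space = query residues x
target nucleotides (panel residues for protein-protein search).  Exact
numerical parity with NCBI BLAST is out of scope; what matters is that the
protocol's published E-value cutoffs operate at their intended scale, and
the acceptance checks confirm the operating points behave as designed.

The spliced aligner is an O(mn) dynamic program over codon-aligned blocks
(Rcpp): global in the query (each residue aligned to a codon or deleted at
4 per residue), local in the genome, introns only between codons, starting
`GT` and ending `AG`, at least 20 nt, at a fixed opening penalty of 20.
Ties prefer fewer introns, then the leftmost genomic end.  Phase-1/2
introns and frameshifts inside blocks are deliberately unmodelled: split
codons are a minority of fungal introns, modelling them costs two extra
state families, and frameshift evidence is the translated search's job.
The intron penalty sits between the cost of deleting a handful of residues
and the score of a typical aligned DBD, so a genuine intron is always
cheaper than deleting the domain it interrupts.

## Profile validation without external HMMs

The published protocol validates candidates against curated Pfam HMMs.  To
stay self-contained, `build_dbd_profile` derives the validation profile
from the reference panel itself: Zn2C6 segments are anchored on their six
motif cysteines and their spacers left-aligned into maximum-width slots
(40 columns); C2H2 segments are stacked by star alignment to the longest
segment.  Column counts become log2-odds against a uniform background with
pseudocounts, weighted by bias-corrected information content so that
non-conserved columns contribute nothing, as near-background emissions
would in a profile HMM.  Skipping a sparsely occupied spacer slot is cheap
(0.2) while skipping a core column costs the full gap penalty, which is
the PSSM analogue of an HMM insert state and is what lets one profile
score domains whose spacers differ in length.  The profile "E-value" is
the empirical upper-tail probability of the candidate's score among 10,000
random uniform-background peptides of 1.5x the profile length (fixed
internal seed, so a profile is reproducible given its panel); the 0.1
acceptance threshold then has a direct false-positive interpretation.

## What the synthetic cohorts emulate

`make_cohort` generates compact fungal-style loci with complete truth
labels.  Each gene is `M + leader (8-20 aa) + DBD + linker (25-45 aa) +
MHD (250 aa) + tail (10-25 aa)`, encoded with uniformly drawn synonymous
codons, with 0-2 short (30-80 nt) GT-AG introns at codon boundaries in the
MHD-coding region and at least 1600 nt of random intergenic flank.  The
MHD is a cohort-wide conserved block mutated 10% per gene, which gives the
neighbor search its signal without attempting to model the real domain's
eight motifs.  The genome encodes a "strain" variant of the clean
reference protein (1% residue divergence; the motif cysteines/histidines
are protected, as they are the family signature being studied).  Spacer
and MHD residues exclude cysteine so the planted motif span is the unique
match and "exactly recovered" is well defined.  Amino-acid backgrounds are
uniform: nothing in the protocol depends on real fungal composition.

Planted error classes: `frameshift` inserts 1-2 nt at a linker codon
boundary (flanked by at least ~25 codons each side, emulating the errors
the 20-residue evidence threshold can see); `assembly_split` cuts the
scaffold between DBD and annotation start; `wrong_start` re-annotates the
gene from a linker codon; `missing_upstream_exon` puts the DBD in its own
exon separated by a 30-700 nt intron that the annotation omits;
`undetermined` removes the DBD-coding DNA altogether; `no_dbd` is a
genuinely DBD-less locus (its panel homolog still carries a fresh DBD, so
the rescue machinery runs and must reject).  Two preset spectra define the
study conditions: `spectrum_sgd_errors()` (frameshift 0.75, split 0.04,
wrong start 0.18, undetermined 0.03 — the observed strain-collection
spectrum) for the diagnosis cohort, generated intronless as in budding
yeast; and `spectrum_rescue_cohort()` (wrong start 0.4, missing upstream
exon 0.4, frameshift 0.2 — alternative starts and missed 5' exons dominate
the curated-database cases) for the rescue cohort, with panel homologs
mutated to 70% identity.

What passing on these cohorts does **not** show: performance on real
genomes with biased composition, repeats, non-canonical splice sites,
phase-1/2 introns, multi-gene scaffolds, or panels whose nearest neighbor
is much further than 70% identity.  The generator also plants exactly one
gene per scaffold and one error per gene.

## Problem sizes and defaults

The shipped tests and the acceptance script use cohorts of 200 genes
(diagnosis, rescue, and each null control), 500 random pairs for the
Smith-Waterman oracle check, exhaustive single-intron enumeration on
~100-130 nt toys, and 1000 random proteins for the motif-engine check;
these sizes give binomial confidence intervals comfortably inside the
margins being asserted.  All tunable parameters live in two objects:
`scoring_params()` (matrix, gaps, Karlin-Altschul, intron penalties,
genetic code — `code = "ctg_ser"` switches CTG to serine for CTG-clade
yeasts, off by default since the protocol's motif arithmetic is
code-agnostic) and `dbd_thresholds()` (all acceptance cutoffs and window
sizes, defaulting to the protocol's published operating points).

## Known limitations

Diagnosis precedence is fixed (split > frameshift > wrong start); a gene
with several simultaneous defects reports the first matching cause.  The
`undetermined` class is a catch-all: a clean single-frame hit with
sub-100% coverage, whatever the real reason.  Candidate boundaries carry
6 residues of slack, so a recovery whose peptide lacks a full motif is
reported untrimmed.  The spliced aligner's micro-exon handling is
best-effort: a 2-residue exon between two introns may be absorbed as
deletions when misplacing it scores no better (the `partial_hit` triage
exists precisely for the resulting five-of-six-cysteine candidates).
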