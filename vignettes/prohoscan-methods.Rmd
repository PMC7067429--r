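---
title: "Methods: comparative prohormone complement annotation"
author: "prohoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative prohormone complement annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prohoscan)
```

## The problem

Neuropeptides are cleaved from larger precursor proteins (prohormones).
Surveying the prohormone complement of a clade of non-model fish means
finding every prohormone gene in a mixed collection of genome and
transcriptome assemblies of uneven quality, reconciling the predictions
across assemblies and species into a gene/isoform catalog, classifying
how completely each assembly recovered each isoform, and summarising
per-gene evolutionary rates and tree congruence. prohoscan implements
that workflow end to end, together with a fully ground-truthed synthetic
clade generator so that every stage can be validated without any
external data.

## Pipeline model

The annotation stage is homology-guided. For each reference query
protein the package runs a Smith-Waterman search of all six frame
translations of every contig (BLOSUM62, gap open 11 / extend 1, so a gap
of length $k$ costs $11 + k$). Hits at or above a threshold —
by default 40% of the query's ungapped self-alignment score, a
deterministic, database-size-free stand-in for an E-value cutoff — are
mapped back to forward-strand nucleotide coordinates (all coordinates in
the package are 0-based half-open) and merged into disjoint loci.

For genome assemblies, the best locus is re-aligned with a
frameshift-aware protein-to-DNA dynamic program over (query position
$\times$ nucleotide position). Besides codon advances and affine
query/codon gaps it allows 1–2 nt "slips" at a penalty of 15, recorded
as frameshifts, and scores query residues against stop codons at a
penalty of 10. Premature stops are retained in the prediction as `*` and
flagged, not truncated: comparison across assemblies downstream is what
resolves them. The DP is query-global — terminal query gaps pay the
affine cost — while DNA flanks are free, except that an alignment
starting off the region's codon grid pays the frameshift penalty.
Regions are extracted codon-aligned to the hit frame, which makes that
grid meaningful and prevents the DP from silently absorbing a
5'-terminal insertion by re-framing the start. Internal uncovered query
positions are rendered as `X` placeholder runs in the predicted protein,
so later stages can distinguish coverage gaps from real sequence
differences.

For transcriptome assemblies, the best-scoring frame's match is expanded
to the enclosing ORF (flanking stops), anchored at the initiator
methionine implied by the query alignment; a prediction is complete only
when that M is present and the ORF ends at a stop codon inside the
transcript.

Evidence from multiple assemblies of one species is merged by preferring
the candidate with the fewest uncovered query positions; two candidates
covering complementary regions that agree exactly on at least 10
overlapping residues are spliced into one merged prediction. Ties break
by assembly-type priority G > H > I > T, then lexicographic assembly id.

### The rescue pass

Fast-evolving genes can score below the 40% first-pass threshold against
a distant reference even though they are present; a survey that stopped
there would misreport them as clade-level losses. After the first pass,
genes undetected in some assemblies are therefore re-searched
iteratively, using the best complete predictions recovered in other
species — and the original reference query — at an absolute score floor
of 60. A raw Smith-Waterman score of 60 corresponds to roughly
$E < 0.01$ for this search-space size under Karlin-Altschul statistics
with BLOSUM62 11/1 parameters, so the floor is permissive but still
significant. Two additional guards keep it from admitting junk: the
accepted alignment must span at least 40% of the rescue query, and the
rescued protein must be a *reciprocal best hit* — aligned back against
the entire reference set, it must match its own gene best. The iteration
matters: a sequence rescued in one species becomes the donor that finds
the gene in its sister species on the next round, so detection
propagates through a diverged clade from any seed.

## Isoform catalog

Within a gene, two predictions belong to the same isoform when their
global alignment differs only by substitutions, terminal coverage gaps,
or placeholder (`X`) regions; an internal indel at mutually covered
positions separates isoforms. Two further rules guard against
assembly-error isoforms: only complete predictions may found a new
isoform cluster (differences in incomplete sequences can be coverage
artifacts), and a non-primary cluster is accepted only with transcript
evidence in at least one species *or* presence as a distinct locus in at
least two genome assemblies. The source text for this rule is garbled in
the original description; we adopted this conservative reading, and the
permissive one (no transcript requirement) is available via
`require_transcript = FALSE`. Isoform ids are assigned deterministically
by descending species prevalence, ties broken by lexicographic exemplar
sequence. Per species, the representative is the prediction with the
fewest uncovered positions (ties: assembly-type priority, then assembly
id).

Clade-level gene loss is called at maximal clades in which every member
carrying a genome-type assembly lacks the gene, no member shows it at
all, and at least one outside species has it; clades with only
transcriptome evidence are reported as unsupported, because absence of
expression cannot prove loss. Duplications are reported when one query
matches two or more disjoint loci in a genome assembly, with per-species
copy counts.

## Recovery classification

Each gene/isoform is aligned across all assemblies (see MSA below) and
each row is classified by its longest run of gap columns: 0 gaps is
Exact, 1–4 Close, 5 or more Partial, and no prediction at all is Missed.
The published class definitions leave a run of exactly 5 unassigned
("less than 5" vs "more than 5"); we assign it to Partial so that Close
is strictly below 5 as printed. Terminal gap runs count toward the run
length — terminal truncations are incomplete recovery. Each sequence is
classified by its own row's runs (not against a designated reference
row). In the per-isoform tabulation, "complete" recovery means class
Exact or Close.

The progressive MSA builds a guide tree by neighbor joining on 3-mer
dissimilarity and merges profiles with an affine-gap profile-profile DP
under sum-of-pairs BLOSUM62 scoring. It is deterministic for a fixed
input order, and row order does not change any classification.

## Peptide features

The signal-peptide and cleavage-site stages are transparent rule-based
predictors, not trained models; the rule that fired is recorded. A
signal peptide requires the classic tripartite architecture over
candidate cut sites 10–40: a basic residue in the first five (n-region),
a hydrophobic stretch of at least 6 of {AILMFVW} (h-region), and small
residues {A,G,S,C,T} at the −3 and −1 positions of the cut (c-region).
Cleavage sites follow known-motif rules: dibasic KR/RR/KK/RK cut after
the second basic; monobasic R cuts when another basic sits at −3, −5 or
−7; sites immediately followed by proline, or inside the signal peptide,
are suppressed. Products are trimmed of C-terminal basics, and a product
ending in G after trimming is flagged as a potential amidation
substrate. Concatenating the signal peptide, the products and their
trimmed basics reconstructs the input exactly; products shorter than 2
aa are kept in the table but marked not retained.

## Evolutionary statistics

Per isoform, pairwise distances are the proportion of differing residues
over mutually ungapped, non-placeholder columns, Poisson-corrected
($d = -\ln(1-p)$, with $p$ capped at 0.999); pairs sharing fewer than 10
columns are flagged unreliable. Trees are built by neighbor joining
(negative branches clamped to zero with the deficit moved to the sibling
edge) — a deterministic, desk-scale stand-in for maximum-likelihood
search, adequate here because all downstream statistics are
property-based rather than likelihood-based.

MeaPED is 100 times the mean patristic (tree-path) distance over all
unordered in-scope leaf pairs, divided by the median ungapped sequence
length; the median of an even count is the mean of the central pair.
"Mean distance between species" is taken as mean patristic distance on
the isoform tree; with fewer than two in-scope leaves the value is
undefined (reported as missing, never 0). MeaPED scales linearly with
branch lengths, which the tests exploit as an exact invariant.

The Robinson-Foulds distance is the count of non-trivial bipartitions
present in exactly one tree, computed on the shared leaf set. nRF
divides by the maximum RF *observed* in the collection (matching the
original wording); division by the theoretical maximum $2(n-3)$ is
available as `mode = "possible"`. Pedges is the mean of the two directed
shared-bipartition fractions, with a star tree contributing 0 on its
side. Each isoform tree is compared against the fixed species reference
tree for its scope; which tree the original comparisons used is not
stated, and one reference per isoform is the reading most consistent
with "for each prohormone isoform". Family summaries are unweighted
means over member isoforms with a Total row; the duplicate-fate screen
labels a gene pair divergent when the MeaPED ratio (max/min) exceeds 5
(zero over zero is similar; nonzero over zero divergent).

## The synthetic clade generator

The generator emulates the data situation the pipeline is built for: a
Yule species tree (depth scaled to 1), a root complement of intronless
single-exon genes with per-gene rates, optional clade-level losses at a
named internal node (propagating to all descendant leaves), tandem
duplications (copies diverged on a star and given independent rate
multipliers in [1/2, 2]), and transcript-only splice isoforms. Proteins
evolve by site-wise substitution — along a branch of length $t$ each
site substitutes with probability $1-e^{-rt}$, replacement uniform over
the other 19 residues — a deliberately simple scheme whose closed-form
expectations provide exact test oracles. The initiator methionine is
pinned after evolution, as the start codon is part of the gene model.
Genome assemblies embed each CDS in ≥200 nt of random flank and apply
per-nucleotide substitutions, 1–2 nt frameshifting indels, in-frame 3 nt
indels, codon-to-stop edits, contig breaks inside the gene (truth class
Partial) and whole-gene omission (Missed). Transcriptomes emit
CDS-plus-UTR transcripts on a random strand, with expression dropout
(optionally forced per gene, emulating tissue-restricted sampling) and
5'/3' truncation (Partial when coding residues are lost). Every emitted
gene copy has one truth-ledger row with its artifact list, so recovery
can be audited directly.

What the generator does not emulate: introns and splice-aware
alignment (the prediction difficulties of interest — stop codons,
indels, coverage gaps — are all representable without introns),
sequencing reads and coverage profiles, codon-usage bias, an empirical
substitution matrix, and base-composition structure in the flanks.
Passing tests therefore demonstrate correctness of the pipeline logic
under a clean generative model, not performance on real assemblies,
where contamination, heterozygosity and mis-assembly add failure modes
the simulator does not produce.

All default artifact probabilities are 0; each study sets the rates it
needs, so a default simulation is the clean-recovery condition.

## Numerical choices and degenerate inputs

* Alignment scores are integers; all DP tie-breaks are fixed by
  evaluation order, so every result is deterministic.
* Local alignment scores are floored at 0; empty inputs give score 0
  and an absent prediction; DNA regions under 3 nt are absent.
* `nj_tree` on 2 labels returns a cherry splitting the distance; on 1,
  a single-leaf stub.
* RF/Pedges need at least 4 shared leaves for a non-trivial bipartition;
  smaller scopes report missing values.
* nRF with an all-zero collection is defined as 0 everywhere.
* Derived sub-seeds are small integer offsets of the run seed, so one
  seed reproduces every artifact byte-identically.

## Validation problem sizes

The test suite validates the kernels against independent plain-R
re-implementations and Biostrings on hundreds of random instances
(lengths ≤ 30), and runs the full pipeline at three scales chosen as
realistic desk-scale study conditions: 6 species × 8 genes artifact-free
(complete exact recovery expected), 12 species × 20 genes with per-gene
rates log-spaced over [0.01, 1.0] plus two injected clade losses and one
3-copy duplication (rank correlation between simulated rate and MeaPED,
exact loss and duplication recovery), and 8 species × 12 genes with 20%
contig breaks and 30% transcript dropout (classification fidelity).

## Known limitations

* The 40% self-score threshold is coarser than E-value statistics; the
  rescue pass compensates for remote homologs but a gene at ~1
  substitution/site over the tree depth sits at the edge of
  detectability for isolated lineages, as it would for any
  fixed-matrix homology search.
* The frameshift DP reads through a frameshift rather than paying the
  slip penalty when the wrong-frame continuation is very short and
  scores mildly (mismatch cost below the penalty); real gene models at
  realistic lengths are unaffected.
* The signal/cleavage rules are deliberately simple stand-ins for
  trained predictors and should not be used for presentation-quality
  peptide calls on real data.
* NJ on Poisson-corrected p-distances is a stand-in for ML tree search;
  topologies for very short or highly saturated isoforms are noisy, and
  the statistics are designed to be robust to that (nRF normalizes
  within the collection, family summaries average over isoforms).
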