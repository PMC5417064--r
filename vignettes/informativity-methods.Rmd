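---
title: "Informativity: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informativity: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(informativity)
```

## The problem and the model

Shotgun sequencing of environmental viral communities (viromes) yields
contigs that are classified, when they can be classified at all, by their
best BLAST hit against annotated genomes. Two properties of phage biology
undermine this: reference databases sample only a sliver of phage diversity,
and lateral gene transfer moves genes freely across taxa, so a strong hit to
a gene of taxon *X* may actually come from an unrelated virus carrying a
homolog of that gene. The method implemented here shifts the unit of
evidence from "a hit to the genome of *X*" to "a hit to a gene of *X*,
weighted by how much taxonomic signal that particular gene carries".

For each annotated coding region of the taxon of interest, two homology
comparisons are made before any metagenome is touched:

* **Step one — within-taxon conservation.** The gene is compared to the
  annotated proteins of each user-chosen relative genome. Per genome the
  best hit is taken; across genomes that have a homolog, the *lowest*
  weighted score — the most dissimilar within-taxon homolog — supplies
  (S~1~, Q~1~), the percent identity and query coverage. Using the most
  dissimilar relative makes the threshold a floor on what "still inside the
  taxon" looks like. A gene with no homolog in any relative gets
  S~1~ = Q~1~ = 0: it is unique to the single reference genome, and nothing
  can be concluded from observing it.
* **Step two — out-group similarity.** The gene is compared to every
  annotated protein of the assayed domain *minus* the taxon and its
  relatives. Here the single *best* hit supplies (S~2~, Q~2~): the strongest
  claim any other taxon has on this gene.

The taxonomic signal threshold is the pair T = (S~1~−S~2~, Q~1~−Q~2~),
collapsed to a scalar t = w~S~(S~1~−S~2~) + w~Q~(Q~1~−Q~2~). Genes with
t > 0 are *informative*; their detection in a sample is evidence for the
taxon (or a close relative). Genes with t ≤ 0 are *uninformative*, for one
of two machine-readable reasons: `outgroup_dominant` (some other taxon
matches the gene at least as well — the lateral-transfer signature) or
`unique_to_type` (no homology anywhere, so no comparative signal).

A metagenomic hit to a gene, with scores (S~H~, Q~H~), has informativity
I = (S~H~, Q~H~) − T, scalarized with the same weights. I is 0 for a hit
exactly at the threshold and reaches 100 only in the limit T = (0, 0) with a
perfect full-length hit; for an informative gene the attainable maximum is
100 − t. Hits at or above threshold (I ≥ 0) are informative; below,
uninformative; hits to uninformative genes are retained but flagged
`gene_uninformative` so that heatmap-style displays remain complete.

Both S and Q enter with equal weight by default. The component pairs
(dS, dQ) and (I~S~, I~Q~) are always emitted alongside the scalars, so any
other weighting can be recomputed from the written tables without re-running
the searches; the tests assert this re-weighting identity exactly.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `weights` | (0.5, 0.5) | — | S vs Q contribution to scalars and best-hit ranking |
| `evalue_max` | 1e-3 | — | hit acceptance, both backends |
| `matrix`, `gap_open`, `gap_extend` | BLOSUM62, 11, 1 | score units | protein local alignment (BLAST protein defaults) |
| `min_aln_len` | 15 | aa | floor on aligned columns, builtin backend |
| `min_orf_aa` | 20 | aa | minimum stop-free ORF emitted from contigs |
| `mode` | `"scalar"` | — | threshold/hit test: scalar vs strict componentwise |
| genetic code | table 1 | — | table 11 available for bacterial-style annotation |

The comparison `mode` exists because a pair inequality like
{S~H~, Q~H~} < T has no unique meaning: the scalar reading matches the equal
weighting of S and Q and is the default; `"componentwise"` demands both
components clear the threshold and is strictly more conservative. The
boundary I = 0 counts as informative, since a hit exactly at the threshold
is indistinguishable from the most dissimilar known member of the taxon.

## Homology backends and numerical choices

The builtin backend computes best local alignments (Smith–Waterman; a gap of
length *k* costs 11 + *k*) via Biostrings. Percent identity is identical
aligned pairs over aligned columns, gaps included (BLAST `pident`
semantics); query coverage is the percent of *query* residues spanned by the
local alignment (`qcovs` semantics), computed in protein space. Genes are
always the queries — against relative proteomes, the out-group, and the
translated-contig database alike — so Q is consistently coverage *of the
gene*. Per (query, subject) pair only the single best alignment is kept,
which keeps S and Q well defined per match; high-scoring-pair tiling is out
of scope.

Raw scores are converted to approximate bit scores and e-values with the
published gapped Karlin–Altschul constants for BLOSUM62 11/1
(λ = 0.267, K = 0.041; search space = query length × database residues),
and hits are accepted when score > 0, alignment length ≥ `min_aln_len`, and
e-value ≤ `evalue_max`. The e-value calibration was a deliberate choice over
a purely ordinal score transform: local alignment of *unrelated* proteins of
realistic length almost always has a positive score and ≥ 15 aligned
columns, so without a significance filter the out-group step and the sample
scans accumulate weak random "homologs" that have no biological meaning.
The approximation is not BLAST's composition-adjusted statistic; when exact
BLAST behavior matters, precomputed tabular results (`outfmt
"6 std qlen qcovs"`) can be supplied and pass through the identical
filtering and best-hit contract. `align_protein_pair()` itself applies no
filter beyond score > 0, so single-pair comparisons remain fully
inspectable.

Tie-breaking in `best_hit()` is total and permutation-invariant: weighted
score, then bit score, then e-value, then lexicographic subject id. All
internal coordinates are 0-based half-open; conversion to and from BLAST's
1-based inclusive convention happens only at the tabular boundary. ORFs are
stop-to-stop segments in all six frames with no start-codon requirement —
fragmentary contigs routinely enter genes mid-frame, and requiring a
methionine would discard most true partial hits. Degenerate inputs resolve
conservatively: contigs shorter than a codon yield no ORFs, an empty
out-group yields S~2~ = Q~2~ = 0 for every gene, and fuzzy codons translate
to `X` (never positively scored) unless every resolution agrees.

The choice of which relative genomes and which out-group to use is the
user's: the taxonomic granularity of the call (strain, species, genus) is
set entirely by that choice, and the package deliberately does not try to
automate it.

## The synthetic community

`community_spec()` / `make_community()` generate the evaluation setting all
end-to-end tests use: a type-species genome of random coding sequences;
relatives whose proteins are copies mutated to a target amino-acid identity
(exact substitution counts at uniformly chosen positions); out-group genomes
of unrelated random proteins; and exact amino-acid copies of selected taxon
genes planted into the out-group — the ground-truth lateral transfers.
Nucleotide sequences come from back-translation with uniformly random
synonymous codons (codon bias is irrelevant downstream, where every
comparison is in protein space). Contigs are genomic substrings with
uniform positions and lengths, random strand, and independent per-base
substitution errors.

Defaults: 5 taxon genomes, 30 genes of 60–150 aa at 85% within-taxon
identity, 4 out-group genomes, 3 planted transfers, 200 contigs of 1–2 kb at
a 0.5% error rate. 85% identity sits in the range typical of congeneric
phage orthologs — far enough from 100% that thresholds are not degenerate,
close enough that every gene keeps a within-taxon homolog; 1–2 kb contigs
comfortably span single genes of the chosen lengths, mimicking short
single-gene-resolving virome assemblies; 0.5% errors approximate
assembly-consensus residual error. With ~200 contigs over nine ~13 kb
genomes (≈3–5× coverage) most genes are recovered at near-full coverage, so
a taxon-present sample yields a high detected fraction while an
out-group-only sample yields none.

What the generator does *not* emulate — realistic codon usage, indels,
coverage biases, chimeric contigs, databases with partially overlapping
taxonomy, paralogous gene families — bounds what the passing tests show: the
pipeline recovers planted signal under idealized evolution, which validates
the bookkeeping and the discrimination logic, not the field performance of
the metric on real viromes.

The validation problem sizes (communities of 6–30 genes, samples of 20–200
contigs, 200 oracle alignment pairs of ≤ 30 aa) were chosen so the full
suite exercises every stage end-to-end in a few minutes on a single core.

## Known limitations

* The e-value approximation ignores composition adjustment and edge
  corrections; near `evalue_max` the builtin and BLAST backends can disagree
  on marginal hits.
* Best-hit-per-sample scoring means multiple distinct copies of a gene in
  one sample collapse to the strongest; abundance is out of scope.
* The per-sample aggregate (counts, fraction detected, mean/max I) is
  descriptive. No probability model is attached, deliberately: the mapping
  from informative-gene detections to a presence call depends on the taxon's
  database context, which the user controls.
* Thresholds are snapshots of the reference databases used to fit them; as
  references grow, refitting can reclassify genes.
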