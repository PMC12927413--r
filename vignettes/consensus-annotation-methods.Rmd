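---
title: "Consensus gene annotation via orthology: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gene annotation via orthology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Gene prediction methods on the same assembly disagree: *ab initio* finders
overcall, transcriptome assemblies miss unexpressed genes, homology
projections depend on the donor species. `consanno` treats the reconciliation
of these sets as an ancestral-genome reconstruction problem. Each source
annotation becomes a pseudo-species leaf on a rooted species tree, clustered
under one internal node (the *consensus node*), with real related species as
outgroups. Orthology is inferred jointly across all leaves; the hierarchical
orthologous groups (HOGs) attached to the consensus node are then candidate
consensus genes, because a HOG at that node is exactly "a set of models that
descend from one gene of the (virtual) common ancestor of the sources" —
i.e. models of the same locus called by different methods.

A candidate with source-support count $s$ and outgroup-ortholog count $o$ is
retained iff $s \ge 2$ or ($s \ge 1$ and $o \ge 1$): every consensus gene is
backed by two independent lines of evidence. Two genes of the *same* source
in one HOG count once (distinct methods are required; in-paralogs within one
source are not corroboration). A HOG containing paralogous contributions
still yields a single consensus gene; the non-representative members remain
visible in the detailed report's `members` column.

## Pipeline stages and their contracts

1. **annotation I/O** — GFF3 is read through a *feature-type map*
   (`source_feature → {gene, transcript, cds}`, case-insensitive) so that
   nonstandard feature names need no file editing. Internally all
   coordinates are 0-based half-open; GFF3 reading/writing is the single
   1-based conversion point. Two-level files (transcripts without gene rows)
   get synthetic genes `gene:<transcript_id>`; missing CDS `phase` is taken
   as 0 with a warning. Each transcript is translated (standard code; minus
   strand reverse-complemented; `phase` bases trimmed from the
   transcription-side 5' segment; codons containing `N` become `X`; the
   trailing stop is removed). An isoform with an in-frame internal stop is
   **excluded, not truncated** — a frame error must not be propagated into
   the orthology stage as a half-real protein. Proteins are namespaced
   `source|gene|transcript`; genes with two or more surviving isoforms are
   recorded in a splice file (one gene per line, ids joined by `"; "`).

2. **orthology engine** — proteins are compared by Smith–Waterman local
   alignment under BLOSUM62 with affine gaps, where a gap of length $L$
   costs `gap_open + L·gap_extend` (defaults 11/1; `X` scores 0 against
   everything). For each gene the *main isoform* is the one maximising the
   summed score of its above-threshold hits in other species (fallback:
   longest; ties: smallest transcript id). Gene-level reciprocal best hits
   (strict by default; `tolerance` allows near-ties) over each species pair
   form a graph; ascending the species tree in post-order, the HOGs of a
   node's child subtrees are merged by the connected components of the pairs
   whose two species have that node as most recent common ancestor. This is
   a deliberately simple, fully deterministic stand-in for full orthology
   inference (no evolutionary distances, no witnesses of non-orthology); the
   `orthoxml` input path exists precisely so a production orthology tool can
   replace it without touching the consensus layer.

3. **consensus extraction** — support bits per candidate, retention rule,
   representative = longest CDS ("longest" = the nucleotide CDS length of
   the gene's longest isoform, not the isoform sum — a documented reading,
   since either is defensible) or priority order; all isoforms of the
   representative are copied with original coordinates; GFF3 + protein FASTA
   + two reports are written deterministically (fixed sort orders
   throughout, so identical inputs give byte-identical outputs).

## Tunable parameters

| parameter | default | units | why this default |
|---|---|---|---|
| `min_score` | 100 | BLOSUM62 half-bit-ish score | see below |
| `min_cov` | 0.5 | fraction of shorter protein | rejects short chance local alignments; true orthologs align near-globally |
| `tolerance` | 0 | score units | strict mutual best; raise to admit near-co-orthologs |
| `gap_open`, `gap_extend` | 11, 1 | score units | standard BLOSUM62 pairing |
| `outgroup_evidence` | `"hog"` | — | "ortholog in a related species" read as root-HOG co-membership; `"pairs"` (direct RBH to an outgroup) is exposed as the alternative reading |
| retention rule | $s\ge2$ or $s\ge1,o\ge1$ | — | fixed; it is the method |

**Why `min_score = 100`.** Local alignment scores of *unrelated* sequences
follow Karlin–Altschul statistics: the expected number of chance hits of
score $\ge S$ over $N$ comparisons of $m \times n$ residues is
$K m n N e^{-\lambda S}$ (gapped BLOSUM62-11/1: $\lambda \approx 0.267$,
$K \approx 0.041$). A realistic run compares $\sim 10^5$–$10^6$ protein
pairs of 60–300 aa, for which chance scores of 40–70 are *expected* — a
threshold of 40 therefore admits spurious reciprocal best hits (we observed
exactly this; in a random matrix, mutual-best coincidences are common,
$\mathbb{E} \approx n_A n_B/(n_A+n_B)$). At $S = 100$ the expected chance-hit
count across $10^6$ comparisons drops below 0.1, while genuine orthologs are
unaffected: even a 60-residue protein at 30 % divergence scores roughly
$60 \times (0.7 \times 5 - 0.3) \approx 190$. The threshold is derived from
this calculation, not fitted to any test, and remains user-configurable.

## What the simulator emulates — and what it does not

`simulate_truth()` writes real coding genes into a random background contig:
ATG start, stop end, no internal stops, 1–4 codon-aligned CDS segments
separated by 30–200 nt introns, random strands, protein lengths uniform on
60–300 aa, residues drawn per-codon from uniform synonymous codons. A pool
of *decoy* ORFs (random proteins, same length range) is placed in intergenic
space at generation time, so that "false predictions" added to a source are
real sequences on the shared genome; `derive_sources()` partitions the decoy
pool disjointly across sources, because a decoy shared by two sources would
*correctly* pass the two-source rule — that would test nothing. Sources are
corrupted by dropping $\lfloor \text{drop\_rate} \cdot n \rfloor$ genes,
adding $\lfloor \text{false\_rate} \cdot n \rfloor$ decoys and jittering
terminal CDS boundaries. Outgroup proteomes substitute each residue with
probability `divergence`, uniformly over the other 19 residues.

Deliberate simplifications, hence what a green test does *not* establish:

* **Jitter is trim-only and frame-preserving** (multiples of 3, terminal
  segments only, internal splice sites untouched). Extending a CDS into
  random intergenic sequence would create in-frame stops and silently
  invalidate models, conflating two failure modes. Consequence: boundary
  errors of the "extended exon" type are not simulated.
* **Uniform (not matrix-weighted) amino-acid substitution** in outgroups —
  adequate for recovering orthologs at divergence ≤ 0.3 with BLOSUM62, but
  not a realistic evolutionary model.
* All CDS phases are 0 in simulated data (phase handling is covered by
  hand-built unit fixtures instead); no UTRs/exons beyond CDS, no repeats,
  no realistic intergenic composition, no expression-level effects.
* One contig; gene density and intergenic gap lengths are convenient, not
  biological.

## Evaluation semantics

CDS segments stand in for exons (the pipeline is CDS-only). Duplicate query
transcripts (identical chains) are discarded first. Multi-exon transcripts
match iff their intron chains are identical and each outer terminal boundary
differs by ≤ 100 nt (applied per end independently, matching observed
GffCompare behaviour); two single-exon transcripts match iff the query
covers ≥ 80 % of the *reference* exon length; single never matches multi.
Loci are single-linkage clusters of overlapping same-strand reference (resp.
query) genes. Reported counts: `tp` = matched reference units, `fn` =
unmatched reference units, `fp` = unmatched query units, so
`sensitivity = 100·tp/(tp+fn)` and `precision = 100·tp/(tp+fp)`. When
matching is one-to-one (the overwhelmingly common case) this equals the
classical definitions; under multi-matching the two sides can differ and we
keep the reference-anchored `tp` for self-consistency of the formulas.

## Numerical and degenerate-input choices

* Ties are broken deterministically everywhere: representative selection by
  (CDS length, declared source order, gene id); isoform selection by
  (summed hit score, transcript id); all iteration orders are sorted.
* An empty reference in evaluation is an error (sensitivity undefined);
  an empty consensus writes a header-only GFF3.
* A gene whose every isoform fails translation is dropped with a warning —
  it could never enter the consensus.
* orthoXML groups get their taxonomic level from a `TaxRange` property when
  it names a tree node label, else from the MRCA of their member species.
  Slicing at the consensus node: an `orthologGroup` at/below that level is
  one candidate (in-paralogs included); source genes referenced directly in
  higher groups become singleton candidates; `paralogGroup`s above the
  consensus level are recursed into. Outgroup evidence from an orthoXML
  forest is necessarily of the `"hog"` kind — pairwise orthologs are not in
  the file.

## Known limitations

* The built-in engine is a proxy, not a replacement, for full orthology
  inference; distant or fast-evolving single-source genes below the score
  threshold will lack outgroup support and be dropped (by design, the rule
  errs toward precision).
* Positional overlap is never used as a joining signal — two sources calling
  dissimilar sequences at the same locus stay separate candidates.
* Gene models are taken as-is: no boundary refinement, no UTR modelling, no
  downstream curation.
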