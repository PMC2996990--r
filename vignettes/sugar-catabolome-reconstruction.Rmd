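---
title: "Reconstructing bacterial sugar utilization machinery from genome panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing bacterial sugar utilization machinery from genome panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarcat)
```

## The problem

Carbohydrate catabolism in bacteria is organized into *peripheral
pathways* — a transport system that brings a sugar across the outer and
inner membranes, a short chain of cytoplasmic enzymes (kinases,
isomerases, hydrolases, aldolases) that funnels it into central carbon
metabolism, and usually a committed transcriptional regulator. Projecting
known pathways onto newly sequenced genomes by sequence similarity alone
is unreliable: the same functional role is frequently filled by
non-orthologous genes in different lineages, and paralogous transporters
and kinases differ in substrate specificity in ways homology cannot
resolve. Comparative-genomics reconstruction compensates with *functional
context*: genes of one pathway cluster into operons on the chromosome,
share transcription-factor binding sites (regulons), and co-occur across
genomes (phyletic profiles).

`sugarcat` implements this reconstruction workflow end to end, at desk
scale, against synthetic genome panels with planted ground truth, plus
packaged fixtures transcribing a published 19-genome sugar-catabolome
inventory (a 170-family registry, a per-genome panel table, and a
14-strain by 12-substrate predicted/observed growth matrix).

## The pipeline

1. **Homology scanning** (`scan_families`, `scan_panel`). Each family is
   represented by one query sequence; candidate members are detected by
   Smith–Waterman local alignment with affine gaps,
   score of a gap run of length $k$ = `gap_open` $+ k \cdot$
   `gap_extend`. Defaults: BLOSUM62, open 11, extend 1 — the ubiquitous
   protein-search defaults — with minimum score 50 and minimum identity
   30% (identity is matches over alignment columns, gaps included).
   These cutoffs are this package's choice; the source workflow does not
   state its search parameters. An optional shared 4-mer prefilter skips
   hopeless pairs; it is provably lossless for any pair whose optimal
   alignment contains an exact 4-mer and is disabled in all oracle tests.
2. **Orthology** (`bbh_orthologs`). Bidirectional best hits, with
   deterministic tie-breaking (score, then identity, then lexicographic
   gene id) so "best" is always unique.
3. **Genome context** (`call_clusters`, `cooccurrence_score`,
   `propose_gap_fillers`). Candidate operons are maximal runs of
   same-strand neighbors with intergenic gaps of at most `max_gap` = 200
   bp — a common prokaryotic operon heuristic; the source states none.
   Functional coupling is quantified by the co-clustering fraction over
   co-present genomes and the Jaccard index of phyletic profiles.
   Missing pathway roles are filled by unassigned genes sharing a
   cluster and/or a regulon with assigned pathway genes, ranked
   both > cluster-only > regulon-only, ties by chromosomal distance.
4. **Regulon inference** (`extract_upstream`, `discover_motif`,
   `training_threshold`, `scan_regions`, `conservation_filter`).
   Upstream windows span $-300\ldots+20$ bp around the translation
   start, truncated at the upstream neighbor; the window is typical of
   bacterial regulon studies, the source gives no value. Motif discovery
   is a greedy one-occurrence-per-sequence (OOPS) procedure: from a seed
   word, repeatedly (i) pick the best-scoring window per training region
   on both strands, (ii) rebuild the PWM, until the site set is stable;
   the run maximizing total information content over many seeds wins.
   The site-search threshold is **the lowest score observed in the
   training set**, which guarantees by construction that re-scanning the
   training material recovers every training gene. New regulon members
   are retained only when orthologs in at least two other genomes also
   carry candidate sites, or when the gene's family already belongs to
   the pathway under study.
5. **Pathway calling** (`assign_roles`, `call_pathway`). A pathway is
   *present* when **all** of its required roles are covered by intact
   genes; *impaired* when some role is covered only by pseudogenes
   (frameshift or insertion element — the pathway is deemed
   nonfunctional); *absent* otherwise. Required roles are the transport
   and enzyme families; regulators and auxiliary/upstream components are
   informative but not required, matching how the source calls pathways
   present in genomes that lack, e.g., a dedicated regulator. A glucose
   (Glc) definition is synthesized as "a glucose permease (either
   paralogous locus variant) plus the glucokinase", since the inventory
   table has no Glc row but the phenotype matrix has a Glc column.
6. **Phenotype concordance** (`predict_growth`, `score_concordance`).
   Growth on a diagnostic substrate is predicted exactly when the mapped
   pathway is present (impaired predicts no growth). Observed states are
   `p` (growth), `w` (weak), `n` (none), `nd` (not determined); `w`
   counts as growth-positive — the printed growth counts include a weak
   grower — and `nd` cells are untested rather than discordant.

## PWM model and numerical choices

A PWM over sites $s_1 \ldots s_N$ of length $L$ scores base $b$ at
position $k$ as

$$w(b,k) = \ln\frac{n(b,k) + c}{(N + 4c)\,q(b)}$$

with per-base pseudocount $c = 0.5$ and background $q$ (uniform by
default); a word's score is the sum of its per-position weights, and
column information content is $2 + \sum_b p(b)\log_2 p(b)$ bits with $p$
the pseudocounted frequencies. The published workflow used an internal
tool whose scoring function is not public; any per-column monotone
transform of the weights yields identical site rankings and identical
behavior under the minimum-training-score threshold rule, so this
specific log-odds form is a free design choice made for transparency.
Other numerical decisions:

* Motif length $L$ is a per-regulator configuration input (dyad motifs
  of LacI/GntR-type regulators are typically 16–20 nt); there is no
  automatic length search.
* The palindromic option averages the count matrix with its reverse
  complement, making a word and its reverse complement score
  identically. It is off by default.
* The iterative refinement only accepts an update when total information
  content does not decrease, making the objective trace monotone and
  termination certain (at most 100 iterations).
* Overlapping scan hits collapse to the best-scoring window; ties break
  leftmost, then `+` strand — determinism everywhere.
* `scan_regions` subtracts a $10^{-9}$ guard from the threshold so the
  training site that *defines* the minimum is never lost to
  floating-point summation order.
* `uniroot` solves the planted-PWM consensus probability to $10^{-10}$.

## What the synthetic generator states, and what it does not

`simulate_panel` builds single-replicon genomes containing, for each
pathway present in a genome: one compact same-strand operon of the
pathway's non-regulator genes (intergenic gaps 20–120 bp), a separately
placed regulator gene, and one binding site per regulated transcription
unit sampled from a truth PWM and embedded in the upstream window of the
operon's lead gene (the OOPS model that discovery assumes). Its stated
world: 10 genomes; protein identity to the family consensus 60%
(substitution-only, so realized identity is exact up to rounding;
replacements are BLOSUM62-weighted to keep distant homologs detectable);
planted motif information content 1.2 bits/column over 16 positions;
300-bp upstream windows; mosaic pathway presence with probability 0.7
per genome; 5 unrelated decoy genes per genome; pseudogene lesions
(single-nucleotide frameshift or 1-kb insertion cassette) applied from
an explicit plan. Intergenic background is i.i.d. uniform nucleotides —
the simplest null for motif-discovery power.

The generator deliberately does **not** emulate: codon usage and GC
skew, phylogenetically structured divergence (each gene diverges
independently from its family consensus), insertions/deletions within
proteins, multi-replicon genomes, overlapping genes, or operon
rearrangements. A green truth-recovery test therefore establishes that
the inference machinery is correct under its own model assumptions — not
that it would perform identically on real genomes, where divergence is
tree-structured and upstream regions contain structured background.

## Reproducibility

Every stochastic operation routes through one integer seed; the same
configuration reproduces byte-identical FASTA/GFF3/TSV/JSON outputs.
Coordinates are 0-based half-open internally, 1-based inclusive in
emitted GFF3, and 0-based half-open in emitted BED, as those formats
require.

## Known limitations

* One representative sequence per family stands in for profile-based
  family search; no E-values, no profile HMMs.
* Scanning covers extracted upstream regions only, not whole genomes;
  whether the original workflow scanned complete genomes is unstated.
* Domain-fusion evidence, a recognized coupling signal, is not
  implemented.
* The packaged registry names non-novel families with canonical role
  names where the source text identifies them and generic names
  otherwise; only the printed counts are authoritative.
* The genome-scale results of the original study (real regulon contents,
  per-genome inventories) cannot be regenerated without the 19 genomes;
  the package substitutes property-based validation on synthetic panels,
  and the packaged predicted-phenotype column is a transcription, not a
  recomputation.
* The panel table's per-genome pathway counts and the inventory table's
  per-pathway genome counts do not reconcile in the source; both are
  stored verbatim.
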