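---
title: "Comparative analysis of splicing-factor-dependent exon programs"
author: "spliceEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of splicing-factor-dependent exon programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceEvo)
```

## Scope and model

spliceEvo implements a comparative pipeline for studying how a splicing
factor's exon program evolves across species. Its stages mirror a typical
RNA-seq perturbation study of an RNA-binding protein (an Esrp-like
epithelial splicing regulator is the motivating case):

1. **Differential splicing** from percent-spliced-in (PSI) tables of
   alternative-splicing events (cassette exons, intron retention,
   alternative 5'/3' splice sites), quantified upstream by an external tool
   and consumed here as a table of PSI values, read counts and ordinal
   coverage tiers (`N < VLOW < LOW < OK < SOK`).
2. **Differential expression** from gene read counts via cRPKM (reads per
   kilobase of uniquely mappable positions per million mapped reads).
3. **Homologous exon clusters** across species, from intron-position-aware
   pairwise protein alignments plus transitive linking of accepted pairs.
4. **RNA regulatory maps and direct/indirect classification**, from exact
   hexamer motif scans over a standardized exon-centric region schema.
5. **Cross-species bookkeeping** of shared regulation, and a category
   selection rule for externally computed GO enrichment tables.
6. A **synthetic-data generator** that produces all of the above inputs
   with known ground truth, so each stage (and the whole pipeline) is
   testable without any download.

## Differential-splicing calls

For each event, with loss-of-function orientation (ΔPSI = mean control PSI
− mean perturbed PSI), an event is called factor-dependent when

* every compared sample has coverage tier VLOW or better;
* |ΔPSI| meets the species threshold — 15 PSI units by default (10 for the
  sea-urchin-like low-coverage setting), inclusive at the boundary; the
  multi-source combination (below) uses a strict inequality, following the
  two phrasings these filters are conventionally given in;
* every control × perturbed pairwise ΔPSI is at least 5 in one consistent
  direction (all ≥ +5 or all ≤ −5; mixed signs fail);
* intron-retention events additionally require a two-sided exact binomial
  test of the two intron-boundary read counts (p ≥ 0.05 in **every**
  sample; with both counts zero there is no evidence of balance and the
  event fails). Sidedness is configurable; two-sided is the default since
  an imbalance in either direction indicates an artefact.

Direction is *enhanced* when inclusion is higher with the factor
functional. Gain-of-function samples are folded in by flipping the ΔPSI
orientation, so reported directions are always loss-oriented.

`combineGroupings()` reproduces the combination used when perturbation
data come from heterogeneous sources: several declared groupings are
evaluated independently (|ΔPSI| > 15, all pairwise > 5) and an event is
accepted if it passes any one of them. A grouping may pool replicates by
summing inclusion/exclusion reads and recomputing PSI and tier from the
pooled counts, and a grouping pairing a loss-of-function with a
gain-of-function comparison requires the two ΔPSI values to have opposite
signs.

`rescueLowCoverage()` re-admits an event that failed the coverage gate
when a homologous exon is factor-dependent in another species, exactly one
sample is below VLOW, and that sample still has ≥ 2 supporting reads; the
ΔPSI cutoffs themselves are never relaxed.

## Differential expression

cRPKM = reads / (mappable kb) / (mapped millions). A gene is called when
(i) cRPKM > 2 in all replicates of at least one condition, (ii) ≥ 50 raw
reads in at least one sample, (iii) the fold difference between condition
means is ≥ 2 (or 1.5 in the low-coverage setting), and (iv) every pairwise
cross-condition fold is ≥ 1.5 (or 1.2) in the direction of the mean
change. Fold differences are symmetric (max/min) with direction tracked
separately, and cRPKM values are floored at 0.01 before ratios — the
filters say nothing about zeros, so the floor (config-exposed) makes the
behaviour explicit. Means of per-replicate cRPKM are compared (rather than
cRPKM of pooled reads); a config flag could add the alternative but the
pooled variant is not implemented because the pairwise clause already
guards against single-replicate artefacts.

## Homologous exon clusters

Gene orthology is consumed as evidence from three sources (OMA-like,
Multiparanoid-like, and reciprocal BlastP-style ranked hits, where each
gene must be within the other's first three hits — ties at the third-best
score are counted inclusively, the only deterministic reading of a rank
tie). Pairs supported by ≥ 2 of 3 sources form a graph whose connected
components are the gene clusters ("guilt by association").

Within a cluster, protein isoforms are aligned pairwise (global alignment,
BLOSUM62, gap open 10 / extend 0.5 — pinned defaults, since behaviour must
be reproducible even though any sensible scoring works) and each intron is
projected onto the alignment as a marker column plus its phase (coding
nucleotides before the intron, mod 3). For a cassette exon of species A
and a candidate exon of species B:

* **similarity** is the percent of alignment columns shared by the two
  exons in which the residues are identical *or positively scoring* under
  the substitution matrix (gap columns excluded from the denominator).
  "Similarity" is deliberately scored this way rather than as strict
  identity; an identity-only reading would be stricter than the standard
  use of the word. The acceptance threshold is > 20%.
* the **structure clause** requires both flanking intron positions to have
  a marker of identical phase within ≤ 3 alignment columns in the partner.
* an **automatic** verdict needs similarity > 20%, a significantly aligned
  flanking constitutive exon (same 20% criterion on that exon's span), and
  the structure clause. If exactly one of the similarity or structure
  clauses fails, the pair is flagged for **manual** review (written to a
  review file; an approvals table can whitelist flagged pairs, and the
  automated pipeline never promotes them silently). When several
  candidates exceed 20%, the exon amino-acid sequences are locally
  realigned and the best-scoring candidate kept.

Accepted pairs are assembled into exon clusters by connected components;
a component containing two distinct exons of one gene is kept but flagged
as a conflict rather than silently merged.

## Regulatory maps and the positional code

Motifs are exact hexamers (T/U-equivalent). The shipped default set is a
**synthetic GU-rich stand-in** for an experimentally derived (SELEX-type)
splicing-factor motif list, which is an input, not something this package
derives. Region schema per event: 75 nt from both alternative-exon ends,
250 nt from both ends of both flanking introns, and 75 nt of each
neighbouring exon; a feature shorter than its segment is dropped, never
padded (the two segments of a 250–500 nt intron therefore overlap). The
schema's neighbour-exon segments are taken verbatim from the distal ends
(5' end of the upstream exon, 3' end of the downstream exon); a
`junction_proximal_flanks` switch selects the junction-proximal reading
instead, since the distal phrasing may well be a transcription slip — the
package implements the stated rule and exposes the alternative rather
than silently correcting it.

Coverage profiles slide a 51-nt window along each segment and report the
fraction of window positions covered by ≥ 1 motif hit, averaged over
events; at segment ends the window is truncated and the actual span is the
denominator (no padding, so edges are not artificially suppressed).

Direct/indirect classification scans the alternative exon, the first and
last 250 nt of both introns, and the 25-nt exon edges, and assigns each
hit by its start position. *Restricted* scenario — silenced exons may
carry motifs in the alternative exon, the first 6 nt of the downstream
intron (the 5' splice-site overlap) and/or the last 250 nt of the upstream
intron; enhanced exons in the first 250 nt of the downstream intron
excluding that same 6-nt span (the two quoted region definitions are kept
mutually consistent). *Expanded* adds the first 250 nt of the upstream
intron for silenced exons, and for enhanced exons the upstream-exon edge
with the upstream intron (minus its last 50 nt) or the last 250 nt of the
downstream intron. An exon is *direct* when the motif total over its
allowed regions reaches the threshold (1–4; totals are summed across
regions, not required per region); *indirect* when additionally its
direction-specific control regions are motif-free; otherwise *discarded*.

Conservation profiles average a per-base score track over exons plus
150-nt flanks, smoothing with a 10-position running mean. The window is
anchored trailing (starting at each position) by default — the
conventional description of the smoothing does not fix the anchor — with a
centered option.

## The synthetic generator

`simulateGeneFamilies()` evolves, per family, an ancestral multi-exon
coding gene down a labelled species tree: i.i.d. per-site amino-acid
substitution, and optional exon gain/loss, per branch (probabilities scale
with branch length). Junction phases are drawn at the ancestor and
inherited; the internal cassette exon is kept frame-preserving. Proteins
are back-translated with a fixed codon table into one-chromosome-per-gene
genomes with random introns, on alternating strands so strand handling is
exercised everywhere. Orthology evidence is emitted truth-consistently
(with a configurable dropout), because in the real workflow that evidence
is an external input.

Study conditions are fixed as generator defaults: 5–8 exons of 20–60
codons, introns of 300–800 nt, half of families factor-dependent with a
planted effect of 30 PSI units (half enhanced / half silenced, half of
dependent exons direct targets), two control and two loss-of-function
replicates, constant depth 60, negative-binomial expression with
dispersion 0.1. Control PSI is drawn Beta(2,2)-scaled to [40, 90] for
enhanced targets, [10, 60] for silenced targets and [0, 100] for
non-dependent exons — an exon enhanced by the factor is included while the
factor is functional, a silenced one is not, which also keeps a ±30 shift
inside the PSI range (any clamping is recorded in the truth table). Read
noise is pure binomial by default; a beta-binomial option (`rho`) adds
overdispersion. All generators are pure functions of (parameters, seed).

`plantMotifs()` first scrubs every chance hexamer occurrence from the scan
universe of all events — without this, indirect truth would be ill-defined
because random sequence carries GU-rich hexamers at an appreciable rate —
and then writes motifs into scenario-consistent regions of direct targets
(downstream-intron 5' region for enhanced, upstream-intron 3' region for
silenced targets, away from the splice-site exclusion zones). Planting
edits genomic sequence only; protein truth is not rewritten, so planted
genomes are meant for motif analyses, not for re-deriving proteins.

What the generator does *not* emulate: indels within exons, codon usage,
splice-site consensus sequences, realistic intron length distributions,
correlated noise between replicates, or partial isoform structures.
Passing recovery tests therefore demonstrates correctness of the decision
rules under their stated model, not performance on real RNA-seq.

## Numerical and design choices

* Internal coordinates are 0-based half-open; strand is resolved at parse
  time so all downstream geometry is transcript-oriented.
* Coverage-tier boundaries (N < 5, VLOW 5–14, LOW 15–24, OK 25–99,
  SOK ≥ 100 reads) are an explicit stand-in for the upstream quantifier's
  unpublished mapping, and configurable.
* PSI/count consistency tolerance is 0.05 PSI units (absorbs printed
  rounding); motif hit coordinates are 1-based in the R API.
* ΔPSI boundary semantics: `>=` where a value is phrased as a stated
  minimum, `>` for the multi-source combination; both configurable.
* The pairwise cluster metrics (precision/recall/F1 over within-cluster
  member pairs) are the standard order-independent way to compare two
  clusterings without label matching.
* Pairwise per-site divergence in the cluster-recovery analyses is
  measured tip-to-tip: a tree of total path length 1 with a per-unit
  substitution probability of 0.3 gives ~30% differing sites between any
  two species.
* Problem sizes used by the tests and the acceptance analysis — 600
  two-species families for ΔPSI recovery, 200 three-species families at
  30% divergence for cluster recovery, 510 planted events for the
  scenario classifier — were chosen so that every recovery estimate rests
  on ≥ 500 observations per class while a full run completes in minutes.

## Known limitations

* Orthology evidence is consumed, never computed; there is no built-in
  BLAST or orthology inference, and no liftOver-style secondary homolog
  search (externally produced extra pairs can be appended to the pair
  table).
* Only single-interval events are modelled; complex multi-exon skipping
  events are out of scope, as is PSI quantification itself.
* No false-discovery machinery: calling uses the fixed ΔPSI/fold
  thresholds by design.
* GO enrichment is not computed; only the cross-species category-selection
  rule over precomputed tables is provided (in strict mode a category must
  be tested in every species to be selectable).

## Reproducing the end-to-end run

```{r, eval = FALSE}
cfg <- pipelineConfig(seed = 7, n_families = 30)
res <- runPipeline(cfg, "run1")
res$metrics           # recovery metrics vs simulation truth
res$manifest$files    # md5 checksums; identical across reruns
```
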