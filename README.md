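# spliceEvo

Comparative analysis of splicing-factor-dependent exon programs.

RNA-binding splicing factors such as the epithelial regulators of the Esrp
family control programs of alternative exons, and those programs turn over
surprisingly quickly in evolution. Studying that turnover from RNA-seq
perturbation experiments in several species requires a chain of analyses
that are usually re-implemented ad hoc: calling factor-dependent splicing
events from percent-spliced-in (PSI) tables, calling expression changes,
deciding which cassette exons in different species are *the same* exon,
asking whether regulated exons carry the factor's binding motifs where an
RNA regulatory map predicts them, and tallying how much regulation is
shared between species. spliceEvo packages that chain, together with a
ground-truth synthetic-data generator, for analysts who want a tested,
reproducible version of each step.

## The statistics at the core

For an event with control samples $c_1..c_n$ and loss-of-function samples
$k_1..k_m$,

$$\Delta\mathrm{PSI} = \overline{\mathrm{PSI}}_{ctl} - \overline{\mathrm{PSI}}_{pert},$$

and an event is called factor-dependent iff every sample has read-coverage
tier VLOW or better, $|\Delta\mathrm{PSI}| \ge 15$ (10 in the low-coverage
setting; strict $>$ in the multi-source combination), and every pairwise
control × perturbed difference is $\ge 5$ in one consistent direction.
Intron-retention events additionally require a two-sided exact binomial
test of the two intron-boundary read counts to be non-significant
(p ≥ 0.05) in every sample. Expression uses cRPKM
($\mathrm{reads} / \mathrm{mappable\ kb} / \mathrm{mapped\ millions}$)
with expression, read-support, mean-fold and all-pairwise-fold filters.
Cross-species exon homology combines 2-of-3 orthology evidence, global
protein alignment with intron positions and phases intercalated
(conserved = identical phase within ≤ 3 alignment columns), a >20%
exon-similarity rule and transitive clustering. Direct targets are
regulated exons with ≥ *k* exact hexamer motifs in the positions a
regulatory map predicts for their direction (Restricted or Expanded
region scenarios); enrichment of shared regulation among direct targets
is a one-sided Fisher exact test.

## Worked example

Call one cassette exon from a two-replicate perturbation:

```r
library(spliceEvo)
pe <- PsiExperiment(
  psi = matrix(c(95, 85, 60, 70), 1,
               dimnames = list("EX1", c("c1", "c2", "k1", "k2"))),
  inc = matrix(c(95L, 85L, 60L, 70L), 1),
  exc = matrix(c(5L, 15L, 40L, 30L), 1),
  rowData = data.frame(gene_id = "GENE1", type = "AltEx"))
design <- sampleDesign(c("c1", "c2", "k1", "k2"),
                       c("control", "control", "perturbed", "perturbed"))
callSpeciesEvents(pe, design, speciesParams("zebrafish"))
#>   event_id   species  type direction dpsi_avg dpsi_pairwise_min coverage_ok
#> 1      EX1 zebrafish AltEx  enhanced       25                15        TRUE
#>   ir_balance_ok called provenance
#> 1            NA   TRUE       main
```

Inclusion drops from ~90 to ~65 upon factor loss: ΔPSI = 25 with all four
pairwise differences ≥ 15, so the exon is called *enhanced* (the factor
promotes its inclusion).

An end-to-end synthetic run — simulate three-species gene families with
planted effects, call splicing and expression, cluster homologous exons,
plant and classify motifs, and score everything against the known truth:

```r
cfg <- pipelineConfig(seed = 7, n_families = 20)
res <- runPipeline(cfg, "run1")
str(res$metrics)
#> List of 6
#>  $ dpsi_sensitivity    : num 1
#>  $ dpsi_false_call_rate: num 0.0303
#>  $ classifier_accuracy : num 1
#>  $ n_events            : int 60
#>  $ n_called            : int 28
#>  $ exon_cluster_f1     : num 1
```

Of 60 simulated cassette exons, all 27 planted 30-PSI-unit effects are
recovered plus one false call among the 33 nulls; homologous-exon clusters
and direct/indirect labels match the simulation truth exactly. Every stage
writes a TSV/FASTA/GTF/JSON artifact under the run directory, and
`manifest.json` records the effective configuration and md5 checksum of
every output, so a rerun with the same seed is checksum-identical.

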