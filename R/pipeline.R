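#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic run. All thresholds
#' default to the values used for per-species calling (see
#' [speciesParams()], [exprParams()]); validation fails naming the first
#' missing key.
#'
#' @param seed single integer driving all randomness.
#' @param n_families number of simulated gene families.
#' @param species_tree newick species tree.
#' @param sim a [simParams()] bundle.
#' @param design a [sampleDesign()] (default 2 control + 2 loss replicates).
#' @param depth,rho read-depth model and overdispersion for
#'   [simulatePsiTables()].
#' @param splice_params named list of [speciesParams()] per species; a
#'   single bundle is recycled to all species.
#' @param expr_params an [exprParams()] bundle.
#' @param motifs a [motifSet()] (default [defaultMotifSet()]).
#' @param scenario,min_motifs direct/indirect classification settings.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(seed = 1L, n_families = 30L,
                           species_tree = "((spA:1,spB:1):1,spC:2);",
                           sim = simParams(), design = NULL, depth = 60,
                           rho = 0, splice_params = speciesParams("custom"),
                           expr_params = exprParams("custom"),
                           motifs = NULL,
                           scenario = "restricted", min_motifs = 1L) {
    if (is.null(design))
        design <- sampleDesign(c("ctl1", "ctl2", "ko1", "ko2"),
                               c("control", "control", "perturbed",
                                 "perturbed"))
    if (is.null(motifs)) motifs <- defaultMotifSet()
    cfg <- structure(list(seed = as.integer(seed),
                          n_families = as.integer(n_families),
                          species_tree = species_tree, sim = sim,
                          design = design, depth = depth, rho = rho,
                          splice_params = splice_params,
                          expr_params = expr_params, motifs = motifs,
                          scenario = scenario,
                          min_motifs = as.integer(min_motifs)),
                     class = "pipeline_config")
    validatePipelineConfig(cfg)
    cfg
}

#' @rdname pipelineConfig
#' @param config a `pipeline_config`.
#' @export
validatePipelineConfig <- function(config) {
    need <- c("seed", "n_families", "species_tree", "sim", "design",
              "depth", "rho", "splice_params", "expr_params", "motifs",
              "scenario", "min_motifs")
    for (k in need)
        if (is.null(config[[k]]))
            stop("pipeline config is missing key: ", k)
    spKeys <- c("min_dpsi", "min_pairwise", "ir_alpha")
    checkSp <- function(p, label)
        for (k in spKeys) if (is.null(p[[k]]))
            stop("species threshold missing: ", label, "$", k)
    if (inherits(config$splice_params, "species_params"))
        checkSp(config$splice_params, "splice_params")
    else for (sp in names(config$splice_params))
        checkSp(config$splice_params[[sp]], sp)
    for (k in c("min_crpkm", "min_reads", "fold_avg", "fold_pairwise"))
        if (is.null(config$expr_params[[k]]))
            stop("expression threshold missing: expr_params$", k)
    invisible(TRUE)
}

.spliceParamsFor <- function(config, sp) {
    p <- config$splice_params
    if (inherits(p, "species_params")) return(p)
    if (!sp %in% names(p))
        stop("species threshold missing: splice_params$", sp)
    p[[sp]]
}

#' Cross-species homologous-exon pairs for the cassette exons
#'
#' For each gene cluster, aligns the protein isoforms of every cross-species
#' gene pair ([alignWithStructure()]) and assesses homology of the first
#' gene's cassette exon against all exons of the second
#' ([assessExonHomology()]).
#'
#' @param proteins per-species named lists of [ProteinIsoform-class].
#' @param geneClusters data.frame `gene_id`, `cluster_id` (see
#'   [buildGeneClusters()]).
#' @param altExons data.frame `species`, `gene_id`, `exon_index` (cassette
#'   exon index per gene; genes without one are skipped).
#' @param scoring an [alignScoring()] configuration.
#' @return data.frame of pair verdicts suitable for [buildExonClusters()].
#' @export
exonHomologyPairs <- function(proteins, geneClusters, altExons,
                              scoring = alignScoring()) {
    spOf <- function(g) {
        for (sp in names(proteins)) if (g %in% names(proteins[[sp]]))
            return(sp)
        NA_character_
    }
    rows <- list()
    for (cl in unique(geneClusters$cluster_id)) {
        genes <- geneClusters$gene_id[geneClusters$cluster_id == cl]
        if (length(genes) < 2) next
        sps <- vapply(genes, spOf, character(1))
        for (i in seq_along(genes)) for (j in seq_along(genes)) {
            if (i == j || sps[i] == sps[j]) next
            ga <- genes[i]; gb <- genes[j]
            alt <- altExons[altExons$gene_id == ga, ]
            if (nrow(alt) == 0 || is.na(alt$exon_index[1])) next
            if (ga > gb) next  # assess each unordered pair from one side
            struct <- alignWithStructure(proteins[[sps[i]]][[ga]],
                                         proteins[[sps[j]]][[gb]], scoring)
            res <- assessExonHomology(struct, alt$exon_index[1])
            rows[[length(rows) + 1L]] <- data.frame(
                species_a = sps[i], gene_a = ga,
                exon_a = paste0("ex", alt$exon_index[1]),
                species_b = sps[j], gene_b = gb,
                exon_b = paste0("ex", res$bestCandidate),
                verdict = res$verdict, similarity = res$similarity,
                stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0)
        return(data.frame(species_a = character(), gene_a = character(),
                          exon_a = character(), species_b = character(),
                          gene_b = character(), exon_b = character(),
                          verdict = character(), similarity = numeric()))
    do.call(rbind, rows)
}

#' Precision/recall/F1 of a clustering against truth, over member pairs
#'
#' Both clusterings are reduced to their sets of unordered within-cluster
#' member pairs and compared.
#'
#' @param predicted,truth data.frames with columns `cluster_id` and
#'   `member` (unique member keys).
#' @return list `precision`, `recall`, `f1`.
#' @export
clusterPairMetrics <- function(predicted, truth) {
    pairsOf <- function(df) {
        out <- character(0)
        for (cl in unique(df$cluster_id)) {
            m <- sort(unique(df$member[df$cluster_id == cl]))
            if (length(m) < 2) next
            cmb <- utils::combn(m, 2)
            out <- c(out, paste(cmb[1, ], cmb[2, ], sep = "~"))
        }
        unique(out)
    }
    pp <- pairsOf(predicted); tp <- pairsOf(truth)
    prec <- if (length(pp) == 0) 1 else mean(pp %in% tp)
    rec <- if (length(tp) == 0) 1 else mean(tp %in% pp)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    list(precision = prec, recall = rec, f1 = f1)
}

#' Run the full synthetic pipeline
#'
#' Stages, in dependency order: simulate gene families, PSI and expression
#' tables; per-species differential-splicing and differential-expression
#' calls; gene and exon homology clustering; motif planting, regulatory-map
#' profiles and direct/indirect classification; cross-species overlap
#' bookkeeping; recovery metrics against the simulation truth. Every stage
#' output is written under `outdir` and listed, with its MD5 checksum, in
#' `manifest.json` together with the effective configuration, so a rerun
#' with the same config and seed reproduces identical checksums.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outdir) {
    validatePipelineConfig(config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    put <- function(name) {
        p <- file.path(outdir, name)
        files <<- c(files, p)
        p
    }
    wtsv <- function(df, name) {
        p <- put(name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        p
    }

    # -- simulate ---------------------------------------------------------
    sim <- simulateGeneFamilies(config$n_families, config$species_tree,
                                config$sim, seed = config$seed)
    for (sp in sim$species) {
        Biostrings::writeXStringSet(sim$genome[[sp]],
                                    put(paste0(sp, ".genome.fa")))
        writeGeneModels(sim$models[[sp]], put(paste0(sp, ".models.gtf")))
        aa <- Biostrings::AAStringSet(vapply(sim$proteins[[sp]],
                                             function(p) p@sequence,
                                             character(1)))
        names(aa) <- vapply(sim$proteins[[sp]], function(p) p@isoformId,
                            character(1))
        Biostrings::writeXStringSet(aa, put(paste0(sp, ".proteins.fa")))
        wtsv(sim$events[[sp]], paste0(sp, ".events.tsv"))
    }
    wtsv(sim$truth$evidence, "evidence.tsv")
    truthPath <- put("truth.json")
    jsonlite::write_json(sim$truth, truthPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")

    psiSim <- simulatePsiTables(sim, config$design, depth = config$depth,
                                rho = config$rho, seed = config$seed)
    for (sp in names(psiSim$psi))
        writePsiTable(psiSim$psi[[sp]], put(paste0(sp, ".psi.tsv")))
    wtsv(psiSim$design, "design.tsv")

    # -- differential splicing -------------------------------------------
    calls <- list()
    for (sp in names(psiSim$psi)) {
        calls[[sp]] <- callSpeciesEvents(psiSim$psi[[sp]], config$design,
                                         .spliceParamsFor(config, sp))
        wtsv(calls[[sp]], paste0(sp, ".splice_calls.tsv"))
    }

    # -- differential expression -----------------------------------------
    expr <- simulateExpression(sim, config$design, config$sim,
                               seed = config$seed)
    exprCalls <- list()
    for (sp in names(expr)) {
        reads <- expr[[sp]]$reads
        total <- colSums(reads)
        crpkm <- sweep(reads / (expr[[sp]]$mappable / 1000), 2,
                       total / 1e6, "/")
        exprCalls[[sp]] <- callDiffGenes(crpkm, reads, config$design,
                                         config$expr_params)
        wtsv(exprCalls[[sp]], paste0(sp, ".expr_calls.tsv"))
    }

    # -- homology ---------------------------------------------------------
    geneClusters <- buildGeneClusters(
        sim$truth$evidence,
        universe = unlist(lapply(sim$models, names), use.names = FALSE))
    wtsv(geneClusters, "gene_clusters.tsv")
    altExons <- sim$truth$exons[sim$truth$exons$present,
                                c("species", "gene_id", "exon_index",
                                  "event_id")]
    pairs <- exonHomologyPairs(sim$proteins, geneClusters, altExons)
    wtsv(pairs, "exon_pairs.tsv")
    wtsv(pairs[pairs$verdict == "manual_flag", , drop = FALSE],
         "manual_review.tsv")
    exonClusters <- buildExonClusters(pairs)
    key <- paste(altExons$gene_id, paste0("ex", altExons$exon_index))
    exonClusters$event_id <- altExons$event_id[
        match(paste(exonClusters$gene_id, exonClusters$exon_id), key)]
    wtsv(exonClusters, "exon_clusters.tsv")

    # -- motif maps & scenarios ------------------------------------------
    plantedSim <- plantMotifs(sim, config$motifs, config$scenario,
                              seed = config$seed)
    wtsv(plantedSim$planted, "planted_motifs.bed.tsv")
    classTab <- list()
    for (sp in sim$species) {
        evs <- sim$events[[sp]]
        tr <- sim$truth$exons[match(evs$event_id,
                                    sim$truth$exons$event_id), ]
        for (i in seq_len(nrow(evs))) {
            if (!tr$esrp_dependent[i]) next
            cnt <- countMotifRegions(evs[i, ], plantedSim$genome[[sp]],
                                     config$motifs)
            cls <- classifyDirectIndirect(tr$direction[i], cnt,
                                          config$scenario,
                                          config$min_motifs)
            classTab[[length(classTab) + 1L]] <- data.frame(
                species = sp, event_id = evs$event_id[i],
                direction = tr$direction[i], predicted = cls,
                truth = ifelse(tr$direct[i], "direct", "indirect"),
                stringsAsFactors = FALSE)
        }
    }
    classTab <- if (length(classTab) > 0) do.call(rbind, classTab) else
        data.frame(species = character(), event_id = character(),
                   direction = character(), predicted = character(),
                   truth = character())
    wtsv(classTab, "direct_indirect.tsv")

    segs <- list()
    for (sp in sim$species) {
        evs <- sim$events[[sp]]
        for (i in seq_len(nrow(evs)))
            segs[[length(segs) + 1L]] <- extractEventRegions(
                evs[i, ], plantedSim$genome[[sp]])
    }
    profile <- coverageProfile(segs, config$motifs)
    wtsv(profile, "coverage_profile.tsv")

    # -- cross-species compare -------------------------------------------
    overlap <- overlapSummary(calls, exonClusters)
    wtsv(overlap, "overlap_summary.tsv")

    # -- recovery metrics -------------------------------------------------
    tt <- merge(psiSim$truth,
                do.call(rbind, calls)[, c("event_id", "called")],
                by = "event_id")
    dep <- tt$esrp_dependent & !tt$clamped
    metrics <- list(
        dpsi_sensitivity = if (any(dep)) mean(tt$called[dep]) else NA,
        dpsi_false_call_rate = if (any(!tt$esrp_dependent))
            mean(tt$called[!tt$esrp_dependent]) else NA,
        classifier_accuracy = if (nrow(classTab) > 0)
            mean(classTab$predicted == classTab$truth) else NA,
        n_events = nrow(tt), n_called = sum(tt$called))
    pred <- data.frame(cluster_id = exonClusters$cluster_id,
                       member = paste(exonClusters$species,
                                      exonClusters$gene_id,
                                      exonClusters$exon_id))
    trw <- sim$truth$exons[sim$truth$exons$present, ]
    tru <- data.frame(cluster_id = paste0("fam", trw$family),
                      member = paste(trw$species, trw$gene_id,
                                     paste0("ex", trw$exon_index)))
    cm <- clusterPairMetrics(pred, tru)
    metrics$exon_cluster_f1 <- cm$f1
    mp <- put("recovery_metrics.json")
    jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA)

    manifest <- list(config = .configFingerprint(config),
                     seed = config$seed,
                     files = lapply(stats::setNames(files, basename(files)),
                                    function(f)
                                        unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(sim = sim, psi = psiSim, calls = calls,
                   exprCalls = exprCalls, geneClusters = geneClusters,
                   exonClusters = exonClusters, classTab = classTab,
                   overlap = overlap, metrics = metrics,
                   manifest = manifest))
}

# Serializable summary of the effective configuration.
.configFingerprint <- function(config) {
    list(seed = config$seed, n_families = config$n_families,
         species_tree = config$species_tree,
         sim = unclass(config$sim),
         design = as.data.frame(config$design),
         depth = config$depth, rho = config$rho,
         splice_params = if (inherits(config$splice_params,
                                      "species_params"))
             unclass(config$splice_params) else
                 lapply(config$splice_params, unclass),
         expr_params = unclass(config$expr_params),
         motifs = as.character(config$motifs),
         scenario = config$scenario, min_motifs = config$min_motifs)
}
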