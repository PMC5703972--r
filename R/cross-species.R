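#' Homolog status of an exon cluster in one species
#'
#' Classifies a homologous exon cluster in a target species as
#' `not_in_genome` (no cluster member in that species), `constitutive`
#' (member present but PSI never within the alternative band at adequate
#' coverage), or `alternative` (PSI within \[`alt_lo`, `alt_hi`\] in at least
#' one sample at tier OK or better). Coverage is the same VLOW-in-all-samples
#' gate used for differential calling.
#'
#' @param clusters exon-cluster table with columns `cluster_id`, `species`,
#'   `event_id` (cluster members mapped to PSI events).
#' @param clusterId cluster to classify.
#' @param species target species.
#' @param pe the species' [PsiExperiment-class] (`NULL` when the species has
#'   no PSI table loaded).
#' @param alt_lo,alt_hi PSI band defining "alternatively spliced" (10-90).
#' @param min_tier tier required for a sample to support the band (OK).
#' @return list: `status`, `coverage_ok`.
#' @export
classifyHomologStatus <- function(clusters, clusterId, species, pe,
                                  alt_lo = 10, alt_hi = 90,
                                  min_tier = "OK") {
    if (!clusterId %in% clusters$cluster_id)
        stop("unknown cluster: ", clusterId)
    mem <- clusters[clusters$cluster_id == clusterId &
                        clusters$species == species, ]
    if (nrow(mem) == 0)
        return(list(status = "not_in_genome", coverage_ok = NA))
    ev <- mem$event_id[1]
    if (is.null(pe) || !ev %in% rownames(pe))
        return(list(status = "constitutive", coverage_ok = FALSE))
    psi <- psiValues(pe)[ev, ]
    tier <- assay(pe, "tier")[ev, ]
    coverage_ok <- !anyNA(tier) && all(tier >= tierCode("VLOW"))
    alt <- any(!is.na(psi) & !is.na(tier) & tier >= tierCode(min_tier) &
                   psi >= alt_lo & psi <= alt_hi)
    list(status = if (alt) "alternative" else "constitutive",
         coverage_ok = coverage_ok)
}

#' Cross-species overlap bookkeeping of regulated exons
#'
#' Assigns every called exon to exactly one category: `NH` when its cluster
#' has no member in any other species (or it belongs to no cluster), `NC`
#' when a homolog exists but some homolog-bearing species lacks sufficient
#' read coverage for the homologous event, or a shared-set label listing the
#' species in which homologs are called in the same loss-of-function
#' direction (the exon's own species alone gives that species' exclusive
#' set).
#'
#' @param calls named list (by species) of call tables from
#'   [callSpeciesEvents()]/[combineGroupings()].
#' @param clusters exon-cluster table with `cluster_id`, `species`,
#'   `event_id`.
#' @return data.frame `species`, `event_id`, `cluster_id`, `category`;
#'   shared-set categories are `+`-joined sorted species names.
#' @export
overlapSummary <- function(calls, clusters) {
    out <- list()
    for (sp in names(calls)) {
        tab <- calls[[sp]]
        tab <- tab[tab$called, , drop = FALSE]
        for (i in seq_len(nrow(tab))) {
            ev <- tab$event_id[i]
            cl <- clusters$cluster_id[clusters$species == sp &
                                          clusters$event_id == ev]
            category <- NULL
            clId <- NA_character_
            if (length(cl) == 0) {
                category <- "NH"
            } else {
                clId <- cl[1]
                mem <- clusters[clusters$cluster_id == clId &
                                    clusters$species != sp, ]
                if (nrow(mem) == 0) {
                    category <- "NH"
                } else {
                    cov <- vapply(seq_len(nrow(mem)), function(j) {
                        osp <- mem$species[j]
                        oc <- calls[[osp]]
                        if (is.null(oc)) return(FALSE)
                        row <- oc[oc$event_id == mem$event_id[j], ]
                        nrow(row) == 1 && isTRUE(row$coverage_ok)
                    }, logical(1))
                    if (!all(cov)) {
                        category <- "NC"
                    } else {
                        shared <- sp
                        for (j in seq_len(nrow(mem))) {
                            osp <- mem$species[j]
                            row <- calls[[osp]][
                                calls[[osp]]$event_id == mem$event_id[j], ]
                            if (nrow(row) == 1 && row$called &&
                                row$direction == tab$direction[i])
                                shared <- c(shared, osp)
                        }
                        category <- paste(sort(unique(shared)),
                                          collapse = "+")
                    }
                }
            }
            out[[length(out) + 1L]] <- data.frame(
                species = sp, event_id = ev, cluster_id = clId,
                category = category, stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0)
        return(data.frame(species = character(), event_id = character(),
                          cluster_id = character(), category = character()))
    do.call(rbind, out)
}

#' Cross-species selection of enriched GO categories
#'
#' A category is selected when it is significantly over-represented in at
#' least one species (p < `alpha`) and its observed/expected ratio exceeds
#' `minRatio` in every species in which it was tested. In strict mode
#' (default) a category absent from any species' table is excluded.
#'
#' @param tables named list (by species) of data.frames with columns
#'   `category`, `p`, `ratio`.
#' @param alpha significance level (0.05).
#' @param minRatio enrichment ratio threshold (1.3).
#' @param strict require the category to be tested in every species.
#' @return character vector of selected category identifiers.
#' @export
selectGoCategories <- function(tables, alpha = 0.05, minRatio = 1.3,
                               strict = TRUE) {
    cats <- unique(unlist(lapply(tables, function(t) t$category)))
    sel <- vapply(cats, function(ct) {
        ps <- ratios <- numeric(0)
        tested <- 0L
        for (t in tables) {
            row <- t[t$category == ct, ]
            if (nrow(row) == 0) next
            tested <- tested + 1L
            ps <- c(ps, row$p[1]); ratios <- c(ratios, row$ratio[1])
        }
        if (strict && tested < length(tables)) return(FALSE)
        any(ps < alpha) && all(ratios > minRatio)
    }, logical(1))
    cats[sel]
}
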