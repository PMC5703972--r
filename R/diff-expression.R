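#' Corrected RPKM (cRPKM)
#'
#' Expression measure using a single reference transcript per gene with a
#' length correction restricted to uniquely mappable positions:
#' `reads / (mappable_kb) / (total_mapped_millions)`.
#'
#' @param rawReads read count(s) assigned to the gene.
#' @param mappableLength uniquely mappable length in nt (> 0).
#' @param totalMapped total mapped reads in the sample (> 0).
#' @return numeric cRPKM value(s).
#' @examples
#' computeCrpkm(1000, 1000, 1e6)  # 1000
#' @export
computeCrpkm <- function(rawReads, mappableLength, totalMapped) {
    if (any(mappableLength <= 0))
        stop("mappable length must be positive (exclude the gene upstream)")
    if (any(totalMapped <= 0)) stop("total mapped reads must be positive")
    rawReads / (mappableLength / 1000) / (totalMapped / 1e6)
}

#' Thresholds for differential-expression calling
#'
#' @param species species label selecting defaults: average fold change 2
#'   (zebrafish) or 1.5 (sea urchin); all-pairwise fold 1.5 (zebrafish) or
#'   1.2 (sea urchin); minimal expression cRPKM > 2 in both replicates of at
#'   least one condition; at least 50 raw reads in at least one sample.
#' @param min_crpkm,min_reads,fold_avg,fold_pairwise override any threshold.
#' @param pseudo floor applied to cRPKM before fold changes (zero handling).
#' @return list of class `expr_params`.
#' @export
exprParams <- function(species = c("zebrafish", "sea_urchin", "custom"),
                       min_crpkm = 2, min_reads = 50,
                       fold_avg = NULL, fold_pairwise = NULL,
                       pseudo = 0.01) {
    species <- match.arg(species)
    if (is.null(fold_avg))
        fold_avg <- switch(species, zebrafish = 2, sea_urchin = 1.5, 2)
    if (is.null(fold_pairwise))
        fold_pairwise <- switch(species, zebrafish = 1.5, sea_urchin = 1.2,
                                1.5)
    structure(list(species = species, min_crpkm = min_crpkm,
                   min_reads = min_reads, fold_avg = fold_avg,
                   fold_pairwise = fold_pairwise, pseudo = pseudo),
              class = "expr_params")
}

#' Call differentially expressed genes
#'
#' Applies, per gene: (i) minimal expression cRPKM > `min_crpkm` in all
#' replicates of at least one condition; (ii) at least `min_reads` raw reads
#' in at least one sample; (iii) fold difference between condition averages
#' of at least `fold_avg`; (iv) fold difference of at least `fold_pairwise`
#' between all control x perturbed replicate pairs, in the direction of the
#' average change. Fold differences are symmetric (`max/min`) with direction
#' tracked separately; cRPKM values are floored at `pseudo` first.
#'
#' @param crpkm,reads numeric matrices genes x samples.
#' @param design a [sampleDesign()] table matching the columns.
#' @param params an [exprParams()] bundle.
#' @return data.frame: `gene_id`, `called`, `direction` (`up`/`down` in the
#'   perturbed condition), `avg_fold`, `min_pairwise_fold`, `expressed`.
#' @export
callDiffGenes <- function(crpkm, reads, design, params = exprParams()) {
    ctrl <- design$sample_id[design$condition == "control"]
    pert <- design$sample_id[design$condition == "perturbed"]
    cc <- pmax(crpkm[, ctrl, drop = FALSE], params$pseudo)
    cp <- pmax(crpkm[, pert, drop = FALSE], params$pseudo)
    exprOk <- apply(crpkm[, ctrl, drop = FALSE] > params$min_crpkm, 1, all) |
        apply(crpkm[, pert, drop = FALSE] > params$min_crpkm, 1, all)
    readsOk <- apply(reads[, c(ctrl, pert), drop = FALSE] >=
                         params$min_reads, 1, any)
    mc <- rowMeans(cc); mp <- rowMeans(cp)
    avgFold <- pmax(mc, mp) / pmin(mc, mp)
    up <- mp > mc  # higher in perturbed
    n <- nrow(crpkm)
    minPair <- dirOk <- numeric(n)
    for (i in seq_len(n)) {
        ratios <- as.numeric(outer(cp[i, ], cc[i, ], `/`))
        folds <- pmax(ratios, 1 / ratios)
        minPair[i] <- min(folds)
        dirOk[i] <- if (up[i]) all(ratios > 1) else all(ratios < 1)
    }
    called <- exprOk & readsOk & avgFold >= params$fold_avg &
        minPair >= params$fold_pairwise & as.logical(dirOk)
    data.frame(gene_id = rownames(crpkm), called = called,
               direction = ifelse(up, "up", "down"),
               avg_fold = avgFold, min_pairwise_fold = minPair,
               expressed = exprOk & readsOk, stringsAsFactors = FALSE,
               row.names = NULL)
}
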