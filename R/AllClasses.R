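#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData colData<-
NULL

#' Ordered read-coverage tiers
#'
#' Quality tiers attached to every PSI estimate, ordered by increasing read
#' support: `N < VLOW < LOW < OK < SOK`.
#' @export
TIER_LEVELS <- c("N", "VLOW", "LOW", "OK", "SOK")

#' PsiExperiment: events-by-samples PSI container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays
#' `psi` (percent spliced in, 0-100), `inc`/`exc` (inclusion/exclusion read
#' counts), `tier` (integer codes into [TIER_LEVELS]) and, for intron-retention
#' events, `b5`/`b3` (reads over the two intron boundaries; `NA` elsewhere).
#' Row metadata carries `gene_id`, `type` (one of `AltEx`, `IR`, `Alt5`,
#' `Alt3`) and `coord`; column metadata carries the sample design
#' (`condition`, `perturbation_sign`, `replicate_id`, `grouping_id`).
#'
#' Validity requires PSI within \[0, 100\] and, wherever `inc + exc > 0`,
#' agreement of `psi` with `100 * inc / (inc + exc)` to 0.05 PSI units.
#'
#' @seealso [PsiExperiment()], [readPsiTable()], [writePsiTable()]
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
    need <- c("psi", "inc", "exc", "tier")
    miss <- setdiff(need, assayNames(object))
    if (length(miss) > 0)
        return(paste("missing assay(s):", paste(miss, collapse = ", ")))
    psi <- assay(object, "psi")
    inc <- assay(object, "inc")
    exc <- assay(object, "exc")
    tier <- assay(object, "tier")
    if (any(psi < -1e-9 | psi > 100 + 1e-9, na.rm = TRUE))
        return("psi values outside [0, 100]")
    if (any(inc < 0, na.rm = TRUE) || any(exc < 0, na.rm = TRUE))
        return("negative read counts")
    if (any(!(tier %in% c(NA, seq_along(TIER_LEVELS)))))
        return("tier codes outside 1..5")
    tot <- inc + exc
    has <- !is.na(tot) & tot > 0 & !is.na(psi)
    if (any(abs(psi[has] - 100 * inc[has] / tot[has]) > 0.05 + 1e-9))
        return("psi inconsistent with inc/exc read counts (tolerance 0.05)")
    if (!all(c("gene_id", "type") %in% colnames(rowData(object))))
        return("rowData must contain gene_id and type")
    TRUE
})

#' GeneModel: exon-intron architecture of one gene
#'
#' Genomic coordinates are stored 0-based half-open; exons of each transcript
#' are kept in transcript (5'->3') orientation, so on the minus strand exon
#' genomic starts decrease along the list.
#'
#' @slot geneId,species,chrom,strand single strings; `strand` is `"+"`/`"-"`.
#' @slot transcripts named list; each element is a `list(exons = <n x 2
#'   integer matrix of start0/end0>, cds = <length-2 integer vector or NULL>)`.
#' @slot mappableLength integer; uniquely mappable exonic positions used for
#'   cRPKM length correction.
#' @export
setClass("GeneModel", representation(
    geneId = "character", species = "character", chrom = "character",
    strand = "character", transcripts = "list", mappableLength = "integer"))

setValidity("GeneModel", function(object) {
    if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
    for (txid in names(object@transcripts)) {
        tx <- object@transcripts[[txid]]
        ex <- tx$exons
        if (is.null(ex) || nrow(ex) == 0)
            return(paste0("transcript ", txid, " has no exons"))
        if (any(ex[, 2] <= ex[, 1]))
            return(paste0("transcript ", txid, " has an empty exon"))
        ord <- if (object@strand == "+") ex[, 1] else -ex[, 1]
        if (nrow(ex) > 1 && any(diff(ord) <= 0))
            return(paste0("transcript ", txid,
                          " exons not ordered 5'->3' or overlapping"))
        if (nrow(ex) > 1) {
            gs <- ex[order(ex[, 1]), , drop = FALSE]
            if (any(gs[-1, 1] < gs[-nrow(gs), 2]))
                return(paste0("transcript ", txid, " exons overlap"))
        }
        if (!is.null(tx$cds)) {
            inside <- any(tx$cds[1] >= ex[, 1] & tx$cds[1] < ex[, 2]) &&
                any(tx$cds[2] > ex[, 1] & tx$cds[2] <= ex[, 2])
            if (!inside)
                return(paste0("CDS of transcript ", txid,
                              " not contained in its exons"))
        }
    }
    exall <- do.call(rbind, lapply(object@transcripts, `[[`, "exons"))
    covered <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(exall[, 1] + 1L, exall[, 2]))))
    if (length(object@mappableLength) == 1 && !is.na(object@mappableLength) &&
        object@mappableLength > covered)
        return("mappableLength exceeds total exonic length")
    TRUE
})

#' ProteinIsoform: a protein with its intron junction map
#'
#' @slot geneId,isoformId single strings.
#' @slot sequence amino-acid string (no stop symbol).
#' @slot junctionMap `data.frame(residue, phase)`: for each intron of the
#'   coding region, `residue` is `floor(cum_coding_nt / 3)` (0-based residue
#'   index the junction precedes) and `phase = cum_coding_nt %% 3`.
#' @export
setClass("ProteinIsoform", representation(
    geneId = "character", isoformId = "character", sequence = "character",
    junctionMap = "data.frame"))

setValidity("ProteinIsoform", function(object) {
    jm <- object@junctionMap
    if (!all(c("residue", "phase") %in% colnames(jm)))
        return("junctionMap needs columns residue, phase")
    if (nrow(jm) > 1 && any(diff(jm$residue) < 0))
        return("junction residues must be non-decreasing")
    if (nrow(jm) > 0 && !all(jm$phase %in% 0:2))
        return("phases must be in {0,1,2}")
    TRUE
})

#' AlignedStructure: pairwise protein alignment with intron markers
#'
#' Result of [alignWithStructure()]: a global pairwise alignment of two
#' protein isoforms with each species' intron positions projected onto
#' alignment columns (phases carried unchanged).
#'
#' @slot alignedA,alignedB gapped aligned sequences (same nchar).
#' @slot markersA,markersB `data.frame(column, phase)`; `column` is the
#'   1-based alignment column of the residue immediately following the intron.
#' @slot isoA,isoB the input [ProteinIsoform] objects.
#' @slot score alignment score under the configured scoring.
#' @slot scoring the scoring configuration used (see [alignScoring()]).
#' @export
setClass("AlignedStructure", representation(
    alignedA = "character", alignedB = "character",
    markersA = "data.frame", markersB = "data.frame",
    isoA = "ProteinIsoform", isoB = "ProteinIsoform",
    score = "numeric", scoring = "list"))

setValidity("AlignedStructure", function(object) {
    if (nchar(object@alignedA) != nchar(object@alignedB))
        return("aligned sequences differ in length")
    if (gsub("-", "", object@alignedA, fixed = TRUE) != object@isoA@sequence)
        return("alignedA does not recover isoA sequence when gaps removed")
    if (gsub("-", "", object@alignedB, fixed = TRUE) != object@isoB@sequence)
        return("alignedB does not recover isoB sequence when gaps removed")
    for (mk in list(object@markersA, object@markersB))
        if (nrow(mk) > 1 && any(diff(mk$column) < 0))
            return("marker columns must be non-decreasing")
    TRUE
})

setMethod("show", "PsiExperiment", function(object) {
    callNextMethod()
    tier <- assay(object, "tier")
    cat("tiers: ", paste(sprintf("%s=%d", TIER_LEVELS,
        tabulate(tier, nbins = 5L)), collapse = " "), "\n", sep = "")
})

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel", object@geneId, sprintf("(%s)", object@species),
        sprintf("%s:%s", object@chrom, object@strand),
        length(object@transcripts), "transcript(s)\n")
})

setMethod("show", "ProteinIsoform", function(object) {
    cat("ProteinIsoform", object@isoformId, "gene", object@geneId,
        sprintf("%d aa, %d junction(s)\n", nchar(object@sequence),
                nrow(object@junctionMap)))
})

setMethod("show", "AlignedStructure", function(object) {
    cat("AlignedStructure:", object@isoA@isoformId, "vs",
        object@isoB@isoformId,
        sprintf("(%d columns, score %.1f)\n", nchar(object@alignedA),
                object@score))
})
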