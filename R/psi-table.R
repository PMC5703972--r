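#' Map supporting read totals to coverage tiers
#'
#' The quantifier that produces PSI tables attaches an ordinal read-support
#' tier to every estimate (`N < VLOW < LOW < OK < SOK`) without publishing the
#' count boundaries; this explicit, overridable mapping keeps downstream
#' gating reproducible. Defaults: N below 5 reads, VLOW 5-14, LOW 15-24,
#' OK 25-99, SOK at or above 100.
#'
#' @param total non-negative integer vector of supporting reads (inc + exc).
#' @param breaks increasing 4-vector of lower bounds for VLOW, LOW, OK, SOK.
#' @return character vector of tier labels (see [TIER_LEVELS]).
#' @export
tierFromReads <- function(total, breaks = c(5L, 15L, 25L, 100L)) {
    stopifnot(length(breaks) == 4, !is.unsorted(breaks))
    idx <- findInterval(total, c(-Inf, breaks))
    TIER_LEVELS[idx]
}

#' @rdname tierFromReads
#' @param tier character vector of tier labels.
#' @return `tierCode()`: integer codes 1..5 following the tier order.
#' @export
tierCode <- function(tier) {
    code <- match(tier, TIER_LEVELS)
    if (anyNA(code) && !all(is.na(tier[is.na(code)])))
        stop("unknown tier label(s): ",
             paste(unique(tier[is.na(code) & !is.na(tier)]), collapse = ", "))
    code
}

#' Construct a PsiExperiment
#'
#' @param psi,inc,exc numeric/integer matrices (events x samples) of PSI
#'   values and inclusion/exclusion read counts.
#' @param tier matrix of tier labels or integer codes; computed from
#'   `inc + exc` via [tierFromReads()] when `NULL`.
#' @param b5,b3 optional matrices of intron-boundary read counts (IR events).
#' @param rowData data.frame with at least `gene_id` and `type`
#'   (`AltEx`/`IR`/`Alt5`/`Alt3`); a `coord` column is carried if present.
#' @param colData data.frame of sample annotations (see [sampleDesign()]).
#' @param tierBreaks passed to [tierFromReads()] when `tier` is `NULL`.
#' @return a [PsiExperiment-class] object.
#' @examples
#' psi <- matrix(c(50, 25), 1, 2, dimnames = list("EV1", c("c1", "k1")))
#' inc <- matrix(c(10L, 5L), 1, 2)
#' exc <- matrix(c(10L, 15L), 1, 2)
#' pe <- PsiExperiment(psi, inc, exc,
#'   rowData = data.frame(gene_id = "G1", type = "AltEx"))
#' @export
PsiExperiment <- function(psi, inc, exc, tier = NULL, b5 = NULL, b3 = NULL,
                          rowData, colData = NULL,
                          tierBreaks = c(5L, 15L, 25L, 100L)) {
    psi <- as.matrix(psi); inc <- as.matrix(inc); exc <- as.matrix(exc)
    if (is.null(colnames(psi)))
        colnames(psi) <- paste0("s", seq_len(ncol(psi)))
    if (is.null(rownames(psi)))
        rownames(psi) <- if (!is.null(rownames(rowData)))
            rownames(rowData) else paste0("EV", seq_len(nrow(psi)))
    if (is.null(tier)) {
        tier <- matrix(tierCode(tierFromReads(inc + exc, tierBreaks)),
                       nrow(psi), ncol(psi))
    } else if (is.character(tier) ||
               (is.matrix(tier) && is.character(tier[1]))) {
        tier <- matrix(tierCode(as.matrix(tier)), nrow(psi), ncol(psi))
    } else {
        tier <- as.matrix(tier)
        storage.mode(tier) <- "integer"
    }
    if (is.null(b5)) b5 <- matrix(NA_integer_, nrow(psi), ncol(psi))
    if (is.null(b3)) b3 <- matrix(NA_integer_, nrow(psi), ncol(psi))
    dn <- dimnames(psi)
    al <- lapply(list(psi = psi, inc = inc, exc = exc, tier = tier,
                      b5 = as.matrix(b5), b3 = as.matrix(b3)),
                 function(m) { dimnames(m) <- dn; m })
    if (is.null(colData)) {
        colData <- DataFrame(row.names = colnames(psi))
    } else if (is.null(rownames(colData)) ||
               identical(rownames(colData),
                         as.character(seq_len(nrow(colData))))) {
        if ("sample_id" %in% colnames(colData))
            rownames(colData) <- colData$sample_id
        else rownames(colData) <- colnames(psi)
    }
    se <- SummarizedExperiment(assays = al, rowData = rowData,
                               colData = colData)
    methods::new("PsiExperiment", se)
}

#' Accessors for PsiExperiment assays
#'
#' @param x a [PsiExperiment-class].
#' @return the corresponding assay matrix; `tierLabels()` returns tier labels.
#' @name psi-accessors
#' @export
psiValues <- function(x) assay(x, "psi")

#' @rdname psi-accessors
#' @export
incReads <- function(x) assay(x, "inc")

#' @rdname psi-accessors
#' @export
excReads <- function(x) assay(x, "exc")

#' @rdname psi-accessors
#' @export
boundaryReads <- function(x) list(b5 = assay(x, "b5"), b3 = assay(x, "b3"))

#' @rdname psi-accessors
#' @export
tierLabels <- function(x) {
    m <- assay(x, "tier")
    out <- matrix(TIER_LEVELS[m], nrow(m), ncol(m), dimnames = dimnames(m))
    out
}

#' @rdname psi-accessors
#' @export
eventType <- function(x) as.character(rowData(x)$type)

#' Sample design table
#'
#' Builds/validates the per-sample design: condition (`control`/`perturbed`),
#' perturbation sign (`loss`/`gain` of splicing-factor function), replicate
#' and grouping labels. Every grouping must contain at least one control and
#' one perturbed sample.
#'
#' @param sample_id,condition,perturbation_sign,replicate_id,grouping_id
#'   vectors recycled to the number of samples.
#' @return data.frame with class `sample_design`.
#' @export
sampleDesign <- function(sample_id, condition,
                         perturbation_sign = "loss",
                         replicate_id = seq_along(sample_id),
                         grouping_id = "main") {
    d <- data.frame(sample_id = as.character(sample_id),
                    condition = as.character(condition),
                    perturbation_sign = as.character(perturbation_sign),
                    replicate_id = as.character(replicate_id),
                    grouping_id = as.character(grouping_id),
                    stringsAsFactors = FALSE)
    stopifnot(all(d$condition %in% c("control", "perturbed")),
              all(d$perturbation_sign %in% c("loss", "gain")))
    for (g in unique(d$grouping_id)) {
        sub <- d[d$grouping_id == g, ]
        if (!any(sub$condition == "control") ||
            !any(sub$condition == "perturbed"))
            stop("grouping '", g, "' lacks a control or a perturbed sample")
    }
    class(d) <- c("sample_design", "data.frame")
    d
}

#' Read / write the PSI table dialect
#'
#' One row per AS event with columns `EVENT`, `GENE`, `TYPE`, `COORD`, then
#' per sample a PSI column `<sample>` and a quality column `<sample>.Q`
#' formatted `tier@inc,exc` (plus `,b5,b3` for intron retention). Rows whose
#' PSI disagrees with `100*inc/(inc+exc)` by more than 0.05 PSI units, or
#' whose PSI falls outside \[0,100\], are rejected; the per-row report is
#' attached as `attr(x, "rejected")`.
#'
#' @param path file path.
#' @param samples optional character vector of expected sample names; a
#'   missing sample column is a hard error naming the sample.
#' @return [readPsiTable()]: a [PsiExperiment-class] (with a `rejected`
#'   attribute); [writePsiTable()]: `path`, invisibly.
#' @export
readPsiTable <- function(path, samples = NULL) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    fixed <- c("EVENT", "GENE", "TYPE", "COORD")
    if (!all(fixed %in% colnames(tab)))
        stop("PSI table must have columns ", paste(fixed, collapse = ", "))
    rest <- setdiff(colnames(tab), fixed)
    qcols <- grep("\\.Q$", rest, value = TRUE)
    scols <- setdiff(rest, qcols)
    if (!is.null(samples)) {
        miss <- setdiff(samples, scols)
        if (length(miss) > 0)
            stop("missing sample column(s): ", paste(miss, collapse = ", "))
        scols <- samples
    }
    for (s in scols)
        if (!paste0(s, ".Q") %in% qcols)
            stop("missing quality column for sample: ", s)

    n <- nrow(tab); k <- length(scols)
    psi <- matrix(NA_real_, n, k, dimnames = list(tab$EVENT, scols))
    inc <- exc <- b5 <- b3 <- tier <-
        matrix(NA_integer_, n, k, dimnames = list(tab$EVENT, scols))
    rejected <- data.frame(row = integer(), event = character(),
                           sample = character(), reason = character())
    for (j in seq_len(k)) {
        s <- scols[j]
        psi[, j] <- suppressWarnings(as.numeric(tab[[s]]))
        q <- tab[[paste0(s, ".Q")]]
        tq <- sub("@.*", "", q)
        tier[, j] <- tierCode(ifelse(tq == "" | is.na(tq), NA, tq))
        nums <- strsplit(sub(".*@", "", q), ",", fixed = TRUE)
        inc[, j] <- vapply(nums, function(v)
            suppressWarnings(as.integer(v[1])), integer(1))
        exc[, j] <- vapply(nums, function(v)
            suppressWarnings(as.integer(v[2])), integer(1))
        b5[, j] <- vapply(nums, function(v)
            if (length(v) >= 4) suppressWarnings(as.integer(v[3]))
            else NA_integer_, integer(1))
        b3[, j] <- vapply(nums, function(v)
            if (length(v) >= 4) suppressWarnings(as.integer(v[4]))
            else NA_integer_, integer(1))
    }
    bad <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in seq_len(k)) {
        p <- psi[i, j]; tot <- inc[i, j] + exc[i, j]
        reason <- NULL
        if (!is.na(p) && (p < 0 || p > 100))
            reason <- sprintf("PSI %.2f outside [0,100]", p)
        else if (!is.na(p) && !is.na(tot) && tot > 0 &&
                 abs(p - 100 * inc[i, j] / tot) > 0.05 + 1e-9)
            reason <- sprintf("PSI %.2f inconsistent with reads %d/%d",
                              p, inc[i, j], tot)
        if (!is.null(reason)) {
            bad[i] <- TRUE
            rejected <- rbind(rejected, data.frame(
                row = i, event = tab$EVENT[i], sample = scols[j],
                reason = reason))
        }
    }
    keep <- !bad
    pe <- PsiExperiment(psi[keep, , drop = FALSE], inc[keep, , drop = FALSE],
                        exc[keep, , drop = FALSE],
                        tier = tier[keep, , drop = FALSE],
                        b5 = b5[keep, , drop = FALSE],
                        b3 = b3[keep, , drop = FALSE],
                        rowData = data.frame(
                            gene_id = tab$GENE[keep], type = tab$TYPE[keep],
                            coord = tab$COORD[keep], row.names = tab$EVENT[keep]))
    attr(pe, "rejected") <- rejected
    pe
}

#' @rdname readPsiTable
#' @param x a [PsiExperiment-class].
#' @export
writePsiTable <- function(x, path) {
    rd <- rowData(x)
    psi <- psiValues(x); inc <- incReads(x); exc <- excReads(x)
    tier <- tierLabels(x); bd <- boundaryReads(x)
    out <- data.frame(EVENT = rownames(x), GENE = rd$gene_id, TYPE = rd$type,
                      COORD = if ("coord" %in% colnames(rd)) rd$coord else ".",
                      check.names = FALSE, stringsAsFactors = FALSE)
    for (s in colnames(x)) {
        out[[s]] <- sprintf("%.2f", psi[, s])
        q <- sprintf("%s@%d,%d", tier[, s], inc[, s], exc[, s])
        isIR <- !is.na(bd$b5[, s])
        q[isIR] <- sprintf("%s,%d,%d", q[isIR], bd$b5[isIR, s],
                           bd$b3[isIR, s])
        out[[paste0(s, ".Q")]] <- q
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
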