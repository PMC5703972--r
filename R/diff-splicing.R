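#' Per-species thresholds for differential splicing and expression
#'
#' Bundles the calling thresholds used for each species: the minimum absolute
#' ΔPSI between condition averages (15 for zebrafish and mouse, 10 for sea
#' urchin, 15 with strict inequality for the human multi-source combination),
#' the minimum pairwise ΔPSI of 5 in a consistent direction, and the IR
#' read-imbalance alpha of 0.05.
#'
#' @param species one of `"zebrafish"`, `"mouse"`, `"sea_urchin"`, `"human"`,
#'   or `"custom"` (then supply values explicitly).
#' @param min_dpsi,min_pairwise ΔPSI thresholds (PSI units).
#' @param dpsi_cmp,pairwise_cmp `">="` (a stated minimum) or `">"` (strict,
#'   as in the human combination phrasing).
#' @param ir_alpha significance level of the IR balance test.
#' @param ir_alternative sidedness of the IR binomial test.
#' @return a list of class `species_params`.
#' @export
speciesParams <- function(species = c("zebrafish", "mouse", "sea_urchin",
                                      "human", "custom"),
                          min_dpsi = NULL, min_pairwise = 5,
                          dpsi_cmp = NULL, pairwise_cmp = NULL,
                          ir_alpha = 0.05,
                          ir_alternative = c("two.sided", "one.sided")) {
    species <- match.arg(species)
    defaults <- list(zebrafish = 15, mouse = 15, sea_urchin = 10, human = 15,
                     custom = 15)
    if (is.null(min_dpsi)) min_dpsi <- defaults[[species]]
    if (is.null(dpsi_cmp)) dpsi_cmp <- if (species == "human") ">" else ">="
    if (is.null(pairwise_cmp))
        pairwise_cmp <- if (species == "human") ">" else ">="
    if (min_dpsi < min_pairwise)
        stop("min_dpsi (", min_dpsi, ") must be >= min_pairwise (",
             min_pairwise, ")")
    structure(list(species = species, min_dpsi = min_dpsi,
                   min_pairwise = min_pairwise, dpsi_cmp = dpsi_cmp,
                   pairwise_cmp = pairwise_cmp, ir_alpha = ir_alpha,
                   ir_alternative = match.arg(ir_alternative)),
              class = "species_params")
}

.cmp <- function(x, thr, op) if (op == ">") x > thr else x >= thr

#' ΔPSI statistics for one event
#'
#' Computes, in loss-of-function orientation, the average ΔPSI
#' (`mean(control PSI) - mean(perturbed PSI)`), every control x perturbed
#' pairwise ΔPSI, and the coverage gate (every compared sample at tier VLOW
#' or higher).
#'
#' @param pe a [PsiExperiment-class].
#' @param eventId event (row) identifier.
#' @param controls,perturbed sample ids of the two groups.
#' @return list with `dpsi_avg`, `pairwise` (numeric vector over all
#'   control x perturbed pairs), `coverage_ok`, and the tiers used.
#' @export
computeEventStats <- function(pe, eventId, controls, perturbed) {
    if (!eventId %in% rownames(pe))
        stop("event not present in PSI table: ", eventId)
    psi <- psiValues(pe)[eventId, , drop = TRUE]
    tier <- assay(pe, "tier")[eventId, , drop = TRUE]
    miss <- setdiff(c(controls, perturbed), colnames(pe))
    if (length(miss) > 0)
        stop("missing sample column(s): ", paste(miss, collapse = ", "))
    pc <- psi[controls]; pp <- psi[perturbed]
    pw <- as.numeric(outer(pc, pp, `-`))
    tiers <- tier[c(controls, perturbed)]
    coverage_ok <- !anyNA(psi[c(controls, perturbed)]) &&
        !anyNA(tiers) && all(tiers >= tierCode("VLOW"))
    list(dpsi_avg = mean(pc) - mean(pp), pairwise = pw,
         coverage_ok = coverage_ok,
         tiers = TIER_LEVELS[tiers])
}

#' Binomial test for intron-retention read imbalance
#'
#' Reads supporting a retained intron should split evenly between its two
#' exon-intron boundaries; a significant imbalance indicates an artefact and
#' disqualifies the IR event. With both counts zero there is no evidence of
#' balance and `NA` is returned (the event then fails IR gating).
#'
#' @param b5,b3 reads over the upstream / downstream intron boundary.
#' @param alternative `"two.sided"` (default) or `"one.sided"` (probability
#'   of an imbalance at least as large in the observed direction).
#' @return p-value, or `NA` when both counts are zero.
#' @examples
#' irBalanceTest(10, 10)  # 1
#' irBalanceTest(0, 20)   # 2 * 0.5^20
#' @export
irBalanceTest <- function(b5, b3,
                          alternative = c("two.sided", "one.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(b5 >= 0, b3 >= 0)
    n <- b5 + b3
    if (n == 0) return(NA_real_)
    if (alternative == "two.sided")
        stats::binom.test(b5, n, p = 0.5)$p.value
    else
        stats::pbinom(min(b5, b3), n, 0.5)
}

# Shared threshold logic: called iff |dpsi_avg| passes min_dpsi and all
# pairwise values pass min_pairwise with one consistent sign.
.passesDpsi <- function(dpsi_avg, pairwise, params) {
    magOk <- .cmp(abs(dpsi_avg), params$min_dpsi, params$dpsi_cmp)
    up <- all(.cmp(pairwise, params$min_pairwise, params$pairwise_cmp))
    dn <- all(.cmp(-pairwise, params$min_pairwise, params$pairwise_cmp))
    dirOk <- (dpsi_avg > 0 && up) || (dpsi_avg < 0 && dn)
    magOk && dirOk
}

#' Call splicing-factor-dependent events for one species
#'
#' An event is called when (i) every compared sample has read coverage at
#' tier VLOW or higher, (ii) the absolute ΔPSI between condition averages
#' passes the species threshold, and (iii) every control x perturbed pairwise
#' ΔPSI passes 5 PSI units in the same direction. Intron-retention events
#' additionally require the boundary-read imbalance test to be non-significant
#' in every sample. Direction is `enhanced` when inclusion is higher with the
#' factor functional (positive loss-of-function ΔPSI).
#'
#' @param pe a [PsiExperiment-class].
#' @param design a [sampleDesign()] table; gain-of-function samples have
#'   their ΔPSI orientation flipped into loss orientation.
#' @param params a [speciesParams()] bundle.
#' @return data.frame, one row per event: `event_id`, `species`, `type`,
#'   `direction`, `dpsi_avg`, `dpsi_pairwise_min`, `coverage_ok`,
#'   `ir_balance_ok`, `called`, `provenance`.
#' @export
callSpeciesEvents <- function(pe, design, params = speciesParams()) {
    ctrl <- design$sample_id[design$condition == "control"]
    pert <- design$sample_id[design$condition == "perturbed"]
    signs <- unique(design$perturbation_sign[design$condition == "perturbed"])
    if (length(signs) != 1)
        stop("mixed loss/gain perturbations; use combineGroupings() with a ",
             "declared sign contract")
    flip <- if (signs == "gain") -1 else 1
    bd <- boundaryReads(pe)
    types <- eventType(pe)
    out <- lapply(seq_len(nrow(pe)), function(i) {
        ev <- rownames(pe)[i]
        st <- computeEventStats(pe, ev, ctrl, pert)
        dpsi <- flip * st$dpsi_avg
        pw <- flip * st$pairwise
        irOk <- NA
        if (types[i] == "IR") {
            ps <- vapply(c(ctrl, pert), function(s)
                irBalanceTest(bd$b5[ev, s], bd$b3[ev, s],
                              alternative = params$ir_alternative),
                numeric(1))
            irOk <- !anyNA(ps) && all(ps >= params$ir_alpha)
        }
        called <- st$coverage_ok && .passesDpsi(dpsi, pw, params) &&
            (types[i] != "IR" || isTRUE(irOk))
        data.frame(event_id = ev, species = params$species, type = types[i],
                   direction = if (dpsi >= 0) "enhanced" else "silenced",
                   dpsi_avg = dpsi,
                   dpsi_pairwise_min = if (dpsi >= 0) min(pw) else max(pw),
                   coverage_ok = st$coverage_ok, ir_balance_ok = irOk,
                   called = called, provenance = "main",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Merge samples by pooling reads
#'
#' Builds a pseudo-sample by summing inclusion/exclusion (and boundary) reads
#' over `samples`, recomputing PSI as `100*inc/(inc+exc)` and the tier from
#' the pooled total.
#'
#' @param pe a [PsiExperiment-class].
#' @param samples sample ids to pool.
#' @param name name of the pooled pseudo-sample.
#' @return a one-column [PsiExperiment-class].
#' @export
mergeSamples <- function(pe, samples, name = "merged") {
    inc <- rowSums(incReads(pe)[, samples, drop = FALSE])
    exc <- rowSums(excReads(pe)[, samples, drop = FALSE])
    bd <- boundaryReads(pe)
    b5 <- rowSums(bd$b5[, samples, drop = FALSE])
    b3 <- rowSums(bd$b3[, samples, drop = FALSE])
    tot <- inc + exc
    psi <- ifelse(tot > 0, 100 * inc / tot, NA_real_)
    m <- function(v) matrix(v, ncol = 1, dimnames = list(rownames(pe), name))
    PsiExperiment(m(psi), m(as.integer(inc)), m(as.integer(exc)),
                  b5 = m(as.integer(b5)), b3 = m(as.integer(b3)),
                  rowData = rowData(pe))
}

#' Combine calls across sample groupings (multi-source design)
#'
#' Implements the combination used when perturbation data come from several
#' sources: an event enters the combined set if it passes the ΔPSI cutoffs
#' (|ΔPSI| > 15 between averages, |ΔPSI| > 5 for all pairwise comparisons in
#' a consistent direction) in at least one declared grouping. A grouping is
#' either a single loss- or gain-of-function comparison (optionally on pooled
#' pseudo-samples, see [mergeSamples()]), or a pair of a loss and a gain
#' comparison whose ΔPSI values must be of opposite sign. The final direction
#' is reported in loss-of-function orientation.
#'
#' @param pe a [PsiExperiment-class] containing all samples.
#' @param groupings named list; each element is a list of one or two
#'   comparisons `list(control=, perturbed=, sign="loss"/"gain",
#'   merge=FALSE)`. Two-comparison groupings must pair one loss with one
#'   gain.
#' @param params a [speciesParams()] bundle (defaults to the strict human
#'   thresholds).
#' @return data.frame as in [callSpeciesEvents()], with `provenance` listing
#'   the groupings in which each event passed (comma-separated).
#' @export
combineGroupings <- function(pe, groupings,
                             params = speciesParams("human")) {
    prep <- lapply(names(groupings), function(g) {
        lapply(groupings[[g]], function(cmp) {
            stopifnot(!is.null(cmp$control), !is.null(cmp$perturbed))
            sign <- if (is.null(cmp$sign)) "loss" else cmp$sign
            if (!sign %in% c("loss", "gain"))
                stop("comparison sign must be 'loss' or 'gain'")
            sub <- pe
            ctl <- cmp$control; prt <- cmp$perturbed
            if (isTRUE(cmp$merge)) {
                mc <- mergeSamples(pe, ctl, paste0(g, ".ctl"))
                mp <- mergeSamples(pe, prt, paste0(g, ".prt"))
                sub <- methods::new("PsiExperiment",
                                    SummarizedExperiment::cbind(mc, mp))
                ctl <- paste0(g, ".ctl"); prt <- paste0(g, ".prt")
            }
            list(pe = sub, control = ctl, perturbed = prt, sign = sign)
        })
    })
    names(prep) <- names(groupings)
    for (g in names(prep))
        if (length(prep[[g]]) == 2) {
            ss <- sort(unname(vapply(prep[[g]], `[[`, "", "sign")))
            if (!identical(ss, c("gain", "loss")))
                stop("grouping '", g, "' pairs two comparisons but not one ",
                     "loss with one gain (no declared sign contract)")
        }
    out <- lapply(rownames(pe), function(ev) {
        passed <- character(0)
        lossDpsi <- NA_real_
        for (g in names(prep)) {
            parts <- lapply(prep[[g]], function(p) {
                st <- computeEventStats(p$pe, ev, p$control, p$perturbed)
                ok <- st$coverage_ok && .passesDpsi(st$dpsi_avg, st$pairwise,
                                                    params)
                list(ok = ok, dpsi = st$dpsi_avg, sign = p$sign)
            })
            ok <- all(vapply(parts, `[[`, TRUE, "ok"))
            if (ok && length(parts) == 2) {
                d <- vapply(parts, `[[`, 0, "dpsi")
                ok <- prod(d) < 0  # opposite raw directions
            }
            if (ok) {
                passed <- c(passed, g)
                if (is.na(lossDpsi)) {
                    lossIdx <- which(vapply(parts, `[[`, "", "sign") == "loss")
                    lossDpsi <- if (length(lossIdx) > 0)
                        parts[[lossIdx[1]]]$dpsi else -parts[[1]]$dpsi
                }
            }
        }
        if (is.na(lossDpsi)) {  # report first grouping's loss-oriented dpsi
            p1 <- prep[[1]][[1]]
            st <- computeEventStats(p1$pe, ev, p1$control, p1$perturbed)
            lossDpsi <- if (p1$sign == "gain") -st$dpsi_avg else st$dpsi_avg
        }
        data.frame(event_id = ev, species = params$species,
                   type = eventType(pe)[match(ev, rownames(pe))],
                   direction = if (lossDpsi >= 0) "enhanced" else "silenced",
                   dpsi_avg = lossDpsi, dpsi_pairwise_min = NA_real_,
                   coverage_ok = NA, ir_balance_ok = NA,
                   called = length(passed) > 0,
                   provenance = paste(passed, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Low-coverage rescue of events with a regulated homolog
#'
#' An event that failed the initial coverage gate is re-admitted when a
#' homologous exon is factor-dependent in another species, exactly one of its
#' samples falls below tier VLOW, and that sample still has at least two
#' supporting reads; the event is then re-evaluated against the unchanged
#' ΔPSI cutoffs.
#'
#' @param pe a [PsiExperiment-class].
#' @param eventId event to consider.
#' @param design a [sampleDesign()] table.
#' @param homologCalledElsewhere is a homologous exon called in another
#'   species?
#' @param params a [speciesParams()] bundle.
#' @return list `rescued` (coverage gate waived?) and `called` (final verdict
#'   after re-evaluation; `FALSE` when not rescued).
#' @export
rescueLowCoverage <- function(pe, eventId, design, homologCalledElsewhere,
                              params = speciesParams()) {
    if (!isTRUE(homologCalledElsewhere))
        return(list(rescued = FALSE, called = FALSE))
    ctrl <- design$sample_id[design$condition == "control"]
    pert <- design$sample_id[design$condition == "perturbed"]
    samples <- c(ctrl, pert)
    tiers <- assay(pe, "tier")[eventId, samples]
    low <- which(is.na(tiers) | tiers < tierCode("VLOW"))
    if (length(low) != 1) return(list(rescued = FALSE, called = FALSE))
    s <- samples[low]
    reads <- incReads(pe)[eventId, s] + excReads(pe)[eventId, s]
    if (is.na(reads) || reads < 2)
        return(list(rescued = FALSE, called = FALSE))
    st <- computeEventStats(pe, eventId, ctrl, pert)
    sign <- unique(design$perturbation_sign[design$condition == "perturbed"])
    flip <- if (identical(sign, "gain")) -1 else 1
    called <- !anyNA(psiValues(pe)[eventId, samples]) &&
        .passesDpsi(flip * st$dpsi_avg, flip * st$pairwise, params)
    list(rescued = TRUE, called = called)
}
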