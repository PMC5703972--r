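test_that("generators are pure functions of (params, seed)", {
    s1 <- simulateGeneFamilies(4, params = simParams(divergence = 0.1,
                                                     exon_gain = 0.1,
                                                     exon_loss = 0.1),
                               seed = 9)
    s2 <- simulateGeneFamilies(4, params = simParams(divergence = 0.1,
                                                     exon_gain = 0.1,
                                                     exon_loss = 0.1),
                               seed = 9)
    expect_identical(lapply(s1$genome, as.character),
                     lapply(s2$genome, as.character))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateGeneFamilies(4, params = simParams(divergence = 0.1),
                               seed = 10)
    expect_false(identical(as.character(s1$genome$spA),
                           as.character(s3$genome$spA)))
})

test_that("zero divergence yields identical orthologous proteins", {
    sim <- simulateGeneFamilies(5, params = simParams(divergence = 0),
                                seed = 2)
    for (fam in 1:5) {
        seqs <- vapply(sim$species, function(sp)
            sim$proteins[[sp]][[sprintf("%s_g%03d", sp, fam)]]@sequence,
            character(1))
        expect_equal(length(unique(seqs)), 1)
    }
})

test_that("no gain/loss keeps exon counts equal across species", {
    sim <- simulateGeneFamilies(5, params = simParams(exon_gain = 0,
                                                      exon_loss = 0,
                                                      divergence = 0.2),
                                seed = 3)
    for (fam in 1:5) {
        counts <- vapply(sim$species, function(sp)
            nrow(sim$models[[sp]][[sprintf("%s_g%03d",
                                           sp, fam)]]@transcripts$t1$exons),
            integer(1))
        expect_equal(length(unique(counts)), 1)
    }
})

test_that("species trees need at least two leaves", {
    expect_error(simulateGeneFamilies(2, speciesTree = "(spA:1);"),
                 "at least 2")
})

test_that("perturbation shifts follow the stated sign conventions", {
    # high depth so observed PSI is close to truth
    sim <- simulateGeneFamilies(40, speciesTree = "(spA:1,spB:1);",
                                params = simParams(p_dependent = 1),
                                seed = 4)
    ps <- simulatePsiTables(sim, depth = 5000L, seed = 4)
    tr <- ps$truth
    obs <- psiValues(ps$psi$spA)[tr$event_id[tr$species == "spA"], ]
    trA <- tr[tr$species == "spA", ]
    pert <- rowMeans(obs[, c("ko1", "ko2")])
    ctl <- rowMeans(obs[, c("ctl1", "ctl2")])
    enh <- trA$direction == "enhanced" & !trA$clamped
    sil <- trA$direction == "silenced" & !trA$clamped
    # loss of an enhancing factor lowers inclusion by dpsi_true
    expect_equal(unname(pert[enh]), trA$control_psi[enh] - 30,
                 tolerance = 0.15)
    expect_equal(unname(pert[sil]), trA$control_psi[sil] + 30,
                 tolerance = 0.15)
    expect_equal(unname(ctl), trA$control_psi, tolerance = 0.15)
    # gain-of-function flips the shift and clamps at the PSI bounds
    dGain <- sampleDesign(c("c1", "c2", "oe1", "oe2"),
                          c("control", "control", "perturbed", "perturbed"),
                          perturbation_sign = c("loss", "loss", "gain",
                                                "gain"))
    psG <- simulatePsiTables(sim, design = dGain, depth = 5000L, seed = 4)
    trG <- psG$truth[psG$truth$species == "spA", ]
    obsG <- psiValues(psG$psi$spA)[trG$event_id, ]
    enhG <- trG$direction == "enhanced"
    expG <- pmin(100, pmax(0, trG$control_psi[enhG] + 30))
    expect_equal(unname(rowMeans(obsG[enhG, c("oe1", "oe2")])), expG,
                 tolerance = 0.2)
})

test_that("observed null |dPSI| shrinks like depth^-1/2", {
    sim <- simulateGeneFamilies(350, speciesTree = "(spA:1,spB:1);",
                                params = simParams(p_dependent = 0,
                                                   n_exons = c(4L, 5L),
                                                   exon_aa = c(10L, 14L),
                                                   intron_len = c(80L,
                                                                  120L)),
                                seed = 5)
    dpsiAt <- function(depth, seed) {
        ps <- simulatePsiTables(sim, depth = depth, seed = seed)
        obs <- psiValues(ps$psi$spA)
        mean(abs(rowMeans(obs[, c("ctl1", "ctl2")]) -
                     rowMeans(obs[, c("ko1", "ko2")])))
    }
    m40 <- dpsiAt(40L, 11)
    m160 <- dpsiAt(160L, 12)
    # quadrupling depth should halve the null deviation (within 20%)
    expect_lt(abs(m40 / m160 - 2), 0.4)
})

test_that("truth records resolve to generated entities (closure)", {
    sim <- simulateGeneFamilies(6, params = simParams(exon_loss = 0.3,
                                                      divergence = 0.1),
                                seed = 6)
    tr <- sim$truth$exons
    for (i in seq_len(nrow(tr))) {
        sp <- tr$species[i]
        expect_true(tr$gene_id[i] %in% names(sim$models[[sp]]))
        expect_true(tr$gene_id[i] %in% names(sim$genome[[sp]]))
        if (tr$present[i])
            expect_true(tr$event_id[i] %in% sim$events[[sp]]$event_id)
        else
            expect_false(tr$event_id[i] %in% sim$events[[sp]]$event_id)
    }
    ev <- sim$truth$evidence
    genes <- unlist(lapply(sim$models, names), use.names = FALSE)
    expect_true(all(c(ev$gene_a, ev$gene_b) %in% genes))
    # each simulated event appears exactly once per species table
    for (sp in sim$species)
        expect_false(any(duplicated(sim$events[[sp]]$event_id)))
})

test_that("simulated models parse, translate and re-derive junctions", {
    sim <- simulateGeneFamilies(3, seed = 7)
    for (sp in sim$species) for (g in names(sim$models[[sp]])) {
        m <- sim$models[[sp]][[g]]
        isoStored <- sim$proteins[[sp]][[g]]
        isoFromGenome <- deriveProteinJunctionMap(m, "t1",
                                                  genome = sim$genome[[sp]])
        expect_identical(isoFromGenome@sequence, isoStored@sequence)
        expect_identical(isoFromGenome@junctionMap, isoStored@junctionMap)
    }
})

test_that("motif planting gives direct targets hits and indirect none", {
    sim <- simulateGeneFamilies(12, params = simParams(p_dependent = 1,
                                                       p_direct = 0.5),
                                seed = 8)
    m <- defaultMotifSet()
    pl <- plantMotifs(sim, m, "restricted", nPlant = 2L, seed = 8)
    tr <- sim$truth$exons
    for (sp in sim$species) {
        evs <- sim$events[[sp]]
        for (i in seq_len(nrow(evs))) {
            t1 <- tr[tr$event_id == evs$event_id[i], ]
            cnt <- countMotifRegions(evs[i, ], pl$genome[[sp]], m)
            if (t1$direct) {
                # planted sites are recovered by the scanner
                if (t1$direction == "enhanced")
                    expect_gte(cnt[["dn_int_rest"]], 2)
                else expect_gte(cnt[["up_int_last250"]], 2)
            } else {
                # scenario regions of indirect targets are scrubbed clean
                if (t1$direction == "silenced")
                    expect_equal(cnt[["up_int_all"]] + cnt[["alt_exon"]], 0)
                else expect_equal(cnt[["dn_int_all"]] +
                                      cnt[["up_int_last250"]], 0)
            }
        }
    }
    # closing the loop: classifier recovers the planted labels
    for (sp in sim$species) {
        evs <- sim$events[[sp]]
        for (i in seq_len(nrow(evs))) {
            t1 <- tr[tr$event_id == evs$event_id[i], ]
            cnt <- countMotifRegions(evs[i, ], pl$genome[[sp]], m)
            cls <- classifyDirectIndirect(t1$direction, cnt, "restricted",
                                          1)
            expect_identical(cls,
                             ifelse(t1$direct, "direct", "indirect"))
        }
    }
})
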