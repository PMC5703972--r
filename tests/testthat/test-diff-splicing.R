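test_that("event statistics enumerate all control x perturbed pairs", {
    pe <- peFromPsi(matrix(c(95, 85, 60, 70), 1,
                           dimnames = list("EV1", c("c1", "c2", "k1",
                                                    "k2"))))
    st <- computeEventStats(pe, "EV1", c("c1", "c2"), c("k1", "k2"))
    expect_equal(st$dpsi_avg, 25)
    expect_setequal(st$pairwise, c(35, 25, 25, 15))
    expect_true(st$coverage_ok)
    expect_error(computeEventStats(pe, "NOPE", "c1", "k1"), "NOPE")
})

test_that("any sample below VLOW fails the coverage gate", {
    inc <- matrix(c(10L, 10L, 2L, 10L), 1)
    exc <- matrix(c(10L, 10L, 1L, 10L), 1)
    pe <- peFromCounts(inc, exc)  # third sample: 3 reads -> tier N
    st <- computeEventStats(pe, "EV1", c("s1", "s2"), c("s3", "s4"))
    expect_false(st$coverage_ok)
})

test_that("IR balance test matches closed forms and enumeration", {
    expect_equal(irBalanceTest(10, 10), 1)
    expect_equal(irBalanceTest(0, 20), 2 * 0.5^20, tolerance = 1e-12)
    # brute-force two-sided: sum of P(k) over k with P(k) <= P(observed)
    p <- dbinom(0:20, 20, 0.5)
    expect_equal(irBalanceTest(8, 12), sum(p[p <= p[9] * (1 + 1e-7)]),
                 tolerance = 1e-12)
    expect_true(is.na(irBalanceTest(0, 0)))
})

test_that("species thresholds gate calls at the stated boundaries", {
    mk <- function(psiC, psiP) peFromPsi(
        matrix(c(psiC, psiP), 1,
               dimnames = list("EV1", c("c1", "c2", "k1", "k2"))))
    d <- design22()
    # dpsi 25, min pairwise 15: called enhanced at min_dpsi 15
    calls <- callSpeciesEvents(mk(c(95, 85), c(60, 70)), d,
                               speciesParams("zebrafish"))
    expect_true(calls$called); expect_identical(calls$direction, "enhanced")
    # dpsi_avg 14 misses min_dpsi 15
    c14 <- callSpeciesEvents(mk(c(80, 80), c(66, 66)), d,
                             speciesParams("zebrafish"))
    expect_false(c14$called)
    # exactly 15 passes with ">=" (stated minimum) but not with ">"
    c15 <- callSpeciesEvents(mk(c(80, 80), c(65, 65)), d,
                             speciesParams("zebrafish"))
    expect_true(c15$called)
    c15h <- callSpeciesEvents(mk(c(80, 80), c(65, 65)), d,
                              speciesParams("human"))
    expect_false(c15h$called)
    # sea urchin threshold 10
    c12 <- callSpeciesEvents(mk(c(80, 80), c(68, 68)), d,
                             speciesParams("sea_urchin"))
    expect_true(c12$called)
})

test_that("IR events need balanced boundary reads in every sample", {
    psi <- matrix(c(90, 90, 60, 60), 1,
                  dimnames = list("EV1", c("c1", "c2", "k1", "k2")))
    inc <- matrix(as.integer(psi / 100 * 100), 1, dimnames = dimnames(psi))
    exc <- 100L - inc
    bal <- matrix(10L, 1, 4); imb5 <- matrix(c(10L, 10L, 0L, 10L), 1)
    imb3 <- matrix(c(10L, 10L, 20L, 10L), 1)
    d <- design22()
    ok <- callSpeciesEvents(peFromCounts(inc, exc, type = "IR", b5 = bal,
                                         b3 = bal), d, speciesParams())
    expect_true(ok$called); expect_true(ok$ir_balance_ok)
    bad <- callSpeciesEvents(peFromCounts(inc, exc, type = "IR", b5 = imb5,
                                          b3 = imb3), d, speciesParams())
    expect_false(bad$called); expect_false(bad$ir_balance_ok)
})

test_that("pairwise values must share one direction", {
    pe <- peFromPsi(matrix(c(90, 50, 70, 70), 1,
                           dimnames = list("EV1", c("c1", "c2", "k1",
                                                    "k2"))))
    # pairs: +20, +20, -20, -20 -> mixed signs, avg 0
    calls <- callSpeciesEvents(pe, design22(), speciesParams())
    expect_false(calls$called)
})

test_that("multi-grouping combination applies the opposite-direction rule", {
    # samples: H358 KD pair, PNT2 KD pair, MB231 OE pair
    psi <- matrix(c(80, 60, 85, 60, 60, 78), 1,
                  dimnames = list("EV1", c("hc", "hk", "pc", "pk", "mc",
                                           "mo")))
    pe <- peFromPsi(psi)
    grpPair <- list(
        kd = list(control = "pc", perturbed = "pk", sign = "loss"),
        oe = list(control = "mc", perturbed = "mo", sign = "gain"))
    res <- combineGroupings(pe, list(iii = grpPair))
    # KD dpsi +25, OE dpsi -18: opposite directions -> called enhanced
    expect_true(res$called)
    expect_identical(res$direction, "enhanced")
    expect_identical(res$provenance, "iii")

    # same-direction KD and OE changes fail the grouping
    psi2 <- psi; psi2[, "mo"] <- 40  # OE dpsi +20, same sign as KD
    res2 <- combineGroupings(peFromPsi(psi2), list(iii = grpPair))
    expect_false(res2$called)

    # union semantics: passing a single-comparison grouping suffices
    res3 <- combineGroupings(pe, list(
        i = list(list(control = "hc", perturbed = "hk", sign = "loss")),
        iii = grpPair))
    expect_true(res3$called)
    expect_identical(res3$provenance, "i,iii")

    # two-part grouping without a loss/gain contract is an error
    expect_error(combineGroupings(pe, list(bad = list(
        a = list(control = "pc", perturbed = "pk", sign = "loss"),
        b = list(control = "hc", perturbed = "hk", sign = "loss")))),
        "sign contract")
})

test_that("merged pseudo-samples pool reads before recomputing PSI", {
    inc <- matrix(c(2L, 3L, 10L), 1,
                  dimnames = list("EV1", c("r1", "r2", "r3")))
    exc <- matrix(c(3L, 2L, 10L), 1, dimnames = dimnames(inc))
    pe <- peFromCounts(inc, exc)
    m <- mergeSamples(pe, c("r1", "r2", "r3"), "pool")
    expect_equal(unname(incReads(m)[1, 1]), 15L)
    expect_equal(unname(psiValues(m)[1, 1]), 100 * 15 / 30)
    expect_identical(unname(tierLabels(m)[1, 1]), "OK")  # 30 pooled reads
})

test_that("low-coverage rescue needs one low sample with >= 2 reads", {
    d <- design22()
    mk <- function(lowReads, nLow = 1) {
        inc <- matrix(c(40L, 40L, 8L, 8L), 1,
                      dimnames = list("EV1", d$sample_id))
        exc <- matrix(c(10L, 10L, 12L, 12L), 1, dimnames = dimnames(inc))
        # force low tiers by shrinking read totals
        lowCols <- seq_len(nLow) + 2L
        for (j in lowCols) {
            inc[1, j] <- as.integer(round(lowReads * 0.4))
            exc[1, j] <- lowReads - inc[1, j]
        }
        peFromCounts(inc, exc)
    }
    # one sample with 3 reads, dpsi 80-40 = 40: rescued and called
    r <- rescueLowCoverage(mk(3L), "EV1", d, TRUE, speciesParams())
    expect_true(r$rescued); expect_true(r$called)
    # a single supporting read is not enough
    expect_false(rescueLowCoverage(mk(1L), "EV1", d, TRUE,
                                   speciesParams())$rescued)
    # two low-coverage samples disqualify
    expect_false(rescueLowCoverage(mk(3L, nLow = 2), "EV1", d, TRUE,
                                   speciesParams())$rescued)
    # no regulated homolog elsewhere: not applicable
    expect_false(rescueLowCoverage(mk(3L), "EV1", d, FALSE,
                                   speciesParams())$rescued)
})

test_that("raising thresholds never adds a call (monotonicity)", {
    set.seed(42)
    d <- design22()
    for (rep in 1:25) {
        psi <- matrix(runif(4, 0, 100), 1,
                      dimnames = list("EV1", d$sample_id))
        loose <- callSpeciesEvents(peFromPsi(psi), d,
                                   speciesParams("custom", min_dpsi = 10,
                                                 min_pairwise = 5))
        tight <- callSpeciesEvents(peFromPsi(psi), d,
                                   speciesParams("custom", min_dpsi = 20,
                                                 min_pairwise = 10))
        expect_true(loose$called | !tight$called)
    }
})

test_that("swapping condition labels flips direction and negates dpsi", {
    set.seed(43)
    d <- design22()
    dRev <- sampleDesign(d$sample_id, rev(d$condition))
    for (rep in 1:25) {
        psi <- matrix(runif(4, 0, 100), 1,
                      dimnames = list("EV1", d$sample_id))
        a <- callSpeciesEvents(peFromPsi(psi), d, speciesParams())
        b <- callSpeciesEvents(peFromPsi(psi), dRev, speciesParams())
        expect_equal(a$dpsi_avg, -b$dpsi_avg, tolerance = 1e-9)
        expect_identical(a$called, b$called)
        if (abs(a$dpsi_avg) > 1e-9)
            expect_false(a$direction == b$direction)
    }
})
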