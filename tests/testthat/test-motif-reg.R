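test_that("motif scanning reports overlapping hits and is T/U blind", {
    m <- motifSet("GTGTGT")
    expect_identical(scanMotifs("GTGTGTGT", m), c(1L, 3L))
    expect_identical(scanMotifs("GUGUGUGU", m), c(1L, 3L))
    expect_identical(scanMotifs("GTGTGTGT", motifSet("gugugu")), c(1L, 3L))
    expect_identical(scanMotifs("AAAAAAAA", m), integer(0))
    expect_identical(scanMotifs("GTGTG", m), integer(0))  # shorter than 6
    expect_error(motifSet("GTGTG"), "hexamers")
    expect_error(motifSet(character(0)), "empty")
})

test_that("coverage profile matches hand-computed window fractions", {
    m <- motifSet("GGTGGT")
    # single hit exactly mid-segment, full 51-nt window: 6/51
    L <- 151L
    s <- paste0(strrep("A", 73), "GGTGGT", strrep("A", 72))
    prof <- coverageProfile(list(list(seg = s)), m)
    expect_equal(prof$value[prof$position == 76], 6 / 51)
    # all-zero profile without hits
    z <- coverageProfile(list(list(seg = strrep("A", 100))), m)
    expect_true(all(z$value == 0))
    # motifs tiling the whole segment saturate interior positions to 1
    sat <- coverageProfile(list(list(seg = strrep("GGTGGT", 30))), m)
    expect_true(all(sat$value == 1))
    # truncated windows use the actual span as denominator
    s2 <- paste0("GGTGGT", strrep("A", 94))
    p2 <- coverageProfile(list(list(seg = s2)), m)
    expect_equal(p2$value[p2$position == 1], 6 / 26)  # window [1,26]
})

test_that("coverage profile equals a brute-force windowed count", {
    set.seed(21)
    m <- defaultMotifSet()
    for (i in 1:5) {
        s <- randDNA(160)
        prof <- coverageProfile(list(list(x = s)), m)
        hits <- scanMotifs(s, m)
        covered <- rep(FALSE, nchar(s))
        for (h in hits) covered[h:min(nchar(s), h + 5)] <- TRUE
        for (p in c(1, 26, 80, 135, 160)) {
            win <- max(1, p - 25):min(nchar(s), p + 25)
            expect_equal(prof$value[prof$position == p],
                         mean(covered[win]), tolerance = 1e-12)
        }
    }
})

test_that("region extraction follows the 75/250 schema with drops", {
    set.seed(22)
    te <- toyEvent(upExon = randDNA(80), upIntron = randDNA(400),
                   altExon = randDNA(90), dnIntron = randDNA(400),
                   dnExon = randDNA(80))
    segs <- extractEventRegions(te$ev, te$genome)
    expect_setequal(names(segs),
                    c("up_exon", "up_int_5p", "up_int_3p", "alt_5p",
                      "alt_3p", "dn_int_5p", "dn_int_3p", "dn_exon"))
    expect_equal(nchar(segs$up_int_5p), 250)
    expect_equal(nchar(segs$alt_5p), 75)
    # intron of 400: segments [1,250] and [151,400] overlap by 100 nt
    expect_identical(substr(segs$up_int_5p, 151, 250),
                     substr(segs$up_int_3p, 1, 100))
    # alternative exon of 60 nt: both exon-end segments neglected
    te2 <- toyEvent(randDNA(80), randDNA(400), randDNA(60), randDNA(400),
                    randDNA(80))
    segs2 <- extractEventRegions(te2$ev, te2$genome)
    expect_false(any(c("alt_5p", "alt_3p") %in% names(segs2)))
    # 200-nt introns: intron segments neglected
    te3 <- toyEvent(randDNA(80), randDNA(200), randDNA(90), randDNA(200),
                    randDNA(80))
    expect_false(any(grepl("int", names(extractEventRegions(te3$ev,
                                                            te3$genome)))))
})

test_that("minus-strand regions come back in transcript orientation", {
    set.seed(23)
    parts <- list(up = randDNA(80), ui = randDNA(400), alt = randDNA(90),
                  di = randDNA(400), dn = randDNA(80))
    plus <- toyEvent(parts$up, parts$ui, parts$alt, parts$di, parts$dn,
                     strand = "+")
    minus <- toyEvent(parts$up, parts$ui, parts$alt, parts$di, parts$dn,
                      strand = "-")
    sp <- extractEventRegions(plus$ev, plus$genome)
    sm <- extractEventRegions(minus$ev, minus$genome)
    expect_identical(sp, sm)
})

test_that("scenario classifier follows the positional code", {
    m <- motifSet("GGTGGT")
    base <- function(...) {
        cnt <- c(alt_exon = 0, up_exon_last25 = 0, dn_exon_first25 = 0,
                 up_int_all = 0, up_int_first250 = 0, up_int_last250 = 0,
                 up_int_excl_last50 = 0, dn_int_all = 0,
                 dn_int_first250 = 0, dn_int_first6 = 0, dn_int_rest = 0,
                 dn_int_last250 = 0)
        over <- c(...)
        cnt[names(over)] <- over
        cnt
    }
    # silenced exon with one motif inside the alternative exon: direct
    expect_identical(classifyDirectIndirect(
        "silenced", base(alt_exon = 1), "restricted", 1), "direct")
    # enhanced exon with motifs only in the 5'ss-overlapping first 6 nt:
    # excluded from direct, downstream intron not clean -> discarded
    expect_identical(classifyDirectIndirect(
        "enhanced", base(dn_int_all = 1, dn_int_first250 = 1,
                         dn_int_first6 = 1), "restricted", 1), "discarded")
    # silenced exon with zero motifs anywhere: indirect
    expect_identical(classifyDirectIndirect(
        "silenced", base(), "restricted", 1), "indirect")
    # enhanced + motif beyond the 5'ss: direct in both scenarios
    enh <- base(dn_int_all = 1, dn_int_first250 = 1, dn_int_rest = 1)
    expect_identical(classifyDirectIndirect("enhanced", enh, "restricted",
                                            1), "direct")
    expect_identical(classifyDirectIndirect("enhanced", enh, "expanded",
                                            1), "direct")
    # expanded widens silenced to the full upstream intron
    sil <- base(up_int_all = 1, up_int_first250 = 1)
    expect_identical(classifyDirectIndirect("silenced", sil, "restricted",
                                            1), "discarded")
    expect_identical(classifyDirectIndirect("silenced", sil, "expanded",
                                            1), "direct")
    # enhanced expanded: upstream-exon edge motifs count
    upx <- base(up_exon_last25 = 1)
    expect_identical(classifyDirectIndirect("enhanced", upx, "restricted",
                                            1), "indirect")
    expect_identical(classifyDirectIndirect("enhanced", upx, "expanded",
                                            1), "direct")
})

test_that("classifier is monotone in min_motifs and scenario nesting", {
    set.seed(24)
    lv <- c(direct = 3, discarded = 2, indirect = 1)
    regions <- c("alt_exon", "up_exon_last25", "dn_exon_first25",
                 "up_int_first250", "up_int_last250", "dn_int_first6",
                 "dn_int_rest", "dn_int_last250")
    for (i in 1:60) {
        raw <- rpois(length(regions), 0.6)
        names(raw) <- regions
        cnt <- c(raw,
                 up_int_all = unname(raw["up_int_first250"] +
                                         raw["up_int_last250"]),
                 up_int_excl_last50 = unname(raw["up_int_first250"] +
                                                 raw["up_int_last250"]),
                 dn_int_all = unname(raw["dn_int_first6"] +
                                         raw["dn_int_rest"] +
                                         raw["dn_int_last250"]),
                 dn_int_first250 = unname(raw["dn_int_first6"] +
                                              raw["dn_int_rest"]))
        dir <- sample(c("enhanced", "silenced"), 1)
        for (sc in c("restricted", "expanded")) {
            prev <- classifyDirectIndirect(dir, cnt, sc, 1)
            for (k in 2:4) {
                cur <- classifyDirectIndirect(dir, cnt, sc, k)
                # raising the threshold never promotes toward direct
                expect_lte(lv[cur], lv[prev])
                prev <- cur
            }
        }
        # restricted-direct implies expanded-direct at the same threshold
        for (k in 1:4)
            if (classifyDirectIndirect(dir, cnt, "restricted", k) ==
                "direct")
                expect_identical(
                    classifyDirectIndirect(dir, cnt, "expanded", k),
                    "direct")
    }
})

test_that("coverage is invariant under duplicated motif entries", {
    set.seed(25)
    s <- randDNA(300)
    m1 <- motifSet(c("GGTGGT", "TGGTGG"))
    m2 <- motifSet(c("GGTGGT", "TGGTGG", "GGTGGT"))
    expect_identical(scanMotifs(s, m1), scanMotifs(s, m2))
    p1 <- coverageProfile(list(list(x = s)), m1)
    p2 <- coverageProfile(list(list(x = s)), m2)
    expect_equal(p1, p2)
    expect_true(all(p1$value <= 1))
})

test_that("one-sided Fisher enrichment matches closed forms", {
    expect_equal(sharedRegulationEnrichment(10, 0, 0, 10),
                 1 / choose(20, 10), tolerance = 1e-12)
    expect_gt(sharedRegulationEnrichment(5, 5, 5, 5), 0.5)
    expect_equal(sharedRegulationEnrichment(0, 0, 0, 0), 1)
})

test_that("conservation profile smooths and averages correctly", {
    # constant track: profile constant, any smoothing
    track <- list(chr1 = rep(0.4, 1000))
    ex <- data.frame(chrom = "chr1", start0 = 400L, end0 = 500L,
                     strand = "+")
    pr <- conservationProfile(ex, track)
    expect_equal(nrow(pr), 100 + 300)  # exon length + 2 flanks
    expect_true(all(abs(pr$value - 0.4) < 1e-12))
    # step track: trailing 10-mean reproduced by a brute-force oracle
    v <- c(rep(0, 700), rep(1, 300))
    track2 <- list(chr1 = v)
    pr2 <- conservationProfile(ex, track2, flank = 150, smooth = 10)
    w <- v[(400 - 150 + 1):(500 + 150)]
    oracle <- vapply(seq_along(w), function(p)
        mean(w[p:min(length(w), p + 9)]), numeric(1))
    expect_equal(pr2$value, oracle, tolerance = 1e-12)
    # minus strand reverses orientation
    exm <- data.frame(chrom = "chr1", start0 = 400L, end0 = 500L,
                      strand = "-")
    prm <- conservationProfile(exm, track2)
    wrev <- rev(w)
    oracleM <- vapply(seq_along(wrev), function(p)
        mean(wrev[p:min(length(wrev), p + 9)]), numeric(1))
    expect_equal(prm$value, oracleM, tolerance = 1e-12)
    # out-of-bounds exons are skipped with a message
    ex2 <- rbind(ex, data.frame(chrom = "chr1", start0 = 20L, end0 = 80L,
                                strand = "+"))
    expect_message(pr3 <- conservationProfile(ex2, track), "skipped")
    expect_equal(max(pr3$n_exons), 1)
})

test_that("score tracks round-trip through bedGraph", {
    track <- list(chrA = c(NA, NA, 0.2, 0.2, 0.5, NA, 0.7, 0.7, 0.7, NA))
    f <- tempfile(fileext = ".bedGraph")
    writeScoreTrack(track, f)
    back <- readScoreTrack(f, c(chrA = 10L))
    expect_equal(back$chrA, track$chrA)
})
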