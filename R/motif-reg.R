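#' Hexamer motif sets
#'
#' Validates a set of length-6 motifs over the DNA/RNA alphabet; U is
#' normalised to T so scans are T/U-equivalent. The shipped default set
#' (`defaultMotifSet()`) is a synthetic GU-rich stand-in for an
#' experimentally derived splicing-factor motif list, stored at
#' `inst/extdata/esrp_like_hexamers_synthetic.txt`.
#'
#' @param motifs character vector of hexamers, or a path passed to
#'   [readMotifSet()] (one motif per line).
#' @return character vector of class `motif_set` (uppercase, DNA alphabet).
#' @export
motifSet <- function(motifs) {
    m <- toupper(motifs)
    m <- chartr("U", "T", m)
    if (length(m) == 0) stop("motif set is empty")
    if (any(nchar(m) != 6)) stop("all motifs must be hexamers")
    if (any(!grepl("^[ACGT]+$", m))) stop("motifs must be over ACGT/U")
    structure(m, class = "motif_set")
}

#' @rdname motifSet
#' @param path file with one hexamer per line.
#' @export
readMotifSet <- function(path) motifSet(readLines(path, warn = FALSE))

#' @rdname motifSet
#' @export
defaultMotifSet <- function() {
    readMotifSet(system.file("extdata", "esrp_like_hexamers_synthetic.txt",
                             package = "spliceEvo", mustWork = TRUE))
}

#' Scan a sequence for exact hexamer matches
#'
#' Reports every start position (1-based) whose 6-mer window equals one of
#' the motifs; overlapping occurrences are all reported. T and U are
#' equivalent on both sides of the comparison.
#'
#' @param seq a character string or [Biostrings::DNAString].
#' @param motifs a [motifSet()].
#' @return sorted integer vector of match start positions (empty for
#'   sequences shorter than 6 nt).
#' @examples
#' scanMotifs("GTGTGTGT", motifSet("GTGTGT"))  # 1, 3
#' @export
scanMotifs <- function(seq, motifs) {
    s <- chartr("U", "T", toupper(as.character(seq)))
    L <- nchar(s)
    if (L < 6L) return(integer(0))
    starts <- seq_len(L - 5L)
    starts[substring(s, starts, starts + 5L) %in% unclass(motifs)]
}

#' Region schema around an alternative exon
#'
#' Segment lengths of the standardized exon-centric region set used for RNA
#' regulatory maps: 75 nt from both alternative-exon ends, 250 nt from both
#' ends of both flanking introns, 75 nt of the upstream and downstream
#' flanking exons. Segments longer than the underlying feature are dropped,
#' never padded.
#'
#' @param exon_flank,intron_flank,neighbor_exon segment lengths in nt.
#' @param junction_proximal_flanks if `TRUE`, take the flanking-exon segments
#'   from the junction-proximal ends (3' end of the upstream exon, 5' end of
#'   the downstream exon) instead of the distal ends used by default.
#' @return list of class `region_schema`.
#' @export
regionSchema <- function(exon_flank = 75L, intron_flank = 250L,
                         neighbor_exon = 75L,
                         junction_proximal_flanks = FALSE) {
    structure(list(exon_flank = as.integer(exon_flank),
                   intron_flank = as.integer(intron_flank),
                   neighbor_exon = as.integer(neighbor_exon),
                   junction_proximal_flanks = junction_proximal_flanks),
              class = "region_schema")
}

# Strand-aware sequence of a genomic 0-based half-open interval, returned in
# transcript orientation.
.fetchSeq <- function(genome, chrom, start0, end0, strand) {
    if (end0 <= start0) return("")
    s <- Biostrings::subseq(genome[[chrom]], start0 + 1L, end0)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
}

# Intron intervals (transcript orientation) flanking the alternative exon.
# ev is one row of an AS-event table.
.eventGeometry <- function(ev) {
    if (ev$strand == "+") {
        list(upIntron = c(ev$up_end, ev$alt_start),
             dnIntron = c(ev$alt_end, ev$dn_start))
    } else {
        list(upIntron = c(ev$alt_end, ev$up_start),
             dnIntron = c(ev$dn_end, ev$alt_start))
    }
}

# First / last n nt of a transcript-oriented feature given its genomic
# interval [s0, e0) and strand; returns genomic 0-based intervals.
.firstN <- function(s0, e0, strand, n) {
    len <- e0 - s0
    n <- min(n, len)
    if (strand == "+") c(s0, s0 + n) else c(e0 - n, e0)
}
.lastN <- function(s0, e0, strand, n) {
    len <- e0 - s0
    n <- min(n, len)
    if (strand == "+") c(e0 - n, e0) else c(s0, s0 + n)
}

#' Extract the region-schema sequences of an AS event
#'
#' Returns the named segments of the exon-centric schema, each in transcript
#' orientation. Features shorter than the schema segment are omitted
#' (`neglected`), except that intron segments may overlap each other when
#' the intron is between one and two segment lengths long.
#'
#' @param ev one row of an AS-event table: columns `event_id`, `chrom`,
#'   `strand`, `alt_start`, `alt_end`, `up_start`, `up_end`, `dn_start`,
#'   `dn_end` (genomic, 0-based half-open; `up`/`dn` in transcript
#'   orientation).
#' @param genome [Biostrings::DNAStringSet] keyed by chromosome.
#' @param schema a [regionSchema()].
#' @return named list of segment sequences, in schema order: `up_exon`,
#'   `up_int_5p`, `up_int_3p`, `alt_5p`, `alt_3p`, `dn_int_5p`, `dn_int_3p`,
#'   `dn_exon`. Omitted segments are absent from the list.
#' @export
extractEventRegions <- function(ev, genome, schema = regionSchema()) {
    if (!ev$chrom %in% names(genome))
        stop("chromosome not in genome: ", ev$chrom)
    st <- ev$strand
    geo <- .eventGeometry(ev)
    segs <- list()
    addSeg <- function(name, iv, minLen) {
        if (iv[2] - iv[1] >= minLen)
            segs[[name]] <<- .fetchSeq(genome, ev$chrom, iv[1], iv[2], st)
    }
    exLen <- ev$alt_end - ev$alt_start
    upLen <- geo$upIntron[2] - geo$upIntron[1]
    dnLen <- geo$dnIntron[2] - geo$dnIntron[1]
    fl <- schema$exon_flank; il <- schema$intron_flank
    ne <- schema$neighbor_exon
    # upstream-exon segment: 5' (distal) end by default, 3' end if
    # junction_proximal_flanks
    upIv <- if (schema$junction_proximal_flanks)
        .lastN(ev$up_start, ev$up_end, st, ne)
    else .firstN(ev$up_start, ev$up_end, st, ne)
    if (ev$up_end - ev$up_start >= ne) segs[["up_exon"]] <-
        .fetchSeq(genome, ev$chrom, upIv[1], upIv[2], st)
    if (upLen >= il) {
        segs[["up_int_5p"]] <- .fetchSeq(
            genome, ev$chrom, .firstN(geo$upIntron[1], geo$upIntron[2], st,
                                      il)[1],
            .firstN(geo$upIntron[1], geo$upIntron[2], st, il)[2], st)
        segs[["up_int_3p"]] <- .fetchSeq(
            genome, ev$chrom, .lastN(geo$upIntron[1], geo$upIntron[2], st,
                                     il)[1],
            .lastN(geo$upIntron[1], geo$upIntron[2], st, il)[2], st)
    }
    if (exLen >= fl) {
        a5 <- .firstN(ev$alt_start, ev$alt_end, st, fl)
        a3 <- .lastN(ev$alt_start, ev$alt_end, st, fl)
        segs[["alt_5p"]] <- .fetchSeq(genome, ev$chrom, a5[1], a5[2], st)
        segs[["alt_3p"]] <- .fetchSeq(genome, ev$chrom, a3[1], a3[2], st)
    }
    if (dnLen >= il) {
        segs[["dn_int_5p"]] <- .fetchSeq(
            genome, ev$chrom, .firstN(geo$dnIntron[1], geo$dnIntron[2], st,
                                      il)[1],
            .firstN(geo$dnIntron[1], geo$dnIntron[2], st, il)[2], st)
        segs[["dn_int_3p"]] <- .fetchSeq(
            genome, ev$chrom, .lastN(geo$dnIntron[1], geo$dnIntron[2], st,
                                     il)[1],
            .lastN(geo$dnIntron[1], geo$dnIntron[2], st, il)[2], st)
    }
    dnIv <- if (schema$junction_proximal_flanks)
        .firstN(ev$dn_start, ev$dn_end, st, ne)
    else .lastN(ev$dn_start, ev$dn_end, st, ne)
    if (ev$dn_end - ev$dn_start >= ne) segs[["dn_exon"]] <-
        .fetchSeq(genome, ev$chrom, dnIv[1], dnIv[2], st)
    segs
}

#' Motif hit counts over the scenario scan universe
#'
#' Scans the alternative exon, the first and last 250 nt of both flanking
#' introns, the last 25 nt of the upstream exon and the first 25 nt of the
#' downstream exon, and tabulates hit counts (overlapping hits included) by
#' the sub-regions the positional scenarios use. Hits are assigned to
#' sub-regions by their start position in intron coordinates; within-intron
#' duplicate positions arising from overlapping first/last segments are
#' counted once.
#'
#' @param ev one AS-event row (see [extractEventRegions()]).
#' @param genome [Biostrings::DNAStringSet].
#' @param motifs a [motifSet()].
#' @param intron_flank,exon_edge scan lengths (250 and 25 nt).
#' @return named integer vector of counts: `alt_exon`, `up_exon_last25`,
#'   `dn_exon_first25`, `up_int_all`, `up_int_first250`, `up_int_last250`,
#'   `up_int_excl_last50`, `dn_int_all`, `dn_int_first250`, `dn_int_first6`,
#'   `dn_int_rest`, `dn_int_last250`.
#' @export
countMotifRegions <- function(ev, genome, motifs, intron_flank = 250L,
                              exon_edge = 25L) {
    st <- ev$strand
    geo <- .eventGeometry(ev)
    scanIntron <- function(iv) {
        len <- iv[2] - iv[1]
        if (len < 6) return(list(pos = integer(0), len = len))
        pos <- integer(0)
        f <- .firstN(iv[1], iv[2], st, min(intron_flank, len))
        hits <- scanMotifs(.fetchSeq(genome, ev$chrom, f[1], f[2], st),
                           motifs)
        pos <- c(pos, hits)  # intron coordinates: first segment starts at 1
        if (len > intron_flank) {
            l <- .lastN(iv[1], iv[2], st, min(intron_flank, len))
            hits <- scanMotifs(.fetchSeq(genome, ev$chrom, l[1], l[2], st),
                               motifs)
            pos <- c(pos, hits + (len - min(intron_flank, len)))
        }
        list(pos = sort(unique(pos)), len = len)
    }
    up <- scanIntron(geo$upIntron)
    dn <- scanIntron(geo$dnIntron)
    altHits <- scanMotifs(.fetchSeq(genome, ev$chrom, ev$alt_start,
                                    ev$alt_end, st), motifs)
    upEx <- .lastN(ev$up_start, ev$up_end, st,
                   min(exon_edge, ev$up_end - ev$up_start))
    dnEx <- .firstN(ev$dn_start, ev$dn_end, st,
                    min(exon_edge, ev$dn_end - ev$dn_start))
    upExHits <- scanMotifs(.fetchSeq(genome, ev$chrom, upEx[1], upEx[2], st),
                           motifs)
    dnExHits <- scanMotifs(.fetchSeq(genome, ev$chrom, dnEx[1], dnEx[2], st),
                           motifs)
    inFirst <- function(x, lenReg, n) sum(x$pos <= min(n, lenReg))
    c(alt_exon = length(altHits),
      up_exon_last25 = length(upExHits),
      dn_exon_first25 = length(dnExHits),
      up_int_all = length(up$pos),
      up_int_first250 = inFirst(up, up$len, intron_flank),
      up_int_last250 = sum(up$pos > up$len - intron_flank),
      up_int_excl_last50 = sum(up$pos <= up$len - 50L),
      dn_int_all = length(dn$pos),
      dn_int_first250 = inFirst(dn, dn$len, intron_flank),
      dn_int_first6 = sum(dn$pos <= 6L),
      dn_int_rest = inFirst(dn, dn$len, intron_flank) - sum(dn$pos <= 6L),
      dn_int_last250 = sum(dn$pos > dn$len - intron_flank))
}

#' Classify a regulated exon as direct or indirect target
#'
#' Positional-code classification under two scenarios. Restricted:
#' factor-silenced exons may carry motifs in the alternative exon, the first
#' 6 nt of the downstream intron (the 5' splice-site overlap) and/or the last
#' 250 nt of the upstream intron; factor-enhanced exons in the first 250 nt
#' of the downstream intron excluding the 5' splice site. Expanded adds, for
#' silenced exons, the first 250 nt of the upstream intron, and for enhanced
#' exons the last 25 nt of the upstream exon together with the upstream
#' intron (excluding the last 50 nt before the 3' splice site) or the last
#' 250 nt of the downstream intron. `direct` requires at least `minMotifs`
#' hits summed over the allowed regions; `indirect` requires, in addition to
#' not being direct, zero motifs in the upstream intron and alternative exon
#' (silenced) or in the downstream intron and the last 250 nt of the upstream
#' intron (enhanced); everything else is `discarded`.
#'
#' @param direction `"enhanced"` or `"silenced"`.
#' @param counts named counts from [countMotifRegions()].
#' @param scenario `"restricted"` or `"expanded"`.
#' @param minMotifs minimum motif count for a direct call (1-4).
#' @return `"direct"`, `"indirect"`, or `"discarded"`.
#' @export
classifyDirectIndirect <- function(direction, counts,
                                   scenario = c("restricted", "expanded"),
                                   minMotifs = 1L) {
    scenario <- match.arg(scenario)
    stopifnot(direction %in% c("enhanced", "silenced"))
    k <- function(n) unname(counts[[n]])
    if (direction == "silenced") {
        allowed <- if (scenario == "restricted")
            k("alt_exon") + k("dn_int_first6") + k("up_int_last250")
        else k("alt_exon") + k("dn_int_first6") + k("up_int_all")
        cleanRegions <- k("up_int_all") + k("alt_exon")
    } else {
        allowed <- if (scenario == "restricted") k("dn_int_rest")
        else k("dn_int_rest") + k("dn_int_last250") +
            k("up_exon_last25") + k("up_int_excl_last50")
        cleanRegions <- k("dn_int_all") + k("up_int_last250")
    }
    if (allowed >= minMotifs) "direct"
    else if (cleanRegions == 0) "indirect"
    else "discarded"
}

#' Sliding-window motif coverage profile (RNA regulatory map)
#'
#' For each event and schema segment, a 51-nt window is slid along the
#' segment; the value at a position is the fraction of window positions
#' covered by at least one motif hit, the window being truncated at segment
#' ends (the actual span is the denominator). Profiles are averaged across
#' events; positions no event contributes to are absent.
#'
#' @param segments list (one element per event) of named lists of segment
#'   sequences, as produced by [extractEventRegions()].
#' @param motifs a [motifSet()].
#' @param window window width in nt (51).
#' @return data.frame `segment`, `position`, `value`, `n_events`.
#' @export
coverageProfile <- function(segments, motifs, window = 51L) {
    half <- (window - 1L) %/% 2L
    acc <- list()
    for (segs in segments) {
        for (nm in names(segs)) {
            s <- segs[[nm]]
            L <- nchar(s)
            if (L == 0) next
            covered <- rep(FALSE, L)
            for (h in scanMotifs(s, motifs))
                covered[h:min(L, h + 5L)] <- TRUE
            cum <- c(0L, cumsum(covered))
            lo <- pmax(1L, seq_len(L) - half)
            hi <- pmin(L, seq_len(L) + half)
            frac <- (cum[hi + 1L] - cum[lo]) / (hi - lo + 1L)
            key <- nm
            if (is.null(acc[[key]]))
                acc[[key]] <- list(sum = numeric(0), n = integer(0))
            if (length(acc[[key]]$sum) < L) {
                acc[[key]]$sum <- c(acc[[key]]$sum,
                                    numeric(L - length(acc[[key]]$sum)))
                acc[[key]]$n <- c(acc[[key]]$n,
                                  integer(L - length(acc[[key]]$n)))
            }
            acc[[key]]$sum[1:L] <- acc[[key]]$sum[1:L] + frac
            acc[[key]]$n[1:L] <- acc[[key]]$n[1:L] + 1L
        }
    }
    out <- do.call(rbind, lapply(names(acc), function(nm) {
        n <- acc[[nm]]$n
        keep <- n > 0
        data.frame(segment = nm, position = which(keep),
                   value = acc[[nm]]$sum[keep] / n[keep],
                   n_events = n[keep])
    }))
    if (is.null(out))
        out <- data.frame(segment = character(), position = integer(),
                          value = numeric(), n_events = integer())
    out
}

#' One-sided enrichment test for shared regulation among direct targets
#'
#' One-sided Fisher exact test (hypergeometric tail) that direct targets are
#' at least as enriched for shared cross-species regulation as observed,
#' against indirect targets.
#'
#' @param directShared,directNot,indirectShared,indirectNot 2x2 cell counts.
#' @return one-sided p-value (1 for the all-zero table).
#' @examples
#' sharedRegulationEnrichment(10, 0, 0, 10)  # 1 / choose(20, 10)
#' @export
sharedRegulationEnrichment <- function(directShared, directNot,
                                       indirectShared, indirectNot) {
    tab <- matrix(c(directShared, directNot, indirectShared, indirectNot),
                  2, 2, byrow = TRUE)
    stopifnot(all(tab >= 0))
    if (sum(tab) == 0) return(1)
    stats::fisher.test(tab, alternative = "greater")$p.value
}
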