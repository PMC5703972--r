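#' Per-base score tracks
#'
#' A score track is a named list of per-base numeric vectors (one per
#' chromosome, position i = base i), with `NA` as the explicit sentinel for
#' positions the track does not cover. [readScoreTrack()] expands a bedGraph
#' file into this representation.
#'
#' @param path bedGraph file.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return named list of numeric vectors.
#' @export
readScoreTrack <- function(path, seqlengths) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    track <- lapply(seqlengths, function(n) rep(NA_real_, n))
    for (i in seq_along(gr)) {
        ch <- as.character(GenomicRanges::seqnames(gr))[i]
        if (!ch %in% names(track)) next
        s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
        track[[ch]][s:e] <- gr$score[i]
    }
    track
}

#' @rdname readScoreTrack
#' @param track named list of numeric vectors.
#' @export
writeScoreTrack <- function(track, path) {
    rows <- list()
    for (ch in names(track)) {
        v <- track[[ch]]
        ok <- !is.na(v)
        if (!any(ok)) next
        # one bedGraph line per maximal run of equal, contiguous values
        pos <- which(ok)
        runStart <- pos[c(TRUE, diff(pos) > 1 | v[pos[-1]] != v[pos[-length(pos)]])]
        runEnd <- pos[c(diff(pos) > 1 | v[pos[-1]] != v[pos[-length(pos)]], TRUE)]
        rows[[ch]] <- data.frame(chrom = ch, start0 = runStart - 1L,
                                 end = runEnd, score = v[runStart])
    }
    df <- do.call(rbind, rows)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Smoothed conservation profile over exons and flanks
#'
#' Extracts, for each exon, the track values over the exon plus `flank` nt on
#' both sides (reversed into transcript orientation on the minus strand),
#' smooths each exon's vector with a trailing `smooth`-position running mean
#' (the window starting at each position, truncated at the end; a centered
#' window is available), and averages across exons by position index.
#' Positions no exon contributes to are absent; exons extending beyond the
#' track bounds are skipped with a message.
#'
#' @param exons data.frame with `chrom`, `start0`, `end0`, `strand`
#'   (0-based half-open exon bodies).
#' @param track a score track (see [readScoreTrack()]).
#' @param flank flanking length in nt (150).
#' @param smooth smoothing window in positions (10).
#' @param anchor `"trailing"` (default) or `"centered"` smoothing window.
#' @return data.frame `position`, `value`, `n_exons`; position 1 is the
#'   start of the upstream flank.
#' @export
conservationProfile <- function(exons, track, flank = 150L, smooth = 10L,
                                anchor = c("trailing", "centered")) {
    anchor <- match.arg(anchor)
    sums <- numeric(0); ns <- integer(0); skipped <- 0L
    for (i in seq_len(nrow(exons))) {
        ex <- exons[i, ]
        if (!ex$chrom %in% names(track)) { skipped <- skipped + 1L; next }
        v <- track[[ex$chrom]]
        s <- ex$start0 - flank + 1L; e <- ex$end0 + flank
        if (s < 1 || e > length(v)) { skipped <- skipped + 1L; next }
        w <- v[s:e]
        if (identical(ex$strand, "-")) w <- rev(w)
        L <- length(w)
        sm <- numeric(L)
        for (p in seq_len(L)) {
            win <- if (anchor == "trailing") p:min(L, p + smooth - 1L)
            else max(1L, p - smooth %/% 2L):min(L, p + (smooth - 1L) %/% 2L)
            sm[p] <- mean(w[win], na.rm = TRUE)
        }
        if (length(sums) < L) {
            sums <- c(sums, numeric(L - length(sums)))
            ns <- c(ns, integer(L - length(ns)))
        }
        contrib <- !is.nan(sm)
        sums[seq_len(L)][contrib] <- sums[seq_len(L)][contrib] + sm[contrib]
        ns[seq_len(L)][contrib] <- ns[seq_len(L)][contrib] + 1L
    }
    if (skipped > 0)
        message(skipped, " exon(s) beyond track bounds skipped")
    keep <- ns > 0
    data.frame(position = which(keep), value = sums[keep] / ns[keep],
               n_exons = ns[keep])
}
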