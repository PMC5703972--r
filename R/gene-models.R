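#' @importFrom GenomicRanges GRanges start end strand seqnames mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Construct a GeneModel
#'
#' @param geneId,species,chrom,strand identifiers; `strand` is `"+"`/`"-"`.
#' @param transcripts named list of `list(exons = <n x 2 matrix of 0-based
#'   half-open genomic intervals, ordered 5'->3' in transcript orientation>,
#'   cds = <c(start0, end0) or NULL>)`.
#' @param mappableLength uniquely mappable exonic length (nt); defaults to
#'   the exon-union length.
#' @return a validated [GeneModel-class].
#' @export
GeneModel <- function(geneId, species, chrom, strand, transcripts,
                      mappableLength = NA_integer_) {
    transcripts <- lapply(transcripts, function(tx) {
        ex <- as.matrix(tx$exons)
        storage.mode(ex) <- "integer"
        dimnames(ex) <- list(NULL, c("start", "end"))
        list(exons = ex,
             cds = if (is.null(tx$cds)) NULL else as.integer(tx$cds))
    })
    if (is.na(mappableLength)) {
        exall <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
        mappableLength <- sum(IRanges::width(IRanges::reduce(
            IRanges(exall[, 1] + 1L, exall[, 2]))))
    }
    methods::new("GeneModel", geneId = geneId, species = species,
                 chrom = chrom, strand = strand, transcripts = transcripts,
                 mappableLength = as.integer(mappableLength))
}

#' @rdname GeneModel
#' @param x a GeneModel.
#' @export
geneId <- function(x) x@geneId

#' @rdname GeneModel
#' @export
transcriptIds <- function(x) names(x@transcripts)

#' Read gene models from GTF/GFF3
#'
#' Parses `exon` and `CDS` features with rtracklayer, converts 1-based
#' inclusive coordinates to the internal 0-based half-open convention, and
#' orders exons 5'->3' in transcript orientation (reversed genomic order on
#' the minus strand). A transcript with zero exons, or with a CDS not
#' contained in its exons, is an error naming the transcript.
#'
#' @param path GTF or GFF3 file (format guessed from the extension).
#' @param species species label stored on each model.
#' @param geneAttr,txAttr attribute names holding gene/transcript ids.
#' @param mappableLengths optional named vector gene_id -> mappable length.
#' @return named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path, species = NA_character_,
                           geneAttr = "gene_id", txAttr = "transcript_id",
                           mappableLengths = NULL) {
    gr <- rtracklayer::import(path)
    md <- as.data.frame(mcols(gr))
    if (!geneAttr %in% colnames(md))
        stop("attribute '", geneAttr, "' not found in ", path)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start0 = start(gr) - 1L, end0 = end(gr),
                     strand = as.character(strand(gr)),
                     type = as.character(md$type),
                     gene = as.character(md[[geneAttr]]),
                     tx = as.character(md[[txAttr]]),
                     stringsAsFactors = FALSE)
    df <- df[df$type %in% c("exon", "CDS"), ]
    models <- list()
    for (g in unique(df$gene)) {
        sub <- df[df$gene == g, ]
        strand <- sub$strand[1]
        txs <- list()
        for (t in unique(sub$tx)) {
            stx <- sub[sub$tx == t, ]
            ex <- stx[stx$type == "exon", c("start0", "end0")]
            if (nrow(ex) == 0)
                stop("transcript ", t, " has zero exons")
            ex <- as.matrix(ex[order(ex$start0, decreasing = strand == "-"),
                               , drop = FALSE])
            cds <- stx[stx$type == "CDS", c("start0", "end0")]
            cdsiv <- NULL
            if (nrow(cds) > 0) {
                cdsiv <- c(min(cds$start0), max(cds$end0))
                ok <- all(vapply(seq_len(nrow(cds)), function(i)
                    any(cds$start0[i] >= ex[, 1] & cds$end0[i] <= ex[, 2]),
                    logical(1)))
                if (!ok)
                    stop("CDS not contained in exons for transcript ", t)
            }
            txs[[t]] <- list(exons = ex, cds = cdsiv)
        }
        ml <- if (!is.null(mappableLengths) && g %in% names(mappableLengths))
            mappableLengths[[g]] else NA_integer_
        models[[g]] <- GeneModel(g, species, sub$chrom[1], strand, txs,
                                 mappableLength = as.integer(ml))
    }
    models
}

#' @rdname readGeneModels
#' @param models list of GeneModel objects.
#' @return `writeGeneModels()`: `path`, invisibly. Coordinates are converted
#'   back to 1-based inclusive GTF intervals (an involution with
#'   [readGeneModels()]).
#' @export
writeGeneModels <- function(models, path) {
    rows <- list()
    for (m in models) for (t in names(m@transcripts)) {
        tx <- m@transcripts[[t]]
        ex <- tx$exons
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = m@chrom, start0 = ex[, 1], end0 = ex[, 2],
            strand = m@strand, type = "exon", gene = m@geneId, tx = t)
        if (!is.null(tx$cds)) {
            pieces <- cdsPieces(m, t)
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = m@chrom, start0 = pieces$start0, end0 = pieces$end0,
                strand = m@strand, type = "CDS", gene = m@geneId, tx = t)
        }
    }
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start0 + 1L, df$end0),
                  strand = df$strand)
    mcols(gr)$type <- df$type
    mcols(gr)$gene_id <- df$gene
    mcols(gr)$transcript_id <- df$tx
    mcols(gr)$source <- "spliceEvo"
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

# Per-exon CDS pieces of a transcript, in transcript order.
cdsPieces <- function(model, transcriptId) {
    tx <- model@transcripts[[transcriptId]]
    if (is.null(tx)) stop("unknown transcript: ", transcriptId)
    if (is.null(tx$cds)) stop("transcript ", transcriptId, " has no CDS")
    ex <- tx$exons
    s0 <- pmax(ex[, 1], tx$cds[1])
    e0 <- pmin(ex[, 2], tx$cds[2])
    keep <- e0 > s0
    data.frame(exon = which(keep), start0 = s0[keep], end0 = e0[keep],
               len = (e0 - s0)[keep])
}

#' Project intron positions onto protein coordinates
#'
#' Walks the coding exons of a transcript in 5'->3' order and, at each
#' exon-exon junction inside the CDS, records the protein residue index
#' `floor(cumulative_coding_nt / 3)` (0-based) and the intron phase
#' `cumulative_coding_nt %% 3`. The CDS length must be a multiple of 3 (a
#' trailing stop codon may be included in the final exon's CDS).
#'
#' @param model a [GeneModel-class].
#' @param transcriptId transcript to use.
#' @param sequence amino-acid sequence; if `NULL` and `genome` is given the
#'   CDS is extracted and translated.
#' @param genome optional [Biostrings::DNAStringSet] keyed by chromosome.
#' @return a [ProteinIsoform-class].
#' @export
deriveProteinJunctionMap <- function(model, transcriptId, sequence = NULL,
                                     genome = NULL) {
    pieces <- cdsPieces(model, transcriptId)
    total <- sum(pieces$len)
    if (total %% 3L != 0L)
        stop("CDS length of ", transcriptId, " (", total,
             " nt) is not a multiple of 3")
    cum <- cumsum(pieces$len)
    jm <- if (nrow(pieces) > 1) {
        cuts <- cum[-nrow(pieces)]
        data.frame(residue = cuts %/% 3L, phase = cuts %% 3L)
    } else data.frame(residue = integer(), phase = integer())
    if (is.null(sequence)) {
        if (!is.null(genome)) {
            chromSeq <- genome[[model@chrom]]
            segs <- lapply(seq_len(nrow(pieces)), function(i)
                Biostrings::subseq(chromSeq, pieces$start0[i] + 1L,
                                   pieces$end0[i]))
            # assemble in ascending genomic order, then orient
            if (model@strand == "-") segs <- rev(segs)
            cdsSeq <- do.call(Biostrings::xscat, segs)
            if (model@strand == "-")
                cdsSeq <- Biostrings::reverseComplement(cdsSeq)
            sequence <- sub("\\*$", "", as.character(
                Biostrings::translate(cdsSeq)))
        } else {
            sequence <- strrep("X", total %/% 3L)
        }
    }
    methods::new("ProteinIsoform", geneId = model@geneId,
                 isoformId = transcriptId, sequence = sequence,
                 junctionMap = jm)
}

#' Residue spans of coding exons
#'
#' Returns, for each coding exon of an isoform, the 0-based half-open span of
#' residues whose codons start in that exon (a residue straddling a non-zero
#' phase junction is attributed to the downstream exon, matching the junction
#' map's floor convention).
#'
#' @param iso a [ProteinIsoform-class].
#' @return data.frame(exon, res_start, res_end) with 0-based half-open spans.
#' @export
exonResidueSpans <- function(iso) {
    n <- nchar(iso@sequence)
    bounds <- c(0L, iso@junctionMap$residue, n)
    data.frame(exon = seq_len(length(bounds) - 1L),
               res_start = bounds[-length(bounds)], res_end = bounds[-1])
}
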