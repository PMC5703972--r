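#' Reciprocal top-3 orthology evidence from ranked hit tables
#'
#' Two genes of different species are related when each is among the other's
#' first three hits. Ranks are dense ranks of the hit score (descending), so
#' hits tying the third-best score all count as within the first three.
#'
#' @param hits data.frame with columns `query_gene`, `query_species`,
#'   `hit_gene`, `hit_species`, `score`.
#' @param topN rank cutoff (3).
#' @return data.frame `gene_a`, `gene_b`, `source = "BlastP"` with unordered
#'   pair semantics (`gene_a < gene_b` lexicographically).
#' @export
blastReciprocalRule <- function(hits, topN = 3L) {
    key <- paste(hits$query_gene, hits$hit_species, sep = "\r")
    inTop <- unlist(lapply(split(seq_len(nrow(hits)), key), function(idx) {
        sc <- hits$score[idx]
        denseRank <- match(sc, sort(unique(sc), decreasing = TRUE))
        idx[denseRank <= topN]
    }), use.names = FALSE)
    top <- hits[sort(inTop), c("query_gene", "hit_gene")]
    fwd <- paste(top$query_gene, top$hit_gene, sep = "\r")
    rev <- paste(top$hit_gene, top$query_gene, sep = "\r")
    mutual <- top[fwd %in% rev, ]
    if (nrow(mutual) == 0)
        return(data.frame(gene_a = character(), gene_b = character(),
                          source = character()))
    a <- pmin(mutual$query_gene, mutual$hit_gene)
    b <- pmax(mutual$query_gene, mutual$hit_gene)
    unique(data.frame(gene_a = a, gene_b = b, source = "BlastP",
                      stringsAsFactors = FALSE))
}

#' Orthologous gene clusters from multi-source evidence
#'
#' Accepts gene pairs supported by at least `minSources` distinct evidence
#' sources and returns the connected components of the accepted-pair graph
#' (guilt-by-association).
#'
#' @param evidence data.frame `gene_a`, `gene_b`, `source`; one row per
#'   (pair, source), deduplicated internally.
#' @param minSources sources required to accept a pair (2 of 3).
#' @param universe optional gene ids to report as singletons when unlinked.
#' @return data.frame `gene_id`, `cluster_id`.
#' @export
buildGeneClusters <- function(evidence, minSources = 2L, universe = NULL) {
    if (nrow(evidence) > 0) {
        a <- pmin(evidence$gene_a, evidence$gene_b)
        b <- pmax(evidence$gene_a, evidence$gene_b)
        ev <- unique(data.frame(a = a, b = b, source = evidence$source))
        nsrc <- table(paste(ev$a, ev$b, sep = "\r"))
        keys <- names(nsrc)[nsrc >= minSources]
        pairs <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    } else pairs <- NULL
    verts <- unique(c(as.vector(pairs), universe))
    if (length(verts) == 0)
        return(data.frame(gene_id = character(), cluster_id = character()))
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(sort(verts))
    if (!is.null(pairs) && nrow(pairs) > 0)
        g <- g + igraph::edges(as.vector(t(pairs)))
    comp <- igraph::components(g)
    data.frame(gene_id = names(comp$membership),
               cluster_id = sprintf("GC%04d", comp$membership),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Alignment scoring configuration
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings).
#' @param gapOpening,gapExtension affine gap penalties.
#' @return list used by [alignWithStructure()].
#' @export
alignScoring <- function(matrix = "BLOSUM62", gapOpening = 10,
                         gapExtension = 0.5) {
    list(matrix = matrix, gapOpening = gapOpening,
         gapExtension = gapExtension)
}

.substMatrixCache <- new.env(parent = emptyenv())

.substMatrix <- function(name) {
    if (!is.null(.substMatrixCache[[name]]))
        return(.substMatrixCache[[name]])
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    .substMatrixCache[[name]] <- get(name, envir = env)
    .substMatrixCache[[name]]
}

# Replace residues absent from the substitution matrix by the wildcard X.
.sanitizeAA <- function(seq, mat) {
    ok <- rownames(mat)
    chars <- strsplit(seq, "")[[1]]
    bad <- !(chars %in% ok)
    if (any(bad)) {
        message("mapping ", sum(bad), " non-standard residue(s) to X")
        chars[bad] <- "X"
    }
    paste(chars, collapse = "")
}

#' Global pairwise alignment with intercalated intron markers
#'
#' Aligns two protein isoforms globally (affine gaps, BLOSUM62 by default)
#' and projects each isoform's intron junction map onto alignment columns:
#' a junction preceding residue `r` (0-based) is placed at the column where
#' that residue aligns; phases are carried unchanged.
#'
#' @param isoA,isoB [ProteinIsoform-class] objects.
#' @param scoring an [alignScoring()] configuration.
#' @return an [AlignedStructure-class].
#' @export
alignWithStructure <- function(isoA, isoB, scoring = alignScoring()) {
    stopifnot(nchar(isoA@sequence) > 0, nchar(isoB@sequence) > 0)
    mat <- .substMatrix(scoring$matrix)
    sa <- .sanitizeAA(isoA@sequence, mat)
    sb <- .sanitizeAA(isoB@sequence, mat)
    pa <- Biostrings::pairwiseAlignment(
        sa, sb, type = "global", substitutionMatrix = mat,
        gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
    alnA <- unname(as.character(Biostrings::alignedPattern(pa)))
    alnB <- unname(as.character(Biostrings::alignedSubject(pa)))
    project <- function(aln, jm) {
        resCol <- which(strsplit(aln, "")[[1]] != "-")
        n <- length(resCol)
        col <- vapply(jm$residue, function(r)
            if (r >= n) nchar(aln) + 1L else resCol[r + 1L], integer(1))
        data.frame(column = col, phase = jm$phase)
    }
    methods::new("AlignedStructure",
                 alignedA = alnA, alignedB = alnB,
                 markersA = project(alnA, isoA@junctionMap),
                 markersB = project(alnB, isoB@junctionMap),
                 isoA = isoA, isoB = isoB,
                 score = Biostrings::score(pa), scoring = scoring)
}

# Map each species' residues (0-based) to 1-based alignment columns.
.residueColumns <- function(aln) which(strsplit(aln, "")[[1]] != "-")

# Percent of columns, among those where both sequences are aligned within
# colsA (and colsB when given), that are identical or positively scoring.
.columnSimilarity <- function(struct, colsA, colsB = NULL) {
    a <- strsplit(struct@alignedA, "")[[1]]
    b <- strsplit(struct@alignedB, "")[[1]]
    mat <- .substMatrix(struct@scoring$matrix)
    cols <- colsA
    if (!is.null(colsB)) cols <- intersect(colsA, colsB)
    cols <- cols[a[cols] != "-" & b[cols] != "-"]
    if (length(cols) == 0) return(0)
    good <- vapply(cols, function(j)
        a[j] == b[j] || mat[a[j], b[j]] > 0, logical(1))
    100 * mean(good)
}

# Alignment columns spanned by residues [res_start, res_end) of one species.
.spanColumns <- function(aln, resStart, resEnd) {
    rc <- .residueColumns(aln)
    if (resEnd <= resStart) return(integer())
    rc[(resStart + 1L):min(resEnd, length(rc))]
}

#' Assess homology of an alternative exon against candidate exons
#'
#' For the alternative exon `altExonA` (exon index in isoform A), every
#' candidate exon of isoform B is scored for (i) alternative-exon sequence
#' similarity (> 20% of aligned columns identical or positively scoring),
#' (ii) significant alignment of at least one flanking constitutive exon of A
#' (same 20% criterion over that exon's span), and (iii) conservation of both
#' flanking intron positions: an intron marker with identical phase within at
#' most 3 alignment columns in each species. Verdicts: `automatic` when all
#' three hold; `manual_flag` when the similarity clauses pass but the
#' structure clause fails, or the structure clause passes with low exon
#' similarity; `none` otherwise. If several candidates exceed 20%, the exon
#' sequences are locally realigned and the highest-similarity candidate kept.
#'
#' @param struct an [AlignedStructure-class].
#' @param altExonA exon index (1-based, transcript order) in isoform A.
#' @param candidatesB candidate exon indices in isoform B (default: all).
#' @param simThreshold percent similarity threshold (20).
#' @param maxOffset maximum marker deviation in alignment columns (3).
#' @return list: `verdict`, `similarity`, `bestCandidate`, and the
#'   per-candidate table `candidates`.
#' @export
assessExonHomology <- function(struct, altExonA, candidatesB = NULL,
                               simThreshold = 20, maxOffset = 3) {
    spansA <- exonResidueSpans(struct@isoA)
    spansB <- exonResidueSpans(struct@isoB)
    if (is.null(candidatesB)) candidatesB <- spansB$exon
    altSpan <- spansA[spansA$exon == altExonA, ]
    if (nrow(altSpan) != 1) stop("unknown exon index: ", altExonA)
    colsAlt <- .spanColumns(struct@alignedA, altSpan$res_start,
                            altSpan$res_end)
    if (length(colsAlt) == 0) {
        message("alternative exon span empty after gap removal")
        return(list(verdict = "none", similarity = 0,
                    bestCandidate = NA_integer_,
                    candidates = data.frame()))
    }

    # similarity of each candidate exon of B against the alt exon of A
    cand <- do.call(rbind, lapply(candidatesB, function(e) {
        sp <- spansB[spansB$exon == e, ]
        colsB <- .spanColumns(struct@alignedB, sp$res_start, sp$res_end)
        data.frame(exon_b = e,
                   similarity = .columnSimilarity(struct, colsAlt, colsB))
    }))
    passing <- cand[cand$similarity > simThreshold, , drop = FALSE]
    if (nrow(passing) > 1) {
        # local realignment of the exon amino-acid sequences alone
        seqA <- substr(struct@isoA@sequence, altSpan$res_start + 1,
                       altSpan$res_end)
        cand$realigned <- NA_real_
        for (i in seq_len(nrow(cand))) {
            if (!cand$exon_b[i] %in% passing$exon_b) next
            sp <- spansB[spansB$exon == cand$exon_b[i], ]
            seqB <- substr(struct@isoB@sequence, sp$res_start + 1, sp$res_end)
            sub <- alignWithStructure(
                methods::new("ProteinIsoform", geneId = "a", isoformId = "a",
                             sequence = seqA,
                             junctionMap = data.frame(residue = integer(),
                                                      phase = integer())),
                methods::new("ProteinIsoform", geneId = "b", isoformId = "b",
                             sequence = seqB,
                             junctionMap = data.frame(residue = integer(),
                                                      phase = integer())),
                struct@scoring)
            cand$realigned[i] <- .columnSimilarity(
                sub, seq_len(nchar(sub@alignedA)))
        }
        best <- cand$exon_b[which.max(cand$realigned)]
        sim <- cand$similarity[cand$exon_b == best]
    } else if (nrow(passing) == 1) {
        best <- passing$exon_b; sim <- passing$similarity
    } else {
        best <- cand$exon_b[which.max(cand$similarity)]
        sim <- max(cand$similarity)
    }
    simPass <- sim > simThreshold

    # flanking constitutive exon significance (either neighbour of alt)
    flankSig <- FALSE
    for (e in intersect(c(altExonA - 1L, altExonA + 1L), spansA$exon)) {
        sp <- spansA[spansA$exon == e, ]
        cols <- .spanColumns(struct@alignedA, sp$res_start, sp$res_end)
        if (length(cols) > 0 &&
            .columnSimilarity(struct, cols) > simThreshold) {
            flankSig <- TRUE
            break
        }
    }

    # structure clause: both flanking intron positions conserved with
    # identical phase within maxOffset columns
    mkA <- struct@markersA; mkB <- struct@markersB
    flankJunctions <- c(altExonA - 1L, altExonA)  # junction indices in A
    structOK <- all(vapply(flankJunctions, function(j) {
        if (j < 1 || j > nrow(mkA)) return(FALSE)
        any(mkB$phase == mkA$phase[j] &
                abs(mkB$column - mkA$column[j]) <= maxOffset)
    }, logical(1)))

    verdict <- if (simPass && flankSig && structOK) "automatic"
    else if ((simPass && flankSig && !structOK) || (structOK && !simPass))
        "manual_flag"
    else "none"
    list(verdict = verdict, similarity = sim, bestCandidate = best,
         candidates = cand, structure_ok = structOK,
         flank_significant = flankSig)
}

#' Assemble homologous exon clusters from accepted pairs
#'
#' Connected components (guilt-by-association) over exon pairs accepted
#' automatically plus operator-approved manual flags. A component containing
#' two distinct exons of one gene is kept but flagged as a conflict.
#'
#' @param pairs data.frame with columns `species_a`, `gene_a`, `exon_a`,
#'   `species_b`, `gene_b`, `exon_b`, `verdict`.
#' @param approvals optional data.frame of the same pair columns listing
#'   manually approved `manual_flag` pairs.
#' @return data.frame `cluster_id`, `species`, `gene_id`, `exon_id`,
#'   `conflict`.
#' @export
buildExonClusters <- function(pairs, approvals = NULL) {
    keyOf <- function(sp, g, e) paste(sp, g, e, sep = "|")
    acc <- pairs[pairs$verdict == "automatic", , drop = FALSE]
    if (!is.null(approvals) && nrow(approvals) > 0) {
        man <- pairs[pairs$verdict == "manual_flag", , drop = FALSE]
        pk <- function(d) paste(keyOf(d$species_a, d$gene_a, d$exon_a),
                                keyOf(d$species_b, d$gene_b, d$exon_b))
        acc <- rbind(acc, man[pk(man) %in% pk(approvals), , drop = FALSE])
    }
    if (nrow(acc) == 0)
        return(data.frame(cluster_id = character(), species = character(),
                          gene_id = character(), exon_id = character(),
                          conflict = logical()))
    va <- keyOf(acc$species_a, acc$gene_a, acc$exon_a)
    vb <- keyOf(acc$species_b, acc$gene_b, acc$exon_b)
    verts <- sort(unique(c(va, vb)))
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(verts)
    g <- g + igraph::edges(as.vector(rbind(va, vb)))
    comp <- igraph::components(g)
    parts <- do.call(rbind, strsplit(names(comp$membership), "|",
                                     fixed = TRUE))
    out <- data.frame(cluster_id = sprintf("EC%04d", comp$membership),
                      species = parts[, 1], gene_id = parts[, 2],
                      exon_id = parts[, 3], row.names = NULL,
                      stringsAsFactors = FALSE)
    dup <- stats::aggregate(exon_id ~ cluster_id + gene_id, out,
                            function(x) length(unique(x)))
    conf <- dup$cluster_id[dup$exon_id > 1]
    out$conflict <- out$cluster_id %in% conf
    out[order(out$cluster_id, out$species, out$gene_id, out$exon_id), ]
}
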