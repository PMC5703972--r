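# Small in-code fixtures shared across the suite.

# PsiExperiment from inclusion/exclusion count matrices (PSI derived).
peFromCounts <- function(inc, exc, type = "AltEx", b5 = NULL, b3 = NULL,
                         tier = NULL, genes = NULL) {
    inc <- as.matrix(inc); exc <- as.matrix(exc)
    if (is.null(rownames(inc)))
        rownames(inc) <- rownames(exc) <- paste0("EV", seq_len(nrow(inc)))
    if (is.null(colnames(inc)))
        colnames(inc) <- colnames(exc) <- paste0("s", seq_len(ncol(inc)))
    tot <- inc + exc
    psi <- ifelse(tot > 0, 100 * inc / tot, NA_real_)
    if (is.null(genes)) genes <- paste0("G", seq_len(nrow(inc)))
    PsiExperiment(psi, inc, exc, tier = tier, b5 = b5, b3 = b3,
                  rowData = data.frame(gene_id = genes,
                                       type = rep(type, length.out =
                                                      nrow(inc)),
                                       row.names = rownames(inc)))
}

# PsiExperiment directly from PSI values at a fixed read depth.
peFromPsi <- function(psi, depth = 200L, ...) {
    psi <- as.matrix(psi)
    inc <- round(psi / 100 * depth)
    exc <- depth - inc
    storage.mode(inc) <- "integer"; storage.mode(exc) <- "integer"
    pe <- peFromCounts(inc, exc, ...)
    pe
}

design22 <- function() sampleDesign(c("c1", "c2", "k1", "k2"),
                                    c("control", "control", "perturbed",
                                      "perturbed"))

protein <- function(seq, residues = integer(), phases = integer(),
                    gene = "G", iso = "I") {
    methods::new("ProteinIsoform", geneId = gene, isoformId = iso,
                 sequence = seq,
                 junctionMap = data.frame(residue = as.integer(residues),
                                          phase = as.integer(phases)))
}

# A single-gene genome + event row for motif/region tests: constitutive
# upstream exon, alternative exon and downstream exon with two introns,
# built from explicit sequences (transcript orientation).
toyEvent <- function(upExon, upIntron, altExon, dnIntron, dnExon,
                     strand = "+", chrom = "chrT") {
    tx <- paste0(upExon, upIntron, altExon, dnIntron, dnExon)
    lens <- nchar(c(upExon, upIntron, altExon, dnIntron, dnExon))
    cuts <- cumsum(lens)
    if (strand == "+") {
        seqs <- Biostrings::DNAStringSet(tx)
        s <- c(0L, cuts[1], cuts[2], cuts[3], cuts[4])
        e <- cuts
        iv <- cbind(c(0, cuts[-5]), cuts)
    } else {
        seqs <- Biostrings::DNAStringSet(as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(tx))))
        total <- cuts[5]
        iv <- cbind(total - cuts, total - c(0, cuts[-5]))
    }
    names(seqs) <- chrom
    ev <- data.frame(event_id = "EV1", gene_id = "G1", type = "AltEx",
                     chrom = chrom, strand = strand,
                     alt_start = iv[3, 1], alt_end = iv[3, 2],
                     up_start = iv[1, 1], up_end = iv[1, 2],
                     dn_start = iv[5, 1], dn_end = iv[5, 2],
                     stringsAsFactors = FALSE)
    list(ev = ev, genome = seqs)
}

randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
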