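#' Parameters of the synthetic multi-species generator
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' gene families with 5-8 exons of 20-60 codons separated by 300-800 nt
#' introns, one internal cassette exon per family, half of the families
#' carrying a splicing-factor-dependent effect of 30 PSI units (half
#' enhanced, half silenced; half of the dependent exons direct targets),
#' negative-binomial expression counts with dispersion 0.1, and no sequence
#' divergence or exon gain/loss unless requested.
#'
#' @param n_exons integer range of exon counts per family.
#' @param exon_aa integer range of exon lengths in codons.
#' @param intron_len integer range of intron lengths (nt).
#' @param divergence per-branch, per-site amino-acid substitution
#'   probability per unit branch length.
#' @param exon_gain,exon_loss per-branch probabilities of gaining / losing
#'   one internal exon per unit branch length.
#' @param p_dependent fraction of families whose cassette exon is
#'   factor-dependent.
#' @param p_enhanced fraction of dependent exons with enhanced inclusion.
#' @param dpsi_true planted |ΔPSI| in PSI units.
#' @param p_direct fraction of dependent exons that are direct targets.
#' @param evidence_dropout probability that any one orthology-evidence source
#'   misses a true gene pair.
#' @param de_fraction,de_fold fraction of differentially expressed genes and
#'   their planted fold change.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param expr_meanlog,expr_sdlog log-normal baseline expression.
#' @return list of class `sim_params`.
#' @export
simParams <- function(n_exons = c(5L, 8L), exon_aa = c(20L, 60L),
                      intron_len = c(300L, 800L), divergence = 0,
                      exon_gain = 0, exon_loss = 0, p_dependent = 0.5,
                      p_enhanced = 0.5, dpsi_true = 30, p_direct = 0.5,
                      evidence_dropout = 0, de_fraction = 0.2, de_fold = 3,
                      nb_dispersion = 0.1, expr_meanlog = log(300),
                      expr_sdlog = 1) {
    structure(as.list(environment()), class = "sim_params")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic codon per amino acid (first codon in alphabetical order).
.codonTable <- function() {
    gc <- Biostrings::GENETIC_CODE
    vapply(.AA20, function(a) sort(names(gc)[gc == a])[1], character(1))
}

.randomAA <- function(n) paste(sample(.AA20, n, replace = TRUE),
                               collapse = "")

.mutateAA <- function(seq, p) {
    if (p <= 0) return(seq)
    chars <- strsplit(seq, "")[[1]]
    hit <- stats::runif(length(chars)) < p
    if (any(hit))
        chars[hit] <- vapply(chars[hit], function(a)
            sample(setdiff(.AA20, a), 1), character(1))
    paste(chars, collapse = "")
}

.randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Back-translate an AA string with the deterministic codon table.
.backTranslate <- function(aa, tab = .codonTable()) {
    paste(tab[strsplit(aa, "")[[1]]], collapse = "")
}

#' Simulate multi-species gene families with known descent
#'
#' Generates, for each family, an ancestral multi-exon coding gene (one
#' internal cassette exon) and evolves it along a labelled species tree:
#' i.i.d. per-site amino-acid substitution, and optional gain/loss of
#' internal exons, per branch. Orthologous exons therefore share
#' descent-simulated sequences and conserved intron positions/phases except
#' where gain/loss applied. Proteins are back-translated with a fixed codon
#' table into genomic sequences (one chromosome per gene; alternating
#' strands) with random introns. Truth records family membership, the
#' cassette exon's per-species presence, planted dependence/direction/
#' directness, and a three-source orthology-evidence table.
#'
#' @param nFamilies number of gene families.
#' @param speciesTree newick string with >= 2 leaves (branch lengths scale
#'   the per-branch probabilities).
#' @param params a [simParams()] bundle.
#' @param seed integer seed; all output is a pure function of
#'   `(params, seed)`.
#' @return list with `species`, `models`, `proteins`, `genome` (per-species
#'   [Biostrings::DNAStringSet]), `events` (per-species AS-event tables) and
#'   `truth` (list of `exons`, `genes`, `evidence` data.frames).
#' @export
simulateGeneFamilies <- function(nFamilies, speciesTree =
                                     "((spA:1,spB:1):1,spC:2);",
                                 params = simParams(), seed = 1) {
    set.seed(seed)
    tree <- if (inherits(speciesTree, "phylo")) speciesTree
    else .parseNewick(speciesTree)
    species <- tree$tip.label
    if (length(species) < 2)
        stop("species tree must have at least 2 leaves")
    codons <- .codonTable()

    models <- stats::setNames(vector("list", length(species)), species)
    proteins <- stats::setNames(vector("list", length(species)), species)
    genomeSeqs <- stats::setNames(
        replicate(length(species), character(0), simplify = FALSE), species)
    events <- stats::setNames(
        replicate(length(species), list(), simplify = FALSE), species)
    exonTruth <- list(); geneTruth <- list(); evidence <- list()

    for (fam in seq_len(nFamilies)) {
        nEx <- sample(params$n_exons[1]:params$n_exons[2], 1)
        altIdx <- sample(2:(nEx - 1), 1)
        aa <- vapply(seq_len(nEx), function(i)
            .randomAA(sample(params$exon_aa[1]:params$exon_aa[2], 1)),
            character(1))
        phases <- sample(0:2, nEx - 1, replace = TRUE)
        # frame-preserving cassette exon: equal flanking phases
        if (altIdx > 1) phases[altIdx] <- phases[altIdx - 1]
        ids <- paste0("anc", seq_len(nEx))
        dep <- stats::runif(1) < params$p_dependent
        direction <- if (!dep) NA_character_ else
            if (stats::runif(1) < params$p_enhanced) "enhanced" else
                "silenced"
        direct <- dep && stats::runif(1) < params$p_direct
        ancestor <- list(aa = aa, phases = phases, ids = ids,
                         altId = ids[altIdx])

        leafStates <- .evolveFamily(tree, ancestor, params)
        strand <- if (fam %% 2 == 0) "-" else "+"
        famGenes <- character(0)
        for (sp in species) {
            st <- leafStates[[sp]]
            gene <- sprintf("%s_g%03d", sp, fam)
            altPos <- match(ancestor$altId, st$ids)
            hasAlt <- !is.na(altPos) && altPos > 1 && altPos < length(st$ids)
            built <- .buildGene(gene, sp, st, strand, params, codons)
            models[[sp]][[gene]] <- built$model
            proteins[[sp]][[gene]] <- built$protein
            genomeSeqs[[sp]][[gene]] <- built$chromSeq
            famGenes <- c(famGenes, gene)
            if (hasAlt) {
                ev <- .altEventRow(gene, built, altPos)
                events[[sp]][[length(events[[sp]]) + 1L]] <- ev
            }
            exonTruth[[length(exonTruth) + 1L]] <- data.frame(
                family = fam, species = sp, gene_id = gene,
                ancestral_exon = ancestor$altId,
                exon_index = ifelse(hasAlt, altPos, NA_integer_),
                event_id = ifelse(hasAlt, paste0(gene, "_alt"),
                                  NA_character_),
                present = hasAlt, alternative = hasAlt,
                esrp_dependent = dep, direction = direction,
                direct = direct, stringsAsFactors = FALSE)
            geneTruth[[length(geneTruth) + 1L]] <- data.frame(
                family = fam, species = sp, gene_id = gene,
                stringsAsFactors = FALSE)
        }
        for (i in seq_along(famGenes)) for (j in seq_along(famGenes)) {
            if (j <= i) next
            for (src in c("OMA", "Multiparanoid", "BlastP"))
                if (stats::runif(1) >= params$evidence_dropout)
                    evidence[[length(evidence) + 1L]] <- data.frame(
                        gene_a = min(famGenes[i], famGenes[j]),
                        gene_b = max(famGenes[i], famGenes[j]),
                        source = src, stringsAsFactors = FALSE)
        }
    }
    genome <- lapply(genomeSeqs, function(x)
        Biostrings::DNAStringSet(unlist(x)))
    events <- lapply(events, function(e)
        if (length(e) > 0) do.call(rbind, e) else
            data.frame(event_id = character(), gene_id = character(),
                       type = character(), chrom = character(),
                       strand = character(), alt_start = integer(),
                       alt_end = integer(), up_start = integer(),
                       up_end = integer(), dn_start = integer(),
                       dn_end = integer()))
    out <- list(species = species, models = models, proteins = proteins,
         genome = genome, events = events,
         truth = list(exons = do.call(rbind, exonTruth),
                      genes = do.call(rbind, geneTruth),
                      evidence = if (length(evidence) > 0)
                          do.call(rbind, evidence) else
                              data.frame(gene_a = character(),
                                         gene_b = character(),
                                         source = character())))
    attr(out, "params") <- params
    out
}

# Minimal newick wrapper: use ape when available without importing it.
.parseNewick <- function(txt) {
    if (!requireNamespace("ape", quietly = TRUE))
        stop("reading newick trees requires the ape package")
    ape::read.tree(text = txt)
}

# Evolve the ancestral exon state along every branch; returns leaf states.
.evolveFamily <- function(tree, ancestor, params) {
    nTip <- length(tree$tip.label)
    root <- nTip + 1L
    states <- list()
    states[[as.character(root)]] <- ancestor
    edges <- tree$edge
    bl <- if (!is.null(tree$edge.length)) tree$edge.length else
        rep(1, nrow(edges))
    remaining <- seq_len(nrow(edges))
    while (length(remaining) > 0) {
        prog <- FALSE
        for (k in remaining) {
            p <- as.character(edges[k, 1]); c <- as.character(edges[k, 2])
            if (!is.null(states[[p]])) {
                states[[c]] <- .evolveBranch(states[[p]], bl[k], params,
                                             ancestor$altId)
                remaining <- setdiff(remaining, k)
                prog <- TRUE
            }
        }
        if (!prog) stop("species tree traversal failed")
    }
    out <- stats::setNames(lapply(seq_len(nTip), function(i)
        states[[as.character(i)]]), tree$tip.label)
    out
}

.evolveBranch <- function(state, bl, params, altId) {
    pSub <- 1 - (1 - params$divergence)^bl
    state$aa <- vapply(state$aa, .mutateAA, character(1), p = pSub)
    names(state$aa) <- NULL
    nEx <- length(state$aa)
    altPos <- match(altId, state$ids)
    # loss: one internal exon, never the cassette exon or its neighbours
    if (stats::runif(1) < params$exon_loss * bl && nEx > 3) {
        cand <- setdiff(2:(nEx - 1),
                        c(altPos - 1, altPos, altPos + 1))
        cand <- cand[!is.na(cand)]
        if (length(cand) > 0) {
            i <- if (length(cand) == 1) cand else sample(cand, 1)
            state$aa <- state$aa[-i]
            state$ids <- state$ids[-i]
            state$phases <- state$phases[-(i - 1)]
        }
    }
    # gain: a new lineage-specific internal exon
    if (stats::runif(1) < params$exon_gain * bl) {
        nEx <- length(state$aa)
        i <- sample(2:nEx, 1)  # insert before exon i
        newAA <- .randomAA(sample(params$exon_aa[1]:params$exon_aa[2], 1))
        newId <- paste0("gain_", paste(sample(letters, 8, replace = TRUE),
                                       collapse = ""))
        state$aa <- append(state$aa, newAA, after = i - 1)
        state$ids <- append(state$ids, newId, after = i - 1)
        state$phases <- append(state$phases, sample(0:2, 1), after = i - 1)
    }
    state
}

# Build one gene: genomic sequence (own chromosome), GeneModel, protein.
.buildGene <- function(gene, sp, st, strand, params, codons) {
    nEx <- length(st$aa)
    A <- nchar(st$aa)
    p <- c(0L, st$phases, 0L)  # p[i] = phase of junction before exon i
    lens <- integer(nEx)
    for (i in seq_len(nEx)) lens[i] <- 3L * A[i] + p[i + 1L] - p[i]
    protein <- paste(st$aa, collapse = "")
    cds <- .backTranslate(protein, codons)
    cuts <- cumsum(lens)
    exonSeqs <- substring(cds, c(1L, cuts[-nEx] + 1L), cuts)
    intrLens <- sample(params$intron_len[1]:params$intron_len[2], nEx - 1,
                       replace = TRUE)
    introns <- vapply(intrLens, .randomDNA, character(1))
    pad <- 50L
    txSeq <- paste0(c(rbind(exonSeqs, c(introns, ""))), collapse = "")
    full <- paste0(.randomDNA(pad), txSeq, .randomDNA(pad))
    # transcript-oriented genomic starts (plus strand layout)
    starts <- pad + c(0L, cumsum(lens + c(intrLens, 0L))[-nEx])
    exPlus <- cbind(starts, starts + lens)
    total <- nchar(full)
    if (strand == "+") {
        chromSeq <- full
        exons <- exPlus
    } else {
        chromSeq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(full)))
        exons <- cbind(total - exPlus[, 2], total - exPlus[, 1])
    }
    cdsIv <- c(min(exons), max(exons))
    model <- GeneModel(gene, sp, gene, strand,
                       list(t1 = list(exons = exons, cds = cdsIv)))
    prot <- deriveProteinJunctionMap(model, "t1", sequence = protein)
    prot@geneId <- gene
    prot@isoformId <- paste0(gene, ".t1")
    list(model = model, protein = prot, chromSeq = chromSeq,
         exons = exons)
}

.altEventRow <- function(gene, built, altPos) {
    ex <- built$exons
    data.frame(event_id = paste0(gene, "_alt"), gene_id = gene,
               type = "AltEx", chrom = gene,
               strand = built$model@strand,
               alt_start = ex[altPos, 1], alt_end = ex[altPos, 2],
               up_start = ex[altPos - 1, 1], up_end = ex[altPos - 1, 2],
               dn_start = ex[altPos + 1, 1], dn_end = ex[altPos + 1, 2],
               stringsAsFactors = FALSE)
}

#' Simulate replicate PSI tables with planted effects
#'
#' Draws, for every simulated cassette exon, a control-condition PSI
#' (factor-enhanced targets on \[40, 90\], silenced targets on \[10, 60\],
#' non-dependent exons on \[0, 100\], all via scaled Beta(2,2) — an enhanced
#' exon is included while the factor is functional, a silenced one is not),
#' shifts it by the planted ΔPSI in the perturbed condition (sign flipped for
#' gain-of-function samples; out-of-range values clamped and recorded), and
#' samples inclusion reads binomially (or beta-binomially with correlation
#' `rho`) at the configured depth. Tiers follow [tierFromReads()].
#'
#' @param sim output of [simulateGeneFamilies()].
#' @param design a [sampleDesign()]; default two control and two
#'   loss-of-function replicates.
#' @param depth expected total reads per event: a number (constant) or
#'   `list(type = "lognormal", meanlog=, sdlog=)`.
#' @param rho beta-binomial overdispersion in \[0, 1); 0 = pure binomial.
#' @param seed integer seed.
#' @param tierBreaks passed to [tierFromReads()].
#' @return list: `psi` (per-species [PsiExperiment-class]) and `truth`
#'   (per-event control PSI, loss-oriented effective ΔPSI, clamping flag).
#' @export
simulatePsiTables <- function(sim, design = NULL, depth = 60, rho = 0,
                              seed = 1, tierBreaks = c(5L, 15L, 25L, 100L)) {
    set.seed(seed + 1L)
    if (is.null(design))
        design <- sampleDesign(c("ctl1", "ctl2", "ko1", "ko2"),
                               c("control", "control", "perturbed",
                                 "perturbed"))
    drawDepth <- function(n) {
        if (is.list(depth))
            pmax(1L, as.integer(round(stats::rlnorm(n, depth$meanlog,
                                                    depth$sdlog))))
        else rep(as.integer(depth), n)
    }
    psiOut <- list(); truthOut <- list()
    exTruth <- sim$truth$exons
    for (sp in sim$species) {
        evs <- sim$events[[sp]]
        if (nrow(evs) == 0) next
        tr <- exTruth[match(evs$event_id, exTruth$event_id), ]
        n <- nrow(evs); k <- nrow(design)
        ctlPsi <- numeric(n)
        for (i in seq_len(n)) {
            b <- stats::rbeta(1, 2, 2)
            ctlPsi[i] <- if (!tr$esrp_dependent[i]) 100 * b
            else if (tr$direction[i] == "enhanced") 40 + 50 * b
            else 10 + 50 * b
        }
        dp <- simParamsOf(sim)$dpsi_true
        shift <- ifelse(!tr$esrp_dependent, 0,
                        ifelse(tr$direction == "enhanced", -dp, dp))
        psi <- inc <- exc <- matrix(0, n, k,
                                    dimnames = list(evs$event_id,
                                                    design$sample_id))
        trueLossDpsi <- numeric(n); clamped <- logical(n)
        for (j in seq_len(k)) {
            isPert <- design$condition[j] == "perturbed"
            flip <- if (design$perturbation_sign[j] == "gain") -1 else 1
            pTrue <- if (isPert) ctlPsi + flip * shift else ctlPsi
            cl <- pTrue < 0 | pTrue > 100
            clamped <- clamped | (isPert & cl)
            pTrue <- pmin(100, pmax(0, pTrue))
            if (isPert && flip == 1)
                trueLossDpsi <- ctlPsi - pTrue
            tot <- drawDepth(n)
            pr <- pTrue / 100
            if (rho > 0) {
                a <- pr * (1 - rho) / rho
                b <- (1 - pr) * (1 - rho) / rho
                pr <- stats::rbeta(n, pmax(a, 1e-8), pmax(b, 1e-8))
                pr[pTrue == 0] <- 0; pr[pTrue == 100] <- 1
            }
            inc[, j] <- stats::rbinom(n, tot, pr)
            exc[, j] <- tot - inc[, j]
            psi[, j] <- ifelse(tot > 0, 100 * inc[, j] / tot, NA_real_)
        }
        pe <- PsiExperiment(psi, inc, exc,
                            rowData = data.frame(gene_id = evs$gene_id,
                                                 type = evs$type,
                                                 coord = sprintf(
                                                     "%s:%d-%d", evs$chrom,
                                                     evs$alt_start + 1L,
                                                     evs$alt_end),
                                                 row.names = evs$event_id),
                            colData = design, tierBreaks = tierBreaks)
        psiOut[[sp]] <- pe
        truthOut[[sp]] <- data.frame(
            species = sp, event_id = evs$event_id, control_psi = ctlPsi,
            dpsi_true_loss = trueLossDpsi, planted_shift = -shift,
            esrp_dependent = tr$esrp_dependent, direction = tr$direction,
            clamped = clamped, stringsAsFactors = FALSE)
    }
    list(psi = psiOut, truth = do.call(rbind, truthOut), design = design)
}

# params used to build a simulation (stored by runPipeline; falls back to
# defaults so standalone simulateGeneFamilies output still works).
simParamsOf <- function(sim) {
    p <- attr(sim, "params")
    if (is.null(p)) simParams() else p
}

#' Plant scenario-consistent motifs for direct targets
#'
#' First scrubs every chance motif occurrence from the scan universe of all
#' simulated events (so indirect truth is well defined), then writes
#' `nPlant` motif copies into scenario-consistent regions of each direct
#' target: factor-enhanced targets into the first 250 nt of the downstream
#' intron (beyond the 6-nt splice-site overlap), silenced targets into the
#' last 250 nt of the upstream intron. Regions shorter than a hexamer are
#' skipped and recorded. Planting edits genomic sequence only; protein
#' truth is not rewritten (planted genomes are for motif analyses).
#'
#' @param sim output of [simulateGeneFamilies()].
#' @param motifs a [motifSet()].
#' @param scenario `"restricted"` or `"expanded"` (controls which regions
#'   are eligible for planting).
#' @param nPlant motifs planted per direct target.
#' @param seed integer seed.
#' @return list: `genome` (edited per-species
#'   [Biostrings::DNAStringSet]), `planted` (BED-like data.frame of planted
#'   sites), `skipped` (events whose region was too short).
#' @export
plantMotifs <- function(sim, motifs = defaultMotifSet(),
                        scenario = c("restricted", "expanded"), nPlant = 2L,
                        seed = 1) {
    scenario <- match.arg(scenario)
    set.seed(seed + 2L)
    genome <- lapply(sim$genome, function(g) {
        stats::setNames(as.character(g), names(g))
    })
    planted <- list(); skipped <- character(0)
    exTruth <- sim$truth$exons
    for (sp in sim$species) {
        evs <- sim$events[[sp]]
        for (i in seq_len(nrow(evs))) {
            ev <- evs[i, ]
            tr <- exTruth[exTruth$event_id == ev$event_id, ]
            genome[[sp]][ev$chrom] <- .scrubScanUniverse(
                genome[[sp]][[ev$chrom]], ev, motifs)
            if (!isTRUE(tr$direct)) next
            mot <- sample(unclass(motifs), nPlant, replace = TRUE)
            res <- .plantInRegion(genome[[sp]][[ev$chrom]], ev,
                                  tr$direction, mot)
            if (is.null(res)) {
                skipped <- c(skipped, ev$event_id)
                next
            }
            genome[[sp]][ev$chrom] <- res$seq
            planted[[length(planted) + 1L]] <- data.frame(
                species = sp, event_id = ev$event_id, chrom = ev$chrom,
                start0 = res$start0, end0 = res$start0 + 6L,
                motif = res$motif, strand = ev$strand,
                stringsAsFactors = FALSE)
        }
    }
    list(genome = lapply(genome, Biostrings::DNAStringSet),
         planted = if (length(planted) > 0) do.call(rbind, planted) else
             data.frame(species = character(), event_id = character(),
                        chrom = character(), start0 = integer(),
                        end0 = integer(), motif = character(),
                        strand = character()),
         skipped = skipped)
}

# Replace the middle bases of every motif occurrence in the scan universe
# until none remain.
.scrubScanUniverse <- function(chromSeq, ev, motifs) {
    geo <- .eventGeometry(ev)
    st <- ev$strand
    regions <- list(c(ev$alt_start, ev$alt_end),
                    .lastN(ev$up_start, ev$up_end, st,
                           min(25L, ev$up_end - ev$up_start)),
                    .firstN(ev$dn_start, ev$dn_end, st,
                            min(25L, ev$dn_end - ev$dn_start)))
    for (iv in list(geo$upIntron, geo$dnIntron)) {
        len <- iv[2] - iv[1]
        regions <- c(regions,
                     list(.firstN(iv[1], iv[2], st, min(250L, len)),
                          .lastN(iv[1], iv[2], st, min(250L, len))))
    }
    chars <- strsplit(chromSeq, "")[[1]]
    for (iter in 1:20) {
        dirty <- FALSE
        for (iv in regions) {
            if (iv[2] - iv[1] < 6) next
            segment <- paste(chars[(iv[1] + 1L):iv[2]], collapse = "")
            hits <- scanMotifs(if (st == "-")
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(segment))) else segment, motifs)
            if (length(hits) == 0) next
            dirty <- TRUE
            for (h in hits) {
                # genomic position of the hit's 3rd base
                gpos <- if (st == "+") iv[1] + h + 2L
                else iv[2] - h - 1L  # 0-based
                base <- chars[gpos + 1L]
                chars[gpos + 1L] <- if (base %in% c("A", "C")) "G"
                else "A"
            }
        }
        if (!dirty) break
    }
    paste(chars, collapse = "")
}

# Plant motifs at spaced offsets inside the direction-appropriate region;
# returns NULL when the region cannot host them.
.plantInRegion <- function(chromSeq, ev, direction, motifSeqs) {
    st <- ev$strand
    geo <- .eventGeometry(ev)
    if (direction == "enhanced") {
        iv <- geo$dnIntron
        len <- iv[2] - iv[1]
        lo <- 10L; hi <- min(245L, len) - 5L
        region <- .firstN(iv[1], iv[2], st, min(250L, len))
        anchor <- "first"
    } else {
        iv <- geo$upIntron
        len <- iv[2] - iv[1]
        lo <- 10L; hi <- min(250L, len) - 60L
        region <- .lastN(iv[1], iv[2], st, min(250L, len))
        anchor <- "last"
    }
    n <- length(motifSeqs)
    if (hi - lo < 8L * n) return(NULL)
    offs <- lo + (seq_len(n) - 1L) * 8L +
        sample.int(max(1L, (hi - lo) %/% n - 8L), n, replace = TRUE)
    chars <- strsplit(chromSeq, "")[[1]]
    starts <- integer(n)
    for (i in seq_len(n)) {
        o <- offs[i]  # 1-based offset within the transcript-oriented region
        if (st == "+") {
            gstart0 <- region[1] + o - 1L
            repl <- strsplit(motifSeqs[i], "")[[1]]
        } else {
            gstart0 <- region[2] - o - 5L
            repl <- rev(strsplit(chartr("ACGT", "TGCA", motifSeqs[i]),
                                 "")[[1]])
        }
        chars[(gstart0 + 1L):(gstart0 + 6L)] <- repl
        starts[i] <- gstart0
    }
    list(seq = paste(chars, collapse = ""), start0 = starts,
         motif = motifSeqs)
}

#' Simulate expression count tables
#'
#' Per-gene negative-binomial counts with a log-normal baseline and a
#' planted fold change for a fraction of genes (direction at random).
#'
#' @param sim output of [simulateGeneFamilies()].
#' @param design a [sampleDesign()].
#' @param params a [simParams()] bundle.
#' @param seed integer seed.
#' @return list per species: `reads` (genes x samples), `mappable`
#'   (named vector), `truth` (gene fold changes).
#' @export
simulateExpression <- function(sim, design = NULL, params = simParams(),
                               seed = 1) {
    set.seed(seed + 3L)
    if (is.null(design))
        design <- sampleDesign(c("ctl1", "ctl2", "ko1", "ko2"),
                               c("control", "control", "perturbed",
                                 "perturbed"))
    out <- list()
    for (sp in sim$species) {
        genes <- names(sim$models[[sp]])
        n <- length(genes)
        mu <- stats::rlnorm(n, params$expr_meanlog, params$expr_sdlog)
        de <- stats::runif(n) < params$de_fraction
        upDir <- stats::runif(n) < 0.5
        fold <- ifelse(de, ifelse(upDir, params$de_fold,
                                  1 / params$de_fold), 1)
        reads <- matrix(0L, n, nrow(design),
                        dimnames = list(genes, design$sample_id))
        for (j in seq_len(nrow(design))) {
            m <- if (design$condition[j] == "perturbed") mu * fold else mu
            reads[, j] <- stats::rnbinom(n, mu = m,
                                         size = 1 / params$nb_dispersion)
        }
        mappable <- vapply(sim$models[[sp]], function(m) m@mappableLength,
                           integer(1))
        out[[sp]] <- list(reads = reads, mappable = mappable,
                          truth = data.frame(gene_id = genes, fold = fold,
                                             de = de, up = upDir,
                                             stringsAsFactors = FALSE))
    }
    out
}

#' Simulate a smooth per-base score track
#'
#' A logistic-transformed Gaussian random walk per chromosome, in (0, 1),
#' optionally elevated over supplied intervals (e.g. conserved exons).
#'
#' @param genome per-species [Biostrings::DNAStringSet] or a single set.
#' @param elevate optional data.frame `chrom`, `start0`, `end0` of intervals
#'   whose scores are pushed toward 1.
#' @param seed integer seed.
#' @param stepSd random-walk step standard deviation.
#' @return named list of numeric vectors (a score track).
#' @export
simulateScoreTrack <- function(genome, elevate = NULL, seed = 1,
                               stepSd = 0.05) {
    set.seed(seed + 4L)
    track <- list()
    for (ch in names(genome)) {
        n <- Biostrings::width(genome[ch])
        v <- stats::plogis(cumsum(stats::rnorm(n, 0, stepSd)))
        track[[ch]] <- v
    }
    if (!is.null(elevate))
        for (i in seq_len(nrow(elevate))) {
            ch <- elevate$chrom[i]
            if (!ch %in% names(track)) next
            idx <- (elevate$start0[i] + 1L):elevate$end0[i]
            track[[ch]][idx] <- 0.5 + 0.5 * track[[ch]][idx]
        }
    track
}
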