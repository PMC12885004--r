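## Synthetic assembly generator. Produces desk-scale genomes with planted
## telomeric arrays, satellite-filled centromeres, domain-bearing LTR
## elements and gene intervals, together with exact truth tables, so that
## every scanner in the package can be validated against known ground
## truth. All randomness flows through the R RNG seeded from the config.

.BASES <- c("A", "C", "G", "T")

.baseProbs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

.randomBases <- function(n, gc) {
    sample(.BASES, n, replace = TRUE, prob = .baseProbs(gc))
}

## substitute `rate` of positions with a different base (char vector in/out)
.mutateBases <- function(x, rate) {
    if (rate <= 0 || length(x) == 0) return(x)
    k <- rbinom(1L, length(x), rate)
    if (k == 0) return(x)
    idx <- sample.int(length(x), k)
    cur <- x[idx]
    sub <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L), "",
                  USE.NAMES = FALSE)
    x[idx] <- sub
    x
}

.revcomp <- function(s) {
    as.character(reverseComplement(DNAString(s)))
}

#' Simulation configuration
#'
#' Builds and validates the configuration list consumed by
#' \code{\link{simulateAssembly}}. The per-chromosome plan gives the
#' chromosome length, the motif and copy number of the left and right
#' terminal telomeric arrays, and (optionally) the start and length of a
#' satellite-filled centromere. The LTR plan gives, per family, the
#' element count, length range, the domain peptide embedded in each
#' element and the centromeric enrichment factor (>= 1): an element lands
#' in the centromeric partition with probability f*Lc / (f*Lc + Lnc), so
#' the centromeric/noncentromeric density ratio converges to f.
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length},
#'   \code{leftMotif}, \code{leftCopies}, \code{rightMotif},
#'   \code{rightCopies}, \code{cenStart}, \code{cenLength} (NA for no
#'   centromere).
#' @param seed integer RNG seed.
#' @param backgroundGC background GC fraction (default 0.39).
#' @param telomereSubRate per-base substitution rate applied to planted
#'   telomeric arrays (default 0, i.e. perfect copies).
#' @param monomerLength centromeric satellite monomer length in bases.
#' @param monomerDivergence per-base substitution rate applied to each
#'   planted monomer copy.
#' @param ltrPlan data.frame with columns \code{family},
#'   \code{superfamily}, \code{count}, \code{minLen}, \code{maxLen},
#'   \code{enrichment}, \code{peptide}; NULL for no LTR elements.
#' @param genesPerWindow target gene count per \code{geneWindow} bases.
#' @param geneWindow window used to express gene density (default 500 kb).
#' @param geneLenRange length range of planted gene intervals.
#' @param margin telomere-proximal exclusion zone for LTRs/genes (bases).
#' @return a validated config list.
#' @export
simConfig <- function(chromosomes, seed = 1L, backgroundGC = 0.39,
                      telomereSubRate = 0, monomerLength = 200L,
                      monomerDivergence = 0.02, ltrPlan = NULL,
                      genesPerWindow = 7, geneWindow = 500000L,
                      geneLenRange = c(1000L, 3000L), margin = 20000L) {
    cfg <- list(chromosomes = chromosomes, seed = as.integer(seed),
                backgroundGC = backgroundGC,
                telomereSubRate = telomereSubRate,
                monomerLength = as.integer(monomerLength),
                monomerDivergence = monomerDivergence,
                ltrPlan = ltrPlan, genesPerWindow = genesPerWindow,
                geneWindow = as.integer(geneWindow),
                geneLenRange = as.integer(geneLenRange),
                margin = as.integer(margin))
    validateSimConfig(cfg)
    cfg
}

#' @rdname simConfig
#' @param config a config list to validate.
#' @export
validateSimConfig <- function(config) {
    ch <- config$chromosomes
    need <- c("name", "length", "leftMotif", "leftCopies", "rightMotif",
              "rightCopies", "cenStart", "cenLength")
    if (!all(need %in% names(ch)))
        stop("chromosome plan must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(ch$name)) stop("chromosome names must be unique")
    if (config$backgroundGC <= 0 || config$backgroundGC >= 1)
        stop("backgroundGC must be in (0, 1)")
    teloLen <- nchar(ch$leftMotif) * ch$leftCopies +
               nchar(ch$rightMotif) * ch$rightCopies
    hasCen <- !is.na(ch$cenStart)
    cenLoad <- ifelse(hasCen, ch$cenLength, 0)
    if (any(teloLen + cenLoad > ch$length))
        stop("infeasible packing: telomeres + centromere exceed chromosome ",
             paste(ch$name[teloLen + cenLoad > ch$length], collapse = ", "))
    if (any(hasCen & (ch$cenStart + ch$cenLength - 1 > ch$length)))
        stop("centromere extends beyond chromosome end")
    if (any(hasCen & (ch$cenStart <= nchar(ch$leftMotif) * ch$leftCopies)))
        stop("centromere overlaps left telomeric array")
    if (!is.null(config$ltrPlan)) {
        lp <- config$ltrPlan
        if (any(lp$enrichment < 1))
            stop("LTR enrichment factors must be >= 1")
        if (any(lp$minLen > lp$maxLen) || any(lp$minLen < 3))
            stop("invalid LTR length range")
    }
    invisible(TRUE)
}

#' Default LTR family plan
#'
#' Nine REXdb-style families spanning the Ty3/Gypsy (Athila, TatI-III,
#' Phygy, Selgy), Ty1/Copia (Bryco, SIRE) and Bel-Pao superfamilies. The
#' Tat, Phygy and Selgy lineages carry strong centromeric enrichment and
#' Bel-Pao a moderate one, emulating genomes whose Gypsy-family density
#' rises toward the centromere; Copia-lineage families are unenriched.
#' Peptides are taken from the packaged synthetic domain library.
#'
#' @param library a \code{\link{DomainLibrary}}; defaults to the packaged
#'   synthetic library.
#' @param countScale multiplier on the per-family element counts.
#' @return a data.frame usable as \code{ltrPlan} in \code{\link{simConfig}}.
#' @export
defaultLtrPlan <- function(library = readDomainLibrary(), countScale = 1) {
    fam <- c("Athila", "TatI", "TatII", "TatIII", "Phygy", "Selgy",
             "Bryco", "SIRE", "Bel-Pao")
    sup <- c("Gypsy", "Gypsy", "Gypsy", "Gypsy", "Gypsy", "Gypsy",
             "Copia", "Copia", "Bel-Pao")
    cnt <- round(c(50, 45, 45, 45, 50, 50, 40, 40, 12) * countScale)
    enr <- c(2, 8, 8, 8, 6, 6, 1, 1, 5)
    pep <- as.character(domainPeptides(library)[fam])
    data.frame(family = fam, superfamily = sup, count = cnt,
               minLen = 1000L, maxLen = 3000L, enrichment = enr,
               peptide = pep, stringsAsFactors = FALSE)
}

#' Desk-scale configuration mirroring the published chromosome plan
#'
#' Scales the nine published chromosome lengths and centromere
#' coordinates by \code{scale} (default 1/100) while keeping the printed
#' telomere copy numbers unscaled — the copy counts, not the chromosome
#' lengths, are the recovery targets. Scaled centromeres are kept at a
#' minimum of 25 kb so that desk-scale satellite regions remain above the
#' centromere caller's default minimum extent.
#'
#' @param seed integer RNG seed.
#' @param scale linear scale factor on lengths and coordinates.
#' @param withLtr logical; include the \code{\link{defaultLtrPlan}}.
#' @param ... passed through to \code{\link{simConfig}}.
#' @return a config list.
#' @export
simConfigScaled <- function(seed = 1L, scale = 0.01, withLtr = TRUE, ...) {
    tab <- apopelliaChromosomes()
    ch <- data.frame(
        name = tab$name,
        length = round(tab$length * scale),
        leftMotif = tab$leftMotif, leftCopies = tab$leftCopies,
        rightMotif = tab$rightMotif, rightCopies = tab$rightCopies,
        cenStart = round(tab$cenStart * scale),
        cenLength = pmax(round((tab$cenEnd - tab$cenStart + 1) * scale),
                         25000L),
        stringsAsFactors = FALSE)
    ltr <- if (withLtr) defaultLtrPlan() else NULL
    simConfig(ch, seed = seed, ltrPlan = ltr, ...)
}

#' Plant a tandem array into a sequence
#'
#' Writes exactly \code{copies} concatenated copies of \code{motif} into
#' \code{sequence} starting at position \code{at} (1-based), optionally
#' substituting bases at rate \code{subRate} (each substitution changes
#' the base). Planting beyond the sequence end is an error.
#'
#' @param sequence a character scalar DNA sequence.
#' @param motif the repeat unit.
#' @param copies number of copies (0 leaves the sequence unchanged).
#' @param at 1-based start position of the array.
#' @param subRate per-base substitution rate (default 0).
#' @return the modified sequence.
#' @examples
#' plantArray(strrep("A", 30), "CCCTAAA", 3)
#' @export
plantArray <- function(sequence, motif, copies, at = 1L, subRate = 0) {
    if (copies == 0) return(sequence)
    k <- nchar(motif)
    span <- copies * k
    if (at + span - 1L > nchar(sequence))
        stop("array overflows sequence: need ", at + span - 1L,
             " bases, have ", nchar(sequence))
    arr <- strsplit(strrep(motif, copies), "")[[1]]
    arr <- .mutateBases(arr, subRate)
    substr(sequence, at, at + span - 1L) <- paste(arr, collapse = "")
    sequence
}

## first codon (alphabetically) per amino acid of the standard table
.codonFor <- function() {
    aa <- Biostrings::GENETIC_CODE
    split_codons <- split(names(aa), unname(aa))
    vapply(split_codons, function(cs) sort(cs)[1], "")
}

#' Reverse-translate a peptide with a fixed codon table
#'
#' Deterministic reverse translation: for each amino acid the
#' alphabetically first codon of the standard genetic code is used, so
#' translation of the result reproduces the peptide exactly.
#'
#' @param peptide a character scalar of one-letter amino acids (no stop).
#' @return a DNA string of length 3 * nchar(peptide).
#' @export
reverseTranslate <- function(peptide) {
    if (grepl("\\*", peptide)) stop("peptide contains a stop symbol")
    codons <- .codonFor()
    aa <- strsplit(peptide, "")[[1]]
    if (!all(aa %in% names(codons)))
        stop("unknown amino acid(s): ",
             paste(unique(aa[!aa %in% names(codons)]), collapse = ","))
    paste(codons[aa], collapse = "")
}

#' Embed a peptide as an in-frame ORF
#'
#' Writes the reverse-translated codons of \code{peptide} into
#' \code{sequence} in the requested reading frame and strand, so that
#' six-frame translation of the result recovers the peptide in exactly
#' that frame. Frames are 0/1/2 offsets from the 5' end of the chosen
#' strand; \code{codonOffset} shifts the start by whole codons within the
#' frame.
#'
#' @param sequence a character scalar DNA sequence.
#' @param peptide one-letter amino acids, stop-free.
#' @param frame integer 0, 1 or 2.
#' @param strand "+" or "-".
#' @param codonOffset whole-codon offset of the ORF start (default 0).
#' @return the modified sequence.
#' @examples
#' embedDomainOrf(strrep("C", 12), "MK", frame = 0)
#' @export
embedDomainOrf <- function(sequence, peptide, frame = 0L, strand = "+",
                           codonOffset = 0L) {
    stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
    dna <- reverseTranslate(peptide)
    n <- nchar(dna)
    at <- frame + 3L * codonOffset + 1L
    if (at + n - 1L > nchar(sequence))
        stop("ORF does not fit: need ", at + n - 1L, " bases, have ",
             nchar(sequence))
    if (strand == "+") {
        substr(sequence, at, at + n - 1L) <- dna
        sequence
    } else {
        rc <- .revcomp(sequence)
        substr(rc, at, at + n - 1L) <- dna
        .revcomp(rc)
    }
}

#' Simulate a genome assembly with truth tables
#'
#' Generates the configured chromosomes: i.i.d. background bases at the
#' configured GC, telomeric arrays planted verbatim at both termini,
#' centromeres composed of satellite monomer tandem fills (mutated at the
#' divergence rate) interleaved with centromere-assigned LTR elements,
#' noncentromeric LTR elements placed uniformly in the remaining space,
#' and gene intervals at the target density. Each LTR element carries its
#' family's domain peptide as an in-frame ORF at a random frame, strand
#' and codon offset. Placement uses rejection sampling with a
#' 10,000-attempt cap; infeasible packings error before any sequence is
#' emitted. Deterministic for a given config (the config seed drives all
#' randomness).
#'
#' @param config a list from \code{\link{simConfig}} or
#'   \code{\link{simConfigScaled}}.
#' @return a \code{\link{SimulatedAssembly}}.
#' @export
simulateAssembly <- function(config) {
    validateSimConfig(config)
    set.seed(config$seed)
    ch <- config$chromosomes
    nChr <- nrow(ch)
    gc <- config$backgroundGC

    ## per-chromosome satellite monomer (deterministic from the seed)
    monomers <- vapply(seq_len(nChr), function(i)
        paste(.randomBases(config$monomerLength, 0.5), collapse = ""), "")

    seqs <- lapply(seq_len(nChr), function(i)
        .randomBases(ch$length[i], gc))
    names(seqs) <- ch$name

    truth <- list()

    ## ---- telomeres -------------------------------------------------------
    teloRows <- list()
    for (i in seq_len(nChr)) {
        L <- ch$length[i]
        if (ch$leftCopies[i] > 0) {
            spanL <- nchar(ch$leftMotif[i]) * ch$leftCopies[i]
            arr <- strsplit(strrep(ch$leftMotif[i], ch$leftCopies[i]), "")[[1]]
            seqs[[i]][seq_len(spanL)] <-
                .mutateBases(arr, config$telomereSubRate)
            teloRows[[length(teloRows) + 1L]] <- data.frame(
                chrom = ch$name[i], start = 1L, end = spanL,
                chromEnd = "left", motif = ch$leftMotif[i],
                copies = ch$leftCopies[i], stringsAsFactors = FALSE)
        }
        if (ch$rightCopies[i] > 0) {
            spanR <- nchar(ch$rightMotif[i]) * ch$rightCopies[i]
            arrR <- strsplit(strrep(ch$rightMotif[i], ch$rightCopies[i]),
                             "")[[1]]
            seqs[[i]][(L - spanR + 1L):L] <-
                .mutateBases(arrR, config$telomereSubRate)
            teloRows[[length(teloRows) + 1L]] <- data.frame(
                chrom = ch$name[i], start = L - spanR + 1L, end = L,
                chromEnd = "right", motif = ch$rightMotif[i],
                copies = ch$rightCopies[i], stringsAsFactors = FALSE)
        }
    }
    teloDf <- do.call(rbind, teloRows)
    truth$telomeres <- if (is.null(teloDf)) GRanges() else
        GRanges(teloDf$chrom, IRanges(teloDf$start, teloDf$end),
                chromEnd = teloDf$chromEnd, motif = teloDf$motif,
                copies = teloDf$copies)

    ## ---- centromere spans ------------------------------------------------
    hasCen <- !is.na(ch$cenStart)
    cenGr <- GRanges(ch$name[hasCen],
        IRanges(ch$cenStart[hasCen],
                ch$cenStart[hasCen] + ch$cenLength[hasCen] - 1L))
    truth$centromeres <- cenGr

    ## occupied space per chromosome (telomeres + margin; centromeres
    ## reserved for their own internal packing)
    occupied <- lapply(seq_len(nChr), function(i) {
        L <- ch$length[i]
        spanL <- nchar(ch$leftMotif[i]) * ch$leftCopies[i]
        spanR <- nchar(ch$rightMotif[i]) * ch$rightCopies[i]
        ir <- IRanges(c(1L, L - spanR - config$margin + 1L),
                      c(min(spanL + config$margin, L), L))
        if (hasCen[i])
            ir <- c(ir, IRanges(ch$cenStart[i],
                                ch$cenStart[i] + ch$cenLength[i] - 1L))
        reduce(ir)
    })

    ## ---- LTR elements ----------------------------------------------------
    ltrDf <- NULL
    cenOccupied <- vector("list", nChr)   # LTR spans inside each centromere
    for (i in seq_len(nChr)) cenOccupied[[i]] <- IRanges()
    if (!is.null(config$ltrPlan) && sum(config$ltrPlan$count) > 0) {
        lp <- config$ltrPlan
        Lc <- sum(as.numeric(ch$cenLength[hasCen]))
        Lnc <- sum(as.numeric(ch$length)) - Lc
        cenIdx <- which(hasCen)
        rows <- list()
        eid <- 0L
        for (f in seq_len(nrow(lp))) {
            fct <- lp$enrichment[f]
            pCen <- if (Lc > 0) fct * Lc / (fct * Lc + Lnc) else 0
            for (e in seq_len(lp$count[f])) {
                eid <- eid + 1L
                elen <- sample(lp$minLen[f]:lp$maxLen[f], 1L)
                placed <- FALSE
                for (attempt in seq_len(10000L)) {
                    inCen <- runif(1) < pCen
                    if (inCen) {
                        ci <- if (length(cenIdx) == 1L) cenIdx else
                            sample(cenIdx, 1L,
                                   prob = as.numeric(ch$cenLength[cenIdx]))
                        lo <- ch$cenStart[ci]
                        hi <- ch$cenStart[ci] + ch$cenLength[ci] - elen
                        if (hi < lo) next
                        st <- sample(lo:hi, 1L)
                        cand <- IRanges(st, st + elen - 1L)
                        if (length(findOverlaps(cand, cenOccupied[[ci]])) == 0) {
                            cenOccupied[[ci]] <- reduce(c(cenOccupied[[ci]], cand))
                            chrIdx <- ci; placed <- TRUE
                        }
                    } else {
                        chrIdx <- sample(seq_len(nChr), 1L,
                            prob = as.numeric(ch$length) -
                                   ifelse(hasCen, ch$cenLength, 0))
                        hi <- ch$length[chrIdx] - elen
                        if (hi < 1L) next
                        st <- sample.int(hi, 1L)
                        cand <- IRanges(st, st + elen - 1L)
                        if (length(findOverlaps(cand, occupied[[chrIdx]])) == 0) {
                            occupied[[chrIdx]] <- reduce(c(occupied[[chrIdx]], cand))
                            placed <- TRUE
                        }
                    }
                    if (placed) break
                }
                if (!placed)
                    stop("infeasible packing: could not place LTR element of ",
                         "family ", lp$family[f], " after 10000 attempts")
                ## element sequence with the family domain ORF embedded
                eseq <- paste(.randomBases(elen, gc), collapse = "")
                plen <- nchar(lp$peptide[f])
                frame <- sample(0:2, 1L)
                strandE <- sample(c("+", "-"), 1L)
                maxOff <- (elen - frame - 3L * plen) %/% 3L
                off <- if (maxOff > 0) sample(0:maxOff, 1L) else 0L
                eseq <- embedDomainOrf(eseq, lp$peptide[f], frame, strandE, off)
                seqs[[chrIdx]][st:(st + elen - 1L)] <- strsplit(eseq, "")[[1]]
                rows[[eid]] <- data.frame(
                    chrom = ch$name[chrIdx], start = st, end = st + elen - 1L,
                    id = sprintf("LTR%05d", eid), family = lp$family[f],
                    superfamily = lp$superfamily[f], strand = strandE,
                    inCentromere = inCen, stringsAsFactors = FALSE)
            }
        }
        ltrDf <- do.call(rbind, rows)
    }
    truth$ltr <- if (is.null(ltrDf)) GRanges() else
        GRanges(ltrDf$chrom, IRanges(ltrDf$start, ltrDf$end),
                strand = ltrDf$strand, id = ltrDf$id, family = ltrDf$family,
                superfamily = ltrDf$superfamily,
                inCentromere = ltrDf$inCentromere)

    ## ---- satellite fills -------------------------------------------------
    satRows <- list()
    for (ci in which(hasCen)) {
        cen <- IRanges(ch$cenStart[ci], ch$cenStart[ci] + ch$cenLength[ci] - 1L)
        gaps <- IRanges::setdiff(cen, cenOccupied[[ci]])
        mono <- strsplit(monomers[ci], "")[[1]]
        mlen <- length(mono)
        for (g in seq_along(gaps)) {
            w <- width(gaps)[g]
            if (w < mlen) next
            fill <- rep(mono, length.out = w)
            fill <- .mutateBases(fill, config$monomerDivergence)
            st <- start(gaps)[g]
            seqs[[ci]][st:(st + w - 1L)] <- fill
            satRows[[length(satRows) + 1L]] <- data.frame(
                chrom = ch$name[ci], start = st, end = st + w - 1L,
                monomer = monomers[ci], copies = w %/% mlen,
                stringsAsFactors = FALSE)
        }
    }
    satDf <- do.call(rbind, satRows)
    truth$satellites <- if (is.null(satDf)) GRanges() else
        GRanges(satDf$chrom, IRanges(satDf$start, satDf$end),
                monomer = satDf$monomer, copies = satDf$copies)

    ## ---- genes -----------------------------------------------------------
    geneRows <- list()
    gid <- 0L
    if (config$genesPerWindow > 0) {
        for (i in seq_len(nChr)) {
            nGenes <- round(ch$length[i] / config$geneWindow *
                            config$genesPerWindow)
            for (g in seq_len(nGenes)) {
                glen <- sample(config$geneLenRange[1]:config$geneLenRange[2], 1L)
                placed <- FALSE
                for (attempt in seq_len(10000L)) {
                    hi <- ch$length[i] - glen
                    st <- sample.int(hi, 1L)
                    cand <- IRanges(st, st + glen - 1L)
                    if (length(findOverlaps(cand, occupied[[i]])) == 0) {
                        occupied[[i]] <- reduce(c(occupied[[i]], cand))
                        placed <- TRUE; break
                    }
                }
                if (!placed)
                    stop("infeasible packing: could not place gene on ",
                         ch$name[i])
                gid <- gid + 1L
                geneRows[[gid]] <- data.frame(
                    chrom = ch$name[i], start = st, end = st + glen - 1L,
                    id = sprintf("gene%05d", gid),
                    strand = sample(c("+", "-"), 1L),
                    stringsAsFactors = FALSE)
            }
        }
    }
    geneDf <- do.call(rbind, geneRows)
    truth$genes <- if (is.null(geneDf)) GRanges() else
        GRanges(geneDf$chrom, IRanges(geneDf$start, geneDf$end),
                strand = geneDf$strand, id = geneDf$id)

    genome <- DNAStringSet(vapply(seqs, paste, "", collapse = ""))
    names(genome) <- ch$name
    sl <- setNames(ch$length, ch$name)
    for (nm in names(truth)) {
        if (length(truth[[nm]])) {
            seqlevels(truth[[nm]]) <- ch$name
            seqlengths(truth[[nm]]) <- sl
        }
    }

    new("SimulatedAssembly", genome = genome, truth = truth,
        config = config, seed = config$seed)
}

#' Write a simulated assembly and its truth tables to disk
#'
#' Writes the FASTA, truth BED files (telomeres, centromeres), a truth
#' GFF3 (LTR elements with ID and family attributes; genes) and a JSON
#' manifest holding the seed and a digest of the config.
#'
#' @param sim a \code{\link{SimulatedAssembly}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        fasta = file.path(dir, "assembly.fa"),
        telomeres = file.path(dir, "telomeres_truth.bed"),
        centromeres = file.path(dir, "centromeres_truth.bed"),
        features = file.path(dir, "features_truth.gff3"),
        manifest = file.path(dir, "manifest.json"))
    writeGenome(simGenome(sim), paths["fasta"])
    tr <- simTruth(sim)
    telo <- tr$telomeres
    names(telo) <- paste0("telomere_", seqnames(telo), "_", telo$chromEnd)
    rtracklayer::export(telo, paths[["telomeres"]], format = "BED")
    cen <- tr$centromeres
    if (length(cen)) names(cen) <- paste0("centromere_", seqnames(cen))
    rtracklayer::export(cen, paths[["centromeres"]], format = "BED")
    feats <- c(
        local({ g <- tr$ltr
                if (length(g)) { g$type <- "LTR_retrotransposon"
                                 g$ID <- g$id }
                g }),
        local({ g <- tr$genes
                if (length(g)) { g$type <- "gene"; g$ID <- g$id }
                g }))
    rtracklayer::export(feats, paths[["features"]], format = "GFF3")
    manifest <- list(seed = sim@seed,
                     configDigest = digestConfig(sim@config),
                     chromosomes = names(simGenome(sim)),
                     totalLength = sum(as.numeric(width(simGenome(sim)))))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(paths)
}

## stable digest of a config list (serialization md5)
digestConfig <- function(config) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(config, tf, version = 2)
    unname(tools::md5sum(tf))
}
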