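## Format I/O, interval algebra, windowed tracks and summary statistics.
## FASTA via Biostrings, GFF3/BED via rtracklayer; coordinates are GRanges
## 1-based closed throughout.

#' Read a genome assembly from FASTA
#'
#' Reads a multi-record FASTA into a named DNAStringSet. Sequences are
#' uppercased and any character outside A/C/G/T/N (IUPAC ambiguity codes
#' included) is normalized to N with a warning, since all downstream
#' scans are defined over the 5-letter alphabet. Duplicate headers are a
#' hard error.
#'
#' @param path path to a FASTA file.
#' @return a DNAStringSet named by the first whitespace-delimited token
#'   of each header, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), tf)
#' readGenome(tf)
#' @export
readGenome <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    if (file.size(path) == 0)
        stop("FASTA file is empty: ", path)
    dss <- readDNAStringSet(path)
    if (length(dss) == 0)
        stop("no sequences in FASTA file: ", path)
    names(dss) <- sub("\\s.*$", "", names(dss))
    dup <- names(dss)[duplicated(names(dss))]
    if (length(dup))
        stop("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", "))
    ## normalize to the {A,C,G,T,N} alphabet
    chr <- toupper(as.character(dss))
    if (any(grepl("[^ACGTN]", chr))) {
        warning("characters outside {A,C,G,T,N} normalized to N")
        chr <- gsub("[^ACGTN]", "N", chr)
    }
    out <- DNAStringSet(chr)
    names(out) <- names(dss)
    out
}

#' Write a genome assembly to FASTA
#'
#' @param genome a named DNAStringSet.
#' @param path output path; records are wrapped at 80 columns.
#' @return invisibly, \code{path}.
#' @export
writeGenome <- function(genome, path) {
    writeXStringSet(genome, path, width = 80L)
    invisible(path)
}

#' Read features from GFF3 or BED
#'
#' Thin wrapper over \code{rtracklayer::import} returning a GRanges in
#' 1-based closed coordinates (rtracklayer performs the BED half-open to
#' 1-based conversion). GFF3 \code{ID} attributes are kept as the
#' \code{id} metadata column. If \code{genome} is supplied, features
#' extending beyond chromosome ends (or on unknown chromosomes) are a
#' hard error naming the offending records.
#'
#' @param path path to the annotation file.
#' @param format "gff3" or "bed" (default guessed from the extension).
#' @param genome optional DNAStringSet used to validate coordinates.
#' @return a GRanges with metadata columns \code{type} and \code{id}
#'   (where available).
#' @export
readFeatures <- function(path, format = c("auto", "gff3", "bed"),
                         genome = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "gff3"
    }
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    gr <- rtracklayer::import(path, format = format)
    mc <- mcols(gr)
    if (format == "gff3") {
        id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
        type <- if ("type" %in% names(mc)) as.character(mc$type) else NA_character_
    } else {
        id <- if ("name" %in% names(mc)) as.character(mc$name) else NA_character_
        type <- rep(NA_character_, length(gr))
    }
    keep <- mc[, intersect(c("source", "score", "family"), names(mc)),
               drop = FALSE]
    mcols(gr) <- cbind(DataFrame(type = type, id = id), keep)
    if (!is.null(genome)) {
        lens <- setNames(width(genome), names(genome))
        bad <- !(as.character(seqnames(gr)) %in% names(lens)) |
            end(gr) > lens[as.character(seqnames(gr))] | start(gr) < 1L
        if (any(bad))
            stop("feature(s) out of chromosome bounds: ",
                 paste(utils::head(paste0(seqnames(gr)[bad], ":",
                       start(gr)[bad], "-", end(gr)[bad]), 5), collapse = ", "))
    }
    gr
}

#' Assembly summary statistics
#'
#' Computes total length, N50/L50 and length extremes. N50 follows the
#' cumulative-half definition: the length of the sequence at which the
#' cumulative sum of descending-sorted lengths first reaches at least
#' half the total. Ties resolve to the shared crossing length.
#'
#' @param x a DNAStringSet, or a numeric vector of sequence lengths.
#' @return an \code{\link{AssemblyStats}} object.
#' @examples
#' assemblyStats(c(10, 20, 30, 40))
#' @export
setGeneric("assemblyStats", function(x) standardGeneric("assemblyStats"))

#' @rdname assemblyStats
#' @export
setMethod("assemblyStats", "numeric", function(x) {
    if (length(x) == 0)
        stop("empty assembly: no sequence lengths")
    if (any(x <= 0))
        stop("sequence lengths must be positive")
    len <- sort(as.numeric(x), decreasing = TRUE)
    total <- sum(len)
    cs <- cumsum(len)
    i <- which(cs >= total / 2)[1]
    new("AssemblyStats",
        totalLength = total,
        nSequences  = length(len),
        n50         = len[i],
        l50         = as.integer(i),
        longest     = len[1],
        shortest    = len[length(len)])
})

#' @rdname assemblyStats
#' @export
setMethod("assemblyStats", "DNAStringSet", function(x) {
    assemblyStats(as.numeric(width(x)))
})

#' Windowed GC-content and gene-density tracks
#'
#' Tiles each chromosome into fixed windows (the last window may be
#' partial) and reports per-window GC fraction and, if gene features are
#' supplied, gene counts. GC is (G+C)/(A+C+G+T): N bases are excluded
#' from the denominator, and an all-N window yields NA. A gene is counted
#' in the single window containing its start position by default, or in
#' every window it overlaps with \code{geneRule = "overlap"}.
#'
#' @param genome a named DNAStringSet.
#' @param genes optional GRanges of gene features.
#' @param windowSize window width in bases (default 500 kb).
#' @param geneRule "start" (default) or "overlap".
#' @return a data.frame with columns chrom, windowStart, windowEnd
#'   (1-based closed), gc and (when genes are given) geneCount.
#' @export
windowTracks <- function(genome, genes = NULL, windowSize = 500000L,
                         geneRule = c("start", "overlap")) {
    geneRule <- match.arg(geneRule)
    if (windowSize <= 0) stop("windowSize must be > 0")
    out <- lapply(names(genome), function(nm) {
        L <- width(genome)[match(nm, names(genome))]
        starts <- seq.int(1L, L, by = windowSize)
        ends <- pmin(starts + windowSize - 1L, L)
        v <- Views(genome[[nm]], start = starts, end = ends)
        freq <- letterFrequency(v, c("G", "C", "A", "T"))
        denom <- rowSums(freq)
        gc <- ifelse(denom == 0, NA_real_, (freq[, "G"] + freq[, "C"]) / denom)
        df <- data.frame(chrom = nm, windowStart = starts, windowEnd = ends,
                         gc = gc)
        if (!is.null(genes)) {
            g <- genes[as.character(seqnames(genes)) == nm]
            win <- GRanges(nm, IRanges(starts, ends))
            gq <- if (geneRule == "start")
                GRanges(nm, IRanges(start(g), width = 1L)) else granges(g)
            df$geneCount <- GenomicRanges::countOverlaps(win, gq)
        }
        df
    })
    do.call(rbind, out)
}

#' Complement of an interval set over a genome
#'
#' Returns the intervals that, together with the merged input, tile each
#' chromosome exactly: the noncentromeric partition is obtained by
#' subtracting the merged centromeric intervals from the whole-genome
#' intervals. Total returned length equals genome length minus merged
#' input length, to the base.
#'
#' @param genome a named DNAStringSet (or a named numeric vector of
#'   chromosome lengths).
#' @param features GRanges to complement (may be empty).
#' @return a GRanges covering the complement.
#' @export
complementPartition <- function(genome, features) {
    lens <- if (is.numeric(genome)) genome else setNames(width(genome), names(genome))
    whole <- GRanges(names(lens), IRanges(1L, as.integer(lens)))
    if (length(features) == 0)
        return(whole)
    merged <- reduce(granges(features), ignore.strand = TRUE)
    GenomicRanges::setdiff(whole, merged, ignore.strand = TRUE)
}

#' Summary of an interval set (syntenic-block style)
#'
#' Block-size statistics over a feature set: count, total span, mean and
#' median width, and per-strand tallies.
#'
#' @param features a non-empty GRanges.
#' @return a list with nBlocks, totalSpan, meanSize, medianSize, nPlus,
#'   nMinus.
#' @export
intervalSummary <- function(features) {
    if (length(features) == 0)
        stop("empty feature set")
    w <- as.numeric(width(features))
    s <- as.character(strand(features))
    list(
        nBlocks    = length(features),
        totalSpan  = sum(w),
        meanSize   = mean(w),
        medianSize = median(w),
        nPlus      = sum(s == "+"),
        nMinus     = sum(s == "-")
    )
}

#' Percentage share per category
#'
#' Converts a named count vector into percentage shares reported to one
#' decimal (100 * count / total).
#'
#' @param counts named non-negative numeric with positive sum.
#' @return named numeric of shares rounded to one decimal.
#' @examples
#' categoryShare(c(BP = 96, MF = 66, CC = 51))
#' @export
categoryShare <- function(counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    total <- sum(counts)
    if (total <= 0) stop("all counts are zero")
    round(100 * counts / total, 1)
}
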