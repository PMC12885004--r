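## Genome-wide satellite-array discovery and centromere calling.
## Sliding-window period detection seeds candidate periods from the
## distances between reoccurring 13-mers (avoiding an O(window^2) scan),
## scores each candidate by the fraction of positions matching at lag p,
## and refines merged hit regions to base-resolution array spans.

## integer codes 0..3 for A/C/G/T, NA otherwise
.codeMap <- local({
    m <- rep(NA_integer_, 128L)
    m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
    m[utf8ToInt("G")] <- 2L; m[utf8ToInt("T")] <- 3L
    m
})

.seqCodes <- function(s) .codeMap[utf8ToInt(s)]

## centered rolling mean with partial edges
.rollMean <- function(x, half) {
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## rolling k-mer ids (base-4 polynomial, exact in doubles for k <= 13)
.kmerIds <- function(codes, k = 13L) {
    n <- length(codes)
    if (n < k) return(numeric(0))
    id <- as.numeric(codes[seq_len(n - k + 1L)])
    for (j in 2:k)
        id <- id * 4 + codes[j:(n - k + j)]
    id
}

## candidate periods in a window: distances between successive
## occurrences of identical 13-mers, restricted to [minPeriod, maxPeriod]
.candidatePeriods <- function(km, minPeriod, maxPeriod, maxCandidates = 8L) {
    ok <- !is.na(km)
    pos <- which(ok)
    if (length(pos) < 2L) return(integer(0))
    kk <- km[pos]
    o <- order(kk, pos)
    d <- diff(pos[o])
    same <- diff(kk[o]) == 0
    per <- d[same & d >= minPeriod & d <= maxPeriod]
    if (!length(per)) return(integer(0))
    tab <- sort(table(per), decreasing = TRUE)
    as.integer(names(tab))[seq_len(min(length(tab), maxCandidates))]
}

#' Find satellite-scale tandem arrays genome-wide
#'
#' Slides a window along each chromosome; within each window, candidate
#' periods are seeded from the distances between reoccurring 13-mers and
#' the period maximizing the fraction of positions with
#' \code{seq[i] == seq[i + p]} is retained when that fraction reaches
#' \code{minFraction}. Overlapping window hits are merged and each merged
#' region is refined to base resolution: positions whose rolling
#' period-length match density stays above 0.5 define the array, giving
#' span recovery within about one monomer of a planted array. Arrays
#' shorter than \code{minCopies} monomers are dropped.
#'
#' @param genome a named DNAStringSet.
#' @param window sliding window width in bases (default 10,000).
#' @param step window step (default window / 2).
#' @param minPeriod,maxPeriod monomer period range searched (default
#'   50-2,000).
#' @param minCopies minimum monomer copies per reported array (default 5).
#' @param minFraction window-level match-fraction threshold (default 0.5).
#' @return a GRanges of arrays with metadata columns \code{period},
#'   \code{copies}, \code{purity}, \code{monomer} (canonical form of the
#'   repeat unit read at the array start).
#' @export
findTandemArrays <- function(genome, window = 10000L, step = window %/% 2L,
                             minPeriod = 50L, maxPeriod = 2000L,
                             minCopies = 5L, minFraction = 0.5) {
    if (maxPeriod >= window)
        stop("maxPeriod must be smaller than the window")
    allRows <- list()
    for (nm in names(genome)) {
        s <- as.character(genome[[nm]])
        L <- nchar(s)
        codes <- .seqCodes(s)
        km <- .kmerIds(codes, 13L)
        starts <- unique(c(seq.int(1L, max(1L, L - window + 1L), by = step),
                           max(1L, L - window + 1L)))
        ## window-level hits: (start, end, period)
        hs <- integer(0); he <- integer(0); hp <- integer(0)
        for (a in starts) {
            b <- min(a + window - 1L, L)
            if (b - a + 1L <= maxPeriod) next
            cand <- .candidatePeriods(km[a:min(b - 12L, length(km))],
                                      minPeriod, maxPeriod)
            if (!length(cand)) next
            wcodes <- codes[a:b]
            nW <- length(wcodes)
            bestP <- 0L; bestF <- 0
            for (p in cand) {
                cmp <- wcodes[seq_len(nW - p)] == wcodes[(p + 1L):nW]
                f <- mean(cmp, na.rm = TRUE)
                if (!is.na(f) && f > bestF) { bestF <- f; bestP <- p }
            }
            if (bestP > 0L && bestF >= minFraction) {
                hs <- c(hs, a); he <- c(he, b); hp <- c(hp, bestP)
            }
        }
        if (!length(hs)) next
        hits <- IRanges(hs, he)
        regions <- reduce(hits)
        ov <- findOverlaps(hits, regions)
        for (ri in seq_along(regions)) {
            mem <- queryHits(ov)[subjectHits(ov) == ri]
            ## dominant period among member windows
            p <- as.integer(names(sort(table(hp[mem]), decreasing = TRUE))[1])
            a <- max(1L, start(regions)[ri] - window)
            b <- min(L, end(regions)[ri] + window)
            sub <- codes[a:b]
            nS <- length(sub)
            if (nS <= p + 1L) next
            m <- sub[seq_len(nS - p)] == sub[(p + 1L):nS]
            m[is.na(m)] <- FALSE
            ## rolling match density over half a monomer each side
            above <- .rollMean(m, p %/% 2L) >= 0.5
            r <- rle(above)
            ends <- cumsum(r$lengths)
            rstarts <- ends - r$lengths + 1L
            for (j in which(r$values)) {
                spanStart <- a + rstarts[j] - 1L
                spanEnd <- a + ends[j] - 1L + p
                spanEnd <- min(spanEnd, L)
                span <- spanEnd - spanStart + 1L
                copies <- span %/% p
                if (copies < minCopies) next
                seg <- m[rstarts[j]:min(ends[j], length(m))]
                purity <- mean(seg)
                monomer <- substr(s, spanStart, spanStart + p - 1L)
                allRows[[length(allRows) + 1L]] <- data.frame(
                    chrom = nm, start = spanStart, end = spanEnd,
                    period = p, copies = copies, purity = purity,
                    monomer = monomer, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(allRows)) {
        gr <- GRanges()
        seqlevels(gr) <- names(genome)
        seqlengths(gr) <- setNames(width(genome), names(genome))
        return(gr)
    }
    df <- do.call(rbind, allRows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), period = df$period,
                  copies = df$copies, purity = df$purity,
                  monomer = df$monomer)
    ## collapse duplicate/overlapping reports of the same array (adjacent
    ## refinement regions can re-find the same span); metadata from the
    ## largest member
    red <- reduce(gr, ignore.strand = TRUE)
    ov <- findOverlaps(red, gr)
    keep <- vapply(seq_along(red), function(i) {
        mem <- subjectHits(ov)[queryHits(ov) == i]
        mem[which.max(width(gr)[mem])]
    }, 0L)
    out <- red
    mcols(out) <- mcols(gr)[keep, , drop = FALSE]
    out$copies <- width(out) %/% out$period
    out$purity <- gr$purity[keep]
    seqlevels(out) <- names(genome)
    seqlengths(out) <- setNames(width(genome), names(genome))
    out
}

#' Cluster tandem arrays by genomic proximity
#'
#' Single-linkage merge of arrays on the same chromosome whose gaps are
#' at most \code{clusterGap}. Coverage is the exact fraction of the
#' cluster span covered by member arrays; the dominant monomer is the
#' canonical form of the largest member's repeat unit.
#'
#' @param arrays a GRanges from \code{\link{findTandemArrays}}.
#' @param clusterGap maximum gap joining two arrays (default 100 kb).
#' @return a GRanges of clusters with metadata columns \code{nArrays},
#'   \code{arrayCoverage}, \code{dominantMonomer}, \code{dominantPeriod}.
#' @export
clusterArrays <- function(arrays, clusterGap = 100000L) {
    if (length(arrays) == 0) return(GRanges())
    cl <- reduce(arrays, min.gapwidth = clusterGap + 1L,
                 ignore.strand = TRUE)
    ov <- findOverlaps(cl, arrays)
    nArr <- integer(length(cl))
    cov <- numeric(length(cl))
    mono <- character(length(cl))
    per <- integer(length(cl))
    for (i in seq_along(cl)) {
        mem <- subjectHits(ov)[queryHits(ov) == i]
        nArr[i] <- length(mem)
        cov[i] <- sum(width(reduce(arrays[mem]))) / width(cl)[i]
        big <- mem[which.max(width(arrays)[mem])]
        mono[i] <- canonicalMotif(arrays$monomer[big])
        per[i] <- arrays$period[big]
    }
    cl$nArrays <- nArr
    cl$arrayCoverage <- cov
    cl$dominantMonomer <- mono
    cl$dominantPeriod <- per
    cl
}

#' Call one candidate centromere per chromosome
#'
#' From the array clusters of each chromosome, the cluster maximizing
#' span length * array coverage is called, provided its span is at least
#' \code{minExtent}; chromosomes with no qualifying cluster get no call
#' (monocentric by construction).
#'
#' @param genome a named DNAStringSet (supplies chromosome names and
#'   lengths).
#' @param clusters a GRanges from \code{\link{clusterArrays}}.
#' @param minExtent minimum called span in bases (default 20,000).
#' @return a \code{\link{CentromereCalls}} object.
#' @export
callCentromeres <- function(genome, clusters, minExtent = 20000L) {
    rows <- list()
    for (nm in names(genome)) {
        cc <- clusters[as.character(seqnames(clusters)) == nm]
        cc <- cc[width(cc) >= minExtent]
        if (!length(cc)) next
        score <- as.numeric(width(cc)) * cc$arrayCoverage
        best <- which.max(score)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = nm, start = start(cc)[best], end = end(cc)[best],
            monomer = cc$dominantMonomer[best],
            period = cc$dominantPeriod[best],
            arrayCoverage = cc$arrayCoverage[best], score = score[best],
            stringsAsFactors = FALSE)
    }
    params <- list(minExtent = minExtent)
    if (!length(rows))
        return(new("CentromereCalls", calls = GRanges(), params = params))
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), monomer = df$monomer,
                  period = df$period, arrayCoverage = df$arrayCoverage,
                  score = df$score, retroSupport = NA)
    seqlevels(gr) <- names(genome)
    seqlengths(gr) <- setNames(width(genome), names(genome))
    new("CentromereCalls", calls = gr, params = params)
}

#' Windowed retroelement density with a moving-average trend
#'
#' Per-window density of feature coverage (covered bases per window /
#' window size) along one chromosome, with a centered moving-average
#' trend (default 9 windows; partial averages at the chromosome ends).
#' The trend substitutes a LOESS fit for corroborating centromere calls:
#' a call has retroelement support when the global trend maximum lies
#' within the called span plus/minus one window.
#'
#' @param features GRanges of elements on one chromosome (e.g. the
#'   Gypsy-superfamily LTR elements).
#' @param chromLength chromosome length in bases.
#' @param window window width (default 500 kb).
#' @param trendWindows moving-average width in windows (default 9).
#' @return a data.frame with windowStart, windowEnd, density, trend.
#' @export
retroDensityProfile <- function(features, chromLength, window = 500000L,
                                trendWindows = 9L) {
    starts <- seq.int(1L, chromLength, by = window)
    ends <- pmin(starts + window - 1L, chromLength)
    win <- IRanges(starts, ends)
    if (length(features)) {
        fr <- reduce(ranges(features))
        ov <- findOverlaps(win, fr)
        covered <- numeric(length(win))
        if (length(ov)) {
            pint <- pintersect(win[queryHits(ov)], fr[subjectHits(ov)])
            agg <- tapply(width(pint), queryHits(ov), sum)
            covered[as.integer(names(agg))] <- agg
        }
    } else covered <- numeric(length(win))
    dens <- covered / as.numeric(width(win))
    half <- trendWindows %/% 2L
    nW <- length(dens)
    trend <- vapply(seq_len(nW), function(i)
        mean(dens[max(1L, i - half):min(nW, i + half)]), 0)
    data.frame(windowStart = starts, windowEnd = ends, density = dens,
               trend = trend)
}

#' Set retroelement support flags on centromere calls
#'
#' For each called chromosome, computes the \code{\link{retroDensityProfile}}
#' of the supplied retroelement features and flags the call supported
#' when the global trend maximum falls within the call span extended by
#' one window on each side.
#'
#' @param calls a \code{\link{CentromereCalls}}.
#' @param retroFeatures GRanges of retroelements (genome-wide).
#' @param genome a named DNAStringSet for chromosome lengths.
#' @param window,trendWindows passed to \code{\link{retroDensityProfile}}.
#' @return the calls with the \code{retroSupport} column filled.
#' @export
addRetroSupport <- function(calls, retroFeatures, genome,
                            window = 500000L, trendWindows = 9L) {
    gr <- granges(calls)
    if (!length(gr)) return(calls)
    supp <- logical(length(gr))
    for (i in seq_along(gr)) {
        nm <- as.character(seqnames(gr)[i])
        L <- width(genome)[match(nm, names(genome))]
        feats <- retroFeatures[as.character(seqnames(retroFeatures)) == nm]
        prof <- retroDensityProfile(feats, L, window, trendWindows)
        peak <- which.max(prof$trend)
        supp[i] <- prof$windowEnd[peak] >= start(gr)[i] - window &&
                   prof$windowStart[peak] <= end(gr)[i] + window
    }
    gr$retroSupport <- supp
    new("CentromereCalls", calls = gr,
        params = c(calls@params, list(retroWindow = window,
                                      trendWindows = trendWindows)))
}
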