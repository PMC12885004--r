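## Centromeric-enrichment statistics: per-domain occupied length and
## distinct-element counts in the centromeric vs noncentromeric
## partitions, one-tailed Fisher exact tests on both, and the
## occupancy-proportion report.

#' One-tailed Fisher exact test (enrichment)
#'
#' Upper-tail hypergeometric probability P(X >= a) for the 2x2 table
#' \code{(a, b; c, d)}, with X ~ Hypergeometric(N = a+b+c+d, K = a+b,
#' n = a+c). Log-probabilities are computed with \code{lgamma} and the
#' tail is summed from its largest term (log-sum-exp), which keeps the
#' result exact to at least ten significant digits for margins up to
#' 1e7. Degenerate tables (a zero margin) return p = 1 by convention so
#' sparse domains still appear in reports.
#'
#' @param a,b,c,d non-negative integer cells; \code{a} is the
#'   "centromeric and occupied" cell whose enrichment is tested.
#' @return the one-tailed p-value in (0, 1].
#' @examples
#' fisherOneTailed(5, 0, 0, 5)   # 1 / choose(10, 5)
#' @export
fisherOneTailed <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
        stop("cells must be non-negative integers")
    N <- a + b + c + d
    K <- a + b
    n <- a + c
    if (K == 0 || n == 0 || K == N || n == N)
        return(1)
    lo <- max(0, K + n - N)
    hi <- min(K, n)
    if (a <= lo) return(1)
    j <- a:hi
    lchoose2 <- function(nn, kk) lgamma(nn + 1) - lgamma(kk + 1) -
        lgamma(nn - kk + 1)
    lp <- lchoose2(K, j) + lchoose2(N - K, n - j) - lchoose2(N, n)
    m <- max(lp)
    p <- exp(m) * sum(exp(lp - m))
    min(p, 1)
}

#' Partition occupancy of domain-bearing elements
#'
#' For each domain label, computes the occupied length (exact base
#' overlap) and the count of distinct elements in the centromeric and
#' noncentromeric partitions. An element's length is apportioned to the
#' partitions by exact overlap, so per domain
#' \code{lenCen + lenNon} equals the element bases exactly; for the
#' count test, an element is assigned to the centromeric partition when
#' more than half of its length overlaps centromeres (majority rule),
#' and each element is counted once.
#'
#' @param elements GRanges of LTR elements with an \code{id} column.
#' @param domainMap named list from \code{\link{buildDomainMap}} (element
#'   id -> labels).
#' @param centromeres GRanges of non-overlapping centromeric spans.
#' @param genome a named DNAStringSet, or named numeric chromosome
#'   lengths.
#' @return a list: \code{perDomain} data.frame (label, lenCen, lenNon,
#'   countCen, countNon), \code{totals} list (cenLength, nonLength,
#'   genomeLength), \code{nCenElements}, \code{nNonElements}.
#' @export
partitionOccupancy <- function(elements, domainMap, centromeres, genome) {
    lens <- if (is.numeric(genome)) genome else
        setNames(as.numeric(width(genome)), names(genome))
    chrom <- as.character(seqnames(elements))
    if (length(elements) && !all(chrom %in% names(lens)))
        stop("element(s) on unknown chromosome: ",
             paste(unique(chrom[!chrom %in% names(lens)]), collapse = ", "))
    cen <- reduce(granges(centromeres), ignore.strand = TRUE)
    genomeLength <- sum(lens)
    cenLength <- sum(as.numeric(width(cen)))
    nonLength <- genomeLength - cenLength

    ## per-element centromeric overlap (bases)
    ovBases <- numeric(length(elements))
    if (length(elements) && length(cen)) {
        ov <- findOverlaps(granges(elements), cen, ignore.strand = TRUE)
        if (length(ov)) {
            pint <- pintersect(granges(elements)[queryHits(ov)],
                               cen[subjectHits(ov)])
            agg <- tapply(width(pint), queryHits(ov), sum)
            ovBases[as.integer(names(agg))] <- agg
        }
    }
    w <- as.numeric(width(elements))
    isCen <- ovBases > w / 2          # majority rule for the count test
    ids <- elements$id
    labels <- sort(unique(unlist(domainMap)))
    perDomain <- do.call(rbind, lapply(labels, function(lab) {
        has <- vapply(domainMap[ids], function(x) lab %in% x, TRUE)
        data.frame(label = lab,
                   lenCen = sum(ovBases[has]),
                   lenNon = sum(w[has] - ovBases[has]),
                   countCen = sum(has & isCen),
                   countNon = sum(has & !isCen),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(perDomain))
        perDomain <- data.frame(label = character(0), lenCen = numeric(0),
                                lenNon = numeric(0), countCen = integer(0),
                                countNon = integer(0))
    list(perDomain = perDomain,
         totals = list(cenLength = cenLength, nonLength = nonLength,
                       genomeLength = genomeLength),
         nCenElements = sum(isCen), nNonElements = sum(!isCen))
}

## round half up to whole blocks; raw > 0 reports at least one block
.toBlocks <- function(bases, unit) {
    b <- floor(bases / unit + 0.5)
    ifelse(bases > 0 & b < 1, 1, b)
}

#' Per-domain centromeric-enrichment table
#'
#' For each domain, a one-tailed Fisher exact test on occupied length
#' (cells converted to \code{lengthUnit}-sized blocks, rounded half up,
#' minimum one block for any nonzero occupancy — base-resolution cells
#' overstate the number of independent trials) and on distinct-element
#' counts (against all elements assigned to each partition). Rows are
#' sorted by the length-test p-value. Significance is raw p < alpha on
#' either test by default; Benjamini-Hochberg correction (applied per
#' test across domains) is available with \code{correction = "BH"}.
#'
#' @param occupancy result of \code{\link{partitionOccupancy}}.
#' @param lengthUnit block size in bases for the length test (default
#'   1000; use 1 for base resolution).
#' @param correction "none" (default) or "BH".
#' @param alpha significance level (default 0.05).
#' @return an \code{\link{EnrichmentResult}}; the table has one row per
#'   domain with lenCen, lenNon, countCen, countNon, propCen, propNon,
#'   pLength, pCount and significant.
#' @export
enrichmentTable <- function(occupancy, lengthUnit = 1000,
                            correction = c("none", "BH"), alpha = 0.05) {
    correction <- match.arg(correction)
    tot <- occupancy$totals
    if (tot$cenLength <= 0 || tot$nonLength <= 0)
        stop("zero-length partition")
    pd <- occupancy$perDomain
    cenBlocks <- max(round(tot$cenLength / lengthUnit), 1)
    nonBlocks <- max(round(tot$nonLength / lengthUnit), 1)
    rows <- lapply(seq_len(nrow(pd)), function(i) {
        aL <- min(.toBlocks(pd$lenCen[i], lengthUnit), cenBlocks)
        cL <- min(.toBlocks(pd$lenNon[i], lengthUnit), nonBlocks)
        pLength <- fisherOneTailed(aL, cenBlocks - aL, cL, nonBlocks - cL)
        pCount <- fisherOneTailed(
            pd$countCen[i], occupancy$nCenElements - pd$countCen[i],
            pd$countNon[i], occupancy$nNonElements - pd$countNon[i])
        data.frame(label = pd$label[i],
                   lenCen = pd$lenCen[i], lenNon = pd$lenNon[i],
                   countCen = pd$countCen[i], countNon = pd$countNon[i],
                   propCen = pd$lenCen[i] / tot$cenLength,
                   propNon = pd$lenNon[i] / tot$nonLength,
                   pLength = pLength, pCount = pCount,
                   stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(label = character(0), lenCen = numeric(0),
                   lenNon = numeric(0), countCen = integer(0),
                   countNon = integer(0), propCen = numeric(0),
                   propNon = numeric(0), pLength = numeric(0),
                   pCount = numeric(0))
    if (nrow(tab)) {
        pL <- tab$pLength; pC <- tab$pCount
        if (correction == "BH") {
            pL <- stats::p.adjust(pL, "BH")
            pC <- stats::p.adjust(pC, "BH")
        }
        tab$significant <- pL < alpha | pC < alpha
        tab <- tab[order(tab$pLength, tab$label), ]
        rownames(tab) <- NULL
    } else tab$significant <- logical(0)
    new("EnrichmentResult", table = tab, totals = tot,
        params = list(lengthUnit = lengthUnit, correction = correction,
                      alpha = alpha))
}

#' Top significantly enriched domains
#'
#' The k most significant rows with p below the configured alpha (on
#' either test, after the configured correction), each with its
#' occupancy proportions — the "proportion of regional length occupied"
#' report. Fewer than k rows are returned when fewer qualify.
#'
#' @param result an \code{\link{EnrichmentResult}}.
#' @param k maximum rows (default 6).
#' @return a data.frame (possibly zero rows, with a \code{note}
#'   attribute when nothing qualifies).
#' @export
topEnriched <- function(result, k = 6L) {
    tab <- enrichmentRows(result)
    sig <- tab[tab$significant, , drop = FALSE]
    out <- head(sig, k)
    rownames(out) <- NULL
    if (nrow(out) == 0)
        attr(out, "note") <- "no significantly enriched domains"
    out
}
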