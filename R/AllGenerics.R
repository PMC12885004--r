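## Accessor generics. `granges` is reused from GenomicRanges so calls,
## like other range-backed Bioconductor objects, expose their intervals
## through the familiar verb.

#' @rdname accessors
#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))

#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname accessors
#' @export
setGeneric("simConfigOf", function(x) standardGeneric("simConfigOf"))

#' @rdname accessors
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname accessors
#' @export
setGeneric("domainThresholds", function(x) standardGeneric("domainThresholds"))

#' @rdname accessors
#' @export
setGeneric("domainPeptides", function(x) standardGeneric("domainPeptides"))

#' @rdname accessors
#' @export
setGeneric("enrichmentRows", function(x) standardGeneric("enrichmentRows"))

#' @rdname accessors
#' @export
setGeneric("partitionTotals", function(x) standardGeneric("partitionTotals"))

#' Accessors for TeloCentR result objects
#'
#' \code{granges} returns the interval representation of telomere or
#' centromere calls; \code{simGenome}/\code{simTruth}/\code{simConfigOf}
#' unpack a \code{\link{SimulatedAssembly}};
#' \code{domainLabels}/\code{domainThresholds}/\code{domainPeptides}
#' access a \code{\link{DomainLibrary}}; \code{enrichmentRows} and
#' \code{partitionTotals} access an \code{\link{EnrichmentResult}}.
#'
#' @param x a TeloCentR S4 object.
#' @return See details; accessors return the underlying slot value.
#' @name accessors
#' @aliases granges,TelomereCalls-method granges,CentromereCalls-method
NULL

#' @rdname accessors
#' @export
setMethod("granges", "TelomereCalls",
    function(x, use.names = TRUE, use.mcols = FALSE, ...) x@calls)

#' @rdname accessors
#' @export
setMethod("granges", "CentromereCalls",
    function(x, use.names = TRUE, use.mcols = FALSE, ...) x@calls)

setMethod("simGenome", "SimulatedAssembly", function(x) x@genome)
setMethod("simTruth", "SimulatedAssembly", function(x) x@truth)
setMethod("simConfigOf", "SimulatedAssembly", function(x) x@config)

setMethod("domainLabels", "DomainLibrary", function(x) names(x@peptides))
setMethod("domainThresholds", "DomainLibrary", function(x) x@thresholds)
setMethod("domainPeptides", "DomainLibrary", function(x) x@peptides)

setMethod("enrichmentRows", "EnrichmentResult", function(x) x@table)
setMethod("partitionTotals", "EnrichmentResult", function(x) x@totals)

#' @export
setMethod("length", "TelomereCalls", function(x) length(x@calls))

#' @export
setMethod("length", "CentromereCalls", function(x) length(x@calls))

#' @export
setMethod("length", "DomainLibrary", function(x) length(x@peptides))

## ---- show methods -------------------------------------------------------

setMethod("show", "AssemblyStats", function(object) {
    cat("AssemblyStats\n")
    cat(sprintf("  sequences: %d  total: %s bp\n",
        object@nSequences, format(object@totalLength, big.mark = ",")))
    cat(sprintf("  N50: %s bp  (L50 = %d)\n",
        format(object@n50, big.mark = ","), object@l50))
    cat(sprintf("  longest: %s  shortest: %s\n",
        format(object@longest, big.mark = ","),
        format(object@shortest, big.mark = ",")))
})

setMethod("show", "SimulatedAssembly", function(object) {
    cat("SimulatedAssembly\n")
    cat(sprintf("  %d chromosomes, %s bp total (seed %d)\n",
        length(object@genome),
        format(sum(as.numeric(width(object@genome))), big.mark = ","),
        object@seed))
    tr <- object@truth
    cat(sprintf("  truth: %d telomeres, %d centromeres, %d LTR elements, %d genes\n",
        length(tr$telomeres), length(tr$centromeres),
        length(tr$ltr), length(tr$genes)))
})

setMethod("show", "TelomereCalls", function(object) {
    n <- length(object@calls)
    nc <- sum(object@calls$isCanonical)
    cat(sprintf("TelomereCalls: %d calls (%d canonical, %d noncanonical)\n",
        n, nc, n - nc))
    if (n) {
        df <- as.data.frame(object@calls)
        print(head(df[, c("seqnames", "start", "end", "chromEnd",
                          "motif", "copies", "isCanonical")], 10))
        if (n > 10) cat("  ...\n")
    }
})

setMethod("show", "CentromereCalls", function(object) {
    cat(sprintf("CentromereCalls: %d calls\n", length(object@calls)))
    if (length(object@calls)) {
        df <- as.data.frame(object@calls)
        keep <- intersect(c("seqnames", "start", "end", "width",
                            "arrayCoverage", "retroSupport"), names(df))
        print(head(df[, keep], 10))
    }
})

setMethod("show", "DomainLibrary", function(object) {
    cat(sprintf("DomainLibrary: %d families\n", length(object@peptides)))
    cat("  ", paste(names(object@peptides), collapse = ", "), "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult: %d domains (cen %s bp / non-cen %s bp)\n",
        nrow(object@table),
        format(object@totals$cenLength, big.mark = ","),
        format(object@totals$nonLength, big.mark = ",")))
    print(head(object@table, 8))
    if (nrow(object@table) > 8) cat("  ...\n")
})

setMethod("show", "CharacterizationReport", function(object) {
    cat("CharacterizationReport\n")
    show(object@stats)
    print(object@perChromosome)
})
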