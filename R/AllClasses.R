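## S4 containers for the package's central results.  Interval-valued
## results are carried as GRanges (1-based closed, the Bioconductor
## convention used throughout); the classes below wrap them together
## with the parameters that produced them.

#' AssemblyStats: summary statistics of a genome assembly
#'
#' Holds total length, sequence count, N50/L50 and the length extremes of
#' an assembly. N50 is the length of the sequence at which the cumulative
#' length of the descending-sorted sequences first reaches at least half
#' of the assembly total; L50 is the number of sequences needed to reach
#' it.
#'
#' @slot totalLength numeric(1) total assembly length in bases.
#' @slot nSequences integer(1) number of sequences.
#' @slot n50 numeric(1) N50 in bases.
#' @slot l50 integer(1) L50 count.
#' @slot longest numeric(1) longest sequence length.
#' @slot shortest numeric(1) shortest sequence length.
#'
#' @seealso \code{\link{assemblyStats}}
#' @exportClass AssemblyStats
setClass("AssemblyStats",
    representation(
        totalLength = "numeric",
        nSequences  = "integer",
        n50         = "numeric",
        l50         = "integer",
        longest     = "numeric",
        shortest    = "numeric"
    )
)

setValidity("AssemblyStats", function(object) {
    msg <- character()
    if (object@nSequences < 1L)
        msg <- c(msg, "nSequences must be >= 1")
    if (object@shortest > object@n50 || object@n50 > object@longest)
        msg <- c(msg, "N50 must lie between shortest and longest")
    if (object@totalLength < object@longest)
        msg <- c(msg, "totalLength must be >= longest")
    if (length(msg)) msg else TRUE
})

#' DomainLibrary: labelled peptide consensus library
#'
#' A set of protein-domain consensus peptides with REXdb-style family
#' labels (e.g. Athila, Tat, Phygy, Selgy, Bryco, SIRE) and a per-label
#' alignment score threshold used by \code{\link{scanDomains}}.
#'
#' @slot peptides AAStringSet of consensus peptides, named by label.
#' @slot thresholds named numeric of per-label score thresholds (> 0).
#'
#' @seealso \code{\link{readDomainLibrary}}, \code{\link{scanDomains}}
#' @exportClass DomainLibrary
setClass("DomainLibrary",
    representation(
        peptides   = "AAStringSet",
        thresholds = "numeric"
    )
)

setValidity("DomainLibrary", function(object) {
    msg <- character()
    nm <- names(object@peptides)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "peptide labels must be present and unique")
    if (length(object@thresholds) != length(object@peptides))
        msg <- c(msg, "one threshold per peptide required")
    if (!all(object@thresholds > 0))
        msg <- c(msg, "thresholds must be > 0")
    if (!identical(names(object@thresholds), nm))
        msg <- c(msg, "threshold names must match peptide labels")
    if (length(msg)) msg else TRUE
})

#' SimulatedAssembly: a synthetic genome with its truth tables
#'
#' The result of \code{\link{simulateAssembly}}: the generated sequences
#' plus the planted-feature truth (telomeres, centromeres, satellite
#' sub-arrays, LTR elements with family and domain labels, genes), the
#' configuration used and the seed.
#'
#' @slot genome DNAStringSet of chromosome sequences.
#' @slot truth named list of GRanges: \code{telomeres}, \code{centromeres},
#'   \code{satellites}, \code{ltr}, \code{genes}.
#' @slot config the \code{\link{simConfig}} list used.
#' @slot seed integer(1) RNG seed.
#'
#' @exportClass SimulatedAssembly
setClass("SimulatedAssembly",
    representation(
        genome = "DNAStringSet",
        truth  = "list",
        config = "list",
        seed   = "integer"
    )
)

setValidity("SimulatedAssembly", function(object) {
    need <- c("telomeres", "centromeres", "satellites", "ltr", "genes")
    msg <- character()
    if (!all(need %in% names(object@truth)))
        msg <- c(msg, paste("truth must contain:", paste(need, collapse = ", ")))
    if (is.null(names(object@genome)) || anyDuplicated(names(object@genome)))
        msg <- c(msg, "chromosome names must be present and unique")
    if (length(msg)) msg else TRUE
})

#' TelomereCalls: per-end telomere calls
#'
#' Wraps a GRanges of terminal tandem-array calls (at most one per
#' chromosome end) with the scan parameters. Metadata columns:
#' \code{chromEnd} ("left"/"right"), \code{motif} (forward-strand phase at
#' the array start), \code{canonicalMotif}, \code{copies}, \code{purity},
#' \code{isCanonical}.
#'
#' @slot calls GRanges of calls (1-based closed coordinates).
#' @slot params list of scan parameters.
#'
#' @seealso \code{\link{callTelomeres}}
#' @exportClass TelomereCalls
setClass("TelomereCalls",
    representation(calls = "GRanges", params = "list"))

#' CentromereCalls: per-chromosome centromere calls
#'
#' Wraps a GRanges with at most one call per chromosome. Metadata
#' columns: \code{monomer} (canonical form of the dominant satellite
#' monomer), \code{arrayCoverage}, \code{score}, and \code{retroSupport}
#' (NA until set by \code{\link{retroDensityProfile}} corroboration).
#'
#' @slot calls GRanges of calls (1-based closed coordinates).
#' @slot params list of caller parameters.
#'
#' @seealso \code{\link{callCentromeres}}
#' @exportClass CentromereCalls
setClass("CentromereCalls",
    representation(calls = "GRanges", params = "list"))

#' EnrichmentResult: per-domain centromeric-enrichment table
#'
#' One row per domain label with occupied length and distinct-element
#' counts in the centromeric and noncentromeric partitions, one-tailed
#' Fisher p-values on both, occupancy proportions and a significance
#' flag. Rows are sorted by the length-test p-value.
#'
#' @slot table data.frame of per-domain rows.
#' @slot totals list with \code{cenLength}, \code{nonLength},
#'   \code{genomeLength} (bases).
#' @slot params list (length unit, correction, alpha).
#'
#' @seealso \code{\link{enrichmentTable}}, \code{\link{topEnriched}}
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(table = "data.frame", totals = "list", params = "list"))

setValidity("EnrichmentResult", function(object) {
    tl <- object@totals
    if (!all(c("cenLength", "nonLength", "genomeLength") %in% names(tl)))
        return("totals must contain cenLength, nonLength, genomeLength")
    if (abs(tl$cenLength + tl$nonLength - tl$genomeLength) > 0.5)
        return("cenLength + nonLength must equal genomeLength")
    TRUE
})

#' CharacterizationReport: end-to-end per-chromosome report
#'
#' Mirrors a telomere/centromere characterization table: one row per
#' chromosome with length, left/right telomere copies and motifs, and
#' centromere coordinates (1-based closed), together with assembly
#' statistics, the enrichment result and a run manifest.
#'
#' @slot perChromosome data.frame, one row per chromosome.
#' @slot stats an \code{\link{AssemblyStats}} object.
#' @slot telomeres a \code{\link{TelomereCalls}} object.
#' @slot centromeres a \code{\link{CentromereCalls}} object.
#' @slot enrichment an \code{\link{EnrichmentResult}} or NULL.
#' @slot manifest list: seed, parameters, input checksums, timestamps.
#'
#' @seealso \code{\link{runPipeline}}
#' @exportClass CharacterizationReport
setClass("CharacterizationReport",
    representation(
        perChromosome = "data.frame",
        stats         = "AssemblyStats",
        telomeres     = "TelomereCalls",
        centromeres   = "CentromereCalls",
        enrichment    = "ANY",
        manifest      = "list"
    )
)
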