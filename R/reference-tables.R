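#' Published chromosome architecture of the Apopellia endiviifolia
#' telomere-to-telomere assembly
#'
#' The per-chromosome numbers reported for the A. endiviifolia T2T
#' assembly: chromosome lengths, telomere repeat counts at the left and
#' right ends with their motifs (the canonical plant motif CCCTAAA /
#' TTTAGGG at sixteen ends; the noncanonical motifs ACGCAGC at the left
#' end of chromosome 3 and TGCGTCG at the right end of chromosome 6), and
#' the centromere coordinates (1-based closed). These values serve both
#' as exact-arithmetic inputs (assembly size, N50, centromere lengths)
#' and as the template of \code{\link{simConfigScaled}} synthetic
#' fixtures.
#'
#' @return a data.frame with one row per chromosome: \code{name},
#'   \code{length}, \code{leftCopies}, \code{leftMotif},
#'   \code{rightCopies}, \code{rightMotif}, \code{cenStart},
#'   \code{cenEnd}.
#' @examples
#' tab <- apopelliaChromosomes()
#' sum(tab$length)                      # assembly size in bp
#' assemblyStats(tab$length)            # N50 of the nine chromosomes
#' @export
apopelliaChromosomes <- function() {
    data.frame(
        name = paste0("Ch", 1:9),
        length = c(529742643, 473504363, 468157909, 317755521, 310129949,
                   244886949, 236110306, 234121349, 100551284),
        leftCopies  = c(425, 352, 115, 408, 481, 419, 393, 428, 446),
        leftMotif   = c("CCCTAAA", "CCCTAAA", "ACGCAGC", "CCCTAAA",
                        "CCCTAAA", "CCCTAAA", "CCCTAAA", "CCCTAAA",
                        "CCCTAAA"),
        rightCopies = c(418, 422, 414, 402, 421, 176, 452, 403, 420),
        rightMotif  = c("TTTAGGG", "TTTAGGG", "TTTAGGG", "TTTAGGG",
                        "TTTAGGG", "TGCGTCG", "TTTAGGG", "TTTAGGG",
                        "TTTAGGG"),
        cenStart = c(359400001, 232800001, 446400001, 239340762, 37548478,
                     242160000, 189670000, 202730000, 89933334),
        cenEnd   = c(363400000, 237800000, 449400000, 241950761, 39527839,
                     244159999, 191669999, 204729999, 93766667),
        stringsAsFactors = FALSE
    )
}
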