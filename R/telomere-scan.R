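## Terminal tandem-repeat scanning: motif canonicalization, de novo
## period discovery in terminal windows, exact repeat counting, and
## per-end telomere calling. Scans compare integer-coded bases
## (utf8ToInt) so the inner loops are vectorized.

.rotations <- function(s) {
    n <- nchar(s)
    vapply(0:(n - 1L), function(i)
        paste0(substr(s, i + 1L, n), substr(s, 1L, i)), "")
}

#' Canonical form of a tandem-repeat motif
#'
#' Returns the lexicographically smallest string among all rotations of
#' the motif and all rotations of its reverse complement. This gives one
#' strand- and phase-independent name per repeat class: CCCTAAA and
#' TTTAGGG (the two strand readings of the canonical plant telomere
#' repeat) share the canonical form AAACCCT. Idempotent.
#'
#' @param motif character vector of DNA motifs over A/C/G/T.
#' @return character vector of canonical forms.
#' @examples
#' canonicalMotif(c("CCCTAAA", "TTTAGGG"))
#' @export
canonicalMotif <- function(motif) {
    vapply(motif, function(m) {
        if (nchar(m) == 0) stop("empty motif")
        if (grepl("[^ACGT]", m)) stop("motif must be over {A,C,G,T}: ", m)
        min(c(.rotations(m), .rotations(.revcomp(m))))
    }, "", USE.NAMES = FALSE)
}

#' Discover the dominant terminal tandem repeat in a window
#'
#' For each candidate period p in \code{minPeriod:maxPeriod}, positions i
#' with \code{seq[i] == seq[i + p]} are marked and maximal match runs
#' (runs separated by gaps of at most 2p are merged, to tolerate isolated
#' substitutions) are scored. The array maximizing copies * period,
#' subject to \code{copies >= minCopies} and \code{purity >= minPurity},
#' is returned; ties resolve to the smaller period. Absence of a
#' qualifying array returns NULL.
#'
#' @param window a character scalar, the terminal window sequence.
#' @param minPeriod,maxPeriod candidate period range (default 4-12).
#' @param minCopies minimum repeat copies to accept (default 20).
#' @param minPurity minimum fraction of period-matching bases (default 0.9).
#' @return NULL, or a list with \code{motif} (phase observed at the array
#'   start), \code{period}, \code{start} (1-based within the window),
#'   \code{span}, \code{copies} (floor of span / period) and \code{purity}.
#' @export
discoverTerminalMotif <- function(window, minPeriod = 4L, maxPeriod = 12L,
                                  minCopies = 20L, minPurity = 0.9) {
    n <- nchar(window)
    if (n < 2L * maxPeriod)
        stop("window shorter than twice the maximum period")
    x <- utf8ToInt(window)
    best <- NULL
    for (p in minPeriod:maxPeriod) {
        m <- x[seq_len(n - p)] == x[(p + 1L):n]
        r <- rle(m)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        ## seed on significant runs (>= one monomer of matches, i.e. two
        ## aligned copies); short background runs never seed and are only
        ## swallowed when bridging substitutions inside a real array
        ti <- which(r$values & r$lengths >= p)
        if (!length(ti)) next
        ## merge significant runs separated by gaps <= 2p
        rs <- starts[ti]; re <- ends[ti]
        merged_s <- rs[1]; merged_e <- re[1]
        if (length(ti) > 1) {
            for (j in 2:length(ti)) {
                if (rs[j] - merged_e[length(merged_e)] - 1L <= 2L * p) {
                    merged_e[length(merged_e)] <- re[j]
                } else {
                    merged_s <- c(merged_s, rs[j])
                    merged_e <- c(merged_e, re[j])
                }
            }
        }
        cm <- cumsum(m)
        for (j in seq_along(merged_s)) {
            a <- merged_s[j]; b <- merged_e[j]
            span <- b - a + 1L + p
            copies <- span %/% p
            if (copies < minCopies) next
            matches <- cm[b] - if (a > 1L) cm[a - 1L] else 0L
            purity <- matches / (span - p)
            if (purity < minPurity) next
            score <- copies * p
            if (is.null(best) || score > best$score ||
                (score == best$score && p < best$period)) {
                best <- list(motif = substr(window, a, a + p - 1L),
                             period = p, start = a, span = span,
                             copies = copies, purity = purity,
                             score = score)
            }
        }
    }
    if (is.null(best)) return(NULL)
    best$score <- NULL
    best
}

#' Count tandem repeat copies around an anchor
#'
#' Maximal bidirectional extension of \code{motif} from the unit starting
#' at \code{anchor}: a unit is accepted when its per-unit mismatch
#' fraction is at most \code{tolerance}; when \code{tolerance > 0}, up to
#' two consecutive over-tolerance units are bridged provided an
#' acceptable unit follows, so isolated substitutions inside a long array
#' do not truncate the count. Copies are whole units; the reported span
#' is copies * motif length.
#'
#' @param sequence a character scalar DNA sequence.
#' @param motif the repeat unit expected at \code{anchor}.
#' @param anchor 1-based start of one repeat unit.
#' @param tolerance maximum per-unit mismatch fraction (default 0).
#' @return a list with \code{copies}, \code{start}, \code{span},
#'   \code{purity} (copies = 0 when the anchor unit itself fails).
#' @export
countRepeats <- function(sequence, motif, anchor, tolerance = 0) {
    n <- nchar(sequence)
    k <- nchar(motif)
    if (anchor < 1L || anchor + k - 1L > n)
        stop("anchor out of range")
    x <- utf8ToInt(sequence)
    mot <- utf8ToInt(motif)
    allowed <- floor(tolerance * k)
    maxSkip <- if (tolerance > 0) 2L else 0L

    unitMM <- function(at) {
        if (at < 1L || at + k - 1L > n) return(NA_integer_)
        sum(x[at:(at + k - 1L)] != mot)
    }

    extend <- function(from, step) {
        ## returns c(nUnits, totalMM) of accepted units walking in `step`
        ## direction, not counting the anchor unit
        nUnits <- 0L; totalMM <- 0L
        at <- from
        repeat {
            mm <- unitMM(at)
            if (is.na(mm)) break
            if (mm <= allowed) {
                nUnits <- nUnits + 1L; totalMM <- totalMM + mm
                at <- at + step
            } else if (maxSkip > 0L) {
                ## bridge up to maxSkip bad units if a good one follows
                bridged <- FALSE
                for (s in seq_len(maxSkip)) {
                    mmAhead <- unitMM(at + s * step)
                    if (!is.na(mmAhead) && mmAhead <= allowed) {
                        badMM <- sum(vapply(seq_len(s) - 1L, function(q)
                            unitMM(at + q * step), 0L))
                        nUnits <- nUnits + s + 1L
                        totalMM <- totalMM + badMM + mmAhead
                        at <- at + (s + 1L) * step
                        bridged <- TRUE
                        break
                    }
                }
                if (!bridged) break
            } else break
        }
        c(nUnits, totalMM)
    }

    mm0 <- unitMM(anchor)
    if (is.na(mm0) || mm0 > allowed)
        return(list(copies = 0L, start = anchor, span = 0L, purity = NA_real_))
    right <- extend(anchor + k, k)
    left <- extend(anchor - k, -k)
    copies <- 1L + right[1] + left[1]
    totalMM <- mm0 + right[2] + left[2]
    start <- anchor - left[1] * k
    span <- copies * k
    list(copies = copies, start = start, span = span,
         purity = 1 - totalMM / span)
}

#' Call telomeres by scanning chromosome ends
#'
#' Scans the first and last \code{terminalWindow} bases of every
#' chromosome with \code{\link{discoverTerminalMotif}}, then refines each
#' discovery with \code{\link{countRepeats}} anchored at the discovered
#' array start. At most one call is made per chromosome end. Motifs are
#' reported in the phase observed on the forward strand at the array
#' start; \code{canonicalMotif} unifies strand and phase, and a call is
#' flagged canonical when its canonical form equals that of the plant
#' telomeric repeat CCCTAAA.
#'
#' @param genome a named DNAStringSet.
#' @param terminalWindow terminal scan width in bases (default 10,000).
#' @param minCopies,minPurity,minPeriod,maxPeriod passed to
#'   \code{\link{discoverTerminalMotif}}.
#' @param tolerance per-unit mismatch tolerance for
#'   \code{\link{countRepeats}} refinement (default 0, perfect units).
#' @return a \code{\link{TelomereCalls}} object.
#' @export
callTelomeres <- function(genome, terminalWindow = 10000L, minCopies = 20L,
                          minPurity = 0.9, minPeriod = 4L, maxPeriod = 12L,
                          tolerance = 0) {
    canonTelo <- canonicalMotif("CCCTAAA")
    rows <- list()
    for (nm in names(genome)) {
        s <- as.character(genome[[nm]])
        L <- nchar(s)
        w <- min(terminalWindow, L)
        for (side in c("left", "right")) {
            offset <- if (side == "left") 0L else L - w
            win <- substr(s, offset + 1L, offset + w)
            hit <- discoverTerminalMotif(win, minPeriod, maxPeriod,
                                         minCopies, minPurity)
            if (is.null(hit)) next
            anchor <- offset + hit$start
            motif <- substr(s, anchor, anchor + hit$period - 1L)
            cnt <- countRepeats(s, motif, anchor, tolerance)
            if (cnt$copies < minCopies) next
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = nm, start = cnt$start,
                end = cnt$start + cnt$span - 1L, chromEnd = side,
                motif = motif, canonicalMotif = canonicalMotif(motif),
                copies = cnt$copies, purity = cnt$purity,
                stringsAsFactors = FALSE)
        }
    }
    params <- list(terminalWindow = terminalWindow, minCopies = minCopies,
                   minPurity = minPurity, minPeriod = minPeriod,
                   maxPeriod = maxPeriod, tolerance = tolerance)
    if (!length(rows)) {
        return(new("TelomereCalls", calls = GRanges(), params = params))
    }
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                  chromEnd = df$chromEnd, motif = df$motif,
                  canonicalMotif = df$canonicalMotif, copies = df$copies,
                  purity = df$purity,
                  isCanonical = df$canonicalMotif == canonTelo)
    seqlevels(gr) <- names(genome)
    seqlengths(gr) <- setNames(width(genome), names(genome))
    new("TelomereCalls", calls = gr, params = params)
}

#' Tabulate telomere calls per chromosome
#'
#' One row per chromosome with left/right copies and motifs, mirroring a
#' published telomere table layout.
#'
#' @param calls a \code{\link{TelomereCalls}}.
#' @param chromNames optional chromosome order (default: seqlevels).
#' @return a data.frame.
#' @export
telomereTable <- function(calls, chromNames = NULL) {
    gr <- granges(calls)
    mc <- as.data.frame(gr)
    if (is.null(chromNames))
        chromNames <- GenomeInfoDb::seqlevels(gr)
    out <- data.frame(name = chromNames, leftCopies = NA_integer_,
                      leftMotif = NA_character_, rightCopies = NA_integer_,
                      rightMotif = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mc))) {
        r <- match(as.character(mc$seqnames[i]), out$name)
        if (mc$chromEnd[i] == "left") {
            out$leftCopies[r] <- mc$copies[i]
            out$leftMotif[r] <- mc$motif[i]
        } else {
            out$rightCopies[r] <- mc$copies[i]
            out$rightMotif[r] <- mc$motif[i]
        }
    }
    out
}
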