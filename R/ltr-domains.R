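## LTR element extraction, six-frame translation and protein-domain
## scanning against a labelled consensus-peptide library. The scan is
## local alignment (match +2, mismatch -1, affine gaps) of every
## stop-free translated segment against every consensus, vectorized per
## library entry through Biostrings::pairwiseAlignment.

#' Extract LTR element sequences from an annotation
#'
#' Slices each annotated element from the forward strand of its
#' chromosome (the strand is recorded, not applied, matching the
#' downstream six-frame translation which scans both strands anyway).
#' Features without an ID and spans outside chromosome bounds are hard
#' errors.
#'
#' @param genome a named DNAStringSet.
#' @param features GRanges (e.g. from \code{\link{readFeatures}}) with an
#'   \code{id} metadata column.
#' @param typeFilter optional value(s) of the \code{type} column to keep
#'   (e.g. "LTR_retrotransposon"); NULL keeps everything.
#' @return a GRanges with metadata columns \code{id}, \code{family} (if
#'   present) and \code{sequence} (character).
#' @export
extractElements <- function(genome, features, typeFilter = NULL) {
    gr <- features
    if (!is.null(typeFilter) && length(gr))
        gr <- gr[!is.na(gr$type) & gr$type %in% typeFilter]
    if (length(gr) == 0) {
        out <- GRanges()
        return(out)
    }
    ids <- gr$id
    if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
        stop("element(s) without an ID: ",
             paste(head(which(is.na(ids) | ids == ""), 5), collapse = ", "))
    if (anyDuplicated(ids))
        stop("duplicate element ID(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    lens <- setNames(width(genome), names(genome))
    chrom <- as.character(seqnames(gr))
    if (!all(chrom %in% names(lens)))
        stop("unknown chromosome(s): ",
             paste(unique(chrom[!chrom %in% names(lens)]), collapse = ", "))
    if (any(end(gr) > lens[chrom]) || any(start(gr) < 1L))
        stop("element span(s) out of bounds for ID(s): ",
             paste(ids[end(gr) > lens[chrom] | start(gr) < 1L], collapse = ", "))
    seqs <- vapply(seq_along(gr), function(i)
        as.character(subseq(genome[[chrom[i]]], start(gr)[i], end(gr)[i])),
        "")
    gr$sequence <- seqs
    gr
}

#' Six-frame translation with stop splitting
#'
#' Translates a DNA sequence in frames +1/+2/+3 of the forward strand and
#' -1/-2/-3 of the reverse complement under the standard genetic code,
#' drops trailing partial codons, splits each frame's peptide at stop
#' codons and discards segments shorter than \code{minOrf} residues.
#'
#' @param sequence a character scalar (or DNAString) of length >= 3.
#' @param minOrf minimum stop-free segment length in residues (default 30).
#' @return a named list of six character vectors ("+1", "+2", "+3", "-1",
#'   "-2", "-3"); each element additionally carries an integer attribute
#'   \code{"offsets"} with the residue offset of each segment in its
#'   frame translation (0-based), used to map hits back to coordinates.
#' @export
sixFrameTranslate <- function(sequence, minOrf = 30L) {
    s <- if (is(sequence, "DNAString")) sequence else DNAString(sequence)
    if (length(s) < 3L) stop("sequence shorter than one codon")
    ## fuzzy-codon handling is only needed when ambiguity codes are
    ## present (it is far slower, so take the fast path when possible)
    fuzzy <- sum(letterFrequency(s, "ACGT")) < length(s)
    tr <- if (fuzzy)
        function(x) translate(x, if.fuzzy.codon = "X", no.init.codon = TRUE)
    else function(x) translate(x, no.init.codon = TRUE)
    rc <- reverseComplement(s)
    out <- vector("list", 6L)
    names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
    for (i in 1:6) {
        src <- if (i <= 3) s else rc
        off <- (i - 1L) %% 3L
        n <- length(src) - off
        n <- n - n %% 3L
        if (n < 3L) {
            segs <- character(0)
            attr(segs, "offsets") <- integer(0)
            out[[i]] <- segs
            next
        }
        pep <- as.character(tr(subseq(src, off + 1L, off + n)))
        parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
        offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
        keep <- nchar(parts) >= minOrf
        segs <- parts[keep]
        attr(segs, "offsets") <- offs[keep]
        out[[i]] <- segs
    }
    out
}

#' Read a labelled domain-consensus library
#'
#' Parses a labelled peptide FASTA whose headers are
#' \code{"label threshold"}; the packaged synthetic library (ten
#' REXdb-style family labels with randomly generated consensus peptides,
#' for use with the simulator) is read when \code{path} is NULL.
#'
#' @param path path to the library FASTA, or NULL for the packaged
#'   synthetic library.
#' @return a \code{\link{DomainLibrary}}.
#' @export
readDomainLibrary <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "synthetic_domain_library.faa",
                            package = "TeloCentR", mustWork = TRUE)
    aa <- readAAStringSet(path)
    hdr <- strsplit(names(aa), "\\s+")
    labels <- vapply(hdr, `[`, "", 1L)
    thr <- suppressWarnings(as.numeric(vapply(hdr, `[`, "", 2L)))
    thr[is.na(thr)] <- 60
    names(aa) <- labels
    new("DomainLibrary", peptides = aa, thresholds = setNames(thr, labels))
}

## identity-scoring substitution matrix over the amino-acid alphabet
.aaIdentityMatrix <- function(match = 2, mismatch = -1) {
    letters <- strsplit("ARNDCQEGHILKMFPSTWYVBJZXUO*", "")[[1]]
    m <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- match
    m["X", ] <- mismatch; m[, "X"] <- mismatch
    m["*", ] <- mismatch; m[, "*"] <- mismatch
    m
}

#' Scan translated frames for domain hits
#'
#' Locally aligns every stop-free translated segment of every element
#' against every library consensus (match +2, mismatch -1, gap opening
#' -10, gap extension -1 per gapped position) and reports hits whose
#' score reaches \code{max(minScore, label threshold)}. Only the best
#' hit per (element, label) pair is retained: downstream enrichment
#' counts distinct elements, so within-element multiplicity is
#' irrelevant.
#'
#' Candidate segments are pre-screened by word seeding (a segment is
#' aligned against a consensus only when the two share at least one
#' exact \code{seedLength}-mer, the classic BLAST-style heuristic);
#' \code{seedLength = 0} disables the screen and aligns everything.
#'
#' @param frames a named list: element id -> result of
#'   \code{\link{sixFrameTranslate}}.
#' @param library a \code{\link{DomainLibrary}}.
#' @param minScore global score floor applied on top of the per-label
#'   thresholds (default 0).
#' @param seedLength word length of the seeding pre-screen (default 4).
#' @return a data.frame with columns elementId, label, frame, pepStart,
#'   pepEnd (1-based residue coordinates within the frame translation)
#'   and score; zero rows when nothing passes.
#' @export
scanDomains <- function(frames, library, minScore = 0, seedLength = 4L) {
    if (length(library) == 0) stop("empty domain library")
    ## flatten to a segment table
    segElem <- character(0); segFrame <- character(0)
    segOff <- integer(0); segPep <- character(0)
    for (eid in names(frames)) {
        fr <- frames[[eid]]
        for (fname in names(fr)) {
            segs <- fr[[fname]]
            if (!length(segs)) next
            offs <- attr(segs, "offsets")
            segElem <- c(segElem, rep(eid, length(segs)))
            segFrame <- c(segFrame, rep(fname, length(segs)))
            segOff <- c(segOff, offs)
            segPep <- c(segPep, as.character(segs))
        }
    }
    empty <- data.frame(elementId = character(0), label = character(0),
                        frame = character(0), pepStart = integer(0),
                        pepEnd = integer(0), score = numeric(0))
    if (!length(segPep)) return(empty)
    mat <- .aaIdentityMatrix()
    kmers <- function(s, k) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    }
    segK <- if (seedLength > 0) lapply(segPep, kmers, k = seedLength)
    hits <- list()
    for (lab in domainLabels(library)) {
        thr <- max(minScore, domainThresholds(library)[[lab]])
        pat <- domainPeptides(library)[[lab]]
        cand <- seq_along(segPep)
        if (seedLength > 0) {
            libK <- unique(kmers(as.character(pat), seedLength))
            cand <- which(vapply(segK, function(k) any(k %in% libK), TRUE))
            if (!length(cand)) next
        }
        aln <- pairwiseAlignment(AAStringSet(segPep[cand]), pat,
                                 type = "local", substitutionMatrix = mat,
                                 gapOpening = 10, gapExtension = 1)
        sc <- score(aln)
        pass <- which(sc >= thr)
        if (!length(pass)) next
        ok <- cand[pass]
        pstart <- start(pattern(aln))[pass]
        pend <- end(pattern(aln))[pass]
        hits[[lab]] <- data.frame(
            elementId = segElem[ok], label = lab, frame = segFrame[ok],
            pepStart = segOff[ok] + pstart, pepEnd = segOff[ok] + pend,
            score = sc[pass], stringsAsFactors = FALSE)
    }
    if (!length(hits)) return(empty)
    df <- do.call(rbind, hits)
    rownames(df) <- NULL
    ## best hit per (element, label)
    key <- paste(df$elementId, df$label, sep = "\r")
    df <- df[order(key, -df$score), ]
    df <- df[!duplicated(paste(df$elementId, df$label, sep = "\r")), ]
    rownames(df) <- NULL
    df
}

#' Map element IDs to their detected domain-label sets
#'
#' @param elementIds character vector of all element IDs (elements with
#'   no hits appear with empty sets).
#' @param hits data.frame from \code{\link{scanDomains}}.
#' @return a named list: element id -> character vector of labels.
#' @export
buildDomainMap <- function(elementIds, hits) {
    if (anyDuplicated(elementIds))
        stop("duplicate element IDs")
    bad <- setdiff(unique(hits$elementId), elementIds)
    if (length(bad))
        stop("hit(s) reference unknown element ID(s): ",
             paste(head(bad, 5), collapse = ", "))
    m <- setNames(vector("list", length(elementIds)), elementIds)
    for (eid in elementIds) m[[eid]] <- character(0)
    if (nrow(hits)) {
        sp <- split(hits$label, hits$elementId)
        for (eid in names(sp)) m[[eid]] <- sort(unique(sp[[eid]]))
    }
    m
}

#' Translate and scan a set of extracted elements
#'
#' Convenience composition: \code{\link{sixFrameTranslate}} on every
#' element sequence followed by \code{\link{scanDomains}}.
#'
#' @param elements GRanges from \code{\link{extractElements}} (with
#'   \code{id} and \code{sequence} columns).
#' @param library a \code{\link{DomainLibrary}}.
#' @param minOrf,minScore passed through.
#' @return list with \code{hits} (data.frame) and \code{map} (named list
#'   from \code{\link{buildDomainMap}}).
#' @export
scanElements <- function(elements, library, minOrf = 30L, minScore = 0) {
    frames <- lapply(setNames(seq_along(elements), elements$id),
                     function(i) sixFrameTranslate(elements$sequence[i],
                                                   minOrf))
    hits <- scanDomains(frames, library, minScore)
    list(hits = hits, map = buildDomainMap(elements$id, hits))
}
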